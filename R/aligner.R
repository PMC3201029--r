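# Build the integer encoding shared by all alignment entry points: a score
# lookup covering every residue code seen in the sequences. Standard
# residues use the 20x20 table; ambiguity codes (B, Z, X, U, O, J) use the
# matrix's ambiguity column when present, else score 0 against everything.
encode_for_alignment <- function(seq_a, seq_b, m) {
  if (!inherits(m, "similarity_matrix")) stop("m must be a similarity_matrix")
  ca <- chars(seq_a); cb <- chars(seq_b)
  bad <- setdiff(unique(c(ca, cb)), .AA_VALID)
  if (length(bad))
    stop("residue(s) with no defined score: ", paste(bad, collapse = ", "))
  letters <- c(.AA, intersect(.AA_AMBIG, unique(c(ca, cb))))
  n <- length(letters)
  S <- matrix(0L, n, n, dimnames = list(letters, letters))
  S[.AA, .AA] <- m$scores
  for (l in setdiff(letters, .AA)) {
    v <- if (!is.null(m$ambiguity) && l %in% names(m$ambiguity))
      m$ambiguity[[l]] else stats::setNames(integer(20L), .AA)
    S[.AA, l] <- v
    S[l, .AA] <- v
  }
  list(a = match(ca, letters) - 1L, b = match(cb, letters) - 1L, S = S,
       ca = ca, cb = cb)
}

cols_to_rows <- function(ca_chars, cb_chars, cols_a, cols_b) {
  row_a <- ifelse(cols_a > 0L, ca_chars[pmax(cols_a, 1L)], "-")
  row_b <- ifelse(cols_b > 0L, cb_chars[pmax(cols_b, 1L)], "-")
  list(row_a = paste(row_a, collapse = ""),
       row_b = paste(row_b, collapse = ""))
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Finds an optimal global alignment maximizing the sum of similarity
#' scores over residue-residue columns minus, for every gap run of length
#' m, the affine cost G(m) = alpha + (m-1)*beta. Uses the three-state Gotoh
#' recurrence with integer scores throughout. Traceback ties are broken
#' deterministically: diagonal, then gap-in-b (up), then gap-in-a (left),
#' evaluated from the terminal cell.
#'
#' @param seq_a,seq_b Ungapped residue strings (non-empty).
#' @param m A [similarity_matrix()].
#' @param g A [gap_penalties()].
#' @param free_end_gaps If `TRUE`, terminal gap runs cost nothing
#'   (semi-global alignment). Off by default: end gaps are penalized like
#'   internal gaps.
#' @param id_a,id_b Identifiers for the returned alignment.
#' @return List with elements `alignment` (a [pairwise_alignment()]) and
#'   `score` (integer).
#' @export
#' @examples
#' m <- read_matrix(bundled_matrix("BLOSUM62"))
#' global_align("HEAGAWGHEE", "PAWHEAE", m, gap_penalties(8, 2))$score
global_align <- function(seq_a, seq_b, m, g, free_end_gaps = FALSE,
                         id_a = "a", id_b = "b") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("sequences must be non-empty")
  enc <- encode_for_alignment(seq_a, seq_b, m)
  res <- .nw_align_cpp(enc$a, enc$b, enc$S, g$alpha, g$beta, free_end_gaps)
  rows <- cols_to_rows(enc$ca, enc$cb, res$cols_a, res$cols_b)
  list(alignment = pairwise_alignment(id_a, id_b, rows$row_a, rows$row_b),
       score = res$score)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Optimal local alignment under the same scoring objective as
#' [global_align()]. The score is never negative; when no cell scores
#' above zero the alignment is empty (`alignment = NULL`, `score = 0`).
#'
#' @inheritParams global_align
#' @return List with elements `alignment` (a [pairwise_alignment()] of the
#'   best-scoring segment pair, or `NULL` if empty) and `score`.
#' @export
local_align <- function(seq_a, seq_b, m, g, id_a = "a", id_b = "b") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!nchar(seq_a) || !nchar(seq_b)) stop("sequences must be non-empty")
  enc <- encode_for_alignment(seq_a, seq_b, m)
  res <- .sw_align_cpp(enc$a, enc$b, enc$S, g$alpha, g$beta)
  if (length(res$cols_a) == 0L || res$score == 0L)
    return(list(alignment = NULL, score = 0L))
  rows <- cols_to_rows(enc$ca, enc$cb, res$cols_a, res$cols_b)
  list(alignment = pairwise_alignment(id_a, id_b, rows$row_a, rows$row_b),
       score = res$score)
}

#' Score a fixed alignment
#'
#' Applies the exact objective maximized by [global_align()] to an existing
#' alignment: matrix scores summed over residue-residue columns minus
#' alpha + (m-1)*beta for every gap run of length m (each run pays the
#' initiation charge). Independent of the dynamic-programming code path, so
#' it doubles as a consistency check on returned alignments.
#'
#' @param aln A [pairwise_alignment()].
#' @param m A [similarity_matrix()].
#' @param g A [gap_penalties()].
#' @param free_end_gaps If `TRUE`, terminal gap runs cost nothing.
#' @return Integer score.
#' @export
score_alignment <- function(aln, m, g, free_end_gaps = FALSE) {
  ca <- chars(aln$row_a); cb <- chars(aln$row_b)
  enc <- encode_for_alignment(ungap(aln$row_a), ungap(aln$row_b), m)
  letters <- rownames(enc$S)
  rr <- ca != "-" & cb != "-"
  sub_score <- sum(enc$S[cbind(match(ca[rr], letters),
                               match(cb[rr], letters))])
  run_cost <- function(mask) {
    r <- rle(mask)
    lens <- r$lengths[r$values]
    if (free_end_gaps && length(lens)) {
      keep <- rep(TRUE, length(r$values))
      gi <- which(r$values)
      if (r$values[1L]) keep[gi[1L]] <- FALSE
      if (r$values[length(r$values)]) keep[gi[length(gi)]] <- FALSE
      lens <- r$lengths[r$values & keep]
    }
    sum(gap_cost(lens, g))
  }
  as.integer(sub_score - run_cost(ca == "-") - run_cost(cb == "-"))
}
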