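#' Count aligned residue pairs in a reference group
#'
#' Every residue-residue column across all of the group's alignments
#' contributes one unordered amino acid pair. Gap columns and columns
#' containing non-standard residue codes contribute nothing; the latter
#' are tallied in a skip log.
#'
#' @param group A [reference_group()].
#' @return An object of class `pair_counts`: `f` is the symmetric 20x20
#'   count table (entry (i,j) = (j,i) = count of the unordered pair), `n`
#'   the total number of counted pairs (the sum over the upper triangle
#'   including the diagonal), `skipped` the number of columns dropped for
#'   non-standard residues.
#' @export
count_pairs <- function(group) {
  f <- matrix(0L, 20L, 20L, dimnames = list(.AA, .AA))
  skipped <- 0L
  for (aln in group$alignments) {
    ca <- chars(aln$row_a); cb <- chars(aln$row_b)
    rr <- ca != "-" & cb != "-"
    ia <- aa_index(ca); ib <- aa_index(cb)
    ok <- rr & !is.na(ia) & !is.na(ib)
    skipped <- skipped + sum(rr & !ok)
    if (!any(ok)) next
    i <- pmin(ia[ok], ib[ok]); j <- pmax(ia[ok], ib[ok])
    tab <- tabulate((i - 1L) * 20L + j, nbins = 400L)
    add <- matrix(tab, 20L, 20L, byrow = TRUE)  # row = i, col = j (i <= j)
    f <- f + add + t(add) - diag(diag(add))
  }
  n <- sum(f[upper.tri(f, diag = TRUE)])
  if (n == 0L)
    stop("group '", group$name, "' has no countable residue-residue columns")
  structure(list(f = f, n = as.integer(n), skipped = skipped),
            class = "pair_counts")
}

#' Estimate the frequency model behind a group-specific matrix
#'
#' From unordered pair counts computes the observed pair frequencies
#' q(i,j) = f(i,j)/n, the single-residue frequencies
#' p(i) = q(i,i) + sum_{j != i} q(i,j)/2, the expected pair frequencies
#' e(i,i) = p(i)^2 and e(i,j) = 2 p(i) p(j) for i != j, and the blend
#' weight w = 1 - 10^(-n/blend_constant) that governs how much the
#' group-specific log-odds score contributes relative to the
#' general-purpose fallback score. w(0) = 0, w(8000) = 0.9 at the default
#' constant, and w increases strictly with n.
#'
#' @param counts A [count_pairs()] result.
#' @param blend_constant Denominator of the weight exponent (default 8000,
#'   chosen by grid search in the original work).
#' @return An object of class `frequency_model` with fields `q`, `p`, `e`,
#'   `w`, `n`. `q` and `e` are stored as full symmetric matrices whose
#'   off-diagonal entries are unordered-pair frequencies, so the sum over
#'   the upper triangle (with diagonal) is 1.
#' @export
estimate_frequencies <- function(counts, blend_constant = 8000) {
  if (!inherits(counts, "pair_counts")) stop("counts must be pair_counts")
  n <- counts$n
  if (n < 1L) stop("cannot estimate frequencies from zero pairs")
  q <- counts$f / n
  p <- diag(q) + (rowSums(q) - diag(q)) / 2
  e <- 2 * outer(p, p)
  diag(e) <- p * p
  w <- 1 - 10^(-n / blend_constant)
  structure(list(q = q, p = p, e = e, w = w, n = n),
            class = "frequency_model")
}

#' Weight of the group-specific score in the blend
#' @param n Total number of aligned residue pairs.
#' @param blend_constant Default 8000.
#' @return w = 1 - 10^(-n/blend_constant), in [0, 1).
#' @export
blend_weight <- function(n, blend_constant = 8000) 1 - 10^(-n / blend_constant)

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Closed-form log-odds matrix of a joint pair distribution
#'
#' For a known symmetric joint substitution distribution (full-matrix sum
#' 1), returns round(2*log2(P(i,j)/e(i,j))) where P is the unordered-pair
#' probability (2*J(i,j) off-diagonal, J(i,i) on it) and e the expected
#' frequency under the marginals. This is the infinite-data limit of
#' [derive_matrix()] with w = 1 and serves as the derivation oracle in the
#' synthetic benchmarks.
#'
#' @param joint Symmetric non-negative 20x20 matrix summing to 1.
#' @return 20x20 numeric matrix of (unrounded) log-odds scores; cells with
#'   zero expected frequency are `NA`.
#' @export
log_odds_from_joint <- function(joint) {
  if (!isTRUE(all.equal(sum(joint), 1, tolerance = 1e-8)))
    stop("joint must sum to 1")
  P <- 2 * joint
  diag(P) <- diag(joint)
  p <- rowSums(joint)
  e <- 2 * outer(p, p)
  diag(e) <- p * p
  out <- matrix(NA_real_, 20L, 20L, dimnames = dimnames(joint))
  ok <- e > 0
  out[ok] <- 2 * log2(P[ok] / e[ok])
  out
}

#' Derive a group-specific similarity matrix from pair counts
#'
#' Each element is the weighted combination of the group-specific half-bit
#' log-odds score and the general-purpose fallback score:
#' `s(i,j) = round(w * 2*log2(q~(i,j)/e(i,j)) + (1-w) * v(i,j))`, with
#' `w = 1 - 10^(-n/blend_constant)`. As the number of observed pairs grows
#' the group-specific term dominates; tiny groups reproduce the fallback.
#'
#' Zero observed counts would make the logarithm undefined, so the observed
#' frequency is smoothed with background-proportional pseudocounts,
#' `q~(i,j) = (f(i,j) + mass * e(i,j)) / (n + mass)`; the smoothing
#' preserves the unit sum and vanishes as n grows. Cells whose expected
#' frequency is exactly zero (a residue never seen in the group) take the
#' fallback score verbatim. Scores are rounded to the nearest integer,
#' ties away from zero.
#'
#' @param counts A [count_pairs()] result.
#' @param fallback General-purpose [similarity_matrix()] supplying v(i,j).
#' @param pseudocount_mass Total pseudocount mass (default 1).
#' @param blend_constant Weight constant (default 8000).
#' @param eq1 `"score-blend"` (default): convex combination of the two
#'   scores. `"frequency-blend"`: blend in frequency space before the
#'   logarithm, `2*log2((w*q~ + (1-w)*e*2^(v/2)) / e)` — exposed for
#'   sensitivity checks.
#' @param name,source Metadata for the derived matrix.
#' @return A [similarity_matrix()].
#' @export
derive_matrix_from_counts <- function(counts, fallback,
                                      pseudocount_mass = 1,
                                      blend_constant = 8000,
                                      eq1 = c("score-blend",
                                              "frequency-blend"),
                                      name = "derived",
                                      source = "family-specific") {
  eq1 <- match.arg(eq1)
  if (!inherits(fallback, "similarity_matrix"))
    stop("fallback similarity matrix is missing or invalid")
  fm <- estimate_frequencies(counts, blend_constant)
  v <- fallback$scores
  qs <- (counts$f + pseudocount_mass * fm$e) / (fm$n + pseudocount_mass)
  s <- matrix(NA_real_, 20L, 20L, dimnames = list(.AA, .AA))
  ok <- fm$e > 0
  if (eq1 == "score-blend") {
    group_score <- 2 * log2(qs[ok] / fm$e[ok])
    s[ok] <- fm$w * group_score + (1 - fm$w) * v[ok]
  } else {
    qb <- fm$w * qs[ok] + (1 - fm$w) * fm$e[ok] * 2^(v[ok] / 2)
    s[ok] <- 2 * log2(qb / fm$e[ok])
  }
  s[!ok] <- v[!ok]
  similarity_matrix(round_half_away(s), name = name, source = source)
}

#' Derive a group-specific similarity matrix from a reference group
#'
#' Counts aligned residue pairs in the group's reference alignments and
#' applies [derive_matrix_from_counts()]. By default only groups with at
#' least 10 reference alignments are accepted; smaller groups do not carry
#' enough observed substitutions (the floor can be overridden, e.g. for
#' training splits inside cross-validation).
#'
#' @param group A [reference_group()].
#' @param fallback General-purpose [similarity_matrix()].
#' @param pseudocount_mass,blend_constant,eq1 See
#'   [derive_matrix_from_counts()].
#' @param min_alignments Eligibility floor (default 10).
#' @return A [similarity_matrix()] named after the group, tagged
#'   `"fold-specific"` for TWI groups and `"family-specific"` otherwise.
#' @export
#' @examples
#' aln <- pairwise_alignment("s1", "s2", "ACDE", "ACDE")
#' grp <- reference_group("toy", rep(list(aln), 10))
#' fb <- read_matrix(bundled_matrix("BLOSUM62"))
#' derive_matrix(grp, fb)
derive_matrix <- function(group, fallback, pseudocount_mass = 1,
                          blend_constant = 8000,
                          eq1 = c("score-blend", "frequency-blend"),
                          min_alignments = 10L) {
  if (!is_derivation_eligible(group, min_alignments))
    stop("group '", group$name, "' has ", length(group$alignments),
         " reference alignments; at least ", min_alignments,
         " are required for matrix derivation")
  src <- if (identical(group$subset_tag, "TWI")) "fold-specific"
         else "family-specific"
  derive_matrix_from_counts(count_pairs(group), fallback,
                            pseudocount_mass = pseudocount_mass,
                            blend_constant = blend_constant,
                            eq1 = match.arg(eq1),
                            name = group$name, source = src)
}
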