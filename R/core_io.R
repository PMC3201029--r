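#' Construct a pairwise alignment
#'
#' Two equal-length gapped residue strings plus identifiers. Both reference
#' alignments (from structural superposition or simulation) and test
#' alignments (from the aligner) use this container.
#'
#' @param id_a,id_b Sequence identifiers.
#' @param row_a,row_b Equal-length gapped residue strings; `-` is the gap.
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(id_a, id_b, row_a, row_b) {
  row_a <- toupper(row_a); row_b <- toupper(row_b)
  if (nchar(row_a) != nchar(row_b))
    stop("alignment rows have unequal lengths (", nchar(row_a), " vs ",
         nchar(row_b), ") for '", id_a, "'/'", id_b, "'")
  if (nchar(row_a) == 0L) stop("alignment is empty")
  ca <- chars(row_a); cb <- chars(row_b)
  allgap <- which(ca == "-" & cb == "-")
  if (length(allgap) > 0L)
    stop("alignment '", id_a, "'/'", id_b, "' has all-gap column(s) at ",
         paste(utils::head(allgap, 5L), collapse = ", "))
  bad <- setdiff(unique(c(ca, cb)), c(.AA_VALID, "-"))
  if (length(bad) > 0L)
    stop("invalid residue code(s) in alignment: ",
         paste(bad, collapse = ", "))
  structure(list(id_a = id_a, id_b = id_b, row_a = row_a, row_b = row_b),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment:", x$id_a, "/", x$id_b,
      "(", nchar(x$row_a), "columns )\n")
  invisible(x)
}

#' Alignment length in columns
#' @param aln A [pairwise_alignment()].
#' @return Integer number of columns.
#' @export
alignment_length <- function(aln) nchar(aln$row_a)

#' Ungapped sequences underlying an alignment
#' @param aln A [pairwise_alignment()].
#' @return Named character vector of the two ungapped sequences.
#' @export
aligned_sequences <- function(aln) {
  out <- c(ungap(aln$row_a), ungap(aln$row_b))
  names(out) <- c(aln$id_a, aln$id_b)
  out
}

#' Construct affine gap penalties
#'
#' Positive magnitudes of the affine gap cost G(m) = alpha + (m-1)*beta for
#' a gap run of length m: a run of length 1 costs `alpha`, each additional
#' gapped position costs `beta`.
#'
#' @param alpha Gap initiation magnitude (positive integer).
#' @param beta Gap extension magnitude (positive integer).
#' @return An object of class `gap_penalties`.
#' @export
#' @examples
#' gap_penalties(15, 1)   # the default general-purpose combination
gap_penalties <- function(alpha, beta) {
  alpha <- as.integer(alpha); beta <- as.integer(beta)
  if (length(alpha) != 1L || length(beta) != 1L || is.na(alpha) ||
      is.na(beta) || alpha < 1L || beta < 1L)
    stop("alpha and beta must be single positive integers")
  structure(list(alpha = alpha, beta = beta), class = "gap_penalties")
}

#' @export
print.gap_penalties <- function(x, ...) {
  cat("gap penalties: alpha =", x$alpha, ", beta =", x$beta, "\n")
  invisible(x)
}

#' Total affine cost of a gap run
#' @param m Gap run length(s).
#' @param g A [gap_penalties()] object.
#' @return Numeric cost alpha + (m-1)*beta.
#' @export
gap_cost <- function(m, g) ifelse(m <= 0, 0, g$alpha + (m - 1) * g$beta)

#' Construct a similarity matrix
#'
#' A symmetric 20x20 integer score table over [aa_alphabet()], in half-bit
#' log-odds units, with optional extra rows/columns for ambiguity codes.
#'
#' @param scores 20x20 integer matrix with dimnames equal to the alphabet.
#' @param name Matrix name.
#' @param source Provenance: `"general-purpose"`, `"family-specific"` or
#'   `"fold-specific"`.
#' @param ambiguity Optional named list of integer score vectors (one per
#'   extra letter, each of length 20 in alphabet order) for codes such as
#'   B, Z, X.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(scores, name = "unnamed",
                              source = "general-purpose",
                              ambiguity = NULL) {
  scores <- as.matrix(scores)
  if (!all(dim(scores) == c(20L, 20L)))
    stop("scores must be 20x20")
  if (is.null(dimnames(scores)))
    dimnames(scores) <- list(.AA, .AA)
  if (!identical(rownames(scores), .AA) || !identical(colnames(scores), .AA))
    scores <- scores[.AA, .AA]
  if (any(scores != round(scores)))
    stop("similarity matrix entries must be integers")
  if (any(scores != t(scores))) {
    bad <- which(scores != t(scores), arr.ind = TRUE)[1L, ]
    stop("similarity matrix is not symmetric at pair (",
         .AA[bad[1L]], ", ", .AA[bad[2L]], ")")
  }
  storage.mode(scores) <- "integer"
  structure(list(name = name, scores = scores, source = source,
                 ambiguity = ambiguity),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix '", x$name, "' (", x$source, ")\n", sep = "")
  print(x$scores[1:5, 1:5])
  cat("... 20 x 20 integer table\n")
  invisible(x)
}

#' Construct a reference group
#'
#' A named set of reference pairwise alignments (one protein family or
#' structural fold) — the unit of matrix derivation and evaluation. A group
#' is eligible for matrix derivation only if it holds at least 10 reference
#' alignments; smaller groups do not contain enough observed substitutions
#' for a meaningful group-specific matrix.
#'
#' @param name Group name.
#' @param alignments List of [pairwise_alignment()] objects.
#' @param subset_tag `"SUP"` (homologous superfamily), `"TWI"`
#'   (twilight-zone fold) or other.
#' @return An object of class `reference_group` with the deduplicated
#'   underlying ungapped sequences in `$sequences`.
#' @export
reference_group <- function(name, alignments, subset_tag = "SUP") {
  if (!length(alignments)) stop("group '", name, "' has no alignments")
  seqs <- character(0)
  for (aln in alignments) {
    s <- aligned_sequences(aln)
    for (id in names(s)) {
      if (!is.null(seqs[id]) && !is.na(seqs[id]) && seqs[id] != s[id])
        stop("sequence id '", id, "' appears with two different sequences ",
             "in group '", name, "'")
      seqs[id] <- s[id]
    }
  }
  structure(list(name = name, subset_tag = subset_tag,
                 alignments = alignments, sequences = seqs),
            class = "reference_group")
}

#' @export
print.reference_group <- function(x, ...) {
  cat("reference_group '", x$name, "' [", x$subset_tag, "]: ",
      length(x$alignments), " alignments, ", length(x$sequences),
      " sequences", if (!is_derivation_eligible(x))
        " (ineligible for derivation: < 10 alignments)", "\n", sep = "")
  invisible(x)
}

#' Is a group eligible for matrix derivation?
#' @param group A [reference_group()].
#' @param min_alignments Eligibility floor (default 10).
#' @return Logical.
#' @export
is_derivation_eligible <- function(group, min_alignments = 10L) {
  length(group$alignments) >= min_alignments
}

#' Read a FASTA file
#'
#' @param path File path.
#' @return List of `(id, sequence)` pairs, in file order, sequences
#'   uppercased. Records with invalid residue characters raise a parse
#'   error naming the offending line.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list(); id <- NULL; seq <- character(0); id_line <- 0L
  flush <- function() {
    if (is.null(id)) return()
    s <- toupper(paste(seq, collapse = ""))
    if (nchar(s) == 0L)
      stop("FASTA parse error at line ", id_line, ": record '", id,
           "' has an empty sequence")
    recs[[length(recs) + 1L]] <<- list(id = id, sequence = s)
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (nchar(ln) == 0L) next
    if (startsWith(ln, ">")) {
      flush()
      id <- trimws(sub("^>", "", ln))
      id <- strsplit(id, "[ \t]")[[1]][1]
      if (is.na(id) || nchar(id) == 0L)
        stop("FASTA parse error at line ", k, ": empty header")
      id_line <- k; seq <- character(0)
    } else {
      if (is.null(id))
        stop("FASTA parse error at line ", k, ": sequence before header")
      bad <- setdiff(chars(toupper(ln)), c(.AA_VALID, "-"))
      if (length(bad) > 0L)
        stop("FASTA parse error at line ", k, ": invalid residue(s) ",
             paste(bad, collapse = ", "))
      seq <- c(seq, ln)
    }
  }
  flush()
  if (!length(recs)) stop("FASTA parse error: no records in ", path)
  recs
}

#' Write sequences or an alignment to FASTA
#'
#' @param x Either a list of `(id, sequence)` records as returned by
#'   [read_fasta()], or a [pairwise_alignment()] (written as two gapped
#'   records, i.e. aligned FASTA).
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "pairwise_alignment"))
    x <- list(list(id = x$id_a, sequence = x$row_a),
              list(id = x$id_b, sequence = x$row_b))
  con <- file(path, "w"); on.exit(close(con))
  for (r in x) {
    writeLines(paste0(">", r$id), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned-FASTA pair file as a pairwise alignment
#' @param path File with exactly two equal-length gapped records.
#' @return A [pairwise_alignment()].
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path)
  if (length(recs) != 2L)
    stop("aligned pair file ", path, " must contain exactly 2 records, ",
         "found ", length(recs))
  tryCatch(
    pairwise_alignment(recs[[1]]$id, recs[[2]]$id,
                       recs[[1]]$sequence, recs[[2]]$sequence),
    error = function(e) stop("in file ", path, ": ", conditionMessage(e)))
}

#' Read a directory of aligned-FASTA pairs as a reference group
#'
#' Emulates the layout of a structural-superposition benchmark: one
#' directory per group, one aligned-FASTA file (2 gapped records) per
#' reference pair.
#'
#' @param dir Directory path.
#' @param name Group name; defaults to the directory basename.
#' @param subset_tag `"SUP"`, `"TWI"` or other.
#' @return A [reference_group()].
#' @export
read_reference_group <- function(dir, name = basename(normalizePath(dir)),
                                 subset_tag = "SUP") {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|afa)$",
                           full.names = TRUE))
  if (!length(files)) stop("no aligned-FASTA pair files in ", dir)
  reference_group(name, lapply(files, read_alignment), subset_tag)
}

#' Read an EMBOSS/NCBI-style similarity matrix file
#'
#' Expects a header row of letters and one labelled row per letter; `#`
#' lines are comments. The 20 standard residues are required and stored as
#' the 20x20 score table; extra columns (B, Z, X, `*`, ...) are parsed and
#' stored separately as ambiguity scores.
#'
#' @param path Matrix file path.
#' @param name Matrix name; defaults to a `# name:` comment if present,
#'   else the file basename.
#' @param source Provenance tag.
#' @return A [similarity_matrix()].
#' @export
read_matrix <- function(path, name = NULL, source = "general-purpose") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(name)) {
    nm <- grep("^#\\s*name:", lines, value = TRUE)
    name <- if (length(nm)) trimws(sub("^#\\s*name:", "", nm[1]))
            else basename(path)
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("matrix file ", path, " has no data lines")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(ln) strsplit(trimws(ln), "\\s+")[[1]])
  labels <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) stop("non-numeric score in matrix file ", path,
                       " row '", r[1], "'")
    v
  })
  if (any(lengths(vals) != length(header)))
    stop("matrix file ", path, ": row length does not match header")
  full <- do.call(rbind, vals)
  dimnames(full) <- list(labels, header)
  missing <- setdiff(.AA, intersect(labels, header))
  if (length(missing))
    stop("matrix file ", path, " is missing standard residue(s): ",
         paste(missing, collapse = ", "))
  core <- full[.AA, .AA]
  asym <- which(core != t(core), arr.ind = TRUE)
  if (nrow(asym))
    stop("matrix file ", path, " is asymmetric at pair(s): ",
         paste(unique(apply(asym, 1L, function(ij)
       paste0("(", .AA[ij[1]], ",", .AA[ij[2]], ")"))), collapse = " "))
  extra <- setdiff(header, .AA)
  ambiguity <- NULL
  if (length(extra)) {
    ambiguity <- lapply(extra, function(l) {
      v <- as.integer(round(full[.AA, l]))
      names(v) <- .AA
      v
    })
    names(ambiguity) <- extra
  }
  similarity_matrix(round(core), name = name, source = source,
                    ambiguity = ambiguity)
}

#' Write a similarity matrix in NCBI text format
#'
#' Round-trip property: `read_matrix(write_matrix(m, f))` reproduces `m`.
#' The matrix name and provenance are preserved in comment headers.
#'
#' @param m A [similarity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (!inherits(m, "similarity_matrix")) stop("m must be a similarity_matrix")
  letters <- c(.AA, names(m$ambiguity))
  tab <- matrix(0L, length(letters), length(letters),
                dimnames = list(letters, letters))
  tab[.AA, .AA] <- m$scores
  for (l in names(m$ambiguity)) {
    tab[.AA, l] <- m$ambiguity[[l]]
    tab[l, .AA] <- m$ambiguity[[l]]
    tab[l, l] <- if (l %in% names(m$ambiguity[[l]])) m$ambiguity[[l]][[l]] else 0L
  }
  # ambiguity-ambiguity cross terms default to the minimum score, as in
  # NCBI-distributed files
  for (l1 in names(m$ambiguity)) for (l2 in names(m$ambiguity))
    if (l1 != l2) tab[l1, l2] <- min(m$scores)
  w <- max(nchar(as.character(tab))) + 1L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("# name: ", m$name), paste0("# source: ", m$source)),
             con)
  writeLines(paste0(" ", paste(formatC(letters, width = w), collapse = "")),
             con)
  for (l in letters)
    writeLines(paste0(l, paste(formatC(tab[l, ], width = w), collapse = "")),
               con)
  invisible(path)
}

#' Read / write a TSV table of per-group optimized gap penalties
#'
#' Columns: `group_name`, `alpha`, `beta`.
#'
#' @param path File path.
#' @return For `read_penalties`, a named list of [gap_penalties()] keyed by
#'   group name.
#' @export
read_penalties <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("group_name", "alpha", "beta")
  if (!all(need %in% names(df)))
    stop("penalty table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)),
                function(i) gap_penalties(df$alpha[i], df$beta[i]))
  names(out) <- df$group_name
  out
}

#' @rdname read_penalties
#' @param penalties Named list of [gap_penalties()] keyed by group name.
#' @export
write_penalties <- function(penalties, path) {
  df <- data.frame(group_name = names(penalties),
                   alpha = vapply(penalties, `[[`, 0L, "alpha"),
                   beta = vapply(penalties, `[[`, 0L, "beta"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to a similarity matrix bundled with the package
#'
#' BLOSUM62 and BLOSUM50 (public NCBI score tables) are shipped as
#' general-purpose fallback matrices; any other EMBOSS/NCBI-style matrix
#' file (e.g. VTML200) can be supplied to [read_matrix()] directly.
#'
#' @param name `"BLOSUM62"` or `"BLOSUM50"`.
#' @return File path.
#' @export
#' @examples
#' m <- read_matrix(bundled_matrix("BLOSUM62"))
bundled_matrix <- function(name = c("BLOSUM62", "BLOSUM50")) {
  name <- match.arg(name)
  system.file("extdata", "matrices", name, package = "fsmalign",
              mustWork = TRUE)
}
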