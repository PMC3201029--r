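# residue-residue correspondences of an alignment as integer keys
# (position-in-a, position-in-b); gap columns contribute nothing.
aligned_pair_keys <- function(aln) {
  ca <- chars(aln$row_a); cb <- chars(aln$row_b)
  pa <- cumsum(ca != "-"); pb <- cumsum(cb != "-")
  rr <- ca != "-" & cb != "-"
  pa[rr] * (nchar(ungap(aln$row_b)) + 1) + pb[rr]
}

# reference map for the C++ grid loop: for each position of sequence a,
# the reference-aligned position of b (0 if aligned to a gap)
reference_map <- function(aln) {
  ca <- chars(aln$row_a); cb <- chars(aln$row_b)
  pa <- cumsum(ca != "-"); pb <- cumsum(cb != "-")
  map <- integer(sum(ca != "-"))
  rr <- ca != "-" & cb != "-"
  map[pa[rr]] <- pb[rr]
  map
}

#' Alignment quality against a reference alignment
#'
#' The developer score f_D = n_I / l_R * 100 and the modeler score
#' f_M = n_I / l_T * 100, where n_I is the number of residue pairs aligned
#' identically in the test and reference alignments (the same
#' position-in-a / position-in-b correspondence in both; gap columns never
#' count), l_R and l_T the numbers of aligned residue pairs
#' (residue-residue columns) of the reference and test alignments. With
#' this normalization Q = 100 holds exactly when, and only when, the two
#' alignments align the identical set of residue pairs.
#'
#' @param test,ref [pairwise_alignment()]s of the same two ungapped
#'   sequences (same order).
#' @return An object of class `quality_score` with fields `f_d`, `f_m`,
#'   `q`, `n_i`, `l_r`, `l_t`.
#' @export
#' @examples
#' a <- pairwise_alignment("x", "y", "ACDE", "ACDE")
#' quality(a, a)$q  # 100
quality <- function(test, ref) {
  if (!identical(unname(aligned_sequences(test)),
                 unname(aligned_sequences(ref))))
    stop("test and reference alignments are over different sequences")
  kt <- aligned_pair_keys(test); kr <- aligned_pair_keys(ref)
  n_i <- length(intersect(kt, kr))
  l_r <- length(kr); l_t <- length(kt)
  if (l_r == 0L || l_t == 0L)
    stop("alignment without residue-residue columns cannot be scored")
  f_d <- 100 * n_i / l_r
  f_m <- 100 * n_i / l_t
  structure(list(f_d = f_d, f_m = f_m, q = (f_d + f_m) / 2,
                 n_i = n_i, l_r = l_r, l_t = l_t),
            class = "quality_score")
}

# fixed 26-letter encoding (20 standard + ambiguity codes) shared by all
# pairs in one grid run, so indices agree with a single score table
grid_encoding <- function(m) {
  letters <- c(.AA, .AA_AMBIG)
  S <- matrix(0L, 26L, 26L, dimnames = list(letters, letters))
  S[.AA, .AA] <- m$scores
  for (l in intersect(.AA_AMBIG, names(m$ambiguity))) {
    S[.AA, l] <- m$ambiguity[[l]]
    S[l, .AA] <- m$ambiguity[[l]]
  }
  list(letters = letters, S = S)
}

# shared precomputation for the C++ grid loop
grid_pair_structs <- function(refs, letters) {
  lapply(refs, function(ref) {
    sq <- aligned_sequences(ref)
    list(a = match(chars(sq[[1]]), letters) - 1L,
         b = match(chars(sq[[2]]), letters) - 1L,
         ref_map = reference_map(ref),
         l_ref = length(aligned_pair_keys(ref)))
  })
}

#' Grid search for optimal gap penalties
#'
#' Aligns every training pair with every integer penalty combination in
#' `alpha_range` x `beta_range` (defaults 1..50 x 1..30) and returns the
#' combination with the highest mean quality score Q against the training
#' references. Ties are broken deterministically: smallest alpha, then
#' smallest beta.
#'
#' @param train_refs List of reference [pairwise_alignment()]s; the
#'   sequences to align are their ungapped rows.
#' @param m A [similarity_matrix()].
#' @param alpha_range,beta_range Integer vectors of candidate magnitudes.
#' @param free_end_gaps Passed to the aligner.
#' @return A [gap_penalties()] with attributes `mean_q` (the achieved mean
#'   training Q) and `q_grid` (the full mean-Q matrix, alphas x betas).
#' @export
grid_search_penalties <- function(train_refs, m, alpha_range = 1:50,
                                  beta_range = 1:30,
                                  free_end_gaps = FALSE) {
  if (!length(train_refs)) stop("empty training set")
  alpha_range <- as.integer(alpha_range); beta_range <- as.integer(beta_range)
  enc <- grid_encoding(m)
  pairs <- grid_pair_structs(train_refs, enc$letters)
  qg <- .grid_q_cpp(pairs, enc$S, alpha_range, beta_range, free_end_gaps)
  best <- max(qg)
  hit <- which(qg >= best - 1e-9, arr.ind = TRUE)
  # rows are alphas in ascending order, so the first hit in row-major
  # scan order over (alpha, beta) is the lexicographically smallest
  hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE][1L, ]
  out <- gap_penalties(alpha_range[hit[1L]], beta_range[hit[2L]])
  attr(out, "mean_q") <- qg[hit[1L], hit[2L]]
  attr(out, "q_grid") <- qg
  out
}

# NOTE: grid_pair_structs uses the sequences present in the alignments;
# the C++ loop recomputes the same Q as quality() (cross-checked in tests).

#' Scoring-function specifications for evaluation
#'
#' A scoring function is either a fixed similarity matrix (training =
#' optimizing its gap penalties on the training folds) or a group-specific
#' derivation (training = deriving the matrix from the training folds'
#' reference alignments, then optimizing its penalties).
#'
#' @param matrix Fixed [similarity_matrix()] to evaluate.
#' @param penalties Optional fixed [gap_penalties()]; if `NULL` (default)
#'   penalties are grid-searched on each training split.
#' @return A scoring specification for [run_cross_validation()].
#' @export
scoring_fixed <- function(matrix, penalties = NULL) {
  structure(list(type = "fixed", matrix = matrix, penalties = penalties,
                 label = matrix$name), class = "scoring_spec")
}

#' @rdname scoring_fixed
#' @param fallback General-purpose fallback [similarity_matrix()] for the
#'   derivation blend.
#' @param pseudocount_mass,blend_constant,eq1 See [derive_matrix()].
#' @export
scoring_group_specific <- function(fallback, pseudocount_mass = 1,
                                   blend_constant = 8000,
                                   eq1 = "score-blend") {
  structure(list(type = "group-specific", fallback = fallback,
                 pseudocount_mass = pseudocount_mass,
                 blend_constant = blend_constant, eq1 = eq1,
                 label = "group-specific"), class = "scoring_spec")
}

#' Partition a group's pairs into cross-validation folds
#'
#' Seeded uniform shuffle followed by a round-robin split: folds are
#' pairwise disjoint, cover all pairs, and their sizes differ by at most 1.
#'
#' @param n Number of pairs.
#' @param k Number of folds (default 3).
#' @param seed Integer seed (required, for reproducible partitions).
#' @return Integer vector of fold labels (1..k), one per pair.
#' @export
make_cv_folds <- function(n, k = 3L, seed) {
  if (n < k) stop("cannot make ", k, " folds from ", n, " pairs")
  perm <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(k), n)
  folds
}

# train one scoring spec on a set of reference alignments
train_spec <- function(spec, train_refs, group_name, alpha_range,
                       beta_range, free_end_gaps) {
  m <- if (spec$type == "fixed") spec$matrix
  else {
    sub <- reference_group(group_name, train_refs)
    derive_matrix(sub, spec$fallback,
                  pseudocount_mass = spec$pseudocount_mass,
                  blend_constant = spec$blend_constant, eq1 = spec$eq1,
                  min_alignments = 1L)
  }
  g <- if (!is.null(spec$penalties)) spec$penalties
       else grid_search_penalties(train_refs, m, alpha_range, beta_range,
                                  free_end_gaps)
  list(matrix = m, penalties = g)
}

#' Cross-validated per-pair alignment quality for scoring functions
#'
#' 3-fold cross-validation of one or more scoring functions on a reference
#' group. For each fold, every scoring function is trained on the other
#' folds (matrix derivation for group-specific specs, then gap-penalty
#' grid search), the held-out pairs are aligned with the trained matrix
#' and penalties, and each receives a quality score Q against its
#' reference. Training never sees the test fold's alignments.
#'
#' @param group A [reference_group()] with at least `k` pairs.
#' @param scoring_fns Named list of specs from [scoring_fixed()] /
#'   [scoring_group_specific()].
#' @param seed Integer seed controlling the fold partition.
#' @param k Number of folds (default 3).
#' @param alpha_range,beta_range Grid-search ranges (defaults 1..50,
#'   1..30).
#' @param folds Optional precomputed fold assignment (overrides `seed`'s
#'   partition; used by leakage instrumentation).
#' @param free_end_gaps Passed to the aligner.
#' @return Matrix of Q scores, one row per pair (in group order), one
#'   column per scoring function, with attributes `folds` and `trace`
#'   (per-fold trained matrices and penalties, for audit).
#' @export
run_cross_validation <- function(group, scoring_fns, seed, k = 3L,
                                 alpha_range = 1:50, beta_range = 1:30,
                                 folds = NULL, free_end_gaps = FALSE) {
  n <- length(group$alignments)
  if (n < k) stop("group '", group$name, "' has fewer than ", k, " pairs")
  if (is.null(names(scoring_fns)) || any(!nzchar(names(scoring_fns))))
    names(scoring_fns) <- vapply(scoring_fns, `[[`, "", "label")
  if (is.null(folds)) folds <- make_cv_folds(n, k, seed)
  q <- matrix(NA_real_, n, length(scoring_fns),
              dimnames = list(NULL, names(scoring_fns)))
  trace <- list()
  for (f in sort(unique(folds))) {
    train_refs <- group$alignments[folds != f]
    test_idx <- which(folds == f)
    trained <- lapply(scoring_fns, train_spec, train_refs = train_refs,
                      group_name = group$name, alpha_range = alpha_range,
                      beta_range = beta_range,
                      free_end_gaps = free_end_gaps)
    trace[[as.character(f)]] <- list(train_idx = which(folds != f),
                                     trained = trained)
    for (i in test_idx) {
      ref <- group$alignments[[i]]
      sq <- aligned_sequences(ref)
      for (s in seq_along(trained)) {
        res <- global_align(sq[[1]], sq[[2]], trained[[s]]$matrix,
                            trained[[s]]$penalties,
                            free_end_gaps = free_end_gaps)
        q[i, s] <- quality(res$alignment, ref)$q
      }
    }
  }
  attr(q, "folds") <- folds
  attr(q, "trace") <- trace
  q
}

#' Two-sided paired t-test on quality scores
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the paired differences d = a - b, with
#' a two-sided p-value from Student's t on n-1 degrees of freedom.
#' All-zero differences give t = 0, p = 1 (the degenerate identical case).
#'
#' @param scores_a,scores_b Equal-length numeric vectors, n >= 2.
#' @return List with `t_statistic`, `p_value`, `mean_diff`, `n`, `df`.
#' @export
#' @examples
#' paired_t_test(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors have different lengths")
  n <- length(scores_a)
  if (n < 2L) stop("paired t-test requires at least 2 pairs")
  d <- scores_a - scores_b
  s <- stats::sd(d)
  if (s == 0) {
    t <- 0; p <- 1
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t_statistic = t, p_value = p, mean_diff = mean(d), n = n, df = n - 1L)
}

verdict_from_test <- function(tt, alpha_sig = 0.05) {
  if (tt$p_value < alpha_sig && tt$mean_diff > 0) "A-better"
  else if (tt$p_value < alpha_sig && tt$mean_diff < 0) "B-better"
  else "no-significant-difference"
}

#' Compare two scoring functions across reference groups
#'
#' Runs cross-validation for both scoring functions on every eligible
#' group (same fold partition for both, so the per-pair Q scores are
#' paired), applies the two-sided paired t-test per group, and tallies the
#' tournament counts in the "A-better;B-better" convention.
#'
#' @param groups List of [reference_group()]s.
#' @param spec_a,spec_b Scoring specs ([scoring_fixed()] /
#'   [scoring_group_specific()]).
#' @param seed Integer seed; each group's fold partition derives from it.
#' @param p_significant Significance threshold (default 0.05).
#' @param min_alignments Group eligibility floor for group-specific specs
#'   (default 10).
#' @param ... Passed to [run_cross_validation()].
#' @return List with `counts` (named: `a_better`, `b_better`, `tie`) and
#'   `comparisons`, a list of per-group records of class
#'   `group_comparison` (group name, paired Q vectors, t, p, mean
#'   difference, verdict).
#' @export
compare_matrices_on_groups <- function(groups, spec_a, spec_b, seed,
                                       p_significant = 0.05,
                                       min_alignments = 10L, ...) {
  needs_floor <- spec_a$type == "group-specific" ||
    spec_b$type == "group-specific"
  eligible <- Filter(function(g) !needs_floor ||
                       is_derivation_eligible(g, min_alignments), groups)
  if (!length(eligible)) stop("no eligible groups to compare on")
  comparisons <- lapply(eligible, function(g) {
    q <- run_cross_validation(g, list(A = spec_a, B = spec_b),
                              seed = derive_seed(seed, g$name), ...)
    tt <- paired_t_test(q[, "A"], q[, "B"])
    structure(list(group_name = g$name, n = nrow(q),
                   scores_a = q[, "A"], scores_b = q[, "B"],
                   mean_q_a = mean(q[, "A"]), mean_q_b = mean(q[, "B"]),
                   t_statistic = tt$t_statistic, p_value = tt$p_value,
                   mean_diff = tt$mean_diff,
                   verdict = verdict_from_test(tt, p_significant)),
              class = "group_comparison")
  })
  verdicts <- vapply(comparisons, `[[`, "", "verdict")
  list(counts = c(a_better = sum(verdicts == "A-better"),
                  b_better = sum(verdicts == "B-better"),
                  tie = sum(verdicts == "no-significant-difference")),
       comparisons = comparisons)
}

#' Venn partition of significant-group sets
#'
#' Given two or more named sets of group identifiers (the groups on which
#' each pairwise matrix comparison reached significance), computes the
#' size of every exclusive intersection region.
#'
#' @param sets Named list (length >= 2) of vectors of group identifiers.
#' @return Named integer vector; names are region labels like
#'   `"A&B"` (elements in exactly the named sets and no others).
#' @export
#' @examples
#' overlap_analysis(list(A = c(1, 2, 3), B = c(3, 4), C = c(3, 5)))
overlap_analysis <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  out <- integer(nrow(combos))
  labels <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    mask <- as.logical(combos[r, ])
    labels[r] <- paste(names(sets)[mask], collapse = "&")
    if (length(universe) == 0L) { out[r] <- 0L; next }
    inreg <- rep(TRUE, length(universe))
    for (j in seq_len(k)) inreg <- inreg & (member[, j] == mask[j])
    out[r] <- sum(inreg)
  }
  stats::setNames(out, labels)
}
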