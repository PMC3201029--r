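check_same_alphabet <- function(mats) {
  for (m in mats)
    if (!identical(rownames(m$scores), .AA))
      stop("matrix '", m$name, "' is not over the standard alphabet")
}

#' Average element-wise difference between family matrices and a fallback
#'
#' D1(i,j) = mean over family matrices of s_k(i,j) - v(i,j). Identically
#' zero when every family matrix equals the fallback; positive entries
#' mark pairs scored more favourably by the family-specific matrices.
#'
#' @param family_matrices List of [similarity_matrix()].
#' @param fallback General-purpose [similarity_matrix()].
#' @return An object of class `matrix_delta`: `d1` (symmetric 20x20
#'   numeric) and `n_matrices`.
#' @export
average_delta <- function(family_matrices, fallback) {
  if (!length(family_matrices)) stop("no family matrices given")
  check_same_alphabet(c(family_matrices, list(fallback)))
  d1 <- Reduce(`+`, lapply(family_matrices,
                           function(m) m$scores - fallback$scores)) /
    length(family_matrices)
  structure(list(d1 = d1, n_matrices = length(family_matrices)),
            class = "matrix_delta")
}

#' Contrast better-performing vs similar-performing matrices
#'
#' BP(i,j) and SP(i,j) are the element-wise mean score tables over the
#' matrices that perform significantly better than the fallback and over
#' those that perform similarly to it; D2 = BP - SP highlights which
#' residue pairs the better-performing matrices re-score.
#'
#' @param better,similar Non-empty lists of [similarity_matrix()].
#' @return An object of class `performance_contrast` with `bp`, `sp`,
#'   `d2`, `nb`, `ns`.
#' @export
performance_contrast <- function(better, similar) {
  if (!length(better)) stop("the 'better' class of matrices is empty")
  if (!length(similar)) stop("the 'similar' class of matrices is empty")
  check_same_alphabet(c(better, similar))
  bp <- Reduce(`+`, lapply(better, `[[`, "scores")) / length(better)
  sp <- Reduce(`+`, lapply(similar, `[[`, "scores")) / length(similar)
  structure(list(bp = bp, sp = sp, d2 = bp - sp,
                 nb = length(better), ns = length(similar)),
            class = "performance_contrast")
}

#' Classify per-group comparisons into performance classes
#'
#' With A = the family-specific matrix and B = the fallback in each
#' comparison: "better" means p < `p_better` with the mean paired Q
#' difference favouring the family matrix; "worse" means p < `p_better`
#' favouring the fallback; "similar" means p > `p_similar_floor`; the
#' band in between (a trend toward significance) is excluded. The four
#' classes partition the input.
#'
#' @param comparisons List of `group_comparison` records (see
#'   [compare_matrices_on_groups()]).
#' @param p_better Significance threshold (default 0.05).
#' @param p_similar_floor Floor of the "similar" class (default 0.1).
#' @return List of four character vectors of group names: `better`,
#'   `similar`, `worse`, `excluded`.
#' @export
classify_matrices <- function(comparisons, p_better = 0.05,
                              p_similar_floor = 0.1) {
  cls <- vapply(comparisons, function(cmp) {
    p <- cmp$p_value
    if (p < p_better && cmp$mean_diff > 0) "better"
    else if (p < p_better && cmp$mean_diff < 0) "worse"
    else if (p > p_similar_floor) "similar"
    else "excluded"
  }, "")
  nms <- vapply(comparisons, `[[`, "", "group_name")
  list(better = nms[cls == "better"], similar = nms[cls == "similar"],
       worse = nms[cls == "worse"], excluded = nms[cls == "excluded"])
}
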