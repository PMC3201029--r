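b62 <- read_matrix(bundled_matrix("BLOSUM62"))

test_that("quality implements the developer/modeler score identities", {
  # identical alignments score exactly 100
  set.seed(21)
  for (k in 1:10) {
    bench <- tiny_benchmark()
    ref <- bench$groups[[1 + k %% 2]]$alignments[[1 + k %% 6]]
    qs <- quality(ref, ref)
    expect_equal(qs$q, 100)
    expect_equal(qs$f_d, 100)
    expect_equal(qs$f_m, 100)
  }

  # forced construction: n_I=4, l_R=10, l_T=8 -> f_D=40, f_M=50, Q=45.
  # a and b have 12 residues each; the reference aligns pairs (i,i) for
  # i=1..10, the test aligns (1,1)..(4,4) plus the shifted (5,6)..(8,9).
  ref  <- pairwise_alignment("a", "b", "AAAAAAAAAAAA--", "RRRRRRRRRR--RR")
  test <- pairwise_alignment("a", "b", "AAAA-AAAAAAAA---",
                                       "RRRRRRRRR----RRR")
  qs <- quality(test, ref)
  expect_identical(qs$n_i, 4L)
  expect_equal(qs$f_d, 40)
  expect_equal(qs$f_m, 50)
  expect_equal(qs$q, 45)

  # disjoint correspondences -> 0
  t2 <- pairwise_alignment("a", "b", "AA", "RR")      # pairs (1,1),(2,2)
  r2 <- pairwise_alignment("a", "b", "AA-", "-RR")    # pair (2,1)
  expect_equal(quality(t2, r2)$q, 0)

  # mismatched sequences are rejected
  r3 <- pairwise_alignment("a", "b", "AAC", "RRC")
  expect_error(quality(t2, r3), "different sequences")
})

test_that("n_I is bounded by both alignments' residue-residue columns", {
  set.seed(31)
  bench <- tiny_benchmark()
  g <- gap_penalties(11, 1)
  for (ref in bench$groups[[1]]$alignments[1:4]) {
    sq <- aligned_sequences(ref)
    test <- global_align(sq[[1]], sq[[2]], b62, g)$alignment
    qs <- quality(test, ref)
    rr <- function(aln) sum(strsplit(aln$row_a, "")[[1]] != "-" &
                              strsplit(aln$row_b, "")[[1]] != "-")
    expect_lte(qs$n_i, min(rr(ref), rr(test)))
    expect_lte(qs$f_d, 100); expect_lte(qs$f_m, 100)
  }
})

test_that("grid search maximizes mean Q with lexicographic tie-break", {
  bench <- tiny_benchmark()
  refs <- bench$groups[[1]]$alignments[1:4]
  alphas <- 8:14; betas <- 1:4
  got <- grid_search_penalties(refs, b62, alphas, betas)
  # independent route: align + quality in R for every combination
  qm <- matrix(NA_real_, length(alphas), length(betas))
  for (ia in seq_along(alphas)) for (ib in seq_along(betas)) {
    qs <- vapply(refs, function(ref) {
      sq <- aligned_sequences(ref)
      res <- global_align(sq[[1]], sq[[2]], b62,
                          gap_penalties(alphas[ia], betas[ib]))
      quality(res$alignment, ref)$q
    }, 0)
    qm[ia, ib] <- mean(qs)
  }
  expect_equal(attr(got, "q_grid"), qm, ignore_attr = TRUE)
  best <- which(qm >= max(qm) - 1e-9, arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  expect_identical(got$alpha, as.integer(alphas[best[1]]))
  expect_identical(got$beta, as.integer(betas[best[2]]))
  expect_error(grid_search_penalties(list(), b62), "empty training set")
})

test_that("grid search recovers a planted unique optimum", {
  # construct a training pair whose reference is reproduced perfectly by
  # exactly one penalty combination on a small grid (found by scanning
  # with the independent R route, then asserted against the C++ path)
  bench <- tiny_benchmark()
  ref <- bench$groups[[2]]$alignments[[1]]
  sq <- aligned_sequences(ref)
  alphas <- 5:20; betas <- 1:6
  qm <- matrix(NA_real_, length(alphas), length(betas))
  for (ia in seq_along(alphas)) for (ib in seq_along(betas)) {
    res <- global_align(sq[[1]], sq[[2]], b62,
                        gap_penalties(alphas[ia], betas[ib]))
    qm[ia, ib] <- quality(res$alignment, ref)$q
  }
  got <- grid_search_penalties(list(ref), b62, alphas, betas)
  best <- which(qm >= max(qm) - 1e-9, arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  expect_identical(got$alpha, as.integer(alphas[best[1]]))
  expect_identical(got$beta, as.integer(betas[best[2]]))
  expect_equal(attr(got, "mean_q"), max(qm))
})

test_that("cv folds are disjoint, covering, balanced and seeded", {
  f <- make_cv_folds(12, 3, seed = 5)
  expect_identical(sort(unique(f)), 1:3)
  expect_true(all(table(f) == 4))
  expect_identical(f, make_cv_folds(12, 3, seed = 5))
  expect_false(identical(f, make_cv_folds(12, 3, seed = 6)))
  f13 <- make_cv_folds(13, 3, seed = 1)
  expect_lte(diff(range(table(f13))), 1)
  expect_error(make_cv_folds(2, 3, seed = 1), "cannot make")
})

test_that("cross-validation scores every pair once and is deterministic", {
  bench <- tiny_benchmark()
  g <- bench$groups[[1]]
  specs <- list(fixed = scoring_fixed(b62),
                fam = scoring_group_specific(b62))
  q1 <- run_cross_validation(g, specs, seed = 3, alpha_range = 5:20,
                             beta_range = 1:4)
  expect_identical(dim(q1), c(6L, 2L))
  expect_false(anyNA(q1))
  expect_true(all(q1 >= 0 & q1 <= 100))
  q2 <- run_cross_validation(g, specs, seed = 3, alpha_range = 5:20,
                             beta_range = 1:4)
  expect_identical(q1, q2)
  expect_error(run_cross_validation(
    reference_group("s", g$alignments[1:2]), specs, seed = 1),
    "fewer than 3")
})

test_that("cross-validation training never sees the test fold", {
  bench <- tiny_benchmark()
  g <- bench$groups[[2]]
  folds <- make_cv_folds(length(g$alignments), 3, seed = 9)
  specs <- list(fam = scoring_group_specific(b62))
  q1 <- run_cross_validation(g, specs, seed = 9, folds = folds,
                             alpha_range = 8:14, beta_range = 1:3)
  tr1 <- attr(q1, "trace")
  # remove one test-fold pair of fold 1 and rerun with the same folds:
  # fold-1 training artifacts must be identical
  drop <- which(folds == 1)[1]
  g2 <- reference_group(g$name, g$alignments[-drop])
  q2 <- run_cross_validation(g2, specs, seed = 9, folds = folds[-drop],
                             alpha_range = 8:14, beta_range = 1:3)
  tr2 <- attr(q2, "trace")
  expect_identical(tr1[["1"]]$trained$fam$matrix$scores,
                   tr2[["1"]]$trained$fam$matrix$scores)
  expect_identical(tr1[["1"]]$trained$fam$penalties$alpha,
                   tr2[["1"]]$trained$fam$penalties$alpha)
  expect_identical(tr1[["1"]]$trained$fam$penalties$beta,
                   tr2[["1"]]$trained$fam$penalties$beta)
  # and the surviving fold-1 test pairs keep their scores
  keep <- setdiff(which(folds == 1), drop)
  keep2 <- match(keep, setdiff(seq_along(folds), drop))
  expect_identical(q1[keep, "fam"], q2[keep2, "fam"])
})

test_that("paired t-test matches its closed form and reference", {
  # identical scores: zero differences
  tt <- paired_t_test(c(50, 60, 70), c(50, 60, 70))
  expect_identical(tt$t_statistic, 0)
  expect_identical(tt$p_value, 1)

  # d = 1..5: t = 3/(sd/sqrt(5)), p ~ 0.0132
  tt2 <- paired_t_test(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(tt2$t_statistic, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(tt2$t_statistic, 4.242641, tolerance = 1e-6)
  expect_equal(tt2$p_value, 0.01324, tolerance = 1e-3)

  # antisymmetry
  set.seed(13)
  a <- runif(10, 0, 100); b <- runif(10, 0, 100)
  t_ab <- paired_t_test(a, b); t_ba <- paired_t_test(b, a)
  expect_equal(t_ab$t_statistic, -t_ba$t_statistic)
  expect_equal(t_ab$p_value, t_ba$p_value)

  # agreement with stats::t.test on random paired samples
  for (k in 1:100) {
    n <- sample(3:30, 1)
    a <- rnorm(n, 50, 20); b <- rnorm(n, 48, 20)
    ref <- stats::t.test(a, b, paired = TRUE)
    got <- paired_t_test(a, b)
    expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  }

  expect_error(paired_t_test(1:3, 1:4), "different lengths")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("compare_matrices_on_groups: identical specs tie everywhere", {
  bench <- tiny_benchmark()
  res <- compare_matrices_on_groups(
    unname(bench$groups), scoring_fixed(b62), scoring_fixed(b62),
    seed = 2, min_alignments = 3L, alpha_range = 10:14, beta_range = 1:2)
  expect_identical(unname(res$counts["a_better"]), 0L)
  expect_identical(unname(res$counts["b_better"]), 0L)
  expect_identical(unname(res$counts["tie"]), 2L)
  for (cmp in res$comparisons)
    expect_identical(cmp$verdict, "no-significant-difference")
})

test_that("compare_matrices_on_groups is antisymmetric", {
  bench <- tiny_benchmark()
  scr <- scramble_matrix(b62, seed = 3)
  ab <- compare_matrices_on_groups(
    unname(bench$groups), scoring_fixed(b62), scoring_fixed(scr),
    seed = 4, min_alignments = 3L, alpha_range = 10:14, beta_range = 1:2)
  ba <- compare_matrices_on_groups(
    unname(bench$groups), scoring_fixed(scr), scoring_fixed(b62),
    seed = 4, min_alignments = 3L, alpha_range = 10:14, beta_range = 1:2)
  expect_identical(unname(ab$counts["a_better"]),
                   unname(ba$counts["b_better"]))
  expect_identical(unname(ab$counts["b_better"]),
                   unname(ba$counts["a_better"]))
})

test_that("overlap_analysis computes exclusive Venn regions", {
  r <- overlap_analysis(list(A = c(1, 2, 3), B = c(3, 4), C = c(3, 5)))
  expect_identical(unname(r["A&B&C"]), 1L)
  expect_identical(unname(r["A"]), 2L)
  expect_identical(unname(r["B"]), 1L)
  expect_identical(unname(r["A&B"]), 0L)

  # identical sets: full overlap only
  r2 <- overlap_analysis(list(X = 1:3, Y = 1:3))
  expect_identical(unname(r2["X&Y"]), 3L)
  expect_identical(unname(r2["X"]), 0L)

  # disjoint sets
  r3 <- overlap_analysis(list(X = 1:2, Y = 3:4))
  expect_identical(unname(r3["X&Y"]), 0L)
  expect_identical(unname(r3["X"]), 2L)
  expect_error(overlap_analysis(list(A = 1:2)), "at least 2")
})
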