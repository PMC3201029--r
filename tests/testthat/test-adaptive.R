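b62 <- read_matrix(bundled_matrix("BLOSUM62"))

test_that("family_database validates and excludes", {
  db <- family_database(c("s1", "s2"), c("f1", "f2"), c("ACDE", "WYHK"),
                        exclusions = "s2")
  expect_error(family_database(c("s1", "s1"), c("f", "f"), c("A", "A")),
               "unique")
  db2 <- exclude_ids(db, "s1")
  expect_setequal(db2$exclusions, c("s1", "s2"))
})

test_that("assign_family finds the family of a near-identical member", {
  bench <- tiny_benchmark()
  db <- bench$db
  id <- db$records$id[1]
  a <- assign_family(db$records$sequence[1], db, matrix = b62,
                     n_shuffles = 50L, seed = 5, query_id = id)
  expect_identical(a$family, db$records$family[1])
  expect_lt(a$significance, 0.05)
  expect_false(a$best_hit == id)  # the query itself is excluded

  # determinism: identical call, identical result
  a2 <- assign_family(db$records$sequence[1], db, matrix = b62,
                      n_shuffles = 50L, seed = 5, query_id = id)
  expect_identical(a, a2)
})

test_that("a shuffled random query is not assigned", {
  bench <- tiny_benchmark()
  set.seed(99)
  junk <- random_seq(60)
  a <- assign_family(junk, bench$db, matrix = b62, n_shuffles = 100L,
                     seed = 17, query_id = "junk")
  expect_true(is.na(a$family))
  expect_gte(a$significance, 0.05)
})

test_that("exclusion soundness: excluded ids never surface as hits", {
  bench <- tiny_benchmark()
  db <- bench$db
  id <- db$records$id[3]
  a1 <- assign_family(db$records$sequence[3], db, matrix = b62,
                      n_shuffles = 30L, seed = 2, query_id = id)
  db2 <- exclude_ids(db, a1$best_hit)
  a2 <- assign_family(db$records$sequence[3], db2, matrix = b62,
                      n_shuffles = 30L, seed = 2, query_id = id)
  expect_false(identical(a2$best_hit, a1$best_hit))
  expect_error(assign_family("ACD", family_database("q", "f", "ACD"),
                             matrix = b62, query_id = "q"),
               "empty after exclusions")
})

test_that("the external backend consumes tabular search output", {
  db <- family_database(c("s1", "s2", "s3"), c("f1", "f1", "f2"),
                        c("ACDEF", "ACDEW", "WYHKR"))
  hits <- data.frame(query = c("q", "q", "q"),
                     subject = c("s1", "s2", "s3"),
                     evalue = c(1e-8, 1e-3, 0.2))
  a <- assign_family("ACDEF", db, backend = "external", hits = hits,
                     query_id = "q")
  expect_identical(a$family, "f1")
  expect_identical(a$best_hit, "s1")
  expect_equal(a$significance, 1e-8)

  # no significant hit -> no family
  a2 <- assign_family("ACDEF", db, backend = "external",
                      hits = hits[hits$evalue > 0.1, , drop = FALSE],
                      query_id = "q")
  expect_true(is.na(a2$family))

  # excluded subject cannot win
  db3 <- exclude_ids(db, "s1")
  a3 <- assign_family("ACDEF", db3, backend = "external", hits = hits,
                      query_id = "q")
  expect_identical(a3$best_hit, "s2")
})

test_that("select_scoring applies the same-family rule", {
  fams <- list(matrices = list(F = random_similarity_matrix(1)),
               penalties = list(F = gap_penalties(9, 2)))
  store <- matrix_store(fams$matrices, fams$penalties)
  mk <- function(fam) structure(list(query_id = "q", family = fam,
                                     best_hit = "h", significance = 0.01,
                                     backend = "internal"),
                                class = "family_assignment")
  same <- select_scoring(mk("F"), mk("F"), store, b62)
  expect_identical(same$provenance, "family")
  expect_identical(same$matrix$name, "random1")
  expect_identical(same$penalties$alpha, 9L)

  diff <- select_scoring(mk("F"), mk("G"), store, b62)
  expect_identical(diff$provenance, "general")
  expect_identical(diff$matrix$name, b62$name)
  expect_identical(diff$penalties$alpha, 15L)
  expect_identical(diff$penalties$beta, 1L)

  none <- select_scoring(mk("F"), mk(NA_character_), store, b62)
  expect_identical(none$provenance, "general")

  # same family but matrix missing from the store: warn and fall back
  expect_warning(
    miss <- select_scoring(mk("Z"), mk("Z"), store, b62),
    "no stored matrix")
  expect_identical(miss$provenance, "general")
})

test_that("adaptive_align routes, aligns and reports deterministically", {
  bench <- tiny_benchmark()
  db <- bench$db
  fams <- unique(db$records$family)
  store <- matrix_store(
    stats::setNames(lapply(bench$groups, derive_matrix, fallback = b62,
                           min_alignments = 1L), fams),
    stats::setNames(rep(list(gap_penalties(12, 2)), length(fams)), fams))

  # two members of the same family route to that family's matrix
  g1 <- bench$groups[[1]]
  ids <- names(g1$sequences)[1:2]
  r <- adaptive_align(g1$sequences[[1]], g1$sequences[[2]], db, store, b62,
                      id_a = ids[1], id_b = ids[2], n_shuffles = 50L,
                      seed = 23)
  expect_identical(r$report$provenance, "family")
  expect_identical(r$report$family, fams[1])
  expect_identical(r$report$alpha, 12L)
  expect_s3_class(r$alignment, "pairwise_alignment")

  # cross-family pair falls back to the general matrix at (15, 1)
  g2 <- bench$groups[[2]]
  idb <- names(g2$sequences)[1]
  r2 <- adaptive_align(g1$sequences[[1]], g2$sequences[[1]], db, store, b62,
                       id_a = ids[1], id_b = idb, n_shuffles = 50L,
                       seed = 23)
  expect_identical(r2$report$provenance, "general")
  expect_identical(r2$report$alpha, 15L)
  expect_identical(r2$report$beta, 1L)

  # determinism of the full report
  r3 <- adaptive_align(g1$sequences[[1]], g1$sequences[[2]], db, store, b62,
                       id_a = ids[1], id_b = ids[2], n_shuffles = 50L,
                       seed = 23)
  expect_identical(r$report, r3$report)
  expect_identical(r$alignment, r3$alignment)

  # fallback totality: junk input still aligns
  set.seed(1)
  r4 <- adaptive_align(random_seq(30), random_seq(25), db, store, b62,
                       id_a = "j1", id_b = "j2", n_shuffles = 30L, seed = 3)
  expect_s3_class(r4$alignment, "pairwise_alignment")
  expect_identical(r4$report$provenance, "general")
})
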