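#' Construct a family-labelled sequence database
#'
#' The search target of the adaptive aligner: protein sequences labelled
#' with their family of origin, with an exclusion set for sequences
#' withheld as test inputs (excluded ids never appear in search results).
#'
#' @param ids Character vector of sequence ids (unique).
#' @param families Character vector of family names, parallel to `ids`.
#' @param sequences Character vector of ungapped sequences.
#' @param exclusions Character vector of withheld ids.
#' @return An object of class `family_database`.
#' @export
family_database <- function(ids, families, sequences,
                            exclusions = character(0)) {
  if (anyDuplicated(ids)) stop("database ids must be unique")
  if (length(families) != length(ids) || length(sequences) != length(ids))
    stop("ids, families and sequences must have equal lengths")
  structure(list(records = data.frame(id = ids, family = families,
                                      sequence = toupper(sequences),
                                      stringsAsFactors = FALSE),
                 exclusions = unique(exclusions)),
            class = "family_database")
}

#' @export
print.family_database <- function(x, ...) {
  cat("family_database:", nrow(x$records), "sequences,",
      length(unique(x$records$family)), "families,",
      length(x$exclusions), "excluded\n")
  invisible(x)
}

#' Exclude additional ids from a database
#' @param db A [family_database()].
#' @param ids Ids to withhold.
#' @return The database with the ids added to its exclusion set.
#' @export
exclude_ids <- function(db, ids) {
  db$exclusions <- unique(c(db$exclusions, ids))
  db
}

# active (searchable) records
db_active <- function(db) {
  db$records[!(db$records$id %in% db$exclusions), , drop = FALSE]
}

#' Assign a family to a query sequence by homology search
#'
#' Searches the query against the non-excluded database sequences and
#' assigns the family of the most significant hit when its significance
#' is below `threshold`, else no family. Ties on significance are broken
#' by higher raw alignment score, then lexicographically smaller id.
#'
#' The default `"internal"` backend is hermetic: Smith-Waterman local
#' alignment with `matrix` at penalties (11, 1), significance estimated as
#' an empirical p-value of the best hit score against a null of shuffled
#' queries (the analogue of a search E-value < threshold, with no
#' external binary). The null is seeded per query id, so repeated runs
#' are identical. The `"external"` backend consumes standard tabular
#' search output (columns `query`, `subject`, `evalue`) produced by any
#' protein search tool, e.g. BLASTP.
#'
#' @param query Ungapped query sequence.
#' @param db A [family_database()].
#' @param threshold Significance threshold (default 0.05).
#' @param backend `"internal"` or `"external"`.
#' @param matrix Similarity matrix for the internal backend.
#' @param penalties Internal-backend gap penalties (default (11, 1)).
#' @param n_shuffles Null-distribution size (default 200).
#' @param seed Base seed; the per-query stream derives from it and the
#'   query id.
#' @param query_id Id of the query (used for self-exclusion, the seeded
#'   null, and external-hit lookup).
#' @param hits For the external backend: data frame of tabular search
#'   output with columns `query`, `subject`, `evalue`.
#' @return An object of class `family_assignment`: `query_id`, `family`
#'   (name or `NA`), `best_hit` (id or `NA`), `significance`, `backend`.
#' @export
assign_family <- function(query, db, threshold = 0.05,
                          backend = c("internal", "external"),
                          matrix = NULL, penalties = gap_penalties(11, 1),
                          n_shuffles = 200L, seed = 1L,
                          query_id = "query", hits = NULL) {
  backend <- match.arg(backend)
  active <- db_active(db)
  active <- active[active$id != query_id, , drop = FALSE]
  if (!nrow(active)) stop("database is empty after exclusions")
  if (backend == "internal") {
    if (is.null(matrix)) stop("internal backend requires a similarity matrix")
    enc <- grid_encoding(matrix)
    q <- match(chars(toupper(query)), enc$letters) - 1L
    dbseqs <- lapply(active$sequence,
                     function(s) match(chars(s), enc$letters) - 1L)
    obs <- .sw_best_scores_cpp(q, dbseqs, enc$S, penalties$alpha,
                               penalties$beta)
    best_score <- max(obs)
    cand <- active$id[obs == best_score]
    best_id <- sort(cand)[1L]
    null_max <- with_seed(derive_seed(seed, query_id), {
      vapply(seq_len(n_shuffles), function(s) {
        max(.sw_best_scores_cpp(sample(q), dbseqs, enc$S,
                                penalties$alpha, penalties$beta))
      }, 0L)
    })
    signif <- (1 + sum(null_max >= best_score)) / (1 + n_shuffles)
  } else {
    if (is.null(hits)) stop("external backend requires a 'hits' table")
    need <- c("query", "subject", "evalue")
    if (!all(need %in% names(hits)))
      stop("hits table must have columns: ", paste(need, collapse = ", "))
    h <- hits[hits$query == query_id & hits$subject %in% active$id, ,
              drop = FALSE]
    if (!nrow(h)) {
      signif <- Inf; best_id <- NA_character_
    } else {
      best_e <- min(h$evalue)
      cand <- h$subject[h$evalue == best_e]
      if (length(cand) > 1L && "bitscore" %in% names(h)) {
        bs <- h$bitscore[h$evalue == best_e]
        cand <- cand[bs == max(bs)]
      }
      best_id <- sort(cand)[1L]
      signif <- best_e
    }
  }
  assigned <- !is.na(best_id) && signif < threshold
  structure(list(query_id = query_id,
                 family = if (assigned)
                   active$family[active$id == best_id] else NA_character_,
                 best_hit = if (assigned) best_id else NA_character_,
                 significance = signif, backend = backend),
            class = "family_assignment")
}

#' Matrix/penalty store for the adaptive aligner
#'
#' @param matrices Named list of [similarity_matrix()] keyed by family.
#' @param penalties Named list of [gap_penalties()] keyed by family.
#' @return An object of class `matrix_store`.
#' @export
matrix_store <- function(matrices, penalties) {
  if (!setequal(names(matrices), names(penalties)))
    stop("matrices and penalties must cover the same family names")
  structure(list(matrices = matrices, penalties = penalties),
            class = "matrix_store")
}

#' Select the scoring function for a pair of family assignments
#'
#' If both sequences are assigned to the same family, that family's
#' matrix and its optimized gap penalties are selected. If the
#' assignments differ, or at least one sequence received no assignment,
#' the general-purpose fallback with the default penalties (15, 1) is
#' selected. A same-family assignment whose matrix is missing from the
#' store falls back with a warning (store incompleteness, not user
#' error).
#'
#' @param assign_a,assign_b `family_assignment`s for the two sequences.
#' @param store A [matrix_store()].
#' @param fallback General-purpose [similarity_matrix()].
#' @param default_penalties Fallback penalties (default (15, 1)).
#' @return List with `matrix`, `penalties`, `provenance` (`"family"` or
#'   `"general"`) and `family` (name or `NA`).
#' @export
select_scoring <- function(assign_a, assign_b, store, fallback,
                           default_penalties = gap_penalties(15, 1)) {
  fam_a <- assign_a$family; fam_b <- assign_b$family
  if (!is.na(fam_a) && !is.na(fam_b) && fam_a == fam_b) {
    if (fam_a %in% names(store$matrices))
      return(list(matrix = store$matrices[[fam_a]],
                  penalties = store$penalties[[fam_a]],
                  provenance = "family", family = fam_a))
    warning("no stored matrix for family '", fam_a,
            "'; falling back to the general-purpose matrix")
  }
  list(matrix = fallback, penalties = default_penalties,
       provenance = "general", family = NA_character_)
}

#' Adaptive family-specific global alignment
#'
#' Runs two independent family searches (one per input sequence, each
#' excluding both query ids from the database), selects the scoring
#' function by the same-family rule of [select_scoring()], and aligns the
#' pair globally. The report records the backend, both assignments and
#' significances, and the matrix and penalties used, so a run is fully
#' reproducible.
#'
#' @param seq_a,seq_b Ungapped input sequences.
#' @param db A [family_database()].
#' @param store A [matrix_store()].
#' @param fallback General-purpose [similarity_matrix()].
#' @param id_a,id_b Input sequence ids (also self-excluded from the
#'   search when present in the database).
#' @param default_penalties Fallback penalties (default (15, 1)).
#' @param ... Passed to [assign_family()] (threshold, backend, matrix,
#'   seed, ...). The internal backend's search matrix defaults to
#'   `fallback`.
#' @return List with `alignment`, `score` and `report`.
#' @export
adaptive_align <- function(seq_a, seq_b, db, store, fallback,
                           id_a = "query_a", id_b = "query_b",
                           default_penalties = gap_penalties(15, 1), ...) {
  db2 <- exclude_ids(db, c(id_a, id_b))
  args <- list(...)
  if (is.null(args$matrix)) args$matrix <- fallback
  aa <- do.call(assign_family, c(list(query = seq_a, db = db2,
                                      query_id = id_a), args))
  ab <- do.call(assign_family, c(list(query = seq_b, db = db2,
                                      query_id = id_b), args))
  sel <- select_scoring(aa, ab, store, fallback, default_penalties)
  res <- global_align(seq_a, seq_b, sel$matrix, sel$penalties,
                      id_a = id_a, id_b = id_b)
  list(alignment = res$alignment, score = res$score,
       report = list(backend = aa$backend,
                     assignment_a = aa, assignment_b = ab,
                     provenance = sel$provenance, family = sel$family,
                     matrix = sel$matrix$name,
                     alpha = sel$penalties$alpha,
                     beta = sel$penalties$beta))
}
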