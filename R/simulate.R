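#' Define a synthetic family substitution model
#'
#' The generative model behind a synthetic reference group: aligned
#' residue-pair columns are emitted from a symmetric joint substitution
#' distribution, interleaved with indel runs of geometric length. The
#' joint distribution stands in for the evolutionary process that real
#' reference alignments (from structural superposition) sample.
#'
#' @param name Family name.
#' @param joint_sub_probs Symmetric non-negative 20x20 matrix summing to 1
#'   (full-matrix convention; the unordered probability of pair (i,j),
#'   i != j, is twice the entry).
#' @param indel_open_prob Probability of opening an indel run before a
#'   substitution column (default 0.03 per column, a realistic indel
#'   density for homologous single-domain proteins).
#' @param indel_extend_prob Geometric extension parameter; mean run length
#'   1/(1-p) (default 0.3, mean ~1.4 residues).
#' @param ancestor_coupling Star-phylogeny coupling s in [0, 1): each
#'   member residue copies a latent family ancestor residue with
#'   probability s, else draws from the background marginal. With s > 0
#'   all family members are homologous to each other (not only within a
#'   pair), which is what a real superfamily group looks like and what
#'   the adaptive aligner's database search needs. The induced joint
#'   distribution between any two members is
#'   s^2 diag(p) + (1-s^2) p p', so s > 0 is only valid when
#'   `joint_sub_probs` has that mixture form (checked); the default 0
#'   emits each pair independently from `joint_sub_probs`.
#' @return An object of class `family_model`.
#' @export
family_model <- function(name, joint_sub_probs, indel_open_prob = 0.03,
                         indel_extend_prob = 0.3,
                         ancestor_coupling = 0) {
  J <- as.matrix(joint_sub_probs)
  if (!all(dim(J) == c(20L, 20L))) stop("joint_sub_probs must be 20x20")
  if (is.null(dimnames(J))) dimnames(J) <- list(.AA, .AA)
  if (any(J < 0)) stop("joint_sub_probs must be non-negative")
  if (!isTRUE(all.equal(sum(J), 1, tolerance = 1e-8)))
    stop("joint_sub_probs must sum to 1")
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-10)))
    stop("joint_sub_probs must be symmetric")
  if (all(J == 0)) stop("degenerate model: all-zero probabilities")
  if (indel_open_prob < 0 || indel_open_prob >= 1 ||
      indel_extend_prob < 0 || indel_extend_prob >= 1)
    stop("indel probabilities must be in [0, 1)")
  if (ancestor_coupling < 0 || ancestor_coupling >= 1)
    stop("ancestor_coupling must be in [0, 1)")
  if (ancestor_coupling > 0) {
    p <- rowSums(J)
    s2 <- ancestor_coupling^2
    Jmix <- s2 * diag(p) + (1 - s2) * outer(p, p)
    if (!isTRUE(all.equal(unname(J), unname(Jmix), tolerance = 1e-6)))
      stop("ancestor_coupling > 0 requires joint_sub_probs of the ",
           "mixture form s^2*diag(p) + (1-s^2)*p%o%p")
  }
  structure(list(name = name, joint_sub_probs = J,
                 indel_open_prob = indel_open_prob,
                 indel_extend_prob = indel_extend_prob,
                 ancestor_coupling = ancestor_coupling),
            class = "family_model")
}

#' Random family model with controlled within-family identity
#'
#' Draws a family-specific residue preference p from a Dirichlet (so
#' different families favour different residues and cross-family identity
#' stays low) and mixes an identity-concentrated diagonal with the
#' independent-pair background:
#' J = identity_mass * diag(p) + (1 - identity_mass) * p p'.
#' The expected within-family column identity is about `identity_mass`
#' plus the background coincidence term.
#'
#' @param name Family name.
#' @param seed Integer seed.
#' @param identity_mass Diagonal (conserved-column) mass, default 0.6 —
#'   a moderately conserved homologous family.
#' @param concentration Dirichlet concentration (default 3; smaller values
#'   give more skewed, more family-distinctive residue usage).
#' @param indel_open_prob,indel_extend_prob See [family_model()].
#' @param ancestor_coupling Star-phylogeny coupling (see
#'   [family_model()]); defaults to `sqrt(identity_mass)`, which makes the
#'   member-to-member joint distribution equal the declared mixture and
#'   the whole family mutually homologous. Set to 0 for independent
#'   pairs (e.g. pure frequency-recovery checks).
#' @return A [family_model()].
#' @export
random_family_model <- function(name, seed, identity_mass = 0.6,
                                concentration = 3,
                                indel_open_prob = 0.03,
                                indel_extend_prob = 0.3,
                                ancestor_coupling = sqrt(identity_mass)) {
  p <- with_seed(seed, {
    g <- stats::rgamma(20L, shape = concentration)
    g / sum(g)
  })
  J <- identity_mass * diag(p) + (1 - identity_mass) * outer(p, p)
  J <- (J + t(J)) / 2
  dimnames(J) <- list(.AA, .AA)
  family_model(name, J / sum(J), indel_open_prob, indel_extend_prob,
               ancestor_coupling = ancestor_coupling)
}

# one aligned pair from a family model; returns a pairwise_alignment.
# `template` (optional) is the family ancestor's residue-index vector for
# ancestor-coupled emission.
sample_pair <- function(model, mean_len, id_a, id_b, template = NULL) {
  J <- model$joint_sub_probs
  p_marg <- rowSums(J)
  n_match <- max(10L, stats::rpois(1L, mean_len))
  if (is.null(template)) {
    cells <- sample.int(400L, n_match, replace = TRUE, prob = as.vector(J))
    # column-major: cell = (j-1)*20 + i
    ri <- ((cells - 1L) %% 20L) + 1L
    rj <- ((cells - 1L) %/% 20L) + 1L
  } else {
    n_match <- min(n_match, length(template))
    x <- template[seq_len(n_match)]
    s <- model$ancestor_coupling
    emit <- function() {
      copy <- stats::runif(n_match) < s
      out <- integer(n_match)
      out[copy] <- x[copy]
      out[!copy] <- sample.int(20L, sum(!copy), replace = TRUE,
                               prob = p_marg)
      out
    }
    ri <- emit(); rj <- emit()
  }
  ca <- .AA[ri]; cb <- .AA[rj]
  if (model$indel_open_prob > 0) {
    out_a <- character(0); out_b <- character(0)
    for (c in seq_len(n_match)) {
      if (stats::runif(1L) < model$indel_open_prob) {
        len <- 1L + stats::rgeom(1L, 1 - model$indel_extend_prob)
        ins <- sample(.AA, len, replace = TRUE, prob = p_marg)
        if (stats::runif(1L) < 0.5) {
          out_a <- c(out_a, ins); out_b <- c(out_b, rep("-", len))
        } else {
          out_a <- c(out_a, rep("-", len)); out_b <- c(out_b, ins)
        }
      }
      out_a <- c(out_a, ca[c]); out_b <- c(out_b, cb[c])
    }
    ca <- out_a; cb <- out_b
  }
  pairwise_alignment(id_a, id_b, paste(ca, collapse = ""),
                     paste(cb, collapse = ""))
}

#' Sample a synthetic reference group
#'
#' Generates `n_pairs` reference pairwise alignments from a family model:
#' substitution columns drawn from the joint distribution, indel runs of
#' geometric length assigned to either row with equal probability (never
#' producing an all-gap column, because runs are inserted at column
#' boundaries). The emitted alignment is stored as the reference; the
#' ungapped rows are the member sequences.
#'
#' @param model A [family_model()].
#' @param n_pairs Number of reference pairs (>= 1).
#' @param mean_len Mean ungapped match length (>= 10; default 100,
#'   a typical single-domain protein length).
#' @param seed Integer seed.
#' @param subset_tag Group subset tag (default `"SUP"`).
#' @return A [reference_group()] named after the model.
#' @export
sample_reference_group <- function(model, n_pairs, mean_len = 100L, seed = 1L,
                                   subset_tag = "SUP") {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (mean_len < 10L) stop("mean_len must be >= 10")
  alignments <- with_seed(derive_seed(seed, model$name), {
    template <- if (model$ancestor_coupling > 0)
      sample.int(20L, mean_len * 3L, replace = TRUE,
                 prob = rowSums(model$joint_sub_probs))
    lapply(seq_len(n_pairs), function(k)
      sample_pair(model, mean_len,
                  sprintf("%s_p%02d_a", model$name, k),
                  sprintf("%s_p%02d_b", model$name, k),
                  template = template))
  })
  reference_group(model$name, alignments, subset_tag)
}

#' Build a full synthetic benchmark
#'
#' Generates one reference group per family model, a family-labelled
#' sequence database over all member sequences (for adaptive-alignment
#' tests), and truth tables (the generating joint distributions and true
#' family labels) for parameter-recovery assertions.
#'
#' @param models List of [family_model()]s with distinct names.
#' @param pairs_per_family Reference pairs per group (default 12).
#' @param mean_len Mean match length (default 100).
#' @param seed Integer seed; the whole benchmark is a deterministic
#'   function of it.
#' @return List with `groups` (named list of [reference_group()]),
#'   `db` (a [family_database()]) and `truth` (named list with the
#'   generating `joint` and `labels`).
#' @export
make_benchmark <- function(models, pairs_per_family = 12L, mean_len = 100L,
                           seed = 1L) {
  nms <- vapply(models, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate family names")
  if (length(models) < 2L) stop("need at least 2 family models")
  groups <- lapply(models, sample_reference_group,
                   n_pairs = pairs_per_family, mean_len = mean_len,
                   seed = seed)
  names(groups) <- nms
  ids <- unlist(lapply(groups, function(g) names(g$sequences)))
  seqs <- unlist(lapply(groups, function(g) unname(g$sequences)))
  fams <- rep(nms, vapply(groups, function(g) length(g$sequences), 0L))
  truth <- lapply(models, function(m) list(joint = m$joint_sub_probs))
  names(truth) <- nms
  list(groups = groups,
       db = family_database(ids, fams, seqs),
       truth = list(joint = truth,
                    labels = stats::setNames(fams, ids)))
}

#' Write a benchmark to the standard on-disk layout
#'
#' One directory per group holding aligned-FASTA pair files, a
#' `database.fasta` of all member sequences, and a `families.tsv` label
#' table — the layout consumed by the command-line workflows.
#'
#' @param bench A [make_benchmark()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in bench$groups) {
    gdir <- file.path(dir, "groups", g$name)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(g$alignments))
      write_fasta(g$alignments[[k]],
                  file.path(gdir, sprintf("pair%03d.fasta", k)))
  }
  recs <- lapply(seq_len(nrow(bench$db$records)), function(i)
    list(id = bench$db$records$id[i],
         sequence = bench$db$records$sequence[i]))
  write_fasta(recs, file.path(dir, "database.fasta"))
  utils::write.table(
    data.frame(id = bench$db$records$id, family = bench$db$records$family),
    file.path(dir, "families.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
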