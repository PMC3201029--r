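---
title: "Family-specific similarity matrices for global protein alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-specific similarity matrices for global protein alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmalign)
```

## The problem

Global pairwise alignment of protein sequences by dynamic programming is
driven by a scoring function: a 20x20 amino acid similarity matrix plus
affine gap penalties. General-purpose matrices (BLOSUM, PAM, VTML, ...)
average substitution frequencies over the whole protein universe, so
family-specific substitution patterns are averaged out. When the two
sequences being aligned are known — or can be inferred — to belong to one
protein family, a matrix derived from that family's own reference
alignments can place gaps and equivalences closer to the structural
truth. `fsmalign` implements the full framework: matrix derivation from
reference alignments, the alignment engine, a statistically careful
evaluation protocol, analytics over collections of derived matrices, an
adaptive aligner that picks the family matrix automatically, and a
synthetic benchmark generator that makes all of it testable without any
external download.

## The derivation model

Reference pairwise alignments for a group (a protein family or a
structural fold) are reduced to counts `f(i,j)` of unordered aligned
residue pairs; gap columns and columns containing non-standard residue
codes contribute nothing. With `n` total pairs, the model is

* observed pair frequencies `q(i,j) = f(i,j)/n`,
* residue frequencies `p(i) = q(i,i) + sum_{j != i} q(i,j)/2`,
* expected frequencies `e(i,i) = p(i)^2`, `e(i,j) = 2 p(i) p(j)`,
* a blend weight `w = 1 - 10^(-n/8000)`.

Each derived element is the weighted combination of the group-specific
half-bit log-odds score and a general-purpose fallback score `v(i,j)`:

```
s(i,j) = round( w * 2*log2(q~(i,j)/e(i,j)) + (1-w) * v(i,j) )
```

so tiny groups reproduce the fallback and data-rich groups converge to
their own log-odds. `blend_weight(0) = 0`, `blend_weight(8000) = 0.9`
exactly, and the weight rises strictly with `n`. The constant 8000 is a
tunable (`blend_constant`); its default is the value selected by grid
search in the study the model comes from.

Two numerical choices are deliberately explicit because the source
description leaves them open:

* **What the weight multiplies.** The typeset formula is ambiguous; the
  text ("the weighted combination of the group-specific score and the
  general score") supports a convex combination of the two *scores*,
  which is the default (`eq1 = "score-blend"`). The alternative — blend
  in frequency space before the logarithm, using the fallback's implied
  pair frequency `e * 2^(v/2)` — is available as
  `eq1 = "frequency-blend"` for sensitivity checks; the two agree as
  `w -> 1` and as `w -> 0`.
* **Zero counts.** The log-odds is undefined at `q = 0`, and the source
  is silent on smoothing (its data scale may simply never have hit a
  zero). We use background-proportional pseudocounts
  `q~ = (f + mass*e)/(n + mass)` with `mass = 1` by default: the unit
  sum is preserved, rare pairs stay finite, and the correction vanishes
  as `n` grows, so the convergence property above is untouched. Cells
  whose *expected* frequency is exactly zero (a residue never observed
  in the group at all) take the fallback score verbatim.
* **Rounding** is to the nearest integer, ties away from zero.

The eligibility floor — at least 10 reference alignments per group —
applies to the *group*. Inside cross-validation the training split of an
eligible group is necessarily smaller (8 of 12 pairs, say), so
derivation within a training fold overrides the floor; any published
use of 3-fold cross-validation with a 10-alignment floor implies the
same.

## The alignment engine

`global_align()` is a three-state (Gotoh) Needleman–Wunsch with the
affine cost `G(m) = alpha + (m-1)*beta` per gap run: a length-1 gap
costs `alpha`, each extension `beta`. Penalties are positive magnitudes;
quoted defaults like "-15/-1" are interpreted as `(15, 1)`, consistent
with the positive grid-search ranges. Scoring is integer throughout, so
there are no floating-point ties. Traceback ties are broken
deterministically — diagonal, then gap-in-b (up), then gap-in-a (left),
from the terminal cell — so repeated runs and cross-implementations can
match column for column. End gaps are charged like internal gaps (true
global alignment); a `free_end_gaps` flag exposes semi-global mode but
is off by default, because the benchmark protocol we mirror describes
plain global alignment. `local_align()` (Smith–Waterman) exists for the
adaptive module's internal homology search; its score is never negative
and an empty alignment is legal.

The C++ kernels are cross-checked in the test suite by two independent
oracles: exhaustive enumeration of all global alignments for short
sequences (exact, any penalty combination), and
`Biostrings::pairwiseAlignment` for longer ones (mapped via
`gapOpening = alpha - beta`, `gapExtension = beta`, valid when
`alpha >= beta`).

## Evaluating scoring functions

A test alignment is scored against its reference with
`Q = (f_D + f_M)/2`, where `f_D = n_I/l_R * 100` (developer score) and
`f_M = n_I/l_T * 100` (modeler score); `n_I` counts residue pairs
aligned identically in both, and `l_R`, `l_T` are the reference and
test counts of aligned residue pairs. With this normalization
`Q = 100` exactly when the two alignments agree on every residue pair —
the defining property of the measure. (Normalizing by column counts
including gap columns would break that identity for any gapped
reference.)

Gap penalties are optimized per group and matrix by exhaustive grid
search over integer `1 <= alpha <= 50`, `1 <= beta <= 30`, maximizing
mean training `Q`; ties go to the smallest `alpha`, then `beta`. To
avoid overfitting, per-pair `Q` scores come from 3-fold
cross-validation: a seeded shuffle partitions the group's pairs into
three folds of near-equal size; for each fold the other two train
(derive the matrix, for group-specific scoring, then optimize
penalties) and the held-out pairs are scored once. Training never sees
test-fold alignments; the returned trace records each fold's training
artifacts so leakage is auditable, and the test suite asserts that
removing a test-fold pair leaves the fold's trained matrix and
penalties byte-identical.

Two scoring functions are compared per group by a two-sided paired
t-test on the per-pair `Q` vectors (`t = mean(d)/(sd(d)/sqrt(n))`,
Student's t with `n-1` df; all-zero differences give `t = 0, p = 1`).
Significance is `p < 0.05`; matrices "performing similarly" are defined
by `p > 0.1`, and the band `0.05 <= p <= 0.1` (a trend toward
significance) is excluded from the better/similar contrast. No
multiple-testing correction is applied across groups, matching the
per-group testing protocol we mirror. Collections of derived matrices
are summarized by `average_delta()` (mean element difference from the
fallback) and `performance_contrast()` (mean tables of
better-performing vs similar-performing matrices and their difference).

## Adaptive alignment

When family membership is unknown, each input sequence is assigned by
homology search against a family-labelled database (excluding the test
sequences themselves). If both sequences land in the same family, that
family's matrix and optimized penalties are used; otherwise — different
families, or no significant hit — the general-purpose fallback at
`(15, 1)` is used, so every valid input pair gets a valid alignment.

The original procedure used BLASTP with an E-value threshold of 0.05.
To keep this package hermetic (testable offline with no external
binary), the default backend is internal: Smith–Waterman with the
fallback matrix at `(11, 1)`, with significance estimated as an
empirical p-value of the best hit score against a null of 200 shuffled
copies of the query (seeded per query id, so runs are reproducible).
The shuffle null preserves query length and composition, which is the
property an E-value calibrates against; the 0.05 threshold carries
over. An external adapter consumes standard tabular search output
(`query`, `subject`, `evalue` columns) from any search tool for users
who want exact BLASTP behaviour; the original BLASTP parameterization
is not fixed because it was never specified.

## The synthetic benchmark and what a green test establishes

`sample_reference_group()` emits reference alignments column by column:
substitution columns from a family's symmetric joint distribution,
interleaved with indel runs of geometric length placed in either row
with equal probability (never creating an all-gap column). Defaults,
chosen once as realistic for homologous single-domain proteins: mean
ungapped length 100, indel opening probability 0.03 per column,
geometric extension 0.3 (mean run ~1.4), within-family identity mass
0.6, and per-family residue preferences drawn from a Dirichlet
(concentration 3) so families differ in composition and cross-family
identity stays low (~5% expected).

`random_family_model()` additionally couples all members of a family to
a latent ancestor sequence: each member residue copies the ancestor
with probability `s = sqrt(identity_mass)`, else draws from the family
background. For the mixture-form joint this induces *exactly* the
declared pair distribution between any two members, while making the
whole family mutually homologous — which is what the adaptive module's
database search requires, and what independent per-pair emission cannot
provide. Pure frequency-recovery tests set `ancestor_coupling = 0` so
the empirical pair counts converge to the declared joint; this is also
the regime in which `derive_matrix()` provably converges to
`round(2*log2(P/e))` of the generating model, the suite's central
derivation oracle.

The generator emulates substitution statistics and affine-gap geometry;
it does not emulate protein structure, position-specific conservation,
phylogenetic correlation beyond the star ancestor, or multi-domain
architecture. A green test suite therefore establishes that the
machinery — counting, blending, aligning, grid search,
cross-validation, testing, routing — is correct on data whose truth is
known, not that family-specific matrices improve alignment on any
particular real benchmark: that empirical claim requires the real
reference data, which is an external input to this package.

## Known limitations

* The bundled general-purpose matrices are BLOSUM62 and BLOSUM50; the
  VTML200 matrix used as the fallback in the original study is not
  redistributable here, but any EMBOSS/NCBI-format matrix file can be
  supplied to `read_matrix()` and used as the fallback everywhere.
* The aligner is a plain O(nm) dynamic program without banding or
  vectorization; the grid search is exhaustive by design.
* Single-domain sequences are assumed throughout; the adaptive
  procedure has no domain segmentation.
* The internal search backend's empirical p-value saturates at
  `1/(n_shuffles+1)`, so with the default 200 shuffles the smallest
  reportable significance is ~0.005.

## A minimal session

```{r example}
fb <- read_matrix(bundled_matrix("BLOSUM62"))
models <- lapply(1:2, function(k)
  random_family_model(paste0("fam", k), seed = k))
bench <- make_benchmark(models, pairs_per_family = 12, mean_len = 60,
                        seed = 42)
fam1 <- derive_matrix(bench$groups[[1]], fb)
fam1$scores[1:6, 1:6]

ref <- bench$groups[[1]]$alignments[[1]]
sq <- aligned_sequences(ref)
res <- global_align(sq[[1]], sq[[2]], fam1, gap_penalties(15, 1))
quality(res$alignment, ref)$q
```
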