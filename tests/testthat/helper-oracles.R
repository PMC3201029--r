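# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately avoid the package's dynamic-programming code paths.

AA <- aa_alphabet()

split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Exhaustive enumeration of every global alignment of two short sequences,
# scored with the affine law alpha + (m-1)*beta per gap run. Pure
# recursion over column choices; no memoization, no DP.
enum_global_score <- function(a, b, sc, alpha, beta) {
  ca <- split1(a); cb <- split1(b)
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m)
      best <- max(best, sc[ca[i + 1], cb[j + 1]] + rec(i + 1, j + 1, "M"))
    if (i < n)
      best <- max(best, -(if (prev == "X") beta else alpha) +
                    rec(i + 1, j, "X"))
    if (j < m)
      best <- max(best, -(if (prev == "Y") beta else alpha) +
                    rec(i, j + 1, "Y"))
    best
  }
  rec(0L, 0L, "none")
}

# Brute-force local score: best global score over all substring pairs
# (including the empty alignment at 0).
enum_local_score <- function(a, b, sc, alpha, beta) {
  ca <- split1(a); cb <- split1(b)
  n <- length(ca); m <- length(cb)
  best <- 0
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:m) for (j2 in j1:m) {
    s <- enum_global_score(paste(ca[i1:i2], collapse = ""),
                           paste(cb[j1:j2], collapse = ""),
                           sc, alpha, beta)
    if (s > best) best <- s
  }
  best
}

# Random symmetric integer similarity matrix (positive-leaning diagonal,
# mixed off-diagonal), as a similarity_matrix object.
random_similarity_matrix <- function(seed, lo = -6L, hi = 6L) {
  set.seed(seed)
  s <- matrix(sample(lo:hi, 400L, replace = TRUE), 20L, 20L)
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- abs(diag(s)) + 2L
  similarity_matrix(s, name = paste0("random", seed))
}

random_seq <- function(len) paste(sample(AA, len, replace = TRUE),
                                  collapse = "")

# Tiny deterministic benchmark shared by evaluation/adaptive unit tests
# (kept small so unit tests stay fast; acceptance tests build their own).
tiny_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      models <- lapply(1:2, function(k)
        random_family_model(sprintf("tfam%d", k), seed = 100 + k))
      cache <<- make_benchmark(models, pairs_per_family = 6L,
                               mean_len = 40L, seed = 11L)
    }
    cache
  }
})

# A scrambled version of a similarity matrix: the 210 unordered-pair
# entries are randomly permuted (seeded) and the table rebuilt
# symmetrically. The score distribution is preserved but the mapping from
# residue pairs to scores — including the identity reward on the
# diagonal — is destroyed.
scramble_matrix <- function(m, seed = 1L) {
  set.seed(seed)
  ut <- upper.tri(m$scores, diag = TRUE)
  s <- matrix(0L, 20L, 20L, dimnames = dimnames(m$scores))
  s[ut] <- sample(m$scores[ut])
  s <- s + t(s) - diag(diag(s))
  similarity_matrix(s, name = paste0(m$name, "_scrambled"))
}
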