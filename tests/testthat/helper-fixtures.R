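# Shared helpers: hand-built genotype tables and small cached fixtures.

# Construct a genotype_table directly from allele matrices, for tests that
# need full control over every call.
make_genotype_table <- function(a1, a2, role, family = NULL,
                                loci = NULL) {
  ids <- rownames(a1)
  structure(list(ids = ids, role = role,
                 family = family %||% rep(NA_character_, length(ids)),
                 a1 = a1, a2 = a2, loci = loci, pedigree = NULL),
            class = "genotype_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small fixture reused across files (built once per test run).
small_fx <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture("small", seed = 11)
    cache
  }
})

# Equifrequent panel used by the relatedness calibration tests.
equal_panel <- function(n_loci = 11, n_alleles = 11)
  locus_panel(n_loci = n_loci, n_alleles = n_alleles, freq = "equal",
              allele_range = c(2, 19))

# Independent brute-force grid search over the IBD-coefficient simplex,
# used as an oracle for the dyadml optimizer.
grid_search_dyad <- function(P, step = 0.01) {
  k1 <- seq(0, 1, by = step)
  best <- list(loglik = -Inf)
  for (x in k1) for (y in seq(0, 1 - x, by = step)) {
    k <- c(1 - x - y, x, y)
    ll <- sum(log(pmax(P %*% k, 1e-300)))
    if (ll > best$loglik) best <- list(k = k, loglik = ll)
  }
  best
}

# Per-locus IBD-mode probabilities recomputed independently of the package
# internals (direct translation of the non-inbred dyad model).
modes_oracle <- function(g1, g2, p) {
  gp <- function(x, y) if (x == y) p[x]^2 else 2 * p[x] * p[y]
  P0 <- gp(g1[1], g1[2]) * gp(g2[1], g2[2])
  P2 <- if (setequal_multiset(g1, g2)) gp(g1[1], g1[2]) else 0
  P1 <- 0
  for (z in unique(g1[g1 %in% g2])) {
    o1 <- if (g1[1] == z) g1[2] else g1[1]
    o2 <- if (g2[1] == z) g2[2] else g2[1]
    P1 <- P1 + p[z] * p[o1] * p[o2]
  }
  c(P0, P1, P2)
}
setequal_multiset <- function(a, b) all(sort(a) == sort(b))

# All unordered single-locus genotypes over A alleles.
all_genotypes <- function(A) {
  g <- rbind(cbind(seq_len(A), seq_len(A)),
             if (A > 1) t(utils::combn(A, 2)))
  g
}
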