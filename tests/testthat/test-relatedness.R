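test_that("allele frequencies are estimated by counting", {
  a1 <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("i1", "i2"), "L1"))
  a2 <- matrix(c(1L, 2L), 2, 1, dimnames = list(c("i1", "i2"), "L1"))
  g <- make_genotype_table(a1, a2, role = rep("offspring", 2))
  fr <- estimate_allele_frequencies(g)
  expect_equal(unname(fr$L1$freq), c(0.75, 0.25))

  a2[2, 1] <- 1L
  mono <- make_genotype_table(a1, a2, role = rep("offspring", 2))
  expect_warning(estimate_allele_frequencies(mono), "monomorphic")

  # estimated frequencies are valid distributions over observed alleles
  d <- build_design(blocks = 6, mating = mating_design(4), seed = 21)
  panel <- locus_panel(n_loci = 3, seed = 21)
  geno <- simulate_genotypes(d, panel, mating_design(4), seed = 21)
  est <- estimate_allele_frequencies(geno)
  for (l in names(panel)) {
    expect_equal(sum(est[[l]]$freq), 1)
    expect_true(all(est[[l]]$freq > 0))
    expect_true(all(names(est[[l]]$freq) %in% names(panel[[l]]$freq)))
  }
})

test_that("single-locus dyad likelihood matches the IBD-mode algebra", {
  fr <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  # no shared allele: only the IBD-0 mode contributes
  k <- c(0.2, 0.5, 0.3)
  l_ab_cd <- dyad_locus_likelihood(c("a", "b"), c("c", "d"), fr, k)
  expect_equal(l_ab_cd, 0.2 * (2 * 0.4 * 0.3) * (2 * 0.2 * 0.1))
  # unrelated limit: likelihood is the product of genotype probabilities
  expect_equal(dyad_locus_likelihood(c("a", "a"), c("a", "b"), fr,
                                     c(1, 0, 0)),
               0.4^2 * 2 * 0.4 * 0.3)
  expect_error(dyad_locus_likelihood(c("z", "a"), c("a", "b"), fr, k),
               "absent")
  expect_error(dyad_locus_likelihood(c("a", "a"), c("a", "b"), fr,
                                     c(0.5, 0.4, 0.3)), "probability")
})

test_that("IBD-mode probability tables sum to one over all genotype pairs", {
  for (A in 2:5) {
    set.seed(A)
    p <- runif(A) + 0.1
    p <- p / sum(p)
    names(p) <- as.character(seq_len(A))
    gts <- all_genotypes(A)
    tot <- c(0, 0, 0)
    for (i in seq_len(nrow(gts))) for (j in seq_len(nrow(gts))) {
      g1 <- as.character(gts[i, ]); g2 <- as.character(gts[j, ])
      tot <- tot + vapply(
        list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
        function(k) dyad_locus_likelihood(g1, g2, p, k), 1)
    }
    expect_equal(tot, c(1, 1, 1), tolerance = 1e-12)
  }
})

test_that("the likelihood tables match an independent re-derivation", {
  set.seed(31)
  p <- runif(5) + 0.05
  p <- p / sum(p)
  names(p) <- as.character(1:5)
  for (rep in 1:30) {
    g1 <- sample(1:5, 2, TRUE)
    g2 <- sample(1:5, 2, TRUE)
    for (mode in 1:3) {
      k <- c(0, 0, 0); k[mode] <- 1
      expect_equal(
        dyad_locus_likelihood(as.character(g1), as.character(g2), p, k),
        modes_oracle(g1, g2, unname(p))[mode])
    }
  }
})

test_that("dyadml matches a brute-force grid search and dominates the vertices", {
  panel <- equal_panel(n_loci = 8, n_alleles = 6)
  dy <- simulate_dyads(6, "half", loci = panel, seed = 41, estimate = FALSE)
  for (d in dy) {
    fit <- dyadml(d$g1, d$g2, panel)
    P <- t(vapply(seq_len(ncol(d$g1)), function(l)
      modes_oracle(d$g1[, l], d$g2[, l], unname(panel[[l]]$freq)),
      numeric(3)))
    oracle <- grid_search_dyad(P, step = 0.01)
    expect_gte(fit$loglik, oracle$loglik - 1e-9)
    # within one 0.01 grid step of the oracle in likelihood
    expect_lt(abs(fit$loglik - oracle$loglik), 0.05)
    # optimum dominates the simplex vertices
    for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
      expect_gte(fit$loglik, sum(log(pmax(P %*% v, 1e-300))) - 1e-9)
    expect_equal(fit$k0 + fit$k1 + fit$k2, 1, tolerance = 1e-9)
    expect_equal(fit$r, fit$k1 / 2 + fit$k2)
  }
})

test_that("relatedness is symmetric and invariant to allele relabeling", {
  panel <- locus_panel(n_loci = 6, n_alleles = 6, freq = "dirichlet",
                       seed = 7)
  dy <- simulate_dyads(4, "full", loci = panel, seed = 43,
                       estimate = FALSE)
  set.seed(43)
  for (d in dy) {
    f12 <- dyadml(d$g1, d$g2, panel)
    f21 <- dyadml(d$g2, d$g1, panel)
    expect_equal(f12$r, f21$r)
    expect_equal(f12$loglik, f21$loglik)
    # relabel alleles by a fixed permutation at every locus
    perm <- sample(6)
    relab <- function(g) matrix(perm[g], nrow = 2,
                                dimnames = dimnames(g))
    panel2 <- lapply(panel, function(lo)
      locus_model(lo$locus_id, unname(lo$freq[order(perm)])))
    f_rel <- dyadml(relab(d$g1), relab(d$g2), panel2)
    expect_equal(f_rel$r, f12$r, tolerance = 1e-9)
  }
})

test_that("identical genotypes with informative loci push relatedness high", {
  set.seed(17)
  panel <- equal_panel(n_loci = 12, n_alleles = 12)
  g <- vapply(panel, function(lo) sample.int(12, 2), numeric(2))
  colnames(g) <- names(panel)
  fit <- dyadml(g, g, panel)
  expect_gte(fit$r, 0.5)
})

test_that("mean estimates track pedigree expectations for simulated sib classes", {
  # moderate-n calibration; the full 500-dyad check runs in the acceptance
  # suite. Constrained ML cannot go below r = 0, so unrelated dyads carry
  # a small positive boundary bias; assert it stays modest.
  full <- simulate_dyads(150, "full", seed = 51)
  half <- simulate_dyads(150, "half", seed = 52)
  unrel <- simulate_dyads(150, "unrelated", seed = 53)
  expect_lt(abs(mean(full$r) - 0.5), 0.04)
  expect_lt(abs(mean(half$r) - 0.25), 0.04)
  expect_gte(min(unrel$r), 0)
  expect_lt(mean(unrel$r), 0.09)
  expect_true(all(full$loci_used == 11))
})

test_that("missing data handling: pairs without co-typed loci are reported missing", {
  panel <- equal_panel(n_loci = 3, n_alleles = 4)
  g1 <- matrix(c(1L, 2L, NA, NA, 3L, 4L), 2)
  g2 <- matrix(c(NA, NA, 1L, 2L, NA, NA), 2)
  colnames(g1) <- colnames(g2) <- names(panel)
  fit <- dyadml(g1, g2, panel)
  expect_true(is.na(fit$r))
  expect_equal(fit$loci_used, 0)
})

test_that("plot summaries compute lineage counts and mean within-plot relatedness", {
  fx <- small_fx()
  freqs <- estimate_allele_frequencies(fx$geno)
  ok <- fx$maternity$status %in% c("assigned", "flagged_one_mismatch")
  analyzable <- intersect(
    fx$design$sapling_id[fx$design$alive & fx$design$genotyped %in% TRUE],
    fx$maternity$offspring_id[ok])
  pairs <- do.call(rbind, lapply(unique(fx$design$plot), function(pl) {
    v <- intersect(fx$design$sapling_id[fx$design$plot == pl], analyzable)
    if (length(v) < 2) return(NULL)
    t(combn(v, 2))
  }))
  rel <- relatedness_matrix(fx$geno, freqs, pairs = pairs)
  ps <- plot_summaries(rel, fx$maternity, fx$design)
  expect_equal(nrow(ps), 6)
  expect_true(all(ps$GD <= ps$gd_planted))
  # relatedness declines with diversity; the two indices correlate negatively
  expect_gt(mean(ps$GR[ps$gd_planted == 1]),
            mean(ps$GR[ps$gd_planted == 2]))
  cmp <- gr_gd_comparison(ps)
  expect_lt(cmp$correlation, 0)
})
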