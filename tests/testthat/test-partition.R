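test_that("relative forage is a guarded ratio", {
  expect_equal(relative_forage(6, 6), 1)
  expect_equal(relative_forage(4, 6), 2 / 3, tolerance = 1e-12)
  expect_equal(relative_forage(0, 5), 0)
  expect_error(relative_forage(1, 0), "M_i")
  expect_error(relative_forage(-1, 2), "C_i")
})

test_that("the worked two-family partition matches the hand computation", {
  p <- partition_mixture(M = c(A = 6, B = 8), C = c(A = 4, B = 5))
  expect_equal(unname(p$RF_O), c(2 / 3, 5 / 8), tolerance = 1e-12)
  expect_equal(unname(p$dRC), c(1 / 6, 1 / 8), tolerance = 1e-12)
  expect_equal(p$NGDE, 2.0, tolerance = 1e-12)
  expect_equal(p$CE, 49 / 24, tolerance = 1e-12)   # 2.041667
  expect_equal(p$SE, -1 / 24, tolerance = 1e-12)   # -0.041667
  expect_equal(p$RF_E, c(0.5, 0.5))
})

test_that("proportional damage gives a null partition; equal deviations kill SE", {
  M <- c(5, 7, 9)
  null <- partition_mixture(M, C = M / 3)
  expect_equal(null$NGDE, 0, tolerance = 1e-12)
  expect_equal(null$CE, 0, tolerance = 1e-12)
  expect_equal(null$SE, 0, tolerance = 1e-12)
  # uniform relative over-consumption: all dRC equal -> SE = 0, NGDE = CE
  up <- partition_mixture(M, C = M * (1 / 3 + 0.1))
  expect_equal(up$SE, 0, tolerance = 1e-10)
  expect_equal(up$NGDE, up$CE, tolerance = 1e-12)
  expect_gt(up$CE, 0)
})

test_that("additivity and scaling invariance hold across random mixtures", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:4, 1)
    M <- runif(n, 0.5, 12)
    C <- runif(n, 0, 6)
    p <- partition_mixture(M, C)
    expect_equal(p$NGDE, p$CE + p$SE,
                 tolerance = 1e-10 * max(1, abs(p$NGDE)))
    # common positive rescaling scales effects, leaves ratios unchanged
    s <- runif(1, 0.2, 5)
    ps <- partition_mixture(s * M, s * C)
    expect_equal(ps$NGDE, s * p$NGDE, tolerance = 1e-9)
    expect_equal(ps$CE, s * p$CE, tolerance = 1e-9)
    expect_equal(ps$SE, s * p$SE, tolerance = 1e-9)
    expect_equal(ps$RF_O, p$RF_O, tolerance = 1e-12)
    expect_equal(ps$dRC, p$dRC, tolerance = 1e-12)
  }
})

test_that("simulated over-consumption and spill-over reproduce the sign contract", {
  set.seed(62)
  ce_vals <- se_vals <- numeric(200)
  for (i in 1:200) {
    M <- runif(4, 2, 10)
    # uniform over-consumption in mixture (+20% relative forage) -> CE > 0
    C_up <- (M / 4) * 1.2 * exp(rnorm(4, 0, 0.02))
    ce_vals[i] <- partition_mixture(M, C_up)$CE
    # spill-over: resistant families (small M) deviate upward -> SE < 0
    dev <- 1 + 0.4 * (mean(M) - M) / mean(M)
    se_vals[i] <- partition_mixture(M, (M / 4) * dev)$SE
  }
  expect_gt(mean(ce_vals), 0)
  expect_lt(mean(se_vals), 0)
})

test_that("cohort-wide partitioning yields one result per mixture with block-local references", {
  fx <- small_fx()
  pa <- partition_all(fx$pheno, fx$design, fx$maternity)
  expect_equal(nrow(pa), 2)               # one 2-family mixture per block
  expect_true(all(pa$gd == 2))
  fams <- attr(pa, "families")
  expect_equal(nrow(fams), 4)
  # monoculture-only designs give an empty result set
  d1 <- build_design(blocks = 1, mating = mating_design(1), seed = 1)
  ph1 <- simulate_herbivory(d1, seed = 1)
  expect_equal(nrow(partition_all(ph1, d1)), 0)
})

test_that("missing monoculture references are reported, not fabricated", {
  fx <- small_fx()
  ph <- fx$pheno
  # delete every monoculture sapling of family MT1 in block 1
  mono_plots <- unique(fx$design$plot[fx$design$gd == 1 &
                                        fx$design$family == "MT1" &
                                        fx$design$block == 1])
  ph2 <- ph[!(ph$plot %in% mono_plots), ]
  pa <- partition_all(ph2, fx$design, fx$maternity)
  bad <- pa[pa$block == 1, ]
  expect_false(any(bad$complete))
  expect_match(bad$reason, "monoculture")
})

test_that("one-sided t-tests match the textbook formula and handle the null edge", {
  x <- c(0.8, 1.4, -0.2, 0.5, 1.1, 0.9)
  res <- data.frame(block = 1, plot = paste0("p", 1:6), gd = 2,
                    NGDE = x, CE = x, SE = -x, complete = TRUE,
                    reason = NA)
  tt <- partition_tests(res)
  ngde <- tt[tt$effect == "NGDE", ]
  oracle <- t.test(x, alternative = "greater")
  expect_equal(ngde$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(ngde$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(ngde$df, 5)
  se <- tt[tt$effect == "SE", ]
  oracle_less <- t.test(-x, alternative = "less")
  expect_equal(se$p, oracle_less$p.value, tolerance = 1e-12)

  # all-zero effects: t = 0, one-sided p = 0.5
  res0 <- res
  res0$NGDE <- res0$CE <- res0$SE <- 0
  tt0 <- partition_tests(res0)
  expect_true(all(tt0$t == 0))
  expect_true(all(tt0$p == 0.5))
})

test_that("the across-diversity ANOVA reduces to the pooled t-test with two levels", {
  set.seed(63)
  res <- data.frame(block = 1, plot = paste0("p", 1:20),
                    gd = rep(2:3, each = 10),
                    NGDE = rnorm(20), CE = rnorm(20), SE = rnorm(20),
                    complete = TRUE, reason = NA)
  an <- partition_anova(res)
  t2 <- t.test(NGDE ~ gd, data = res, var.equal = TRUE)$statistic
  expect_equal(an$F[an$effect == "NGDE"], unname(t2^2), tolerance = 1e-10)
  # separated groups produce a large F
  res$CE <- res$CE + ifelse(res$gd == 2, 0, 50)
  an2 <- partition_anova(res)
  expect_gt(an2$F[an2$effect == "CE"], 100)
  expect_lt(an2$p[an2$effect == "CE"], 1e-10)
  expect_error(partition_anova(res[res$gd == 2, ]), "levels")
})

test_that("the ANOVA holds its type-I error rate under an exchangeable null", {
  set.seed(64)
  rej <- replicate(400, {
    res <- data.frame(block = 1, plot = paste0("p", 1:18),
                      gd = rep(2:4, each = 6),
                      NGDE = rnorm(18), CE = 0, SE = 0,
                      complete = TRUE, reason = NA)
    partition_anova(res, effects = "NGDE")$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})
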