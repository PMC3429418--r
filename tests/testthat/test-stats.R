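test_that("logit transform handles boundaries and inverts cleanly", {
  expect_equal(as.numeric(logit_transform(0.5, eps = 0.01)), 0)
  expect_equal(as.numeric(logit_transform(0.073, eps = 0)), -2.5416,
               tolerance = 1e-4)
  # default eps = half the smallest nonzero proportion
  x <- c(0, 0.04, 0.2)
  tr <- logit_transform(x)
  expect_equal(attr(tr, "eps"), 0.02)
  expect_true(all(is.finite(tr)))
  # strictly increasing
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(logit_transform(grid)) > 0))
  # exact round trip at eps = 0 on the interior
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(inv_logit(as.numeric(logit_transform(p, eps = 0))), p,
               tolerance = 1e-10)
  expect_error(logit_transform(1.2), "0, 1")
  expect_error(logit_transform(c(0, 0)), "eps")
})

test_that("standardization centres, scales, and preserves slope algebra", {
  expect_equal(standardize(1:3), c(-1, 0, 1))
  set.seed(71)
  x <- rnorm(100, 50, 9)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize(rep(3, 5)), "constant")
  # slope on standardized x equals raw slope times sd(x)
  y <- 2 + 0.7 * x + rnorm(100, 0, 0.5)
  raw <- coef(lm(y ~ x))[2]
  std <- coef(lm(y ~ z))[2]
  expect_equal(unname(std), unname(raw * sd(x)), tolerance = 1e-10)
})

test_that("model specs forbid GD and GR in one model and build formulas", {
  expect_error(model_spec("y", fixed = c("gd_std", "gr_std")),
               "separately")
  sp <- model_spec("y", fixed = c("h_std", "MT"),
                   interactions = "h_std:MT")
  expect_s3_class(sp, "model_spec")
})

# Shared simulated dataset with nested block/plot structure.
sim_mm_data <- function(n_plot = 40, n_per = 12, interaction = 0,
                        seed = 72) {
  set.seed(seed)
  block <- factor(rep(rep(1:4, length.out = n_plot), each = n_per))
  plot <- factor(rep(seq_len(n_plot), each = n_per))
  x1 <- rnorm(n_plot * n_per)
  x2 <- rep(rnorm(n_plot), each = n_per)
  y <- 1 + 0.5 * x1 + 0.3 * x2 + interaction * x1 * x2 +
    rep(rnorm(4, 0, 0.2), length.out = n_plot * n_per) +
    rep(rnorm(n_plot, 0, 0.2), each = n_per) + rnorm(n_plot * n_per)
  data.frame(y = y, x1 = x1, x2 = x2, block = block, plot = plot)
}

test_that("simplification drops absent interactions and keeps real ones", {
  dat <- sim_mm_data(interaction = 0)
  sp <- model_spec("y", fixed = c("x1", "x2"), interactions = "x1:x2")
  out <- simplify_model(sp, dat)
  expect_equal(out$spec$interactions, character(0))
  expect_equal(out$dropped, "x1:x2")
  expect_equal(out$spec$fixed, c("x1", "x2"))   # main effects survive

  strong <- sim_mm_data(interaction = 0.8)
  out2 <- simplify_model(sp, strong)
  expect_equal(out2$spec$interactions, "x1:x2")
  expect_equal(out2$dropped, character(0))

  # empty interaction set returns the model specification unchanged
  sp0 <- model_spec("y", fixed = c("x1", "x2"))
  out0 <- simplify_model(sp0, dat)
  expect_equal(out0$spec$fixed, sp0$fixed)
  expect_equal(out0$dropped, character(0))
})

test_that("simplification terminates within the interaction budget", {
  dat <- sim_mm_data(interaction = 0)
  dat$x3 <- rnorm(nrow(dat))
  sp <- model_spec("y", fixed = c("x1", "x2", "x3"),
                   interactions = c("x1:x2", "x1:x3"))
  out <- simplify_model(sp, dat)
  expect_lte(length(out$dropped) + length(out$spec$interactions), 2)
  expect_true(all(c("x1", "x2", "x3") %in% out$spec$fixed))
})

test_that("fit summaries report standardized coefficients invariant to rescaling", {
  d <- build_design(blocks = 6, mating = mating_design(4), seed = 73)
  ph <- simulate_herbivory(d, herbivory_effects(), seed = 73)
  fits <- fit_table1(ph)
  tab <- fits$table
  expect_true(all(c("ecto_GD", "miner_GD") %in% tab$model))
  # height effects recovered with the right signs
  h_ecto <- tab[tab$model == "ecto_GD" & tab$term == "h_std", ]
  expect_gt(h_ecto$estimate, 0)
  h_miner <- tab[tab$model == "miner_GD" & tab$term == "h_std", ]
  expect_gt(h_miner$estimate, 0)
  expect_lt(h_miner$p, 0.001)
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1, na.rm = TRUE))

  # affine rescaling of raw height leaves standardized coefficients alone
  ph2 <- ph
  ph2$height <- 100 * ph$height + 7
  fits2 <- fit_table1(ph2)
  h2 <- fits2$table[fits2$table$model == "ecto_GD" &
                      fits2$table$term == "h_std", ]
  expect_equal(h2$estimate, h_ecto$estimate, tolerance = 1e-6)
})

test_that("GD and GR slopes take opposite signs when the indices anticorrelate", {
  d <- build_design(blocks = 6, mating = mating_design(4), seed = 74)
  ph <- simulate_herbivory(d, herbivory_effects(gd_slope = 0.3),
                           seed = 74)
  # synthetic plot relatedness, negatively tied to lineage count as in a
  # half-sib cohort
  plots <- unique(ph[, c("plot", "gd")])
  set.seed(74)
  ps <- data.frame(plot = plots$plot,
                   GR = 0.45 - 0.1 * plots$gd + rnorm(nrow(plots), 0, 0.01))
  fits <- fit_table1(ph, plot_summary = ps)
  gd <- fits$table[fits$table$model == "ecto_GD" &
                     fits$table$term == "gd_std", "estimate"]
  gr <- fits$table[fits$table$model == "ecto_GR" &
                     fits$table$term == "gr_std", "estimate"]
  expect_gt(gd, 0)
  expect_lt(gr, 0)
})
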