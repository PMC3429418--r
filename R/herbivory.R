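#' Damage class table for visual herbivory scoring
#'
#' Visual assessment assigns each leaf's percentage of damaged area to one
#' of seven classes. Scoring converts a class back to a number via its
#' interval midpoint; the open top class (`>76`) is scored 88, the midpoint
#' of 76--100.
#'
#' @return Data frame with columns `class`, `lower`, `upper`, `score`.
#' @export
damage_classes <- function() {
  data.frame(
    class = c("0", "1-5", "6-15", "16-25", "26-50", "51-75", ">76"),
    lower = c(0, 0, 5, 15, 25, 50, 75),
    upper = c(0, 5, 15, 25, 50, 75, 100),
    score = c(0, 3, 10.5, 20.5, 38, 63, 88),
    stringsAsFactors = FALSE)
}

#' Classify percentage leaf damage and return the class midpoint score
#'
#' @param percent Numeric vector of damaged leaf-area percentages in
#'   `[0, 100]`.
#' @return Data frame with columns `percent`, `class` (factor over the seven
#'   classes) and `score` (class midpoint).
#' @examples
#' classify_damage(c(0, 3, 6.9, 80))
#' @export
classify_damage <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100))
    stop("percent leaf damage must lie in [0, 100]", call. = FALSE)
  dc <- damage_classes()
  idx <- ifelse(percent == 0, 1L,
                findInterval(percent, c(dc$lower[-1], Inf),
                             left.open = TRUE) + 1L)
  data.frame(percent = percent,
             class = factor(dc$class[idx], levels = dc$class),
             score = dc$score[idx])
}

#' Effect sizes and dispersions of the herbivory generator
#'
#' Parameters of the generative model for leaf damage by ectophagous
#' (externally feeding) insects and for leaf-miner counts. Ectophage damage
#' is generated leaf by leaf on the logit scale: family baseline (monoculture
#' mean) plus standardized plot genetic diversity (GD) and sapling height
#' effects plus Gaussian block, plot and leaf noise; each leaf's damage
#' percentage is then discretized through the visual scoring classes
#' ([classify_damage()]) and the 20 leaf scores averaged per sapling. Miner
#' abundance is Poisson on the log scale, driven by sapling height.
#'
#' Default effect sizes are standardized (per SD of the covariate):
#' `gd_slope = 0.06` and `height_slope_ecto = 0.05` on the logit scale,
#' `height_slope_miner = 0.31` on the log scale -- values typical of weak
#' but detectable diversity and apparency effects in oak sapling gardens.
#' Default monoculture family means span 5.5--8.3% of leaf area.
#'
#' @param family_means_monoculture Percent leaf area damaged per family in
#'   monoculture, in `(0, 100)`. `NULL` (default) spreads families evenly
#'   over 5.5--8.3%.
#' @param gd_slope Logit-scale effect of one SD of plot genetic diversity.
#' @param height_slope_ecto Logit-scale effect of one SD of height on
#'   ectophage damage.
#' @param height_slope_miner Log-scale effect of one SD of height on miner
#'   counts.
#' @param miner_intercept Log-scale baseline miner count per 20 leaves.
#' @param block_sd,plot_sd,leaf_sd Dispersions (logit scale) of block, plot
#'   and leaf-level noise; all must be `>= 0`.
#' @param height_meanlog_base,height_meanlog_spread,height_sdlog Family
#'   heights are lognormal; family-specific meanlog values are spread
#'   symmetrically (+/- `height_meanlog_spread`) around the base, giving a
#'   small but real family effect on height.
#' @param leaves_per_sapling Leaves scored per sapling (default 20).
#' @return An object of class `herbivory_effects`.
#' @export
herbivory_effects <- function(family_means_monoculture = NULL,
                              gd_slope = 0.06,
                              height_slope_ecto = 0.05,
                              height_slope_miner = 0.31,
                              miner_intercept = log(0.8),
                              block_sd = 0.15, plot_sd = 0.15, leaf_sd = 1.0,
                              height_meanlog_base = log(120),
                              height_meanlog_spread = 0.05,
                              height_sdlog = 0.25,
                              leaves_per_sapling = 20L) {
  if (any(c(block_sd, plot_sd, leaf_sd, height_sdlog) < 0))
    stop("dispersion parameters must be >= 0", call. = FALSE)
  if (!is.null(family_means_monoculture) &&
      (any(family_means_monoculture <= 0) ||
       any(family_means_monoculture >= 100)))
    stop("monoculture family means must lie in (0, 100)", call. = FALSE)
  structure(list(family_means_monoculture = family_means_monoculture,
                 gd_slope = gd_slope,
                 height_slope_ecto = height_slope_ecto,
                 height_slope_miner = height_slope_miner,
                 miner_intercept = miner_intercept,
                 block_sd = block_sd, plot_sd = plot_sd, leaf_sd = leaf_sd,
                 height_meanlog_base = height_meanlog_base,
                 height_meanlog_spread = height_meanlog_spread,
                 height_sdlog = height_sdlog,
                 leaves_per_sapling = as.integer(leaves_per_sapling)),
            class = "herbivory_effects")
}

#' Observation link of the leaf-damage scoring process
#'
#' Expected per-sapling damage score as a function of the sapling's
#' logit-scale linear predictor `eta`: the expectation, over Gaussian leaf
#' noise, of the class-midpoint score of `100 * plogis(eta + noise)`.
#' `invert_damage_link()` numerically inverts this strictly increasing map;
#' regressing inverted scores on covariates recovers generative slopes on
#' the logit scale without the attenuation that class-midpoint
#' discretization induces in a naive logit regression.
#'
#' @param eta Numeric vector of linear predictor values (logit scale).
#' @param leaf_sd Leaf-level noise SD (logit scale).
#' @return `damage_link()`: expected score (percent); `invert_damage_link()`:
#'   the `eta` whose expected score equals `score`.
#' @details With Gaussian leaf noise the class probabilities have a closed
#'   form: each scoring class corresponds to an interval of the logit-scale
#'   leaf predictor, so its probability is a difference of normal CDFs, and
#'   the expected score is the probability-weighted sum of class midpoints.
#' @export
damage_link <- function(eta, leaf_sd) {
  if (leaf_sd == 0)
    return(classify_damage(100 * stats::plogis(eta))$score)
  dc <- damage_classes()[-1, ]              # the zero class has measure zero
  lo <- stats::qlogis(dc$lower / 100)       # -Inf for the first class
  hi <- stats::qlogis(dc$upper / 100)       # +Inf for the top class
  out <- numeric(length(eta))
  for (c_i in seq_along(dc$score))
    out <- out + dc$score[c_i] *
      (stats::pnorm((hi[c_i] - eta) / leaf_sd) -
         stats::pnorm((lo[c_i] - eta) / leaf_sd))
  out
}

#' @rdname damage_link
#' @param score Observed mean damage score(s), percent.
#' @param eta_range Range of `eta` tabulated for the inversion.
#' @export
invert_damage_link <- function(score, leaf_sd, eta_range = c(-9, 5)) {
  grid <- seq(eta_range[1], eta_range[2], length.out = 1500L)
  m <- damage_link(grid, leaf_sd)
  keep <- !duplicated(m)
  inv <- stats::splinefun(m[keep], grid[keep], method = "hyman")
  inv(pmin(pmax(score, min(m)), max(m)))
}

#' Simulate per-sapling herbivory records
#'
#' Generates heights, leaf-by-leaf ectophage damage and leaf-miner counts
#' for every living sapling in a design, under the generative model of
#' [herbivory_effects()]. Covariates entering the linear predictors (plot
#' genetic diversity and sapling height) are standardized over the living
#' cohort, so slopes are per-SD effects.
#'
#' @param design A `cohort_design` (dropout applied or not; dead saplings
#'   get no record).
#' @param fx A [herbivory_effects] object.
#' @param seed Integer seed.
#' @return Data frame with one row per living sapling: `sapling_id`,
#'   `block`, `plot`, `family`, `gd`, `height`, `ecto_damage` (mean percent
#'   leaf area over the scored leaves), `mine_count` (mines per 20 leaves).
#'   The standardized covariates used in the linear predictors are kept as
#'   columns `gd_std` and `h_std`.
#' @export
simulate_herbivory <- function(design, fx = herbivory_effects(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(fx, "herbivory_effects"))
  m <- attr(design, "n_mothers")
  fam_levels <- sprintf("MT%d", seq_len(m))
  fam_means <- fx$family_means_monoculture %||%
    seq(5.5, 8.3, length.out = m)
  if (length(fam_means) != m)
    stop("need one monoculture mean per family", call. = FALSE)
  if (any(fam_means <= 0) || any(fam_means >= 100))
    stop("monoculture family means must lie in (0, 100)", call. = FALSE)

  d <- design[design$alive, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no living saplings: nothing to simulate herbivory on",
         call. = FALSE)
  fam_idx <- match(d$family, fam_levels)

  with_seed(substream_seed(seed, "herbivory"), {
    meanlog <- fx$height_meanlog_base +
      seq(-1, 1, length.out = m) * fx$height_meanlog_spread
    height <- stats::rlnorm(nrow(d), meanlog[fam_idx], fx$height_sdlog)
    gd_std <- safe_standardize(d$gd)
    h_std <- safe_standardize(height)

    blocks <- sort(unique(d$block))
    plots <- unique(d$plot)
    b_eff <- stats::setNames(stats::rnorm(length(blocks), 0, fx$block_sd),
                             blocks)
    p_eff <- stats::setNames(stats::rnorm(length(plots), 0, fx$plot_sd),
                             plots)

    eta <- stats::qlogis(fam_means[fam_idx] / 100) +
      fx$gd_slope * gd_std + fx$height_slope_ecto * h_std +
      b_eff[as.character(d$block)] + p_eff[d$plot]
    if (any(!is.finite(eta)))
      stop("non-finite linear predictor in herbivory simulation",
           call. = FALSE)

    nl <- fx$leaves_per_sapling
    leaf_eta <- rep(eta, each = nl) +
      stats::rnorm(nrow(d) * nl, 0, fx$leaf_sd)
    leaf_score <- classify_damage(100 * stats::plogis(leaf_eta))$score
    ecto <- colMeans(matrix(leaf_score, nrow = nl))

    lambda <- exp(fx$miner_intercept + fx$height_slope_miner * h_std)
    mines <- stats::rpois(nrow(d), lambda)

    data.frame(sapling_id = d$sapling_id, block = d$block, plot = d$plot,
               family = d$family, gd = d$gd, height = height,
               gd_std = gd_std, h_std = h_std,
               ecto_damage = ecto, mine_count = mines,
               stringsAsFactors = FALSE)
  })
}

#' Write / read the phenotype table
#'
#' @param pheno Data frame from [simulate_herbivory()].
#' @param path File path.
#' @return The path (write) or the data frame (read).
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) utils::read.csv(path,
                                                  stringsAsFactors = FALSE)
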