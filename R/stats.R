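#' Logit transform for proportion data with boundary adjustment
#'
#' `log((p + eps) / (1 - p + eps))`. Exact zeros and ones are common in
#' visually scored damage proportions, so by default `eps` is half the
#' smallest nonzero proportion observed in `p` -- a data-driven boundary
#' adjustment that leaves interior values essentially untouched. Pass
#' `eps = 0` for the raw logit.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @param eps Boundary adjustment; `NULL` (default) uses half the minimum
#'   nonzero value of `p`.
#' @return Transformed vector, with the `eps` used stored as attribute
#'   `"eps"`.
#' @examples
#' logit_transform(0.073, eps = 0)  # -2.5416
#' @export
logit_transform <- function(p, eps = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (is.null(eps)) {
    nz <- p[p > 0]
    if (!length(nz))
      stop("all proportions are zero; supply eps explicitly", call. = FALSE)
    eps <- min(nz) / 2
  }
  structure(log((p + eps) / (1 - p + eps)), eps = eps)
}

#' Inverse of the raw logit
#'
#' @param x Numeric vector on the logit scale.
#' @return Proportions; exact inverse of [logit_transform()] when
#'   `eps = 0`.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Centre and scale a covariate
#'
#' Subtracts the sample mean and divides by the sample standard deviation,
#' so that regression coefficients become per-SD (standardized) effects
#' comparable within and between models.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Standardized vector (mean 0, SD 1).
#' @export
standardize <- function(x) {
  if (length(unique(x[is.finite(x)])) < 2L)
    stop("cannot standardize a constant vector", call. = FALSE)
  (x - mean(x)) / stats::sd(x)
}

#' Specify a herbivory regression model
#'
#' Declares the fixed-effect structure of one herbivory regression:
#' response, main effects, candidate interactions, and the nested random
#' structure (plot within block). The diversity covariate is either `GD`
#' (number of maternal lineages) or `GR` (mean plot relatedness); the two
#' are strongly collinear and never co-occur in one model.
#'
#' @param response Response expression, e.g. `"logit_damage"` or
#'   `"mine_count"`.
#' @param fixed Character vector of main-effect terms.
#' @param interactions Character vector of interaction terms
#'   (e.g. `"h_std:d_std"`).
#' @param random Random-effects clause (default plot nested in block).
#' @param family `"gaussian"` (identity link, linear mixed model) or
#'   `"poisson"` (log link, generalized linear mixed model).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, fixed, interactions = character(),
                       random = "(1 | block/plot)",
                       family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  if (sum(c("gd_std", "gr_std") %in% fixed) > 1L)
    stop("GD and GR must be introduced separately, not in one model",
         call. = FALSE)
  structure(list(response = response, fixed = fixed,
                 interactions = interactions, random = random,
                 family = family),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- paste(c(spec$fixed, spec$interactions, spec$random),
               collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs))
}

fit_spec <- function(spec, data) {
  f <- spec_formula(spec)
  if (spec$family == "gaussian")
    lmerTest::lmer(f, data = data, REML = TRUE)
  else
    lme4::glmer(f, data = data, family = stats::poisson,
                control = lme4::glmerControl(calc.derivs = FALSE))
}

interaction_order <- function(term) lengths(strsplit(term, ":", fixed = TRUE))

# p-value of each candidate interaction term in a fitted model
interaction_pvalues <- function(fit, spec, data) {
  if (!length(spec$interactions)) return(numeric())
  if (spec$family == "gaussian") {
    a <- stats::anova(fit)   # lmerTest: Satterthwaite F tests per term
    p <- a[["Pr(>F)"]]
    names(p) <- rownames(a)
  } else {
    ll_full <- as.numeric(stats::logLik(fit))
    p <- vapply(spec$interactions, function(tm) {
      red <- spec
      red$interactions <- setdiff(red$interactions, tm)
      fit0 <- fit_spec(red, data)
      stats::pchisq(2 * (ll_full - as.numeric(stats::logLik(fit0))),
                    df = 1, lower.tail = FALSE)
    }, 1)
  }
  # normalise term labels (lme4 may reorder a:b)
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(s) paste(sort(s), collapse = ":"), "")
  out <- stats::setNames(rep(NA_real_, length(spec$interactions)),
                         spec$interactions)
  hit <- match(canon(spec$interactions), canon(names(p)))
  out[!is.na(hit)] <- p[hit[!is.na(hit)]]
  out
}

#' Backward simplification of a mixed model's interaction terms
#'
#' Iteratively refits the model, removing the least significant
#' non-significant interaction among those of the highest order still
#' present, until every remaining interaction is significant at `alpha`.
#' Main effects are never dropped. A fit that fails to converge leaves the
#' candidate term in place and flags it.
#'
#' @param spec A [model_spec].
#' @param data Model data frame.
#' @param alpha Retention threshold (default 0.05).
#' @return List: `spec` (simplified), `fit` (final fitted model),
#'   `dropped` (terms removed, in order), `flagged` (terms kept because a
#'   reduced fit failed).
#' @export
simplify_model <- function(spec, data, alpha = 0.05) {
  dropped <- character(); flagged <- character()
  fit <- fit_spec(spec, data)
  while (length(setdiff(spec$interactions, flagged))) {
    p <- interaction_pvalues(fit, spec, data)
    p <- p[setdiff(names(p), flagged)]
    ord <- interaction_order(names(p))
    p <- p[ord == max(ord)]                  # highest order first
    p <- p[is.na(p) | p > alpha]
    if (!length(p)) break
    victim <- names(p)[which.max(replace(p, is.na(p), 1))]
    cand <- spec
    cand$interactions <- setdiff(cand$interactions, victim)
    new_fit <- tryCatch(fit_spec(cand, data), error = function(e) NULL,
                        warning = function(w) NULL)
    if (is.null(new_fit)) {
      flagged <- c(flagged, victim)
      next
    }
    spec <- cand
    fit <- new_fit
    dropped <- c(dropped, victim)
  }
  list(spec = spec, fit = fit, dropped = dropped, flagged = flagged)
}

# Likelihood-ratio based R^2 of one term: proportional reduction
# 1 - exp(-LRT / n) relative to the model without the term.
term_r2 <- function(fit, spec, term, data) {
  red <- spec
  if (term %in% red$interactions)
    red$interactions <- setdiff(red$interactions, term)
  else {
    red$fixed <- setdiff(red$fixed, term)
    # refuse to drop a main effect still involved in an interaction
    if (any(vapply(strsplit(red$interactions, ":", fixed = TRUE),
                   function(s) term %in% s, TRUE)))
      return(NA_real_)
  }
  fit0 <- tryCatch(fit_spec(red, data), error = function(e) NULL)
  if (is.null(fit0)) return(NA_real_)
  lrt <- 2 * (as.numeric(stats::logLik(fit)) -
                as.numeric(stats::logLik(fit0)))
  max(0, 1 - exp(-lrt / nrow(data)))
}

#' Summarise the fixed effects of a fitted herbivory model
#'
#' Produces the machine-readable analogue of a regression summary table:
#' per fixed term the standardized coefficient with its SE (single-df
#' terms), the test statistic (Satterthwaite F for linear mixed models,
#' likelihood-ratio chi-square for Poisson models), its p-value, and a
#' likelihood-ratio R^2 (`1 - exp(-LRT/n)` against the model without the
#' term).
#'
#' @param fitted Output of [simplify_model()] (or a list with `fit` and
#'   `spec`).
#' @param data The model data frame.
#' @return Data frame `term`, `estimate`, `se`, `statistic`, `stat_type`,
#'   `p`, `r2`.
#' @export
fit_summary <- function(fitted, data) {
  fit <- fitted$fit; spec <- fitted$spec
  terms_all <- c(spec$fixed, spec$interactions)
  co <- summary(fit)$coefficients
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(s) paste(sort(s), collapse = ":"), "")
  if (spec$family == "gaussian") {
    a <- stats::anova(fit)
    stat <- stats::setNames(a[["F value"]], rownames(a))
    pval <- stats::setNames(a[["Pr(>F)"]], rownames(a))
    stat_type <- "F"
  } else {
    ll_full <- as.numeric(stats::logLik(fit))
    stat <- pval <- stats::setNames(rep(NA_real_, length(terms_all)),
                                    terms_all)
    for (tm in terms_all) {
      red <- spec
      if (tm %in% red$interactions)
        red$interactions <- setdiff(red$interactions, tm)
      else {
        if (any(vapply(strsplit(red$interactions, ":", fixed = TRUE),
                       function(s) tm %in% s, TRUE))) next
        red$fixed <- setdiff(red$fixed, tm)
      }
      fit0 <- tryCatch(fit_spec(red, data), error = function(e) NULL)
      if (is.null(fit0)) next
      lrt <- 2 * (ll_full - as.numeric(stats::logLik(fit0)))
      df <- attr(stats::logLik(fit), "df") - attr(stats::logLik(fit0), "df")
      stat[tm] <- lrt
      pval[tm] <- stats::pchisq(lrt, df = max(df, 1), lower.tail = FALSE)
    }
    stat_type <- "chisq"
  }
  rows <- lapply(terms_all, function(tm) {
    i <- match(canon(tm), canon(rownames(co)))
    est <- if (!is.na(i)) co[i, "Estimate"] else NA_real_
    se <- if (!is.na(i)) co[i, "Std. Error"] else NA_real_
    j <- match(canon(tm), canon(names(stat)))
    data.frame(term = tm, estimate = est, se = se,
               statistic = if (!is.na(j)) stat[j] else NA_real_,
               stat_type = stat_type,
               p = if (!is.na(j)) pval[j] else NA_real_,
               r2 = term_r2(fit, spec, tm, data),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the four standard herbivory regressions
#'
#' Builds and simplifies the paired model families for a cohort: ectophage
#' damage (logit-transformed proportion, linear mixed model) and leaf-miner
#' counts (Poisson GLMM, log link), each with either GD or GR as the
#' diversity covariate, plus sapling height and maternal family (MT) as
#' fixed effects and the height-by-diversity interaction as the candidate
#' interaction. Random intercepts: plot nested within block. Continuous
#' covariates are standardized internally; estimation is delegated to
#' `lme4`/`lmerTest`.
#'
#' @param pheno Phenotype table with columns `sapling_id`, `block`, `plot`,
#'   `family`, `gd`, `height`, `ecto_damage`, `mine_count`.
#' @param plot_summary Optional output of [plot_summaries()]; required for
#'   the GR models (supplies per-plot `GR`).
#' @param alpha Simplification threshold (default 0.05).
#' @return List with one element per model
#'   (`ecto_GD`, `ecto_GR`, `miner_GD`, `miner_GR`; GR models only when
#'   `plot_summary` is given), each holding `fit`, `spec`, `dropped`,
#'   `flagged` and `summary` (a [fit_summary()] table), plus `table` --
#'   the combined long-format summary across models.
#' @export
fit_table1 <- function(pheno, plot_summary = NULL, alpha = 0.05) {
  dat <- pheno
  dat$logit_damage <- as.numeric(logit_transform(dat$ecto_damage / 100))
  dat$h_std <- standardize(dat$height)
  dat$gd_std <- standardize(dat$gd)
  dat$MT <- factor(dat$family)
  dat$block <- factor(dat$block)
  dat$plot <- factor(dat$plot)
  divs <- "gd_std"
  if (!is.null(plot_summary)) {
    dat$GR <- plot_summary$GR[match(as.character(dat$plot),
                                    plot_summary$plot)]
    if (!all(is.na(dat$GR))) {
      dat$gr_std <- standardize(dat$GR)
      divs <- c(divs, "gr_std")
    }
  }
  out <- list()
  for (dv in divs) {
    for (resp in c("ecto", "miner")) {
      spec <- model_spec(
        response = if (resp == "ecto") "logit_damage" else "mine_count",
        fixed = c("h_std", "MT", dv),
        interactions = paste0("h_std:", dv),
        family = if (resp == "ecto") "gaussian" else "poisson")
      sim <- simplify_model(spec, dat, alpha = alpha)
      sim$summary <- fit_summary(sim, dat)
      nm <- paste0(resp, "_", if (dv == "gd_std") "GD" else "GR")
      sim$summary$model <- nm
      out[[nm]] <- sim
    }
  }
  out$table <- do.call(rbind, lapply(out, `[[`, "summary"))
  rownames(out$table) <- NULL
  out
}
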