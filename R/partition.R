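#' Observed relative forage of a family in a mixture
#'
#' Ratio of the damage attributed to family `i` in a mixture (`C_i`, its
#' contribution to the plot mean response) to the damage observed on that
#' family in its same-block monoculture (`M_i`). Under the null of no
#' diversity effect its expectation is `1/n` for a balanced `n`-family
#' mixture.
#'
#' @param C_i,M_i Numeric vectors (recycled): mixture contribution and
#'   monoculture mean of each family. `M_i` must be strictly positive.
#' @return `C_i / M_i`.
#' @export
relative_forage <- function(C_i, M_i) {
  if (any(!is.finite(M_i)) || any(M_i <= 0))
    stop("monoculture reference M_i must be > 0 (undefined ratio)",
         call. = FALSE)
  if (any(C_i < 0)) stop("C_i must be >= 0", call. = FALSE)
  C_i / M_i
}

#' Additive partition of a mixture's net diversity effect
#'
#' Partitions the net genetic diversity effect (NGDE) on an `n`-family
#' mixture into a complementarity effect (CE) and a selection effect (SE):
#' with `RF_Oi = C_i / M_i` the observed relative forage, `RF_Ei = 1/n` its
#' null expectation and `dRC_i = RF_Oi - 1/n` the deviation,
#'
#' \deqn{NGDE = \sum_i C_i - \frac{1}{n}\sum_i M_i,\quad
#'       CE = n\,\overline{dRC}\,\overline{M},\quad
#'       SE = n\,\mathrm{cov}(dRC, M),}
#'
#' where the covariance is the population form (denominator `n`), which
#' makes `NGDE = CE + SE` an exact algebraic identity. Positive NGDE marks
#' associational susceptibility (more damage in the mixture than expected
#' from monocultures), negative NGDE associational resistance. CE is
#' positive when families are on average consumed more in mixture than
#' their monocultures predict; SE is positive when families damaged more
#' in monoculture also deviate upward in mixture.
#'
#' @param M Named numeric vector of same-block monoculture means, one per
#'   family in the mixture (all `> 0`).
#' @param C Matching vector of mixture contributions (family mean response
#'   in the mixture times its planted proportion `1/n`).
#' @return List of class `partition_result`: `n`, `NGDE`, `CE`, `SE`,
#'   `RF_O`, `RF_E`, `dRC`.
#' @examples
#' partition_mixture(M = c(A = 6, B = 8), C = c(A = 4, B = 5))
#' @export
partition_mixture <- function(M, C) {
  if (length(M) != length(C) || length(M) < 2L)
    stop("need matching M and C for at least 2 families", call. = FALSE)
  n <- length(M)
  RF_O <- relative_forage(C, M)
  dRC <- RF_O - 1 / n
  NGDE <- sum(C) - mean(M)
  CE <- n * mean(dRC) * mean(M)
  SE <- n * mean((dRC - mean(dRC)) * (M - mean(M)))  # population covariance
  structure(list(n = n, NGDE = NGDE, CE = CE, SE = SE,
                 RF_O = RF_O, RF_E = rep(1 / n, n), dRC = dRC),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("%d-family mixture: NGDE = %.4f = CE (%.4f) + SE (%.4f)\n",
              x$n, x$NGDE, x$CE, x$SE))
  invisible(x)
}

#' Partition every mixture plot of a cohort
#'
#' Computes the NGDE/CE/SE partition for each (block, mixture plot)
#' combination. Family membership comes from the maternity assignment when
#' supplied (excluded and ambiguous saplings are dropped), otherwise from
#' the design's true families. For each mixture, `M_i` is the mean response
#' of family `i`'s analyzable saplings in its monoculture plot of the same
#' block, and `C_i` the mean response of the family's analyzable saplings
#' in the mixture divided by the number of planted families. Mixtures with
#' a missing or zero monoculture reference, or with a family unobserved in
#' the mixture, are reported with `NA` effects and a `reason`.
#'
#' @param pheno Phenotype table ([simulate_herbivory()] or equivalent).
#' @param design A `cohort_design`.
#' @param maternity Optional maternity table from [assign_maternity()].
#' @param response Response column of `pheno` to partition
#'   (`"ecto_damage"` or `"mine_count"`).
#' @return Data frame with one row per mixture: `block`, `plot`, `gd`,
#'   `NGDE`, `CE`, `SE`, `complete`, `reason`; attribute `"families"` holds
#'   the per-family long table (`block`, `plot`, `family`, `M`, `C`,
#'   `RF_O`, `dRC`).
#' @export
partition_all <- function(pheno, design, maternity = NULL,
                          response = "ecto_damage") {
  stopifnot(response %in% names(pheno))
  if (is.null(maternity)) {
    fam <- stats::setNames(design$family, design$sapling_id)
    usable <- design$sapling_id[design$alive &
                                  (design$genotyped %in% c(TRUE, NA))]
  } else {
    ok <- maternity$status %in% c("assigned", "flagged_one_mismatch")
    fam <- stats::setNames(maternity$best_mother, maternity$offspring_id)
    usable <- maternity$offspring_id[ok]
  }
  ph <- pheno[pheno$sapling_id %in% usable, , drop = FALSE]
  ph$assigned_family <- fam[ph$sapling_id]
  ph$y <- ph[[response]]

  plots <- unique(design[, c("block", "plot", "gd")])
  plot_family <- function(pl) unique(design$family[design$plot == pl])

  res <- list(); fam_rows <- list()
  for (i in which(plots$gd >= 2L)) {
    b <- plots$block[i]; pl <- plots$plot[i]; n <- plots$gd[i]
    fams <- plot_family(pl)
    # same-block monoculture references
    M <- vapply(fams, function(f) {
      mono <- plots$plot[plots$block == b & plots$gd == 1L]
      mono <- mono[vapply(mono, function(p) plot_family(p) == f, TRUE)]
      if (!length(mono)) return(NA_real_)
      mean(ph$y[ph$plot == mono & ph$assigned_family == f])
    }, 1)
    C <- vapply(fams, function(f) {
      v <- ph$y[ph$plot == pl & ph$assigned_family == f]
      if (!length(v)) return(NA_real_)
      mean(v) / n
    }, 1)
    reason <- NA_character_
    if (anyNA(M) || any(is.nan(M))) reason <- "missing monoculture reference"
    else if (any(M == 0)) reason <- "zero monoculture reference"
    else if (anyNA(C)) reason <- "family unobserved in mixture"
    if (is.na(reason)) {
      p <- partition_mixture(stats::setNames(M, fams),
                             stats::setNames(C, fams))
      res[[length(res) + 1L]] <- data.frame(
        block = b, plot = pl, gd = n, NGDE = p$NGDE, CE = p$CE, SE = p$SE,
        complete = TRUE, reason = NA_character_, stringsAsFactors = FALSE)
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        block = b, plot = pl, family = fams, M = M, C = C,
        RF_O = p$RF_O, dRC = p$dRC, stringsAsFactors = FALSE)
    } else {
      res[[length(res) + 1L]] <- data.frame(
        block = b, plot = pl, gd = n, NGDE = NA_real_, CE = NA_real_,
        SE = NA_real_, complete = FALSE, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(block = integer(), plot = character(), gd = integer(),
               NGDE = numeric(), CE = numeric(), SE = numeric(),
               complete = logical(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "families") <- if (length(fam_rows)) do.call(rbind, fam_rows)
  out
}

#' One-sided t-tests of the partition effects against zero
#'
#' Tests the grand mean (and optionally each diversity level) of NGDE, CE
#' and SE across mixtures against zero with one-sample, one-sided t-tests.
#' The alternative direction is configurable per effect; the default tests
#' NGDE and CE upward (associational susceptibility as the alternative)
#' and SE downward.
#'
#' @param results Data frame from [partition_all()].
#' @param effects Effect columns to test.
#' @param by_gd Also test within each diversity level (default FALSE:
#'   grand mean only).
#' @param direction Named character vector over effects, `"greater"` or
#'   `"less"`.
#' @return Data frame `effect`, `scope`, `n`, `mean`, `t`, `df`, `p`,
#'   `direction`.
#' @export
partition_tests <- function(results,
                            effects = c("NGDE", "CE", "SE"),
                            by_gd = FALSE,
                            direction = c(NGDE = "greater", CE = "greater",
                                          SE = "less")) {
  res <- results[results$complete %in% TRUE, , drop = FALSE]
  scopes <- list(grand = res)
  if (by_gd)
    for (g in sort(unique(res$gd)))
      scopes[[paste0("GD=", g)]] <- res[res$gd == g, , drop = FALSE]
  rows <- list()
  for (sc in names(scopes)) {
    dat <- scopes[[sc]]
    for (ef in effects) {
      x <- dat[[ef]]
      if (length(x) < 2L)
        stop("fewer than 2 mixtures in scope '", sc, "'", call. = FALSE)
      dir <- direction[[ef]] %||% "greater"
      s <- stats::sd(x)
      if (s == 0) {
        if (all(x == 0)) { tstat <- 0; p <- 0.5 }
        else stop("zero variance with nonzero mean in scope '", sc,
                  "': degenerate t-test", call. = FALSE)
      } else {
        tstat <- mean(x) / (s / sqrt(length(x)))
        p <- if (dir == "greater")
          stats::pt(tstat, length(x) - 1, lower.tail = FALSE)
        else stats::pt(tstat, length(x) - 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = ef, scope = sc, n = length(x), mean = mean(x), t = tstat,
        df = length(x) - 1L, p = p, direction = dir,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of partition effects across diversity levels
#'
#' Assesses whether NGDE, CE and SE change along the gradient of genetic
#' diversity with a one-way analysis of variance per effect.
#'
#' @param results Data frame from [partition_all()].
#' @param effects Effect columns to test.
#' @return Data frame `effect`, `F`, `df1`, `df2`, `p`.
#' @export
partition_anova <- function(results, effects = c("NGDE", "CE", "SE")) {
  res <- results[results$complete %in% TRUE, , drop = FALSE]
  lv <- table(res$gd)
  if (length(lv) < 2L || any(lv < 2L))
    stop("need >= 2 diversity levels with >= 2 mixtures each",
         call. = FALSE)
  rows <- lapply(effects, function(ef) {
    fit <- stats::aov(res[[ef]] ~ factor(res$gd))
    s <- summary(fit)[[1]]
    data.frame(effect = ef, F = s$`F value`[1], df1 = s$Df[1],
               df2 = s$Df[2], p = s$`Pr(>F)`[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
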