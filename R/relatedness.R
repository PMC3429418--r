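#' Estimate allele frequencies by counting
#'
#' Reference allele frequencies for the dyadic likelihood are estimated by
#' straight allele counting over every typed individual in the sample
#' (mother trees included).
#'
#' @param geno A `genotype_table`.
#' @return List of [locus_model] objects, one per locus. Monomorphic loci
#'   trigger a warning: they carry no information about relatedness.
#' @export
estimate_allele_frequencies <- function(geno) {
  loci <- colnames(geno$a1)
  out <- lapply(stats::setNames(seq_along(loci), loci), function(l) {
    alleles <- c(geno$a1[, l], geno$a2[, l])
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles))
      stop("locus ", loci[l], " has no typed individuals", call. = FALSE)
    tab <- table(alleles)
    if (length(tab) == 1L)
      warning("locus ", loci[l],
              " is monomorphic: uninformative for relatedness",
              call. = FALSE)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    locus_model(loci[l], p)
  })
  out
}

# Joint probabilities of an ordered pair of single-locus genotypes given
# 0, 1 or 2 alleles shared identical by descent (non-inbred dyad model).
# g1 = (a, b), g2 = (c, d) are allele codes; p is the frequency vector
# indexed by code. Returns c(P0, P1, P2).
dyad_locus_modes <- function(a, b, c, d, p) {
  gp <- function(x, y) if (x == y) p[[x]]^2 else 2 * p[[x]] * p[[y]]
  P0 <- gp(a, b) * gp(c, d)
  same <- (min(a, b) == min(c, d)) && (max(a, b) == max(c, d))
  P2 <- if (same) gp(a, b) else 0
  P1 <- 0
  for (z in unique(c(a, b)[c(a, b) %in% c(c, d)])) {
    o1 <- if (a == z) b else a   # remaining non-IBD allele of each genotype
    o2 <- if (c == z) d else c
    P1 <- P1 + p[[z]] * p[[o1]] * p[[o2]]
  }
  c(P0 = unname(P0), P1 = unname(P1), P2 = unname(P2))
}

#' Single-locus likelihood of a dyad under IBD-mode coefficients
#'
#' For one locus, the probability of observing the genotype pair
#' `(g1, g2)` is `k0 * P0 + k1 * P1 + k2 * P2`, where `P_m` is the joint
#' probability of the pair given that the dyad shares `m` alleles identical
#' by descent, computed from allele frequencies under the non-inbred dyad
#' model. `P2` is zero whenever the two genotypes differ; `P1` is zero when
#' they share no allele.
#'
#' @param g1,g2 Length-2 vectors of allele codes (one genotype each).
#' @param freq Named numeric allele-frequency vector for the locus (or a
#'   [locus_model]).
#' @param k Numeric `c(k0, k1, k2)`; probabilities of sharing 0/1/2 alleles
#'   IBD, summing to 1.
#' @return The likelihood (a probability).
#' @export
dyad_locus_likelihood <- function(g1, g2, freq, k) {
  if (inherits(freq, "locus_model")) freq <- freq$freq
  key <- as.character(c(g1, g2))
  if (!all(key %in% names(freq)))
    stop("allele absent from frequency table", call. = FALSE)
  if (abs(sum(k) - 1) > 1e-9 || any(k < -1e-12))
    stop("k must be a probability vector over 0/1/2 IBD alleles",
         call. = FALSE)
  P <- dyad_locus_modes(key[1], key[2], key[3], key[4], freq)
  sum(k * P)
}

# Grid of IBD-mode coefficient vectors over the 2-simplex, optionally
# restricted to the genetically feasible region k1^2 >= 4 k0 k2.
k_grid <- function(step, k1_range = c(0, 1), k2_range = c(0, 1),
                   constrain_triangle = FALSE) {
  g <- expand.grid(
    k1 = seq(max(0, k1_range[1]), min(1, k1_range[2]), by = step),
    k2 = seq(max(0, k2_range[1]), min(1, k2_range[2]), by = step))
  g <- g[g$k1 + g$k2 <= 1 + 1e-12, , drop = FALSE]
  K <- cbind(k0 = pmax(0, 1 - g$k1 - g$k2), k1 = g$k1, k2 = g$k2)
  if (constrain_triangle)
    K <- K[K[, "k1"]^2 >= 4 * K[, "k0"] * K[, "k2"] - 1e-12, ,
           drop = FALSE]
  K
}

#' Dyadic maximum-likelihood relatedness for one pair
#'
#' Maximizes, over the simplex of IBD-mode coefficients
#' `(k0, k1, k2)`, the product across co-typed loci of the single-locus
#' dyad likelihood, and reports the relatedness `r = k1/2 + k2` at the
#' optimum. Optimization is a coarse simplex grid (step 0.05, which
#' contains the vertices) followed by successive local grid refinements
#' down to a step below `1e-4`; likelihood ties are broken toward the
#' smaller `r`.
#'
#' By default no constraint beyond the simplex is imposed; set
#' `constrain_triangle = TRUE` to restrict the optimum to the genetically
#' feasible region `k1^2 >= 4 k0 k2`.
#'
#' @param g1,g2 2 x L allele matrices ([genotype_of()]).
#' @param freqs List of [locus_model]s (or named frequency vectors), one
#'   per locus, in matrix column order.
#' @param constrain_triangle Restrict to `k1^2 >= 4 k0 k2` (default FALSE).
#' @param grid_step Initial grid step on the simplex (default 0.05).
#' @param refine_levels Number of 5-fold grid refinements (default 5,
#'   giving a final resolution of 8e-5).
#' @return List: `k0`, `k1`, `k2`, `r`, `loglik`, `loci_used`. When the
#'   pair has no co-typed locus all fields are `NA` (the pair is reported
#'   missing).
#' @export
dyadml <- function(g1, g2, freqs, constrain_triangle = FALSE,
                   grid_step = 0.05, refine_levels = 5L) {
  P <- dyad_mode_matrix(g1, g2, freqs)
  if (is.null(P))
    return(list(k0 = NA_real_, k1 = NA_real_, k2 = NA_real_, r = NA_real_,
                loglik = NA_real_, loci_used = 0L))
  fit <- dyadml_optimize(P, constrain_triangle, grid_step, refine_levels)
  list(k0 = unname(fit$k[1]), k1 = unname(fit$k[2]), k2 = unname(fit$k[3]),
       r = unname(fit$k[2] / 2 + fit$k[3]), loglik = fit$loglik,
       loci_used = nrow(P))
}

# L x 3 matrix of per-locus IBD-mode probabilities for the co-typed loci of
# a pair; NULL when no locus is co-typed.
dyad_mode_matrix <- function(g1, g2, freqs) {
  L <- ncol(g1)
  typed <- !is.na(g1[1, ]) & !is.na(g1[2, ]) & !is.na(g2[1, ]) &
    !is.na(g2[2, ])
  if (!any(typed)) return(NULL)
  rows <- lapply(which(typed), function(l) {
    p <- freqs[[l]]
    if (inherits(p, "locus_model")) p <- p$freq
    key <- as.character(c(g1[, l], g2[, l]))
    if (!all(key %in% names(p)))
      stop("allele absent from frequency table at locus ", l, call. = FALSE)
    dyad_locus_modes(key[1], key[2], key[3], key[4], p)
  })
  do.call(rbind, rows)
}

# Grid-refinement maximization of sum(log(P %*% k)) over the simplex.
dyadml_optimize <- function(P, constrain_triangle = FALSE, grid_step = 0.05,
                            refine_levels = 5L) {
  step <- grid_step
  K <- k_grid(step, constrain_triangle = constrain_triangle)
  best <- NULL
  for (lev in seq_len(refine_levels)) {
    LL <- colSums(log(pmax(P %*% t(K), 1e-300)))
    top <- which(LL >= max(LL) - 1e-12)
    r <- K[top, "k1"] / 2 + K[top, "k2"]
    i <- top[which.min(r)]                        # ties -> smaller r
    best <- list(k = K[i, ], loglik = LL[i])
    if (lev == refine_levels) break
    new_step <- step / 5
    K <- k_grid(new_step, best$k["k1"] + c(-step, step),
                best$k["k2"] + c(-step, step), constrain_triangle)
    if (nrow(K) == 0L) K <- matrix(best$k, 1,
                                   dimnames = list(NULL,
                                                   c("k0", "k1", "k2")))
    step <- new_step
  }
  best
}

#' Pairwise relatedness estimates over a set of individuals
#'
#' Runs the dyadic ML estimator ([dyadml()]) for every requested pair.
#'
#' @param geno A `genotype_table`.
#' @param freqs Allele frequencies; default is to estimate them from the
#'   full sample ([estimate_allele_frequencies()]).
#' @param ids Individuals to include; defaults to all offspring with at
#'   least one typed locus.
#' @param pairs Optional two-column matrix / data frame of id pairs; when
#'   given, only these dyads are evaluated (e.g. within-plot pairs).
#' @param min_informative Pairs with fewer co-typed loci than this are
#'   flagged low-confidence (default 3).
#' @param ... Passed to [dyadml()].
#' @return Data frame `id1`, `id2`, `r`, `k0`, `k1`, `k2`, `loci_used`,
#'   `loglik`, `low_confidence`.
#' @export
relatedness_matrix <- function(geno, freqs = NULL, ids = NULL, pairs = NULL,
                               min_informative = 3L, ...) {
  freqs <- freqs %||% estimate_allele_frequencies(geno)
  if (is.null(ids)) {
    typed <- rowSums(!is.na(geno$a1)) > 0
    ids <- geno$ids[geno$role == "offspring" & typed]
  }
  if (is.null(pairs)) {
    if (length(ids) < 2L) stop("need at least 2 individuals", call. = FALSE)
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)
  idx1 <- match(pairs[, 1], geno$ids)
  idx2 <- match(pairs[, 2], geno$ids)
  if (anyNA(idx1) || anyNA(idx2))
    stop("pair refers to unknown individual", call. = FALSE)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g1 <- rbind(geno$a1[idx1[i], ], geno$a2[idx1[i], ])
    g2 <- rbind(geno$a1[idx2[i], ], geno$a2[idx2[i], ])
    res[[i]] <- dyadml(g1, g2, freqs, ...)
  }
  out <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                    r = vapply(res, `[[`, 1, "r"),
                    k0 = vapply(res, `[[`, 1, "k0"),
                    k1 = vapply(res, `[[`, 1, "k1"),
                    k2 = vapply(res, `[[`, 1, "k2"),
                    loci_used = vapply(res, `[[`, 1L, "loci_used"),
                    loglik = vapply(res, `[[`, 1, "loglik"),
                    stringsAsFactors = FALSE)
  out$low_confidence <- out$loci_used < min_informative
  out
}

#' Simulate dyads of known pedigree relationship
#'
#' Draws pairs of multilocus genotypes with a known relationship --
#' full sibs (shared mother and father), half sibs (shared mother,
#' independent fathers) or unrelated (independent draws) -- from a locus
#' panel, and optionally runs the dyadic ML estimator on each pair. Used
#' for estimator calibration: pedigree expectations of relatedness are 0.5,
#' 0.25 and 0 respectively.
#'
#' @param n Number of dyads.
#' @param type `"full"`, `"half"` or `"unrelated"`.
#' @param loci Locus panel; default 11 loci with 11 equifrequent alleles.
#' @param seed Integer seed.
#' @param estimate Run [dyadml()] on each pair (default TRUE).
#' @param ... Passed to [dyadml()].
#' @return Data frame with a row per dyad: `r` (estimate, when requested),
#'   `k0`, `k1`, `k2`, `loglik`, `loci_used`.
#' @export
simulate_dyads <- function(n, type = c("full", "half", "unrelated"),
                           loci = locus_panel(n_loci = 11, n_alleles = 11,
                                              freq = "equal"),
                           seed = 1L, estimate = TRUE, ...) {
  type <- match.arg(type)
  L <- length(loci)
  with_seed(substream_seed(seed, paste0("dyads_", type)), {
    draw_geno <- function() vapply(loci, function(lo)
      sample.int(length(lo$freq), 2L, replace = TRUE, prob = lo$freq),
      numeric(2))
    one <- function() {
      if (type == "unrelated") {
        g1 <- draw_geno(); g2 <- draw_geno()
      } else {
        mom <- draw_geno(); dad1 <- draw_geno()
        dad2 <- if (type == "full") dad1 else draw_geno()
        child <- function(dad)
          rbind(mom[cbind(sample(1:2, L, TRUE), seq_len(L))],
                dad[cbind(sample(1:2, L, TRUE), seq_len(L))])
        g1 <- child(dad1); g2 <- child(dad2)
      }
      colnames(g1) <- colnames(g2) <- names(loci)
      list(g1 = g1, g2 = g2)
    }
    dyads <- replicate(n, one(), simplify = FALSE)
    if (!estimate)
      return(invisible(dyads))
    res <- lapply(dyads, function(d) dyadml(d$g1, d$g2, loci, ...))
    data.frame(r = vapply(res, `[[`, 1, "r"),
               k0 = vapply(res, `[[`, 1, "k0"),
               k1 = vapply(res, `[[`, 1, "k1"),
               k2 = vapply(res, `[[`, 1, "k2"),
               loglik = vapply(res, `[[`, 1, "loglik"),
               loci_used = vapply(res, `[[`, 1L, "loci_used"))
  })
}

#' Plot-level genetic diversity and relatedness summaries
#'
#' For each plot: `GD`, the number of distinct maternal lineages among its
#' analyzable saplings (maternally assigned, per [assign_maternity()]), and
#' `GR`, the mean pairwise dyadic-ML relatedness over all distinct
#' within-plot pairs. Plots with fewer than two analyzable saplings get
#' `GR = NA`.
#'
#' @param rel Pairwise estimates from [relatedness_matrix()]; must contain
#'   the within-plot pairs.
#' @param maternity Maternity table from [assign_maternity()] (or `NULL` to
#'   trust the design's true families).
#' @param design A `cohort_design` with dropout applied.
#' @return Data frame `plot`, `block`, `gd_planted`, `GD`, `GR`,
#'   `n_saplings`.
#' @export
plot_summaries <- function(rel, maternity, design) {
  if (is.null(maternity)) {
    fam <- stats::setNames(design$family, design$sapling_id)
    analyzable <- design$sapling_id[design$alive &
                                      design$genotyped %in% TRUE]
  } else {
    ok <- maternity$status %in% c("assigned", "flagged_one_mismatch")
    fam <- stats::setNames(maternity$best_mother, maternity$offspring_id)
    analyzable <- intersect(
      design$sapling_id[design$alive & design$genotyped %in% TRUE],
      maternity$offspring_id[ok])
  }
  key <- paste(rel$id1, rel$id2)
  key2 <- paste(rel$id2, rel$id1)
  out <- lapply(unique(design$plot), function(pl) {
    ids <- intersect(design$sapling_id[design$plot == pl], analyzable)
    gr <- NA_real_
    if (length(ids) >= 2L) {
      pr <- t(utils::combn(ids, 2L))
      k <- paste(pr[, 1], pr[, 2])
      hit <- match(k, key)
      miss <- is.na(hit)
      hit[miss] <- match(k[miss], key2)
      gr <- mean(rel$r[hit[!is.na(hit)]])
    }
    data.frame(plot = pl, block = design$block[design$plot == pl][1],
               gd_planted = design$gd[design$plot == pl][1],
               GD = length(unique(fam[ids])),
               GR = gr, n_saplings = length(ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare plot relatedness across diversity levels
#'
#' Delegated nonparametric comparison of mean within-plot relatedness (GR)
#' across the number of maternal lineages (GD): Kruskal-Wallis test plus
#' the Pearson correlation between the two indices.
#'
#' @param summaries Output of [plot_summaries()].
#' @return List with the `kruskal` htest object and `correlation`.
#' @export
gr_gd_comparison <- function(summaries) {
  s <- summaries[!is.na(summaries$GR), ]
  list(kruskal = stats::kruskal.test(s$GR, factor(s$GD)),
       correlation = stats::cor(s$GD, s$GR))
}
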