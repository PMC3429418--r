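#' Count Mendelian mismatches between an offspring and a candidate mother
#'
#' A locus counts as a mismatch when the offspring and the candidate mother
#' share no allele there -- impossible under Mendelian transmission from
#' that mother, barring genotyping error or mutation. Loci missing in
#' either individual are skipped.
#'
#' @param offspring,mother 2 x L allele matrices as returned by
#'   [genotype_of()] (columns = loci).
#' @return List with `mismatches` (count), `co_typed` (loci compared) and
#'   `mismatch_loci` (names of mismatching loci).
#' @export
mendelian_mismatches <- function(offspring, mother) {
  stopifnot(ncol(offspring) == ncol(mother))
  typed <- !is.na(offspring[1, ]) & !is.na(offspring[2, ]) &
    !is.na(mother[1, ]) & !is.na(mother[2, ])
  if (!any(typed))
    stop("no co-typed loci: maternity comparison undefined", call. = FALSE)
  share <- offspring[1, ] == mother[1, ] | offspring[1, ] == mother[2, ] |
    offspring[2, ] == mother[1, ] | offspring[2, ] == mother[2, ]
  mm <- typed & !share
  list(mismatches = sum(mm), co_typed = sum(typed),
       mismatch_loci = colnames(offspring)[mm])
}

#' Assign each offspring to a mother tree by Mendelian exclusion
#'
#' Compares every genotyped offspring against every candidate mother and
#' assigns the mother with the fewest mismatching loci. Offspring with zero
#' mismatches against the best mother are `assigned`; exactly one mismatch
#' retains the offspring as `flagged_one_mismatch` (these flag candidate
#' genotyping errors, see [locus_error_screen()]); two or more mismatches
#' against every candidate excludes the offspring (`excluded`). A tie
#' between mothers at a minimum below the threshold is reported as
#' `ambiguous` and treated as excluded downstream.
#'
#' @param geno A `genotype_table`; individuals with `role == "mother"` are
#'   the candidates (their genotypes must be complete).
#' @param threshold Mismatch count at which an offspring is excluded
#'   (default 2).
#' @return A `maternity` data frame: `offspring_id`, `best_mother`,
#'   `mismatches`, `co_typed`, `status`, `mismatch_locus` (the single
#'   offending locus for flagged offspring, else `NA`).
#' @export
assign_maternity <- function(geno, threshold = 2L) {
  mothers <- which(geno$role == "mother")
  if (!length(mothers)) stop("no candidate mothers in genotype table",
                             call. = FALSE)
  if (anyNA(geno$a1[mothers, ]) || anyNA(geno$a2[mothers, ]))
    stop("candidate mothers must have complete genotypes", call. = FALSE)
  off <- which(geno$role == "offspring")
  # keep only offspring with at least one typed locus
  typed_any <- rowSums(!is.na(geno$a1[off, , drop = FALSE])) > 0
  off <- off[typed_any]
  n <- length(off)
  mm <- matrix(NA_integer_, n, length(mothers))

  o1 <- geno$a1[off, , drop = FALSE]
  o2 <- geno$a2[off, , drop = FALSE]
  typed_off <- !is.na(o1) & !is.na(o2)
  for (j in seq_along(mothers)) {
    m1 <- geno$a1[mothers[j], ]
    m2 <- geno$a2[mothers[j], ]
    share <- sweep(o1, 2, m1, "==") | sweep(o1, 2, m2, "==") |
      sweep(o2, 2, m1, "==") | sweep(o2, 2, m2, "==")
    mm[, j] <- rowSums(typed_off & !share)
  }
  best_n <- apply(mm, 1, min)
  n_best <- rowSums(mm == best_n)
  best_j <- max.col(-mm, ties.method = "first")

  status <- ifelse(best_n >= threshold, "excluded",
                   ifelse(n_best > 1L, "ambiguous",
                          ifelse(best_n == 0L, "assigned",
                                 "flagged_one_mismatch")))
  best_mother <- ifelse(status %in% c("assigned", "flagged_one_mismatch"),
                        geno$ids[mothers][best_j], NA_character_)
  mismatch_locus <- rep(NA_character_, n)
  flagged <- which(status == "flagged_one_mismatch")
  for (i in flagged) {
    # recompute offending locus against the best mother
    mml <- mendelian_mismatches(
      rbind(o1[i, ], o2[i, ]),
      rbind(geno$a1[mothers[best_j[i]], ], geno$a2[mothers[best_j[i]], ]))
    mismatch_locus[i] <- mml$mismatch_loci[1]
  }
  structure(data.frame(offspring_id = geno$ids[off],
                       best_mother = best_mother,
                       mismatches = best_n,
                       co_typed = rowSums(typed_off),
                       status = status,
                       mismatch_locus = mismatch_locus,
                       stringsAsFactors = FALSE),
            class = c("maternity", "data.frame"))
}

#' Screen loci for elevated genotyping error rates
#'
#' Offspring carrying exactly one Mendelian mismatch against their best
#' mother point to single-locus genotyping errors. This screen tallies, per
#' locus, the share of those single-mismatch events (relative to the number
#' of flagged offspring) and flags loci whose rate exceeds a threshold as
#' candidates for removal or re-binning.
#'
#' @param maternity A maternity table from [assign_maternity()].
#' @param loci Character vector of locus names (e.g. `colnames(geno$a1)`).
#' @param rate_threshold Flagging threshold on the per-locus rate
#'   (default 0.02).
#' @return Data frame `locus_id`, `n_events`, `rate`, `flagged`; zero rows
#'   when no offspring was flagged.
#' @export
locus_error_screen <- function(maternity, loci, rate_threshold = 0.02) {
  fl <- maternity[maternity$status == "flagged_one_mismatch", , drop = FALSE]
  if (nrow(fl) == 0L)
    return(data.frame(locus_id = character(), n_events = integer(),
                      rate = numeric(), flagged = logical(),
                      stringsAsFactors = FALSE))
  ev <- table(factor(fl$mismatch_locus, levels = loci))
  rate <- as.numeric(ev) / nrow(fl)
  data.frame(locus_id = loci, n_events = as.integer(ev), rate = rate,
             flagged = rate > rate_threshold, stringsAsFactors = FALSE)
}
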