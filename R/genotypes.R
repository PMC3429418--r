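#' Simulate multilocus genotypes for a half-sib cohort
#'
#' Draws mother-tree genotypes from the locus panel's allele frequencies,
#' builds a finite pollen-donor pool per mother (donor usage weighted by a
#' flat Dirichlet draw, so each maternal family is a mixture of full- and
#' half-sib offspring), and transmits alleles Mendelian-fashion: every
#' offspring receives one allele drawn uniformly from its mother's two and
#' one from its assigned donor's two, independently at each locus.
#'
#' Genotyping noise can be layered on top: `error_rate` gives the per
#' locus-call probability that one allele of a call is replaced by a random
#' allele drawn from the locus frequencies (scalar, or one rate per locus),
#' and `failure_rate` the probability that an individual fails to amplify
#' entirely (all calls missing). Mother trees are never subject to either.
#'
#' @param design A `cohort_design` from [build_design()].
#' @param loci List of [locus_model] objects (see [locus_panel()]).
#' @param mating A [mating_design]; `n_mothers` must match the design.
#' @param seed Integer seed.
#' @param error_rate Per-locus genotyping error rate(s), in `[0, 1]`.
#' @param failure_rate Per-individual amplification failure rate.
#' @return A `genotype_table`: list with `ids`, `role` ("mother" or
#'   "offspring"), `family` (maternal family of each individual; a mother's
#'   own id for mothers), `a1`/`a2` (integer allele matrices, individuals x
#'   loci, `NA` = missing call), `loci`, and a `pedigree` data frame
#'   recording each offspring's true mother and donor.
#' @export
simulate_genotypes <- function(design, loci = locus_panel(),
                               mating = mating_design(), seed = 1L,
                               error_rate = 0, failure_rate = 0) {
  stopifnot(inherits(design, "cohort_design"))
  if (any(vapply(loci, function(l) length(l$freq), 1L) < 2L))
    stop("every locus needs at least 2 alleles", call. = FALSE)
  m <- attr(design, "n_mothers")
  if (m != mating$n_mothers)
    stop("mating design has ", mating$n_mothers, " mothers but the cohort ",
         "design was built for ", m, call. = FALSE)
  L <- length(loci)
  locus_ids <- unname(vapply(loci, `[[`, "", "locus_id"))
  error_rate <- rep_len(error_rate, L)
  if (any(error_rate < 0 | error_rate > 1) || failure_rate < 0 ||
      failure_rate > 1)
    stop("error and failure rates must lie in [0, 1]", call. = FALSE)

  mothers <- sprintf("MT%d", seq_len(m))
  off_ids <- design$sapling_id
  n_off <- length(off_ids)
  ids <- c(mothers, off_ids)
  n <- length(ids)

  with_seed(substream_seed(seed, "genotypes"), {
    draw <- function(l) sample.int(length(loci[[l]]$freq), 1L,
                                   prob = loci[[l]]$freq)
    rand_geno <- function() vapply(seq_len(L), function(l)
      c(draw(l), draw(l)), numeric(2))          # 2 x L

    mom_g <- lapply(seq_len(m), function(i) rand_geno())
    donor_g <- lapply(seq_len(m), function(i)
      lapply(seq_len(mating$donors_per_mother), function(j) rand_geno()))
    donor_w <- lapply(seq_len(m), function(i)
      rdirichlet1(mating$donors_per_mother))

    a1 <- matrix(NA_integer_, n, L, dimnames = list(ids, locus_ids))
    a2 <- a1
    for (i in seq_len(m)) {
      a1[i, ] <- mom_g[[i]][1, ]
      a2[i, ] <- mom_g[[i]][2, ]
    }

    fam_idx <- match(design$family, mothers)
    donor_idx <- integer(n_off)
    for (i in seq_len(n_off)) {
      f <- fam_idx[i]
      donor_idx[i] <- sample.int(mating$donors_per_mother, 1L,
                                 prob = donor_w[[f]])
      pick_m <- sample(1:2, L, replace = TRUE)
      pick_d <- sample(1:2, L, replace = TRUE)
      a1[m + i, ] <- mom_g[[f]][cbind(pick_m, seq_len(L))]
      a2[m + i, ] <- donor_g[[f]][[donor_idx[i]]][cbind(pick_d, seq_len(L))]
    }

    # genotyping error: one allele of an offspring call replaced by a draw
    # from the locus's allele frequencies
    if (any(error_rate > 0)) {
      for (l in which(error_rate > 0)) {
        hit <- which(stats::runif(n_off) < error_rate[l]) + m
        if (!length(hit)) next
        new_allele <- sample.int(length(loci[[l]]$freq), length(hit),
                                 replace = TRUE, prob = loci[[l]]$freq)
        which_allele <- stats::runif(length(hit)) < 0.5
        a1[hit[which_allele], l] <- new_allele[which_allele]
        a2[hit[!which_allele], l] <- new_allele[!which_allele]
      }
    }
    if (failure_rate > 0) {
      failed <- which(stats::runif(n_off) < failure_rate) + m
      a1[failed, ] <- NA_integer_
      a2[failed, ] <- NA_integer_
    }

    storage.mode(a1) <- "integer"
    storage.mode(a2) <- "integer"
    structure(list(
      ids = ids,
      role = c(rep("mother", m), rep("offspring", n_off)),
      family = c(mothers, design$family),
      a1 = a1, a2 = a2, loci = loci,
      pedigree = data.frame(id = off_ids, mother = design$family,
                            donor = sprintf("%s_D%d", design$family,
                                            donor_idx),
                            stringsAsFactors = FALSE)),
      class = "genotype_table")
  })
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$ids), "individuals (",
      sum(x$role == "mother"), "mothers ) x", ncol(x$a1), "loci\n")
  invisible(x)
}

#' Extract one individual's multilocus genotype
#'
#' @param geno A `genotype_table`.
#' @param id Individual identifier.
#' @return A 2 x L integer matrix of allele codes (columns named by locus);
#'   `NA` marks missing calls.
#' @export
genotype_of <- function(geno, id) {
  i <- match(id, geno$ids)
  if (is.na(i)) stop("unknown individual: ", id, call. = FALSE)
  rbind(a1 = geno$a1[i, ], a2 = geno$a2[i, ])
}

#' Write / read genotypes as a long-format CSV
#'
#' One row per individual x locus with columns `individual_id`, `role`,
#' `family`, `locus_id`, `allele_1`, `allele_2`; missing calls are empty
#' fields.
#'
#' @param geno A `genotype_table`.
#' @param path Output file path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a `genotype_table` (allele frequencies are not restored; use
#'   [estimate_allele_frequencies()]).
#' @export
write_genotypes <- function(geno, path) {
  L <- ncol(geno$a1)
  long <- data.frame(
    individual_id = rep(geno$ids, each = L),
    role = rep(geno$role, each = L),
    family = rep(geno$family, each = L),
    locus_id = rep(colnames(geno$a1), times = length(geno$ids)),
    allele_1 = as.vector(t(geno$a1)),
    allele_2 = as.vector(t(geno$a2)),
    stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$individual_id)
  loci <- unique(long$locus_id)
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  a1[cbind(match(long$individual_id, ids), match(long$locus_id, loci))] <-
    suppressWarnings(as.integer(long$allele_1))
  a2[cbind(match(long$individual_id, ids), match(long$locus_id, loci))] <-
    suppressWarnings(as.integer(long$allele_2))
  first <- long[!duplicated(long$individual_id), ]
  structure(list(ids = ids, role = first$role, family = first$family,
                 a1 = a1, a2 = a2, loci = NULL, pedigree = NULL),
            class = "genotype_table")
}

#' Export genotypes in GenePop format
#'
#' Writes a GenePop text file with 3-digit allele codes (missing = `000`),
#' one population per plot; mother trees form a leading population of their
#' own.
#'
#' @param geno A `genotype_table`.
#' @param design The matching `cohort_design` (maps saplings to plots).
#' @param path Output file path.
#' @param title Header line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(geno, design, path,
                          title = "oakherb simulated cohort") {
  code <- function(i) {
    a1 <- geno$a1[i, ]; a2 <- geno$a2[i, ]
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    paste(sprintf("%03d%03d", a1, a2), collapse = " ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(geno$a1), con)
  writeLines("POP", con)
  for (i in which(geno$role == "mother"))
    writeLines(paste0(geno$ids[i], " , ", code(i)), con)
  for (pl in unique(design$plot)) {
    writeLines("POP", con)
    for (id in design$sapling_id[design$plot == pl]) {
      i <- match(id, geno$ids)
      writeLines(paste0(id, " , ", code(i)), con)
    }
  }
  invisible(path)
}
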