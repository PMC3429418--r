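#' Define a codominant marker locus by its allele frequencies
#'
#' A locus model holds the population allele frequencies of one codominant
#' (microsatellite-like) marker. Alleles are labelled by integer codes, as
#' produced by allele binning.
#'
#' @param locus_id Character scalar naming the locus.
#' @param allele_frequencies Numeric probability vector over alleles; must be
#'   strictly positive and sum to 1 (tolerance `1e-12`). Names, if present,
#'   are kept as allele labels; otherwise alleles are labelled `1..K`.
#' @return An object of class `locus_model`: a list with `locus_id` and
#'   `freq` (named numeric vector).
#' @examples
#' locus_model("ssrA", c(0.5, 0.3, 0.2))
#' @export
locus_model <- function(locus_id, allele_frequencies) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  p <- as.numeric(allele_frequencies)
  if (length(p) < 1L || any(!is.finite(p)) || any(p <= 0))
    stop("allele frequencies must be strictly positive", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-12)
    stop("allele frequencies must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  names(p) <- names(allele_frequencies) %||% as.character(seq_along(p))
  structure(list(locus_id = locus_id, freq = p), class = "locus_model")
}

#' Build a panel of marker loci
#'
#' Constructs the multilocus marker panel used to genotype the cohort. The
#' default panel mirrors a typical oak microsatellite multiplex: 11 loci
#' averaging 11 alleles each, with per-locus allele counts allowed to range
#' from 6 to 19.
#'
#' @param n_loci Number of loci (default 11).
#' @param n_alleles Either a scalar (same allele count at every locus) or a
#'   vector of per-locus counts. Default: a fixed spread with mean 11.
#' @param freq `"dirichlet"` for uneven frequencies drawn from a flat
#'   Dirichlet (realistic for microsatellites), or `"equal"` for
#'   equifrequent alleles.
#' @param allele_range Permitted range of allele counts per locus
#'   (default `c(6, 19)`).
#' @param seed Integer seed for the frequency draw.
#' @return List of [locus_model] objects, named by locus.
#' @export
locus_panel <- function(n_loci = 11L, n_alleles = NULL,
                        freq = c("dirichlet", "equal"),
                        allele_range = c(6L, 19L), seed = 1L) {
  freq <- match.arg(freq)
  if (is.null(n_alleles)) {
    # fixed default spread, mean 11, within the permitted range
    base <- c(6L, 7L, 9L, 10L, 11L, 11L, 11L, 12L, 13L, 14L, 17L)
    n_alleles <- rep_len(base, n_loci)
  }
  n_alleles <- as.integer(rep_len(n_alleles, n_loci))
  if (any(n_alleles < allele_range[1]) || any(n_alleles > allele_range[2]))
    stop("allele counts per locus must lie in [", allele_range[1], ", ",
         allele_range[2], "]", call. = FALSE)
  with_seed(substream_seed(seed, "locus_panel"), {
    lapply(stats::setNames(seq_len(n_loci), sprintf("L%02d", seq_len(n_loci))),
           function(i) {
             p <- if (freq == "equal") rep(1 / n_alleles[i], n_alleles[i])
                  else rdirichlet1(n_alleles[i])
             # keep every allele genuinely observable
             p <- (p + 1e-3) / sum(p + 1e-3)
             locus_model(sprintf("L%02d", i), p)
           })
  })
}

#' Describe the mating design behind a half-sib cohort
#'
#' Offspring of one mother tree form a half-sib family, but open pollination
#' means saplings sharing a pollen donor are full sibs. The mating design
#' fixes the number of mother trees and the size of each mother's effective
#' pollen-donor pool; donor usage weights are drawn Dirichlet(1) at
#' simulation time, giving a configurable mixture of full- and half-sib
#' dyads within each maternal family.
#'
#' @param n_mothers Number of mother trees (default 4).
#' @param donors_per_mother Effective pollen donors per mother (default 3).
#'   Larger pools mean fewer full-sib pairs within a family.
#' @param offspring_per_family Optional expected offspring count per family;
#'   informational (the planting design determines actual numbers).
#' @return An object of class `mating_design`.
#' @export
mating_design <- function(n_mothers = 4L, donors_per_mother = 3L,
                          offspring_per_family = NULL) {
  n_mothers <- as.integer(n_mothers)
  donors_per_mother <- as.integer(donors_per_mother)
  if (n_mothers < 1L || donors_per_mother < 1L)
    stop("all mating design counts must be >= 1", call. = FALSE)
  if (!is.null(offspring_per_family) && offspring_per_family < 1)
    stop("all mating design counts must be >= 1", call. = FALSE)
  structure(list(n_mothers = n_mothers,
                 donors_per_mother = donors_per_mother,
                 offspring_per_family = offspring_per_family),
            class = "mating_design")
}

#' @export
print.mating_design <- function(x, ...) {
  cat("Mating design:", x$n_mothers, "mothers,",
      x$donors_per_mother, "pollen donors per mother\n")
  invisible(x)
}
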