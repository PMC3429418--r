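#' Build the common-garden planting design
#'
#' Lays out a randomized block design in which every block contains one plot
#' for each non-empty subset of the maternal families: with `m` mothers that
#' is `2^m - 1` plots per block, spanning a gradient from monocultures to
#' the full `m`-family mixture. Each plot holds 12 saplings on a 4-row by
#' 3-column grid, families planted at equal density in a regular alternating
#' pattern so that two saplings of the same family are never adjacent
#' (4-neighbourhood) in mixed plots.
#'
#' @param blocks Number of blocks (default 6).
#' @param mating A [mating_design]; its `n_mothers` sets the family pool.
#' @param seed Integer seed controlling plot order within blocks and the
#'   family-to-pattern assignment within plots.
#' @param plot_rows,plot_cols Plot grid dimensions (default 4 x 3 = 12).
#' @return A `cohort_design`: a data frame with one row per planted sapling
#'   and columns `sapling_id`, `block`, `plot` (unique label), `gd`
#'   (number of families planted in the plot), `row`, `col`, `family`,
#'   `alive`, `genotyped`. Attributes `n_mothers` and `blocks` record the
#'   design size.
#' @examples
#' d <- build_design(blocks = 1, mating = mating_design(n_mothers = 2))
#' table(d$plot)
#' @export
build_design <- function(blocks = 6L, mating = mating_design(), seed = 1L,
                         plot_rows = 4L, plot_cols = 3L) {
  stopifnot(inherits(mating, "mating_design"))
  blocks <- as.integer(blocks)
  if (blocks < 1L) stop("blocks must be >= 1", call. = FALSE)
  m <- mating$n_mothers
  plot_size <- plot_rows * plot_cols
  if (any(plot_size %% seq_len(m) != 0))
    stop("equal family density is impossible: ", plot_size,
         " positions cannot be split evenly among all subset sizes 1..", m,
         call. = FALSE)
  families <- sprintf("MT%d", seq_len(m))
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(m, k, simplify = FALSE)), recursive = FALSE)

  with_seed(substream_seed(seed, "design"), {
    rows <- vector("list", blocks * length(subsets))
    idx <- 1L
    for (b in seq_len(blocks)) {
      order_b <- sample.int(length(subsets))  # random plot placement in block
      for (j in seq_along(order_b)) {
        fams <- families[subsets[[order_b[j]]]]
        k <- length(fams)
        fams <- sample(fams)                   # random pattern assignment
        plot_label <- sprintf("B%dP%02d", b, j)
        grid <- expand.grid(row = seq_len(plot_rows), col = seq_len(plot_cols))
        # alternating pattern: family index (row + col) mod k differs between
        # horizontal and vertical neighbours whenever k >= 2
        fam_at <- fams[((grid$row - 1L) + (grid$col - 1L)) %% k + 1L]
        rows[[idx]] <- data.frame(
          sapling_id = sprintf("%sS%02d", plot_label, seq_len(plot_size)),
          block = b, plot = plot_label, gd = k,
          row = grid$row, col = grid$col, family = fam_at,
          alive = TRUE, genotyped = NA,
          stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, n_mothers = m, blocks = blocks,
              class = c("cohort_design", "data.frame"))
  })
}

#' Flag mortality and genotyping failure in a cohort design
#'
#' Applies two independent Bernoulli dropout processes: sapling death and
#' genotyping failure (unamplified DNA) among survivors. Defaults are
#' calibrated so that a 1080-sapling design yields, in expectation, 25 dead
#' saplings and about 78 saplings unusable overall, i.e. roughly 1002
#' analyzable individuals.
#'
#' @param design A `cohort_design` from [build_design()].
#' @param death_rate Probability a sapling dies before assessment
#'   (default 25/1080).
#' @param fail_rate Probability genotyping fails for a surviving sapling
#'   (default 53/1055).
#' @param seed Integer seed.
#' @return The design with `alive` and `genotyped` filled in.
#' @export
apply_dropout <- function(design, death_rate = 25 / 1080,
                          fail_rate = 53 / 1055, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (death_rate < 0 || death_rate > 1 || fail_rate < 0 || fail_rate > 1)
    stop("dropout rates must lie in [0, 1]", call. = FALSE)
  with_seed(substream_seed(seed, "dropout"), {
    n <- nrow(design)
    design$alive <- stats::runif(n) >= death_rate
    design$genotyped <- design$alive & (stats::runif(n) >= fail_rate)
  })
  design
}

#' Check the no-same-family-adjacency property of a design
#'
#' In mixed plots, saplings of the same family must never occupy
#' horizontally or vertically adjacent grid positions.
#'
#' @param design A `cohort_design`.
#' @return `TRUE` if no mixed plot has two adjacent same-family saplings.
#' @export
design_adjacency_ok <- function(design) {
  for (pl in unique(design$plot)) {
    d <- design[design$plot == pl, ]
    if (d$gd[1] < 2L) next
    fam <- matrix(NA_character_, max(d$row), max(d$col))
    fam[cbind(d$row, d$col)] <- d$family
    horiz <- fam[, -1, drop = FALSE] == fam[, -ncol(fam), drop = FALSE]
    vert <- fam[-1, , drop = FALSE] == fam[-nrow(fam), , drop = FALSE]
    if (any(horiz, na.rm = TRUE) || any(vert, na.rm = TRUE)) return(FALSE)
  }
  TRUE
}

#' Count analyzable saplings from stage losses
#'
#' The bookkeeping identity of the screening pipeline: saplings that remain
#' analyzable are those planted minus the dead minus those with unusable
#' genotypes (unamplified or maternally mismatched).
#'
#' @param planted,dead,unusable Stage counts.
#' @return `planted - dead - unusable`.
#' @export
analyzable_count <- function(planted, dead, unusable) planted - dead - unusable

#' Number of distinct unordered pairs among n individuals
#'
#' @param n Number of individuals.
#' @return `n * (n - 1) / 2`.
#' @export
n_dyads <- function(n) n * (n - 1) / 2

#' Summarise stage-by-stage sample counts for a processed cohort
#'
#' @param design A `cohort_design` with dropout applied.
#' @param maternity Optional maternity table from [assign_maternity()].
#' @return Named list of counts: planted, dead, alive, genotyped,
#'   unamplified, and (when maternity is supplied) mismatched and analyzable.
#' @export
cohort_counts <- function(design, maternity = NULL) {
  counts <- list(planted = nrow(design),
                 dead = sum(!design$alive),
                 alive = sum(design$alive),
                 genotyped = sum(design$genotyped, na.rm = TRUE),
                 unamplified = sum(design$alive & !design$genotyped,
                                   na.rm = TRUE))
  if (!is.null(maternity)) {
    ok <- maternity$status %in% c("assigned", "flagged_one_mismatch")
    assigned_ids <- maternity$offspring_id[ok]
    geno_ids <- design$sapling_id[design$genotyped %in% TRUE]
    counts$mismatched <- sum(!geno_ids %in% assigned_ids)
    counts$analyzable <- analyzable_count(
      counts$planted, counts$dead, counts$unamplified + counts$mismatched)
  }
  counts
}
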