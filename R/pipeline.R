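#' Pipeline configuration
#'
#' A single serializable list that fully determines a pipeline run: one
#' root seed (stage substreams are derived from it), design sizes, locus
#' panel, dropout rates, herbivory effect sizes and partition test
#' directions. A run is reproducible from its config alone.
#'
#' @param seed Root seed.
#' @param blocks,n_mothers,donors_per_mother Design and mating sizes.
#' @param n_loci,n_alleles,locus_freq Locus panel (see [locus_panel()]).
#' @param error_rate,death_rate,fail_rate Genotyping error and dropout
#'   rates.
#' @param effects Herbivory generator parameters ([herbivory_effects()] or
#'   the equivalent plain list).
#' @param directions One-sided test directions per partition effect.
#' @param fit_models Run the mixed-model stage (slowest stage;
#'   default TRUE).
#' @param outdir Default output directory for [run_pipeline()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, blocks = 6L, n_mothers = 4L,
                            donors_per_mother = 3L, n_loci = 11L,
                            n_alleles = NULL, locus_freq = "dirichlet",
                            error_rate = 0, death_rate = 25 / 1080,
                            fail_rate = 53 / 1055,
                            effects = herbivory_effects(),
                            directions = c(NGDE = "greater",
                                           CE = "greater", SE = "less"),
                            fit_models = TRUE, outdir = "oakherb_run") {
  structure(list(seed = as.integer(seed), blocks = as.integer(blocks),
                 n_mothers = as.integer(n_mothers),
                 donors_per_mother = as.integer(donors_per_mother),
                 n_loci = as.integer(n_loci), n_alleles = n_alleles,
                 locus_freq = locus_freq, error_rate = error_rate,
                 death_rate = death_rate, fail_rate = fail_rate,
                 effects = unclass(effects), directions = as.list(directions),
                 fit_models = fit_models, outdir = outdir),
            class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return The path (write) or the config (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$effects <- do.call(herbivory_effects, cfg$effects[
    names(cfg$effects) %in% names(formals(herbivory_effects))])
  cfg
}

# All distinct within-plot id pairs among a set of analyzable saplings.
within_plot_pairs <- function(design, ids) {
  out <- lapply(unique(design$plot), function(pl) {
    v <- intersect(design$sapling_id[design$plot == pl], ids)
    if (length(v) < 2L) return(NULL)
    t(utils::combn(v, 2L))
  })
  do.call(rbind, out)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes generate -> QC -> relatedness -> partition -> regression stages
#' on a synthetic cohort and (optionally) writes all result tables plus a
#' run manifest to `outdir`. Stage-level messages report sample counts at
#' every filter (planted, alive, genotyped, maternally assigned,
#' analyzable).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory; `NULL` keeps everything in memory.
#' @param quiet Suppress stage messages.
#' @return Invisible list with `design`, `geno`, `maternity`,
#'   `locus_errors`, `pheno`, `freqs`, `rel`, `plot_summary`, `gr_gd`,
#'   `partition` (per response), `partition_tests`, `partition_anova`,
#'   `models` (when `fit_models`), and `counts`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         outdir = config$outdir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  fx <- if (inherits(config$effects, "herbivory_effects")) config$effects
        else do.call(herbivory_effects, config$effects[
          names(config$effects) %in% names(formals(herbivory_effects))])
  mating <- mating_design(config$n_mothers, config$donors_per_mother)
  loci <- locus_panel(config$n_loci, config$n_alleles,
                      freq = config$locus_freq, seed = config$seed)

  design <- build_design(config$blocks, mating, seed = config$seed)
  design <- apply_dropout(design, config$death_rate, config$fail_rate,
                          seed = config$seed)
  say("planted: ", nrow(design), " | alive: ", sum(design$alive),
      " | genotyped: ", sum(design$genotyped))

  geno <- simulate_genotypes(design, loci, mating, seed = config$seed,
                             error_rate = config$error_rate)
  # align genotype availability with the dropout flags
  blank <- match(design$sapling_id[!(design$genotyped %in% TRUE)], geno$ids)
  geno$a1[blank, ] <- NA_integer_
  geno$a2[blank, ] <- NA_integer_

  maternity <- assign_maternity(geno)
  locus_errors <- locus_error_screen(maternity, colnames(geno$a1))
  counts <- cohort_counts(design, maternity)
  say("maternally assigned: ",
      sum(maternity$status %in% c("assigned", "flagged_one_mismatch")),
      " | excluded: ", sum(maternity$status %in% c("excluded", "ambiguous")),
      " | analyzable: ", counts$analyzable)

  pheno <- simulate_herbivory(design, fx, seed = config$seed)

  ok <- maternity$offspring_id[maternity$status %in%
                                 c("assigned", "flagged_one_mismatch")]
  analyzable <- intersect(design$sapling_id[design$alive &
                                              design$genotyped %in% TRUE],
                          ok)
  freqs <- estimate_allele_frequencies(geno)
  pairs <- within_plot_pairs(design, analyzable)
  rel <- relatedness_matrix(geno, freqs, pairs = pairs)
  plot_summary <- plot_summaries(rel, maternity, design)
  gr_gd <- tryCatch(gr_gd_comparison(plot_summary), error = function(e) NULL)
  say("within-plot dyads estimated: ", nrow(rel))

  directions <- unlist(config$directions)
  partition <- list(); ptests <- list(); panova <- list()
  for (resp in c("ecto_damage", "mine_count")) {
    part <- partition_all(pheno, design, maternity, response = resp)
    partition[[resp]] <- part
    ptests[[resp]] <- cbind(response = resp,
                            partition_tests(part, by_gd = TRUE,
                                            direction = directions))
    panova[[resp]] <- tryCatch(cbind(response = resp,
                                     partition_anova(part)),
                               error = function(e) NULL)
  }
  say("mixture partitions: ", nrow(partition$ecto_damage), " (",
      sum(partition$ecto_damage$complete), " complete)")

  models <- NULL
  if (isTRUE(config$fit_models)) {
    keep <- pheno$sapling_id %in% analyzable
    models <- fit_table1(pheno[keep, , drop = FALSE], plot_summary)
  }

  out <- list(design = design, geno = geno, maternity = maternity,
              locus_errors = locus_errors, pheno = pheno, freqs = freqs,
              rel = rel, plot_summary = plot_summary, gr_gd = gr_gd,
              partition = partition,
              partition_tests = do.call(rbind, ptests),
              partition_anova = if (length(panova))
                do.call(rbind, panova),
              models = models, counts = counts, config = config)
  rownames(out$partition_tests) <- NULL

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    utils::write.csv(as.data.frame(design), p("design.csv"),
                     row.names = FALSE)
    write_genotypes(geno, p("genotypes.csv"))
    write_genepop(geno, design, p("genotypes.gen"))
    write_phenotypes(pheno, p("phenotypes.csv"))
    utils::write.csv(as.data.frame(maternity), p("maternity.csv"),
                     row.names = FALSE)
    utils::write.csv(locus_errors, p("locus_errors.csv"), row.names = FALSE)
    utils::write.csv(rel, p("relatedness.csv"), row.names = FALSE)
    utils::write.csv(plot_summary, p("plot_summary.csv"), row.names = FALSE)
    for (resp in names(partition))
      utils::write.csv(partition[[resp]],
                       p(paste0("partition_", resp, ".csv")),
                       row.names = FALSE)
    utils::write.csv(out$partition_tests, p("partition_tests.csv"),
                     row.names = FALSE)
    if (!is.null(out$partition_anova))
      utils::write.csv(out$partition_anova, p("partition_anova.csv"),
                       row.names = FALSE)
    if (!is.null(models))
      utils::write.csv(models$table, p("table1.csv"), row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("oakherb")),
      r_version = R.version.string,
      seed = config$seed,
      config = unclass(config),
      counts = counts,
      files = list.files(outdir))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(out)
}

#' Build a miniature or full-scale test dataset
#'
#' `"small"` is a 2-block, 2-mother design (3 plots per block, 72
#' saplings) that runs in seconds and is used throughout the test suite;
#' `"paper"` is the full 6-block, 4-mother design (15 plots per block,
#' 1080 saplings).
#'
#' @param scale `"small"` or `"paper"`.
#' @param seed Root seed.
#' @param ... Overrides passed to [pipeline_config()].
#' @return List with `config`, `design` (dropout applied), `geno`,
#'   `maternity`, `pheno`.
#' @export
make_fixture <- function(scale = c("small", "paper"), seed = 1L, ...) {
  scale <- match.arg(scale)
  config <- if (scale == "small")
    pipeline_config(seed = seed, blocks = 2L, n_mothers = 2L,
                    n_loci = 8L, fit_models = FALSE, ...)
  else pipeline_config(seed = seed, ...)
  mating <- mating_design(config$n_mothers, config$donors_per_mother)
  loci <- locus_panel(config$n_loci, config$n_alleles,
                      freq = config$locus_freq, seed = seed)
  design <- build_design(config$blocks, mating, seed = seed)
  design <- apply_dropout(design, config$death_rate, config$fail_rate,
                          seed = seed)
  geno <- simulate_genotypes(design, loci, mating, seed = seed,
                             error_rate = config$error_rate)
  fx <- do.call(herbivory_effects, config$effects[
    names(config$effects) %in% names(formals(herbivory_effects))])
  list(config = config, design = design, geno = geno,
       maternity = assign_maternity(geno),
       pheno = simulate_herbivory(design, fx, seed = seed))
}
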