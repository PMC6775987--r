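# End-to-end orchestration: simulate -> measure -> compose -> rtf ->
# stats -> report, with deterministic outputs.

#' Configuration for [run_pipeline()]
#'
#' Bundles the simulation scenario, the dilution design, and every
#' analysis threshold (defaults encode the framework's standard values:
#' 90 percent monoculture purity, 85 percent constitutability coverage,
#' 2000-read depth filter, richness bins at 12 and 26, CUE grid 0-0.6 by
#' 0.01, window widths 2-10).
#'
#' @param scenario Scenario regime (see [scenario_config()]).
#' @param seed Integer master seed.
#' @param n_taxa,n_substrates Regional pool size.
#' @param design Dilution design tibble (default the full 185-vessel
#'   design from [enumerate_dilution_design()]).
#' @param inoculum_cells Undiluted inoculum size (default 1e6).
#' @param n_isolates,mono_replicates Dilution-to-extinction stage size.
#' @param min_reads Depth filter (default 2000).
#' @param purity Monoculture purity rule (default 0.90).
#' @param coverage Constitutability coverage rule (default 0.85).
#' @param richness_breaks Richness bin boundaries (default `c(12, 26)`).
#' @param cue_grid Expected-CUE grid for rCUE (default
#'   `seq(0, 0.6, 0.01)`).
#' @param widths Sliding-window widths (default `2:10`).
#' @param run_screen Run the sliding-window screen stage (default
#'   `TRUE`; the slowest stage).
#' @param n_mc Monte-Carlo draws for fit confidence bands.
#' @param noiseless Propagated to [scenario_config()].
#' @param scenario_args Extra arguments passed to [scenario_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = "mixed", seed = 1,
                            n_taxa = 300, n_substrates = 40,
                            design = enumerate_dilution_design(),
                            inoculum_cells = 1e6,
                            n_isolates = 40, mono_replicates = 3,
                            min_reads = 2000, purity = 0.90, coverage = 0.85,
                            richness_breaks = c(12, 26),
                            cue_grid = seq(0, 0.6, by = 0.01),
                            widths = 2:10, run_screen = TRUE,
                            n_mc = 2000, noiseless = FALSE,
                            scenario_args = list()) {
  check_number(purity, "purity", min = 0, max = 1)
  check_number(coverage, "coverage", min = 0, max = 1)
  check_count(seed, "seed", min = 0)
  structure(list(
    scenario = scenario, seed = as.integer(seed),
    n_taxa = n_taxa, n_substrates = n_substrates, design = design,
    inoculum_cells = inoculum_cells, n_isolates = n_isolates,
    mono_replicates = mono_replicates,
    min_reads = min_reads, purity = purity, coverage = coverage,
    richness_breaks = richness_breaks, cue_grid = cue_grid,
    widths = widths, run_screen = run_screen, n_mc = n_mc,
    noiseless = noiseless, scenario_args = scenario_args
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on a synthetic dataset (or, via
#' `simulation`, on a pre-built one): simulation of the two-stage
#' dilution experiment, measurement summarisation, composition QC and
#' diversity, the RTF core (monoculture catalog, constitutability,
#' RTF/RMF, decomposition bounds, rCUE), and the statistical layer
#' (diversity-function fits with AIC selection, richness-bin tests,
#' optionally the sliding-window screen).  All stage outputs are written
#' as TSVs plus a JSON summary and a YAML run manifest; re-running with
#' the same configuration is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent); `NULL` to skip
#'   writing files.
#' @param simulation Optional pre-built `relfun_simulation` to analyse
#'   instead of simulating from `config`.
#' @return (Invisibly) a list with every stage result: `simulation`,
#'   `summaries`, `asv_qc`, `abundance`, `richness`, `catalog`,
#'   `constitution`, `rtf`, `bounds`, `rcue`, `fits`, `bin_tests`,
#'   `screen`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         simulation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_counts <- list()

  ## -- simulate ----------------------------------------------------------
  if (is.null(simulation)) {
    pool_args <- scenario_pool_args(config$scenario)
    pool <- do.call(build_regional_pool, c(
      list(n_taxa = config$n_taxa, n_substrates = config$n_substrates,
           seed = derive_seed(config$seed, 1L)),
      pool_args))
    scen <- do.call(scenario_config, c(
      list(scenario = config$scenario, noiseless = config$noiseless),
      config$scenario_args))
    simulation <- simulate_experiment(
      pool, config$design, scen,
      inoculum_cells = config$inoculum_cells,
      n_isolates = config$n_isolates,
      mono_replicates = config$mono_replicates,
      seed = derive_seed(config$seed, 2L))
  }
  scen <- simulation$scenario

  ## -- measure -----------------------------------------------------------
  blank_ids <- simulation$asv$sample_id[simulation$asv$blank]
  ts <- simulation$timeseries
  blank_series <- ts[ts$sample_id %in% blank_ids, , drop = FALSE]
  sample_series <- ts[!(ts$sample_id %in% blank_ids), , drop = FALSE]
  summaries <- summarize_functions(sample_series, blanks = blank_series,
                                   volume_ml = scen$volume_ml)

  ## -- compose -----------------------------------------------------------
  asv <- filter_min_depth(simulation$asv, config$min_reads)
  log_counts$samples_dropped_depth <- nrow(simulation$asv) - nrow(asv)
  asv <- remove_contaminants(asv)
  log_counts$contaminants_removed <- length(attr(asv, "removed_taxa"))
  stages <- setNames(simulation$samples$stage, simulation$samples$sample_id)
  comm_asv <- asv[!asv$blank & stages[asv$sample_id] == "community", ]
  ext_asv <- asv[!asv$blank & stages[asv$sample_id] == "extinction", ]
  abund_comm <- relative_abundance(comm_asv)
  abund_ext <- relative_abundance(ext_asv)
  rich <- observed_richness(comm_asv)

  ## -- rtf ---------------------------------------------------------------
  catalog <- identify_monocultures(
    abund_ext, summaries[summaries$sample_id %in% ext_asv$sample_id, ],
    purity = config$purity)
  log_counts$catalog_taxa <- dplyr::n_distinct(catalog$taxon_id)
  constitution <- assess_constitutable(abund_comm, catalog,
                                       coverage = config$coverage)
  consti <- unique(constitution[, c("sample_id", "constitutable")])
  log_counts$communities <- nrow(consti)
  log_counts$constitutable <- sum(consti$constitutable)
  per_taxon <- per_taxon_functions(constitution, summaries)
  rtf <- compute_rtf(per_taxon, catalog)
  bounds <- decomposition_bounds(rtf)
  rtf_wide <- tidyr::pivot_wider(rtf, id_cols = c("sample_id", "n_taxa",
                                                  "coverage"),
                                 names_from = "fn", values_from = c("rtf", "rmf"))
  rcue <- estimate_rcue(rtf_wide$rtf_co2, rtf_wide$rtf_protein,
                        cue_grid = config$cue_grid,
                        sample_id = rtf_wide$sample_id)

  ## -- stats -------------------------------------------------------------
  fit_data <- dplyr::inner_join(summaries, rich, by = "sample_id")
  fits <- list(
    cells = fit_diversity_function(fit_data, "richness", "max_cell_density",
                                   n_mc = config$n_mc,
                                   seed = derive_seed(config$seed, 31L)),
    protein = fit_diversity_function(fit_data, "richness", "max_total_protein",
                                     n_mc = config$n_mc,
                                     seed = derive_seed(config$seed, 32L)),
    co2 = fit_diversity_function(fit_data, "richness", "total_co2_110h",
                                 n_mc = config$n_mc,
                                 seed = derive_seed(config$seed, 33L)))
  rtf_long <- rtf |>
    dplyr::inner_join(rich, by = "sample_id") |>
    dplyr::transmute(sample_id = .data$sample_id, richness = .data$richness,
                     fn = .data$fn, value = .data$rtf)
  bin_tests <- richness_bin_tests(rtf_long, breaks = config$richness_breaks)
  screen <- NULL
  if (config$run_screen) {
    fn_long <- summaries |>
      dplyr::filter(.data$sample_id %in% comm_asv$sample_id) |>
      dplyr::select("sample_id", value_cells = "max_cell_density",
                    value_protein = "max_total_protein",
                    value_co2 = "total_co2_110h") |>
      tidyr::pivot_longer(-"sample_id", names_to = "fn", names_prefix = "value_",
                          values_to = "value")
    screen <- sliding_window_screen(abund_comm, fn_long, rich,
                                    widths = config$widths)
  }

  ## -- report ------------------------------------------------------------
  per_bin <- rtf_long |>
    dplyr::mutate(bin = cut(.data$richness,
                            c(-Inf, config$richness_breaks, Inf))) |>
    dplyr::group_by(.data$fn, .data$bin) |>
    dplyr::summarise(mean_rtf = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  summary <- list(
    counts = log_counts,
    per_bin_rtf = as.data.frame(dplyr::mutate(per_bin, bin = as.character(.data$bin))),
    mean_rcue = mean(rcue$mean_rcue),
    selected_families = vapply(fits, function(f) f$selected, character(1)),
    n_window_hits = if (is.null(screen)) NA_integer_ else sum(screen$hit)
  )

  result <- list(simulation = simulation, summaries = summaries,
                 asv_qc = asv, abundance = abund_comm, richness = rich,
                 catalog = catalog, constitution = constitution,
                 rtf = rtf, rtf_wide = rtf_wide, bounds = bounds,
                 rcue = rcue, fits = fits, bin_tests = bin_tests,
                 screen = screen, summary = summary, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  invisible(result)
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
  }
  write_asv_table(result$simulation$asv, file.path(out_dir, "asv_table.tsv"))
  w(result$simulation$timeseries, "timeseries.tsv")
  w(result$simulation$truth, "ground_truth.tsv")
  w(result$summaries, "function_summary.tsv")
  w(result$abundance, "relative_abundance.tsv")
  w(result$richness, "richness.tsv")
  w(result$catalog, "monoculture_catalog.tsv")
  w(dplyr::left_join(result$rtf_wide,
                     result$bounds[, c("sample_id", "uptake_lo", "uptake_hi",
                                       "sbar_lo", "sbar_hi", "regime")],
                     by = "sample_id"),
    "rtf_results.tsv")
  w(dplyr::select(result$rcue, -"grid"), "rcue.tsv")
  w(dplyr::bind_rows(lapply(names(result$fits), function(nm) {
    dplyr::mutate(glance(result$fits[[nm]]), fn = nm, .before = 1)
  })), "fits.tsv")
  w(result$bin_tests, "bin_tests.tsv")
  if (!is.null(result$screen)) w(result$screen, "window_hits.tsv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- result$config
  manifest <- list(
    seed = cfg$seed, scenario = cfg$scenario,
    thresholds = list(min_reads = cfg$min_reads, purity = cfg$purity,
                      coverage = cfg$coverage,
                      richness_breaks = cfg$richness_breaks,
                      widths = range(cfg$widths),
                      cue_grid = range(cfg$cue_grid)),
    pool = list(n_taxa = cfg$n_taxa, n_substrates = cfg$n_substrates),
    design_rows = nrow(cfg$design),
    noiseless = cfg$noiseless)
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}

#' @param object An `rtf_result`.
#' @param richness Optional tibble `sample_id`, `richness` to place
#'   communities on a richness axis (default: the cataloged taxon count).
#' @param ... Unused.
#' @describeIn compute_rtf RTF against richness per function, with the
#'   null line at 1.
#' @exportS3Method ggplot2::autoplot
autoplot.rtf_result <- function(object, richness = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(richness)) {
    df <- dplyr::inner_join(dplyr::select(df, -"n_taxa"),
                            dplyr::rename(richness, n_taxa = "richness"),
                            by = "sample_id")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_taxa, y = .data$rtf)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~fn, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "taxonomic richness", y = "relative total function")
}

#' @param object An `rcue_estimate`.
#' @param ... Unused.
#' @describeIn estimate_rcue rCUE across the expected-CUE grid per
#'   community, with the mean highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.rcue_estimate <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cue, y = .data$rcue,
                                     group = .data$sample_id)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "expected CUE", y = "relative CUE")
}
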