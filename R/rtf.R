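# The relative total function (RTF) framework: monoculture catalog,
# constitutability, per-taxon functions, RTF/RMF, the uptake/efficiency
# decomposition bounds, adjustment factors, and relative CUE.

# community functions RTF is computed on; `co2` uses the 0-40 h total
# because composition is measured at early stationary phase (~40 h)
.rtf_functions <- c(cells = "max_cell_density",
                    protein = "max_total_protein",
                    co2 = "total_co2_40h")

#' Build the monoculture function catalog from extinction samples
#'
#' A dilution-to-extinction sample qualifies as an operational monoculture
#' of its dominant taxon when that taxon holds at least `purity` of the
#' sample's reads (default 0.90, boundary inclusive).  The qualifying
#' sample's community functions are used directly as the monoculture
#' functions; multiple qualifying samples for the same taxon are
#' aggregated (mean by default).
#'
#' @param abundances Long relative abundances (`sample_id`, `taxon_id`,
#'   `rel_abund`) of the extinction samples, e.g. from
#'   [relative_abundance()] on the extinction subset of an ASV table.
#' @param summaries Function summaries for the same samples, as from
#'   [summarize_functions()].
#' @param purity Minimum top-taxon read fraction (default 0.90).
#' @param aggregate `"mean"` (default) or `"median"` across qualifying
#'   samples.
#' @return A `monoculture_catalog` tibble, one row per (taxon, function):
#'   `taxon_id`, `fn` (`cells`, `protein`, `co2`, `co2_110h`), `f_mono`,
#'   `n_samples`, `purity` (mean top fraction of the qualifying samples).
#' @export
identify_monocultures <- function(abundances, summaries, purity = 0.90,
                                  aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  check_columns(abundances, c("sample_id", "taxon_id", "rel_abund"), "abundances")
  check_columns(summaries, c("sample_id", unname(.rtf_functions), "total_co2_110h"),
                "summaries")
  agg <- if (aggregate == "mean") mean else median

  tops <- abundances |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::slice_max(.data$rel_abund, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$rel_abund >= purity)

  fn_long <- summaries |>
    dplyr::select("sample_id", dplyr::all_of(unname(.rtf_functions)),
                  "total_co2_110h") |>
    tidyr::pivot_longer(-"sample_id", names_to = "measure", values_to = "value") |>
    dplyr::mutate(fn = dplyr::recode(.data$measure,
                                     max_cell_density = "cells",
                                     max_total_protein = "protein",
                                     total_co2_40h = "co2",
                                     total_co2_110h = "co2_110h"))

  out <- tops |>
    dplyr::inner_join(fn_long, by = "sample_id") |>
    dplyr::group_by(.data$taxon_id, .data$fn) |>
    dplyr::summarise(f_mono = agg(.data$value),
                     n_samples = dplyr::n(),
                     purity = mean(.data$rel_abund), .groups = "drop") |>
    dplyr::arrange(.data$taxon_id, .data$fn)
  class(out) <- c("monoculture_catalog", class(out))
  out
}

#' Coverage and renormalised abundances under the constitutability rule
#'
#' A community is constitutable when the taxa present in the monoculture
#' catalog cover at least `coverage` (default 0.85, boundary inclusive)
#' of its reads; the remaining reads are assumed to behave like the
#' covered part, so the covered abundances are renormalised to sum to 1.
#'
#' @param abundances Long relative abundances of the community samples.
#' @param catalog A `monoculture_catalog` from [identify_monocultures()].
#' @param coverage Minimum catalog coverage (default 0.85).
#' @return A tibble, one row per (sample, cataloged taxon):
#'   `sample_id`, `taxon_id`, `rel_abund`, `renorm_abund`, plus the
#'   per-sample `coverage`, `n_catalog_taxa` and `constitutable` flag
#'   repeated on each row.  Samples with zero cataloged taxa appear as a
#'   single row with `taxon_id = NA`.
#' @export
assess_constitutable <- function(abundances, catalog, coverage = 0.85) {
  check_columns(abundances, c("sample_id", "taxon_id", "rel_abund"), "abundances")
  taxa <- unique(catalog$taxon_id)
  per_sample <- abundances |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      coverage = sum(.data$rel_abund[.data$taxon_id %in% taxa]),
      n_catalog_taxa = sum(.data$taxon_id %in% taxa & .data$rel_abund > 0),
      .groups = "drop") |>
    dplyr::mutate(constitutable = .data$coverage >= !!coverage)
  abundances |>
    dplyr::filter(.data$taxon_id %in% taxa, .data$rel_abund > 0) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(renorm_abund = .data$rel_abund / sum(.data$rel_abund)) |>
    dplyr::ungroup() |>
    dplyr::right_join(per_sample, by = "sample_id") |>
    dplyr::select("sample_id", "taxon_id", "rel_abund", "renorm_abund",
                  "coverage", "n_catalog_taxa", "constitutable") |>
    dplyr::arrange(.data$sample_id, .data$taxon_id)
}

#' Apportion community functions to member taxa
#'
#' Estimates each taxon's in-community function as
#' \eqn{F_{C,i} = F_C \cdot R_{C,i}} using the renormalised relative
#' abundances - exact for cell counts, and an approximation (adjustment
#' factor assumed 1) for protein and CO2.
#'
#' @param constitution Output of [assess_constitutable()]; only
#'   constitutable samples are used.
#' @param summaries Function summaries of the same community samples.
#' @return A long tibble `sample_id`, `taxon_id`, `renorm_abund`, `fn`,
#'   `f_taxon`, plus `coverage` and `n_catalog_taxa` carried through.
#' @export
per_taxon_functions <- function(constitution, summaries) {
  check_columns(constitution, c("sample_id", "taxon_id", "renorm_abund",
                                "constitutable"), "constitution")
  check_columns(summaries, c("sample_id", unname(.rtf_functions)), "summaries")
  fc <- summaries |>
    dplyr::select("sample_id", dplyr::all_of(unname(.rtf_functions))) |>
    tidyr::pivot_longer(-"sample_id", names_to = "measure", values_to = "f_c") |>
    dplyr::mutate(fn = dplyr::recode(.data$measure,
                                     max_cell_density = "cells",
                                     max_total_protein = "protein",
                                     total_co2_40h = "co2")) |>
    dplyr::select(-"measure")
  used <- dplyr::filter(constitution, .data$constitutable, !is.na(.data$taxon_id))
  missing <- setdiff(unique(used$sample_id), unique(fc$sample_id))
  if (length(missing)) {
    abort(sprintf("missing function measurements for sample(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "relfun_incomplete_measurement")
  }
  used |>
    dplyr::inner_join(fc, by = "sample_id", relationship = "many-to-many") |>
    dplyr::mutate(f_taxon = .data$f_c * .data$renorm_abund) |>
    dplyr::select("sample_id", "taxon_id", "renorm_abund", "fn", "f_taxon",
                  "coverage", "n_catalog_taxa")
}

#' Relative total function and relative mean function per community
#'
#' \eqn{RTF_C = \sum_i F_{C,i} / F_i} over the cataloged member taxa,
#' computed for each function (`cells`, `protein`, and `co2`, the latter
#' on the 0-40 h CO2 totals); \eqn{RMF_C = RTF_C / N_C}.  `RTF = 1` is
#' the null expectation of no interaction effects.
#'
#' @param per_taxon Per-taxon function estimates from
#'   [per_taxon_functions()] (or ground-truth per-taxon functions in the
#'   same layout).
#' @param catalog A `monoculture_catalog`.
#' @param n_c How to count taxa for RMF: `"catalog"` (default; the number
#'   of cataloged, renormalised taxa) or `"observed"` (supply observed
#'   richness via `richness`).
#' @param richness Optional tibble `sample_id`, `richness` used when
#'   `n_c = "observed"`.
#' @return An `rtf_result` tibble, one row per (sample, function):
#'   `sample_id`, `fn`, `n_taxa`, `coverage`, `rtf`, `rmf`.
#' @export
compute_rtf <- function(per_taxon, catalog, n_c = c("catalog", "observed"),
                        richness = NULL) {
  n_c <- match.arg(n_c)
  check_columns(per_taxon, c("sample_id", "taxon_id", "fn", "f_taxon"), "per_taxon")
  check_columns(catalog, c("taxon_id", "fn", "f_mono"), "catalog")
  if (any(catalog$f_mono <= 0)) {
    abort("catalog contains non-positive monoculture function values.",
          class = "relfun_degenerate_monoculture")
  }
  absent <- setdiff(unique(per_taxon$taxon_id), unique(catalog$taxon_id))
  if (length(absent)) {
    abort(sprintf("taxa missing from catalog: %s.", paste(absent, collapse = ", ")),
          class = "relfun_invalid_argument")
  }
  joined <- dplyr::inner_join(per_taxon, catalog[, c("taxon_id", "fn", "f_mono")],
                              by = c("taxon_id", "fn"))
  out <- joined |>
    dplyr::group_by(.data$sample_id, .data$fn) |>
    dplyr::summarise(
      n_taxa = dplyr::n_distinct(.data$taxon_id),
      coverage = if ("coverage" %in% names(joined)) .data$coverage[1] else NA_real_,
      rtf = sum(.data$f_taxon / .data$f_mono),
      .groups = "drop")
  if (n_c == "observed") {
    if (is.null(richness)) {
      abort("`richness` must be supplied when n_c = \"observed\".",
            class = "relfun_invalid_argument")
    }
    out <- out |>
      dplyr::select(-"n_taxa") |>
      dplyr::inner_join(dplyr::rename(richness, n_taxa = "richness"),
                        by = "sample_id")
  }
  out <- dplyr::mutate(out, rmf = .data$rtf / .data$n_taxa) |>
    dplyr::arrange(.data$sample_id, .data$fn)
  class(out) <- c("rtf_result", class(out))
  out
}

#' RTF directly from a simulation (or equivalent dataset)
#'
#' Convenience wrapper running the estimation path end to end on a
#' `relfun_simulation`: measurement summaries (blank-corrected),
#' contaminant removal, relative abundances, monoculture catalog,
#' constitutability, per-taxon functions and [compute_rtf()].
#'
#' @param sim A `relfun_simulation` (from [simulate_experiment()] or
#'   [simulate_communities()]).
#' @param purity,coverage Catalog and constitutability thresholds.
#' @param min_reads Depth filter applied before anything else (default 0:
#'   keep all samples).
#' @return An `rtf_result` tibble.
#' @export
rtf_from_simulation <- function(sim, purity = 0.90, coverage = 0.85,
                                min_reads = 0) {
  stopifnot(inherits(sim, "relfun_simulation"))
  blank_ids <- sim$asv$sample_id[sim$asv$blank]
  ts <- sim$timeseries
  summaries <- summarize_functions(
    ts[!(ts$sample_id %in% blank_ids), , drop = FALSE],
    blanks = ts[ts$sample_id %in% blank_ids, , drop = FALSE],
    volume_ml = sim$scenario$volume_ml)
  asv <- sim$asv
  if (min_reads > 0) asv <- filter_min_depth(asv, min_reads)
  asv <- suppressMessages(remove_contaminants(asv))
  stages <- setNames(sim$samples$stage, sim$samples$sample_id)
  comm <- asv[!asv$blank & stages[asv$sample_id] == "community", , drop = FALSE]
  ext <- asv[!asv$blank & stages[asv$sample_id] == "extinction", , drop = FALSE]
  catalog <- identify_monocultures(
    relative_abundance(ext),
    summaries[summaries$sample_id %in% ext$sample_id, , drop = FALSE],
    purity = purity)
  constitution <- assess_constitutable(relative_abundance(comm), catalog,
                                       coverage = coverage)
  per_taxon <- per_taxon_functions(constitution, summaries)
  compute_rtf(per_taxon, catalog)
}

#' Bounds on relative resource uptake from the RTF decomposition
#'
#' Because a community has a single relative total resource uptake
#' \eqn{\sum_i S_{C,i}/S_i} and the conversion efficiencies for CO2 and
#' biomass must move in opposite directions, the uptake sum is bracketed
#' by \eqn{[\min, \max]} of `RTF(co2)` and `RTF(protein)`; dividing by
#' \eqn{N_C} brackets the mean per-taxon relative uptake
#' \eqn{\bar S_c} (realized over fundamental niche of the average
#' member).
#'
#' @param rtf An `rtf_result` from [compute_rtf()] containing both the
#'   `co2` and `protein` functions.
#' @return A tibble per sample: `sample_id`, `n_taxa`, `uptake_lo`,
#'   `uptake_hi`, `sbar_lo`, `sbar_hi`, and `regime` -
#'   `"net_complementation"` when the whole interval is above 1,
#'   `"net_competition"` when below 1, else `"indeterminate"`.
#' @export
decomposition_bounds <- function(rtf) {
  check_columns(rtf, c("sample_id", "fn", "n_taxa", "rtf"), "rtf")
  wide <- rtf |>
    dplyr::filter(.data$fn %in% c("co2", "protein")) |>
    tidyr::pivot_wider(id_cols = c("sample_id", "n_taxa"),
                       names_from = "fn", values_from = "rtf")
  if (!all(c("co2", "protein") %in% names(wide)) ||
      any(is.na(wide$co2)) || any(is.na(wide$protein))) {
    abort("both `co2` and `protein` RTF values are required per sample.",
          class = "relfun_invalid_argument")
  }
  wide |>
    dplyr::mutate(
      uptake_lo = pmin(.data$co2, .data$protein),
      uptake_hi = pmax(.data$co2, .data$protein),
      sbar_lo = .data$uptake_lo / .data$n_taxa,
      sbar_hi = .data$uptake_hi / .data$n_taxa,
      regime = dplyr::case_when(
        uptake_lo > 1 ~ "net_complementation",
        uptake_hi < 1 ~ "net_competition",
        TRUE ~ "indeterminate")) |>
    dplyr::select("sample_id", "n_taxa", "uptake_lo", "uptake_hi",
                  "sbar_lo", "sbar_hi", "regime")
}

#' Null-model adjustment factors for abundance-based apportioning
#'
#' Apportioning a non-cell function by read fractions is exact only when
#' every member shares the same per-cell function value.  Under the null
#' model the per-taxon adjustment factor for function `g` in community C
#' is the taxon's monoculture per-cell ratio divided by the unweighted
#' community mean of those ratios,
#' \eqn{(F_i(g)/F_i(cell)) / \mathrm{mean}_{j \in C}(F_j(g)/F_j(cell))};
#' factors near 1 justify the approximation (empirically most fall in
#' `[0.5, 2]`).  Factors are invariant to the units of either function.
#'
#' @param catalog A `monoculture_catalog` with `cells` plus the target
#'   function(s).
#' @param membership Tibble `sample_id`, `taxon_id` giving each
#'   community's cataloged members.
#' @param fns Functions to evaluate (default `c("protein", "co2")`).
#' @return A tibble `sample_id`, `taxon_id`, `fn`, `factor`, `in_range`
#'   (whether the factor lies in `[0.5, 2]`).
#' @export
adjustment_factors <- function(catalog, membership, fns = c("protein", "co2")) {
  check_columns(membership, c("sample_id", "taxon_id"), "membership")
  wide <- catalog |>
    dplyr::select("taxon_id", "fn", "f_mono") |>
    tidyr::pivot_wider(names_from = "fn", values_from = "f_mono")
  check_columns(wide, c("cells", fns), "catalog (pivoted)")
  out <- lapply(fns, function(g) {
    ratio <- setNames(wide[[g]] / wide$cells, wide$taxon_id)
    membership |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::reframe(taxon_id = .data$taxon_id,
                     fn = g,
                     factor = unname(ratio[.data$taxon_id] /
                                       mean(ratio[.data$taxon_id])))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(in_range = .data$factor >= 0.5 & .data$factor <= 2) |>
    dplyr::arrange(.data$sample_id, .data$fn, .data$taxon_id)
}

#' Relative carbon-use efficiency from the CO2-to-protein RTF ratio
#'
#' Treating the community as an average taxon whose monoculture CUE is
#' the expected CUE, the relative-to-expected CUE satisfies
#' \deqn{rCUE = 1 / (Ratio_{RTF} (1 - CUE) + CUE),}
#' where \eqn{Ratio_{RTF} = RTF(CO2) / RTF(protein)}.  Because the
#' expected CUE is unknown, rCUE is evaluated over a grid of plausible
#' CUE values (default 0 to 0.6 in steps of 0.01, endpoints included -
#' 0.6 being the thermodynamic ceiling) and summarised by its mean.
#'
#' @param rtf_co2,rtf_protein Positive RTF values (vectorised; recycled
#'   pairwise).
#' @param cue_grid Grid of expected CUE values.
#' @param sample_id Optional ids for the output (defaults to the element
#'   index).
#' @return An `rcue_estimate` tibble, one row per input pair:
#'   `sample_id`, `ratio_rtf`, `mean_rcue`, and `grid`, a list-column of
#'   tibbles `cue`, `rcue`.
#' @export
estimate_rcue <- function(rtf_co2, rtf_protein,
                          cue_grid = seq(0, 0.6, by = 0.01),
                          sample_id = NULL) {
  if (any(rtf_protein <= 0) || any(rtf_co2 <= 0)) {
    abort("RTF values must be > 0.", class = "relfun_invalid_argument")
  }
  n <- max(length(rtf_co2), length(rtf_protein))
  rtf_co2 <- rep_len(rtf_co2, n)
  rtf_protein <- rep_len(rtf_protein, n)
  sample_id <- sample_id %||% as.character(seq_len(n))
  ratio <- rtf_co2 / rtf_protein
  out <- tibble::tibble(
    sample_id = sample_id,
    ratio_rtf = ratio,
    grid = lapply(ratio, function(r) {
      tibble::tibble(cue = cue_grid, rcue = 1 / (r * (1 - cue_grid) + cue_grid))
    })
  )
  out$mean_rcue <- vapply(out$grid, function(g) mean(g$rcue), numeric(1))
  out <- out[, c("sample_id", "ratio_rtf", "mean_rcue", "grid")]
  class(out) <- c("rcue_estimate", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.rcue_estimate <- function(x, ...) {
  tidyr::unnest(dplyr::select(x, "sample_id", "ratio_rtf", "grid"), "grid")
}

#' @exportS3Method generics::glance
glance.rcue_estimate <- function(x, ...) {
  tibble::tibble(n = nrow(x),
                 mean_ratio = mean(x$ratio_rtf),
                 mean_rcue = mean(x$mean_rcue))
}

#' @exportS3Method generics::tidy
tidy.rtf_result <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.rtf_result <- function(x, ...) {
  x |>
    dplyr::group_by(.data$fn) |>
    dplyr::summarise(n = dplyr::n(), mean_rtf = mean(.data$rtf),
                     mean_rmf = mean(.data$rmf), .groups = "drop")
}
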