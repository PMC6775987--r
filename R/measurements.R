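#' Bead-normalised cell density from FACS event counts
#'
#' Converts gated cell event counts to absolute densities using absolute
#' count beads run at a known concentration: each well's cell events are
#' scaled by the ratio of the bead stock concentration to the bead events
#' recorded in the same volume.
#'
#' @param cell_events Number of gated cell events (vectorised).
#' @param bead_events Number of bead events recorded alongside; must be > 0.
#' @param bead_concentration Bead stock concentration in beads/mL
#'   (default 990000, the standard CountBright concentration).
#' @return Cell density in cells/mL.
#' @export
#' @examples
#' cells_per_ml(500, 1000) # 495000
cells_per_ml <- function(cell_events, bead_events, bead_concentration = 990000) {
  if (any(bead_events <= 0)) {
    abort("`bead_events` must be > 0 (degenerate bead standard).",
          class = "relfun_degenerate_standard")
  }
  if (any(cell_events < 0)) {
    abort("`cell_events` must be >= 0.", class = "relfun_invalid_argument")
  }
  cell_events / bead_events * bead_concentration
}

#' Per-cell protein signal normalised to a fixed standard
#'
#' @param mean_fluorescence Mean per-cell protein-stain fluorescence of the
#'   sample.
#' @param standard_mean_fluorescence Mean fluorescence of the fixed
#'   standard wells on the same plate; must be > 0.
#' @return Normalised protein units per cell (dimensionless ratio).
#' @export
protein_per_cell <- function(mean_fluorescence, standard_mean_fluorescence) {
  if (any(standard_mean_fluorescence <= 0)) {
    abort("`standard_mean_fluorescence` must be > 0 (degenerate standard).",
          class = "relfun_degenerate_standard")
  }
  mean_fluorescence / standard_mean_fluorescence
}

# Calibration constants of the colorimetric headspace-CO2 assay:
# %CO2 = .co2_cal$a / (delta572 - .co2_cal$d0) - .co2_cal$b
.co2_cal <- list(a = 0.1648, d0 = 0.2457, b = 0.2301)

#' Headspace CO2 from indicator-plate absorbance
#'
#' Inverts the hyperbolic calibration of the colorimetric CO2 indicator:
#' `%CO2 = 0.1648 / (delta572 - 0.2457) - 0.2301`, where `delta572` is the
#' difference in A572 between the start and end of the measurement
#' interval.  Values in the formula's small negative range near the blank
#' are clamped to 0 (physical non-negativity); readings at or below the
#' 0.2457 asymptote are out of calibration and raise an error.
#'
#' @param delta572 Absorbance difference at 572 nm; must be > 0.2457.
#' @return CO2 concentration, percent (v/v), >= 0.
#' @seealso [absorbance_from_co2()] for the exact inverse.
#' @export
co2_percent_from_absorbance <- function(delta572) {
  if (any(!is.finite(delta572)) || any(delta572 <= .co2_cal$d0)) {
    abort(sprintf("`delta572` must be > %.4f (calibration asymptote).", .co2_cal$d0),
          class = "relfun_out_of_calibration")
  }
  pmax(0, .co2_cal$a / (delta572 - .co2_cal$d0) - .co2_cal$b)
}

#' Indicator absorbance expected for a given headspace CO2
#'
#' Algebraic inverse of [co2_percent_from_absorbance()]; used by the
#' simulator to emit raw absorbance readings.
#'
#' @param co2_percent CO2 concentration, percent (v/v); must be >= 0.
#' @return delta572 absorbance difference.
#' @export
absorbance_from_co2 <- function(co2_percent) {
  if (any(co2_percent < 0)) {
    abort("`co2_percent` must be >= 0.", class = "relfun_invalid_argument")
  }
  .co2_cal$d0 + .co2_cal$a / (co2_percent + .co2_cal$b)
}

#' Blank-corrected total CO2 production over a time window
#'
#' Sums CO2 production over the sampling intervals whose midpoints fall in
#' `window`.  Each interval contributes
#' `rate x duration x volume`, with the per-interval rate defined as
#' `%CO2 / duration`, so an interval contributes `%CO2 x volume`.
#' Atmospheric background is removed by subtracting, per interval, the
#' mean `%CO2` of the blank wells before summation.
#'
#' @param series A data frame of interval readings with columns `start_h`,
#'   `end_h` and `co2_percent` (one row per sampling interval).
#' @param blanks Optional data frame of blank-well readings in the same
#'   format (possibly several blank wells per interval); the per-interval
#'   mean is subtracted.  `NULL` for no correction.
#' @param window Length-2 numeric `(start, end)` in hours; intervals are
#'   included when their midpoint lies strictly inside `(start, end]`.
#' @param volume_ml Culture volume in mL (default 0.58, i.e. 580 uL).
#' @return Normalised total CO2 (percent x mL units), a single number >= 0
#'   unless the blank signal exceeds the sample's.
#' @export
total_co2 <- function(series, blanks = NULL, window = c(0, 110), volume_ml = 0.58) {
  check_columns(series, c("start_h", "end_h", "co2_percent"), "series")
  if (length(window) != 2L || window[2] <= window[1]) {
    abort("`window` must be an increasing (start, end) pair.",
          class = "relfun_invalid_argument")
  }
  if (any(series$end_h <= series$start_h)) {
    abort("interval `end_h` must exceed `start_h`.", class = "relfun_invalid_argument")
  }
  mid <- (series$start_h + series$end_h) / 2
  keep <- mid > window[1] & mid <= window[2]
  if (!any(keep)) {
    abort("no sampling interval lies inside `window`.", class = "relfun_invalid_argument")
  }
  co2 <- series$co2_percent[keep]
  if (!is.null(blanks)) {
    check_columns(blanks, c("start_h", "end_h", "co2_percent"), "blanks")
    key <- paste(series$start_h[keep], series$end_h[keep])
    bl <- tapply(blanks$co2_percent, paste(blanks$start_h, blanks$end_h), mean)
    adj <- unname(bl[key])
    adj[is.na(adj)] <- 0
    co2 <- co2 - adj
  }
  sum(co2 * volume_ml)
}

#' Summarise a per-sample function time series
#'
#' Reduces a growth/function time series to the community-function
#' summaries used by the RTF framework: maximum cell density within
#' `max_time_h`, maximum total protein (cell density times per-cell
#' protein, computed pointwise), maximum protein per cell taken as the
#' *ratio of the maxima* (maximum total protein / maximum cell density,
#' which is robust to cell clumping at late time points, unlike the
#' maximum of the pointwise ratio), total CO2 over (0, `max_time_h`] and
#' over (0, 40] h, and the earliest time at which the maximum cell density
#' is attained.
#'
#' @param series Data frame with columns `sample_id`, `time_h`,
#'   `cells_per_ml`, `protein_fluor_per_cell`, and either `co2_percent` or
#'   `delta572` carrying the CO2 reading for the interval ending at
#'   `time_h` (`NA` at time 0).  Rows may be in any order and may contain
#'   several samples.
#' @param blanks Optional blank-well series in the same format, used for
#'   CO2 background correction.
#' @param max_time_h Latest time point used (default 110 h; later points,
#'   e.g. a 160 h reading, are excluded).
#' @param co2_window Window for the short CO2 total (default `c(0, 40)` h,
#'   the window used for RTF on respiration).
#' @param volume_ml Culture volume in mL for CO2 totals.
#' @return A tibble, one row per sample: `sample_id`, `max_cell_density`,
#'   `max_total_protein`, `max_protein_per_cell`, `total_co2_110h`,
#'   `total_co2_40h`, `time_to_peak_h`.
#' @export
summarize_functions <- function(series, blanks = NULL, max_time_h = 110,
                                co2_window = c(0, 40), volume_ml = 0.58) {
  check_columns(series, c("sample_id", "time_h", "cells_per_ml",
                          "protein_fluor_per_cell"), "series")
  if (!("co2_percent" %in% names(series))) {
    if ("delta572" %in% names(series)) {
      series$co2_percent <- NA_real_
      ok <- !is.na(series$delta572)
      series$co2_percent[ok] <- co2_percent_from_absorbance(series$delta572[ok])
    } else {
      series$co2_percent <- NA_real_
    }
  }
  blank_series <- NULL
  if (!is.null(blanks)) {
    if (!("co2_percent" %in% names(blanks)) && "delta572" %in% names(blanks)) {
      blanks$co2_percent <- NA_real_
      ok <- !is.na(blanks$delta572)
      blanks$co2_percent[ok] <- co2_percent_from_absorbance(blanks$delta572[ok])
    }
    blank_series <- .co2_intervals(blanks, max_time_h)
  }

  series |>
    dplyr::filter(.data$time_h <= max_time_h) |>
    dplyr::arrange(.data$sample_id, .data$time_h) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        abort("each sample needs >= 2 time points within `max_time_h`.",
              class = "relfun_invalid_argument")
      }
      total_protein <- df$cells_per_ml * df$protein_fluor_per_cell
      max_cells <- max(df$cells_per_ml)
      max_prot <- max(total_protein)
      iv <- .co2_intervals(df, max_time_h)
      bl <- blank_series
      tibble::tibble(
        max_cell_density = max_cells,
        max_total_protein = max_prot,
        max_protein_per_cell = max_prot / max_cells,
        total_co2_110h = total_co2(iv, bl, window = c(0, max_time_h), volume_ml = volume_ml),
        total_co2_40h = total_co2(iv, bl, window = co2_window, volume_ml = volume_ml),
        time_to_peak_h = df$time_h[which.max(df$cells_per_ml)]
      )
    }) |>
    dplyr::ungroup()
}

# interval table (start_h, end_h, co2_percent) from a point series whose
# CO2 reading at time t covers the interval (previous t, t]
.co2_intervals <- function(df, max_time_h) {
  df <- df[order(df$time_h), , drop = FALSE]
  df <- df[df$time_h <= max_time_h, , drop = FALSE]
  if (nrow(df) < 2L) {
    abort("need >= 2 time points for CO2 intervals.", class = "relfun_invalid_argument")
  }
  out <- tibble::tibble(
    start_h = df$time_h[-nrow(df)],
    end_h = df$time_h[-1],
    co2_percent = df$co2_percent[-1]
  )
  out$co2_percent[is.na(out$co2_percent)] <- 0
  out
}

#' Detect onset of stationary phase in a cell-count series
#'
#' Stationary phase is called at the first time point whose growth from
#' the previous point is below `growth_threshold` (default 20 percent),
#' provided some earlier consecutive pair grew by more than the threshold
#' (so that lag-phase flatness is not mistaken for stationarity).
#'
#' @param cell_counts Numeric vector of cell counts at successive time
#'   points; all must be > 0 and at least 3 points are required.
#' @param growth_threshold Fractional growth threshold (default 0.20).
#' @return The 1-based index of the first stationary time point, or `NA`
#'   if the series never slows after growing.
#' @export
detect_stationary <- function(cell_counts, growth_threshold = 0.20) {
  if (length(cell_counts) < 3L) {
    abort("need >= 3 points.", class = "relfun_invalid_argument")
  }
  if (any(cell_counts <= 0)) {
    abort("cell counts must be > 0.", class = "relfun_invalid_argument")
  }
  growth <- diff(cell_counts) / cell_counts[-length(cell_counts)]
  grew <- FALSE
  for (k in seq_along(growth)) {
    if (grew && growth[k] < growth_threshold) return(k + 1L)
    if (growth[k] > growth_threshold) grew <- TRUE
  }
  NA_integer_
}

#' Dissolved organic matter concentration of the growth medium
#'
#' Design arithmetic for the seaweed-seawater medium (SSM): lyophilising
#' `stock_volume_ml` of the concentrated extract stock yields
#' `dry_mass_mg` of dried material; the stock is diluted `dilution`-fold
#' into pasteurised seawater to make the working medium.  The default
#' values (22 mg from 10 mL of a 10x stock) give 0.022 percent (w/v).
#'
#' @param dry_mass_mg Dry mass recovered from the stock aliquot (mg).
#' @param stock_volume_ml Volume of stock lyophilised (mL).
#' @param dilution Fold dilution of the stock into the working medium.
#' @return DOM concentration in percent (w/v).
#' @export
ssm_dom_percent <- function(dry_mass_mg = 22, stock_volume_ml = 10, dilution = 10) {
  check_number(dry_mass_mg, "dry_mass_mg", min = 0)
  check_number(stock_volume_ml, "stock_volume_ml", min = 1e-12)
  check_number(dilution, "dilution", min = 1e-12)
  mg_per_ml <- dry_mass_mg / stock_volume_ml / dilution
  mg_per_ml / 1000 * 100 # g per 100 mL
}
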