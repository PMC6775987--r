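# Richness-binned hypothesis tests, the sliding-window key-taxa screen,
# the Loreau-Hector partition, and the initial-density covariate check.

#' Richness-binned tests of RTF against the null value
#'
#' Splits communities into richness bins (default boundaries 12 and 26:
#' low `<= 12`, moderate `(12, 26]`, high `> 26`) and runs, per bin:
#' a one-sample two-tailed t-test of each function's values against
#' `mu` (default 1, the null RTF); and for each pair of functions a
#' paired two-tailed t-test plus a paired Wilcoxon signed-rank test
#' (pairing by community).  The Wilcoxon `alternative` applies to the
#' first-named function of each pair minus the second.
#'
#' @param data Long tibble `sample_id`, `richness`, `fn`, `value`.
#' @param breaks Bin boundaries (default `c(12, 26)`).
#' @param mu Null value for the one-sample tests (default 1).
#' @param wilcoxon_alternative `"two.sided"` (default), `"less"` or
#'   `"greater"`.
#' @param min_n Minimum communities per tested bin (default 3); smaller
#'   bins are skipped with a notice.
#' @return A tibble: `test`, `fn` (or `fn_a`/`fn_b` for paired tests),
#'   `bin`, `n`, `estimate`, `statistic`, `df`, `p_value`.
#' @export
richness_bin_tests <- function(data, breaks = c(12, 26), mu = 1,
                               wilcoxon_alternative = "two.sided",
                               min_n = 3) {
  check_columns(data, c("sample_id", "richness", "fn", "value"), "data")
  brks <- c(-Inf, sort(breaks), Inf)
  labs <- character(length(brks) - 1)
  labs[1] <- sprintf("<=%g", brks[2])
  if (length(brks) > 3) {
    for (k in 2:(length(brks) - 2)) {
      labs[k] <- sprintf("(%g,%g]", brks[k], brks[k + 1])
    }
  }
  labs[length(labs)] <- sprintf(">%g", brks[length(brks) - 1])
  data$bin <- cut(data$richness, brks, labels = labs)

  rows <- list()
  for (b in levels(data$bin)) {
    db <- data[data$bin == b, , drop = FALSE]
    for (f in unique(db$fn)) {
      v <- db$value[db$fn == f]
      if (length(v) < min_n) {
        inform(sprintf("richness_bin_tests: bin %s skipped for %s (n = %d < %d).",
                       b, f, length(v), min_n))
        next
      }
      tol <- 1e-10 * max(1, abs(mu), abs(mean(v)))
      tt <- if (sd(v) < tol) {
        # numerically constant data: a t-test is degenerate
        if (abs(mean(v) - mu) <= tol) {
          list(statistic = 0, parameter = length(v) - 1, p.value = 1,
               estimate = mean(v))
        } else {
          list(statistic = sign(mean(v) - mu) * Inf,
               parameter = length(v) - 1, p.value = 0, estimate = mean(v))
        }
      } else {
        t.test(v, mu = mu)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        test = "t_one_sample", fn_a = f, fn_b = NA_character_, bin = b,
        n = length(v), estimate = unname(tt$estimate),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value)
    }
    fns <- sort(unique(db$fn))
    if (length(fns) >= 2) {
      for (pair in utils::combn(fns, 2, simplify = FALSE)) {
        wide <- db |>
          dplyr::filter(.data$fn %in% pair) |>
          tidyr::pivot_wider(id_cols = "sample_id", names_from = "fn",
                             values_from = "value") |>
          tidyr::drop_na()
        if (nrow(wide) < min_n) next
        a <- wide[[pair[1]]]
        v <- wide[[pair[2]]]
        d <- a - v
        if (all(abs(d) <= 1e-10 * max(1, abs(mean(a))))) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            test = c("t_paired", "wilcoxon_paired"),
            fn_a = pair[1], fn_b = pair[2], bin = b, n = nrow(wide),
            estimate = 0, statistic = c(0, 0), df = c(nrow(wide) - 1, NA),
            p_value = c(1, 1))
          next
        }
        tt <- t.test(a, v, paired = TRUE)
        wt <- suppressWarnings(
          wilcox.test(a, v, paired = TRUE,
                      alternative = wilcoxon_alternative))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          test = c("t_paired", "wilcoxon_paired"),
          fn_a = pair[1], fn_b = pair[2], bin = b, n = nrow(wide),
          estimate = unname(tt$estimate),
          statistic = c(unname(tt$statistic), unname(wt$statistic)),
          df = c(unname(tt$parameter), NA),
          p_value = c(tt$p.value, wt$p.value))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Sliding-window screen for key taxa
#'
#' Screens for taxa whose relative abundance correlates with a community
#' function within sliding windows of taxonomic richness: for every
#' window width in `widths` and every window position (step 1 richness
#' unit), the Kendall rank correlation (tau-b) between each taxon's
#' relative abundance (0 where absent) and the function value is
#' computed across the communities falling in that window.  P-values are
#' Benjamini-Hochberg adjusted, pooled within each (function, width)
#' stratum by default; hits are windows with `q < q_threshold`.
#'
#' @param abundances Long tibble `sample_id`, `taxon_id`, `rel_abund`.
#' @param functions Long tibble `sample_id`, `fn`, `value`.
#' @param richness Tibble `sample_id`, `richness`.
#' @param widths Window widths in richness units (default `2:10`).
#' @param q_threshold FDR threshold (default 0.05).
#' @param min_n Minimum communities per window (default 5).
#' @param min_presence Minimum communities in which the taxon must be
#'   present (default 3).
#' @param stratify `"function_width"` (default) pools the BH correction
#'   within each (function, width) stratum; `"all"` pools everything.
#' @return A tibble of all tested (taxon, window, function) combinations:
#'   `taxon_id`, `fn`, `width`, `richness_lo`, `richness_hi`, `n`,
#'   `tau`, `p_value`, `q_value`, `direction`, `hit`.
#' @export
sliding_window_screen <- function(abundances, functions, richness,
                                  widths = 2:10, q_threshold = 0.05,
                                  min_n = 5, min_presence = 3,
                                  stratify = c("function_width", "all")) {
  stratify <- match.arg(stratify)
  check_columns(abundances, c("sample_id", "taxon_id", "rel_abund"), "abundances")
  check_columns(functions, c("sample_id", "fn", "value"), "functions")
  check_columns(richness, c("sample_id", "richness"), "richness")

  rich <- setNames(richness$richness, richness$sample_id)
  ab_wide <- tidyr::pivot_wider(
    abundances[, c("sample_id", "taxon_id", "rel_abund")],
    names_from = "taxon_id", values_from = "rel_abund", values_fill = 0)
  ab_mat <- as.matrix(ab_wide[, -1, drop = FALSE])
  rownames(ab_mat) <- ab_wide$sample_id

  rows <- list()
  for (f in unique(functions$fn)) {
    fv <- functions[functions$fn == f, ]
    vals <- setNames(fv$value, fv$sample_id)
    ids <- intersect(names(vals), intersect(rownames(ab_mat), names(rich)))
    if (length(ids) < min_n) next
    r <- rich[ids]
    for (w in widths) {
      for (lo in seq(min(r), max(r) - w + 1)) {
        hi <- lo + w - 1
        in_win <- ids[r >= lo & r <= hi]
        if (length(in_win) < min_n) next
        y <- vals[in_win]
        if (sd(y) == 0) next
        sub <- ab_mat[in_win, , drop = FALSE]
        candidates <- colnames(sub)[colSums(sub > 0) >= min_presence]
        for (tx in candidates) {
          xv <- sub[, tx]
          if (sd(xv) == 0) next
          ct <- suppressWarnings(cor.test(xv, y, method = "kendall",
                                          exact = FALSE))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            taxon_id = tx, fn = f, width = w,
            richness_lo = lo, richness_hi = hi, n = length(in_win),
            tau = unname(ct$estimate), p_value = ct$p.value)
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(taxon_id = character(), fn = character(),
                          width = integer(), richness_lo = numeric(),
                          richness_hi = numeric(), n = integer(),
                          tau = numeric(), p_value = numeric(),
                          q_value = numeric(), direction = character(),
                          hit = logical()))
  }
  out <- dplyr::bind_rows(rows)
  out <- if (stratify == "function_width") {
    out |>
      dplyr::group_by(.data$fn, .data$width) |>
      dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(out, q_value = p.adjust(.data$p_value, method = "BH"))
  }
  out |>
    dplyr::mutate(direction = ifelse(.data$tau >= 0, "positive", "negative"),
                  hit = .data$q_value < q_threshold) |>
    dplyr::arrange(.data$fn, .data$width, .data$richness_lo, .data$taxon_id)
}

#' Loreau-Hector partition of the net biodiversity effect
#'
#' Decomposes the deviation between observed and expected community
#' function into complementarity and selection:
#' \eqn{\Delta RY_i = F_{C,i}/M_i - RY_{e,i}};
#' complementarity \eqn{= N \overline{\Delta RY}\, \overline M};
#' selection \eqn{= N\,\mathrm{cov}(\Delta RY, M)} (population
#' covariance); and the identity
#' net \eqn{= \sum_i F_{C,i} - \sum_i RY_{e,i} M_i =}
#' complementarity + selection holds exactly.  When all monoculture
#' values equal \eqn{M}, selection vanishes and complementarity equals
#' \eqn{(RTF - 1) M} - the linear link between the complementarity
#' effect and the RTF index.
#'
#' @param f_obs Observed per-taxon functions in the community
#'   \eqn{F_{C,i}}.
#' @param m Monoculture functions \eqn{M_i}; all must be > 0.
#' @param ry_expected Expected relative yields (default uniform
#'   `1/N`); must sum to 1.
#' @return One-row tibble: `net`, `complementarity`, `selection`, and a
#'   `per_taxon` list-column (`f_obs`, `m`, `ry_expected`, `delta_ry`).
#' @export
loreau_hector_partition <- function(f_obs, m, ry_expected = NULL) {
  n <- length(f_obs)
  if (length(m) != n) {
    abort("`f_obs` and `m` must have equal length.", class = "relfun_invalid_argument")
  }
  if (any(m <= 0)) {
    abort("all monoculture values must be > 0.", class = "relfun_invalid_argument")
  }
  ry_expected <- ry_expected %||% rep(1 / n, n)
  if (abs(sum(ry_expected) - 1) > 1e-8) {
    abort("`ry_expected` must sum to 1.", class = "relfun_invalid_argument")
  }
  delta_ry <- f_obs / m - ry_expected
  pop_cov <- mean(delta_ry * m) - mean(delta_ry) * mean(m)
  tibble::tibble(
    net = sum(f_obs) - sum(ry_expected * m),
    complementarity = n * mean(delta_ry) * mean(m),
    selection = n * pop_cov,
    per_taxon = list(tibble::tibble(f_obs = f_obs, m = m,
                                    ry_expected = ry_expected,
                                    delta_ry = delta_ry))
  )
}

#' Function-richness regression controlling for initial cell density
#'
#' Ordinary least squares of a community function on richness and
#' log10 initial cell density, with type-II sum-of-squares F tests per
#' predictor (via [car::Anova()]) - the check that diversity-function
#' relationships survive adjustment for inoculum size.
#'
#' @param data Data frame with the three columns named below.
#' @param value,richness,density Column names (strings).
#' @return A tibble `term`, `sumsq`, `df`, `statistic`, `p_value`, with
#'   the fitted `lm` attached as attribute `"model"`.
#' @export
regression_with_density <- function(data, value = "value",
                                    richness = "richness",
                                    density = "initial_density") {
  check_columns(data, c(value, richness, density), "data")
  df <- tibble::tibble(y = as.numeric(data[[value]]),
                       richness = as.numeric(data[[richness]]),
                       log_density = log10(as.numeric(data[[density]])))
  if (nrow(df) <= 3L) {
    abort("need n > number of predictors + 1.", class = "relfun_invalid_argument")
  }
  fit <- lm(y ~ richness + log_density, data = df)
  if (fit$rank < 3L) {
    abort("collinear predictors: design matrix is rank deficient.",
          class = "relfun_rank_deficiency")
  }
  if (sum(stats::residuals(fit)^2) <= 1e-14 * max(1, sum(df$y^2))) {
    # degenerate response (e.g. constant): no evidence either way
    out <- tibble::tibble(term = c("richness", "log_density", "Residuals"),
                          sumsq = 0, df = c(1, 1, fit$df.residual),
                          statistic = c(0, 0, NA), p_value = c(1, 1, NA))
    attr(out, "model") <- fit
    return(out)
  }
  a2 <- car::Anova(fit, type = 2)
  out <- tibble::tibble(
    term = rownames(a2),
    sumsq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    statistic = a2[["F value"]],
    p_value = a2[["Pr(>F)"]])
  attr(out, "model") <- fit
  out
}
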