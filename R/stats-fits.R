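# Diversity-function curve fitting with AIC model selection.

.fit_families <- c("linear", "log_linear", "hyperbolic")

#' Fit diversity-function curves and select a family by AIC
#'
#' Least-squares fits of three candidate families relating a community
#' function to taxonomic richness: linear (`y = a + b x`), log-linear
#' (`y = a + b ln x`) and hyperbolic Michaelis-Menten
#' (`y = V x / (K + x)`).  The family with the least AIC (Gaussian
#' likelihood) is selected; families whose AIC is within `aic_tol` of the
#' minimum are treated as comparable and the tie resolves toward the
#' simpler family (linear before log-linear before hyperbolic).  A 95
#' percent pointwise confidence band for the selected curve is produced
#' by Monte-Carlo draws from the asymptotic parameter covariance.
#'
#' @param data Data frame holding the observations.
#' @param x,y Column names (strings) of richness and function value.
#' @param families Candidate families (default all three).
#' @param aic_tol AIC comparability margin (default 2).
#' @param n_mc Monte-Carlo draws for the band (default 5000).
#' @param level Band level (default 0.95).
#' @param grid_n Number of x-grid points for the band (default 100).
#' @param seed Optional seed for the Monte-Carlo draws.
#' @return A `div_fun_fit` object; see [tidy()], [glance()],
#'   [autoplot()], and `predict()`.
#' @export
fit_diversity_function <- function(data, x = "richness", y = "value",
                                   families = .fit_families,
                                   aic_tol = 2, n_mc = 5000, level = 0.95,
                                   grid_n = 100, seed = NULL) {
  families <- match.arg(families, .fit_families, several.ok = TRUE)
  check_columns(data, c(x, y), "data")
  df <- tibble::tibble(x = as.numeric(data[[x]]), y = as.numeric(data[[y]]))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 4L) {
    abort("need >= 4 complete observations.", class = "relfun_invalid_argument")
  }
  if ("log_linear" %in% families && any(df$x <= 0)) {
    abort("log-linear family requires x > 0.", class = "relfun_invalid_argument")
  }
  fits <- list()
  if ("linear" %in% families) fits$linear <- lm(y ~ x, data = df)
  if ("log_linear" %in% families) fits$log_linear <- lm(y ~ log(x), data = df)
  if ("hyperbolic" %in% families) {
    hyp <- tryCatch(
      minpack.lm::nlsLM(y ~ V * x / (K + x), data = df,
                        start = list(V = max(df$y), K = max(median(df$x), 1e-6)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        warn(sprintf("hyperbolic fit failed (%s); family dropped.",
                     conditionMessage(e)))
        NULL
      })
    if (!is.null(hyp)) fits$hyperbolic <- hyp
  }
  if (!length(fits)) {
    abort("no family could be fitted.", class = "relfun_invalid_argument")
  }
  aic <- vapply(fits, AIC, numeric(1))
  # comparable AICs resolve toward the simpler family; numerically
  # perfect fits (zero residual variance) are all treated as tied,
  # since their AICs differ only by floating-point noise
  order_pref <- intersect(.fit_families, names(fits))
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  perfect <- rss <= 1e-16 * max(1, sum(df$y^2))
  comparable <- if (any(perfect)) {
    order_pref[perfect[order_pref]]
  } else {
    order_pref[aic[order_pref] <= min(aic) + aic_tol]
  }
  selected <- comparable[1]

  grid <- seq(min(df$x), max(df$x), length.out = grid_n)
  band <- .mc_band(fits[[selected]], selected, grid, n_mc, level, seed)

  structure(list(
    data = df, fits = fits, aic = aic, selected = selected,
    aic_tol = aic_tol, band = band, level = level
  ), class = "div_fun_fit")
}

.curve_fun <- function(family) {
  switch(family,
    linear = function(p, x) p[1] + p[2] * x,
    log_linear = function(p, x) p[1] + p[2] * log(x),
    hyperbolic = function(p, x) p["V"] * x / (p["K"] + x))
}

.mc_band <- function(fit, family, grid, n_mc, level, seed = NULL) {
  f <- .curve_fun(family)
  est <- coef(fit)
  V <- vcov(fit)
  # degenerate designs (e.g. constant x) give NA coefficients; treat the
  # affected directions as fixed at zero rather than failing
  est[!is.finite(est)] <- 0
  V[!is.finite(V)] <- 0
  V <- (V + t(V)) / 2
  draws <- with_seed(seed, MASS::mvrnorm(n_mc, mu = est, Sigma = V))
  curves <- apply(draws, 1, function(p) f(setNames(p, names(est)), grid))
  alpha <- (1 - level) / 2
  tibble::tibble(
    x = grid,
    fit = f(est, grid),
    lo = apply(curves, 1, quantile, probs = alpha),
    hi = apply(curves, 1, quantile, probs = 1 - alpha)
  )
}

#' @export
print.div_fun_fit <- function(x, ...) {
  cat(sprintf("<div_fun_fit> selected: %s (AIC %s)\n", x$selected,
              paste(sprintf("%s=%.2f", names(x$aic), x$aic), collapse = ", ")))
  invisible(x)
}

#' @export
predict.div_fun_fit <- function(object, newdata = NULL, family = NULL, ...) {
  family <- family %||% object$selected
  xs <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata[[1]] else as.numeric(newdata)
  .curve_fun(family)(coef(object$fits[[family]]), xs)
}

#' @exportS3Method generics::tidy
tidy.div_fun_fit <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(fam) {
    est <- coef(x$fits[[fam]])
    se <- sqrt(diag(vcov(x$fits[[fam]])))
    tibble::tibble(family = fam, term = names(est),
                   estimate = unname(est), std_error = unname(se),
                   selected = fam == x$selected)
  })
}

#' @exportS3Method generics::glance
glance.div_fun_fit <- function(x, ...) {
  tibble::tibble(family = names(x$aic), aic = unname(x$aic),
                 delta_aic = unname(x$aic - min(x$aic)),
                 selected = names(x$aic) == x$selected)
}

#' @param object A `div_fun_fit`.
#' @param ... Unused.
#' @describeIn fit_diversity_function data, selected curve and its
#'   Monte-Carlo confidence band as a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.div_fun_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$x, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.25) +
    ggplot2::geom_line(data = object$band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "taxonomic richness", y = "community function",
                  title = sprintf("selected family: %s", object$selected))
}

#' Compare two fitted curves after scaling each to a maximum of 1
#'
#' Evaluates both fits on a common x-grid, divides each curve by its
#' maximum on the grid, and runs a paired two-tailed t-test over the grid
#' points - the standard way to ask whether one function (e.g.
#' respiration) rises faster with richness than another (e.g. cell
#' density) irrespective of units.
#'
#' @param fit_a,fit_b `div_fun_fit` objects.
#' @param grid Common x-grid; default the range shared by both fits
#'   (100 points).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_diff`
#'   (mean of scaled a minus scaled b).
#' @export
scaled_comparison <- function(fit_a, fit_b, grid = NULL) {
  stopifnot(inherits(fit_a, "div_fun_fit"), inherits(fit_b, "div_fun_fit"))
  if (is.null(grid)) {
    lo <- max(min(fit_a$data$x), min(fit_b$data$x))
    hi <- min(max(fit_a$data$x), max(fit_b$data$x))
    grid <- seq(lo, hi, length.out = 100)
  }
  ya <- predict(fit_a, grid)
  yb <- predict(fit_b, grid)
  if (max(abs(ya)) == 0 || max(abs(yb)) == 0) {
    abort("a curve is identically zero on the grid; cannot scale.",
          class = "relfun_degenerate_scaling")
  }
  sa <- ya / max(ya)
  sb <- yb / max(yb)
  if (isTRUE(all.equal(sa, sb, tolerance = 1e-12))) {
    return(tibble::tibble(statistic = 0, df = length(grid) - 1,
                          p_value = 1, mean_diff = 0))
  }
  tt <- t.test(sa, sb, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = unname(tt$estimate))
}
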