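test_that("AIC selection: exact linear data and the simplicity tie rule", {
  x <- 1:40
  df <- data.frame(richness = x, value = 2 + 0.5 * x)
  fit <- suppressWarnings(
    fit_diversity_function(df, n_mc = 50, seed = 1))
  expect_equal(fit$selected, "linear")
  expect_equal(unname(coef(fit$fits$linear)[2]), 0.5, tolerance = 1e-6)

  # constant response: every family is comparable; tie goes to linear
  dfc <- data.frame(richness = x, value = rep(3, 40))
  fitc <- suppressWarnings(fit_diversity_function(dfc, n_mc = 50, seed = 1))
  expect_equal(fitc$selected, "linear")
  expect_lt(abs(coef(fitc$fits$linear)[2]), 1e-8)

  expect_error(fit_diversity_function(df[1:3, ]),
               class = "relfun_invalid_argument")
})

test_that("hyperbolic parameters are recovered from noisy saturating data", {
  ok <- 0
  for (s in 1:5) {
    set.seed(400 + s)
    x <- runif(60, 1, 60)
    y <- 10 * x / (5 + x) + rnorm(60, 0, 0.05 * 10)
    fit <- fit_diversity_function(data.frame(richness = x, value = y),
                                  n_mc = 50, seed = s)
    if (fit$selected == "hyperbolic") {
      p <- coef(fit$fits$hyperbolic)
      if (abs(p["V"] - 10) / 10 < 0.1 && abs(p["K"] - 5) / 5 < 0.25) ok <- ok + 1
    }
  }
  expect_gte(ok, 4)
})

test_that("fit accessors: tidy, glance, band and autoplot", {
  set.seed(2)
  df <- data.frame(richness = 1:30, value = 1 + 0.3 * (1:30) + rnorm(30, 0, 0.5))
  fit <- fit_diversity_function(df, n_mc = 200, seed = 3)
  td <- tidy(fit)
  expect_true(all(c("family", "term", "estimate", "std_error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(sum(gl$selected), 1)
  expect_equal(gl$family[which.min(gl$aic)],
               gl$family[gl$delta_aic == 0])
  expect_true(all(fit$band$lo <= fit$band$hi))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("richness-bin tests: degenerate, powered and paired cases", {
  d1 <- tibble::tibble(sample_id = sprintf("c%d", 1:10), richness = 5,
                       fn = "cells", value = 1)
  r1 <- richness_bin_tests(d1)
  one <- r1[r1$test == "t_one_sample", ]
  expect_equal(one$statistic, 0)
  expect_equal(one$p_value, 1)

  set.seed(9)
  d2 <- tibble::tibble(sample_id = sprintf("c%d", 1:30), richness = 5,
                       fn = "cells", value = 1 + rnorm(30, 0.5, 0.01))
  r2 <- richness_bin_tests(d2)
  expect_lt(r2$p_value[r2$test == "t_one_sample"], 1e-6)

  # paired identical vectors: no signal, p = 1 for both paired tests
  d3 <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("c%d", 1:8), richness = 20,
                   fn = "cells", value = seq(0.9, 1.1, length.out = 8)),
    tibble::tibble(sample_id = sprintf("c%d", 1:8), richness = 20,
                   fn = "protein", value = seq(0.9, 1.1, length.out = 8)))
  r3 <- richness_bin_tests(d3)
  expect_equal(r3$p_value[r3$test == "wilcoxon_paired"], 1)
  expect_equal(r3$p_value[r3$test == "t_paired"], 1)

  # undersized bins are skipped with a notice
  d4 <- tibble::tibble(sample_id = c("a", "b"), richness = c(5, 30),
                       fn = "cells", value = c(1, 2))
  expect_message(out <- richness_bin_tests(d4), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("scaled comparison is scale-invariant and ordered by K", {
  x <- 1:100
  mk_fit <- function(K) {
    suppressWarnings(fit_diversity_function(
      data.frame(richness = x, value = 10 * x / (K + x)),
      families = "hyperbolic", n_mc = 20, seed = 1))
  }
  fa <- mk_fit(5)
  fb <- mk_fit(30)
  # identical fits and scalar multiples both give p = 1
  expect_equal(scaled_comparison(fa, fa)$p_value, 1)
  fa2 <- mk_fit(5)
  fa2$fits$hyperbolic <- minpack.lm::nlsLM(
    value ~ V * richness / (K + richness),
    data = data.frame(richness = x, value = 35 * x / (5 + x)),
    start = list(V = 35, K = 5))
  expect_equal(scaled_comparison(fa, fa2)$p_value, 1)
  # the small-K (fast-saturating) curve dominates after scaling
  cmp <- scaled_comparison(fa, fb)
  expect_gt(cmp$statistic, 0)
  expect_lt(cmp$p_value, 1e-10)
  ya <- predict(fa, x) / max(predict(fa, x))
  yb <- predict(fb, x) / max(predict(fb, x))
  expect_true(all(ya >= yb - 1e-12))
})

test_that("Kendall tau engine matches the tau-b oracle on tied data", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:30, 1)
    x <- sample(0:5, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.5)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(unname(cor(x, y, method = "kendall")), oracle_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("sliding-window screen finds a planted association, none when flat", {
  set.seed(5)
  n <- 40
  rich <- tibble::tibble(sample_id = sprintf("c%d", 1:n),
                         richness = round(seq(10, 25, length.out = n)))
  fnv <- tibble::tibble(sample_id = rich$sample_id, fn = "cells",
                        value = rich$richness + runif(n))
  # the key taxon's abundance is a strictly increasing transform of the
  # function; bystander taxa are noise
  ab <- dplyr::bind_rows(
    tibble::tibble(sample_id = rich$sample_id, taxon_id = "KEY",
                   rel_abund = plogis((fnv$value - 17) / 4)),
    tibble::tibble(sample_id = rich$sample_id, taxon_id = "N1",
                   rel_abund = runif(n)),
    tibble::tibble(sample_id = rich$sample_id, taxon_id = "N2",
                   rel_abund = runif(n)))
  hits <- sliding_window_screen(ab, fnv, rich, widths = c(4, 6))
  key <- hits[hits$taxon_id == "KEY", ]
  expect_true(all(abs(key$tau - 1) < 1e-12))
  expect_true(any(key$hit))
  expect_true(all(key$direction == "positive"))
  # q-values are monotone in p within each stratum and bounded by 1
  expect_true(all(hits$q_value <= 1))
  for (w in unique(hits$width)) {
    hw <- hits[hits$width == w & hits$fn == "cells", ]
    ord <- order(hw$p_value)
    expect_true(all(diff(hw$q_value[ord]) >= -1e-12))
    expect_true(all(hw$q_value >= hw$p_value - 1e-12))
  }
  # a constant function yields no hits
  flat <- dplyr::mutate(fnv, value = 1)
  expect_equal(nrow(sliding_window_screen(ab, flat, rich, widths = c(4, 6))), 0)
})

test_that("Loreau-Hector partition: identity, degenerate and constant-M cases", {
  # observed equals expected: all effects vanish
  m <- c(4, 2, 8)
  ry <- c(0.2, 0.3, 0.5)
  lh0 <- loreau_hector_partition(ry * m, m, ry)
  expect_equal(lh0$net, 0)
  expect_equal(lh0$complementarity, 0, tolerance = 1e-12)
  expect_equal(lh0$selection, 0, tolerance = 1e-12)

  # the identity holds exactly on random instances
  set.seed(14)
  for (rep in 1:10) {
    k <- 5
    m <- runif(k, 1, 10)
    ry <- runif(k); ry <- ry / sum(ry)
    fo <- runif(k, 0, 5)
    lh <- loreau_hector_partition(fo, m, ry)
    expect_equal(lh$net, lh$complementarity + lh$selection, tolerance = 1e-12)
  }

  # constant monocultures: selection 0, complementarity = (RTF - 1) * M
  k <- 4; M <- 3
  fo <- c(1.2, 0.5, 0.9, 1.1)
  lh <- loreau_hector_partition(fo, rep(M, k), rep(1 / k, k))
  rtf <- sum(fo / M)
  expect_equal(lh$selection, 0, tolerance = 1e-12)
  expect_equal(lh$complementarity, (rtf - 1) * M, tolerance = 1e-12)

  expect_error(loreau_hector_partition(1:2, c(1, 0)),
               class = "relfun_invalid_argument")
  expect_error(loreau_hector_partition(1:2, 1:2, c(0.4, 0.4)),
               class = "relfun_invalid_argument")
})

test_that("density-adjusted regression: type-II tests and rank checks", {
  set.seed(8)
  n <- 60
  df <- data.frame(richness = runif(n, 2, 50),
                   initial_density = 10^runif(n, 3, 5))
  df$value <- 3 + 0.8 * df$richness + rnorm(n, 0, 0.5)
  out <- regression_with_density(df)
  expect_lt(out$p_value[out$term == "richness"], 1e-10)
  expect_gt(out$p_value[out$term == "log_density"], 0.01)

  # constant response: nothing is significant
  dfc <- df; dfc$value <- 5
  outc <- suppressWarnings(regression_with_density(dfc))
  expect_true(all(outc$p_value[1:2] > 0.99))

  # collinear predictors are an explicit error
  dfx <- df; dfx$initial_density <- 10^dfx$richness
  expect_error(regression_with_density(dfx), class = "relfun_rank_deficiency")

  # balanced (orthogonal) design: type-II equals sequential sums of squares
  bal <- expand.grid(richness = c(10, 20, 30, 40),
                     ld = c(3, 4, 5))
  bal$initial_density <- 10^bal$ld
  set.seed(9)
  bal$value <- 1 + 0.5 * bal$richness + 2 * bal$ld + rnorm(nrow(bal), 0, 0.3)
  out2 <- regression_with_density(bal)
  fit1 <- lm(value ~ richness + log10(initial_density), data = bal)
  a1 <- anova(fit1)  # sequential
  expect_equal(out2$sumsq[out2$term == "richness"],
               a1["richness", "Sum Sq"], tolerance = 1e-8)
})
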