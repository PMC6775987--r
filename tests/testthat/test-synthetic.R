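test_that("regional pool: determinism, disjoint profiles, abundance skew", {
  p1 <- build_regional_pool(300, 40, seed = 7)
  p2 <- build_regional_pool(300, 40, seed = 7)
  expect_identical(p1, p2)

  # disjoint breadth: two taxa, two substrates, one each
  pd <- disjoint_pool()
  expect_equal(unname(rowSums(pd$profile > 0)), c(1, 1))
  expect_equal(unname(colSums(pd$profile > 0)), c(1, 1))

  # every taxon uses at least one substrate; abundances sum to 1
  expect_true(all(rowSums(p1$profile > 0) >= 1))
  expect_equal(sum(p1$taxa$regional_abundance), 1)

  # log-abundances match the configured log-normal (sdlog known; the
  # normalising constant only shifts the mean)
  la <- log(p1$taxa$regional_abundance)
  ks <- stats::ks.test(la, "pnorm", mean = mean(la), sd = 1.5)
  expect_gt(ks$p.value, 0.01)

  expect_error(build_regional_pool(0, 5), class = "relfun_invalid_argument")
  expect_error(build_regional_pool(3, 2, niche_breadth = "disjoint"),
               class = "relfun_invalid_argument")
})

test_that("dilution design enumeration reproduces the vessel counts", {
  expect_equal(nrow(enumerate_dilution_design()), 185)
  expect_equal(nrow(enumerate_dilution_design(1, exponents = integer(0),
                                              extra = c())), 1)
  # 2 undiluted + 2 x 2 levels + 3 extra = 9
  d <- enumerate_dilution_design(2, fold = 4, exponents = 1:2,
                                 extra = c("2" = 3))
  expect_equal(nrow(d), 9)
  expect_equal(sort(unique(d$dilution_factor)), c(1, 4, 16))
  expect_false(anyDuplicated(d$community_id) > 0)
})

test_that("inoculum assembly: extreme dilution, presence, richness trend", {
  pool <- shared_pool()
  pool$taxa$regional_abundance <- c(0.5, 0.5)

  # expected cells round to zero -> empty community
  expect_equal(nrow(assemble_inoculum(pool, 1e12, 1e6, seed = 1)), 0)
  expect_error(assemble_inoculum(pool, -1), class = "relfun_invalid_argument")

  # 1e6 cells from a uniform 2-taxon pool: both present essentially surely
  both <- vapply(1:100, function(s) {
    nrow(assemble_inoculum(pool, 1, 1e6, seed = s)) == 2
  }, logical(1))
  expect_true(all(both))

  # richness declines (weakly) with dilution
  big <- build_regional_pool(50, 10, seed = 3)
  mean_rich <- vapply(4^(0:8), function(df) {
    mean(vapply(1:50, function(s) {
      nrow(assemble_inoculum(big, df, 1e6, seed = 100 + s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rich) <= 1e-9))
})

test_that("growth on a shared pool reproduces the worked two-taxon cases", {
  ids <- c("ASV_001", "ASV_002")

  # C1: identical niches, equal split, efficiencies untouched
  c1 <- simulate_growth(ids, shared_pool(), scenario_config("null"))
  expect_equal(c1$uptake_ratio, c(0.5, 0.5))
  expect_equal(c1$a_ratio_cells, c(1, 1))
  expect_equal(true_rtf(c1)$rtf, rep(1, 3), tolerance = 1e-12)

  # C2: interference halves conversion efficiency at full overlap
  c2 <- simulate_growth(ids, shared_pool(), scenario_config("interference"))
  expect_equal(c2$overlap, c(1, 1))
  expect_equal(c2$a_ratio_cells, c(0.5, 0.5))
  expect_equal(true_rtf(c2)$rtf[true_rtf(c2)$fn == "cells"], 0.5)

  # C3: disjoint niches, full fundamental uptake retained
  c3 <- simulate_growth(ids, disjoint_pool(), scenario_config("complementation"))
  expect_equal(c3$uptake_ratio, c(1, 1))
  expect_equal(true_rtf(c3)$uptake_sum[1], 2)
  expect_equal(true_rtf(c3)$rtf, rep(2, 3))

  expect_error(simulate_growth(character(), shared_pool()),
               class = "relfun_invalid_argument")
})

test_that("uptake conserves the substrate pool", {
  set.seed(5)
  for (rep in 1:20) {
    pool <- build_regional_pool(12, 6, niche_breadth = runif(1, 0.2, 0.9),
                                seed = rep)
    members <- sample(pool$taxa$taxon_id, sample(2:8, 1))
    tr <- simulate_growth(members, pool, scenario_config("mixed"))
    total <- sum(pool$substrates$amount)
    expect_lte(sum(tr$s_comm), total + 1e-12)
    covered <- colSums(pool$profile[members, , drop = FALSE] > 0) >= 1
    if (all(covered)) expect_equal(sum(tr$s_comm), total, tolerance = 1e-12)
  }
})

test_that("noiseless measurements recover the true functions exactly", {
  pool <- null_pool(6, 3, seed = 2)
  members <- pool$taxa$taxon_id[1:4]
  tr <- simulate_growth(members, pool, scenario_config("null"))
  scen <- scenario_config("null", noiseless = TRUE)
  m <- simulate_measurements(list(comm = tr), scen, seed = 1, pool = pool)
  blanks <- m$timeseries[grepl("^BLANK", m$timeseries$sample_id), ]
  s <- summarize_functions(m$timeseries[m$timeseries$sample_id == "comm", ],
                           blanks = blanks, volume_ml = scen$volume_ml)
  vol <- scen$volume_ml
  expect_equal(s$max_cell_density * vol, sum(tr$cells), tolerance = 1e-9)
  expect_equal(s$max_total_protein * vol, sum(tr$protein), tolerance = 1e-9)
  expect_equal(s$total_co2_110h, sum(tr$co2), tolerance = 1e-9)
  # growth saturates by 40 h, so the short window captures everything
  expect_equal(s$total_co2_40h, sum(tr$co2), tolerance = 1e-9)
  expect_equal(s$max_protein_per_cell, sum(tr$protein) / sum(tr$cells),
               tolerance = 1e-9)
})

test_that("read sampling is unbiased at multinomial scale", {
  pool <- null_pool(3, 3, seed = 4)
  # engineer cell fractions (0.5, 0.3, 0.2) via regional abundances on a
  # fully shared pool: equal split makes fractions equal, so instead use
  # per-taxon private substrates sized to the target
  pool$profile[] <- diag(3)
  pool$substrates$amount <- c(0.5, 0.3, 0.2) * 2
  tr <- simulate_growth(pool$taxa$taxon_id, pool, scenario_config("null"))
  expect_equal(tr$cells / sum(tr$cells), c(0.5, 0.3, 0.2))

  scen <- scenario_config("null", sequencing_depth = 2000,
                          sample_contaminant_fraction = 0.01)
  est <- matrix(NA_real_, 200, 3)
  for (s in 1:200) {
    m <- simulate_measurements(list(c1 = tr), scen, seed = s, pool = pool)
    counts <- asv_counts(m$asv)["c1", pool$taxa$taxon_id]
    est[s, ] <- counts / sum(counts)
  }
  se <- sqrt(c(0.5, 0.3, 0.2) * c(0.5, 0.7, 0.8) / 2000 / 200)
  expect_true(all(abs(colMeans(est) - c(0.5, 0.3, 0.2)) < 3 * se))
})

test_that("planted blank contaminants are flagged by the composition filter", {
  pool <- null_pool(8, 4, seed = 6)
  sets <- list(a = pool$taxa$taxon_id[1:4], b = pool$taxa$taxon_id[3:8])
  sim <- simulate_communities(pool, sets, scenario_config("null"),
                              mono_replicates = 1, seed = 2)
  out <- suppressMessages(remove_contaminants(sim$asv))
  expect_true("CONTAM_01" %in% attr(out, "removed_taxa"))
  expect_true("BLANK_BG" %in% attr(out, "removed_taxa"))
  expect_false(any(pool$taxa$taxon_id %in% attr(out, "removed_taxa")))
})

test_that("simulation is deterministic end to end for a fixed seed", {
  pool <- build_regional_pool(20, 8, seed = 9)
  design <- enumerate_dilution_design(2, exponents = 2:5, extra = c())
  scen <- scenario_config("mixed")
  s1 <- simulate_experiment(pool, design, scen, n_isolates = 10,
                            mono_replicates = 2, seed = 42)
  s2 <- simulate_experiment(pool, design, scen, n_isolates = 10,
                            mono_replicates = 2, seed = 42)
  expect_identical(s1$asv, s2$asv)
  expect_identical(s1$timeseries, s2$timeseries)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(pool, design, scen, n_isolates = 10,
                            mono_replicates = 2, seed = 43)
  expect_false(identical(s1$asv, s3$asv))
})

test_that("richer communities peak earlier (time to peak pattern)", {
  pool <- null_pool(30, 6, seed = 11)
  scen <- scenario_config("null", noiseless = TRUE)
  small <- simulate_growth(pool$taxa$taxon_id[1:2], pool, scen)
  large <- simulate_growth(pool$taxa$taxon_id[1:20], pool, scen)
  expect_gte(max(small$t_sat_h), max(large$t_sat_h))
  expect_true(all(large$t_sat_h <= 40))
})
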