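test_that("monoculture catalog: purity boundary and replicate aggregation", {
  ab <- tibble::tibble(
    sample_id = c("m1", "m1", "m2", "m2", "m3", "m4"),
    taxon_id = c("A", "x", "A", "x", "B", "B"),
    rel_abund = c(0.90, 0.10, 0.95, 0.05, 0.89, 0.92))
  su <- mk_summary(c("m1", "m2", "m3", "m4"),
                   cells = c(10, 14, 100, 50),
                   protein = c(1, 3, 9, 9), co2_40 = c(2, 2, 2, 2),
                   co2 = c(4, 4, 4, 4))
  cat <- identify_monocultures(ab, su)
  # A qualifies at exactly 0.90 and at 0.95; mean of 10 and 14 is 12
  expect_equal(cat$f_mono[cat$taxon_id == "A" & cat$fn == "cells"], 12)
  expect_equal(cat$n_samples[cat$taxon_id == "A" & cat$fn == "cells"], 2L)
  # m3 (0.89) is excluded; B's catalog comes from m4 alone
  expect_equal(cat$f_mono[cat$taxon_id == "B" & cat$fn == "cells"], 50)
  expect_true(all(cat$purity >= 0.90))
  # median aggregation available
  cat_med <- identify_monocultures(ab, su, aggregate = "median")
  expect_equal(cat_med$f_mono[cat_med$taxon_id == "A" & cat_med$fn == "cells"], 12)
})

test_that("constitutability: coverage boundary and renormalisation", {
  cat <- tibble::tibble(taxon_id = c("A", "B"), fn = "cells", f_mono = 1)
  ab <- tibble::tibble(
    sample_id = rep(c("c1", "c2", "c3"), each = 3),
    taxon_id = rep(c("A", "B", "zz"), 3),
    rel_abund = c(0.5, 0.35, 0.15,   # exactly 0.85 -> constitutable
                  0.5, 0.34, 0.16,   # 0.84 -> not
                  0.6, 0.40, 0.00))
  cc <- assess_constitutable(ab, cat)
  c1 <- cc[cc$sample_id == "c1", ]
  expect_true(all(c1$constitutable))
  expect_equal(c1$coverage[1], 0.85)
  expect_equal(sort(c1$renorm_abund), sort(c(0.5, 0.35) / 0.85),
               tolerance = 1e-12)
  expect_equal(c1$renorm_abund[c1$taxon_id == "A"], 0.588235294,
               tolerance = 1e-6)
  expect_false(any(cc$constitutable[cc$sample_id == "c2"]))
  expect_equal(sum(cc$renorm_abund[cc$sample_id == "c3"]), 1)
})

test_that("per-taxon apportioning conserves the community function", {
  consti <- tibble::tibble(
    sample_id = "c1", taxon_id = c("A", "B"),
    rel_abund = c(0.6, 0.4), renorm_abund = c(0.6, 0.4),
    coverage = 1, n_catalog_taxa = 2L, constitutable = TRUE)
  su <- mk_summary("c1", cells = 100, protein = 10, co2_40 = 5, co2 = 6)
  pt <- per_taxon_functions(consti, su)
  expect_equal(sort(pt$f_taxon[pt$fn == "cells"]), c(40, 60))
  expect_equal(sum(pt$f_taxon[pt$fn == "cells"]), 100, tolerance = 1e-12)
  expect_equal(sum(pt$f_taxon[pt$fn == "protein"]), 10, tolerance = 1e-12)
  # single-taxon community receives the whole function
  single <- dplyr::mutate(consti[1, ], renorm_abund = 1)
  expect_equal(per_taxon_functions(single, su)$f_taxon[1], 100)
  # missing measurements are an explicit error
  expect_error(per_taxon_functions(consti, su[su$sample_id == "zz", ]),
               class = "relfun_incomplete_measurement")
})

test_that("RTF through the full estimation path matches the worked examples", {
  scen_null <- scenario_config("null", noiseless = TRUE)
  ids <- c("ASV_001", "ASV_002")

  sim1 <- simulate_communities(shared_pool(), list(C1 = ids), scen_null,
                               mono_replicates = 2, seed = 5)
  r1 <- rtf_from_simulation(sim1)
  expect_equal(r1$rtf, rep(1, 3), tolerance = 1e-9)
  expect_equal(r1$rmf, rep(0.5, 3), tolerance = 1e-9)

  scen_int <- scenario_config("interference", noiseless = TRUE)
  sim2 <- simulate_communities(shared_pool(), list(C2 = ids), scen_int,
                               mono_replicates = 2, seed = 5)
  r2 <- rtf_from_simulation(sim2)
  expect_equal(r2$rtf[r2$fn == "cells"], 0.5, tolerance = 1e-9)
  expect_lt(r2$rtf[r2$fn == "protein"], 1)
  expect_gt(r2$rtf[r2$fn == "co2"], 1)

  scen_comp <- scenario_config("complementation", noiseless = TRUE)
  sim3 <- simulate_communities(disjoint_pool(), list(C3 = ids), scen_comp,
                               mono_replicates = 2, seed = 5)
  r3 <- rtf_from_simulation(sim3)
  expect_equal(r3$rtf, rep(2, 3), tolerance = 1e-9)
  expect_equal(r3$rmf, rep(1, 3), tolerance = 1e-9)
})

test_that("degenerate monoculture values are rejected", {
  cat <- tibble::tibble(taxon_id = "A", fn = "cells", f_mono = 0)
  pt <- tibble::tibble(sample_id = "c", taxon_id = "A", renorm_abund = 1,
                       fn = "cells", f_taxon = 5)
  expect_error(compute_rtf(pt, cat), class = "relfun_degenerate_monoculture")
  # and taxa absent from the catalog
  cat2 <- tibble::tibble(taxon_id = "B", fn = "cells", f_mono = 1)
  expect_error(compute_rtf(pt, cat2), class = "relfun_invalid_argument")
})

test_that("decomposition bounds bracket the uptake sum", {
  rtf <- structure(tibble::tibble(
    sample_id = rep(c("u", "v"), each = 2),
    fn = rep(c("co2", "protein"), 2),
    n_taxa = 2L, coverage = 1,
    rtf = c(1, 1, 1.8, 1.0)),
    class = c("rtf_result", class(tibble::tibble())))
  rtf$rmf <- rtf$rtf / rtf$n_taxa
  b <- decomposition_bounds(rtf)
  expect_equal(b$uptake_lo[b$sample_id == "u"], 1)
  expect_equal(b$uptake_hi[b$sample_id == "u"], 1)
  expect_equal(b$regime[b$sample_id == "u"], "indeterminate")
  expect_equal(b$uptake_lo[b$sample_id == "v"], 1.0)
  expect_equal(b$uptake_hi[b$sample_id == "v"], 1.8)
  expect_equal(b$sbar_hi[b$sample_id == "v"], 0.9)
})

test_that("adjustment factors are ratios to the community mean and unit-free", {
  cat <- tibble::tibble(
    taxon_id = rep(c("A", "B", "C"), each = 2),
    fn = rep(c("cells", "protein"), 3),
    f_mono = c(1, 2, 1, 0.5, 1, 0.5))
  mem <- tibble::tibble(sample_id = "c1", taxon_id = c("A", "B", "C"))
  af <- adjustment_factors(cat, mem, fns = "protein")
  # protein/cell ratios (2, 0.5, 0.5); mean 1 -> factors (2, 0.5, 0.5)
  expect_equal(af$factor, c(2, 0.5, 0.5))
  expect_true(all(af$in_range))
  # scale invariance in the function's units
  cat10 <- dplyr::mutate(cat, f_mono = ifelse(fn == "protein",
                                              f_mono * 10, f_mono))
  expect_equal(adjustment_factors(cat10, mem, fns = "protein")$factor,
               af$factor)
  # identical per-cell ratios give factors of exactly 1
  cat1 <- dplyr::mutate(cat, f_mono = ifelse(fn == "protein", 3, f_mono))
  expect_equal(adjustment_factors(cat1, mem, fns = "protein")$factor,
               rep(1, 3))
})

test_that("rCUE formula: identity at ratio 1, arithmetic, monotonicity", {
  e1 <- estimate_rcue(1, 1)
  g <- e1$grid[[1]]
  expect_equal(nrow(g), 61)
  expect_equal(range(g$cue), c(0, 0.6))
  expect_equal(g$rcue, rep(1, 61))
  expect_equal(e1$mean_rcue, 1)

  e2 <- estimate_rcue(2, 1)
  expect_equal(e2$grid[[1]]$rcue[e2$grid[[1]]$cue == 0.5], 2 / 3)

  # strictly decreasing in the ratio at any fixed CUE
  ratios <- c(0.5, 1, 2, 4)
  vals <- vapply(ratios, function(r) {
    estimate_rcue(r, 1)$grid[[1]]$rcue[31]  # cue = 0.30
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(estimate_rcue(-1, 1), class = "relfun_invalid_argument")
  expect_error(estimate_rcue(1, 0), class = "relfun_invalid_argument")
})

test_that("noiseless recovery: estimated RTF equals the ground-truth identity", {
  # homogeneous-trait scenarios: the full estimation path is exact
  for (scen_name in c("null", "interference", "complementation")) {
    pool <- if (scen_name == "complementation") {
      build_regional_pool(6, 6, niche_breadth = "disjoint", cue_sd = 0,
                          protein_per_cell_cv = 0, seed = 8)
    } else {
      null_pool(6, 3, seed = 8)
    }
    scen <- scenario_config(scen_name, noiseless = TRUE)
    sets <- list(g1 = pool$taxa$taxon_id[1:3], g2 = pool$taxa$taxon_id[2:6])
    sim <- simulate_communities(pool, sets, scen, mono_replicates = 1,
                                seed = 3)
    est <- rtf_from_simulation(sim)
    for (sid in names(sets)) {
      tr <- simulate_growth(sets[[sid]], pool, scen)
      truth <- true_rtf(tr)
      for (f in truth$fn) {
        expect_equal(est$rtf[est$sample_id == sid & est$fn == f],
                     truth$rtf[truth$fn == f], tolerance = 1e-9)
      }
    }
  }

  # heterogeneous traits: computing RTF from true per-taxon functions
  # still satisfies the efficiency-times-uptake identity exactly
  pool <- build_regional_pool(10, 8, niche_breadth = 0.4, cue_sd = 0.1,
                              protein_per_cell_cv = 0.3, seed = 12)
  scen <- scenario_config("mixed", noiseless = TRUE)
  members <- pool$taxa$taxon_id[1:5]
  tr <- simulate_growth(members, pool, scen)
  catalog <- tibble::tibble(
    taxon_id = rep(tr$taxon_id, 3),
    fn = rep(c("cells", "protein", "co2"), each = nrow(tr)),
    f_mono = c(tr$cells_mono, tr$protein_mono, tr$co2_mono),
    n_samples = 1L, purity = 1)
  pt <- tibble::tibble(
    sample_id = "truth",
    taxon_id = rep(tr$taxon_id, 3),
    fn = rep(c("cells", "protein", "co2"), each = nrow(tr)),
    f_taxon = c(tr$cells, tr$protein, tr$co2))
  est <- compute_rtf(pt, catalog)
  truth <- true_rtf(tr)
  expect_equal(est$rtf[match(truth$fn, est$fn)], truth$rtf, tolerance = 1e-9)
})

test_that("estimation error shrinks as measurement noise vanishes", {
  pool <- null_pool(20, 5, seed = 21)
  sets <- lapply(1:12, function(i) sample(pool$taxa$taxon_id, 2 + i))
  names(sets) <- sprintf("c%02d", 1:12)
  med_dev <- vapply(c(0.2, 0.1, 0.05, 0), function(cv) {
    scen <- if (cv == 0) scenario_config("null", noiseless = TRUE) else
      scenario_config("null", cells_cv = cv, protein_cv = cv, co2_cv = cv)
    sim <- simulate_communities(pool, sets, scen, mono_replicates = 3,
                                seed = 77)
    r <- rtf_from_simulation(sim)
    median(abs(r$rtf - 1))
  }, numeric(1))
  expect_true(all(diff(med_dev) < 0))
  expect_lt(med_dev[4], 1e-9)
})

test_that("RTF is invariant to taxon relabeling and common rescaling", {
  cat <- tibble::tibble(taxon_id = rep(c("A", "B"), each = 3),
                        fn = rep(c("cells", "protein", "co2"), 2),
                        f_mono = c(10, 2, 1, 20, 1, 3))
  pt <- tibble::tibble(sample_id = "c",
                       taxon_id = rep(c("A", "B"), each = 3),
                       fn = rep(c("cells", "protein", "co2"), 2),
                       f_taxon = c(4, 1, 0.5, 12, 0.3, 2))
  base <- compute_rtf(pt, cat)
  # relabel
  swap <- function(x) dplyr::mutate(x, taxon_id = dplyr::recode(
    .data$taxon_id, A = "B", B = "A"))
  relab <- compute_rtf(swap(pt), swap(cat))
  expect_equal(relab$rtf, base$rtf)
  # multiply community and monoculture functions by a common constant
  scaled <- compute_rtf(dplyr::mutate(pt, f_taxon = f_taxon * 7.3),
                        dplyr::mutate(cat, f_mono = f_mono * 7.3))
  expect_equal(scaled$rtf, base$rtf, tolerance = 1e-12)
})
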