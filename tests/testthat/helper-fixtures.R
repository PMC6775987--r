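# Shared fixture builders; everything is generated in code.

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# two generalist taxa on a single shared substrate (worked example C1/C2)
shared_pool <- function(seed = 1) {
  build_regional_pool(2, 1, niche_breadth = 1, cue_sd = 0,
                      protein_per_cell_cv = 0, seed = seed)
}

# two specialist taxa on disjoint substrates (worked example C3)
disjoint_pool <- function(seed = 1) {
  build_regional_pool(2, 2, niche_breadth = "disjoint", cue_sd = 0,
                      protein_per_cell_cv = 0, seed = seed)
}

# a homogeneous-trait generalist pool for null-model recovery designs
null_pool <- function(n_taxa = 40, n_substrates = 8, seed = 99) {
  build_regional_pool(n_taxa, n_substrates, niche_breadth = 1, cue_sd = 0,
                      protein_per_cell_cv = 0, seed = seed)
}

# minimal function-summary tibble for hand-built RTF inputs
mk_summary <- function(sample_id, cells, protein, co2_40 = co2, co2 = 1) {
  tibble::tibble(sample_id = sample_id,
                 max_cell_density = cells,
                 max_total_protein = protein,
                 max_protein_per_cell = protein / cells,
                 total_co2_40h = co2_40,
                 total_co2_110h = co2,
                 time_to_peak_h = 40)
}

# wide ASV table from a named list of count vectors
mk_asv <- function(counts, blank = NULL, stage = NULL) {
  taxa <- sort(unique(unlist(lapply(counts, names))))
  m <- t(vapply(counts, function(x) {
    out <- setNames(rep(0, length(taxa)), taxa)
    out[names(x)] <- x
    out
  }, numeric(length(taxa))))
  dplyr::bind_cols(
    tibble::tibble(sample_id = names(counts),
                   blank = blank %||% rep(FALSE, length(counts)),
                   stage = stage %||% rep("community", length(counts))),
    tibble::as_tibble(m))
}

# brute-force abundance-weighted MPD (double loop)
oracle_mpd <- function(f, d) {
  f <- f / sum(f)
  num <- 0; den <- 0
  for (i in seq_along(f)) for (j in seq_along(f)) {
    if (i != j) {
      num <- num + f[i] * f[j] * d[i, j]
      den <- den + f[i] * f[j]
    }
  }
  unname(num / den)
}

# brute-force abundance-weighted MNTD (recipient-taxon weighting)
oracle_mntd <- function(f, d) {
  f <- f / sum(f)
  unname(sum(vapply(seq_along(f), function(i) {
    f[i] * min(d[i, -i])
  }, numeric(1))))
}

# brute-force Kendall tau-b with tie correction
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}
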