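# Ground-truthed synthetic consumer-resource communities emulating a
# two-stage dilution / dilution-to-extinction experiment: a skewed
# regional taxon pool is serially diluted to assemble communities of
# decreasing richness, each community grows on a shared multi-substrate
# carbon pool (with tunable niche overlap and interference), and noisy
# measurement layers (FACS counts, protein fluorescence, CO2-indicator
# absorbance, multinomial 16S reads with blank contaminants) produce the
# same data shapes the real experiment yields.

# run code with a temporary RNG state when seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Scenario configuration for the community simulator
#'
#' A scenario bundles the interaction regime with the measurement-noise
#' layer.  The four regimes mirror the worked two-taxon examples of the
#' RTF framework:
#' \describe{
#'   \item{null}{full-generalist resource profiles, no interference,
#'     homogeneous conversion traits; the null model holds exactly and
#'     RTF = 1 for every function.}
#'   \item{interference}{as null, but sharing resources costs conversion
#'     efficiency (multiplicative penalty per unit niche overlap), so
#'     biomass RTF < 1 while respiration RTF > 1.}
#'   \item{complementation}{disjoint resource profiles; every taxon keeps
#'     its full fundamental niche in community, so RTF = richness and
#'     RMF = 1.}
#'   \item{mixed}{partial niche overlap, heterogeneous traits and
#'     moderate interference - the realistic regime.}
#' }
#'
#' @param scenario One of `"null"`, `"interference"`, `"complementation"`,
#'   `"mixed"`.
#' @param interference_strength Multiplicative conversion-efficiency
#'   penalty per unit niche overlap, in `[0, 1]`.  Default depends on the
#'   scenario (0, 0.5, 0, 0.3 respectively).
#' @param sequencing_depth Reads per sample for the 16S layer
#'   (default 10000).
#' @param sequencing Simulate multinomial read sampling (`TRUE`, default).
#'   With `FALSE` the ASV table carries expected (non-integer) counts,
#'   making composition exact - the noiseless validation mode.
#' @param cells_cv,protein_cv,co2_cv Coefficients of variation of the
#'   multiplicative log-normal measurement noise on cell counts, per-cell
#'   protein fluorescence, and CO2 readings.  Defaults 0.1, 0.1, 0.04
#'   (the CO2 default matches the +/-4 percent precision typical of the
#'   colorimetric calibration).
#' @param n_blanks Number of blank wells per simulated plate (default 4).
#' @param blank_contaminant_fraction Relative abundance of the planted
#'   contaminant ASV in blank samples (default 0.05).
#' @param sample_contaminant_fraction Contaminant carry-over into real
#'   samples (default 0.01).
#' @param blank_leak_fraction Cross-talk of real taxa into blanks
#'   (default 0.005).
#' @param ambient_co2_percent Atmospheric CO2 signal present in every
#'   well, removed by blank correction (default 0.04 percent).
#' @param volume_ml Culture volume (default 0.58 mL).
#' @param mono_purity Read purity of dilution-to-extinction samples
#'   (default 0.97).
#' @param noiseless Convenience switch: `TRUE` zeroes all CVs and
#'   disables read sampling.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("mixed", "null", "interference",
                                         "complementation"),
                            interference_strength = NULL,
                            sequencing_depth = 10000,
                            sequencing = TRUE,
                            cells_cv = 0.1, protein_cv = 0.1, co2_cv = 0.04,
                            n_blanks = 4,
                            blank_contaminant_fraction = 0.05,
                            sample_contaminant_fraction = 0.01,
                            blank_leak_fraction = 0.005,
                            ambient_co2_percent = 0.04,
                            volume_ml = 0.58,
                            mono_purity = 0.97,
                            noiseless = FALSE) {
  scenario <- match.arg(scenario)
  default_interf <- c(null = 0, interference = 0.5, complementation = 0,
                      mixed = 0.3)
  interference_strength <- interference_strength %||% unname(default_interf[scenario])
  check_number(interference_strength, "interference_strength", min = 0, max = 1)
  check_number(sequencing_depth, "sequencing_depth", min = 1)
  for (cv in c(cells_cv, protein_cv, co2_cv)) check_number(cv, "noise cv", min = 0)
  if (noiseless) {
    cells_cv <- protein_cv <- co2_cv <- 0
    sequencing <- FALSE
  }
  structure(list(
    scenario = scenario,
    interference_strength = interference_strength,
    sequencing_depth = sequencing_depth,
    sequencing = sequencing,
    cells_cv = cells_cv, protein_cv = protein_cv, co2_cv = co2_cv,
    n_blanks = n_blanks,
    blank_contaminant_fraction = blank_contaminant_fraction,
    sample_contaminant_fraction = sample_contaminant_fraction,
    blank_leak_fraction = blank_leak_fraction,
    ambient_co2_percent = ambient_co2_percent,
    volume_ml = volume_ml,
    mono_purity = mono_purity
  ), class = "scenario_config")
}

# pool-construction arguments implied by a scenario regime
scenario_pool_args <- function(scenario) {
  switch(scenario,
    null = list(niche_breadth = 1, cue_sd = 0, protein_per_cell_cv = 0),
    interference = list(niche_breadth = 1, cue_sd = 0, protein_per_cell_cv = 0),
    complementation = list(niche_breadth = "disjoint", cue_sd = 0,
                           protein_per_cell_cv = 0),
    mixed = list(niche_breadth = 0.3, cue_sd = 0.1, protein_per_cell_cv = 0.3)
  )
}

#' Build a regional taxon pool and its shared substrate pool
#'
#' Emulates the source community from which dilution series are seeded: a
#' set of taxa with log-normally skewed regional abundances, each capable
#' of using a subset of the shared carbon substrates, and carrying the
#' ground-truth conversion traits (carbon-use efficiency, cells produced
#' per unit assimilated carbon, protein per cell).
#'
#' @param n_taxa,n_substrates Pool sizes; both must be >= 1.
#' @param niche_breadth Either a fraction in (0, 1] - each taxon uses a
#'   binomial `(n_substrates, niche_breadth)` number of random substrates
#'   (at least one) - or `"disjoint"`, which partitions the substrates
#'   among the taxa so fundamental niches do not overlap (requires
#'   `n_substrates >= n_taxa`).
#' @param abundance_sdlog Log-sd of the log-normal regional abundance
#'   distribution (default 1.5).
#' @param cue_mean,cue_sd Mean and sd of taxon carbon-use efficiency,
#'   truncated to `[0.01, 0.6]` (thermodynamic upper limit 0.6).
#' @param cells_per_carbon Cells produced per unit assimilated carbon
#'   (default 5e5; common to all taxa so that cell count is a clean
#'   resource readout).
#' @param protein_per_cell_mean,protein_per_cell_cv Mean and CV of
#'   per-cell protein (log-normal across taxa; CV 0 gives identical
#'   values).
#' @param substrate_total Total carbon in the shared pool, split equally
#'   across substrates (default 2 carbon units).
#' @param seed Integer seed; identical seeds give identical pools.
#' @return A `regional_pool` list: `taxa` (tibble of traits and regional
#'   abundances), `profile` (taxa x substrates use-weight matrix),
#'   `substrates` (tibble of substrate amounts).
#' @export
build_regional_pool <- function(n_taxa, n_substrates,
                                niche_breadth = 0.3,
                                abundance_sdlog = 1.5,
                                cue_mean = 0.3, cue_sd = 0.1,
                                cells_per_carbon = 5e5,
                                protein_per_cell_mean = 1,
                                protein_per_cell_cv = 0.3,
                                substrate_total = 2,
                                seed = NULL) {
  n_taxa <- check_count(n_taxa, "n_taxa")
  n_substrates <- check_count(n_substrates, "n_substrates")
  check_number(substrate_total, "substrate_total", min = 0)
  with_seed(seed, {
    taxon_id <- sprintf("ASV_%03d", seq_len(n_taxa))
    substrate_id <- sprintf("S%02d", seq_len(n_substrates))
    ab <- rlnorm(n_taxa, meanlog = 0, sdlog = abundance_sdlog)
    profile <- matrix(0, n_taxa, n_substrates,
                      dimnames = list(taxon_id, substrate_id))
    if (identical(niche_breadth, "disjoint")) {
      if (n_substrates < n_taxa) {
        abort("disjoint profiles need `n_substrates >= n_taxa`.",
              class = "relfun_invalid_argument")
      }
      owner <- rep(seq_len(n_taxa), length.out = n_substrates)
      profile[cbind(owner, seq_len(n_substrates))] <- 1
    } else {
      check_number(niche_breadth, "niche_breadth", min = 1e-9, max = 1)
      for (i in seq_len(n_taxa)) {
        k <- max(1L, stats::rbinom(1L, n_substrates, niche_breadth))
        profile[i, sample.int(n_substrates, k)] <- 1
      }
    }
    cue <- pmin(0.6, pmax(0.01, rnorm(n_taxa, cue_mean, cue_sd)))
    ppc <- if (protein_per_cell_cv > 0) {
      protein_per_cell_mean * lognormal_noise(n_taxa, protein_per_cell_cv)
    } else {
      rep(protein_per_cell_mean, n_taxa)
    }
    structure(list(
      taxa = tibble::tibble(
        taxon_id = taxon_id,
        regional_abundance = ab / sum(ab),
        cue = cue,
        cells_per_carbon = cells_per_carbon,
        protein_per_cell = ppc,
        t_sat_h = sample(c(24, 32, 40), n_taxa, replace = TRUE,
                         prob = c(0.3, 0.4, 0.3))
      ),
      profile = profile,
      substrates = tibble::tibble(
        substrate_id = substrate_id,
        amount = rep(substrate_total / n_substrates, n_substrates)
      )
    ), class = "regional_pool")
  })
}

#' @export
print.regional_pool <- function(x, ...) {
  cat(sprintf("<regional_pool> %d taxa x %d substrates (total carbon %.3g)\n",
              nrow(x$taxa), nrow(x$substrates), sum(x$substrates$amount)))
  invisible(x)
}

#' Enumerate the serial-dilution assembly design
#'
#' One record per inoculum vessel: `n_replicates` undiluted communities
#' plus `n_replicates` at each `fold^exponent` dilution level, plus any
#' extra replicates at selected levels.  The defaults reproduce the
#' 185-community design (15 undiluted, 15 at each of levels 4^2..4^11,
#' and 5 and 15 additional sub-communities at the two highest levels).
#'
#' @param n_replicates Replicates per level (default 15).
#' @param fold Dilution fold per step (default 4).
#' @param exponents Integer dilution exponents (default `2:11`).
#' @param extra Named integer vector of additional replicates, names are
#'   exponents (default `c("10" = 5, "11" = 15)`).
#' @return A tibble `community_id`, `replicate`, `exponent`,
#'   `dilution_factor`.
#' @export
enumerate_dilution_design <- function(n_replicates = 15, fold = 4,
                                      exponents = 2:11,
                                      extra = c("10" = 5, "11" = 15)) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  rows <- list(tibble::tibble(exponent = 0L, replicate = seq_len(n_replicates)))
  for (e in exponents) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(exponent = as.integer(e), replicate = seq_len(n_replicates))
  }
  for (nm in names(extra)) {
    e <- as.integer(nm)
    n_extra <- as.integer(extra[[nm]])
    if (n_extra > 0) {
      base <- if (e %in% c(0L, as.integer(exponents))) n_replicates else 0L
      rows[[length(rows) + 1L]] <-
        tibble::tibble(exponent = e, replicate = base + seq_len(n_extra))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$dilution_factor <- as.numeric(fold)^out$exponent
  out$community_id <- sprintf("C_e%02d_r%02d", out$exponent, out$replicate)
  out[, c("community_id", "replicate", "exponent", "dilution_factor")]
}

#' Assemble an inoculum community by diluting the regional pool
#'
#' Draws `round(inoculum_cells / dilution_factor)` founder cells by
#' multinomial sampling from the regional abundance distribution; the
#' community members are the taxa with at least one founder cell.
#'
#' @param pool A `regional_pool`.
#' @param dilution_factor Dilution applied to the source (must be > 0).
#' @param inoculum_cells Cells in the undiluted inoculum (default 1e6,
#'   approximately 3e5 cells/mL in a 30 mL vessel; the slight mismatch of
#'   these two printed figures is inherited from the source design).
#' @param seed Optional integer seed.
#' @return A tibble `taxon_id`, `founder_cells` (possibly zero rows when
#'   the expected cell number rounds to zero).
#' @export
assemble_inoculum <- function(pool, dilution_factor, inoculum_cells = 1e6,
                              seed = NULL) {
  stopifnot(inherits(pool, "regional_pool"))
  check_number(inoculum_cells, "inoculum_cells", min = 0)
  if (!is.numeric(dilution_factor) || dilution_factor <= 0) {
    abort("`dilution_factor` must be > 0.", class = "relfun_invalid_argument")
  }
  n <- round(inoculum_cells / dilution_factor)
  if (n < 1) {
    return(tibble::tibble(taxon_id = character(), founder_cells = integer()))
  }
  with_seed(seed, {
    counts <- as.integer(rmultinom(1, n, pool$taxa$regional_abundance))
    keep <- counts >= 1L
    tibble::tibble(taxon_id = pool$taxa$taxon_id[keep],
                   founder_cells = counts[keep])
  })
}

#' Simulate deterministic growth of a community on the shared pool
#'
#' Each substrate's carbon is split among the member taxa capable of
#' using it, proportionally to their use-profile weights (an equal split
#' when weights are equal); substrates with no capable member go unused.
#' This yields each taxon's realized uptake \eqn{S_{C,i}}.  Interference
#' acts multiplicatively on conversion efficiency only:
#' \eqn{cue_{C,i} = cue_i (1 - s \cdot o_i)} where `s` is the scenario's
#' `interference_strength` and \eqn{o_i} is the fraction of taxon i's
#' fundamental niche (carbon it can reach alone) shared with at least one
#' other member.  Per-taxon functions follow:
#' cells `= cue * S * cells_per_carbon`, protein `= cells *
#' protein_per_cell`, CO2 `= (1 - cue) * S`.  Monoculture counterparts
#' (single member, full pool access, no interference) give
#' \eqn{S_i} and the monoculture functions \eqn{F_i}.
#'
#' @param members Character vector of taxon ids (or a tibble with a
#'   `taxon_id` column, e.g. from [assemble_inoculum()]); must be
#'   non-empty and a subset of the pool.
#' @param pool A `regional_pool`.
#' @param scenario A [scenario_config()].
#' @return A `growth_truth` tibble, one row per member: realized and
#'   fundamental uptake (`s_comm`, `s_mono`), niche `overlap`, community
#'   and monoculture efficiencies, the per-function values in community
#'   (`cells`, `protein`, `co2`) and monoculture (`*_mono`), the
#'   efficiency ratios `a_ratio_*`, and the effective saturation time.
#' @export
simulate_growth <- function(members, pool, scenario = scenario_config("null")) {
  stopifnot(inherits(pool, "regional_pool"), inherits(scenario, "scenario_config"))
  if (is.data.frame(members)) members <- members$taxon_id
  members <- as.character(members)
  if (length(members) == 0L) {
    abort("`members` must be non-empty.", class = "relfun_invalid_argument")
  }
  unknown <- setdiff(members, pool$taxa$taxon_id)
  if (length(unknown)) {
    abort(sprintf("unknown taxa: %s.", paste(unknown, collapse = ", ")),
          class = "relfun_invalid_argument")
  }
  amounts <- pool$substrates$amount
  if (any(amounts < 0)) {
    abort("substrate amounts must be >= 0.", class = "relfun_invalid_argument")
  }
  W <- pool$profile[members, , drop = FALSE]
  usable <- W > 0
  cap <- colSums(W)
  # proportional split of each substrate among capable members
  share <- sweep(W, 2, ifelse(cap > 0, cap, 1), "/")
  share[, cap == 0] <- 0
  s_comm <- as.numeric(share %*% amounts)
  s_mono <- as.numeric(usable %*% amounts)
  shared <- usable & matrix(colSums(usable) > 1, nrow(usable), ncol(usable),
                            byrow = TRUE)
  overlap <- as.numeric(shared %*% amounts) / s_mono
  traits <- pool$taxa[match(members, pool$taxa$taxon_id), ]
  cue_comm <- traits$cue * pmax(0, 1 - scenario$interference_strength * overlap)
  n <- length(members)
  t_cap <- if (n > 12) 24 else if (n > 4) 32 else 40
  tibble::tibble(
    taxon_id = members,
    s_mono = s_mono,
    s_comm = s_comm,
    uptake_ratio = s_comm / s_mono,
    overlap = overlap,
    cue = traits$cue,
    cue_comm = cue_comm,
    cells = cue_comm * s_comm * traits$cells_per_carbon,
    protein = cue_comm * s_comm * traits$cells_per_carbon * traits$protein_per_cell,
    co2 = (1 - cue_comm) * s_comm,
    cells_mono = traits$cue * s_mono * traits$cells_per_carbon,
    protein_mono = traits$cue * s_mono * traits$cells_per_carbon * traits$protein_per_cell,
    co2_mono = (1 - traits$cue) * s_mono,
    a_ratio_cells = cue_comm / traits$cue,
    a_ratio_protein = cue_comm / traits$cue,
    a_ratio_co2 = (1 - cue_comm) / (1 - traits$cue),
    t_sat_h = pmin(traits$t_sat_h, t_cap)
  ) |>
    structure(class = c("growth_truth", "tbl_df", "tbl", "data.frame"))
}

#' Ground-truth RTF of a simulated community
#'
#' The exact relative total function per community function, computed
#' from the generator's per-taxon truth via the efficiency-times-uptake
#' decomposition \eqn{RTF = \sum_i (a_{C,i}/a_i)(S_{C,i}/S_i)}.
#'
#' @param truth A `growth_truth` tibble from [simulate_growth()].
#' @return A tibble `fn` (`cells`, `protein`, `co2`), `rtf`,
#'   `uptake_sum` (\eqn{\sum_i S_{C,i}/S_i}, identical across functions).
#' @export
true_rtf <- function(truth) {
  stopifnot(inherits(truth, "growth_truth"))
  tibble::tibble(
    fn = c("cells", "protein", "co2"),
    rtf = c(sum(truth$a_ratio_cells * truth$uptake_ratio),
            sum(truth$a_ratio_protein * truth$uptake_ratio),
            sum(truth$a_ratio_co2 * truth$uptake_ratio)),
    uptake_sum = sum(truth$uptake_ratio)
  )
}

# growth fraction reached at each time point: 0 at t = 0, saturating
# exponential normalised to hit exactly 1 at t_sat and stay there
growth_fraction <- function(time_h, t_sat) {
  r <- 3 / t_sat
  g <- (1 - exp(-r * pmin(time_h, t_sat))) / (1 - exp(-r * t_sat))
  ifelse(time_h >= t_sat, 1, g)
}

.time_grid <- c(0, 16, 24, 32, 40, 64, 110)

#' Simulate the measurement layer over true per-taxon functions
#'
#' Emits, for each sample, a function time series on the standard grid
#' (0, 16, 24, 32, 40, 64, 110 h) - saturating growth trajectories that
#' reach the true carrying capacities, per-cell protein fluorescence, and
#' per-interval CO2-indicator absorbance (via [absorbance_from_co2()],
#' including the ambient background) - together with a 16S read table
#' with blank wells carrying a planted contaminant.  Multiplicative
#' log-normal noise is applied at the scenario's CVs; with all CVs zero
#' and `sequencing = FALSE` the outputs recover the truth exactly.
#'
#' @param truths Named list of `growth_truth` tibbles (names become
#'   sample ids).
#' @param scenario A [scenario_config()].
#' @param seed Integer seed; per-sample sub-seeds are derived
#'   deterministically.
#' @param stages Optional character vector (same length as `truths`)
#'   labelling each sample `"community"` or `"extinction"`; default
#'   `"community"`.
#' @param pool The `regional_pool` (needed for blank/contaminant
#'   composition and extinction-sample impurity).
#' @return A list: `timeseries` (tibble `sample_id`, `time_h`,
#'   `cells_per_ml`, `protein_fluor_per_cell`, `delta572`), `asv` (wide
#'   ASV table including blank rows), `samples` (per-sample metadata).
#' @export
simulate_measurements <- function(truths, scenario, seed = 1, stages = NULL,
                                  pool = NULL) {
  stopifnot(inherits(scenario, "scenario_config"), is.list(truths))
  if (is.null(names(truths)) || anyDuplicated(names(truths))) {
    abort("`truths` must be a uniquely named list.", class = "relfun_invalid_argument")
  }
  stages <- stages %||% rep("community", length(truths))
  vol <- scenario$volume_ml
  all_taxa <- if (!is.null(pool)) pool$taxa$taxon_id else
    sort(unique(unlist(lapply(truths, function(x) x$taxon_id))))
  contam_id <- "CONTAM_01"

  series <- vector("list", length(truths))
  reads <- vector("list", length(truths))
  mean_comp <- rep(0, length(all_taxa))
  names(mean_comp) <- all_taxa

  for (k in seq_along(truths)) {
    tr <- truths[[k]]
    sid <- names(truths)[k]
    sk <- derive_seed(seed, c(1L, k))
    series[[k]] <- with_seed(sk, {
      g <- outer(tr$t_sat_h, .time_grid, function(ts, t) growth_fraction(t, ts))
      cells_t <- as.numeric(crossprod(g, tr$cells))      # total cells per well
      protein_t <- as.numeric(crossprod(g, tr$protein))
      co2_t <- as.numeric(crossprod(g, tr$co2))
      co2_inc <- diff(co2_t)
      nt <- length(.time_grid)
      cells_obs <- cells_t / vol * lognormal_noise(nt, scenario$cells_cv)
      pfpc <- ifelse(cells_t > 0, protein_t / cells_t, 0) *
        lognormal_noise(nt, scenario$protein_cv)
      co2_pct <- co2_inc / vol + scenario$ambient_co2_percent
      co2_pct <- pmax(0, co2_pct * lognormal_noise(nt - 1L, scenario$co2_cv))
      tibble::tibble(
        sample_id = sid,
        time_h = .time_grid,
        cells_per_ml = cells_obs,
        protein_fluor_per_cell = pfpc,
        delta572 = c(NA_real_, absorbance_from_co2(co2_pct))
      )
    })
    frac <- setNames(rep(0, length(all_taxa)), all_taxa)
    frac[tr$taxon_id] <- tr$cells / sum(tr$cells)
    if (stages[k] == "extinction" && !is.null(pool)) {
      # residual impurity from incomplete extinction
      frac <- frac * scenario$mono_purity
      others <- setdiff(all_taxa, tr$taxon_id)
      if (length(others) && scenario$mono_purity < 1) {
        imp <- with_seed(derive_seed(seed, c(2L, k)),
                         sample(others, min(3L, length(others))))
        frac[imp] <- frac[imp] + (1 - scenario$mono_purity) / length(imp)
      }
    }
    mean_comp <- mean_comp + frac / length(truths)
    p <- c(frac * (1 - scenario$sample_contaminant_fraction),
           setNames(scenario$sample_contaminant_fraction, contam_id))
    reads[[k]] <- .draw_reads(p, scenario, derive_seed(seed, c(3L, k)))
  }

  # blank wells: mostly reagent background + the planted contaminant,
  # with faint cross-talk from real samples
  blank_ids <- sprintf("BLANK_%02d", seq_len(scenario$n_blanks))
  blank_rows <- vector("list", scenario$n_blanks)
  blank_series <- vector("list", scenario$n_blanks)
  if (sum(mean_comp) > 0) mean_comp <- mean_comp / sum(mean_comp)
  for (b in seq_len(scenario$n_blanks)) {
    p <- c(mean_comp * scenario$blank_leak_fraction,
           setNames(scenario$blank_contaminant_fraction, contam_id),
           BLANK_BG = 1 - scenario$blank_leak_fraction -
             scenario$blank_contaminant_fraction)
    blank_rows[[b]] <- .draw_reads(p, scenario, derive_seed(seed, c(4L, b)))
    blank_series[[b]] <- with_seed(derive_seed(seed, c(5L, b)), {
      nt <- length(.time_grid)
      co2_pct <- pmax(0, rep(scenario$ambient_co2_percent, nt - 1L) *
                        lognormal_noise(nt - 1L, scenario$co2_cv))
      tibble::tibble(
        sample_id = blank_ids[b],
        time_h = .time_grid,
        cells_per_ml = 0,
        protein_fluor_per_cell = 0,
        delta572 = c(NA_real_, absorbance_from_co2(co2_pct))
      )
    })
  }

  taxa_cols <- c(all_taxa, contam_id, "BLANK_BG")
  count_mat <- matrix(0, length(truths) + scenario$n_blanks, length(taxa_cols),
                      dimnames = list(NULL, taxa_cols))
  for (k in seq_along(reads)) count_mat[k, names(reads[[k]])] <- reads[[k]]
  for (b in seq_along(blank_rows)) {
    count_mat[length(reads) + b, names(blank_rows[[b]])] <- blank_rows[[b]]
  }
  keep <- colSums(count_mat) > 0
  asv <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = c(names(truths), blank_ids),
      blank = c(rep(FALSE, length(truths)), rep(TRUE, scenario$n_blanks)),
      stage = c(stages, rep("blank", scenario$n_blanks))
    ),
    tibble::as_tibble(count_mat[, keep, drop = FALSE])
  )
  list(
    timeseries = dplyr::bind_rows(c(series, blank_series)),
    asv = asv,
    samples = tibble::tibble(
      sample_id = c(names(truths), blank_ids),
      stage = c(stages, rep("blank", scenario$n_blanks)),
      n_taxa_true = c(vapply(truths, nrow, 1L), rep(0L, scenario$n_blanks))
    )
  )
}

.draw_reads <- function(prob, scenario, seed) {
  prob <- prob[prob > 0]
  prob <- prob / sum(prob)
  if (scenario$sequencing) {
    with_seed(seed, {
      setNames(as.numeric(rmultinom(1, scenario$sequencing_depth, prob)),
               names(prob))
    })
  } else {
    prob * scenario$sequencing_depth
  }
}

#' Simulate a full two-stage dilution experiment
#'
#' Orchestrates the generator end to end: assembles one community per
#' design row by multinomial dilution of the regional pool, grows each on
#' the shared substrate pool, performs an idealized dilution-to-extinction
#' stage (isolating the taxa most abundant across communities and growing
#' each alone on the full pool, in replicate), and passes everything
#' through the measurement layer.
#'
#' @param pool A `regional_pool`.
#' @param design Design tibble from [enumerate_dilution_design()].
#' @param scenario A [scenario_config()].
#' @param inoculum_cells Cells in the undiluted inoculum (default 1e6).
#' @param n_isolates Number of taxa taken to monoculture (default 40,
#'   chosen as those with the highest summed community abundance).
#' @param mono_replicates Extinction samples per isolated taxon
#'   (default 3).
#' @param seed Integer master seed.
#' @return A `relfun_simulation` list: `asv`, `timeseries`, `samples`
#'   (metadata incl. dilution level and true richness), `truth` (long
#'   per-sample, per-taxon ground truth), `pool`, `scenario`, `design`.
#' @export
simulate_experiment <- function(pool, design = enumerate_dilution_design(),
                                scenario = scenario_config("mixed"),
                                inoculum_cells = 1e6,
                                n_isolates = 40, mono_replicates = 3,
                                seed = 1) {
  stopifnot(inherits(pool, "regional_pool"), inherits(scenario, "scenario_config"))
  truths <- list()
  meta <- list()
  for (k in seq_len(nrow(design))) {
    founders <- assemble_inoculum(pool, design$dilution_factor[k],
                                  inoculum_cells, seed = derive_seed(seed, c(10L, k)))
    if (nrow(founders) == 0L) next
    sid <- design$community_id[k]
    truths[[sid]] <- simulate_growth(founders, pool, scenario)
    meta[[sid]] <- tibble::tibble(
      sample_id = sid, stage = "community",
      dilution_factor = design$dilution_factor[k],
      replicate = design$replicate[k],
      richness_true = nrow(founders)
    )
  }
  if (length(truths) == 0L) {
    abort("no community received any founder cells; lower the dilution.",
          class = "relfun_invalid_argument")
  }
  # dilution-to-extinction: isolate the taxa with the largest summed
  # community cell numbers
  totals <- tapply(
    unlist(lapply(truths, function(x) x$cells)),
    unlist(lapply(truths, function(x) x$taxon_id)),
    sum)
  isolates <- names(sort(totals, decreasing = TRUE))
  isolates <- head(isolates, n_isolates)
  mono_scenario <- scenario # same measurement layer; growth is single-taxon
  for (tx in isolates) {
    for (r in seq_len(mono_replicates)) {
      sid <- sprintf("M_%s_r%d", tx, r)
      truths[[sid]] <- simulate_growth(tx, pool, mono_scenario)
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, stage = "extinction",
        dilution_factor = NA_real_, replicate = r,
        richness_true = 1L
      )
    }
  }
  stages <- vapply(meta, function(m) m$stage, character(1))
  measured <- simulate_measurements(truths, scenario,
                                    seed = derive_seed(seed, 20L),
                                    stages = unname(stages), pool = pool)
  truth_long <- dplyr::bind_rows(
    lapply(names(truths), function(sid) {
      dplyr::mutate(tibble::as_tibble(truths[[sid]]), sample_id = sid,
                    .before = 1)
    }))
  structure(list(
    asv = measured$asv,
    timeseries = measured$timeseries,
    samples = dplyr::bind_rows(meta),
    truth = truth_long,
    pool = pool,
    scenario = scenario,
    design = design
  ), class = "relfun_simulation")
}

#' Simulate communities with explicitly chosen memberships
#'
#' A controlled-membership variant of [simulate_experiment()]: instead of
#' assembling communities by dilution, each element of `member_sets`
#' names the taxa of one community.  Every taxon appearing in any
#' community is also grown as an extinction-stage monoculture
#' (`mono_replicates` samples each), and everything passes through the
#' same measurement layer.  Used for validation designs where richness
#' must be set exactly.
#'
#' @param pool A `regional_pool`.
#' @param member_sets List of character vectors of taxon ids.
#' @param scenario A [scenario_config()].
#' @param mono_replicates Extinction samples per taxon (default 3).
#' @param seed Integer master seed.
#' @return A `relfun_simulation` (see [simulate_experiment()]).
#' @export
simulate_communities <- function(pool, member_sets,
                                 scenario = scenario_config("null"),
                                 mono_replicates = 3, seed = 1) {
  stopifnot(inherits(pool, "regional_pool"), is.list(member_sets))
  truths <- list()
  meta <- list()
  for (k in seq_along(member_sets)) {
    sid <- names(member_sets)[k] %||% ""
    if (sid == "") sid <- sprintf("C_%03d", k)
    truths[[sid]] <- simulate_growth(member_sets[[k]], pool, scenario)
    meta[[sid]] <- tibble::tibble(
      sample_id = sid, stage = "community",
      dilution_factor = NA_real_, replicate = k,
      richness_true = length(member_sets[[k]]))
  }
  for (tx in sort(unique(unlist(member_sets)))) {
    for (r in seq_len(mono_replicates)) {
      sid <- sprintf("M_%s_r%d", tx, r)
      truths[[sid]] <- simulate_growth(tx, pool, scenario)
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, stage = "extinction",
        dilution_factor = NA_real_, replicate = r, richness_true = 1L)
    }
  }
  stages <- vapply(meta, function(m) m$stage, character(1))
  measured <- simulate_measurements(truths, scenario,
                                    seed = derive_seed(seed, 20L),
                                    stages = unname(stages), pool = pool)
  truth_long <- dplyr::bind_rows(
    lapply(names(truths), function(sid) {
      dplyr::mutate(tibble::as_tibble(truths[[sid]]), sample_id = sid,
                    .before = 1)
    }))
  structure(list(
    asv = measured$asv, timeseries = measured$timeseries,
    samples = dplyr::bind_rows(meta), truth = truth_long,
    pool = pool, scenario = scenario, design = NULL
  ), class = "relfun_simulation")
}

#' @export
print.relfun_simulation <- function(x, ...) {
  cat(sprintf(
    "<relfun_simulation> %d communities, %d extinction samples, %d blanks (scenario: %s)\n",
    sum(x$samples$stage == "community"), sum(x$samples$stage == "extinction"),
    sum(x$asv$blank), x$scenario$scenario))
  invisible(x)
}
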