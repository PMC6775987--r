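---
title: "Methods: the relative total function framework and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the relative total function framework and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relfun)
```

## The model

`relfun` quantifies the net effect of biotic interactions on community
function by comparing each community to the counterfactual in which its
members perform as they do alone. For any function that is summable
across taxa,

$$\mathrm{RTF}_C = \sum_i^{N_C} \frac{F_{C,i}}{F_i},$$

where $F_{C,i}$ is taxon $i$'s function inside community $C$ and $F_i$
its monoculture function. $\mathrm{RTF}_C = 1$ under the null model of
independent performance; $\mathrm{RMF}_C = \mathrm{RTF}_C / N_C$ asks the
same question of the *average* member. The central assumption is that
carrying-capacity-like functions are linear in resource uptake, so each
ratio factorises as

$$\frac{F_{C,i}}{F_i} = \frac{a_{C,i}}{a_i}\,\frac{S_{C,i}}{S_i},$$

with $S$ total assimilated carbon (the fundamental niche in monoculture,
the realized niche in community) and $a$ the efficiency of converting
uptake into the function. Respiration and biomass efficiencies are
complementary — carbon not respired is retained — so they cannot move in
the same direction, and the community's single relative total uptake
$\sum_i S_{C,i}/S_i$ must lie between $\mathrm{RTF}(\mathrm{CO_2})$ and
$\mathrm{RTF}(\mathrm{protein})$ (`decomposition_bounds()`). Treating
the community as one average taxon whose expected carbon-use efficiency
(CUE) is unknown, the CO₂:protein RTF ratio determines the relative CUE

$$r\mathrm{CUE} = \frac{1}{\mathrm{Ratio}_{\mathrm{RTF}}\,(1-\mathrm{CUE}) + \mathrm{CUE}},$$

evaluated over a grid of expected CUE values from 0 to 0.6 in steps of
0.01 (0.6 being the thermodynamic ceiling for heterotrophic growth) and
summarised by its mean (`estimate_rcue()`).

### Estimating the inputs

$F_{C,i}$ is not observable directly; it is estimated as
$F_C \cdot R_{C,i}$ from the measured total community function and the
16S relative abundances. This is exact for cell counts and approximate
for protein and CO₂: the error is the "adjustment factor", the taxon's
per-cell function relative to the community mean
(`adjustment_factors()`), assumed to be 1. The operational rules are:

* **Monoculture (purity ≥ 0.90, inclusive).** A dilution-to-extinction
  sample whose top ASV holds at least 90 % of reads is the operational
  monoculture of that ASV; its function summaries are used as $F_i$
  directly. Multiple qualifying samples per taxon are averaged
  (arithmetic mean; the median is available — the choice matters little
  when replicates are consistent, and the mean is the natural estimator
  of an expected monoculture function).
* **Constitutability (coverage ≥ 0.85, inclusive).** A community can be
  analysed when cataloged taxa cover at least 85 % of its reads; the
  covered abundances are renormalised to sum to 1, which amounts to
  assuming the uncovered tail behaves like the covered part.
  Communities below the threshold are reported without RTF, never
  imputed.
* **$N_C$ for RMF** counts the cataloged, renormalised taxa —
  consistent with the renormalised abundances entering the sum. Using
  full observed richness instead is exposed via `n_c = "observed"`.
* **CO₂ uses the 0–40 h total** for RTF, because composition is
  measured at early stationary phase (about 40 h); maxima of cell
  density and protein are taken within 110 h.
* A sample never serves as both a monoculture and a community: the
  extinction and community stages are disjoint sample sets.

## Measurement conversions

* Cell densities are FACS event counts normalised to absolute-count
  beads run at 990,000 beads/mL: `cells = events / bead_events ×
  990000` (cells/mL).
* Per-cell protein is the mean stain fluorescence relative to a fixed
  standard mixture on the same plate (dimensionless units/cell). The
  community's maximum protein per cell is the **ratio of maxima**
  (max total protein / max cell density), not the maximum of pointwise
  ratios, which is distorted by cell clumping at late time points.
* Headspace CO₂ follows the hyperbolic indicator calibration
  $\% \mathrm{CO_2} = 0.1648/(\Delta_{572} - 0.2457) - 0.2301$, with
  $\Delta_{572}$ the change in absorbance at 572 nm over a sampling
  interval. The formula is negative in a small range near the blank;
  values there are clamped to 0 (physical non-negativity), and readings
  at or below the 0.2457 asymptote raise an out-of-calibration error.
  The exact algebraic inverse (`absorbance_from_co2()`) is used by the
  simulator, and the pair round-trips to numerical identity.
* Total CO₂ over a window sums rate × interval duration × culture
  volume per interval, where the rate is %CO₂ / duration — so each
  interval contributes %CO₂ × volume. "Average time" is read as the
  interval duration and "average community volume" as the configured
  culture volume (0.58 mL, i.e. 580 µL, by default). Atmospheric
  background is removed by subtracting the per-interval mean of the
  blank wells before summation (per-interval rather than on totals;
  the two differ only when blank signal varies between intervals, and
  the per-interval form makes window additivity exact). Intervals are
  assigned to a window by their midpoints, which makes
  `total(0,40) + total(40,110) = total(0,110)` an identity on the
  standard grid.
* A 160 h time point, when present, is excluded by the default 110 h
  cutoff (`max_time_h`), reflecting late-culture changes in physical
  properties that corrupt FACS readings.
* Stationary phase is called at the first time point with < 20 % growth
  over the previous point, after some earlier consecutive pair grew by
  > 20 % (`detect_stationary()`).

## Composition and diversity

Samples with fewer than 2000 reads (strictly) are dropped. Contaminants
are ASVs exceeding 2 % relative abundance (strictly) in more than 20 %
of blank samples (strictly); their reads are zeroed in biological
samples while blank rows keep their counts — blanks are QC evidence,
not analysis samples — which makes the filter exactly idempotent (a
second application flags the identical set and changes nothing).

Richness is the observed ASV count; estimated-richness corrections are
out of scope, and observed counts are what the downstream analyses
consume. Rarefied richness uses the exact hypergeometric
expectation (`vegan::rarefy`). Phylogenetic diversity uses
abundance-weighted MPD and MNTD with abundances renormalised over
present taxa. MNTD follows the standard picante `abundance.weighted`
definition (each taxon's nearest-neighbour distance weighted by its own
abundance). MPD restricts both the numerator and the normaliser to
distinct pairs ($i \ne j$), so a two-taxon community returns the pair's
distance; the picante variant leaves the $i = j$ mass in the
denominator and shrinks the value by $1 - \sum_i f_i^2$. Both are
verified against brute-force double-loop oracles in the test suite.
Patristic distances come from newick trees via `ape`; tips missing from
the table are an error, extra tips are ignored. The metrics are
computed on the full post-QC table (no re-restriction to cataloged
taxa).

## The statistical layer

* **Curve fitting** (`fit_diversity_function()`): linear
  $y = \alpha + \beta x$, log-linear $y = \alpha + \beta \ln x$
  (natural log) and hyperbolic Michaelis–Menten $y = Vx/(K+x)$ (no
  intercept; an intercept variant can be emulated by shifting $y$), all
  by least squares, the hyperbolic via Levenberg–Marquardt. The family
  with least AIC wins; "comparable" AICs — within ΔAIC ≤ 2, the
  standard information-criterion convention — resolve toward the
  simpler family (linear ≺ log-linear ≺ hyperbolic). Numerically
  perfect fits are treated as tied, since their AICs differ only by
  floating-point noise. Confidence bands are pointwise Monte-Carlo
  quantiles from the asymptotic parameter covariance (5000 draws by
  default) — a single documented method in place of stacked
  Taylor-expansion propagation. Non-convergence of the hyperbolic
  drops that family with a warning rather than failing.
* **Richness-bin tests** (`richness_bin_tests()`): bins at $N_C \le 12$,
  $12 < N_C \le 26$, $N_C > 26$ by default; per bin a two-tailed
  one-sample t-test of RTF against 1, and per function pair a paired
  t-test plus a paired Wilcoxon. The Wilcoxon is the *signed-rank* test:
  the paired analogue (a rank-sum test cannot be paired), with the
  one-tailed direction available via `wilcoxon_alternative`. Bins with
  fewer than 3 communities are skipped with a notice.
* **Scaled comparison** (`scaled_comparison()`): two fitted curves are
  evaluated on a common grid, each divided by its maximum, and compared
  by a paired two-tailed t-test — scale-invariant by construction.
* **Sliding-window screen** (`sliding_window_screen()`): Kendall tau-b
  (tie-corrected) between taxon relative abundance and community
  function within richness windows of widths 2–10, step 1 richness
  unit, requiring ≥ 5 communities per window and taxon presence in ≥ 3
  of them (the step and minima are this package's choices).
  Benjamini–Hochberg correction is pooled within each (function, width)
  stratum by default — comparisons within a stratum ask the same
  question at the same resolution — with global pooling behind
  `stratify = "all"`. Windows are defined on stationary-phase richness.
* **Loreau–Hector partition** (`loreau_hector_partition()`):
  $\Delta RY_i = F_{C,i}/M_i - RY_{e,i}$; complementarity
  $= N\,\overline{\Delta RY}\,\overline{M}$, selection
  $= N\,\mathrm{cov}(\Delta RY, M)$ with the population covariance, so
  net $=$ complementarity $+$ selection holds as an exact algebraic
  identity. With equal monocultures the selection effect vanishes and
  complementarity $= (\mathrm{RTF}-1)\,\overline{M}$ — the linear link
  to the RTF index.
* **Density adjustment** (`regression_with_density()`): OLS of function
  on richness and $\log_{10}$ initial cell density with type-II
  sum-of-squares F tests.

## The synthetic community generator

The simulator provides ground truth with the statistical and mechanistic
structure the analysis assumes, emulating the two-stage design: a
regional pool with log-normally skewed abundances (default sdlog 1.5, a
typical rank-abundance skew for marine bacterioplankton) is serially
diluted 4-fold (15 replicates per level, levels $4^2$–$4^{11}$, plus 5
and 15 extra vessels at the two highest levels — 185 vessels in all,
reproduced by `enumerate_dilution_design()`); founder cells are drawn
multinomially from `round(inoculum_cells / dilution_factor)` (default
inoculum 10⁶ cells — the design's round figure; the alternative reading
of 3×10⁵ cells/mL × 30 mL is noted but not used). Note that the design
enumerates ten 4-fold levels plus the undiluted vessels, although it is
sometimes described as twelve dilution steps; the enumeration is what
reproduces 185.

Growth is deterministic consumer-resource accounting: each substrate's
carbon is split among capable members proportionally to use-profile
weights (an equal split at equal weights — the simplest rule consistent
with the two-taxon picture), giving $S_{C,i}$; a monoculture run with
full pool access gives $S_i$. Interference acts **multiplicatively on
conversion efficiency only**, $cue_{C,i} = cue_i(1 - s\,o_i)$ with
$o_i$ the overlapped fraction of the fundamental niche — never on
uptake — so the two channels of the decomposition stay independently
tunable. Per-taxon functions follow as cells $= cue \cdot S \cdot$
cells-per-carbon, protein $=$ cells × protein-per-cell, CO₂
$= (1 - cue)\,S$.

Four scenario presets operationalise the interaction regimes:

| scenario | profiles | interference | traits |
|---|---|---|---|
| `null` | full generalists | 0 | homogeneous |
| `interference` | full generalists | 0.5 | homogeneous |
| `complementation` | disjoint | 0 | homogeneous |
| `mixed` | partial (breadth 0.3) | 0.3 | heterogeneous |

The null preset *defines* the null model exactly: with homogeneous
conversion traits every adjustment factor is exactly 1 and the full
estimation path returns RTF = 1 to machine precision; with disjoint
profiles RTF equals richness and RMF equals 1. The mixed preset draws
CUE from a truncated normal (mean 0.3, sd 0.1, clamped to [0.01, 0.6])
and per-cell protein log-normally (CV 0.3), so the $F_C R_{C,i}$
estimator is only approximately equal to truth there — deliberately, as
in real data; the exact identity is then verified on true per-taxon
functions instead.

The measurement layer emits the standard time grid (0, 16, 24, 32, 40,
64, 110 h): saturating growth trajectories normalised to reach the true
carrying capacity exactly at a taxon-level saturation time (24/32/40 h)
capped earlier in richer communities, so richer communities peak
earlier and all growth completes by 40 h (making the 0–40 h CO₂ window
capture total respiration); per-interval CO₂ is emitted as indicator
absorbance through the exact inverse calibration with a 0.04 % ambient
background removed by blank correction; reads are multinomial at the
sequencing depth (default 10,000) with a planted contaminant ASV (5 %
of blanks, 1 % carry-over into samples, faint cross-talk of real taxa
into blanks) and 4 blank wells per plate; measurement noise is
multiplicative log-normal with mean 1 at CVs of 0.1 (cells), 0.1
(protein) and 0.04 (CO₂ — the calibration's typical ±4 % precision).
Extinction-stage samples carry 97 % read purity by default, comfortably
above the 90 % rule. All randomness flows from one integer master seed
through deterministic per-sample sub-seeds; identical configurations
are byte-identical on disk.

With all CVs zero and read sampling disabled (`noiseless = TRUE`) the
ASV table carries expected, non-integer counts so relative abundances
are exact — the validation mode in which recovery identities hold to
1e-9. The integer-count invariant applies to the sequenced layer.

### What the generator does not emulate

No sequence-level reads (ASVs are abstract labels), no taxonomy, no
media chemistry, pasteurization or grazers; no taxon loss during growth
(membership is fixed at inoculation, so environmental filtering and
competitive exclusion during regrowth are absent); trajectories are
monotone (no death phase); per-cell traits are constant in time; the
dilution-to-extinction stage isolates the most abundant taxa
deterministically rather than by stochastic terminal dilution. Passing
tests therefore demonstrate correctness of the estimation machinery
under the model's assumptions — not robustness to real-data features
such as uneven 16S copy numbers, compositional biases of amplicon
sequencing, or taxa whose community phenotype differs qualitatively
from monoculture.

## Numerical choices and degenerate inputs

Boundary conventions: purity "at least 90 %" and coverage "85 %" are
inclusive; "more than 2 %", "more than 20 % of blanks" and "less than
2000 reads" are strict. Degenerate inputs raise classed errors
(`relfun_degenerate_standard`, `relfun_out_of_calibration`,
`relfun_degenerate_sample`, `relfun_degenerate_monoculture`,
`relfun_no_blank`, `relfun_undefined_metric`,
`relfun_rank_deficiency`, `relfun_invalid_argument`) rather than
propagating NaNs. Numerically constant data in the t-tests and the
curve fits are handled explicitly (statistic 0, p = 1, or an exact tie
resolved toward the simpler family). Zero-residual regressions return
p = 1 for all terms.

## Validation problem sizes

The test suite validates on deliberately small, fast designs: worked
two-taxon examples exactly; null-model recovery on 20 communities of
richness 2–30 (exact to 1e-9 noiseless; 100 seeded noisy replicates for
the t-test calibration at CV 0.1); the decomposition identity on 200
random mixed-regime communities; oracle equivalence on 100 random
instances each for MPD, MNTD and tau-b; AIC family recovery on 50
trials per family at n = 60 and 5 % noise; screen calibration on 100
permutations of a 40-community dataset; and end-to-end pipeline
determinism on a reduced dilution design. These sizes were chosen as
the smallest that make the statistical checks stable.

## Known limitations

The adjustment-factor assumption (factor ≡ 1) biases protein and CO₂
RTFs when per-cell traits vary strongly between taxa; the package
reports the null-model factors so users can check the 0.5–2 range
expectation. The decomposition interval is a bracket, not an estimate:
it does not narrow with more data. rCUE averages over an assumed CUE
grid rather than estimating CUE. The screen's FDR control is per
stratum; hits in overlapping windows are correlated and should be read
as ranges, not independent discoveries.
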