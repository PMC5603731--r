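---
title: "Methods: models, estimators, and generators in chromvalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators, and generators in chromvalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, numerical choices, and
synthetic-data conventions behind `chromvalence`. Code chunks are shown
but not evaluated; the worked example in the README and the test suite
in `tests/testthat/` carry the computed results.

# FRAP kinetics

## Double normalization

A raw trace has four columns: `time`, bleach-ROI intensity, whole-cell
intensity, and background. `normalize_trace()` computes

```
recovery(t) = [ (roi - background) / (cell - background) ]
              / mean of the same ratio over the pre-bleach frames
```

Dividing by the whole-cell channel corrects acquisition photobleaching
(both channels fade together during imaging), and scaling to the
pre-bleach mean sets the pre-bleach level to 1, so recoveries are
comparable across cells with different expression levels. The bleach
frame index is carried as an attribute; post-bleach time is measured
from the first post-bleach frame.

## Biexponential fit

Post-bleach recovery is modeled as

```
recovery(t) = b + a1 (1 - exp(-k1 t)) + a2 (1 - exp(-k2 t)),   k1 >= k2
```

with `b` the bleach depth, `a1 + a2` the mobile fraction, and
`1 - b - a1 - a2` the immobile fraction. Fitting uses
`minpack.lm::nlsLM` with log-parameterized rates (positivity without
constrained optimization) and a multi-start strategy: candidate rate
pairs are drawn from the decade grid `{100, 10, 1, 0.1} / t_range`
(distinct pairs only), and for each pair the linear parameters
`(b, a1, a2)` are initialized by least-squares projection, clamped to
`b` in `[0, 1]` and amplitudes at least 0.05 so no rate starts with a
zero-amplitude (and hence zero-gradient) component. The best converged
start by residual sum of squares wins; components are reported ordered
`k1 >= k2`. The 100-decade entry matters for second-scale recoveries
observed over minutes, where `10 / t_range` alone undershoots the fast
rate.

A fit is flagged `immobile` when the fitted mobile amplitude falls
below three times the residual noise (no meaningful recovery: the half
time is undefined and reported as `NA`), and `over_recovery` when the
plateau significantly exceeds 1.

## Half time

`half_time()` solves

```
a1 (1 - exp(-k1 t)) + a2 (1 - exp(-k2 t)) = (a1 + a2) / 2
```

by bisection to a relative tolerance of 1e-9. The half point is
measured above the fitted bleach depth, which makes it invariant to the
immobile fraction and to amplitude rescaling; uniqueness follows from
strict monotonicity. Cohorts of per-cell half times are compared with a
two-sided Student's t test (equal variances) via `compare_cohorts()`,
which also reports per-group medians and IQRs.

# Binding affinity

## The depletion isotherm

With total protein `P`, total ligand `L`, and dissociation constant
`Kd` (all micromolar), the exact 1:1 bound fraction is

```
f = [ (P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L) ] / (2 P)
```

This matters because titrations are commonly run with protein
concentrations comparable to the tightest `Kd` in the series; the
hyperbolic approximation `L / (L + Kd)` is only accurate to a relative
error of order `P / (L + Kd)` (about 1% at `P = Kd/100`), so
`fit_kd_fluorescence()` fits the quadratic by default and offers
`model = "hyperbolic"` for the depletion-free limit.

## Fluorescence fit

The observed response is modeled as an affine function of the bound
fraction, `y = r_free + (r_sat - r_free) f(L; Kd)`. The fit uses
`nlsLM` over `log Kd` (bounded to `(1e-6, 1e4]` micromolar) with
multi-starts at `Kd` in `{0.1, 1, 10, 100}` and the amplitudes
initialized by linear projection at each start. The standard error of
`Kd` comes from the delta method applied to the `log Kd` standard
error. The fit aborts with an *unidentifiability* error when the
response is constant, when the `Kd` estimate runs to the upper bound
(no curvature within the titrated range), or when the fitted amplitude
is below three times the residual noise — in all three cases a
confidently reported constant would be spurious.

## NMR CSP global fit

Per-residue chemical shift perturbations are combined across dimensions
as `sqrt(dH^2 + (dN / 5)^2)` (the conventional 1/5 nitrogen weight,
adjustable via `nitrogen_weight`). Residues whose maximal combined CSP
stays below `noise_floor` (default 0.005 ppm) are excluded as
non-responding. All remaining residues share one `Kd`: for a candidate
`Kd` the per-residue amplitudes are available in closed form
(`sum(f y) / sum(f^2)`), so the fit reduces to a 1-D profiled residual
sum of squares over `log Kd`, minimized with `stats::optimize` over
`[1e-4, 1e4]` micromolar; the `Kd` standard error comes from the
numerical curvature of the profile. A `misfit` flag is raised when the
residual standard deviation exceeds 1.5x `noise_floor`, the signature
of residues that do not actually share one site (e.g. two binding
events with different affinities).

# Spike-in calibration

Each sample's calibration factor is `alpha = 1e6 / spike_reads`
("signal per million spike-in reads"). Because every sample received
the same amount of spike material, dividing by spike reads converts
depth-dependent counts into an absolute, cross-sample-comparable unit;
`input_correction = TRUE` additionally multiplies by the paired input's
`spike_reads / target_reads` ratio. The decisive property, exercised in
the tests: when a perturbation halves all target-genome signal but the
library is sequenced to the same total depth, per-depth normalization
sees identical samples (median log2 change ≈ 0) while the spike
fraction of the library doubles, and spike calibration recovers the
true median log2 change of −1.

Interval quantification (`quantify_intervals()`) computes
overlap-length-weighted means of bin values over intervals using
`GenomicRanges::findOverlaps`; bedGraph values are treated as levels
over their run, so refining bins without changing values leaves every
quantification invariant.

# Interval conventions

All interval tables use BED semantics: 0-based starts, half-open
`[start, end)`. A point at position `p` lies in an interval iff
`start <= p < end`; overlap requires at least one shared base.
`overlap_venn()` counts, for each of two sets, how many intervals
overlap at least one interval of the other (verified in the tests
against a brute-force all-pairs oracle). Metaprofiles divide
`[anchor - flank, anchor + flank)` into equal-width bins, quantify each
anchor's window in one pass, reverse minus-strand profiles before
averaging, and exclude (but count) anchors without track coverage.

# The multivalence index

Regions are ranked into `n_bins` (default 20) equal-population H3K4me3
percentile bins; per bin the ratio
`r_b = mean(signal) / mean(reference)` is formed, and the index is the
Spearman correlation of `r_b` against bin rank. A reader whose
occupancy scales with non-methylated DNA alone gives a flat ratio
profile (index ≈ 0, defined as exactly 0 when the profile is constant
to floating-point precision); a multivalent reader's ratio climbs with
the H3K4me3 percentile (index → 1).

Significance uses an exact permutation test: the H3K4me3 bin
assignments are shuffled `n_perm` times (default 200) while each region
keeps its own (reference, signal) pair, so the signal-reference
coupling — including any shared additive background — survives intact
and only the H3K4me3 ordering is broken. The p-value is
`(1 + #permuted |index| >= observed |index|) / (n_perm + 1)`, and the
`multivalent` call is `p <= alpha` with `alpha = 0.02` by default
(chosen to keep the false-call rate on genuinely monovalent data,
bounded by `alpha` under exchangeability, comfortably below the 5%
working tolerance). An earlier design that permuted the signal within
reference strata was measurably anti-conservative, because an additive
background makes each bin's ratio depend on the bin's mean reference
signal — variation that fixed bin compositions can never reproduce;
shuffling the bin assignments instead makes the test exact.

# Synthetic-data generators

All generators take explicit parameter objects with a `seed` and are
fully deterministic given it.

- **FRAP traces** (`simulate_frap_trace`): biexponential recovery with
  defaults `amplitude_fast = 0.5`, `rate_fast = 2 /s`,
  `amplitude_slow = 0.3`, `rate_slow = 0.3 /s`, bleach depth 0.3, acquisition photobleaching
  `exp(-0.002 t)` applied to both channels (so double normalization
  must undo it), Gaussian noise 2% of the pre-bleach level, 8 frames/s,
  50 pre-bleach and up to 1000 post-bleach frames.
- **Titrations** (`simulate_titration`): 10 ligand points spanning 0 to
  40x `kd_true` (saturating the isotherm while resolving the rise),
  responses from the depletion isotherm with `r_free = 1`,
  `r_sat = 0.4`; CSP mode emits per-residue amplitudes spread over
  0.02-0.12 ppm.
- **Toy genome** (`simulate_genome`): one chromosome (`"chrS"`, 5 Mb,
  200-bp bins) with 500 non-methylated islands and 200 background
  regions laid out on a slot grid (disjoint and sorted by
  construction). Bio-CAP intensity is uniform on `[1, 10]`; H3K4me3 is
  assigned by rank with percentile midpoints `(rank - 0.5)/n * 100`
  and paired with Bio-CAP at random, so the two features are
  independent a priori — which is what makes the permutation test
  exact on monovalent data. Expected IP occupancy is `biocap` under
  the monovalent model and
  `biocap * (1 + strength * percentile/100)` under the multivalent
  model; 90% of the expected depth is distributed over islands
  proportionally to occupancy and 10% uniformly as background, with
  Poisson count noise throughout. Problem sizes (500 islands, 1e6
  reads, 1e5 spike reads) are chosen so every analysis runs in seconds
  while Poisson noise remains a visible, realistic fraction of signal.
- **Paired conditions** (`simulate_paired_conditions`): the spike-in
  sequencing model described above — fixed spike material, fixed total
  depth, reads split between target and spike in proportion to
  material present.

# Pipeline

`run_pipeline()` executes YAML-configured stages in dependency order
with per-stage seeds derived as
`(seed + 1000003 * stage_index) mod (2^31 - 1) + 1`, writes each
stage's declared outputs, and records an MD5 manifest
(`manifest.json`); identical configurations produce byte-identical
outputs (hash equality is asserted in the tests). Stage failures leave
a `FAILED_<stage>` marker naming the stage. The thin CLI at
`inst/scripts/chromvalence` wraps the same functions.

# Limitations

- The binding model is strictly 1:1; cooperative or multi-site binding
  must be detected via the `misfit` diagnostics rather than fit.
- FRAP fitting assumes reaction-dominant recovery; diffusion-coupled
  models are out of scope, and the biexponential components are
  descriptive, not assignments to molecular species.
- The toy genome is a single chromosome with independent Bio-CAP and
  H3K4me3 by construction; it is designed for method validation with
  known expectations, not for emulating genome biology (no CpG
  sequence composition, no replication of real correlation structure).
- The multivalence permutation test's exactness rests on
  exchangeability of the H3K4me3 assignment under the null; with
  genuinely correlated covariates a nonzero index can reflect that
  correlation rather than multivalent reading.
- Spike calibration assumes equal spike material per sample and
  negligible cross-mapping between target and spike genomes.
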