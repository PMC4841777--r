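---
title: "A titration sizer for division counting in multiple fission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A titration sizer for division counting in multiple fission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissionsizer)
```

## The model

Multiple fission separates growth from division: a mother cell grows
through a long G1, passes a mid-G1 *commitment* checkpoint at roughly
twice its birth size, and later executes a rapid series of `n`
alternating S phases and mitoses that yields `2^n` equal daughters.
Because daughters do not grow in the dark, daughter size is a direct
readout of how well `n` was matched to mother size.

`fissionsizer` models the counting step as titration of a limiting
nuclear regulator:

1. **Allometric production.** Just before S/M a mother of volume $M$
   holds a regulator stock $S = aM^b$. With $b > 1$, concentration
   ($S/M$) rises with size, matching the observation that large
   mothers reach higher regulator concentrations even on an
   equal-protein-load comparison. Cells below the commitment size
   produce a negligible baseline (default 0).
2. **Fixed nuclear compartment.** Total nuclear volume is constant
   through S/M while nuclei double each round, so per-nucleus volume
   halves per round and the N/C ratio is stage-independent.
3. **Dilution with degradation.** Each round the stock is reduced by a
   net degradation fraction $\delta$ and split over twice as many
   genomes. Per round, nuclear concentration changes by $(1-\delta)$
   (shallow) while the per-genome ratio changes by $(1-\delta)/2$ — at
   least a two-fold drop per division, exactly two-fold when
   $\delta = 0$.
4. **Threshold exit.** Division continues while the sensed quantity is
   $\ge \theta$; committed mothers always complete at least one round
   even with no stock (an explicit property of the commitment
   checkpoint).

Which quantity is sensed — per-genome ratio, per-nucleus amount, or
nuclear concentration — is biologically unresolved; all three are
selectable through `sensed_quantity`, with the per-genome ratio as the
default because a regulator-to-DNA ratio is the natural readout of a
counting mechanism. None is asserted as truth.

### Discrete unit accounting

A complementary discrete reading treats the stock as units consumed
one per mitosis: round $k$ has $2^{k-1}$ nuclei and costs $2^{k-1}$
units, so $n$ rounds cost $2^n - 1$ units — one unit buys one division
(two daughters), seven units buy three rounds ($1+2+4$ mitoses, eight
daughters). `unit_accounting_rounds()` implements the closed form and
`run_division_series()` reproduces it exhaustively in `unit_mode`. In
unit mode the committed-cells-divide-once rule is suspended: a first
round, like every other, requires one unit per nucleus, otherwise the
zero-unit case could not agree between the two formulations.

## Parameters and calibration

| parameter | units | default | rationale |
|---|---|---|---|
| `production_coeff` ($a$) | AU·µm$^{-3b}$ | 6.5e-4 | see below |
| `production_exponent` ($b$) | — | 1.5 | minimal allometric form with concentration rising as $\sqrt M$ |
| `exit_threshold` ($\theta$) | AU/genome | 1 | sets the AU scale; only $a/\theta$ matters |
| `degradation_fraction` ($\delta$) | per round | 0.1 | a small but significant net loss; magnitude is not quantified experimentally, so it is a tunable |
| `commitment_size` | µm³ | 195 | wild-type commitment size |
| `max_rounds` | — | 5 | guard; observed mothers divide at most 4 times |
| `null_exit_threshold` | µm³ | 95 | fallback size control, see scenarios |
| `overexpression_supplement` | AU/nucleus/round | 0 (0.3 in scenario) | see scenarios |

The pair $(a, \theta)$ was calibrated once, before any validation was
run, against the dark-shift phenomenology: mothers just past
commitment divide once, ~350 µm³ mothers divide 1–2 times, ~600 µm³
three times, ~850 µm³ (a full light period of growth) four times.
With $\theta = 1$ this gives $a \approx 6.5\times 10^{-4}$. Because
intensities are in arbitrary units only the ratio $a/\theta$ is
meaningful; $\theta = 1$ AU per genome fixes the scale.

### Genotype scenarios

* **Loss of function** (`cdkg1_null`): production is zeroed. The
  experimental null still divides — just too few times — so exit must
  be handed to a fallback mechanism that the data do not specify. We
  model the simplest one that reproduces "fewer divisions, larger
  daughters": rounds continue while the prospective daughter volume
  stays at or above `null_exit_threshold` (default 95 µm³, the null
  daughter size). This is a deliberate re-interpretation of the
  threshold as a size floor rather than an AU quantity.
* **Mis-expression** (`overexpression`): a constitutive promoter
  supplies `overexpression_supplement` AU per nucleus at the start of
  every round (production is no longer confined to pre-S/M). The
  default 0.3 comes from the fixed point of the supplemented dilution
  map: the refill must stay small enough that dilution outruns it
  (asymptotic sensed value below $\theta$, so series terminate) while
  still buying extra rounds over the relevant mother sizes. An early
  trial value of 0.6 violated the first condition — every series ran
  into the `max_rounds` guard — which is why the guard and its warning
  exist.

## Parameter recovery

`fit_params()` recovers $(\theta, \delta, b)$ by coarse grid search
with two local refinement passes confined to the user grid's ranges,
minimising squared error in division counts. Count data alone leave a
near-flat ridge in $(\log\theta, b)$: the counts constrain
$b\ln M - \ln\theta$ near the centre of the observed volume range, so
a small error in $b$ is amplified exponentially into $\theta$. The
optional per-stage concentration means break this ridge when they are
passed in absolute units together with the anchor cohort's mother and
nuclear volumes: the stage-1 mean pins $aM_{\rm anchor}^b$ (and hence
$b$, since $a$ is carried in the base parameters) and the stage slope
pins $\delta$. Stage means are cohort averages and far more precise
than single-cell counts, so they are weighted at 10 per observation —
an inverse-variance-motivated (in fact conservative) weight. Ties in
the discrete count loss are broken toward the centre of the tied
plateau, which is both deterministic and the natural point estimate
for an interval-valued optimum.

`parameter_recovery_study()` packages the whole known-truth
experiment: 500 mothers log-uniform on 200–1000 µm³ (commitment size
to roughly the largest size reachable in one light period),
multiplicative lognormal noise of CV 0.1 on each mother's stock before
counts are produced, and a 100-cell-per-stage anchor cohort at
600 µm³ with the same noise CV on intensities. The noise is placed on
the measured regulator quantities rather than on the volumes: volume
measurements in this field come from Coulter counters and are far more
precise than immunofluorescence intensities, and noise on the
regressor would (and, in our experiments, does) attenuate $b$ and
bias $\theta$ along the ridge — a classical errors-in-variables
effect the estimator is not meant to correct.

## Population simulation

Growth is exponential in volume, $V \cdot 2^{t/T}$ with doubling time
$T$ (default 4 h so a 14 h light period gives $2^{3.5} \approx 11.3$
fold, "more than ten-fold"), stopped by an optional dark shift, with
mean-one lognormal cell-to-cell noise. Division splits mother volume
exactly equally among $2^n$ daughters (uniform-sized daughters are the
phenomenon being modelled; unequal cleavage is out of scope), so mass
is conserved identically.

`dark_shift_experiment()` reproduces the standard three-population
design — dark shift before commitment (3 h, population I,
non-dividers), mid-light (7 h, small mothers II), and a full 14 h
light period (large mothers III) — from one base daughter population
split round-robin, with per-population seeds derived from one base
seed. It reports division histograms (categories 0/1/2/3+) and the
total regulator per biomass and per cell, the simulation analogues of
equal-protein versus equal-cell-number loading. With $b > 1$ the
per-biomass value is higher in large than in small mothers.

The within-population variance of division number at fixed mother size
is not constrained by any measurement we model; stochasticity in
inherited stocks is therefore off by default in the model module and
lives in the generators and in explicit test constructions.

## Immunofluorescence pipeline

* **Segmentation**: global Otsu threshold on the DAPI channel,
  8-connected component labelling, minimum-area filter. The original
  workflow used interactive cell tracing plus automated DAPI
  segmentation; this package standardises on the automated part for
  reproducibility and takes cell boundaries from ground-truth masks
  (or the whole frame). An all-zero image is a valid empty result; a
  constant non-zero image is a threshold failure. EBImage supplies
  the Otsu threshold; labelling is done over the pixel adjacency graph
  (including diagonals) because the available labeller is 4-connected.
* **Measurement**: per nucleus, the background-subtracted signal
  (scalar background per image, estimated from an untagged control;
  per-pixel excess floored at zero) summed over member pixels; volume
  from the projected area; concentration as sum over volume. Z-stacks
  are reduced by maximum projection before measurement.
* **Geometry conventions**: areas are pixel counts times
  `pixel_size`²; no sub-pixel interpolation. The printed area-to-volume
  formula $V = \tfrac43 (A/\pi)^{3/2}$ omits a factor $\pi$ relative
  to the true sphere volume; both variants are implemented
  (`corrected = TRUE` adds the $\pi$) and all normalised outputs are
  invariant to the choice since the constant cancels. Whether the
  original analysis used the printed or the true form cannot be
  determined from the text, which is why both are kept and the printed
  one is the default.
* **Statistics**: "non-parametric two-tailed t test" is read as the
  Mann–Whitney rank-sum test, the conventional interpretation; exact
  enumeration is used for tie-free groups of at most 20, otherwise the
  tie-corrected normal approximation without continuity correction
  (so identical groups give $p = 1$). A permutation t-test is another
  defensible reading; it is not what we chose. One-way ANOVA on N/C
  ratios uses the classical F statistic with one convention added:
  all-identical groups return $F = 0$, $p = 1$. Stage summaries
  follow the original inclusion rule — only cells from mothers
  predicted by size to complete at least three divisions — and flag
  stages with fewer than 68 cells, the smallest per-stage group size
  used in the imaging experiments.

## Synthetic data

The generators are pure functions of (config, seed) and always emit
ground truth next to the data, so every downstream module has a
known-truth recovery test.

* `gen_size_population()`: lognormal daughter volumes, default mean 75
  µm³ with CV 0.04 (75 ± 3, the wild-type daughter size).
* `gen_if_records()`: per stage $s \in \{1,2,4,8,16\}$, $s$ nuclei of
  volume $V_{\rm tot}/s$ (constant total nuclear volume, default 30
  µm³ = 5% of a 600 µm³ mother); per-nucleus concentrations follow a
  geometric ($c_0(1-\delta)^k$) or linear ($c_0(1 - \delta k)$)
  schedule with multiplicative lognormal noise. The per-DNA ratio then
  declines by the factor $(1-\delta)/2$ per stage by construction.
* `render_cell_image()`: nuclei as filled disks on a jittered grid
  (non-overlap and containment guaranteed by construction — overlap
  handling is deliberately out of scope), DAPI constant inside nuclei,
  tagged-channel per-pixel values chosen so disk sums equal the
  record's intensities, cytoplasmic fraction spread uniformly outside
  nuclei, constant background, optional additive Gaussian pixel noise
  scaled to the nuclear per-pixel amplitude.
* `gen_ble_gfp_geometry()`: live-imaging analogue with a constant true
  N/C ratio (default 0.05), representative nuclear diameters from the
  halving per-nucleus volume, 1.3:1 ellipsoidal cells, multiplicative
  measurement noise on diameters and axes, group sizes 24 per stage
  (11 at the 16-nucleus stage).

Noise models are a choice, not an inference: multiplicative lognormal
for sizes and intensities (biological CVs), additive Gaussian for
pixels. What the generators do **not** emulate: point-spread functions
and optical blur, photobleaching, z-attenuation, chromatic offsets,
touching or overlapping nuclei, irregular cell boundaries, and any
correlation structure between neighbouring cells. Passing the
pipeline's recovery tests therefore demonstrates correctness of the
arithmetic and the segmentation logic on well-separated objects, not
robustness to realistic optics.

## Numerical conventions and problem sizes

Degenerate inputs have explicit contracts: empty populations and
all-background images error or return empty results as documented;
nuclear fractions exactly at one half count as *not* predominantly
nuclear (strict inequality); zero-signal cells are excluded from
fraction scoring with a logged count. Trajectory CSVs and parameter
JSON round-trip exactly; TIFF intensity images carry an explicit
scale because 32-bit TIFF storage is only defined on [0, 1].

The shipped tests and the acceptance script use a few hundred cells
per population, 100-replicate null studies, and a 500-cell recovery
study — sizes chosen so the full suite runs in well under a minute
while keeping Monte-Carlo rates (e.g. the ≥90% non-significant ANOVA
rate) comfortably away from their thresholds.

## Known limitations

* The production law, noise models, and the null-scenario fallback are
  minimal forms consistent with the qualitative observations, not
  fitted mechanisms; absolute daughter sizes under default calibration
  are indicative, and only their genotype ordering is a robust claim.
* Commitment is a parameter, not a modelled pathway; cell-cycle timing
  (the ~8 h post-commitment delay, S/M kinetics) is not simulated.
* The titration model is deterministic given its inputs; biological
  stochasticity enters only through the generators.
* The imaging pipeline is 2-D (projected areas), with a scalar
  background and no flat-field or deconvolution; it is faithful to
  quantitative-IF practice but not a microscope simulator.
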