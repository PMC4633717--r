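---
title: "Modelling two-population quorum-sensing biosensor consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-population quorum-sensing biosensor consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsconsort)
```

## The system being modelled

`qsconsort` simulates and analyses an engineered bacterial consortium that
reads out the interspecies quorum-sensing signal autoinducer-2 (AI-2) as a
colour-binned optical report. Two engineered *E. coli* responder populations
sample the same molecular environment in parallel: responder A activates at
low AI-2 levels and reports in the red channel, responder B requires roughly
an order of magnitude more signal and reports in green. Activation means
expression of a surface-displayed fusion of a fluorescent protein and a
streptavidin-binding peptide, so activated cells can additionally be loaded
with streptavidin-conjugated magnetic nanoparticles and collected by a
magnet. The pipeline therefore has four layers, each its own module:

1. **Dose-response models** (`dose_response()`, `fit_dose_response()`,
   `coculture_fractions()`, `case_library()`): what fraction of each
   population activates at a given AI-2 concentration.
2. **Synthetic data** (`simulate_growth()`, `producer_signal()`,
   `simulate_facs()`, `place_cells()`/`render_field()`): every input the wet
   lab would provide, generated with known ground truth.
3. **Image quantification** (`threshold_and_count()`,
   `classify_particles()`, `colocalization_fraction()`,
   `spatial_density()`, `line_profile()`) and the **magnetic
   capture/focusing model** (`bind_nanoparticles()`, `magnetic_sweep()`,
   `amplification_factor()`).
4. **Phase-plane binning** (`classify_point()`, `sweep_trajectory()`,
   `robustness_score()`, `render_pattern()`) and the orchestration layer
   (`run_pipeline()`).

## The dose-response model

Each responder's activation probability is a saturation curve

$$f(S) = f_0 + (f_\max - f_0)\,\frac{S^n}{K^n + S^n},$$

with baseline fraction $f_0$, saturating fraction $f_\max$, saturation
constant $K$ (µM, the half-maximal signal level) and Hill exponent $n$. The
default $n = 1$ is the Monod-type form appropriate for transport-limited
AI-2 induction; $n$ is exposed because the hypothetical case library needs
steeper, switch-like responses. Monotone-decreasing, band-pass
(rise with constant $K$, fall with constant $K_2 > K$) and constant shapes
cover the qualitative design space of engineered reporters.

Activation is a *population fraction*, not a per-cell intensity: the
observable is quorum size, the percentage of cells whose reporter is on. In
a coculture each member can thus contribute at most its population share;
`coculture_fractions()` returns $w_i f_i(S)$, which is why a saturated 1:1
mix reports 50% per member rather than 100% — the ceiling that makes
coculture outputs comparable across compositions.

### Fitting the saturation constant

`fit_dose_response()` recovers $(f_0, f_\max, K)$ from (dose, fraction)
pairs by least squares. Because generic nonlinear optimisers are sensitive
to starting values, the fit is a deterministic two-stage procedure:

1. a 120-point log-spaced grid over $K$ spanning two decades beyond the dose
   range; at fixed $K$ the model is *linear* in $(f_0, f_\max)$ and is
   solved exactly under $0 \le f_0 \le f_\max \le 1$ (the unconstrained
   2×2 normal equations, projected onto the constraint faces when violated);
2. Brent refinement (golden-section with parabolic steps) of $\log_{10} K$
   between the grid minimiser's neighbours.

The result is seed-free and bit-for-bit reproducible. Identifiability
guards: at least three distinct doses are required, and a response whose
spread is below `degenerate_tol` (default $10^{-3}$) aborts with a
"degenerate response" error since $K$ is then unidentifiable.

The package ships the published responding-fraction values for A and B as
`inst/extdata/dose_response_printed.csv`;
`reproduce_reference_fixtures()` fits both series and re-runs the titration
pipeline at the fitted parameters. This is a calibration, not a validation:
the curves are compared to the points they were fitted to. The fitted
constants ($K_A \approx 1.3$ µM, $K_B \approx 43$ µM) are also the defaults
of `coculture_ab()`, so the default titration reproduces the characteristic
none → red → red+green label ordering with increasing dose.

### The hypothetical case library

The ten response pairs in `case_library()` are the package's canonical
taxonomy of two-reporter designs (identical pair, shifted amplitude,
on/off, opposing, band-pass variants, shifted thresholds, steep vs shallow,
unequal amplitude). Their parameters are fixed constants chosen for clean
qualitative separation, documented on the help page. Case 7 — a shifted-$K$
monotone pair with $K_\text{green} = 10\,K_\text{red}$ and unit amplitudes —
is the configuration matching the package's A/B consortium; its sweep
occupies exactly quadrants Q1, Q2 and Q4 of the phase plane and can never
enter Q3, because by the time the green member clears its threshold the red
member (lower $K$) is always far above its own.

## What the synthetic data emulate — and what they do not

**Growth.** `simulate_growth()` integrates shared-capacity logistic growth
$\dot N_i = r_i N_i (1 - \sum_j N_j / C)$ with `deSolve`. Equal rates make
the share vector a conserved quantity, which the tests verify to $10^{-6}$
over 12 h — the basis for treating a 1:1 inoculum as a 1:1 read-out mix.

**Producer environments.** An AI-2 producer grows logistically and signal
accumulates as $\dot S = k X(t)$. The density-to-AI-2 yield $k$ (default
$2 \times 10^{-9}$ µM per cell h mL$^{-1}$) is a synthetic monotone-linear
calibration, not a measured conversion. The `low_density` and
`high_density` scenarios encode 20:1 and 200:1 producer-to-responder
inoculation against a $10^6$ cells/mL responder inoculum, with dilute-medium
versus rich-medium carrying capacities; under the defaults they reach ~2.6
and ~33 µM terminal AI-2 over 12 h, i.e. above A's threshold only, versus
above both.

**Flow cytometry.** `simulate_facs()` draws per-event activation as a
Bernoulli trial at $f(S)$ and intensities from log-normal "on"
(meanlog $\log 2\times10^4$, sdlog 0.5) and "off" (meanlog $\log 150$,
sdlog 0.8) distributions, an arbitrary-unit scale placed so the
conventional gate of $2\times10^3$ sits between the modes with ~0.1%
background leakage. Only gate placement relative to the modes matters
downstream; no attempt is made to model scatter, doublets or compensation.

**Microscopy.** Cells are 2-D rotated ellipses (length uniform in
1.5–2 µm, 3:1 aspect ratio) at 0.1 µm/px; activated cells are rasterised at
a fixed amplitude, blurred with a Gaussian PSF ($\sigma$ = 0.15 µm,
zero-padded boundaries so nothing wraps across edges), and corrupted with
Poisson shot noise plus Gaussian read noise over a uniform background.
Placement enforces a minimum centre separation of 1.8 µm — just under the
maximum cell length, the regime of a well-dispersed monolayer in which
particle counting is meaningful — with bounded retries, so dense requests
warn and terminate instead of hanging. Nanoparticles are ~100 nm, an order
of magnitude below the cell scale, and are represented only as a boolean
bound flag, never as resolvable image objects. Passing imaging tests
therefore show that the *quantification* chain is faithful on separable
rod-shaped objects; they say nothing about touching-cell segmentation,
3-D stacks, uneven illumination or autofluorescence, which real
micrographs contain and the package does not model.

## Image quantification choices

* Connectivity is 8-connected (diagonal-touching pixels join), matching
  common particle-analysis defaults.
* Thresholding is `>=`, so a pixel exactly at threshold is signal; default
  thresholds are per-channel Otsu unless overridden, because published
  procedures state thresholds were applied uniformly without printing
  values.
* Coordinates are 0-based `(row, column)` with origin top-left, echoed in
  all output tables.
* Colour classification uses the ratio
  $(\bar g + \varepsilon)/(\bar r + \varepsilon)$ with $\varepsilon = 1$
  intensity unit (no divide-by-zero) and ratio threshold 2; components
  below the size threshold are labelled `sub_size` and excluded from colour
  counts, since the size filter is part of the particle-analysis contract.
* The colocalized fraction of an empty primary set is `NA` (no data), never
  0.

## The magnetic capture model

Capture is phenomenological: activated cells bind nanoparticles with
probability $\beta$ (default 0.9), non-activated cells with
$\beta_{ns} \le \beta$ (default 0.01); a sweep captures each bound cell with
efficiency $\eta$ (default 0.9) and repositions it uniformly within a focal
disc of area $a_f$ drawn from a distributed area $a_0$. No magnetophoretic
physics, field geometry, or particle-per-cell stoichiometry is modelled.
Two consequences are load-bearing and tested: capture is colour-blind given
the bound flag, so the captured green:red composition is an unbiased copy of
the pre-sweep activated composition; and the expected fold change in
per-area fluorescent density is $\eta \beta (a_0/a_f)$, so the
amplification observed in an experiment is dominated by the well-to-pellet
geometry, which the model deliberately exposes as a free parameter instead
of asserting any particular fold value.

## Phase-plane binning

A (red, green) output pair is classified against thresholds
$(t_r, t_g)$: Q1 both below (`none`), Q2 red only (`red`), Q3 green only
(`green`), Q4 both (`red+green`). Comparisons use `>=` so boundary points
classify deterministically upward. Outputs carry a unit tag (fraction,
count, or percent area) and classification refuses mismatched units, since
the published phase plots do not fix the axis unit. The default threshold
is 5% of the maximum attainable output per axis — a configurable convention
for "negligible colour", not a measured constant. Q4 is implemented as
both-above-threshold; a stricter "equivalent ratios" reading of the
red+green category is noted but not implemented.

`robustness_score()` quantifies tunability as the fraction of seeded
log-uniform parameter perturbations (relative ranges on $K$ and $f_\max$)
that leave the occupied-quadrant set unchanged — a spec-level definition
chosen here, since no published metric is available. A zero-width
perturbation scores 1 by definition.

## Orchestration and reproducibility

`run_pipeline()` chains the stages for a scenario and returns a tibble-based
report; every stochastic stage receives a seed derived from the master seed
by the fixed affine scheme in `stage_seed()`, so any stage can be re-run in
isolation and identical `(config, seed)` pairs give identical reports. All
simulators take explicit seeds and restore the caller's RNG state
(`withr::with_seed`), and all analysis operations are seed-free and
deterministic on fixed inputs. The package exposes functions rather than a
shell entry point; configurations can be read from YAML/JSON via
`read_run_config()` and curve/responder definitions round-trip through
`write_curve_spec()`/`read_curve_spec()`.

## Problem sizes used by the test suite

The shipped tests exercise the study's conditions at desk scale: 50,000
FACS events per dose where estimator accuracy matters (200 replicate fits
for parameter recovery), 20 seeded 200-cell fields of 512×512 px for
imaging fidelity, 100 seeded sweeps of 600-cell populations for capture
unbiasedness, and 12-hour growth integrations at 0.01 h steps. These sizes
were chosen so each statistical check has comfortable power while the whole
suite runs in well under a minute per module.

## Known limitations

* The dose-response curve is a phenomenological interface; no lsr-operon
  derepression kinetics or T7 amplification cascade is modelled.
* Environments are well-mixed: no chemotaxis, no spatial signal gradients.
* The imaging model is 2-D with non-touching cells; segmentation of dense
  aggregates is out of scope.
* The case library and the robustness metric are package-defined canonical
  choices, suitable for comparing designs within this framework rather than
  reproducing any particular published parameterisation.
* Absolute producer-density-to-AI-2 calibration is synthetic; only the
  ordering (high-density environments accumulate more signal) should be
  interpreted.
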