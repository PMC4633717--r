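# qsconsort

Simulation and analysis of two-population quorum-sensing biosensor
consortia with magnetic binning.

## What problem this addresses

Engineered whole-cell biosensors report a signal molecule's concentration as
the *fraction of a population* that switches on a reporter. Pairing two
sensor populations with shifted detection thresholds — a low-threshold
responder A reporting red and a high-threshold responder B reporting green —
turns a single analyte (here the quorum-sensing signal autoinducer-2, AI-2)
into a colour-binned categorical read-out: no colour, red only, or red plus
green, each band indexing an interval of signal level. Adding magnetic
nanoparticles that bind only activated cells lets a magnet filter and focus
the fluorescent subpopulation into an acute, easily imaged spot.

`qsconsort` is for computational biologists and synthetic-biology modellers
who want to design, simulate and quantify such consortia end to end without
a wet lab: it generates all the inputs (growth, producer environments,
flow-cytometry event tables, two-channel micrographs with ground truth),
implements the quantification chain (particle counting, colour-ratio
classification, colocalization, spatial density), models nanoparticle
capture, and classifies outputs on the phase plane.

## The core model

Each responder activates with probability

    f(S) = f0 + (fmax − f0) · S^n / (K^n + S^n)

where `S` is the AI-2 concentration (µM), `K` the saturation constant and
`n = 1` the default Monod case. In a coculture, member *i* with population
share `w_i` contributes `w_i · f_i(S)` of the total population — so a
saturated 1:1 pair reports 50% per member, not 100%. `fit_dose_response()`
recovers `(f0, fmax, K)` by a deterministic two-stage least-squares
procedure (log-grid over `K` with an exact constrained linear solve per
grid point, then Brent refinement). The (red, green) output pair is binned
by thresholds `(t_r, t_g)` into quadrants Q1–Q4 mapping to
{none, red, green, red+green}; a magnetic sweep captures bound cells with
efficiency `η` and concentrates them from area `a0` into `a_f`, amplifying
per-area fluorescent density by `η·β·(a0/a_f)` in expectation.

## Worked example

Fit the packaged published dose-response series for responder A and run the
default titration pipeline:

```r
library(qsconsort)

a <- subset(read.csv(system.file("extdata", "dose_response_printed.csv",
                                 package = "qsconsort")),
            responder == "A")
fit <- fit_dose_response(a)
tidy(fit)
#> # A tibble: 4 × 3
#>   term  estimate unit
#> 1 f0       0     "fraction"
#> 2 fmax     0.928 "fraction"
#> 3 K        1.31  "uM"
#> 4 n        1     ""

run_pipeline(run_config(seed = 42))
#> <qs_run_report: scenario 'titration', 5 conditions, seed 42>
#> # A tibble: 5 × 5
#>   condition dose_uM red_pct green_pct category
#> 1 0 uM            0     0         0   none
#> 2 2 uM            2    30.3       2.2 red
#> 3 10 uM          10    44.2       9.4 red+green
#> 4 28 uM          28    47.8      19.7 red+green
#> 5 75 uM          75    49.1      31.8 red+green
```

The fitted saturation constant (`K ≈ 1.3 µM`) says responder A half-saturates
near 1.3 µM AI-2; `fmax ≈ 0.93` is its saturating responding fraction. In
the titration report, `red_pct`/`green_pct` are each responder's activated
share of the *total* population (FACS read-out, capped at 50% in a 1:1 mix),
and `category` is the phase-plane bin: the labels step through
none → red → red+green as dose increases, the consortium's colour code for
low/medium/high AI-2. Sweeping the matched shifted-threshold pair from the
case library across doses visits quadrants `Q1>Q2>Q4` and never Q3
(`sweep_trajectory(case_library(7), ...)`): green without red cannot occur
when red has the lower threshold.

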