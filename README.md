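# autoplanr

Autopiloted, DVH-guided radiotherapy plan optimization on synthetic
phantoms.

## The problem

Inverse treatment planning produces beamlet fluences whose dose covers the
planning target volume (PTV) while sparing organs at risk (OARs). In
practice a planner steers the optimizer by hand: run it, look at the
dose-volume histograms (DVHs), adjust the per-structure weighting factors,
run it again. `autoplanr` automates that outer loop. A *reference plan* —
a previously planned case with similar anatomy and prescription, retrieved
from a library by a signed radial contour-difference metric — supplies
per-structure DVH curves, and the autopilot re-parameterizes the inner
optimizer until every DVH segment of the current plan matches the
reference within tolerance:

|d<sub>σj</sub> − d<sub>σj</sub><sup>ref</sup>| < ε<sub>σj</sub>,  σ = 1..N, j = 1..J,

where d<sub>σj</sub> is the dose of the j-th DVH segment of structure σ
(the dose at the j-th fixed volume-fraction control point; 20 points from
2.5% to 97.5% by default) and ε<sub>σj</sub> is 3% of the reference value,
floored at 0.1 Gy. The loop stops when all segments match or after 50
outer iterations, then applies Pareto-safe *trial movements*: objective
perturbations toward better coverage or sparing, accepted only if no DVH
segment of any structure worsens by more than one DVH bin width.

The inner optimizer is a convex surrogate for a commercial fluence-map
optimizer: a weighted quadratic dose objective over nonnegative beamlet
fluences, minimized by monotone accelerated projected gradient descent.
Synthetic 2D phantoms (target + OARs + body contour, pencil-beam influence
matrix) and jittered-geometry reference libraries make the whole pipeline
runnable and testable without patient data. See the methods vignette
(`vignettes/autopilot-methods.Rmd`) for the models, defaults, and known
limitations.

## Worked example

```r
library(autoplanr)

spec    <- phantom_spec(seed = 1L)              # 64x64, 1 PTV + 2 OARs
phantom <- generate_phantom(spec)
case    <- c(phantom, list(site = spec$site))

lib <- generate_reference_library(spec, n_cases = 3, jitter_mm = 2,
                                  seed = 3L)
sel <- select_reference(lib, case)
sel
#> reference_selection: 'ref001' selected (score 0.230 mm) of 3 candidates

fit <- run_autopilot(case, sel$reference, autopilot_config())
fit
#> Autopiloted plan
#>   reference: 'ref001'  prescription: 50.0 Gy
#>   outer iterations: 2 (all DVH segment constraints met at iteration 2)
#>   trial movements: 0 accepted of 3 tried
#>   max relative segment deviation: 2.60%

round(coef(fit), 3)
#> external      ptv    oar_a    oar_b
#>     0.02     1.00     0.27     0.30

aggregate(abs(deviation_gy) ~ structure, residuals(fit), max)
#>   structure abs(deviation_gy)
#> 1     oar_a          0.340375
#> 2     oar_b          0.163575
#> 3       ptv          0.275525
```

The selection score (0.230 mm) is the largest absolute signed radial
difference between the query's and the reference's contours over 144 rays
per structure — well inside the 2 mm (small structure) / 10 mm (skin)
acceptance thresholds. The autopilot warm-starts from the reference's
parameters, finds all 60 DVH segment constraints satisfied after two
re-optimizations (every segment within 3% of the reference, here at most
0.34 Gy off), and leaves the weighting factors close to their warm-start
values. All three post-convergence trial movements were rejected — the
plan already sits on the surrogate objective's Pareto surface, so any
further OAR sparing would cost target coverage.

`plot(fit)` draws the outer-loop convergence trace and the final DVHs
overlaid on the reference's; `summary(fit)` tabulates per-structure
deviations. `run_autopilot(..., output_dir = "out")` writes per-iteration
DVH files (a documented plain-text dialect, see `write_dvh_file()`), a
history table, and the final parameters. Thin command-line wrappers for
selection and planning live in `inst/scripts/`.

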