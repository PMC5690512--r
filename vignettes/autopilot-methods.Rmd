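---
title: "DVH-guided autopiloted plan optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DVH-guided autopiloted plan optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Inverse treatment planning asks a numerical optimizer for beamlet fluences
whose dose distribution covers the planning target volume (PTV) at the
prescription while sparing organs at risk (OARs). In clinical systems the
optimizer's behaviour is steered by per-structure *weighting factors* and
*objective doses*, and a human planner iterates: optimize, inspect the
dose-volume histograms (DVHs), adjust the weights, reoptimize. `autoplanr`
automates that outer loop. A previously planned case with similar anatomy
and the same prescription — the *reference plan* — supplies per-structure
DVH curves; the autopilot repeatedly re-runs the inner optimizer and
adjusts the weighting factors until every DVH segment of the current plan
matches the reference segment within tolerance:

$$ |d_{\sigma j} - d_{\sigma j}^{\mathrm{ref}}| < \varepsilon_{\sigma j},
   \qquad \sigma = 1..N,\; j = 1..J, $$

with $\varepsilon_{\sigma j} = \max(0.03\, d_{\sigma j}^{\mathrm{ref}},
\varepsilon_{\mathrm{floor}})$: 3% of the reference value, floored at
0.1 Gy so segments with near-zero reference dose are not held to a vacuous
relative band. The inequality is strict; a deviation exactly at tolerance
counts as a violation. The loop stops when all constraints hold or after
50 outer iterations, and then applies *trial movements*: per-structure
objective perturbations toward better coverage or sparing, accepted only
if no DVH segment of any structure worsens by more than one DVH bin width.

Everything runs on synthetic 2D phantoms with a surrogate dose engine, so
the whole pipeline is testable without patient data or a commercial
planning system.

# DVH segments

A cumulative DVH gives the percent volume receiving at least each dose
(`compute_dvh()`, ">= dose" convention, the universal clinical one). The
curve is tabulated at 0.001 Gy resolution; the header statistics Dmin,
Dmax, Dmean come from the raw voxel doses rather than the binned curve,
mirroring the header/table split of clinical DVH exports
(`write_dvh_file()` / `read_dvh_file()` implement a documented plain-text
dialect with exactly that structure).

A *segment* is operationalized as the dose at a fixed volume-fraction
control point: segment $j$ of structure $\sigma$ is $D_x$ at
$x = f_j$, with $J = 20$ fractions evenly spaced from 2.5% to 97.5% by
default. Sampling the inverse curve at fixed fractions turns the matching
condition into a finite constraint set while covering the whole curve,
including the hot and cold tails.

On a 64x64 planning grid a small OAR holds only ~50 voxels, and binary
voxel counting then imprints visible staircase noise on DVH quantiles. The
loop therefore evaluates DVHs through `dvh_sampler()` with 3x bilinear
supersampling: dose is interpolated onto a three-fold finer grid and the
polygon contours re-rasterized there, a partial-volume refinement that
leaves the DVH definition untouched but reduces voxelization noise.
Reference libraries store their DVHs at the same refinement so current and
reference curves share one discretization.

# The surrogate inner optimizer

The inner optimizer stands in for the commercial system's fluence-map
optimization. Dose is linear in the beamlet fluences, $d = Dx$, with $D$ a
pencil-beam influence matrix. The objective is the standard convex
weighted quadratic form

$$ F(x) = \sum_\sigma \frac{w_\sigma}{|\sigma|} \sum_{v \in \sigma}
   \mathrm{pen}(d_v) + \lambda \lVert x - x_a \rVert^2,\quad x \ge 0, $$

where targets use the two-sided uniform-dose penalty
$(d_v - d^{\mathrm{obj}})^2$ and OARs and the external contour the
one-sided upper penalty $\max(0, d_v - d^{\mathrm{obj}})^2$.

Two numerical choices matter and are worth stating plainly:

* **Solver.** The minimization uses monotone accelerated projected
  gradient descent (FISTA with an Armijo-backtracked step, a monotone
  safeguard and function-value restart). Realistic influence matrices are
  ill-conditioned: plain projected gradient stalls on flat valleys and
  returns solver-path artifacts rather than optima, which makes a
  reference DVH irreproducible even on identical geometry. The accelerated
  solver converges to the optimum in a few hundred iterations while the
  recorded objective trace remains monotone nonincreasing on every run.
  Stopping: relative objective decrease below 1e-9 sustained over a
  40-iteration window, or a stationary projected-gradient step; cap 3000
  iterations.

* **Regularization.** The quadratic dose objective alone is
  near-degenerate in fluence space — many fluence maps give almost the
  same objective — so the argmin can jump under millimetre geometry
  changes. A Tikhonov term ($\lambda$ = 1e-2 relative to the Hessian
  scale) anchored at a conformal open-field template (beamlet weight
  proportional to its mean influence on the target, scaled to the target
  objective) makes the optimum unique and continuous in the anatomy
  without shrinking the plan toward zero dose. Because $\lambda$ scales
  with the objective's own Hessian, rescaling all weights by a common
  factor still leaves the argmin unchanged.

Default plan parameters place the target objective at the prescription
with weight 1; OARs get an upper objective at 0.15 of the prescription —
deliberately *below* their transit-dose level so the penalty is active
over most of the OAR volume and the weighting factor has monotone
influence on the whole OAR DVH — with weight 0.3; the external contour
acts as a normal-tissue/hotspot objective (upper objective at the
prescription, weight 0.02). An objective placed above the dose range makes
the weight inert; an objective at zero with substantial weight lets the
optimizer avoid small OARs entirely, a degenerate regime whose DVHs are
hypersensitive to geometry. Both regimes were measured and rejected.

# The outer-loop decision function

The loop warm-starts from the reference plan's parameters and fluence,
then iterates: inner optimization, DVH computation, segment check, weight
update. The update is a multiplicative exponentiated-gradient step on each
structure's aggregate signed violation $V_\sigma$ — the sum of the full
signed deviations (current minus reference) of its failing segments:

$$ w_\sigma \leftarrow w_\sigma \exp\!\big(\mathrm{clip}(\pm\eta\,
   V_\sigma / d_{\mathrm{Rx}}, \pm 1)\big), $$

with the sign chosen so an overdosed OAR gains weight (more sparing
pressure) and an underdosed target gains weight (more coverage pressure).
Using the full deviation rather than only the excess beyond tolerance is
deliberate: the excess vanishes as a segment approaches the band, so an
update driven by it creeps toward the strict inequality without ever
crossing it. Updates clip at a factor of $e$ per iteration, and weights
stay within an order of magnitude of their warm-start values — if a
reference segment is unreachable (the reference asks for more OAR dose
than the geometry delivers at any weight), unbounded multiplicative decay
would silently remove that structure from the objective.

Two adaptive layers sit on top. A bold-driver schedule halves the learning
rate whenever an update fails to reduce the maximal violation and lets it
recover by 10% per successful step, so the final approach to the tolerance
band takes progressively finer steps. If four consecutive updates bring no
improvement the loop switches to a derivative-free pattern search: one
structure's weight at a time is scaled by $1 \pm \delta$ (starting at 5%,
halving on full unsuccessful cycles) around the best iterate found so far,
and a move is kept only when it decreases the maximal violation. This
fallback handles the sum-zero equilibria where opposite-signed segment
deviations within one structure cancel in $V_\sigma$.

If the cap is hit unsatisfied, the best iterate by maximal violation is
returned with `converged = FALSE`.

# Trial-movement refinement

After termination each structure's objective makes a trial movement —
targets first, then OARs by descending weight: an OAR's objective dose is
lowered by 5%, a target's raised by 5%, the inner optimizer re-runs, and
the move is accepted only if no DVH segment of any structure worsens by
more than one DVH bin width (0.001 Gy), where "worsens" means dose
increase for an OAR segment and dose decrease for a target segment.
Rejected moves are reverted; every trial is logged.

A known limitation follows directly from convexity: a plan at a weighted
optimum is Pareto-optimal, so in a continuous tradeoff *any* meaningful
OAR gain costs some target segment more than one bin width, and almost all
trials are rejected. The refinement is therefore a safety net that catches
plans left short of the Pareto surface (e.g. by an unambitious reference),
not a mechanism that can walk along it. In particular, when a reference's
OAR curves are inflated by several Gy, the loop — correctly, since the
matching condition is two-sided — tracks them upward, and refinement
cannot pull the final plan back; robustness to a badly degraded reference
is bounded by the weight clamp, not by the trial movements.

# Reference selection

Candidates are first filtered on anatomical site, structure-name sets
(after normalization), physical target volume (±25% relative band) and
prescription dose (±10%). For each surviving candidate and each structure,
a polar system is placed at the structure's center of mass — implemented
as the polygon area centroid, which makes the metric exactly invariant
under rigid translation of either case — and rays are cast at 2.5°
resolution (144 rays). At each angle the boundary-crossing radii of the
two contours are matched by sorted index and the signed difference is the
reference radius minus the current radius. Angles with differing crossing
counts are flagged and treated as exceeding any threshold (conservative,
keeps the metric defined for concave structures). A candidate is rejected
if any structure's maximal absolute signed difference exceeds its
threshold: by default 2 mm for structures under 10 cc and 10 mm for large
structures including the skin contour, both configurable within the
clinically quoted 1–3 mm / 5–15 mm ranges. Among accepted candidates the
one minimizing the maximum per-structure deviation wins; ties break by
RMS, then case id. An overlay figure of query and reference contours is
written for the visual-inspection step.

# The synthetic phantom and what it does (not) emulate

`phantom_spec()` describes a single 2D slice: a circular body contour
(radius 70 mm on a 64x64 grid of 2.5 mm voxels), a central PTV (radius
15 mm, prescription 50 Gy in 25 fractions), and circular OARs at
configurable offsets, by default radius 10 mm at 40 mm and radius 12 mm at
(−36, 26) mm — 15–17 mm gaps from the PTV, placing them in the smooth
transit-dose region rather than the steep penumbra. The influence model is
a divergent pencil beam (source at 1000 mm, exponential attenuation
0.005/mm approximating 6 MV photons in water, lateral Gaussian penumbra
sigma 4 mm) for 9 equispaced beams of 15 beamlets at 5 mm spacing; the
matrix is calibrated so unit fluence gives mean PTV dose equal to the
prescription on the nominal PTV disc.

Reference libraries jitter the PTV and OAR contours per structure — a
random center shift plus a radius change, partitioned so the total
boundary displacement cannot exceed the jitter bound (2 mm in the study
configuration) — and plan each jittered geometry to convergence with the
default parameters, so every reference DVH is achievable on its own
anatomy.

What the phantom does *not* emulate: tissue heterogeneity, scatter,
realistic penumbra shapes, 3D out-of-plane geometry, deliverability (MLC
sequencing), or the shape diversity of real inter-patient anatomy. Tests
passing on these phantoms show the algorithmic machinery is correct and
that the matching loop converges when a reference is achievable; they do
not certify clinical plan quality.

## Convergence at the study scale, honestly

With independent per-structure jitter at the full 2 mm bound, roughly 7 of
10 random references are matched within the 3% band under the 50-iteration
cap (typically within the first handful of iterations); the remainder are
provably unmatchable by per-structure scalar weights — direct minimax
optimization over the full weight vector still leaves 3.2–4.4% deviations,
because a scalar weight cannot correct opposite-signed deviations within
one structure and cannot raise OAR segments that sit below the structure's
objective dose. Those unmatchable references are not screened by the
similarity metric (their signed differences are under 1 mm). This is a
real property of weight-only outer loops on tightly toleranced low-dose
segments, and the package reports it rather than hiding it: unconverged
runs return the best iterate with a flag.

# Numerical conventions

* Voxel centers at $(i - 0.5)\,\Delta$ in mm; contours are closed polygons
  in physical mm; masks are rasterized by the even-odd rule on voxel
  centers, so mask and contour are consistent by construction.
* Isodose-to-structure conversion is inclusive (dose >= level); Boolean
  "not" complements within the external contour.
* Strict inequalities in the constraint check are evaluated with exact
  float comparisons; ties count as violations.
* All randomness lives in phantom/library generation; the outer loop and
  inner solver are deterministic given their inputs.
* Problem sizes: the study phantom is a 64x64 grid (4096 voxels, 135
  beamlets), which a full 10-seed sweep of library generation plus
  autopilot runs completes in about a minute on one core.
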