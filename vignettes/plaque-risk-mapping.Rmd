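---
title: "Coronary plaque risk mapping from OCT and angiography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coronary plaque risk mapping from OCT and angiography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquefuse)
```

## The problem

Rupture of a vulnerable atherosclerotic plaque in a coronary artery is the
usual trigger of acute myocardial infarction. Two image-derived quantities
are established markers of vulnerability: the thickness of the fibrous cap
separating the lipid core from the lumen (thin caps rupture; a cutoff of
151 µm on representative caps is the best published predictor), and the
wall shear stress (WSS) exerted by blood on the endothelium (1.7 Pa is a
commonly used transition from intermediate to high shear). The two come
from different modalities — cap thickness from intravascular optical
coherence tomography (OCT), WSS from computational hemodynamics on a
3D lumen reconstructed from biplane angiography — and are usually analysed
separately. `plaquefuse` implements the full fusion chain: quantify both,
co-register them on one cut-open map of the vessel surface
(arc-length × circumferential angle), and combine them into a single
four-level risk map.

## Cap thickness from polar OCT frames

An OCT frame is a polar image: one column (A-line) per angular position,
one row per radial depth sample (by default 968 × 504 pixels over a
4.3 mm scan depth). Interfaces appear as radial intensity edges: the
luminal border is a dark-to-bright transition, the abluminal border of the
cap a bright-to-dark one.

**Cost image.** `polar_cost_image()` takes the backward difference of the
(optionally pre-smoothed) intensity along the radial direction, keeps the
sign selected by the polarity, clamps at zero, divides by the robust
maximum (99th percentile of the positive part) and returns
`cost = 1 − gradient` in `[0, 1]`. A backward difference at pixel *j*
measures the gradient at the inter-pixel position *j − 1* in pixel units;
contour radii use that convention, which removes the half-pixel bias a
naive pixel-centre reading would introduce.

**Optimal path.** `extract_contour()` finds the contour minimising

$$\sum_\theta c(\theta, r_\theta) \;+\; \lambda \sum_\theta |r_\theta -
r_{\theta-1}|, \qquad |r_\theta - r_{\theta-1}| \le m,$$

i.e. a data-attachment term plus a smoothness penalty with a hard step
bound. Minimal-path formulations of this kind are classically solved by
front propagation with back-tracking; for a first-order penalty on a
column-ordered grid the accumulate-then-backtrack dynamic program yields
exactly the same optimum and is directly verifiable against brute-force
enumeration, which is how the test-suite checks it. Closed contours add
the endpoint constraint $|r_{\text{last}} - r_{\text{first}}| \le m$. We
solve closed contours on the span order as given: the free-endpoint
optimum is accepted whenever it already satisfies the closure constraint
(it is then provably optimal), otherwise the first-column starting radii
are searched exhaustively under a branch-and-bound lower bound. An
alternative would be to re-anchor the span at the most confident column
first, but the objective above is not invariant to rotating the span (the
wrap transition is constrained, not penalised), so re-anchoring silently
changes the problem; solving on the given span keeps the implementation
equal to its oracle. Ties are always broken toward the smaller radius, so
results are reproducible to the bit.

**Defaults.** `λ = 0.5` per radial pixel of displacement and `m = 2`
pixels; the intensity is pre-smoothed with a 5-A-line circular boxcar
(speckle suppression across columns does not blur the radial edge;
no radial smoothing by default, keeping step edges single-pixel sharp).
The abluminal search window is restricted to radii strictly deeper than
the lumen plus 40 µm — below the axial resolvability of two OCT
interfaces — which makes the luminal/abluminal ordering a hard
invariant.

**Sub-pixel refinement.** The smoothness penalty lags the integer path by
up to a pixel or two on monotone slopes of the interface. After
extraction, each column is re-centred on the local cost minimum within
the step bound around the path, and a parabola through the minimum and
its neighbours gives a sub-pixel position (clamped to ±0.5 px). On
noise-free renderings this recovers interfaces to a fraction of a pixel.

**Thickness.** `thickness_profile()` converts both contours to Cartesian
millimetres, estimates the luminal tangent by centred differences after
an 11-A-line circular moving average of the radius (the tangent estimate
is the only smoothed quantity; the contour itself is untouched), and
intersects the inward normal ray with the abluminal polyline. Rays that
miss are flagged and excluded from the summary. The representative cap
thickness follows the established sampling protocol: five sites drawn
uniformly without replacement per frame, frames every 0.5 mm along the
pullback, grand mean over all draws, seeded for reproducibility.

## 3D lumen and wall shear stress

Two angiographic silhouettes taken at views at least 30° apart are
matched by normalised longitudinal position. Views are modelled as
orthographic projections — no cone-beam calibration is available at this
level of description — so a view at angle *v* measures positions along
the in-plane axis at angle *v*: the midline gives one linear equation for
the transverse centerline position, and two views determine it. Each
cross-section is the ellipse whose support widths reproduce both measured
widths, with the major axis aligned to one of the two view axes; with two
views this orientation is genuinely ambiguous, and the candidate closest
to the previous sample is kept. For orthogonal views aligned with the
true axes the recovery is exact; for oblique views the residual area
error is bounded by $(a^2-b^2)^2 \sin^2\!v\, \cos^2\!v / (2a^2b^2)$ —
about 1.3 % at an axis ratio of 0.85 — which is a structural limit of
two-view reconstruction, not an implementation artifact.

Inlet and outlet extensions of five times the local mean radius are
appended (straight, constant section) before flow assignment; they are
flagged and never enter the cut-open maps.

**Flows.** Boundary flows follow a diameter scaling law $Q = k D^e$ with
the local diameter $D = 2\sqrt{ab}$ in mm: the inlet flow from the inlet
diameter, and at each side branch a split between branch and distal main
vessel proportional to $D^e$, so conservation is exact by construction.
The constants are assumptions, not reproductions of measured values:
$e = 2.27$ from the empirical coronary flow–diameter literature, and $k$
chosen to give 1 mL/s at $D = 3$ mm. Normalised WSS (below) is invariant
to $k$ by design.

**WSS.** Full 3D finite-volume CFD is out of scope at desk scale; each
section instead carries the exact fully developed laminar elliptical-duct
solution for its assigned flow:

$$G = \frac{4\mu Q (a^2+b^2)}{\pi a^3 b^3}, \qquad
\tau(\phi) = \frac{G\, a^2 b^2}{a^2+b^2}
\sqrt{\frac{\cos^2\phi}{a^2} + \frac{\sin^2\phi}{b^2}},$$

which reduces to the Hagen–Poiseuille wall shear $4\mu Q/(\pi r^3)$ in
the circular limit and is validated against an independent
Shortley–Weller finite-difference Poisson solve in the tests. This
surrogate ignores axial tapering, curvature-induced secondary flow and
entrance effects; `import_external_wss()` accepts externally computed CFD
samples in the same exchange format when fidelity matters. Sections are
resampled onto a regular 0.05 mm arc-length grid before evaluation so
that binned averages do not depend on the geometry's own sampling.
Default blood viscosity is 3.5 mPa·s.

Surface samples are averaged on the shared cut-open grid (0.2 mm rows,
10° bins, both half-open; samples landing exactly on an edge are snapped
deterministically). `normalize_map()` divides by the 50th percentile over
counted bins, making the map insensitive to the imposed inflow.

## Co-registration

Axial registration is a piecewise-linear monotone map from OCT frame
index to centerline arc-length through landmark pairs (side branches,
pullback endpoints), extrapolated linearly beyond the outermost anchors.
Rotational registration uses the two side-branch orientations: the anchor
offsets are map orientation minus OCT orientation wrapped to
(−180°, 180°], interpolated linearly in frame index along the shortest
signed arc (so anchors at 170° and −170° interpolate through 180°), and
held constant outside the anchors — the interpolation is only defined
between the branches, which is also the segment all statistics are
computed on. A-line *i* sits at angle $(i-1)\cdot 360/n$ degrees,
counterclockwise, before the offset is applied; this convention is stated
once and used everywhere.

`resample_cap_to_grid()` places every thickness sample at
$(s, \theta) = (\text{axial}(f),\ \text{A-line angle} + \text{rot}(f))$
and takes bin means; the total binned count equals the number of samples,
a tested invariant.

## Risk fusion

Each bin with WSS coverage is classified by the two thresholds
(cap ≤ 151 µm is thin, WSS ≥ 1.7 Pa is high — both inclusivities
deliberate):

| cap \\ WSS    | < 1.7 Pa | ≥ 1.7 Pa |
|---------------|----------|----------|
| **> 151 µm**  | LOW      | MED_WSS  |
| **≤ 151 µm**  | MED_CAP  | HIGH     |

Bins without cap coverage are classified as if the cap were thick
(the WSS map covers the whole segment, the cap only the plaque) and
flagged; region fractions are reported both over all classified bins and
over cap-covered bins, since either denominator is defensible and they
answer different questions. The sensitivity analysis rebuilds the map for
the threshold grid {141, 151, 161} µm × {1.6, 1.7, 1.8} Pa — the printed
rounded lists, not a recomputed ±7 % which would give 140.4/161.6 — and
reports each region's minimum and maximum relative area change against
the central map.

## The phantom: what it emulates and what it does not

`phantom_config()` defines the synthetic study conditions: a 20 mm
segment of base radius 1.5 mm (axis ratio 0.9), a Gaussian stenosis of
depth 0.3 at mid-segment, side branches at 3 and 17 mm (daughter
diameters 2.2 and 1.8 mm), a cap over s ∈ [8, 13] mm and 140° of
circumference carrying a Gaussian-dip thickness field from 300 µm down to
120 µm, probe rotation drift of 0.5°/frame, 200 µm between frames, and
multiplicative speckle of amplitude 0.2 on a smooth radial intensity
template (dark lumen, bright wall band between the true interfaces,
attenuated signal beyond). These magnitudes sit inside the ranges
reported for mildly diseased coronary segments: plaques a few mm long
covering roughly a third of the circumference, caps of one to a few
hundred µm, per-frame twist well under a degree.

The OCT template makes no claim of physical speckle statistics, catheter
eccentricity, guide-wire shadows or ECG-phase motion; projections are
orthographic with sub-pixel transverse edge positions on the 76 µm pixel
grid (what observer tracing of such an image yields). Passing the
phantom round-trips therefore demonstrates that the algorithms recover
what their own forward models encode — contract correctness and
numerical accuracy — not clinical performance on patient data.

Ground truth is stored alongside the rendered data: per-frame interface
radii, per-frame rotation offsets, and the thickness field binned on the
cut-open grid. The binned truth is evaluated at the frame positions
falling inside each row (and subsampled over the angular bin), i.e. it is
the ideal binned measurement of that pullback, which is the right
reference for map-level comparisons.

## Numerical choices and degenerate inputs

* Constant cost images segment to the smallest-radius admissible path
  (ties toward smaller radius throughout); constant frames yield uniform
  cost 1 rather than an error.
* Identical luminal and abluminal contours give zero thickness and a
  `degenerate` flag; rays missing the abluminal polyline are excluded
  from summaries.
* Empty bins carry count 0 and are excluded from all statistics;
  normalisation refuses maps with a non-positive median.
* Silhouette gaps are interpolated with a warning; crossing silhouettes
  are an error.
* All randomness (speckle, site sampling) is seeded and restores the
  caller's RNG state; pipeline runs are bit-reproducible given a seed.
* Test problem sizes: unit tests run the phantom at 120 × 80 polar
  pixels, where interface recovery is still sub-pixel; the
  parameter-recovery checks use the full 968 × 504 raster. The
  finite-difference WSS oracle uses a 200 × 200 grid, where the boundary
  shear of the closed form agrees to well under 1 %.

## Known limitations

* Two views cannot identify the ellipse orientation; see the bound above.
  Severely non-elliptical (e.g. ruptured) lumens are outside the model.
* The duct surrogate is exact only for fully developed laminar flow in a
  straight duct of the local section; import real CFD samples where that
  matters.
* Rotational registration accuracy between the two branch anchors cannot
  be validated without additional landmarks; the phantom's linear-drift
  recovery is an artifact-level check of the interpolation machinery,
  not a clinical validation.
* Landmarks and the ROI arrive as annotation files; there is no automatic
  side-branch detection in either modality.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 7)
summary <- run_pipeline(cfg)
write_report(summary)   # report.txt + triptych report.png
```
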