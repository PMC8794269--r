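---
title: "Methods: wall shear estimation and fluorescence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall shear estimation and fluorescence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valveflow)
```

# Scope and assumptions

valveflow implements the quantitative core of a heart-valve
mechanobiology imaging workflow in the embryonic zebrafish: wall shear
stress at the atrioventricular canal (AVC) under two blood-rheology
regimes, an effective-viscosity model for nanoemulsion-laden plasma, image
registration for blood-cell tracking, and two families of fluorescence
quantifications. Blood is treated as Newtonian in both regimes — plasma
with a constant dynamic viscosity of 1.5 mPa·s, with red blood cells
entering only as discrete tracked tracers, never as a rheological phase.
No flow solver is involved anywhere: both shear estimators are
closed-form models evaluated on measured kinematic quantities.

# The two wall-shear regimes

## Two-phase: near-wall linear profile

For blood carrying red blood cells, each tracked cell that passes within a
cutoff distance of the wall yields a shear-rate sample

$$\dot\gamma = \frac{|v_t|}{d},$$

where $d$ is the distance from the cell center to the nearest wall point
and $v_t$ the component of the cell velocity tangential to the wall there.
This is the first-order Taylor expansion of any no-slip profile at the
wall; for true Poiseuille flow a cell at relative radius $\rho = 1 - d/R$
recovers the fraction $(1+\rho)/2$ of the analytic wall shear
$4Q/(\pi R^3)$, so the estimator is biased low by at most $d/(2R)$. The
default cutoff of $0.15\,R$ keeps this Taylor error below about 7.5%, and
the package's cross-validation bound of 15% leaves headroom for tracking
noise.

Three conventions here were genuinely open and are exposed as switches:

* **Tangential projection** (default) versus raw speed. Shear is defined
  by the tangential velocity gradient; wall-normal motion reflects wall
  movement, not shear. `projection = "magnitude"` restores the raw-speed
  convention.
* **Wall-relative velocity** (default on). The AVC wall itself moves over
  the cardiac cycle; cell velocities are taken relative to the velocity of
  the nearest wall point, estimated from the frame-to-frame motion of the
  matching contour vertices.
* **Per-frame aggregation**: the maximum over qualifying cells (the
  workflow reports maximal shear stress); the per-frame mean and count are
  carried alongside. Frames with no qualifying cell are explicit `NA`
  markers, never zeros — zeros would silently deflate aggregates.

## One-phase: volume-derived parabolic profile

Without red blood cells there is nothing to track, so the flow rate is
derived from ventricular volume as $Q = -\mathrm{d}V/\mathrm{d}t$ and wall
shear from a parabolic profile across the **maximum inscribed circle** of
the lumen cross-section:

$$\dot\gamma_{wall} = \frac{4\,|Q|}{\pi r^3}.$$

The inscribed circle is the largest circle fitting in the (generally
non-circular) cross-section; because $\dot\gamma \propto r^{-3}$, using its
radius gives a conservative *maximum* wall shear estimate. Volume traces
may be supplied directly or summed from per-slice lumen polygons
(area × slice spacing).

The derivative uses second-order central differences (one-sided at the
trace ends), chosen over spline fitting because its error bound is
provable: for a sinusoid sampled at 100 points per period the interior
error is below 0.1% of $A\omega$. The one-sided end estimates are only
first-order; comparisons against analytic ground truth therefore use
interior frames.

Unit bookkeeping: flows in nl/s and radii in µm convert internally
(1 nl = 10⁶ µm³) so shear rates are in s⁻¹; stresses are in Pa with
viscosity in mPa·s. `poiseuille_wall_shear()` exposes the raw
unit-coherent formula.

## Post-processing

Periodic traces are circularly shifted so a reference event (e.g. the
frame of widest lumen) lands at a target time — the convention used when
overlaying embryos is alignment at 125 ms — then smoothed with a centered
moving mean over ±2 frames (periodic boundary, so the cycle mean is
conserved exactly). Aggregates reported downstream are the maximum and the
95th percentile over the smoothed cycle. `compare_traces()` reports fold
changes (ratios of maxima and of 95th percentiles) with zero denominators
mapped to missing values, and makes no significance claim.

# Effective viscosity and the injection calculator

The Corcione correlation predicts the viscosity of a dilute nanoparticle
suspension relative to its base fluid from the particle diameter $d_p$,
the volume fraction $\varphi$, and an equivalent base-fluid molecule
diameter $d_f = 0.1\,(6M/(N\pi\rho_{f0}))^{1/3}$. For the plasma defaults
($M = 100$ kg/mol, $\rho_{f0} = 997$ kg/m³), $d_f \approx 6.83 \times
10^{-10}$ m. The correlation was fitted for $\varphi \in [10^{-4},
0.071]$ and $d_p \in [25, 200]$ nm; outside those ranges the package
warns rather than fails, because the plasma $d_p/d_f$ ratio itself sits at
the edge of the tested regime. Divergence of the closed form (denominator
≤ 0) is a hard error. Temperature is carried in `fluid_spec` for
provenance but unused: plasma viscosity is approximately constant over
rearing temperatures.

The injection calculator assumes complete mixing:
$\varphi = \varphi_{stock} \cdot V_{inj} / (V_{inj} + V_{blood})$ with
defaults 4.6 nl injected into 60 nl total blood, and reports the simple
dilution factor $V_{blood}/V_{inj} \approx 13$ that matches the bench
convention of diluting the stock 1:13 to mimic its circulating
concentration. The stock droplet volume fraction is deliberately **not**
defaulted: only the dye loading of the stock is known, so inventing a
droplet fraction would fabricate a parameter.

# Registration and tracking

Frame-to-frame motion is estimated by free-form deformation registration:
displacements live on a regular control grid (default spacing 5.6 µm)
interpolated with cubic B-splines, and the mean squared intensity
difference between the fixed frame and the warped moving frame is
minimized with L-BFGS-B (analytic gradient) over a 3-level
multi-resolution pyramid. Each pair is warm-started with half of the
previous pair's field, which smooths velocity estimates across frames; the
optimizer never returns a field worse than its initialization. Optimizer,
pyramid depth, iteration cap (100 per level) and convergence tolerance
(relative objective change < 10⁻⁵) are this package's decisions — the
original description names only the grid spacing, the metric and the
warm-start halving — and all are exposed as arguments. No smoothness
penalty is applied by default (grid coarseness is the only regularizer),
matching the pure mean-square metric; an optional quadratic penalty on
control-point differences is available.

Particles are segmented by intensity threshold and connected components
(EBImage), with a minimum area of 4 px² to reject single-pixel noise and
an optional maximum area to reject large bright structures such as vessel
walls. Track identity is maintained by nearest-neighbor linking between
each particle's warped position and the next frame's detections within a
gating radius (default 2 × grid spacing); identity maintenance is not part
of the original description, so this plumbing is deliberately simple and
gating failures terminate tracks rather than guess.

Accuracy floor: bilinear sampling of smooth images biases recovered
displacements by roughly 0.1 px, so relative velocity errors are smallest
when displacements are of order 1–3 px per frame. The validation suite
verifies recovery of a pure (2.0, −1.5) px translation within 0.25 px and
a smooth one-bump warp with median endpoint error below 0.5 px on
256² textured pairs, and per-particle velocity errors below 10% away from
the wall on rendered tube movies.

# Dot-density statistic

The single-molecule FISH quantification is an intensity budget defined by
four formulas: a background level per unit area from a signal-free
reference region; a mean background-corrected integrated intensity per dot
over isolated reference dots (protocol: 20; the package generalizes to
any $n \geq 1$ and records $n$); a region count
$(I_{ROI} - B \cdot A_{ROI})/\bar I_{dot}$; and a density count/area.
Negative counts near zero are measurement error and are passed through
unmodified — clamping them would bias region averages upward.

Pixel membership uses pixel-center containment with a half-open boundary
rule (left/top edges in, right/bottom out): deterministic and exactly
additive over polygon tilings, so splitting a region never changes the
total count. Reference-dot selection is the caller's responsibility
(`find_candidate_dots()` merely suggests isolated maxima). Multi-slice
quantification sums measurements over the slices (protocol: the mid-valve
slice ± 1) rather than averaging, keeping counts additive — identical
slices give exactly 3× the single-slice count; per-slice results are also
emitted so the averaging convention remains recoverable.

# Intensity ratios and the rank test

Junctional contrast is the across-interface average of a per-interface
statistic (mean or max intensity along the annotated interface polyline)
for one cell population divided by the same average for another.
Apical–basal polarity is the ratio-of-ratios
$(\sum G_{ap}/\sum R_{ap}) / (\sum G_{ba}/\sum R_{ba})$ with sums over
z-slices, which cancels the gain of each channel independently. Membrane
segments are caller-annotated (segmentation was manual in the source
workflow); intensities are sampled at fixed 1 px arc-length spacing with
bilinear interpolation, so measurements are deterministic and
resolution-independent. Values below zero are not clipped; degenerate
denominators (zero red signal) error out rather than silently
regularizing.

Per-embryo ratios are compared against the theoretical value 1 with a
one-sample Wilcoxon **signed-rank** test (exact null distribution for
n ≤ 25 without ties, normal approximation otherwise, two-sided). The
source workflow names the rank-sum test for this comparison, but a
rank-sum test requires two samples; the signed-rank test is the coherent
one-sample analogue. The test uses additive differences `values − 1` by
default; a `log` switch handles multiplicative symmetry, since a sample
symmetric about 1 on the log scale (e.g. pairs {0.5, 2}) is *not*
symmetric about 1 additively.

# Synthetic data: what it does and does not emulate

The generators provide every input with analytic ground truth:

* `generate_tube_movie()`: a straight 2D tube (default radius 25 µm)
  with sinusoidal Poiseuille flow (peak 1 nl/s, period 0.5 s, 100
  frames/cycle — an AVC-scale scenario with peak axial velocity around
  1 mm/s), 150 tracers of 2 µm radius held at fixed relative radial
  position, wrapping periodically so the tracer count is conserved.
  Ground truth carries exact tracer velocities, the analytic wall shear
  $4|Q|/(\pi R^3)$, and a consistent ventricular volume trace.
* `generate_volume_trace()`: $V = V_0 + A\sin(\omega t)$ with the exact
  $Q = -A\omega\cos(\omega t)$.
* `generate_spot_image()`: uniform background plus isolated Gaussian dots
  (placement by bounded rejection sampling, ≥ 3σ from ROI boundaries,
  ≥ 6σ apart) with a ledger of analytic per-dot intensities
  ($a \cdot 2\pi\sigma^2$) and effective areas.
* `generate_polarity_image()`: a row of rectangular cells with annotated
  apical/basal/interface membranes carrying planted channel intensities,
  drawn so noise-free sampling recovers the planted values exactly.

Noise is additive Gaussian with constant variance — the simplest model
sufficient to test robustness; the imaging noise of the real spinning-disk
data is uncharacterized, so fixture noise levels are free parameters, not
calibrations. The generators do not emulate photorealistic cardiac
imagery, 3D geometry, red-blood-cell deformation, or structured
backgrounds. Passing tests therefore demonstrate correctness of the
estimators under their stated assumptions, not robustness to every
pathology of in vivo movies; in particular the in vivo fold-change between
the two blood regimes is not reproducible from synthetic data and is not
claimed.

All generators are pure functions of their parameters and one integer
seed, leaving the caller's RNG state untouched; identical seeds give
bit-identical outputs, including written TIFF stacks.

# Numerical choices

* **Maximum inscribed circle**: grid search at the user's resolution
  seeds a shrinking-grid descent (5×5 neighborhood, step halved to 10⁻⁷)
  on the distance-to-boundary function. Simplex refinement was rejected:
  the min-over-edges surface has plateaus on which Nelder-Mead stalls at
  its starting point. The result is exact to refinement tolerance on the
  unit square and recovers the inradius $r\cos(\pi/n)$ of regular
  $n$-gons.
* **Smoothing** uses `stats::filter` with circular boundary; degenerate
  traces with missing frames are periodic-linearly interpolated first (or
  rejected, by option).
* **Quantile convention**: the 95th percentile uses R's default type-7
  quantile.
* **Tie-breaks** in pixel containment follow the half-open rule above;
  nearest-wall ties resolve to the first polyline segment encountered.

# Problem sizes

The validation suite runs on deliberately desk-scale problems: 200-frame
scenarios with 150 tracers for the shear cross-validation, 256² images for
registration, 50 seeded 360×330 px spot fixtures for dot recovery, and
110-frame rendered movies (subsets tracked) for the tracker. These sizes
were chosen so the full suite and the acceptance script each complete in a
few minutes on one CPU while leaving every estimator's error regime
clearly resolvable.

# Known limitations

* The two-phase estimator's low bias of up to $d/(2R)$ is inherent to the
  linear profile; it is documented rather than corrected, matching the
  original estimator.
* The registration tracker assumes mostly smooth motion fields; crossing
  particles within one grid cell violate the model and are handled only by
  track termination.
* The Corcione correlation is an extrapolation for particles outside
  25–200 nm or loadings outside $[10^{-4}, 0.071]$; the package warns but
  does not refuse.
* Rheometer measurements of nanoemulsion-spiked buffer are instrument
  data, not model outputs; the package computes the model pathway and the
  dilution arithmetic but does not attempt to reconcile the two.
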