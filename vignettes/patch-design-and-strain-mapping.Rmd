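---
title: "Heart-rate-matched patch design and LV segmental strain mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-matched patch design and LV segmental strain mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelstrain)
```

This vignette is the package's account of its science: the models it
implements, the assumptions and tunable parameters behind them, the
numerical choices that matter, and what its synthetic-data validation does
and does not establish about real data.

## 1. The viscoelastic material model

The patch material is a network of gelatin chains crosslinked by two kinds
of dynamic boronate ester bonds — a plain phenylboronic acid (PBA, fast
exchange) and its fluorinated analogue (FPBA, slow exchange) bound to
catechol groups. Bond exchange makes the network a viscoelastic liquid at
long times, which `gelstrain` represents as a generalized Maxwell
(Prony-series) solid without an equilibrium branch:

$$G(t) = \sum_i G_i e^{-t/\tau_i}, \qquad
  G'(\omega) = \sum_i G_i \frac{(\omega\tau_i)^2}{1 + (\omega\tau_i)^2},
  \qquad
  G''(\omega) = \sum_i G_i \frac{\omega\tau_i}{1 + (\omega\tau_i)^2}.$$

Assumptions: linear response (the calibrating experiments are 1 % strain
sweeps inside the linear regime), isothermal behaviour, and full stress
relaxation at long times (no permanent crosslinks). Nonlinear phenomena —
shear-thinning during injection, self-healing after large strain — are
deliberately outside the model.

Frequencies are user-facing in Hz everywhere; the angular frequency
$\omega = 2\pi f$ appears only inside formulas, because rheometer
protocols and heart rates are reported in Hz.

### The gel point

The *gel point* $(f_{GP}, G'_{GP})$ is the frequency at which $G' = G''$
and the common modulus there. It splits the frequency axis into a viscous
regime (the patch flows, relaxing prestress) and an elastic regime (the
patch carries load). A patch is *heart-rate matched* when $f_{GP}$ sits at
the heart rate: loading at each beat is carried elastically while slower
stresses relax away.

`find_gel_point()` locates the crossover of a sampled sweep by linear
interpolation of $\log(G'/G'')$ against $\log f$ between the two samples
bracketing the sign change — the natural local model for log-spaced sweep
data — and reports the common value of the two log–log interpolants there.
Numerical consequences worth knowing:

* For a single-mode material $\log(G'/G'') = \log(\omega\tau)$ is exactly
  linear in $\log f$, so the frequency is recovered exactly at any
  sampling density; the *modulus* interpolation error is second order in
  the log-spacing (about 1.6 % at 40 points over 2.6 decades, below
  $10^{-6}$ relative at a few thousand points).
* A sweep with no sign change raises a typed `NoCrossover` error; more
  than one sign change raises `MultipleCrossovers` listing every bracket.
  The second case is an error rather than a silent pick because a genuine
  multi-crossover material is qualitatively different, and because noise
  can flip the sign near the crossover — a user seeing the error can
  smooth, refit, or densify rather than trust an arbitrary root. Percent-
  level multiplicative noise on coarse sweeps *will* occasionally trigger
  it; that is intended diagnosability, not a bug.

### Relaxation fitting

`fit_relaxation()` fits $\sum_i G_i e^{-t/\tau_i}$ (default two modes,
matching the two bond populations) by Levenberg–Marquardt least squares on
the log of every parameter, which enforces positivity without explicit
bounds. Exponential-sum fitting is initialization-sensitive; the default
initialization — relaxation times log-spaced over the observed time
window, weights equal at $G(0)/n$ — proved robust across the seeded
replicate suites. Non-decaying input (least-squares slope indistinguishable
from zero at $10^{-9}$ relative) is refused as `DegenerateRelaxation`.

The reported *characteristic relaxation time* is the weight-averaged
$\sum G_i\tau_i / \sum G_i$. This is a package decision: for a multi-mode
fit there is no single canonical "relaxation time", and the weighted mean
is the zero-shear-viscosity-consistent choice
($\eta_0 = \sum G_i \tau_i = G_0 \cdot \tau_{char}$).

### Stress under arbitrary strain histories

`simulate_stress()` evaluates the Boltzmann superposition integral
$\sigma(t) = \int_0^t G(t-s)\,\dot\varepsilon(s)\,ds$ for strain histories
piecewise linear between samples. Because the integral has a closed form
on each linear segment, the per-mode state is advanced by an exact
exponential recursion (with `expm1` for numerically huge $\tau$) — there
is no quadrature error, and linearity in the strain history holds to
rounding. The first sample is treated as an instantaneous step from zero
strain so that a constant history reproduces step-strain relaxation
$\varepsilon_0 G(t)$. `cycles_to_convergence()` reports the first cycle
from which the per-cycle peak stress stays within a relative tolerance of
its predecessor — the "prestress convergence" behaviour of a pre-stretched
patch under cyclic loading — and flags series that never settle.

## 2. Formulation design

### The calibration

Two experimental facts make recipe design tractable: the gel-point
*frequency* is controlled by the FPBA:PBA ratio (pure PBA crosslinking
gels at about 6 Hz, pure FPBA at 0.3 Hz) and the gel-point *modulus* is
controlled independently by the gelatin weight fraction (1.3 kPa at
15 wt%, 2.5 kPa at 20 wt%, tunable over 0.5–2.5 kPa). The default
calibration stores exactly these measured knots, plus the two selected
species design points (rat: 15 wt%, fraction 0.2, 4 Hz / 1.3 kPa; pig:
20 wt%, fraction 0.6, 1.3 Hz / 2.5 kPa). The "~6 Hz" endpoint is treated
as exactly 6.0 Hz, with the approximation recorded in the calibration's
`notes`.

`predict_gel_point()` interpolates $\log f_{GP}$ against the FPBA fraction
with a monotone piecewise-cubic (Fritsch–Carlson) spline — with only four
measured knots, monotonicity and knot exactness are the properties worth
guaranteeing, and log-frequency is the scale on which the knots are close
to evenly curved — and the modulus linearly between its two knots.
Requests outside the knot hull are clamped with a typed warning, or
refused in strict mode: the calibration has no information out there.

### From recipe to Maxwell spectrum

`formulation_to_modes()` builds a spectrum whose analytic crossover equals
the calibrated prediction. Design reasoning, because this was genuinely
open:

* An obvious construction fixes the two mode times from the printed
  pure-component crossovers ($\tau = 1/2\pi f$ at 6 and 0.3 Hz, time
  ratio 20) and solves the weight split. It fails structurally: $G'$ and
  $G''$ are linear in the weight, so the solve is unique, and a two-mode
  Maxwell model with time ratio 20 has a *fold* — for weights near
  0.18–0.19 the loss tangent crosses unity three times, and the
  achievable single-crossover frequencies skip a band that contains the
  porcine target (1.3 Hz). Interior design points simply cannot be
  realized that way as a unique gel point.
* The implemented construction instead lets the mode weights follow the
  recipe — the slow mode carries the FPBA fraction — keeps the two times
  at a fixed 10:1 separation, and solves a *common time scale* by 1-D
  root finding so the crossover lands on the calibrated frequency, then
  scales the stiffness to the calibrated modulus. A numerical scan shows
  a two-mode model keeps a unique crossover at every weight for time
  ratios up to about 12; 10 is the largest round ratio safely inside
  that regime while still giving the modes clearly distinct kinetics.
  At the pure endpoints the construction degenerates to a single mode
  with exactly the printed crossover time.

The round-trip property — sample the constructed spectrum, run the
crossover finder, recover the calibrated prediction to $10^{-4}$ relative
or better — is tested on the two design points and on 50 seeded random
in-hull recipes.

### The matcher

The theoretical model that maps myocardial stiffness and wall/graft
thickness to an optimal gel point is published elsewhere and not
reproduced here; inventing a formula would misattribute precision.
`match_formulation()` therefore performs a species-keyed lookup over the
calibration's measured design points, falling back to the design point
log-nearest to the requested heart-rate band midpoint for unlisted
species, and verifies achievability: a band outside 0.3–6 Hz raises
`UnachievableFrequency`, a target modulus outside 0.5–2.5 kPa raises
`UnachievableModulus`. The heart's stiffness and thicknesses are carried
in the result for documentation. Callers who want a continuous inversion
of the calibration can do it directly with `predict_gel_point()` over a
candidate grid (the `candidates` argument automates exactly that).

## 3. Segmental strain mapping

### Geometry and conventions

The analyzer consumes per-frame closed wall contours (mm). Each contour is
resampled to 360 equally spaced arc-length points (stabilizing the ray
geometry), oriented counterclockwise, and cut into 24 equal angular
sectors — the classic 6-segment short-axis scheme with each segment split
in four — about the *reference-frame* centroid. Conventions: segment 0
starts at `reference_angle`, angles increase counterclockwise, boundary
$k$ sits between segments $k$ and $k+1$ (mod 24), and all indices are
0-based to match the on-disk CSV dialect.

Segments are *Eulerian* angular bins — rays fixed in space about the
end-diastolic centroid — not material-tracked tissue segments. This is an
interpretation: equal-part angular subdivision is what the 24-segment
scheme describes, it needs no speckle tracking, and it makes phantom
ground truth well defined. The cost is that wall material moves through
bins during contraction, a bias shared by the ground-truth definition.

Sector cutting splits each polyline edge exactly where it crosses a
boundary ray (line–ray intersection) and assigns each piece to the sector
containing its midpoint, so the 24 lengths sum to the resampled perimeter
to rounding error on every frame — a conservation law the test suite
asserts at $10^{-9}$ relative. The contour must be star-shaped about the
centroid up to sub-sector jitter: it must wind exactly once
counterclockwise, and its angular coordinate may never fall more than one
sector width (15°) behind its running maximum. The slack tolerates the
small angular backtracks that point noise causes on fine contours while
still rejecting genuinely non-star walls, where a ray would cut the wall
more than once and "the segment between two rays" stops being meaningful.
Noise above roughly 6 % of the ring radius exceeds the slack and is
refused rather than silently mis-segmented.

When endocardial and epicardial contours are both supplied, the analyzed
line is their point-wise midpoint after arc-length resampling (aligned by
angle about the shared centroid); whether a mid-wall, endocardial or
epicardial line best matches any particular echo workflow is unknowable
from the data, so mid-wall is the documented default and single contours
are used as given.

### Strain and differential

With $l_{ref}$ the segment lengths at end-diastole (maximal-area frame,
ties to the earliest) and $l$ the lengths in any frame,

$$\varepsilon_{cc} = \frac{l - l_{ref}}{l_{ref}} \times 100\,\%,
  \qquad
  \Delta\varepsilon_{cc}[k] = \left|\varepsilon_{cc}[k] -
  \varepsilon_{cc}[(k{+}1) \bmod 24]\right|.$$

Negative strain is contraction; a noncontractile infarct shows
$\varepsilon_{cc} \ge 0$ (passive stretch). $\Delta\varepsilon_{cc}$ is a
proxy for the circumferential strain gradient; its maximum over boundaries
and frames (`max_peak_strain_differential()`) is largest at the infarct
border, which is how the analysis localizes the border without any image
segmentation. Strain is reported for every frame, with the minimal-area
frame exposed as end-systole for convenience.

The quantification helpers implement the corresponding scalar formulas:
TUNEL-positive fraction (positives/total × 100), infarct percentage
(fibrotic/total wall circumference × 100), and minimum wall thickness as
the minimum vertex-to-polyline distance from the epicardial to the
endocardial contour after 360-point resampling — vertex-to-polyline rather
than ray-based because it stays well defined for non-convex walls.

## 4. The synthetic generators

All generators are pure functions of their parameters and a seed (local
RNG state, never the caller's).

* `generate_sweep()` / `generate_relaxation_curve()` evaluate the analytic
  moduli and apply *multiplicative lognormal* noise of a given CV —
  moduli are positive and rheometer error scales with signal. The
  relaxation default records 2000 points over 50 s (a 40 Hz acquisition):
  at that density a sub-second fast mode remains statistically
  identifiable under 1 % noise, whereas at 10 Hz sampling no estimator
  recovers it reliably to 5 % — the replicated recovery suite
  (both times within 5 % in ≥ 95 of 100 seeded 1 %-noise replicates) is
  run under the 40 Hz condition.
* `generate_lv_cycle()` builds a mid-wall ring
  $r(\theta, t) = R\,(1 + \varepsilon(\theta)\,s(t)/100)$ with a
  raised-cosine systolic pulse $s(t)$ (0 at end-diastole, 1 at
  end-systole; even frame counts sample the peak exactly) and a strain
  field $\varepsilon(\theta)$ equal to the infarct value inside the arc,
  the healthy value outside, cosine-smoothed over the transition width.
  Additive isotropic Gaussian noise perturbs every point. Defaults are
  rat-scaled (R = 3.5 mm, healthy peak −20 %, infarct +5 %, 90° arc
  centred at 90°, 15° transitions, 180 contour points, 0.25 s period);
  a pig preset scales to R = 25 mm and 0.8 s. Imposing strain on the
  radius makes the per-sector circumferential strain analytic, which is
  the point of the phantom.

Ground truth per segment is computed by independent dense quadrature
(100 000-point polyline) of the continuous wall at end-diastole and peak
systole. Two discretization facts shape the recovery tests:

* With a *sharp* border (zero transition width) the wall has a radial step
  at each infarct edge. The step sits exactly on a sector boundary, the
  analyzer splits its length between the two adjacent segments, and the
  differential at the border is dominated by the step length rather than
  by the strain contrast. Border localization ("argmax within one
  boundary of a true border in ≥ 95 of 100 noisy replicates") is
  unaffected; per-segment strain values *at the border segments* are not
  comparable to truth in that regime.
* With the smooth default transition, analyzer-vs-truth disagreement is
  pure discretization and falls with contour density; the
  self-consistency test (all segments within 1 % of the healthy strain
  scale) is run with 720-point noiseless contours.

A three-rung noise ladder (0, 0.05, 0.15 mm on the rat phantom; 0, 1 %,
10 % CV on relaxation curves) checks that mean recovery error grows
monotonically with noise.

### What passing these tests does not show

The phantom is a single 2-D mid-wall ring with purely radial motion: no
through-plane motion, no rotation/torsion, no speckle decorrelation, no
contour-extraction error model (real contours come from a recognition
program plus manual correction), no papillary anatomy, and noise that is
white rather than spatially correlated. Passing the recovery suites shows
the *geometry and algebra* of the pipeline are right and characterizes
its noise sensitivity — it does not validate echocardiographic strain
against sonomicrometry, and measured strains on real cines inherit every
upstream imaging limitation.

## 5. Problem sizes and runtime

The replicated suites use desk-scale sizes chosen to characterize the
estimators well: 100 seeded replicates for relaxation recovery (2000-point
curves) and border localization (12-frame, 180-point cines at 1 % noise),
50 random recipes for the calibration round trip, 20 seeded instances per
brute-force oracle, and $10^5$-point quadrature for phantom truth. The
full suite runs in well under a minute on a single core.

## 6. Known limitations

* The calibration rests on four frequency knots and two modulus knots;
  between knots it is a smoothness assumption, and outside them it
  refuses to extrapolate.
* The matcher cannot interpolate new species mechanically — it reuses
  measured design points rather than the unpublished mechanical model
  that generated them.
* The two-mode spectrum construction is one of many spectra consistent
  with a gel point; only crossover-level behaviour (not, e.g., the full
  relaxation spectrum of a real gel) should be read from it.
* Segments are angular bins about a fixed centroid; strongly translated
  or torsing ventricles mix material between bins, and contours must stay
  star-shaped about the end-diastolic centroid.
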