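---
title: "Estimating inertial properties from calibrated CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating inertial properties from calibrated CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the models implemented in **inertiaCT**, the
assumptions behind them, and the numerical and design choices that shape the
package.  The workflow turns a CT scan of a specimen into a voxel-level mass
model from which centre of mass (CoM), the inertia tensor and derived
summaries follow, and it implements the trifilar-pendulum measurement model
conventionally used to validate CT-derived moments of inertia (MoI).

## 1. From grey-values to density

A CT volume assigns each voxel an intensity that is, for biological
material, close to linear in the mean mass density of the material inside
the voxel.  Two routes to density are provided:

* **The basic Hounsfield route.** Scanner units are often Hounsfield units
  (HU), defined from attenuation coefficients as
  $\mathrm{HU} = 1000\,(\mu_{\mathrm{voxel}} - \mu_{\mathrm{water}}) /
  \mu_{\mathrm{water}}$, so water is 0 HU and air is −1000 HU.  The basic
  map $\rho = \mathrm{HU} + 1000$ (kg m⁻³) anchors water at 1000 and air at
  0 and is adequate near water density (`hounsfield_from_attenuation()`,
  `density_from_hu()`).
* **The phantom calibration route** (the quantitative one).  Tissue
  characterisation phantom rods of certified density — the laboratory set
  spans 450–1820 kg m⁻³ — are scanned beside the specimen.  Each rod is
  sampled through manually drawn ellipses at its 25/50/75 % planes
  (`roi_ellipse()`, `sample_phantom()`), a region of air is sampled the
  same way, and ordinary least squares of known density on mean grey-value
  gives a per-scan line $\rho = a\,G + b$ (`fit_calibration()`).

Design choices worth stating:

* **Regression direction.** Density is regressed on grey-value, matching
  how the calibration is applied (grey is the measurement; density the
  prediction).
* **Air as a true data point.** The air sample enters at 1.2 kg m⁻³ (room
  conditions) rather than 0.  The difference is negligible against the rod
  densities but it is the physically correct value.
* **Unweighted fit.** All samples carry equal weight; there is no
  principled basis for weighting rods differently.
* **Pooled plane means.** Voxels from the three sampling planes are pooled
  into one mean per rod rather than averaged per plane first.  For the
  near-circular ROIs used here the two differ only in the third decimal of
  the rod mean.
* **Strict voxel-center membership.** A voxel belongs to an ROI only when
  its center is strictly inside the ellipse, which keeps partial-volume
  voxels at the rod boundary out of the phantom means.
* **Per-scan calibration.** Calibration lines differ between scans (field
  of view, scanner state), so a calibration is never reused across scans;
  `write_calibration()` embeds the samples so a stored calibration can be
  refit and verified on read.

## 2. Mass-matched segmentation

Thresholding separates specimen from air, but the "right" threshold is not
obvious from the histogram: feathers and other thin structures live in
voxels whose density is a weighted average with air.  The package follows
the mass-matching principle: choose the threshold so the calibrated mass
estimate (sum of retained voxel masses) equals the specimen mass measured
on a balance (`optimise_threshold()`).

Retained voxel masses are non-negative (negative calibrated densities —
noise below the air line — are clamped to zero with a logged count), so
estimated mass is a non-increasing step function of the threshold and a
deterministic bisection converges on the unique crossing.  Details:

* The candidate levels are either integer grey levels (scanner output
  units; the default) or every distinct grey-value in the bracket
  (`integer_levels = FALSE`; what `run_pipeline()` uses, since a slightly
  imperfect calibration is compensated by cutting fractionally into the
  tissue tail, where integer steps can be coarser than the 0.1 g
  tolerance).
* The default mass tolerance is 0.1 g — the resolution of the laboratory
  balance; a tighter tolerance would chase noise the balance could not
  confirm.
* The bisection probes the bracket midpoint first, so re-running the
  search centred on its own solution returns that solution; bracket
  endpoints become candidates only if the interval collapses, and ties
  resolve to the lower threshold.
* If a non-monotone mass curve is ever detected (possible only with exotic
  calibrations), the search falls back to a full scan over candidate
  levels with a warning.
* Scanner fixtures and the mounting board are removed by a user-supplied
  exclusion mask; there is no automatic fixture detection.

Anatomical partitioning ("virtual dissection") is by an integer label
volume aligned with the scan; `virtual_dissect()` reports per-segment
masses, with label 0 reported as `unassigned` rather than silently merged.

## 3. Voxel mass models and inertial analytics

Every retained voxel becomes a point mass $m_i = \rho_i\,v$ at its center
(`build_mass_model()`).  Centers, not corners, carry the mass: center
sampling makes the discretized volume integrals second-order accurate in
the voxel pitch.  All analytics are in SI (kg, m, kg m²); millimetres exist
only at the I/O boundary.

* CoM is the mass-weighted mean position.
* The inertia tensor about an origin has diagonal
  $I_{xx} = \sum_i m_i (y_i^2 + z_i^2)$ (and cyclic) and off-diagonal
  entries stored as $I_{xy} = -\sum_i m_i x_i y_i$ (and cyclic).  This is
  the convention for which $\mathbf{L} = I\boldsymbol{\omega}$; note that
  some biomechanics tables list the *positive* products of inertia
  $+\sum m x y$, which are the negatives of these tensor entries.
* Principal moments and axes come from the eigendecomposition of the
  symmetric tensor.  Moments are sorted ascending; each axis is sign-fixed
  so its largest-magnitude component is positive, and the third axis is
  flipped if needed to make the frame right-handed.  For (near-)degenerate
  moments the axes within the degenerate eigenspace are an arbitrary
  orthonormal pair, and only the moments are contractual.
* The anatomical roll/pitch/yaw assignment of principal axes is a user
  decision.  Automatic anatomical labelling from scan orientation is
  unreliable, so the dorsoventral direction is instead derived from the
  mounting board: a total-least-squares plane fit to board points
  (`fit_board_plane()`, smallest singular vector of the centered points)
  gives the board normal, oriented toward the specimen's CoM side.
* `translate_tensor()` implements the parallel-axis theorem
  $I' = I + m(\lVert d\rVert^2\,\mathrm{Id} - d d^{\mathsf T})$ exactly;
  `moi_about_axis()` is the contraction $n^{\mathsf T} I n$ computed
  directly as $\sum m_i d_i^2$.

**Compensated summation.** All mass and moment accumulations use Neumaier
summation (a small C++ kernel).  This is what lets conservation identities
— segment masses summing to the total, projection maps and spanwise
profiles summing to their parent quantities — hold at 10⁻¹² relative
rather than drifting with voxel count.

**Uniform-density comparison.** `uniform_density_comparison()` re-runs the
pipeline with every retained voxel assigned `total_mass / n_voxels`,
preserving total mass exactly.  Because tissue is denser near the body core
and feathers dominate the periphery, the uniform assumption moves mass
outward and systematically inflates MoI about central axes; the package
asserts the direction of this bias on constructed scenes and reports its
magnitude for the default synthetic specimen in the acceptance script.

## 4. Spatially resolved summaries

* `project_quantity()` collapses one world axis and accumulates voxel mass
  (or $m_i d_i^2$ about a reference axis) into a uniform planar grid.
  Binning is by voxel center with no kernel spreading, so totals are
  conserved exactly; the normalised map (divided by its maximum) is kept
  alongside the raw map, which is what gets serialized.  The default cell
  size in the pipeline is 5 mm — coarse enough to read as a map, fine
  enough to resolve wing structure; it is purely presentational and does
  not affect any totals.
* `segment_fraction_table()` reports each segment's fraction of mass and
  of MoI about the *shared whole-body* roll/pitch/yaw axes (not per-segment
  CoM axes); every column sums to 1 by construction.
* `spanwise_profile()` bins roll-MoI contributions by signed span
  coordinate normalised by the semispan (the maximum |span coordinate| of
  retained material), so bins cover [−1, 1] referred to the body
  centreline supplied by the user.

## 5. The trifilar pendulum measurement model

A trifilar pendulum — a platform hung on three parallel threads of length
$L$ at radius $R$ — measures MoI through its torsional period.  For small
angles the system is a one-degree-of-freedom oscillator with
$$I = \frac{m g R^2 \tau^2}{4 \pi^2 L}.$$

The observable is angular velocity from a gyroscope (sampled at 70 Hz in
the reference setup), so the damped-oscillator model is fitted in velocity
form,
$$\dot x(t) = X e^{-\zeta \omega_n t}\left[\omega_d \cos(\omega_d t + \phi)
  - \zeta \omega_n \sin(\omega_d t + \phi)\right],
  \qquad \omega_d = \omega_n \sqrt{1 - \zeta^2},$$
by Levenberg–Marquardt least squares on the trailing window of the trace
(default: last 60 s of a roughly 2–3 min recording), skipping the startup
transient.  Initial guesses: $\omega_d$ from the discrete spectrum peak
refined by parabolic interpolation (a raw FFT bin is too coarse — its
frequency error alone drifts the phase by radians across a 60 s window);
$\zeta$ from the log-decrement of successive extrema; amplitude and phase
from the first fitted cycle, with a four-point phase multi-start because a
quarter-turn phase error can strand the optimizer at the degenerate
zero-amplitude solution.  Amplitude and phase are reported relative to the
window start.  The period is $\tau = 2\pi/\omega_d$, and repeated
measurements aggregate as an unweighted mean (`period_estimate()`).

When the specimen's CoM misses the rig's rotation axis by an offset $D$,
the combined system still rotates about the rig axis (the threads enforce
this at small angles, and the platform — hence the combined CoM — rises
identically wherever the mass sits), so the measured MoI contains a
parallel-axis term.  The corrected specimen MoI is
$$I_{\mathrm{dv}} = \frac{(m_b + m_p)\, g R^2 \tau^2}{4\pi^2 L}
  - I_p - m_b D^2,$$
which at $D = 0$ reduces exactly to the plain difference between the
loaded and unloaded pendulum (`specimen_moi_corrected()`).  Machined
blocks with closed-form MoI (`analytic_block_moi()`) are the physical
oracle for this chain.

**The ODE oracle.** For testing, `simulate_pendulum_trace()` integrates
the *exact* trifilar equation of motion — restoring torque
$-M g R^2 \sin\theta / \sqrt{L^2 - 2R^2(1 - \cos\theta)}$ from the thread
geometry, plus linear viscous damping — with a high-order adaptive
integrator (tolerances 10⁻¹⁰), not the small-angle approximation.  The
small-angle error of the measurement formula is therefore *measured*: the
test suite shows the round-trip error at 2° amplitude is well inside 0.5 %
and grows with amplitude.  Also measurable is the damping bias: fitting
$\omega_d$ but using $\tau = 2\pi/\omega_d$ in the undamped formula biases
$I$ by the factor $1/(1-\zeta^2)$, i.e. 0.01 % at $\zeta = 0.01$ —
negligible against the other error sources.

Not modelled: thread mass and elasticity (nylon line is assumed massless
and inextensible) and large-angle MoI estimation.

## 6. The synthetic-scene generator

Real scans of specimens are large and not redistributable, so the package
carries a generator (`scene_spec()`, `rasterize_scene()`) that builds
CT-like volumes from density-defined solids — cuboids/plates, spheres,
cylinders, ellipsoids, with arbitrary rotations — and returns, alongside
the volume, an *analytic* ground truth (masses, CoMs, CoM tensors composed
by rotation and parallel axis, never from voxels) plus center-sampled
voxel bookkeeping (the discretized truth a perfect pipeline run can match
exactly).  Grey-values come from inverting a known calibration line, with
seeded Gaussian noise; all generators are seed-deterministic.

The default bird-like scene (`make_bird_like_scene()`) emulates a
barn-owl-scale raptor pinned wings-outstretched to a board: an ellipsoid
torso (1000 kg m⁻³), a sphere head (1050), thin distal wing plates (350 —
a feather/bone average), leg cylinders (1100) and a tail plate (250),
mirror-symmetric about the mid-sagittal plane, total mass ≈ 0.33 kg.  The
thin distal wing plates are the scientifically load-bearing feature: they
make the wings' share of roll MoI far exceed their share of mass, which is
the defining property of avian mass distribution that the spatial
summaries must resolve.  Voxel pitch defaults to 1 mm isotropic — the
scale of the reference scanner (sub-millimetre in-plane pixels, 1.25 mm
slices) and commensurate with the scene's plate boundaries, keeping
center-sampling discretization error well below the 1 % analytic
comparison tolerances.  Phantom rods (`make_phantom_rods()`) are laid on a
ring with ellipse ROIs generated at the 25/50/75 % planes, strictly inside
each rod.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: partial-volume averaging at material boundaries
(voxels are center-sampled, not anti-aliased, so the feather-edge regime
where a voxel blends air and keratin is absent), beam hardening, scatter,
detector noise correlations, and any nonlinearity between density and
grey-value.  On real scans those effects are exactly why the mass-matched
threshold and per-scan calibration exist, and why validation against a
balance and a pendulum remains good practice.

## 7. Numerical notes and test design

* **Discretization error.** For grid-aligned cuboids, center sampling is
  exact in mass and second-order in moments (the per-cell second-moment
  deficit $h^2/12$).  For curved boundaries the error has a clean
  second-order systematic part plus a lattice-phase fluctuation that
  decays *slower* than $h^2$ pointwise (the Gauss-circle phenomenon); for
  a lattice-aligned cylinder every slice shares the same phase, so the
  fluctuation does not self-average.  The convergence checks therefore use
  generic (off-lattice) placements and tilt the test cylinder a few
  degrees so its cross-section phase decorrelates along the axis —
  restoring visibly second-order behaviour — rather than testing a
  resonant alignment that no physical specimen would exhibit.
* **Problem sizes.** The default test scene is 220×420×80 voxels (≈ 7.4 M);
  primitive-oracle checks run at 64³-equivalent and 128³-equivalent
  resolution; pendulum traces are 120 s at 70 Hz.  These sizes keep the
  full suite at a few minutes on one CPU while leaving discretization and
  fit errors an order of magnitude below the tolerances they are tested
  against.
* **Degenerate inputs** are contracts, not accidents: empty masks, empty
  ROIs, all-equal phantom greys, collinear board points, zero semispan,
  targets outside the achievable mass range, and over-amplitude pendulum
  starts all raise typed errors naming the offending quantity.

## 8. Known limitations

* Density (as opposed to mass) in partial-volume voxels is a weighted
  average with air; per-voxel density maps of feathered structures are
  therefore not quantitative even when total and segment masses are.
* One scan, one pose: there is no articulated re-posing; wings-extended
  and wings-retracted are separate scans (and separate synthetic scenes).
* The DICOM reader covers uncompressed single-frame little-endian series
  only, and treats the slice direction as the first array axis without
  full patient-frame orientation handling.
* Calibration is linear by design; materials far outside the phantom range
  (dense cortical bone, metal) extrapolate on the fitted line.
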