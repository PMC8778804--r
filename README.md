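# inertiaCT

Three-dimensional centre of mass (CoM), inertia tensors and principal axes
of scanned specimens from **calibrated computed tomography**, with the
trifilar-pendulum measurement model used to validate CT-derived moments of
inertia (MoI).

Measuring body and segment inertial parameters traditionally requires
destructive dissection, suspension rigs, or crude uniform-density shape
models. Calibrated CT instead resolves mass at the level of individual
voxels: phantom rods of known density scanned beside the specimen give a
per-scan linear map from scanner grey-value *G* to density,
ρ = *a·G* + *b*, and each retained voxel becomes a point mass ρᵢ·v at its
center. From that mass model the package computes

* CoM: **r̄** = Σmᵢ**r**ᵢ / Σmᵢ;
* the inertia tensor about any origin, with diagonal
  I_xx = Σmᵢ(yᵢ² + zᵢ²) (cyclic) and products of inertia stored as tensor
  entries I_xy = −Σmᵢxᵢyᵢ (the L = Iω convention);
* principal moments and axes (eigendecomposition, ascending moments,
  right-handed axes);
* virtual dissection (per-segment masses from a label volume), projected
  mass/MoI maps, and spanwise roll-MoI profiles;
* the trifilar pendulum chain: damped-harmonic-oscillator fits of
  gyroscope angular-velocity traces, rig MoI from the period via
  I = m·g·R²·τ²/(4π²·L), and specimen MoI corrected for CoM misalignment,
  I_dv = (m_b+m_p)·g·R²·τ²/(4π²·L) − I_p − m_b·D².

The specimen/air threshold is not hand-picked: it is **optimised so the
calibrated mass estimate matches the balance-measured specimen mass** (to
0.1 g, the balance resolution), which is what keeps feathered, partial-
volume-dominated anatomy in the model at the right total mass.

A synthetic-scene generator with exact analytic ground truth (primitive
solids composed by the parallel-axis theorem) and an exact-geometry
trifilar ODE simulator make the entire workflow testable without any scan
data. Intended users: biomechanists and comparative morphologists
estimating body segment inertial parameters non-destructively.

## Worked example

Calibrate from synthetic phantom rods, mass-match the threshold, and
compute inertial properties of the default bird-like specimen (a
barn-owl-scale scene with thin distal wing plates):

```r
library(inertiaCT)

spec  <- make_bird_like_scene(seed = 1)        # 220 x 420 x 80 mm, 1 mm voxels
scene <- rasterize_scene(spec)

rods <- make_phantom_rods(c(450, 580, 700, 900, 1050, 1250, 1500, 1820),
                          calibration_truth = spec$calibration_truth,
                          noise_sigma = spec$noise_sigma, seed = 2)
rod_scene <- rasterize_scene(rods)
samples <- lapply(seq_along(rods$densities), function(i)
  sample_phantom(rod_scene$grid, rods$rois[[i]], rods$densities[i]))
bg  <- rod_scene$labels$labels == 0
cal <- fit_calibration(samples,
                       air_sample = air_sample(mean(rod_scene$grid$values[bg]),
                                               sum(bg)))
cal
#> <density_calibration>  rho = 1.50031 * grey - 80.3454  [kg m^-3]
#>   9 samples, R^2 = 1.000000

thr <- optimise_threshold(scene$grid, cal,
                          target_mass = scene$voxelised$total_mass,
                          bounds = c(65, max(scene$grid$values)),
                          integer_levels = FALSE)
thr
#> <threshold_result>
#>   threshold        73.2278 grey units
#>   estimated mass   0.329109 kg  (target 0.329190 kg, error -0.0805 g)
#>   voxels retained  494436   iterations 6

model <- build_mass_model(apply_calibration(scene$grid, cal), thr$mask)
inertial_properties(model)
#> <inertial_properties>
#>   mass  0.329109 kg
#>   CoM   (0.124302, 0.210003, 0.0409147) m
#>   inertia tensor about (0.124302, 0.210003, 0.0409147) m  [kg m^2]:
#>              [,1]        [,2]         [,3]
#> [1,]  1.46389e-03 6.00925e-09 -4.74986e-07
#> [2,]  6.00925e-09 4.15287e-04  1.96938e-09
#> [3,] -4.74986e-07 1.96938e-09  1.80417e-03
#>   principal moments: 0.000415287, 0.00146389, 0.00180417 kg m^2
```

Reading the output: the calibration recovered the scene's generating line
(slope 1.5, intercept −80) from noisy rods; the threshold search matched
the balance mass to −0.08 g; the fitted mass sits within 0.1 % of the
scene's analytic truth (0.32927 kg), the CoM lies on the mid-sagittal
plane (y = 0.210 m) as the mirror-symmetric anatomy demands, and the
products of inertia are ~5 orders below the moments, so the anatomical
axes are already near-principal. The smallest moment is about the span
(pitch) axis and the largest about the dorsoventral (yaw) axis — the
signature of outstretched wings. Virtual dissection
(`virtual_dissect(model, scene$labels)`) puts ~26 % of the mass in the
wings, while `segment_fraction_table()` shows those wings carrying ~94 %
of the roll MoI: the distal-thin-plate effect the spatial summaries exist
to quantify.

The whole chain (plus projections, spanwise profiles, and the pendulum
closure) runs as one call:

```r
report <- run_pipeline(list(seed = 1, pendulum = list(offset_mm = 20)),
                       out_dir = "ct_results")
```

A thin shell wrapper lives at `inst/cli/ctinertia`
(`ctinertia run|simulate|pendulum`).

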