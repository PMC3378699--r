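# mtpm — tissue phase mapping of murine cardiac phase-contrast MRI

Phase-contrast cine MRI ("tissue phase mapping", TPM) encodes myocardial
velocity in the phase of the MR signal: a motion-compensated reference scan
and three motion-encoded scans are acquired per slice, and the phase
difference between reference and each encoded scan is proportional to the
tissue velocity along that axis, with the velocity-encoding limit *venc*
mapping a phase shift of π to ±venc cm/s.  Applied to the mouse heart on a
short-axis stack (basal, mid-ventricular, apical), this yields voxelwise
radial, circumferential and longitudinal myocardial velocities through the
whole cardiac cycle — the basis for regional function analysis, twist and
torsion.

`mtpm` is an R implementation of that analysis chain for people working
with (or simulating) murine TPM data:

* **Reconstruction** — isotropic k-space zero-filling (×2 by default,
  e.g. 128 → 256 at FOV 25.6 mm for 100 × 100 µm² voxels), radial
  third-order Butterworth apodization
  `H(k) = 1 / (1 + (|k|/k_c)^(2n))`, centered inverse FFT, velocity maps
  `v = venc · Δφ / π` from the phase difference Δφ = φ_ref − φ_enc, and
  linear background-phase correction fitted over a static external
  reference (the agarose-tube surrogate).
* **Kinematics** — per-frame center of mass of the myocardial mask,
  bulk-motion correction (subtraction of the mask-mean translational
  velocity), and projection onto polar components: v_r > 0 toward the
  center (contraction), v_φ > 0 clockwise in the foot-to-head view,
  v_z > 0 base-to-apex.
* **Segments** — AHA model with six equiangular segments on basal and
  mid-ventricular slices, four on the apical slice (segment 17, the apex
  cap, is excluded), each split at its median voxel radius into
  epicardial and endocardial compartments; regional time courses, peak
  systolic/diastolic velocities and bull's-eye tables.
* **Twist & torsion** — segmental angular velocity from the tangential
  velocity (`v_rot = v_φ / r`), twist φ = ∫ v_rot dt from end-diastole to
  end-systole (trapezoidal rule at the native frame interval, reported in
  degrees), torsion = apical twist − basal twist per wall and compartment.
* **Statistics** — Bland–Altman agreement (bias ± 2 SD limits),
  least-squares regression with a Student's *t*-test of slope = 1,
  percent change of diseased vs. control peak velocities
  (Δ = 100 · (v − v_ctrl) / v_ctrl), and 24-sector synchrony correlation
  maps of regional vs. global radial velocity.
* **Synthetic phantom** — an ECG-gated short-axis cine of a contracting,
  twisting, base-to-apex-shortening annulus plus a static reference
  block, with complex Gaussian noise, optional background phase planes
  and artifact modes, and *analytically known* voxelwise velocities,
  twist and flow — so every stage of the pipeline can be validated
  against closed-form ground truth.  A parabolic/plug flow-tube phantom
  mirrors the flow-rate validation experiment.

## Worked example

Simulate a basal-slice acquisition (matrix 128, FOV 25.6 mm, 20 frames at
4.6 ms, venc 6/8 cm/s, SNR 50), reconstruct it, and analyze:

```r
library(mtpm)

spec <- phantom_spec(slice_level = "basal", noise_sd = 0.02, seed = 1)
sim  <- generate_cine(spec)                       # k-space encoding set
sim$set
#> <cine_set> 4 encodings (ref, x, y, z), 128x128 x 20 frames, domain=kspace, slice=basal

seg <- rasterize_segmentation(sim$contours, 256, spec$meta$fov_mm)
vel <- reconstruct_velocity(sim$set, recon_config(), seg)
ana <- analyze_velocity(vel, seg)

ana$es_frame                                      # minimum cavity area
#> [1] 13

head(ana$global, 4)                               # cm/s, global mask means
#>   frame time_ms      v_r    v_phi     v_z
#> 1     1     0.0 -0.00476 -0.00399 0.00218
#> 2     2     4.6  0.14698  0.07842 0.28951
#> 3     3     9.2  0.28579  0.15550 0.48564
#> 4     4    13.8  0.41575  0.19693 0.78265

subset(ana$peaks, compartment == "full" & component == "radial")[1:3, ]
#>   segment segment_name compartment component peak_sys peak_dia
#> 1       1     anterior        full    radial     0.58    -0.85
#> 2       2 anteroseptal        full    radial     0.57    -0.87
#> 3       3 inferoseptal        full    radial     0.56    -0.86

head(ana$twist, 3)                                # degrees, ED -> ES
#>   segment segment_name compartment twist_deg ed_frame es_frame
#> 1       1     anterior        full      2.42        1       13
#> 2       2 anteroseptal        full      2.36        1       13
#> 3       3 inferoseptal        full      2.36        1       13
```

The global radial course rises to its systolic peak and reverses sign in
diastole (contraction then relaxation); basal twist comes out positive
(clockwise) at ~2.4°, and an apical run of the same pipeline yields the
opposite sense, so `torsion_table(basal$twist, apical$twist)` reports
negative torsion with smaller magnitudes in the epicardial than the
endocardial compartment.  Velocities are in cm/s, angles in degrees, all
geometry in mm.

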