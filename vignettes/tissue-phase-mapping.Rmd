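---
title: "Methods: tissue phase mapping analysis of the mouse heart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue phase mapping analysis of the mouse heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtpm)
```

## The measurement model

Tissue phase mapping acquires, for every slice and cardiac frame, one
motion-compensated reference scan and three motion-encoded scans (x, y,
z).  The phase of each encoded scan differs from the reference by an
amount proportional to the local tissue velocity along the encoded axis;
the velocity-encoding limit venc is the velocity that produces a phase
shift of π.  `mtpm` computes

$$v = \mathrm{venc} \cdot \frac{\Delta\varphi}{\pi}, \qquad
  \Delta\varphi = \arg\!\left(S_\mathrm{ref}\, S_\mathrm{enc}^{*}\right)
  \in (-\pi, \pi],$$

per voxel and frame, with the in-plane venc applied to x and y and the
through-plane venc to z.  No phase unwrapping is attempted: velocities
beyond venc alias, exactly as in the acquisition, and
`reconstruct_velocity()` warns when more than 0.5% of myocardial voxels
sit within 5% of ±venc.  Using the two-scan phase difference rather than
a fit over many encodings means any phase structure common to all four
scans (B0 inhomogeneity, off-resonance, receive phase) cancels
identically; what survives is the *differential* phase left by the
encoding gradients, which is why an external static reference is still
needed (below).

Before the phase subtraction, each k-space frame is apodized with a
radially symmetric Butterworth window
$H(k) = 1/(1 + (|k|/k_c)^{2n})$ and zero-filled isotropically.  The
magnitude image used for segmentation is the sum of the four scan
magnitudes.

### Reconstruction parameters

| parameter | default | units | role |
|---|---|---|---|
| `zerofill_factor` | 2 | – | interpolation to the analysis grid; 128 acquired at FOV 25.6 mm → 256, 100 µm voxels |
| `filter_order` | 3 | – | steepness of the Butterworth roll-off |
| `filter_cutoff_frac` | 0.7 | fraction of acquired Nyquist | half-power point of the apodization |
| `background_correction` | `"linear"` | – | `off`, `constant`, or `linear` plane fit over the static reference |

The cutoff default deserves a note.  With the half-power point at the
acquired Nyquist (fraction 1.0) the window barely attenuates anything and
Gibbs ringing at the blood–myocardium and myocardium–air borders leaks
into the phase of near-edge voxels: on the noiseless default phantom the
worst-voxel velocity error then exceeds 1% of venc, which is the error
budget we hold the reconstruction loop to.  At a cutoff of 0.7 the
overshoot is suppressed while the point-spread broadening stays below one
reconstructed voxel, and the worst-voxel error stays within the budget.
Both order and cutoff remain user-visible configuration because the
apodization filter in this class of reconstructions varies between sites
and implementations.

### Background phase correction

Encoding gradients leave spatially smooth phase residues (eddy currents,
Maxwell terms) that do *not* cancel in the reference-minus-encoded
subtraction and appear as a velocity offset.  Following the established
practice of placing a static agarose sample next to the animal, the
correction fits $v \approx a + b x + c y$ by least squares over the
static-reference voxels of each frame and component and subtracts the
fitted plane from the whole map.  The fit is exact for offsets in the
model class, so in noiseless simulation the residual over the reference
is zero to numerical precision; `"constant"` restricts the model to the
offset term, and the linear mode requires at least three reference
voxels.  In the phantom the injected plane is therefore applied to the
encoded scans only — a plane common to all four scans would cancel and
could never exercise the correction.

## Kinematic analysis

All geometry lives in mm on the displayed image, which is taken to be the
foot-to-head view: x grows with the column index (rightward), y with the
row index (downward), origin at the first voxel center, voxel size =
FOV / reconstructed matrix.  Sign conventions: radial velocity is
positive toward the per-frame center of mass (contraction), tangential
velocity is positive for clockwise motion as displayed, longitudinal
velocity is positive base-to-apex.

Per frame the pipeline (i) recomputes the center of mass of the
myocardial mask (the segmentation is frame-by-frame, so the center moves
with it), (ii) subtracts the mask mean of every velocity component (bulk
motion correction), and (iii) projects the in-plane components onto the
radial/tangential basis.  The projection is an orthonormal change of
basis, so in-plane speed is preserved voxelwise, and because the bulk
correction removes exactly the mask means, adding any uniform
translation to the field leaves all polar outputs unchanged.  One
ordering subtlety: bulk correction would zero the *global* longitudinal
mean by construction, so global v_z time courses are taken before bulk
correction while regional and polar maps use the corrected components;
the regional v_z then expresses longitudinal motion relative to the
slice's bulk motion.

Cohort averaging rescales each subject's time axis linearly so that
end-systole maps to normalized time 1, resamples by linear interpolation
onto a common grid and averages pointwise; amplitudes are untouched.
End-systole defaults to the frame of minimum endocardial (cavity) area
and can be overridden (`es_frame`), since gating schemes differ in where
the trigger sits.  End-diastole defaults to frame 1, the trigger, which
in mouse cine is end-diastolic.

## Segments, twist and torsion

Basal and mid-ventricular slices carry six equiangular segments
(anterior, anteroseptal, inferoseptal, inferior, inferolateral,
anterolateral; AHA 1–6 and 7–12), the apical slice four (anterior,
septal, inferior, lateral; AHA 13–16); segment 17 is the apex cap and is
excluded.  Segment boundaries are half-open, so labels are a disjoint
cover of the mask, and the count-weighted mean of segment means equals
the global mask mean identically.  The angular anchor of segment 1 is a
parameter (`reference_angle_deg`, default: anterior centered at 12
o'clock, ordering counterclockwise in the foot-to-head view) because no
anatomical landmark rule for the mouse is universal.  Each segment is
split at the median of its voxel radii: r < median is endocardial,
r ≥ median epicardial, which makes the compartments an exact partition
and leaves all-equal-radius degenerate segments epicardial.

Twist integrates the segmental angular velocity from end-diastole to
end-systole with the trapezoidal rule at the native frame interval
(second-order accurate and telescoping, so twist is additive over
adjacent windows), converted to degrees; torsion is apical minus basal
twist per wall, with the six basal segments collapsed onto the four
apical walls by averaging the two septal and the two lateral segments.

The angular-velocity estimator needs care.  The textbook conversion
divides the segment's mean tangential velocity by a representative
radius (`angular_velocity()` implements exactly that contract).  But for
an annular segment the mean of the voxel radii and their median differ
by about 0.6% at mouse-LV geometry, so composing mean(v_φ) with
median(r) is biased even for a perfectly rigid rotation — an estimator
property, not a measurement error.  The twist pipeline therefore uses
the voxel-mean angular velocity, mean(v_φ / r), which recovers a rigid
rotation exactly and, for a transmural profile linear in r, estimates
the rotation rate at the segment's mean radius.  The per-frame median
radius is still computed and reported for every segment and compartment.

## Agreement and synchrony statistics

Bland–Altman reports bias = mean(a − b) and limits of agreement at
bias ± 2·SD (the 2-SD convention, not 1.96).  Regression tests the null
hypothesis slope = 1 with a two-sided Student's *t* on n − 2 degrees of
freedom; a numerically perfect fit cannot reject (p = 1 at the null).
Paired comparisons match frame-by-frame and truncate to the shorter cine
when frame counts differ, as when bright-blood acquisitions carry a
couple of extra frames.  Percent change of diseased versus control peak
velocities uses the signed control value in the denominator,
Δ = 100 (v − v_ctrl)/v_ctrl, so a reduced magnitude reads negative for
both positive (systolic radial) and negative (diastolic, longitudinal)
components and the measure is invariant under rescaling both inputs.
Synchrony maps correlate each of 24 equiangular sectors' mean radial
velocity course with the global course; near-1 coefficients characterize
synchronous contraction, and sectors corrupted by artifacts fall away
from 1.  Constant series have no defined correlation and are reported
missing, as are empty segments (never zero-filled, which would bias
cohort statistics).

## What the phantom emulates — and what it does not

`phantom_spec()` describes a contracting, twisting annulus with a static
reference block, imaged as an ECG-gated short-axis cine:

* geometry: end-diastolic endo/epi radii 2 / 3 mm; matrix 128 at FOV
  25.6 mm; 20 frames at 4.6 ms; venc 6 cm/s in-plane, 8 cm/s
  through-plane — the acquisition regime of murine TPM at 9.4 T;
* radial motion: smooth periodic wall displacement with fractional
  shortening 0.13 (endo) / 0.05 (epi) and systolic fraction 0.6 of the
  cycle, giving systolic radial peaks below 1 cm/s and faster
  early-diastolic relaxation, i.e. the reported murine velocity regime;
* rotation: slice-level-dependent angular velocity, clockwise at the
  base and counterclockwise at the apex with a few degrees of twist,
  linear transmural profile with the epicardial rate 0.6 of the
  endocardial one — steep enough that the tangential *velocity* (ω·r),
  not only the rate, decreases outward, and giving an epi/endo twist
  ratio of ≈ 0.77;
* longitudinal motion: spatially uniform v_z(t), strongest at the base;
* signal: magnitude 1 in tissue and reference block, 0 outside; complex
  Gaussian noise per channel (default SD 0.02 of the tissue signal);
  optional differential background plane; optional localized
  phase-corruption sector and a bright-blood-style ghosting mode that
  modulates a cavity pool's k-space lines frame to frame.

Velocity phase is evaluated at voxel centers with no intravoxel
dephasing, no partial-volume signal model, no saturation-band or Bloch
simulation, no respiratory motion, and no k-space segmentation timing.
Contours are exact circles (512-gons).  Passing the validation suite
therefore demonstrates that the *analysis* is correct and
self-consistent at realistic mouse-heart geometry and SNR; it does not
certify robustness to partial-volume effects, imperfect manual
contouring, flow-related ghosting in the myocardium, or arrhythmic
gating, all of which real data contain.  For the corrupted-sector
synchrony check the localized phase-corruption mode is used rather than
the ghosting mode: ghost replicas propagate along the phase-encode
column and cross the annulus in two sectors, so "the corrupted sector is
lowest" would not be well-posed for that model.

## Numerical choices and degenerate inputs

* Centered FFT conventions throughout; zero-filling pads symmetrically
  around DC at `floor(n/2)+1`; the apodization cutoff is defined in
  absolute spatial frequency (fraction of the *acquired* Nyquist), which
  makes apodization and zero-filling commute exactly.
* Rasterization uses the even-odd rule on voxel centers with a half-open
  scanline convention; masks are deterministic, and a contour vertex
  landing exactly on a voxel center can be included asymmetrically by at
  most one boundary voxel.  The tissue support of the phantom applies a
  1 nm tolerance at the border radii so voxels at exactly the border
  radius (scaled Pythagorean-triple offsets exist on regular grids) are
  not dropped by floating-point rounding.
* A voxel coinciding with the polar center has no defined direction and
  is excluded with a warning; empty masks, empty phase windows,
  non-nested contours, open polygons, missing vencs and sub-3-voxel
  reference masks are hard errors naming the offending input.
* Missing through-plane encoding (2-encoding protocols) propagates as
  absent longitudinal output, never as zeros.
* The analytic twist oracle integrates ω(r_median(t), t) with adaptive
  quadrature to 1e-10 relative tolerance; the pipeline's trapezoidal
  integration at 4.6 ms frame spacing agrees with it to well under 2%
  for the default kinematics.

## Problem sizes in the test suite

The validation suite runs the full 128→256 reconstruction of the default
20-frame phantom for the voxelwise recovery check and for everything
else uses a quarter-FOV phantom (matrix 64 at FOV 12.8 mm) that keeps
the reconstructed voxel size of the full protocol; the flow-noise
propagation check uses 100 single-frame noise realizations of a
96-matrix tube.  These sizes hold the complete suite to a few tens of
seconds while leaving every check at full spatial fidelity where it
matters (the recovery loop) or at a scale whose statistical power the
tolerances explicitly account for.

## Known limitations

* The exact "modified" Butterworth filter of the original reconstruction
  chain is not public; the standard radial magnitude response with
  configurable order/cutoff stands in for it.
* Torsion is reported in degrees (not normalized per mm of inter-slice
  distance), and the overall-wall torsion is computed from the full-wall
  voxel set rather than by averaging compartment results.
* Time normalization implements pure time-axis rescaling to end-systole;
  protocols that stretch systole and diastole separately would need a
  different warping.
* No strain/strain-rate, no 3-D tracking across slices, no DICOM or
  vendor raw-data ingestion, and no interactive contouring: contours
  come in as JSON polygons.
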