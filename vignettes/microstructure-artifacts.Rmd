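---
title: "Susceptibility and microstructure effects in gradient-echo MRI: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Susceptibility and microstructure effects in gradient-echo MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Gradient-echo (GE) phase images of white matter (WM) are shaped by at least
three distinct mechanisms:

1. **Bulk isotropic susceptibility** — tissue-scale magnetic susceptibility
   differences (chi_I, in ppm) that perturb the field through the standard
   dipole convolution. Quantitative susceptibility mapping (QSM) inverts
   exactly this model.
2. **Bulk anisotropic susceptibility** — the myelin lipid bilayers make the
   voxel-averaged susceptibility of a coherent fiber bundle a cylindrically
   symmetric tensor; the field then depends on the angle between the fiber
   axis and B0. Susceptibility tensor imaging (STI) inverts the general
   tensor model from multi-orientation data.
3. **Microstructure frequency offsets** — water compartments around
   myelinated axons sample the intra-voxel field in a biased way, producing
   a *local* resonance-frequency offset that is **not** a field source and
   therefore is not described by either inversion model.

`qsmsim` implements forward simulation of all three mechanisms, the
experimental pipeline that separates them in a rotated tissue sample, and
the QSM/STI inversions — so that the artifacts the third mechanism imprints
on the first two can be quantified against known ground truth.

# Forward field models

All field models are Fourier-domain convolutions on a zero-padded grid.
For a scalar map chi (ppm), the frequency map is

    f = f0 * IFT{ D(k) FT{chi} },   D(k) = 1/3 - (k.h)^2 / |k|^2,

with `f0 = larmor_scale(B0) = 42.577 * B0` Hz/ppm (proton) and `h` the unit
B0 direction. For a symmetric tensor field X (per-voxel, ppm),

    f = f0 * IFT{ h' Xhat(k) h / 3  -  (k'h)(k' Xhat(k) h)/|k|^2 }.

The cylindrically symmetric convention used throughout is

    X = chi_I * I + chi_A * (3/2) (n n' - I/3),

so the eigenvalues are `chi_I + chi_A` along the axis `n` and
`chi_I - chi_A/2` across it, and the *overall susceptibility anisotropy*
(parallel minus perpendicular) equals `1.5 * chi_A`; a fitted
`chi_A = 0.0113 ppm` corresponds to 0.017 ppm. `cylsym_aniso_field()`
implements the dedicated uniform-axis kernel and is held equal to the
general `tensor_forward()` by test, which is the binding definition.

Numerical choices:

* **k = 0 is set to zero in every kernel.** The volume mean of a frequency
  or susceptibility map is not observable (measured maps are referenced
  arbitrarily; background-filtered maps are re-referenced); all
  reconstructions and round-trip comparisons are therefore defined up to a
  constant per component, and tests compare after mean re-referencing.
* **Padding.** `pad_factor = 2` (default) suppresses circular-convolution
  wrap-around; a dedicated test shows doubling the padding changes the
  masked field by well under 0.5% RMS. Brain-scale simulation/inversion
  experiments use `pad_factor = 1`, so that forward and inverse operators
  are *kernel-consistent* — the artifact analysis then isolates the
  effect of unmodeled signal, not of operator mismatch.
* **Orientation changes rotate the B0 unit vector**, never the volumes:
  exactly equivalent for simulation, and free of interpolation error (the
  physical experiment coregistered all acquisitions into one sample frame).
* **Discrete kernel near field.** The discrete Green's function of the
  dipole kernel carries voxel-scale ringing around a point source; it
  cancels over extended sources. Analytic-oracle tests therefore use
  spheres, cylinders, and compact extended tensor sources, not single
  voxels.

# SHARP background removal

`sharp_filter()` is the spherical-mean-value (SMV) method: fields that are
harmonic inside the mask (produced by sources outside it) are annihilated
by `(delta - rho)` convolution with a normalized sphere `rho`; the masked
difference image is then deconvolved by truncated k-space division and the
result is only valid on the mask eroded by the kernel radius, where its
mean is removed.

Defaults: `kernel_radius = 4` voxels (radius in voxel units — the compact
phantom geometry does not leave room for the multi-millimetre kernels used
on whole-head data), `erosion = kernel_radius`, and `tsvd_threshold =
0.01`. The truncation threshold matters more than is usually appreciated at
desk-scale grids: the stop band of the deconvolution is the k-ball where
`|1 - rho_hat| < t`, whose radius grows as `sqrt(t)/kernel_radius`. At
`t = 0.05` with a 4-voxel kernel this ball is wide enough to reject
structure at the scale of the embedded nerve, so the *internal* residual
offsets of the sample leak — band-limited and sign-inverted — into the
external shell and bias the susceptometry fit (chi_A by tens of percent).
At `t = 0.01` the stop band shrinks to the few lowest-frequency modes,
whose only surviving effect is a per-acquisition constant that the
reference-invariant fit (below) removes exactly. With noisy data the
deconvolution amplifies stop-band-edge noise by at most `1/t`; the noise
replicate test shows the reported standard errors stay honest within a
factor 1.5 at 0.5 Hz frequency noise.

# External-field susceptometry

The bulk susceptibility of an embedded sample is estimated purely from the
field it induces *outside* itself — internal offsets from exchange or
microstructure cannot contaminate the estimate by construction. The
fitting region is `dilate(M, 8) \ dilate(M, 1)` (voxels), with voxels of
`R2* >= 15 1/s` excluded (air-bubble footprints). The joint least-squares
problem over all orientations,

    f_meas = chi_I * F_I + chi_A * F_A,

is solved by QR decomposition; standard errors use the classical
`sigma^2 (G'G)^{-1}` covariance, and the parameter correlation is reported.
Weighting is ordinary least squares; pooled per-angle standard deviations
are reported alongside the means but do not enter the fit by default. Both the
measured and the unit-response maps pass through the *same* SHARP code
path. Each orientation's maps are demeaned over the fitting shell before
fitting (`demean = TRUE`): a frequency map is only defined up to a
per-acquisition reference, and SHARP re-references to the eroded-mask mean
rather than to the shell, so the fit is made exactly invariant to both.

The residual maps `f_R = f_meas - (chi_I F_I + chi_A F_A)` isolate the
local mechanisms. Their mean over the 1-voxel-eroded sample follows

    f_R(theta) = A sin^2(theta) + b,

with `A` (Hz) the microstructure amplitude and `b` (Hz) an
orientation-independent offset (microstructure + exchange). Angles are
folded by the axial symmetry of the model. An F test between the
isotropic-only and the two-parameter external fit quantifies whether the
anisotropic column is justified; its type-I error is verified by
simulation to sit at the nominal 5%.

`nerve_residual_analysis(filtered = FALSE)` subtracts raw model maps from
raw measured maps, recovering an injected offset exactly; with
`filtered = TRUE` both sides are SHARP-filtered first (experiment-style),
and part of the offset falls into the filter's stop band because the SMV
kernel is comparable in size to the nerve cross-section — the recovered
amplitude is then attenuated by roughly 10%.

# The synthetic phantom and brain model

**Nerve-in-sphere phantom** (`make_nerve_phantom()`). A 2 mm-radius,
16 mm-long cylinder of WM embedded in a gel sphere, imaged at 10 angles
(0..90 degrees in 10-degree steps) at 0.5 mm isotropic resolution on a
64^3 grid, padded x2. The sphere is 15 mm in radius — scaled down from the
10 cm experimental vessel so that the phantom, its 8-voxel fitting shell
and the SHARP erosion all fit the desk-scale grid; the nerve geometry,
voxel size, shell radii and exclusion thresholds are kept at their
experimental values. Ground-truth bulk values default to the optic-nerve
estimates (chi_I = -0.08152 ppm, chi_A = 0.01128 ppm relative to gel), the
injected internal offset to `A = -5.59 Hz`, `b = 4.88 Hz`, and noise to
zero (noise is opt-in; the quantitative experiments of the study are
noise-free). The injected offset is spatially uniform inside the eroded
nerve — only its ROI mean is characterized, so no finer structure is
warranted. Air bubbles are emulated as R2*-only markers (> 15 1/s) for the
qualification filter; their magnetostatics are out of scope.

**Digital brain** (`make_brain_model()`). A geometric whole-brain model on
a 64^3, 3 mm grid: ellipsoidal brain and WM compartments; lateral
ventricles; a gyral rim carved by a smooth seeded random field so the
WM/non-WM interface is convoluted (this interface heterogeneity drives the
f_I contribution, as in a real segmentation); bilateral deep grey
ellipsoids with literature susceptibilities (GP 0.15, PU 0.05, CN 0.05,
TH 0.00, PV 0.03 ppm) and `chi_A = 0` inside them; WM `chi_I = -0.05 ppm`
relative to non-WM. The fiber field blends three parametric tract systems
— a left-right arch (corpus callosum), bilateral vertical bundles
(internal capsule / corticospinal) and bilateral anterior-posterior
bundles (optic radiations) — into a smooth unit-vector field; FA is high
on tract cores and decays outward with a mild seeded texture. The
anisotropy map is `chi_A = 0.0113 ppm x FA/0.59`; normalized FA may exceed
1 and is deliberately not clipped. These are parametric vector fields, not
diffusion simulations: the pipeline needs orientation and coherence
structure, not realistic tractography. Three coherent-fiber ROIs (`CC`,
`IC`, `OR`) mark the tract cores.

What the model does *not* emulate: cortical folding at realistic spatial
frequencies, partial-volume mixtures, vasculature, real DTI noise and
fiber-crossing dispersion. Passing tests on this model show the pipeline's
mathematical behaviour under controlled conditions; they do not certify
accuracy on in vivo data.

**Microstructure map.** `f_M = A FA_n (sin^2 theta - 2/3) + b0` on the WM
mask — a direct local map, never convolved, because microstructure shifts
the resonance of the water that samples it rather than acting as a field
source. The `-2/3` makes f_M average to zero over isotropically distributed
fibers, separating it from the global offset `b0` (swept over -3/0/+3 Hz
in the composite-map experiments; 0.01 ppm of exchange is about 3 Hz at
7 T). f_M exists wherever the WM mask does, including deep-GM-adjacent WM.

# QSM by thresholded k-space division

`qsm_tkd()` divides the brain-masked, mean-referenced frequency spectrum by
the dipole kernel, with the kernel floored at a threshold `delta = 0.07`
(reciprocal truncation value about 14). Two variants are provided:
*standard*, the sign-preserving clip `sign(D)/delta` inside the truncation
region (with `sign(0)` fixed to +1 so the measure-zero cone surface is
deterministic), and *fully relaxed*, which this package defines as the
positive truncation value `+1/delta` across the whole sub-threshold region
(the sign structure is relaxed as well); the exact published definition of
the fully relaxed kernel is not restated in the source text, so this
interpretation is frozen here and its delta = 0.07 correction factor is
kept as a regression value. Truncation attenuates the output globally; the
compensation `c = 1/PSF(0)`, with PSF the point spread of
forward-times-inverted kernel, is applied by default (about 1.09 at
delta = 0.07 on a 64^3 grid). The real part is taken after the inverse
transform; the imaginary residue is asserted below 1e-9 of signal.

# STI inversion and its convergence state

`sti_invert()` solves the stacked least-squares system linking the six
k-space tensor spectra to all orientations' frequency spectra by conjugate
gradients on the normal equations, capped at `max_iterations` (default 30,
which dominates over the 1e-6 tolerance). Unmasked data decouple per
k-cell and converge quickly; brain-masked data (no frequency outside the
head) use the mask-aware operator — project to image space, mask, compare —
which couples k-cells and makes the cap meaningful. No regularization is
added. Eigen-analysis (`tensor_eigen()`) uses the closed-form trigonometric
solution of the 3x3 characteristic polynomial (validated against the base
eigensolver to 1e-10; accuracy ~1e-9 at degenerate pairs);
`chi_iso` is the mean eigenvalue, `chi_aniso = lambda_dif - chi_iso` with
`lambda_dif` the eigenvalue farthest from the mean — the convention that
inverts the tensor construction exactly — and the principal eigenvector
(PEV, the fiber estimate) is sign-fixed to non-negative z.

A finding of this implementation worth stating plainly: **the
microstructure-induced anisotropy inflation is a property of the solver's
convergence state.** The local f_M term, matched against the tensor
model's angular signature, corresponds to an apparent prolate anisotropy
of `-2 A FA_n / f0` (about +0.037 ppm x FA_n for A = -5.59 Hz) — but only
through the *local* part of the model. The right-hand-side projection
(early CG iterations) attributes f_M accordingly and inflates chi_aniso in
coherent tracts; the fully converged least-squares solution instead
penalizes the *absence* of the accompanying dipolar signature and maps f_M
to slightly oblate anisotropy. Thirty iterations at the original
acquisition scale (~256-voxel linear grid) sit in the inflationary
transient; thirty iterations on a 64^3 desk-scale grid are effectively
converged. `brain_sti_experiment()` therefore scales the cap with the
linear grid size, `round(30 * nx/256)` = 8 at the default 64^3, to hold
the solver at a comparable point of its trajectory. At that operating
point the corpus-callosum ROI inflates by roughly 1.8x relative to the
microstructure-free reconstruction, the optic-radiation ROI by ~30%, WM
chi_iso is biased less diamagnetic than truth, and the mean PEV angle
error roughly triples — the same artifact pattern as at full scale. The
vertically oriented capsule bundle is resolved faster by the hemispherical
orientation sampling and has already passed its transient at this scale;
its inflation is visible only at caps of about 7 or below and is therefore
reported but not asserted.

# Problem sizes and run times

All defaults are chosen so every experiment runs in minutes on one CPU:
phantom susceptometry on 64^3 (padded 128^3) grids with 10 orientations
(~30 s); brain composition and QSM on 64^3 (~10 s); the STI experiment
with 16 hemispherical orientations and the scaled cap (~1 min per
dataset); the noise-replicate study on a 48^3 phantom with 100 replicates
(~1 min); the F-test calibration with 1000 replicates (~5 s).

# Known limitations

* The brain model is geometric; absolute WM-SD values differ from those of
  a subject-derived model (orderings and artifact directions are the
  reproducible quantities).
* The desk-scale STI experiment requires the iteration-cap scaling
  argument above; at full acquisition scale the literal 30-iteration cap
  is the correct operating point.
* SHARP is the only background-removal method provided; phantom
  simulations contain no background field unless one is injected, so SHARP
  here mainly enforces processing parity between measured and simulated
  maps.
* `fit_orientation_model()` is unweighted; per-angle weights can be passed
  but are not the default.
* Phase unwrapping, coregistration, DTI fitting and tissue segmentation
  are out of scope: synthetic data are generated wrap-free in a common
  sample frame with known fiber fields.
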