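---
title: "laminaprep: models, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{laminaprep: models, phantom design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sub-millimetre gradient-echo BOLD resolves signal across the cortical
depth, but the GE contrast responds to field inhomogeneities around
draining veins as strongly as to the microvasculature next to active
neurons. Pial veins run along the cortical surface and ascending veins
drain deep layers outward, so uncorrected laminar profiles are biased
toward the surface and neighbouring depths share a common macrovascular
signal. `laminaprep` composes the standard cleanup stages into twelve
numbered pipelines and measures, on data with known ground truth, how
much depth-wise specificity each buys.

## The pipeline stages and their models

**Realignment.** Volumes are registered to the first volume by minimizing
the mean squared intensity difference over six rigid parameters (three
rotations in degrees about the volume centre, z–y–x order; three
translations in mm). Numerical design, in order of what mattered in
practice:

* both images are pre-smoothed (Gaussian, sd 1 voxel) before entering the
  cost — voxel-scale texture otherwise biases SSD registration because
  the moving image is interpolated while the reference is not;
* the cost is *symmetric*: both volumes are resampled by half the
  candidate transform, so interpolation blur lands on both arms equally;
* the target grid is offset by a fixed sub-voxel amount (and the cost
  averaged over complementary offsets): at a candidate of exactly zero
  all samples would fall on grid nodes and be spuriously blur-free,
  creating a notch-shaped false minimum;
* the cost is evaluated on an interior box (margin = smoothing radius
  plus a boundary allowance) and excludes out-of-volume samples, with a
  finite growing penalty when the overlap vanishes (NaN costs silently
  abort line searches);
* optimization is BFGS (smooth cost, cheap numerical gradient) followed
  by Nelder–Mead with parameter scaling (a degree of rotation displaces
  content about five times less than a millimetre of translation) and a
  restart, since NM contracts prematurely in six dimensions.

The estimated parameters are undone by inverse resampling; phase volumes
are resampled on the unit circle (interpolate cos φ and sin φ, recombine
via `atan2`) so values near the ±π seam do not average across it.

**Band-pass as projection.** Rather than FFT masking or an IIR filter,
the 0.005–0.12 Hz band-pass is a joint regression against sine/cosine
pairs at every DFT grid frequency outside the closed band (cosine only at
Nyquist) plus Legendre polynomials of degree 0–5. This mirrors the
projection semantics of spectral-regressor deconvolution and makes two
contracts exact: stop-band grid frequencies are annihilated to machine
precision, and residuals are orthogonal to every regressor. One
consequence is stated rather than hidden: Legendre polynomials are not
periodic, so their overlap with grid sinusoids decays only like 1/k —
low pass-band frequencies near the band edge *are* attenuated by the
polynomial block (99% at the third grid frequency, ~5% at the tenth).
That is inherent to polynomial detrending plus projection, not an
implementation artefact.

**RETROICOR.** Cardiac cycle phase is linear 0→2π between detected pulse
peaks (local maxima above the 60th amplitude percentile, minimum
separation 0.25 s, linear extrapolation beyond the first/last peak).
Respiratory phase uses amplitude histogram equalization with an
inspiration/expiration sign from the smoothed derivative; it is evaluated
at volume times through its cos/sin components for the same seam reason
as above. Columns: sin/cos of harmonics 1–5 of each phase (20) plus the
multiplicative block {sin,cos}(mφ_c)·{sin,cos}(nφ_r) for m, n ∈ {1, 2}
(16), i.e. 36 regressors at the default order.

**Single-step regression.** All nuisance blocks a preset requires
(band-stop + polynomials, motion parameters, RETROICOR, CSF/WM mean
courses) are concatenated and removed in one OLS. Joint removal is what
makes the residuals orthogonal to *every* column; regressing blocks
sequentially leaves correlations with the earlier blocks. Numerically the
solve goes through the orthonormal Q factor of the design's QR — the 36
RETROICOR harmonics are mutually correlated enough that normal equations
via Cholesky lose the answer. Rank deficiency (after dropping exact
duplicates) is an error naming the collinear columns. A caveat worth
repeating: regression without an intercept/polynomial block projects the
(large) baseline onto wiggly regressors and inflates residual variance;
every preset includes the polynomial block, but direct users of
`regress_nuisance()` should too.

**Phase-based de-veining.** Per voxel, `M(t) = a·φ(t) + b + r(t)` by OLS;
the corrected course is `r(t) + mean(M)`. The intercept costs nothing and
protects pipelines that reach this stage without demeaning; the temporal
mean is restored because downstream GLMs and spectra need a baseline.
The fit is univariate by construction — the phase of *this* voxel, not a
neighbourhood — and the slope's sign is unconstrained (venous dephasing
can couple either way depending on the reconstruction's phase
convention). Voxels with zero phase variance pass through with slope 0.
The operation refuses magnitude/phase pairs whose provenance step lists
differ, enforcing "the phase received every step the magnitude received".

**GLM.** Boxcar at volume resolution convolved with a shared double-gamma
HRF (modes 6 s and 16 s, undershoot ratio 6 — the same kernel the phantom
uses, so a noise-free simulated response is recovered exactly), unit-peak
scaled, plus intercept. Plain OLS, two-sided Student-t p-values, no
prewhitening: at TR 3.5 s temporal autocorrelation is modest, and the
reference tooling this mirrors fits by OLS as well; this is a documented
limitation, not an oversight. Thresholding is `p < threshold` strict with
no multiplicity correction; the implied t cut at the map's dof is
attached to the mask (at p = 0.001 and ~140 dof it is ≈ 3.36 two-sided —
the conventional "t ≈ 4" is not exactly reproducible from any standard
sidedness at these dof, which is why the operation is parameterized by p
and derives t).

**Metrics.** Power spectra are one-sided squared-magnitude periodograms
of the demeaned course, scaled so total power equals t·var (Parseval);
max-1 normalization divides by the spectrum maximum. fAvLFF is the power
in the closed 0.015–0.04 Hz band over total power. Homogeneity of a pair
of courses is the mean of the signed Pearson correlation and the Welch
magnitude-squared coherence (Hann window, segments of length
min(64, t/2), 50% overlap) averaged over 0.01–0.1 Hz; a line's
homogeneity matrix is 10×10 and the summary averages the strictly
off-diagonal entries. With four Welch segments the null coherence is
biased to ≈ 1/4, so "independent" courses score ≈ 0.13, not 0 — closed
forms (identical → 1, sign-flipped → 0, delayed copy → coherence ≈ 1
with attenuated correlation) pin the two halves of the metric. The noise
correlation stack enumerates 67 labelled components (6 motion, 2 aliased
traces, 36 RETROICOR, 3 tissue means, 10 magnitude + 10 phase line
voxels); the "mean correlation with noise" averages |r| between
magnitude voxels and the 47+3 noise components.

## The phantom: what it emulates and what it does not

Geometry is a flat slab along z — WM base, 5-voxel GM ribbon, 3-voxel CSF
cap at 0.63 mm isotropic — with tissue fractions mixed one voxel at the
interfaces and an in-plane air margin (tissue tapers to zero over two
voxels at the x/y borders) so that head motion moves tissue within the
FOV. Curvature is deliberately absent: every line invariant is satisfied
by straight columns, and curvature adds nothing the metrics would test.

Signals per voxel, all with per-voxel ground truth returned:

* **neural**: band-limited (0.015–0.04 Hz) Gaussian processes per GM
  depth, built as √ρ·shared + √(1−ρ)·own with ρ = 0.6, so cross-depth
  correlation is a controllable ground truth; in task mode, the shared
  HRF-convolved block response instead. Depth profiles: `"M"`
  (deep-layer peak, motor-like), `"M+T"` (mid-layer peak), `"flat"`.
* **vein**: the GM-pooled neural course delayed by 2 s, with amplitude
  `vein_gain · exp(−d / 0.2)` over depth fraction d (the ~20% cortical
  point-spread of the macrovascular contribution) plus a full-amplitude
  pial copy in the CSF layer touching the GM. The phase carries
  `phase_vein_coupling` times the vein component in vein-dominated
  voxels only (pial + GM shallower than the decay depth): magnitude, not
  phase, dominates in the parenchymal microvasculature.
* **physiology**: quasi-periodic oscillators (cardiac 1.1 Hz with a
  second harmonic, respiratory 0.3 Hz, 3% slow frequency jitter)
  recorded at 100 Hz and added to voxels *as sampled at volume times* —
  the aliasing is exact by construction, which one invariant asserts.
  CSF carries the largest gains.
* **drift**: a Legendre mixture (degree ≤ 3) with a spatially varying
  gain; **motion**: a smooth six-parameter trajectory applied by
  Lanczos-3 resampling (trilinear generation blurs the moved volume
  enough to bias any registration by ~0.25°, which would falsely fail
  recovery tests); **thermal**: i.i.d. Gaussian.

Amplitudes are scanner units against a GM baseline of 1000 and were fixed
once for a 7T sub-millimetre regime: neural 10 (1% resting fluctuation),
task response 40 (a strong 4% motor response), vein 2.5× the pooled GM
signal at the surface, cardiac/respiratory CSF gains 15/10, drift 5,
thermal 30 (GM tSNR ≈ 33 — the identifiable end of the published 10–40
range for 0.25 mm³ GE-EPI; at the noisy end, single-run recovery tests
would mostly measure noise), phase noise 0.08 rad (lumping thermal phase
noise with unmodelled physiological field modulation — this sets how
*complete* de-veining can be, and real data's surviving post-correction
CSF activation implies removal is partial). Static anatomical texture
(sd 100) gives registration its in-plane contrast.

What the phantom does **not** emulate — and hence what passing tests do
not show about real data: curved cortex and realistic vascular trees, B0
distortion and its interaction with motion, Rician (multi-coil) noise
statistics, spatially extended BOLD point-spread in-plane, slice-timing
offsets (the generator emits simultaneous slices; the slice-timing stage
is validated against analytic shifted sinusoids instead), and any
between-subject variability. Directional findings on the phantom
(de-veining lowers cross-depth homogeneity, raises the GM/CSF activation
ratio, shifts the superficial profile peak deeper) mirror the mechanism,
not the published effect sizes, which belong to 13 real subjects.

## Degenerate inputs and tie-breaks

Phase files must state their scaling (`phase_scale`); nothing is guessed
from value ranges. A TR missing from a NIfTI header is an error pointing
at the override argument, not a default. Magnitude/phase TR mismatch
greater than 1 µs is an error. Tissue masks use strict `>` at 0.99.
Thresholding uses strict `<`. Zero-variance motion columns are dropped
from the design rather than shipped as all-zero regressors (a motion-free
scan regresses nothing for motion). A GM/CSF beta ratio with no surviving
voxels in either ROI is flagged (`defined = FALSE`), never thrown. The
superficial-peak locator requires a peak to reach 20% of the profile
maximum so noise ripples in the flat CSF segment cannot register.

## Problem sizes

The replicate studies (`rest_phase_study()`, `task_phase_study()`) run 50
phantoms each at the full study geometry (40×40×12 voxels; 174 resting /
148 task volumes) with 8 cross-cortex lines per phantom, and pass the
phantom's true (zero) motion trace to the shared pipeline front-end so
that the twelve-pipeline battery stays within minutes per study.
Estimator calibration uses 200 seeded task phantoms at 12×12×12 for GLM
bias, a 36×36×20 noise-free phantom for motion recovery (the margin
excluded from the registration cost makes smaller grids unstable), 10,000
null voxels for the GLM type-I check and 1,000 draws of 280 pairs for the
paired-test type-I check.
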