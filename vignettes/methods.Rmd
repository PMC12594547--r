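---
title: "Models and methods behind dermoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dermoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dermoct analyses three readouts of a multifunctional skin OCT session —
structural thickness, elastic-wave group velocity, and microvascular lumen
width — together with the nonparametric statistics used to compare them
across groups and time points. This vignette explains each model, the
parameters that matter, and the choices made where the design was open.

## The phantom: what it emulates, and what it does not

Every processing stage is validated against synthetic data with known
ground truth, generated by `phantom_spec()` and the `generate_*()` family.
The phantom emulates the acquisition of a swept-source system at 1300 nm
and a 100 kHz A-line rate scanning a 5.16 × 6.14 mm field with 500 A-lines
per B-scan, 500 B-scans and 5 repeated B-scans per position; these are the
`scan_geometry()` defaults, and the test suite shrinks the grid (roughly
64–220 pixels per axis) purely to keep runtimes around a second per
dataset.

**Speckle.** Tissue backscatter is fully developed speckle: each voxel's
complex scatterer amplitude is circularly symmetric Gaussian with variance
equal to the local backscatter level, so pre-log intensity is exponentially
distributed. Repeated scans share one scatterer realisation and differ only
by additive complex detection noise — the simplest model under which
inter-repeat correlation (the basis of OCTA) is meaningful. Consequences to
keep in mind: averaging repeats suppresses detection noise but *not*
speckle, and phantom-derived accuracy figures do not include bulk motion,
beam-profile or attenuation effects, which real skin data have.

**Geometry.** Interfaces are specified in physical micrometres and placed
at axial pixels via optical path = depth × tissue refractive index
(default 1.376, the standard skin assumption). The axial pitch default of
5 µm optical path per pixel is an instrument constant, configurable.
Pigment patches multiply backscatter by an attenuation factor over a
lateral rectangle.

**Wave.** The elastography phantom injects
$u(x,t) = A\,e^{-\alpha|x-x_0|}\sin\!\big(2\pi f\,(t - |x-x_0|/c)\big)$,
windowed to `n_pushes` cycles and identically zero before arrival — a
single group velocity, no dispersion, because group velocity is the
reported quantity. One cycle stands for the single-push protocol and three
for the push train. The phase modulation is $\Delta\phi = 4\pi n u/\lambda$
on top of a static speckle phase, plus Gaussian phase noise (default SD
0.05 rad, a realistic in-vivo jitter; instrument phase floors are far
lower), wrapped to $(-\pi, \pi]$.

**Vessels.** Tubes of constant diameter around a polyline centerline;
in-lumen voxels have a fraction `decorrelation` of their complex amplitude
resampled per repeat (1 = fully developed flow). The cohort generator draws
per-animal values with a latent intercept scaled so each stated
(group, day) SD is the *marginal* SD and `rho` (default 0.5) is the
between-day correlation.

## Thickness

The pipeline runs in acquisition order: average the repeats, trim 100 edge
frames and 50 edge A-lines per side (at the full acquisition this retains
300 × 400 × 5 = 600 000 A-lines per position), detect surfaces, exclude
pigmented A-lines, convert to micrometres. Averaging and trimming commute,
so the order is a convention, not a constraint.

Surface detection is background-relative: per A-line the threshold is
background mean + `threshold_k` × background SD (default k = 4), with the
background estimated from the shallowest 15 rows; being intensity-relative
makes thickness invariant to global intensity scaling. A crossing must
persist for 2 consecutive pixels (`min_run`), which suppresses
single-speckle false crossings without biasing the edge position the way a
centered smoothing window would; each surface is then median-filtered
laterally over 5 A-lines. The "two surfaces" are generic: the tracker finds
the first and the last sustained supra-threshold pixel, so it serves both
an epidermis-only and a full-skin reading — the reported ~0.5–1 mm
magnitudes correspond to the latter.

Pigment exclusion is automated: A-lines whose mean in-tissue intensity
falls below the `percentile_cut` quantile (default 0.05) of the lateral
distribution are dropped, replacing a manual-confirmation step that cannot
be reproduced in code; the excluded fraction is reported and the deviation
is logged in every run record. On phantoms with an 8% patch at 12 dB
attenuation, a 10% cut removes >90% of the patch with <2% false exclusions.

## Elastography

Displacement comes from temporal phase differencing: wrap each step to
$(-\pi,\pi]$, cumulate, convert by $u = \Delta\phi\,\lambda/(4\pi n)$
(λ/4n ≈ 236.2 nm per π radian at 1300 nm and n = 1.376). Unwrapping is
temporal only; amplitudes in scope stay below the per-step wrap limit, and
the phantom property tests confirm sub-1% RMS recovery there.

The space–time map averages displacement over a sub-surface depth window
(default: 10 pixels from the tracked surface, where the wave energy is
concentrated; the tracked feature and window are configurable because
neither is uniquely determined by the protocol). Arrival delays are the
peaks of normalized cross-correlations against a reference trace — the
first usable position at least 3 lateral pixels from the excitation,
excluding the near field — refined by parabolic interpolation with ties
broken toward the smaller delay. Speed is the slope of the least-squares
distance-vs-delay fit; an estimate is invalid (not an error) when the fit
R² falls below 0.8 or the slope is non-positive. Left and right side
estimates are averaged, then the two perpendicular scan orientations.
Cross-correlation of mean-removed traces makes the estimator invariant to
constant displacement offsets. On reduced phantoms the estimator stays
within 3% of truth without noise and within 10% at the default phase noise
across 1, 5 and 10 kHz and both push counts.

## Angiography

The flow value at a pixel is $1 - \bar r$, where $\bar r$ averages the
zero-normalized cross-correlation of consecutive repeat pairs over a
5 × 5 (depth × lateral) kernel; consecutive pairing among the 5 repeats
minimizes sensitivity to slow drifts, and ZNCC makes the map invariant to
global intensity scaling. Zero-variance kernels are defined to correlate
perfectly when the patches are identical. The implementation uses
box-filter sums and is tested to 1e-10 against a literal per-pixel loop.

The en-face image is a maximum projection over the tissue depth band
(estimated by `tissue_depth_band()`; air above the tissue decorrelates
between repeats and must stay out of the projection). Vessels are enhanced
with a multiscale Hessian filter — response
$\exp(-R_b^2/2\beta^2)(1-\exp(-S^2/2c^2))$ for bright ridges, β = 0.5,
c = half the maximum structureness per scale, scales {1, 2, 4, 8} px —
then thresholded (Otsu), labelled, and skeletonized (Zhang–Suen). Lumen
width is the Gaussian-fit FWHM (2.355 σ) of the flow profile perpendicular
to the local centerline direction, with two numerical details: profiles
with fit R² < 0.7 are discarded, and the correlation kernel's box response
(SD $\sqrt{(k^2-1)/12}$ pixels along the fast axis) is removed from σ in
quadrature — without this the kernel sets a width floor of ~5 pixels and
small vessels are systematically over-read. This automated measurement
replaces a manual caliper protocol; the deviation is logged in run
records. Bulk-motion correction is not implemented (phantoms are
motion-free).

## Statistics

Paired comparisons use the Wilcoxon signed-rank test (zeros dropped,
Wilcoxon's original treatment); between-group comparisons use the
Mann–Whitney U test. Exact two-sided p values come from the package's own
null-distribution recursions — a sign-pattern generating function over
doubled (mid)ranks for the signed-rank statistic (n ≤ 25), and the
standard rank-subset recurrence for U (n₁+n₂ ≤ 20, no ties) — and are
tested against full enumeration. Larger samples use normal approximations
with tie and continuity corrections; the continuity correction keeps the
approximate branch within 0.02 of the exact one at the crossover sizes and
the achieved type-I error within [0.04, 0.06] at α = 0.05 for n = 15.

Hodges–Lehmann estimates are medians of pairwise differences (two-sample)
or Walsh averages (paired), with confidence intervals from order statistics
at ranks that invert the corresponding rank test (exact inversion at small
n, normal approximation beyond); when a requested confidence is not
achievable the widest interval is returned with a warning. Bonferroni
correction is applied over one results table — the family must be stated
in the comparison plan because no canonical family exists. Site-pooled
analyses average the two imaging sites per animal before testing.

The power layer uses the normal-approximation sample-size formula (the
noncentral-t solver is available via `method = "t"` and is one animal more
conservative at the pilot effect size) and the matching minimum detectable
difference. The default pooled SD convention reproduces the printed pilot
arithmetic: g = 1.45, n = 8, MDD = 0.26 m/s at n = 15.

## Known limitations

Phantoms omit bulk motion, beam divergence, depth-dependent attenuation,
multiple scattering and vessel pulsatility, so passing tests demonstrate
algorithmic correctness, not robustness to every in-vivo artifact. The
elastography model is non-dispersive; layered inverse models and modulus
conversion are out of scope. OCTA cannot distinguish outward remodeling
from vasodilation, and the lumen measurement assumes approximately tubular
vessels wider than about half the correlation kernel.
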