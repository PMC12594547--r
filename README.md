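# dermoct

Quantitative analysis of multifunctional optical coherence tomography (OCT)
imaging of skin, for preclinical imaging groups that monitor dermal fibrosis
and its treatment longitudinally in small animals. One acquisition session
yields three readouts, and this package implements the full processing chain
for each:

- **Structural OCT → skin thickness.** Repeated B-scan volumes are averaged,
  edge frames and edge A-lines trimmed, the two tissue surfaces tracked by
  intensity thresholding, weakly backscattering (pigmented) A-lines
  excluded, and the pixel separation converted to physical thickness via
  `d = Δz · axial_pitch / n` with skin group refractive index `n = 1.376`.
- **Optical coherence elastography (OCE) → elastic-wave group velocity.**
  Phase-sensitive M–B-mode records capture a transient wave launched at the
  field centre. Displacement follows from temporal phase differences by
  `u = Δφ · λ / (4π n)`; arrival delays on each side of the excitation are
  estimated by normalized cross-correlation with sub-sample (parabolic)
  refinement, and the group velocity is the slope of the distance-vs-delay
  regression, averaged over sides (and over perpendicular scan
  orientations). Stiffer, more fibrotic skin propagates the wave faster.
- **OCT angiography (OCTA) → vessel lumen width.** Correlation-mapping OCTA
  labels each pixel by the zero-normalized cross-correlation of repeated
  B-scans over a 5 × 5 kernel (`flow = 1 − r̄`); a multiscale Hessian
  (Frangi-type) filter enhances tubular structure, and lumen width is the
  Gaussian-fit FWHM (2.355 σ) of the flow profile perpendicular to the
  vessel centerline, corrected for the correlation kernel's box response.
- **Statistics.** Wilcoxon signed-rank (paired) and Mann–Whitney U
  (between-group) tests with exact small-sample null distributions,
  Bonferroni correction over a results table, Hodges–Lehmann shift
  estimates with rank-inversion confidence intervals, Hedges' g, the
  two-sample sample-size formula `n = ⌈2((z_{1−α/2}+z_{1−β})/g)²⌉`, and the
  minimum detectable difference `(z_{1−α/2}+z_{1−β}) · sd · √(2/n)`.

Because raw instrument data are rarely shareable, the package ships a
synthetic phantom generator (`phantom_spec()`, `generate_*()`) producing
speckle-bearing layered volumes, propagating-wave phase records,
decorrelating vessel stacks and longitudinal cohorts with known ground
truth; the entire test suite runs against these phantoms.

## Worked example

```r
library(dermoct)

# power analysis from a pilot summary: 1.6 ± 0.3 vs 1.2 ± 0.2 m/s, n = 6/6
g <- hedges_g(1.6, 0.3, 6, 1.2, 0.2, 6)
round(g, 2)                                   # 1.45
sample_size_two_sample(g)                     # 8 animals per group
round(minimum_detectable_difference(15, pooled_sd(0.3, 6, 0.2, 6)), 2)
                                              # 0.26 (m/s) at n = 15

# elastography on a simulated M-B-mode record with known wave speed
geom <- scan_geometry(n_alines = 160, n_bscans = 128, n_repeats = 1,
                      n_depth = 48)
spec <- phantom_spec(geom, top_surface_um = 50, bottom_surface_um = 150,
                     wave = wave_spec(frequency_hz = 5000,
                                      group_velocity_m_s = 2.5),
                     seed = 42)
oce <- generate_oce_dataset(spec)
estimate_group_velocity(oce$mb)
#> <velocity_estimate>
#>   left 2.500 m/s (R2 1.000), right 2.499 m/s (R2 1.000)
#>   mean 2.500 m/s
```

The effect size 1.45 says the pilot groups are separated by about one and a
half pooled standard deviations; 8 animals per group suffice for 80% power
at two-sided α = 0.05, and enrolling 15 lets a true velocity difference of
0.26 m/s (≈16% of the stiffer group's mean) be detected. The phantom run
shows the time-of-flight estimator recovering the simulated 2.5 m/s wave on
both sides of the excitation.

End-to-end runs (`run_pipeline()`, or
`inst/scripts/dermoct-pipeline.R --modality oce --seed 3 --out run/`)
write per-stage CSVs and a JSON run record with a checksum for every output
file; the same configuration and seed always reproduce identical checksums.

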