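# phosfit

Quantification of in vivo phosphorus (³¹P) magnetic resonance spectroscopic
imaging, end to end: a 15-component Lorentzian model of the brain ³¹P
spectrum, AMARES-style time-domain fitting with prior knowledge, metabolite
ratios / intracellular pH / free Mg²⁺, chemical-shift-imaging
point-spread-function simulation, voxel quality control, and nonparametric
cohort statistics. A built-in synthetic-cohort generator emulates the
regional metabolite structure of a glioblastoma study — contrast-enhancing
tumor, T2-hyperintense, adjacent, distant ipsilateral, contralateral and
healthy-volunteer tissue — so the full pipeline runs and is tested without
any clinical data.

The intended user is an MRS methodologist or neuroimaging statistician who
wants a reproducible, scriptable version of the standard ³¹P-MRSI analysis
chain: ratios rather than absolute concentrations (PCr/ATP, Pi/ATP, PCr/Pi,
PME/PDE, PME/ATP, PME/Pi, PME/PCr, PDE/ATP, PDE/Pi, PDE/PCr), pH from the
inorganic-phosphate shift and free Mg²⁺ from the β-ATP shift.

## The model

A voxel's free induction decay is fitted in the time domain as

$$\hat y(t_n) = \sum_{k=1}^{15} a_k w_k\, e^{i\phi_k}
  e^{(-d_k + 2\pi i f_k) t_n},$$

15 Lorentzian sinusoids for eleven entities (PE, PC, Pi, GPE, GPC, MM, PCr,
NAD(H), and the γ/α-ATP doublets plus β-ATP triplet), with multiplet
J-splitting, weights, shared dampings/phases, shift windows and
non-negative amplitudes imposed as prior knowledge in a bounded
Levenberg–Marquardt fit with analytic Jacobian. pH follows
pH = pK + log₁₀((δ−δ_a)/(δ_b−δ)) from the Pi shift; free Mg²⁺ follows a
one-site binding curve on the β-ATP shift. The CSI spatial response is the
Fourier transform of the Hamming-apodized 8×8×8 k-space pattern
(FOV 240×240×200 mm³, zero-filled to 16×16×8); its half-maximum isosurface
quantifies the effective voxel. Group comparisons use Kruskal–Wallis with
Dunn post-hoc tests after ROUT outlier removal; correlations use
Spearman's rank coefficient. See the methods vignette
(`vignettes/phosphorus-mrsi-methods.Rmd`) for assumptions, defaults, and
design decisions.

## Worked example

Simulate one tumor voxel, fit it, and read off the metrics:

```r
library(phosfit)

acq   <- acq_params()                 # 49.9 MHz, 1024 pts, 0.25 ms dwell
basis <- build_basis(acq)             # 15 components, J = 16.3 Hz

met   <- sample_region_metrics(cohort_config(), "contrast_enhancing",
                               3, seed = 5)
comps <- metrics_to_components(met[1, ], cohort_config())
fid   <- synthesize_fid(comps, acq,
                        noise_sd = snr_to_noise_sd(comps, acq, 20), seed = 8)
fit   <- fit_spectrum(fid, basis)
glance(fit)
#>   residual_norm relative_residual converged n_iterations n_points
#> 1          15.0             0.638 TRUE                14     1024
quantify_fit(fit)[, c("PCr_ATP", "Pi_ATP", "PME_PDE", "pH", "Mg")]
#>   PCr_ATP Pi_ATP PME_PDE    pH    Mg
#> 1   1.056  0.549   0.942 7.021 0.108
met[1, c("PCr_ATP", "Pi_ATP", "PME_PDE", "pH", "Mg")]   # generating truth
#>   PCr_ATP Pi_ATP PME_PDE    pH    Mg
#> 1   1.038  0.425   0.999 7.016 0.108
```

At a spectral SNR of 20 the strong resonances come back within a few
percent and pH/Mg²⁺ within ~0.01 of the truth; `autoplot(fit, fid)`
overlays data, model and residual.

A small cohort through the whole pipeline (generate → fit → quantify →
inclusion rules → ROUT → tables):

```r
config <- cohort_config(n_subjects = 6,
                        regions = c("contrast_enhancing", "contralateral"),
                        snr = 20)
run <- run_pipeline(config, seed = 2026)
run
#> <p31_run> 36 voxels (25 analysed), 2 regions, seed 2026
regional_table_wide(run$regional)
#>     metric contrast_enhancing contralateral
#> 1  PCr_ATP        1.22 ± 0.31   1.40 ± 0.28
#> 2   Pi_ATP        0.44 ± 0.19   0.40 ± 0.08
#> 4  PME_PDE        1.31 ± 0.61   0.81 ± 0.34
#> 8  PDE_ATP        0.42 ± 0.15   0.64 ± 0.12
#> 11      pH        7.08 ± 0.05   7.06 ± 0.05
#> 12      Mg        0.11 ± 0.00   0.11 ± 0.02   # (rows abridged)
```

Eleven of 36 voxels were dropped by the tissue-fraction and spectrum
screens; the surviving means sit near the generating regional references
(tumor tissue: lower PCr/ATP, higher Pi/ATP and PME/PDE than contralateral
brain). `run$comparisons` holds the Kruskal–Wallis/Dunn results and
`run$correlations` the Spearman table; `run_pipeline(..., out_dir = ...)`
writes CSV/JSON outputs with a seeded, hashed manifest.

The PSF simulation quantifies what a Hamming-apodized CSI voxel really is:

```r
psf_metrics(compute_psf(csi_geometry(), oversample = 32))
#> half-max volume +222.8 % over the 30x30x25 mm nominal voxel
#> (per-axis FWHM 54.4/54.4/45.4 mm; noise-equivalent volume +153.1 %)
```

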