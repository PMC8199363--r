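---
title: "Methods: 31P-MRSI quantification, PSF simulation and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 31P-MRSI quantification, PSF simulation and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosfit)
```

phosfit implements the quantification chain of an in vivo phosphorus
magnetic-resonance spectroscopic imaging (31P-MRSI) study of brain tissue:
time-domain fitting of free induction decays (FIDs) with prior knowledge,
conversion of fitted areas and chemical shifts into metabolite ratios,
intracellular pH and free magnesium, simulation of the chemical-shift-imaging
(CSI) spatial response, voxel quality control, and nonparametric cohort
statistics. Because clinical MRSI raw data are rarely shareable, the package
also contains a first-class synthetic-cohort generator whose defaults encode
the regional statistics of a glioblastoma cohort; the whole pipeline runs,
and is tested, against data it can generate itself.

## The spectral model

The time-domain signal of one voxel is modelled as a sum of 15
Lorentzian-shaped exponentially decaying complex sinusoids,

$$\hat y(t_n) \;=\; \sum_{k=1}^{15} a_k\, w_k\, e^{i\phi_k}\,
  e^{(-d_k + 2\pi i f_k)\, t_n},$$

where $a_k$ is an amplitude (proportional to metabolite area), $w_k$ a fixed
relative weight inside a multiplet, $\phi_k$ a phase, $d_k$ a Lorentzian
decay rate in 1/s (absorption-mode linewidth $d_k/\pi$ Hz) and $f_k$ the
frequency offset corresponding to the chemical shift (1 ppm =
`spectrometer_freq` Hz; PCr defines 0 ppm). The 15 sinusoids represent
eleven spectral entities: phosphoethanolamine (PE) and phosphocholine (PC),
summed for reporting as phosphomonoesters (PME); inorganic phosphate (Pi);
glycerophosphoethanolamine (GPE) and glycerophosphocholine (GPC), summed as
phosphodiesters (PDE); a macromolecule component (MM); phosphocreatine
(PCr); NAD(H); and ATP as two doublets (γ, α) and one triplet (β) split by
the phosphate J-coupling.

Choices a user may care about:

* **Multiplet weights are normalised to sum to one** (1:1 doublets, 1:2:1
  triplet scaled to 1/4, 1/2, 1/4), so each ATP entity's amplitude equals
  its multiplet's total area and the reported ATP area is simply the mean of
  the three (`atp_total()`). This makes the "sum the three ATP signals and
  divide by three" convention exact rather than approximate.
* **Only PCr (0 ppm), MM (2.2 ppm) and NAD(H) (−8.3 ppm) have fixed
  shifts**; all other positions are configuration with literature-typical
  brain defaults (`default_shift_table()`). MM and NAD(H) are fitted but
  excluded from every reported quantity, reflecting their poor
  identifiability at clinical signal-to-noise; their amplitudes remain
  available in the fit object.
* **The β-ATP default position is −16.75 ppm**, not the more commonly quoted
  −16.1 to −16.3 ppm. The package derives free Mg²⁺ from the β-ATP shift
  through its default calibration (below), and −16.75 ppm is exactly where
  that calibration puts a brain-typical free Mg²⁺ of ≈0.105 mMol. Using an
  inconsistent pair of defaults would make the generator place β-ATP far
  from the fitter's starting position; users substituting their own Mg
  calibration should adjust the basis position to match it.
* **Acquisition defaults** are 1024 complex points at 0.25 ms dwell
  (4 kHz sweep) at 49.9 MHz — a 3 T whole-body field. Receiver bandwidth and
  record length of the emulated protocol are not public; these values cover
  the 31P shift range with generous margin and are configuration.
* **J-coupling defaults to 16.3 Hz**, a typical in vivo ATP value, and is
  configurable; no apodization is applied before fitting.

## Prior-knowledge fitting

`fit_spectrum()` minimises $\sum_n |y(t_n)-\hat y(t_n)|^2$ with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) and an analytic Jacobian. Prior
knowledge mirrors standard AMARES practice and is enforced structurally
where possible:

* lines within a multiplet share damping and phase and keep their J-spacing
  and weights *by parameterisation*, so these constraints hold exactly;
* one global zero-order phase is shared by all entities by default
  (per-entity phases are available via `fit_prior(shared_phase = FALSE)`);
* amplitudes are bounded below by zero (areas are physical);
* shifts move inside windows of ±0.2 ppm around the basis positions — wide
  enough for field drift, narrow enough to prevent component swapping. Two
  exceptions carry physiology and get wider windows: Pi (±0.5 ppm, spanning
  about pH 6.8–7.4) and β-ATP (±0.8 ppm, spanning about 0.04–0.5 mMol free
  Mg²⁺);
* dampings are bounded to [5, 100] 1/s (linewidths ≈1.6–32 Hz).

Starting values are read off the magnitude spectrum (peak height over each
window converted to time-domain amplitude through the geometric decay sum;
peak position for entities with a unique strongest line; the phase of the
leading FID samples). Convergence tolerance is 1e-10 on the cost with at
most 500 iterations. A fit with an exactly zero residual is reported as
converged even if the iteration cap was reached: entities with zero
amplitude leave their shift and damping parameters unidentifiable, and the
optimizer can polish them forever without changing the model.

Two degenerate situations are handled explicitly: two free-shift entities
configured at the same position are rejected before optimization, and the
all-zero FID yields all-zero starting amplitudes. Cramér–Rao lower bounds
are not computed in this version; the fit object reserves a field.

### Spectrum quality screen

The screen (`quality_flag()`) rejects non-converged fits, fits whose
residual RMS exceeds 1.5× the estimated noise floor, and fits in which a
ratio-reporting amplitude sits on its zero bound. The noise floor is
estimated from first differences of the residual tail (last quarter of the
record), which is insensitive to smooth unmodelled structure; a white-noise
residual gives a ratio near 1 regardless of SNR or scale. The 1.5 threshold
is a package default, not a published criterion — the clinical
spectrum-quality rules used in practice are not standardised — and is
configurable through `qc_thresholds()`.

## From fits to reported quantities

`quantify_fit()` produces the twelve metrics: ten area ratios (PCr/ATP,
Pi/ATP, PCr/Pi, PME/PDE, PME/ATP, PME/Pi, PME/PCr, PDE/ATP, PDE/Pi,
PDE/PCr), pH and free Mg²⁺. The ratio set is computed from five group areas
(PME, PDE, Pi, PCr, ATP), so its internal identities — e.g.
PCr/Pi = (PCr/ATP)/(Pi/ATP) — hold exactly on every voxel, and all ratios
are invariant to global signal scaling. Zero denominators mark the ratio
undefined and exclude the voxel downstream; nothing is imputed.

**pH** comes from the Pi shift via the Henderson–Hasselbalch form
$\mathrm{pH} = pK + \log_{10}\,(\delta-\delta_a)/(\delta_b-\delta)$ with
defaults $pK = 6.75$, $\delta_a = 3.27$, $\delta_b = 5.69$ ppm — standard in
vivo constants from the cited calibration literature, not values derived
here. **Free Mg²⁺** comes from the β-ATP shift through a one-site binding
curve between the limiting shifts of Mg-free (−18.58 ppm) and fully
complexed (−15.74 ppm) ATP with apparent $K_d = 10^{-4.24}\,$M. Several
variants of these constants circulate and the emulated study does not state
which it used, so absolute pH/Mg agreement with any particular report is
not a testable contract; exact forward/inverse roundtrip consistency is,
and is verified to 1e-10 across the domain. Shifts outside a calibration's
open interval raise an error naming the violated bound (or yield `NA` at
the cohort level, where the odd degenerate voxel must not abort a run).
Mg²⁺ is reported in mMol.

## CSI point-spread-function simulation

The spatial response of a phase-encoded CSI acquisition is the discrete
Fourier transform of its k-space sampling pattern. `compute_psf()` builds
the separable 3D response of an 8×8×8 acquisition over a 240×240×200 mm³
field of view (nominal voxel 30×30×25 mm³), apodized with a Hamming window
over the phase-encode indices, zero-filled to the 16×16×8 reconstruction
matrix (15×15 mm² in-plane grid) and oversampled (default 32× per axis,
sub-millimetre resolution) for lobe-boundary measurements.

Two effective-voxel conventions appear in the MRS literature, and they
differ by a lot, so the package computes both:

* **half-maximum isosurface volume of the PSF magnitude** — the
  "spherical-shaped" region where $|\mathrm{PSF}| \ge 0.5$. For the default
  Hamming geometry this is **+223%** relative to the nominal voxel
  (per-axis FWHM 54.4/54.4/45.4 mm), the figure used as the headline
  effective-voxel increase, consistent with the ≈190% reported for this
  sequence family;
* **noise-equivalent volume** $\int |\mathrm{PSF}|^2\,dV$ (peak normalised
  to 1), which equals the nominal voxel exactly for an unapodized
  acquisition and gives **+153%** under Hamming weighting.

On the squared-magnitude (power) profile, the unapodized response has the
textbook Dirichlet FWHM of 0.886 nominal spacings (1.21 on the magnitude
profile); both are verified against closed forms in the tests. A detail
worth recording: the effective-voxel increase is *not* monotone in the
usual "rect → hann → hamming" listing order — the hann window has the wider
main lobe (FWHM 2.0 vs 1.81 bins), so the true ordering is
rect < hamming < hann.

`bleed_fraction()` quantifies voxel bleed as the fraction of PSF energy
outside a box of configurable half-width; beyond the first Dirichlet zero
(one nominal spacing) Hamming weighting leaks less than the rect baseline,
which is the point of apodizing. Note that the energy outside the nominal
voxel itself is *larger* with Hamming (the main lobe is wider); suppression
of distant side lobes, not main-lobe confinement, is what apodization buys.

## Voxel inclusion rules

A voxel enters the analysis only when more than two-thirds of it is the
desired tissue, and is excluded when necrosis occupies more than one third.
Both are read as strict inequalities, so a voxel at exactly 2/3 desired
tissue is excluded. Necrosis is allowed to overlap the desired tissue
fraction — a necrotic tumor core is still tumor — which is why a voxel can
pass the tissue rule and fail the necrosis rule. The rules apply to the
nominal voxel's fractions; whether the enlarged effective voxel should be
used instead is unknowable from the emulated protocol, and nominal is
assumed. Tissue fractions are inputs (the study derives them by expert
visual matching on structural images, out of scope here); the synthetic
generator draws them directly, with a configurable proportion of violating
voxels.

## Cohort statistics

The statistics stage works on per-voxel values (no mixed-effects modelling
of voxel clustering within subject — the emulated analysis treats voxels as
units, and this package replicates that, which understates between-subject
uncertainty; a known limitation).

* **Outliers**: the ROUT procedure in its single-sample form — median
  centre, robust scale from the 68.27th percentile of absolute residuals
  (scaled by $n/(n-1)$), t-like statistics, and a sequential
  false-discovery-rate test from the most extreme point inward with
  threshold $Q(n-i+1)/n$. On clean data this flags about a fraction $Q$
  (default 1%) of points — the test suite checks the rate on 10⁴ null
  samples. Flagged values are masked per region and metric.
* **Normality**: a one-sample Kolmogorov–Smirnov screen with the Lilliefors
  correction (`nortest::lillie.test`), required because mean and SD are
  estimated from the sample; the screen documents (as in the emulated
  study) that the ratio samples are generally non-normal, motivating rank
  tests.
* **Group comparison**: Kruskal–Wallis omnibus (tie-corrected, via
  `stats::kruskal.test`) followed by Dunn's pairwise z-tests on mean ranks
  with tie correction. The multiplicity adjustment is Holm by default and
  switchable (`p.adjust` methods); the emulated analysis ran in software
  whose default post hoc is Dunn's, but its exact adjustment is not stated
  — this is an assumption, recorded here.
* **Correlations**: Spearman's rank coefficient with the t-approximation
  p-value, cross-checked against `stats::cor.test` in the tests.

## The synthetic cohort

`generate_cohort()` emulates the data structure the analysis assumes:
32 subjects, six region classes (contrast-enhancing tumor, T2-hyperintense,
adjacent, distant ipsilateral, contralateral, healthy-volunteer brain),
3 voxels per region per subject, spectra at SNR 20 (PCr spectral peak over
spectral noise SD), and a 20% rate of QC-violating voxels.

Ten ratios of five areas carry only four degrees of freedom, so the
generator draws **six primary metrics** per voxel — PCr/ATP, Pi/ATP,
PME/ATP, PDE/ATP, pH, Mg²⁺ — from truncated-normal marginals with the
regional means and SDs of the built-in truth table (`region_truth()`), and
derives the other six ratios per voxel. Consequently the derived ratios'
cohort means match their reference values only approximately (e.g. the
mean of a ratio of two noisy quantities exceeds the ratio of the means);
the `primary` column of the truth table records which four ratios are
matched exactly. Ratio marginals truncate at zero; pH at [6.8, 7.4] and
Mg²⁺ at [0.04, 0.5] mMol so that every draw is representable by the
calibrations and lies inside the fitter's shift windows.

Metric vectors become spectra through the exact inverse of the
quantification chain (`metrics_to_components()`): ATP area = per-voxel
scale (log-normal, SD 20%), PME split 45:55 over PC:PE, PDE split evenly,
MM and NAD(H) at 0.25 and 0.15 of the ATP area, dampings log-normal (SD
10%) around 20 1/s, pH and Mg²⁺ encoded as Pi and β-ATP shifts. A
noiseless roundtrip through synthesis, fitting and quantification
reproduces the input metrics to machine precision.

Diffusion metrics (ADC, b1000, FA) attach through a **Gaussian copula**:
each configured pair's Spearman target is converted to a latent Pearson
correlation via $\rho_P = 2\sin(\pi\rho_S/6)$, and the diffusion variable's
latent is built as a linear combination of the normal scores of its target
metrics (solving the score-covariance system when one diffusion variable
has several targets, with a small ridge and proportional attenuation if a
small sample renders the exact system infeasible). Because normal scores
are ranks, this imposes the rank correlation regardless of the marginals —
including for derived targets like PCr/Pi, which cannot be generated
directly. Diffusion marginal means and SDs per region are synthetic,
plausible values; only the rank correlations carry reference numbers.

What the generator deliberately does **not** emulate: baseline and
macromolecule variability beyond a single fixed-shift MM line, non-white
noise, B0 drift, eddy currents, non-Lorentzian lineshapes, partial-volume
mixing of region classes within a voxel, and within-subject correlation of
voxels. Passing tests therefore demonstrate correctness of the estimation
chain under the stated model, not robustness to every artefact of clinical
data.

## Problem sizes and reproducibility

The test suite and the acceptance script choose sizes that resolve each
question without waste: cohort recovery runs the full 32-subject, 3
voxel/region configuration for the tumor and contralateral regions (≈190
fitted spectra, under a minute with the analytic Jacobian); copula fidelity
uses n = 2000 per region; null calibrations use 2000 Kruskal–Wallis
replicates and 10⁴-point ROUT samples; PSF metrics use 32× oversampling
(512 points per in-plane axis). Every stochastic step takes an explicit
integer seed, and a pipeline rerun under the same seed and configuration
reproduces the metric tables bit-identically; `run_pipeline()` writes a
manifest with the seed, configuration and an MD5 hash per output file.
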