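---
title: "SLIM methods: demodulation, layered-skin Monte Carlo, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SLIM methods: demodulation, layered-skin Monte Carlo, and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Structured light imaging mesoscopy (SLIM) projects a single sinusoidal
intensity pattern onto tissue at three phase offsets, demodulates the three
camera images into a per-pixel AC amplitude, and calibrates that amplitude
against a reference phantom to obtain a map of diffuse reflectance
$R_d(\lambda, f_x)$ — no inverse model, no optical-property fit. Because the
modulated component of the illumination decays over a depth set by the
spatial frequency $f_x$, choosing $(\lambda, f_x)$ tunes the depth the map is
sensitive to. This package implements the full chain — image processing,
a layered-skin Monte Carlo forward model that identifies the most
perturbation-sensitive $(\lambda, f_x)$ pairs for dermal scattering changes
(the scleroderma use case), the cohort statistics used to separate patients
from controls, and synthetic-data generators that make every stage testable
without clinical data.

# Image processing

**Demodulation.** For phase images $I_1, I_2, I_3$ acquired at 0°, 120°,
240°,
$$I \;=\; \frac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2 + (I_2-I_3)^2 + (I_3-I_1)^2}.$$
For a pure three-phase sinusoid this recovers the modulation amplitude
exactly at every pixel, independent of the DC offset and the local pattern
phase; a common additive offset cancels and a common gain acts linearly.
These identities are enforced by property tests over random amplitude, DC,
frequency and phase.

**Calibration.** The instrument response (source profile, optics, camera
gain) is multiplicative on the AC amplitude, so the ratio of sample to
phantom amplitude, scaled by the phantom's predicted reflectance, removes
it:
$R_d = (I_\text{sample}/I_\text{phantom}) \cdot R_d^\text{phantom,model}$.
The phantom prediction can be a vendor value or computed by the bundled
Monte Carlo / diffusion models. Calibration is exact (to rounding) whenever
sample and phantom share the response field — the synthetic round trip in
the test suite checks recovery to $10^{-10}$.

**Height/angle correction.** Real limbs are not flat; the published
profilometry-based correction is instrument-specific and is deliberately
not reimplemented. `apply_correction()` accepts any externally computed
positive multiplicative field, and the tests exercise it with constructed
fields (a known cosine falloff and its reciprocal).

**ROIs.** Site defaults follow the clinical protocol: forearm 800×300 px,
hand 300×300 px, five finger ROIs of 100×25 px averaged with equal weight
into one representative value. The default pixel pitch, 0.14375 mm/px, is
the value implied by an 800×300 px ROI spanning ≈11.5×4.3 cm; it is carried
as metadata and never hard-coded in the math. Masked pixels (saturated
pixels, zero phantom signal) propagate as `NA` and are excluded from ROI
means.

# The four-layer skin model

`skin_model()` loads a bundled epidermis / papillary dermis / reticular
dermis / subcutaneous stack (50, 200, 1100, 6150 µm; total 7.5 mm) with the
standard composition values: dermal blood at 46.51 µM total hemoglobin
(37.21 HbO₂ / 9.302 HbR, checked to 0.1%), subcutaneous blood at 162.8 µM,
water and lipid fractions per layer, $g = 0.80$ (0.75 subcutaneous),
$n = 1.37$ epidermis / 1.40 below. Units are fixed package-wide: lengths mm
(layer thickness entered in µm and converted on load), coefficients mm⁻¹,
concentrations µM, wavelengths nm.

**Absorption** is assembled per wavelength from bundled extinction spectra
(oxy/deoxyhemoglobin molar extinction, pure-water, pure-lipid and
melanosome absorption). These are *approximate compilations* in the style
of the standard tissue-optics tabulations, shipped as two-column text files
with linear interpolation; they are adequate for the 650–900 nm window but
are not a metrological reference, which is why every layer also accepts
per-wavelength `mua_mm1` / `musp_mm1` values verbatim in the YAML config.
The blood volume fraction column is carried as documentation only — the
hemoglobin concentrations are used as given, not rescaled, to avoid
double-counting.

**Reduced scattering** uses the standard power law
$\mu_s'(\lambda) = a(\lambda/\lambda_\text{ref})^{-b}$. The dermal
parameters ($a = 2.8501$ mm⁻¹ at 691 nm, $b = 1.3305$) were calibrated once
so that the dermal transport mean free path $1/(\mu_a + \mu_s')$ equals the
two reference values for healthy dermis, 0.35 mm at 691 nm and 0.46 mm at
851 nm; epidermal ($a = 3.30$, $b = 1.40$) and subcutaneous
($a = 1.90$, $b = 0.70$) parameters are representative literature-style
values. The transport-mean-free-path convention adopted throughout is
$1/(\mu_a+\mu_s')$.

**Disease perturbation.** `apply_scleroderma_perturbation()` multiplies
$\mu_s'$ of the papillary and reticular dermis by 0.8 (a 20% reduction, the
magnitude suggested by scattering measurements in sclerodermatous skin and
consistent with the lower scattering of thin, embryonic-type collagen
fibrils) at every wavelength, leaving absorption, geometry and all other
layers bit-identical. **Melanin** enters as an epidermal melanosome volume
fraction (2, 5, 10%) scaling the melanosome absorption spectrum; the
simulation study applies it by perturbation-MC reweighting of a
melanin-free run rather than re-simulating (see below), and
`apply_melanin()` provides the direct variant used to validate the
reweighting.

# Monte Carlo engine

`simulate_pencil_beam()` launches photon packets normally onto the layer
stack and tracks them with the standard layered-slab algorithm:
exponential step sampling with $\mu_t = \mu_a + \mu_s$ where
$\mu_s = \mu_s'/(1-g)$; Henyey–Greenstein scattering via the closed-form
inverse (isotropic fallback at $g=0$); per-collision albedo weighting
(the packet keeps $\mu_s/\mu_t$ of its weight, the absorbed share is
tallied); unpolarized Fresnel reflection/refraction at every
index-mismatched interface, including the specular loss of the incident
beam; and Russian roulette below weight $10^{-4}$ with survival
probability 0.1 (survivor weight ×10). Detection is the full upward
hemisphere. The roulette's net weight change is folded into the absorbed
tally so that reflected + transmitted + absorbed + specular equals the
launched weight *exactly* per run (the estimator stays unbiased in
expectation); the energy-closure check in the tests asserts $<10^{-6}$ and
observes $\sim10^{-11}$.

**Reproducibility.** Each photon draws from its own RNG substream
(xoshiro256++ seeded by splitmix64 from the run seed and the photon index),
so identical `(model, wavelength, n_photons, seed)` give bit-identical
tallies and photon $i$ is reproducible independently of batching.

**Spatial-frequency reflectance.** All frequencies come from one
pencil-beam tally: the radially resolved exit weights are binned (512
uniform bins to 50 mm; overflow weight is kept in an edge bin so the DC
total is exact, with a coverage warning above 0.1%) and
$$R_d(f_x) = \sum_\text{photons} \frac{w_i}{N}\, J_0(2\pi f_x \rho_{c(i)}),$$
the discrete zeroth-order Hankel transform over bin centers. At $f_x = 0$
this reduces *exactly* to the total diffuse reflectance. This is
variance-efficient, standard for spatial-frequency-domain MC, and makes
"DC" literally $f_x = 0$.

**Depth statistics.** Each detected photon records the maximum depth
$z_\text{max}$ it reached. `pzmax_distribution()` accumulates the
frequency-weighted contributions into 25 µm depth bins spanning the full
7.5 mm model, so the distribution sums to $R_d(f_x)$ exactly at every
frequency (same weights — an exact partition). At $f_x > 0$ individual
deep bins can carry small negative weight because $J_0$ changes sign;
at $f_x = 0$ the distribution is nonnegative. `layer_contributions()`
integrates the perturbed-minus-baseline difference over each layer's depth
interval; the layer sums partition the total reflectance change.

**Perturbation MC.** For an absorption-only change $\Delta\mu_a$ in one
layer, each detected packet is reweighted by
$e^{-\Delta\mu_a L_\text{layer}}$ using its recorded per-layer path length;
scattering is untouched. This is exact in expectation for absorption
perturbations and lets one melanin-free run serve all three melanin levels.
The test suite and acceptance script verify pMC against direct simulation
of the perturbed model within 3 combined standard errors up to the 10%
melanin level (observed max |z| ≈ 1.8).

**Baseline-vs-perturbed grids.** `delta_rd_grid()` runs both models per
wavelength with a shared seed (common random numbers; an option disables
this). The standard error of the difference is reported conservatively as
the root sum of squares of the two run SEs — pairing per-photon
trajectories across models is not attempted, so the quoted SEs overstate
the CRN-reduced uncertainty. `optimal_fx()` takes the per-wavelength argmax
of $|\Delta R_d|$ with exact ties broken toward the lower frequency.

**Diffusion cross-check.** `diffusion_rd_fx()` implements the standard
spatial-frequency-domain diffusion reflectance of a homogeneous
semi-infinite medium,
$R_d(f_x) = 3Aa'/[(\mu_\text{eff}'/\mu_\text{tr}+1)(\mu_\text{eff}'/\mu_\text{tr}+3A)]$
with $\mu_\text{eff}' = \sqrt{3\mu_a\mu_\text{tr} + (2\pi f_x)^2}$. It is
used as an independent oracle for the engine *inside its validity domain*:
high albedo ($\mu_s'/\mu_a \ge 100$) **and** $f_x$ small against
$\mu_\text{tr}'$. The cross-check therefore uses a strongly scattering
medium ($\mu_s' = 5$ mm⁻¹, $\mu_a = 0.05$ mm⁻¹), where agreement at
$f_x \le 0.2$ mm⁻¹ is within 5% (observed ≤ 3%). At dermis-like
$\mu_s' \approx 2.5$ mm⁻¹ the $f_x = 0.2$ point sits at
$f_x/\mu_\text{tr}' \approx 0.08$ and the closed form itself deviates by
≈6% — a limitation of the approximation, not of the transport code, which
also matches an independently written Monte Carlo implementation at the
~0.1% level.

# The simulation study

`run_simulation_study()` reproduces the design of the forward study: the
baseline and dermis-perturbed models are simulated at 691, 731, 811,
851 nm; the eight-frequency grid {0 (DC), 0.05, 0.1, 0.15, 0.2, 0.3, 0.4,
0.5} mm⁻¹ is evaluated from each tally; melanin at 2/5/10% is applied by
pMC to both models. With the bundled model the most sensitive frequency
lies in [0.1, 0.2] mm⁻¹ at every wavelength and shifts toward lower $f_x$
at longer wavelengths — the spectral increase of the dermal transport mean
free path (0.35 → 0.46 mm from 691 to 851 nm) moves the scattering
sensitivity toward lower frequencies. Depth statistics at 851 nm /
0.15 mm⁻¹ attribute ≈95% of the reflectance contrast to the papillary +
reticular dermis, with minimal epidermal and subcutaneous contributions.
Photon budgets: the default is $10^6$ per (model, wavelength); the
acceptance script uses $10^6$ for the headline grid and $1$–$2\times10^5$
for the auxiliary cross-checks, and the test suite uses
$2\times10^3$–$1.5\times10^5$ — all with per-point standard errors reported
so the 3σ checks remain meaningful at these sizes.

# Cohort statistics

Observations for ROC analysis are site-level mean reflectances (each
measured site contributes one point, both sides of the body counted
separately, matching the clinical analysis); within-subject clustering is
deliberately not modeled and should be kept in mind when interpreting the
AUC — the heatmap study treats sites as exchangeable. Orientation is fixed
to *lower reflectance indicates patient* (scleroderma reduces $R_d$),
exposed as a flag.

- `roc_auc()` builds the threshold-classifier ROC and computes the AUC as
  the Mann–Whitney pair statistic (ties ½); the stored curve integrates to
  the same value to $10^{-10}$, and 500-instance brute-force enumeration
  backs the implementation.
- `delong_test()` compares two correlated AUCs via placement values:
  per-observation structural components give each AUC's variance and their
  covariance; the difference is referred to a standard normal. Degenerate
  zero-variance differences return $p = 1$ with a warning. The
  implementation is cross-checked against the reference implementation in
  the pROC package.
- `spearman_total()` sums the six site means into a per-subject total
  reflectance and the six site scores into a total skin score, then
  computes Spearman's ρ with average ranks. Rank scores are appropriate
  because the clinical score is ordinal (integers 0–3). By default only
  the patient group enters (the clinical convention; controls score 0
  everywhere and would mechanically inflate the correlation).
- `rank_sum_test()` is two-sided, exact for combined $n \le 12$ without
  ties, normal approximation with tie correction otherwise.
- `build_heatmaps()` fills the wavelength × frequency grid with AUC or ρ,
  reports the argmax cell(s) on $|{\cdot}|$, and supports stratification by
  a self-reported race column (a plain filter; no imputation). No
  multiple-testing correction is applied across the 32 cells by default;
  `rank_sum_grid(adjust = "bonferroni")` provides the corrected variant.

# Synthetic data

`gen_phase_stack()` inverts the demodulation forward model — three
sinusoids at 0/120/240° with configurable DC offset, modulation scale,
multiplicative instrument response, and additive Gaussian noise (negatives
clipped at zero with a logged count). Noise-free it closes the
demodulation and calibration round trips exactly.

`gen_cohort()` emulates the clinical cohort structure (25 patients vs 18
controls by default, six sites each, with a race column drawn in the
clinical proportions). Site reflectance is Gaussian with a subject-shared
noise component (default within-subject correlation 0.3 — the paper offers
no estimate, so a moderate value was chosen once and exposed in the
config); a standardized group difference $d$ (default 1.5) is planted at a
single designated grid cell. Gaussian noise and a Gaussian latent severity
were chosen deliberately: they give closed-form oracles
($E[\text{AUC}] = \Phi(d/\sqrt2)$ for uncorrelated sites) against which
the generator itself is tested. Patient site scores are produced by cutting
the same latent severity that drives the planted-cell reflectance at the
25/50/75% population quantiles into integers 0–3, then flipping one step
with probability 0.1 (ordinal palpation noise, mimicking the documented
interobserver variability of the clinical score); controls score 0
everywhere, the defined meaning of "no palpable thickening". With zero flip
probability the construction makes total reflectance and total score
inversely related by design.

What the generator does *not* emulate: spatial structure within ROIs
(cohort values are drawn at the ROI-mean level), instrument noise
correlated across phases, subject covariates beyond the race label, any
dependence of the effect size on disease stage, and missing-site patterns.
Passing tests therefore demonstrate the statistical machinery and the
processing chain, not clinical performance; the published clinical AUC and
correlation values depend on patient images that are not public and are
not reproduced here.

# Numerical choices and degenerate inputs

- Exact argmax ties in `optimal_fx()` break toward the lower frequency and
  the tie rule is recorded in the result's metadata.
- `hankel_rd()` on an empty tally, ROIs outside the image or fully masked,
  empty groups in the rank statistics, unpaired DeLong inputs, and depth
  edges that would drop weight all raise errors rather than degrade
  silently.
- Scattering-free layers are simulated correctly (first collision absorbs
  the full packet); zero-variance DeLong differences return $p = 1$ with a
  warning; `pmc_reweight(..., delta_mua = 0)` returns the tally
  bit-identically.
- TIFF rasters are stored as 32-bit samples scaled into the writer's [0, 1]
  range with the scale in the JSON sidecar and masks as a second page, so
  maps round-trip at single precision (~$10^{-7}$ relative).

# Known limitations

- The bundled extinction spectra and the epidermal/subcutaneous scattering
  power laws are approximate; analyses that depend on absolute optical
  properties should supply tabulated per-wavelength values in the config.
- Layer thicknesses do not change with disease stage, and the scattering
  perturbation is uniform over the dermis; perturbations confined to a
  single sublayer would shift the optimal imaging parameters.
- Geometry is a flat layered slab: curved surfaces are handled only through
  the image-space multiplicative correction interface, and no detector
  numerical aperture is modeled.
- AUC heatmaps treat site-level observations as independent; subject-level
  clustering widens the true uncertainty of the cell statistics.
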