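# slimr — structured light imaging mesoscopy in R

Structured light imaging mesoscopy (SLIM) is a noncontact optical technique
for mapping subsurface tissue changes: a sinusoidal light pattern of a
single spatial frequency is projected onto skin at three phase offsets
(0°, 120°, 240°), the three camera images are demodulated into a per-pixel
AC amplitude

    I = (√2 / 3) · √((I₁−I₂)² + (I₂−I₃)² + (I₃−I₁)²),

and calibrated against a phantom of known reflectance to yield maps of
diffuse reflectance R_d(λ, f_x) — with no inverse model. Because the
modulated illumination decays over a depth set by f_x, the wavelength /
spatial-frequency pair tunes which tissue depths the measurement is
sensitive to. In scleroderma (systemic sclerosis), collagen remodeling
lowers the reduced scattering coefficient μ_s′ of the papillary and
reticular dermis; choosing (λ, f_x) to target those depths makes R_d a
quantitative, observer-independent alternative to palpation-based skin
scoring (the modified Rodnan skin score, mRSS).

`slimr` is a toolkit for this whole workflow, aimed at biomedical-optics
researchers:

- **Image processing** — three-phase demodulation, phantom calibration, a
  pluggable multiplicative height/angle-correction interface, and
  ROI summaries (forearm / hand / five-finger averaging), with float-TIFF +
  JSON-sidecar IO.
- **Optical model** — a four-layer skin model (epidermis, papillary dermis,
  reticular dermis, subcutaneous tissue; 7.5 mm total) with chromophore-based
  absorption (hemoglobin, water, lipid, melanin) and power-law reduced
  scattering; the dermal spectrum is calibrated so the dermal transport mean
  free path 1/(μ_a + μ_s′) is 0.35 mm at 691 nm and 0.46 mm at 851 nm.
- **Monte Carlo engine** (Rcpp) — layered-slab photon transport
  (Henyey–Greenstein scattering, Fresnel interfaces, Russian roulette,
  per-photon RNG substreams, exact energy bookkeeping), spatial-frequency
  reflectance R_d(f_x) via a zeroth-order Hankel transform of one
  pencil-beam tally, maximum-penetration-depth (zmax) distributions that
  partition R_d(f_x) exactly, and perturbation-MC reweighting for epidermal
  melanin (2/5/10%).
- **Cohort statistics** — threshold-classifier ROC/AUC (Mann–Whitney pair
  counting), DeLong correlated-AUC comparison, Spearman correlation of total
  R_d with total mRSS, Wilcoxon rank-sum tests, and λ×f_x heatmaps with race
  stratification.
- **Synthetic data** — phase-stack and cohort generators with known ground
  truth and closed-form oracles, so the full pipeline is testable without
  clinical data.

## Worked example

Build the bundled skin model, apply the 20% dermal scattering reduction,
and find the most perturbation-sensitive spatial frequency per wavelength:

```r
library(slimr)

model <- skin_model()
model
#> <tissue_model 'baseline'> 4 layers, total 7.5 mm, melanin 0%
#>  wavelengths: 691, 731, 811, 851 nm
#>             layer thickness_mm    g    n    691    731    811    851
#>         epidermis         0.05 0.80 1.37 3.3000 3.0500 2.6373 2.4654
#>  papillary_dermis         0.20 0.80 1.40 2.8501 2.6445 2.3032 2.1603
#>  reticular_dermis         1.10 0.80 1.40 2.8501 2.6445 2.3032 2.1603
#>      subcutaneous         6.15 0.75 1.40 1.9000 1.8266 1.6985 1.6422

round(transport_mfp(model$mua["papillary_dermis", c("691", "851")],
                    model$musp["papillary_dermis", c("691", "851")]), 2)
#>  691  851
#> 0.35 0.46

scler <- apply_scleroderma_perturbation(model, factor = 0.8)
grid <- delta_rd_grid(model, scler, n_photons = 1e5, seed = 1,
                      melanin_level = 0.02)
grid
#> <delta_rd_grid> melanin 2%, 1e+05 photons per run
#>            0     0.05      0.1     0.15      0.2      0.3      0.4      0.5
#> 691 -0.01621 -0.02819 -0.04352 -0.05031 -0.05061 -0.04317 -0.03467 -0.02758
#> 731 -0.01692 -0.02962 -0.04458 -0.04973 -0.04897 -0.04065 -0.03147 -0.02423
#> 811 -0.01967 -0.03258 -0.04804 -0.05141 -0.04838 -0.03753 -0.02645 -0.01976
#> 851 -0.02271 -0.03420 -0.04700 -0.04989 -0.04635 -0.03533 -0.02584 -0.01916

optimal_fx(grid)
#>  691  731  811  851
#> 0.20 0.15 0.15 0.15
```

The dermal scattering reduction lowers reflectance everywhere (ΔR_d < 0),
the effect peaks between 0.1 and 0.2 mm⁻¹, and the optimum shifts to lower
frequency at longer wavelengths — the dermal transport mean free path grows
from 0.35 to 0.46 mm across this range, moving the depth of maximal
sensitivity.

Cohort statistics on a synthetic cohort with a planted effect at
(851 nm, 0.15 mm⁻¹), effect size d = 1.5, 25 patients vs 18 controls:

```r
co <- gen_cohort(n_patient = 25, n_control = 18, effect_size_d = 1.5,
                 wavelengths = c(811, 851),
                 spatial_frequencies = c(0.1, 0.15, 0.2),
                 effect_cell = c(851, 0.15), seed = 7)
build_heatmaps(co, "auc")
#> <heatmap_grid> auc (stratum: all)
#>       0.1  0.15   0.2
#> 811 0.465 0.483 0.396
#> 851 0.407 0.816 0.410
#> argmax:
#>  wavelength spatial_frequency     value
#>         851              0.15 0.8158025

spearman_total(co, 851, 0.15)$rho
#> [1] -0.9019669
```

The heatmap recovers the planted cell (site-level AUC 0.82 ≈ Φ(1.5/√2),
chance elsewhere), and total reflectance correlates negatively with the
total skin score, as the generative model dictates.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/slim.R simulate --config cfg.yaml --out-dir out --seed 1
Rscript inst/cli/slim.R synth    --config cfg.yaml --out-dir out --seed 1
Rscript inst/cli/slim.R process  --config cfg.yaml --out-dir out
Rscript inst/cli/slim.R stats    --cohort out/cohort.csv --out-dir out
```

Every run writes a JSON manifest (config hash, seed, package version,
output digests).

## Package layout

```
R/                  modules: optical model, MC engine, image processing,
                    cohort statistics, synthetic data, pipeline runners
src/mc.cpp          layered-slab Monte Carlo kernel (Rcpp)
inst/extdata/       bundled extinction spectra and the four-layer skin model
inst/cli/slim.R     command-line front end
vignettes/          methods vignette (model, numerics, design choices)
tests/testthat/     unit, property and acceptance test suites
scripts/acceptance.R
```
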