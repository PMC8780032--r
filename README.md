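# aquapolar

Aquaphotomics of polarized near-infrared interactance spectra of fruit.

Short-wave NIR (800–1050 nm) spectra of kiwifruit are dominated by the
second overtone of water. Aquaphotomics reads this region through twelve
water matrix coordinates (WAMACS, bands C1–C12): C1–C5 respond to free
water species, C6–C12 to bound species (S0–S4 = 0–4 hydrogen bonds).
`aquapolar` implements, for the four measurement configurations
Unpeeled/Peeled × Unpolarized/Polarized (UU, UP, PU, PP):

* absorbance conversion `A(λ) = log10(I_ref(λ)/I(λ))`, standard normal
  variate (SNV) and Savitzky–Golay second-derivative preprocessing
  (7-point window, 2nd-order polynomial);
* PCA (SVD with deterministic signs) with loading-extrema extraction;
* the WAMACS band table, SSC (soluble solids content) grouping
  (Low < 12, Medium [12, 15), High ≥ 15 °Brix), SSC difference spectra,
  and three-source activated-wavelength selection;
* aquagrams: the relative-SNV transform
  `A'_λ = (A_λ − μ_λ)/σ_λ` with μ, σ pooled over all samples of all
  configurations, averaged per display group and drawn as radar charts;
* a seeded forward simulator (fruit phantoms with Gaussian WAMACS bands,
  surface-layer polarization retention with co-polarized detection
  `I_co = I_∥ + ½ I_⊥`, skin scattering, SSC-dependent free→bound band
  migration, multiplicative scan noise) so the whole chain is verifiable
  against known injected effects.

It is aimed at chemometricians and postharvest researchers who want the
aquaphotomics chain as tested, reusable functions rather than ad hoc
scripts.

## Worked example

The `analysis/` scripts run the whole study as a numbered workflow
(`Rscript analysis/01_simulate.R` … `05_aquagrams.R`, outputs under
`results/analysis/`). The same chain in a few lines:

```r
library(aquapolar)

pop   <- simulate_population(simulation_design(n_fruit = 200, seed = 42))
ab    <- to_absorbance_set(pop$spectra, pop$references)
snv2d <- run_plan(ab, preprocess_plan())          # SNV then SG(7,2) 2nd deriv

tapply(rowMeans(ab$matrix), ab$sample_table$configuration, mean)
#>     UU     UP     PU     PP
#> 0.8425 0.8837 0.8617 0.9200
```

Mean absorbance rises with the polarizer (UP > UU, PP > PU) and with
peeling (PU > UU, PP > UP), as expected when the analyzer discards light
and cut tissue exposes water-rich flesh.

```r
pca <- fit_pca(snv2d, n_components = 3)
pca$explained_variance_pct[1:3]
#> 86.64  6.19  1.67
```

PC1 carries 86.6 % of the variance and separates the polarized from the
unpolarized configurations (3.0 % overlap at the midpoint threshold).

```r
std  <- relative_snv(aquagram_input(snv2d, published_activated_wavelengths()))
prof <- aquagram_by_configuration(std)
render_aquagram(prof, "aquagram.png")
```

The per-band difference (mean polarized − mean unpolarized standardized
value) printed by `analysis/05_aquagrams.R`:

```
   C1    C2    C3    C4    C5    C6     C7     C8     C9    C10   C11   C12
 1.72  1.27  1.04  0.94  1.47 -1.64  -1.71  -1.37  -1.90  -0.32  1.65  1.39
```

Positive on the free-water bands C1–C5 and the strongly bonded C11–C12,
negative on the bound bands C6–C10: polarized light preferentially
activates free water states. The SSC-group aquagrams show Low > High on
all five free bands and High > Low on all five bound bands in every
configuration — free-water alignment falls as sugar content rises,
independently of the polarization contrast.

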