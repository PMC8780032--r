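---
title: "Aquaphotomics of polarized NIR interactance spectra: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aquaphotomics of polarized NIR interactance spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquapolar)
```

## The problem

Short-wave near-infrared (800–1050 nm) interactance spectra of fruit are
dominated by the second overtone of the water OH stretch. Aquaphotomics
reads this region through twelve water matrix coordinates (WAMACS), bands
C1–C12 that respond to perturbations of the water hydrogen-bond network:
C1–C5 track free water species and C6–C12 bound species (S0–S4 denote 0–4
hydrogen bonds). When kiwifruit are measured under four configurations —
Unpeeled/Peeled crossed with Unpolarized/Polarized detection (UU, UP, PU,
PP) — the question is which water states the polarizer and the skin
emphasise, and whether soluble solids content (SSC) confounds that contrast.

`aquapolar` implements the full analysis chain as a tested package, and a
forward simulator that generates fruit phantoms with *known* injected
effects so every step of the chain can be verified quantitatively — which
is never possible with a field dataset alone.

## The analysis chain

1. **Absorbance.** Interactance intensities are normalised by a
   per-configuration reference scan and converted as
   $A(\lambda) = \log_{10}\!\bigl(I_{\mathrm{ref}}(\lambda)/I(\lambda)\bigr)$,
   so water bands appear as positive peaks.
2. **SNV.** Each spectrum is standardized (mean 0, sd 1 over wavelengths;
   sample $n-1$ denominator throughout the package), removing
   multiplicative scatter and offset differences.
3. **Second derivative (SNV + 2D).** A Savitzky–Golay filter, 7-point
   window and second-order polynomial, sharpens the heavily overlapped
   bands. An absorption band appears as a *negative* second-derivative
   feature at its centre.
4. **PCA.** Singular-value decomposition of the column-centered SNV+2D
   matrix; the first three components' loadings and scores are examined,
   and loading extrema in 900–1020 nm are wavelength candidates.
5. **Activated wavelengths.** For each WAMACS band, candidates are pooled
   from three sources — PCA loading extrema, extrema of each
   configuration's mean SNV+2D spectrum, and extrema of the SSC difference
   spectra (Low-group mean minus each group mean) — and the candidate of
   largest magnitude wins.
6. **Aquagram.** At the activated wavelengths the preprocessed absorbance
   is standardized *across all samples of all configurations*,
   $A'_\lambda = (A_\lambda - \mu_\lambda)/\sigma_\lambda$,
   and group means (per configuration, or per SSC group within a
   configuration) are displayed on a C1→C12 radar chart.

## The forward model

Each phantom fruit carries a 12-vector of band absorption weights, an SSC
value with stem/blossom-end readings, a dry-matter fraction with slice
weights, and a flat skin-scatter term. Its absorbance profile is a sum of
Gaussians at the WAMACS band midpoints (sd 6 nm) over a broad water
envelope (970 nm, sd 35 nm). Gaussian line shapes are a modelling choice:
the profile stays linear in the amplitudes and smooth, which makes the
injected effects analytically traceable; no claim of radiative-transfer
realism is made.

The optical signal is split into a shallow layer — order 1 mm, where
polarization is retained — carrying fraction $w$ (`depol_surface_weight`,
default 0.4) of the signal, and a deep layer whose light is fully
depolarized. Configuration-dependent band modifiers (the 4 × 12 *effect
matrix*) act on the shallow layer only; the deep profile is configuration
independent. Polarized configurations detect the co-polarized intensity
$I_{co}(\lambda) = I_\parallel(\lambda) + \tfrac12 I_\perp(\lambda)$
(the analyzer passes the polarization-retaining component and half of the
depolarized light; the ½ is exposed as `copol_fraction`). The reference
scan for a polarized configuration passes through the same optics, so
analyzer attenuation cancels in absorbance; with $w = 0$ the polarized and
unpolarized absorbance coincide bit-exactly — fully depolarized light
interacts identically, which the test suite asserts.

Unpeeled configurations add the fruit's flat skin baseline (default
0.02 AU). SSC drives a free→bound migration: band weights of C1–C5 scale
by $e^{-r\,\Delta S}$ and C6–C10 by $e^{+r\,\Delta S}$ about the mid-range
SSC ($r$ = `ssc_shift_rate`, default 0.015 per °Brix), so free-water
alignment falls and bound-water alignment rises with sugar content. Scan
noise is multiplicative i.i.d. Gaussian (0.5 % per scan, five scans
averaged); SSC is uniform on 7–20.5 °Brix across 200 fruit.

### Why these defaults

The simulator's defaults are the package's definition of the study
conditions, chosen once so that the known qualitative contrasts are
injected with enough margin to be recovered by the chain:

* **Base band amplitudes** `r paste(default_base_amplitudes(), collapse = ", ")`
  (C1–C12). With 6 nm Gaussians only ~7–15 nm apart and an 18 nm (7-point)
  derivative window, a weak band sitting between two strong neighbours
  lands on a *positive* curvature saddle and its displayed sign flips. The
  amplitudes are balanced so every band keeps a locally negative SNV+2D
  feature at its activated wavelength — i.e. each injected band is
  individually recoverable. C10 in particular must outweigh the wing of
  the polarization-boosted C11 at 995 nm.
* **Effect matrix.** Polarized detection tilts the shallow profile ×1.5 on
  C1–C5 and C11–C12 and ×0.7 on C6–C10; peeling boosts C6–C12 ×1.15.
  Small global uplifts (polarized ×1.10, peeled ×1.15) set the raw
  mean-absorbance orderings (polarized > unpolarized, peeled > unpeeled)
  without touching SNV-normalised shapes, in which uniform per-spectrum
  factors cancel. The tilt magnitude is set so the polarization contrast
  dominates the SSC-driven variation: the two act along nearly opposite
  spectral directions (free up/bound down vs free down/bound up), and only
  when polarization dominates does PC1 cleanly separate the polarized from
  the unpolarized configurations, as observed on real fruit.
* **Per-fruit amplitude variation** is lognormal with 2 % CV. Larger
  values bury the configuration contrast in fruit-to-fruit variance;
  biological variation in relative band weights (as opposed to overall
  water content, which SNV removes) is plausibly this small.
* **Skin baseline 0.02 AU.** A flat term; it must stay below the
  surface-diluted peel band gain or the raw absorbance ordering
  peeled > unpeeled inverts.

## Numerical choices

* **SG derivative scale** is per (grid step)², making polynomial
  reproduction exact (`y = x²` in step units returns exactly 2);
  `per_nm = TRUE` divides by the step squared. Edge points come from the
  one-sided polynomial fit of the boundary window, so output length equals
  input length.
* **"Window width of 7"** is interpreted as 7 grid points (a
  Savitzky–Golay window is defined in points; on the default 3 nm grid a
  literal 7 nm cannot be an odd point count). The window is configurable.
* **PCA signs** are fixed by making the largest-|value| loading element
  positive, so runs are bit-reproducible.
* **Extrema** are strict (greater/less than both neighbours); plateaus
  report their leftmost point.
* **Band intervals** are closed; the single endpoint shared by C10 and C11
  (998 nm) resolves to the upper band, C11 — the only convention under
  which every published activated wavelength (including 1007 nm, C11's
  upper limit) maps into its band.
* **SSC groups** close the gaps left by the printed ranges:
  Low < 12, Medium [12, 15), High ≥ 15 °Brix.
* **Source standardization in selection**: each candidate curve is scaled
  to unit maximum |value| before magnitudes compete, so selection is
  invariant to positive rescaling of any source and to source order; ties
  break to the lower wavelength. PCA components explaining < 1e-6 % of
  variance are skipped as numerically null.
* **Aquagram sign** (`negate_2d`, default on): second-derivative values
  are negated for display so that greater absorbance plots outward; the
  flag's state is recorded in all outputs.
* **Activated wavelengths off the grid** (e.g. 903 or 933 nm on the 3 nm
  grid) snap to the nearest grid column; both requested and used
  wavelengths are recorded.

## What the simulator does and does not emulate

It emulates: the four-configuration design with per-configuration
references, five-scan averaging, multiplicative scan noise, skin
scattering as a flat loss, surface-vs-depth polarization retention with
co-polarized detection, SSC-dependent free/bound migration, and
destructive reference values (DMC as dry/wet weight, SSC as the mean of
the two end readings).

It does not emulate: real radiative transport or scattering phase
functions, starch birefringence, temperature effects on the water bands,
instrument bandwidth/stray light, or skin optics beyond a scalar term.
Passing pattern tests therefore shows the *chain* recovers what was
injected under controlled conditions — not that real kiwifruit behave this
way; the published group sizes and variance splits from real fruit are not
reproduction targets.

## Problem sizes

Tests run the full chain at 200 fruit × 4 configurations (800 spectra × 84
wavelengths) for the pattern checks — across five seeds for the
polarization orderings — and smaller populations (4–60 fruit) for unit
checks; the oracle comparisons use 20 × 10 matrices against a brute-force
covariance eigendecomposition. `scripts/acceptance.R` regenerates all
headline quantities from scratch in well under a minute.

## Known limitations

* Data-driven selection can leave a narrow band (e.g. C2, 916–920 nm)
  without an in-band extremum on a given dataset; the band is then omitted
  with a warning. The published activated wavelengths are available as a
  fixed alternative (`selection = "published"`).
* With uniform SSC sampling the three SSC groups are unequal (Medium is
  the narrowest interval); group sizes are not forced to the published
  counts.
* The aquagram basis is SNV+2D by default and SNV-only by configuration;
  which variant fed the published radar charts is not stated in the
  literature this package follows.
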