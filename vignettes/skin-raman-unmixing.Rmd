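---
title: "Constrained MCR-ALS unmixing of skin Raman spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained MCR-ALS unmixing of skin Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmcr)
```

## The model and its assumptions

A set of `n` Raman spectra measured on `J` wavenumbers is modeled as a
bilinear mixture of `A` pure components,

$$D = C\,S^{\mathsf T} + E,$$

with non-negative concentrations `C` (n × A), non-negative component
spectra `S` (A × J) and residual `E`. The assumptions this buys and their
price:

* **Linearity.** Each measured spectrum is a concentration-weighted sum of
  fixed component spectra. This holds for dilute Raman scattering; it does
  not hold for self-absorption or strongly layered tissue, which this
  package does not model.
* **Common basis.** All samples share one set of component spectra. Tissue
  heterogeneity beyond concentration changes (peak shifts, width changes)
  ends up in `E` or distorts the resolved spectra.
* **Rotational/scale ambiguity.** `C S^T = (C R)(R^{-1} S^T)` for any
  invertible `R` compatible with the constraints. Non-negativity restricts
  the ambiguity, closure removes the per-component scale, and equality
  constraints (a fixed basis) remove it entirely for the fixed rows. All
  recovery claims in the tests are therefore phrased *after* optimal
  component matching (exhaustive permutation search for A ≤ 8) and are
  about correlations, not absolute scales.

## The alternating scheme

Each iteration performs four exact steps: (1) `C` given `S` by per-sample
non-negative least squares; (2) the free rows of `S` given `C` by
per-wavenumber NNLS on the residual left by the fixed rows; (3) equality
constraints re-imposed; (4) equal-area closure of the free rows with the
scale factors absorbed into `C`. Steps 1–2 are exact constrained
least-squares solves, steps 3–4 do not change the data fit (fixed rows are
never re-estimated, closure is a pure reparameterization), so the residual
sum of squares is non-increasing — this monotonicity is asserted to a
1e-9 relative tolerance in the tests rather than assumed.

The NNLS subproblems are solved by an active-set method on the
precomputed normal equations (the fast-NNLS formulation), which makes the
per-iteration cost one Gram matrix per half-step plus many small
(A × A) solves. Exactness matters here: a clip-negatives heuristic would
break the monotonicity property that the whole convergence story rests
on, so the "mild constraint" soft variant was deliberately not made the
default.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_components` | — | count | chosen per analysis; see rank scan |
| `allowed_noise_pct` | 10 | % of max row mean | SIMPLISMA purity offset; standard default, keeps low-mean noisy rows from looking "pure" |
| `max_iter` | 150 | iterations | conventional cap for this workflow |
| `conv_tol_pct` | 0.1 | % change of residual SD | conventional default; at low SNR the residual is noise-dominated and this stops within ~5–10 iterations |
| `closure` | equal_area | — | removes scale indeterminacy; applied to spectra, absorbed into C |
| `divergence_patience` | 3 | iterations | not part of the standard recipe; defined here as 3 consecutive residual-SD increases, returning the best model so far |
| AsLS `lam` | 6 → 1e6 | log10 of penalty | follows the R `baseline` package convention, where the printed "lambda = 6" means 10^6; a flag restores the raw interpretation |
| AsLS `p` | 0.1 | weight | asymmetry: points above the baseline get weight 0.1, below 0.9 |
| Savitzky–Golay | 15 / 1 / 0 | points / order / deriv | conventional probe-workflow smoothing; on a 2 cm⁻¹ grid the window is 28 cm⁻¹, below the narrowest band width used (30 cm⁻¹) |

SIMPLISMA runs in the *sample* direction (purest rows of `D` become the
initial spectral estimates) because the first half-step solves for `C`;
the purity is `sd/(mean + offset)` with determinant re-weighting against
the already-selected rows. Ties break to the lowest index.

## What the synthetic generator emulates — and what it does not

The generator states a world emulating a realistic probe-based clinical
cohort: 1000 spectra
in five classes (540 NS, 113 K, 122 BCC, 67 MM, 158 PN), 785 nm
excitation, a 1114–1874 cm⁻¹ working grid at 2 cm⁻¹ (792–1874 cm⁻¹ in raw
mode), four components with literature band positions (melanin 1390/1520;
proteins 1150/1280/1450/1660 with 1450 dominant; water 1650 broad;
NMF/lipids 1174/1230/1750 plus a 1700–1850 cm⁻¹ band), a smooth
exponential fluorescence pedestal, an additive sinusoid of ~3 nm period
defined on the wavelength axis (etalon fringes), and Gaussian noise
scaled so max clean Raman peak / noise SD = 3.

Stated choices where no value was published, decided once:

* **Line shapes** default to Lorentzian; the two broad melanin bands are
  Gaussian so that the rendered sum actually peaks at the stated 1390 and
  1520 cm⁻¹ (fat Lorentzian tails at 130 cm⁻¹ separation pull the
  maximum ~5 cm⁻¹ inward, violating the band-position contract).
* **Concentrations** are zero-truncated normals with cv 0.25; class means
  put melanin high in K/MM/PN and low in NS/BCC, protein slightly reduced
  in BCC. Real cohorts add comorbidity and phenotype structure that this
  does not attempt.
* **Fluorescence amplitude** is a free parameter (default 2× the unit
  component scale) — its ratio to the Raman signal was never quantified.
* **SNR definition**: max clean Raman peak over noise SD, recorded in the
  output metadata; the dataset generator uses the dataset-wide clean
  maximum so all spectra share one noise floor, as a detector would.

A green test on this generator establishes *algorithmic* correctness
(constraint handling, convergence behavior, recoverability when the data
support it). It does not establish clinical performance: real skin spectra
have component spectra that drift between patients, non-Gaussian noise,
and no ground-truth concentrations at all.

## Numerical choices

* AsLS solves `(W + λ DᵀD) z = W y` with a sparse second-difference matrix
  on interior points (J−2 rows, edges unpenalized); constants and straight
  lines are in the penalty null space and reproduced to 1e-6.
* Savitzky–Golay edge points evaluate the polynomial fitted to the
  first/last full window at the edge offsets (the "interp" convention).
* The rank scan does **not** mean-center before the SVD — closure handles
  scale inside MCR, and centering would remove the mean-spectrum direction
  that the first component legitimately models.
* Floating-point ties in purity selection break to the lowest index;
  an all-zero free initial spectrum is reset to the uniform row.
* An exact fit (residual SD below 1e-12 of the data SD) sets the
  convergence flag immediately — the relative-change rule is 0/0 there.
* A free component whose spectrum collapses to zero area raises an error
  naming the component: it means the chosen `A` exceeds what the data
  support (e.g. a noiseless fit with a complete basis and extra free
  components, which the tests assert errors rather than limps on).

## Open design points, decided

* **Effective excitation wavelength.** Instrument software commonly quotes
  rounded range endpoints (e.g. 792/1114/1874 cm⁻¹ for 837/860/920 nm at
  785 nm excitation) that disagree with the closed form, which gives
  791.4/1110.9/1869.3. The converter takes the excitation wavelength as an
  explicit parameter and makes no attempt to reproduce rounded endpoints;
  tests pin the closed form.
* **Fit-metric pair.** Lack of fit and explained variation are linked by
  `explained = 100·(1 − (lof/100)²)`; the package asserts this identity on
  its own output. (Pairs reported by GUI tools can violate it because the
  two numbers may use different denominators; both standard definitions
  are reported here instead.)
* **Logistic predictors** enter unstandardized (a flag standardizes);
  all components are used with no variable selection and no
  multiple-testing correction, mirroring the usual reporting convention.
* **PLS-DA latent count** defaults to an inner-CV sweep over 1..10
  maximizing out-of-fold AUC, logged in the result, since no published
  value exists.
* **DeLong CI** is the default interval (it is what the standard ROC
  tooling computes); its 93–97% empirical coverage at n = 30+30 nulls is
  part of the acceptance suite.

## Known limitations, and one deliberately red criterion

The acceptance suite asserts, among other things, that at SNR 3 with
1000 samples a 4-component unconstrained fit recovers all component
spectra with matched r ≥ 0.90. In the stated world this is
information-theoretically unattainable, and the criterion is left red
rather than weakened: with noise SD = max clean peak / 3 and
concentration cv 0.25, the 3rd and 4th signal singular values
(≈ 56, 55 at n = 1000, J = 381) sit at the noise floor (≈ 55). The
principal angles between the true spectral rowspace and the best rank-4
subspace of the data are 2°, 14°, 51°, 87° — even an oracle projection
cannot see the weakest component (projected r ≈ 0.30), and ALS started
*at the truth* drifts away from it. Smoothing does not rescue this:
the noise inside the signal passband is untouched. The measured matched
correlations under the stated conditions are about 0.96 (melanin),
0.90 (proteins), 0.88 (water) and 0.71 (NMF/lipids) — the strongly
expressed components are recovered, the weakest is buried. Published
robustness claim comes from designed mixtures with much larger
concentration ranges; at cv 0.25 around a positive mean the minor
components are simply buried. This is exactly the kind of statement the
basis-constrained design exists for: with the four spectra fixed, the
per-sample concentration estimation is a well-posed NNLS regression and
the melanin contrast reaches AUC > 0.9 end to end (criterion 9, green).

Other limitations: no cosmic-ray spikes, no wavenumber/intensity
calibration, no layered-tissue optics, no multiclass classifiers, no
rotation-ambiguity bands on the resolved spectra.
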