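# ramanmcr

Gray-box chemometric analysis of in vivo skin Raman spectra in R:
constrained multivariate curve resolution by alternating least squares
(MCR-ALS), the surrounding preprocessing, and classification of the
resolved concentration profiles — all testable against a synthetic
skin-Raman generator with known ground truth.

## The problem

Raman spectra of skin recorded in vivo with portable probe systems are a
superposition of the spectra of many constituents (melanin, proteins,
water, lipids, the natural moisturizing factor) plus a strong fluorescence
background, a sinusoidal etalon ripple from the back-thinned CCD, and
noise at a signal-to-noise ratio around 3. For diagnostic work one wants
the contribution of each constituent per spectrum, not just a black-box
class prediction.

`ramanmcr` models a set of spectra as the bilinear mixture

    D = C S^T + E

where `D` (samples x wavenumbers) holds the measured spectra, `S` the
pure-component spectra, `C` the component concentrations (arbitrary
units) and `E` the residual. The factorization is estimated by
alternating constrained least squares:

* **initialization** — SIMPLISMA pure-sample selection with purity
  `p_i = sigma_i / (mu_i + alpha)`, offset `alpha` = 10% of the largest
  row mean by default;
* **non-negativity** on `C` and `S`, enforced exactly by an active-set
  fast NNLS on the normal equations;
* **closure** — equal spectral-area normalization of each free spectrum
  (row sum 1), the scale absorbed into `C` so `C S^T` is unchanged;
* **equality constraints** — known spectra can be fixed exactly
  (`NA` sentinel rows mark free components), the "basis" design;
* **stopping** — convergence when the residual standard deviation changes
  by at most 0.1% between iterations, a 150-iteration cap, and divergence
  detection (3 consecutive residual increases).

Fit quality is reported as lack of fit `100 * sqrt(sum(E^2)/sum(D^2))`
and explained variation `100 * (1 - sum(E^2)/sum(D^2))`.

Downstream, resolved concentration profiles are scored by per-component
ROC/AUC with DeLong 95% intervals, binary logistic regression with Wald
predictor significance, and PLS-DA with stratified 10-fold
cross-validation, over the standard contrast battery of a five-class
cohort (normal skin NS, keratosis K, basal cell carcinoma BCC, malignant
melanoma MM, pigmented nevus PN).

## Worked example

```r
library(ramanmcr)

# 1. a synthetic cohort: 1000 spectra (540 NS, 113 K, 122 BCC, 67 MM,
#    158 PN), 4 skin components, fluorescence + etalon ripple, SNR 3
ds <- simulate_dataset(default_class_profiles(),
                       acquisition = acquisition_model(target_snr = 3),
                       seed = 1)

# 2. preprocessing: crop to 1114-1874 cm^-1, asymmetric-least-squares
#    baseline removal (lambda = 6, p = 0.1, 10 iterations),
#    Savitzky-Golay smoothing (window 15, order 1)
pp <- preprocess_spectra(ds$spectra)

# 3. how many components does the data support?
scan_rank(pp, max_rank = 10)
#> rank_scan: suggested rank 1 (drop_ratio); drop heuristic 1, floor heuristic 10
#> leading singular values: 470.18  58.60  33.95  29.60  25.99  25.71 ...

# 4. basis-constrained unmixing: 4 fixed + 4 free components
m <- fit_with_basis(pp, ds$s_true, n_free = 4, seed = 1)
m
#> component_model: 1000 samples x 8 components (4 fixed), 7 iterations, converged
#> lack of fit 22.7013%, explained variation 94.8465%

# 5. does resolved melanin separate pigmented from non-pigmented classes?
pig <- as.integer(pp$labels %in% c("K", "MM", "PN"))
roc_auc(m$concentrations[, "melanin"], pig)
#> AUC 0.947 (0.933-0.961, 95% CI), n_pos 338, n_neg 662
```

The scree shows the gradual decay typical of low-SNR skin spectra: no
abrupt drop after the leading direction, so the drop-ratio heuristic
suggests 1 while the relative-floor count keeps everything above the
noise shoulder — rank choice ultimately rests on prior knowledge, which
is exactly why the basis-constrained design below fixes the four known
spectra instead.

The lack of fit is dominated by the SNR-3 noise floor (noise is not
explainable by an 8-component bilinear model); the melanin concentration
column nevertheless separates the pigmented classes cleanly, which is the
point of the basis-constrained design.

Scenario presets (`pipeline_config` + `run_scenario`) reproduce the three
experiment designs — raw spectra unmixed into 9 components, a 4..30
component sweep on preprocessed normal-skin spectra, and the 8-component
basis-constrained fit with the classification battery — writing CSV/JSON
artifacts and a checksum manifest; reruns with the same seed are
byte-identical. A minimal CLI wraps them:

```sh
Rscript -e 'ramanmcr::raman_cli()' run --scenario basis_constrained_8 \
        --seed 1 --n-scale 0.1 --out artifacts/
```

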