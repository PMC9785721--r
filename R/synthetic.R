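#' Peak specification
#'
#' A single Raman band: Lorentzian (default, the natural Raman line shape) or
#' Gaussian, parameterized by center, full width at half maximum and relative
#' amplitude.
#'
#' @param center band center, cm^-1.
#' @param fwhm full width at half maximum, cm^-1 (> 0).
#' @param amplitude peak height, arbitrary units (>= 0).
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, fwhm, amplitude = 1,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape), class = "peak_spec")
}

render_peak <- function(peak, grid) {
  if (peak$shape == "lorentzian") {
    hw <- peak$fwhm / 2
    peak$amplitude * hw^2 / ((grid - peak$center)^2 + hw^2)
  } else {
    sigma <- peak$fwhm / (2 * sqrt(2 * log(2)))
    peak$amplitude * exp(-(grid - peak$center)^2 / (2 * sigma^2))
  }
}

#' Pure-component spectrum specification
#'
#' A named set of peaks plus an optional smooth broadband pedestal; rendered
#' on a wavenumber grid it gives one row of the ground-truth spectra matrix S.
#'
#' @param name component label, e.g. `"melanin"`.
#' @param peaks list of [peak_spec] objects.
#' @param broadband pedestal amplitude added uniformly (>= 0).
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, peaks, broadband = 0) {
  if (broadband < 0) stop("broadband pedestal must be >= 0")
  if (length(peaks) == 0 && broadband == 0)
    stop("component needs at least one peak or a nonzero pedestal")
  structure(list(name = name, peaks = peaks, broadband = broadband),
            class = "component_spec")
}

#' Render a component spectrum on a grid
#'
#' @param spec a [component_spec].
#' @param grid strictly increasing wavenumber axis, cm^-1.
#' @return Non-negative numeric vector, one intensity per grid point.
#' @export
render_component <- function(spec, grid) {
  for (p in spec$peaks) {
    if (p$center < min(grid) || p$center > max(grid))
      stop("grid does not cover the ", spec$name, " peak at ",
           p$center, " cm^-1")
  }
  y <- rep(spec$broadband, length(grid))
  for (p in spec$peaks) y <- y + render_peak(p, grid)
  y
}

#' Default skin component library
#'
#' Renders the four interpretable skin constituents that a basis-constrained
#' unmixing of in vivo skin spectra resolves:
#' * `melanin` - broad aromatic-ring bands peaking near 1390 and 1520 cm^-1;
#' * `proteins` - amide/C-H bands at 1150, 1280, 1450 and 1660 cm^-1, the
#'   1450 cm^-1 C-H bending band being the most intense;
#' * `water` - a single broad band at 1650 cm^-1;
#' * `nmf_lipids` - natural-moisturizing-factor bands at 1174 and 1230 cm^-1,
#'   a 1750 cm^-1 C=O band and a broad 1700-1850 cm^-1 lipid band.
#'
#' @param grid strictly increasing wavenumber axis covering at least
#'   1114-1874 cm^-1 worth of the band positions used.
#' @return Named list of non-negative intensity vectors (one per component).
#' @export
build_component_library <- function(grid = default_grid()) {
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  specs <- list(
    component_spec("melanin", list(
      # broad aromatic bands; gaussian so the stated maxima stay put
      peak_spec(1390, 90, 1.00, shape = "gaussian"),
      peak_spec(1520, 85, 0.95, shape = "gaussian")
    )),
    component_spec("proteins", list(
      peak_spec(1150, 35, 0.45),
      peak_spec(1280, 40, 0.55),
      peak_spec(1450, 40, 1.00),
      peak_spec(1660, 45, 0.80)
    )),
    component_spec("water", list(
      peak_spec(1650, 160, 1.00)
    )),
    component_spec("nmf_lipids", list(
      peak_spec(1174, 30, 0.75),
      peak_spec(1230, 30, 0.65),
      peak_spec(1750, 35, 1.00),
      peak_spec(1775, 130, 0.35)
    ))
  )
  out <- lapply(specs, render_component, grid = grid)
  names(out) <- vapply(specs, `[[`, "", "name")
  out
}

#' Default wavenumber grid
#'
#' The preprocessed working range 1114-1874 cm^-1 at 2 cm^-1 spacing;
#' `raw = TRUE` gives the full detector range 792-1874 cm^-1.
#'
#' @param raw use the uncropped detector range.
#' @param step grid spacing, cm^-1.
#' @return Numeric vector of Raman shifts.
#' @export
default_grid <- function(raw = FALSE, step = 2) {
  if (raw) seq(792, 1874, by = step) else seq(1114, 1874, by = step)
}

#' Per-class concentration profile
#'
#' Mean concentration and coefficient of variation per component for one
#' tissue class; samples are drawn from a normal truncated at zero.
#'
#' @param class_label one of `"NS"`, `"K"`, `"BCC"`, `"MM"`, `"PN"` (other
#'   labels allowed for custom scenarios).
#' @param mean_concentration named non-negative vector, one entry per library
#'   component.
#' @param cv coefficient of variation (sd/mean), recycled per component.
#' @param n_samples number of spectra to generate for the class.
#' @return A `class_profile` list.
#' @export
class_profile <- function(class_label, mean_concentration, cv = 0.25,
                          n_samples = 1) {
  if (any(mean_concentration < 0)) stop("mean concentrations must be >= 0")
  if (any(cv < 0)) stop("cv must be >= 0")
  if (n_samples < 1) stop("n_samples must be >= 1")
  cv <- rep_len(cv, length(mean_concentration))
  structure(list(class_label = class_label,
                 mean_concentration = mean_concentration,
                 cv = cv, n_samples = as.integer(n_samples)),
            class = "class_profile")
}

#' Default cohort class profiles
#'
#' Emulates the five-class in vivo cohort (540 NS, 113 K, 122 BCC, 67 MM,
#' 158 PN) over the four-component default library. Mean melanin is elevated
#' in the pigmented classes (K, MM, PN) and low in NS and BCC; protein
#' content is slightly reduced in BCC.
#'
#' @param n_scale multiply all class sizes by this factor (sizes are rounded
#'   up to at least 1); use < 1 for quick tests.
#' @return Named list of [class_profile] objects.
#' @export
default_class_profiles <- function(n_scale = 1) {
  n <- function(k) max(1L, as.integer(round(k * n_scale)))
  comp <- c("melanin", "proteins", "water", "nmf_lipids")
  mk <- function(lab, m, size)
    class_profile(lab, stats::setNames(m, comp), cv = 0.25, n_samples = size)
  list(
    NS  = mk("NS",  c(0.30, 1.00, 0.80, 0.50), n(540)),
    K   = mk("K",   c(1.00, 0.90, 0.75, 0.55), n(113)),
    BCC = mk("BCC", c(0.35, 0.75, 0.85, 0.45), n(122)),
    MM  = mk("MM",  c(1.20, 0.70, 0.80, 0.50), n(67)),
    PN  = mk("PN",  c(1.10, 0.95, 0.75, 0.55), n(158))
  )
}

#' Profiles with exact pure samples for recovery tests
#'
#' Three-component scenario (melanin, proteins, water) in which each class is
#' either a pure component or a fixed mixture; with `cv = 0` and artifacts
#' disabled the factorization D = C S^T is exactly recoverable.
#'
#' @param n_pure samples per pure class.
#' @param n_mixed samples in the mixed class.
#' @param cv concentration coefficient of variation.
#' @return Named list of [class_profile] objects.
#' @export
exact_recovery_profiles <- function(n_pure = 10, n_mixed = 20, cv = 0.2) {
  comp <- c("melanin", "proteins", "water")
  mk <- function(lab, m, size)
    class_profile(lab, stats::setNames(m, comp), cv = cv, n_samples = size)
  list(
    pure_melanin  = mk("pure_melanin",  c(1.0, 0.0, 0.0), n_pure),
    pure_proteins = mk("pure_proteins", c(0.0, 1.0, 0.0), n_pure),
    pure_water    = mk("pure_water",    c(0.0, 0.0, 1.0), n_pure),
    mixed         = mk("mixed",         c(0.6, 0.8, 0.7), n_mixed)
  )
}

#' Acquisition / artifact model
#'
#' Describes the instrument effects applied on top of the clean bilinear
#' signal: a smooth fluorescence background, a sinusoidal etalon ripple
#' defined on the wavelength axis, and Gaussian noise scaled to a target
#' signal-to-noise ratio (max clean Raman peak / noise sd).
#'
#' @param excitation_nm laser wavelength, nm.
#' @param target_snr target SNR (> 0); `Inf` disables noise.
#' @param fluorescence list with `enabled`, `amplitude` (>= 0, in units of
#'   the clean signal) and `decay` (exponential scale, cm^-1).
#' @param ripple list with `enabled`, `amplitude`, `period_nm` (> 0),
#'   `phase` (radians) and `mode` (`"additive"` or `"multiplicative"`).
#' @return An `acquisition_model` list.
#' @export
acquisition_model <- function(excitation_nm = 785, target_snr = 3,
                              fluorescence = list(enabled = TRUE,
                                                  amplitude = 2,
                                                  decay = 800),
                              ripple = list(enabled = TRUE, amplitude = 0.05,
                                            period_nm = 3, phase = 0,
                                            mode = "additive")) {
  if (target_snr <= 0) stop("target_snr must be > 0")
  fl <- utils::modifyList(list(enabled = TRUE, amplitude = 2, decay = 800),
                          fluorescence)
  rp <- utils::modifyList(list(enabled = TRUE, amplitude = 0.05,
                               period_nm = 3, phase = 0, mode = "additive"),
                          ripple)
  if (fl$amplitude < 0) stop("fluorescence amplitude must be >= 0")
  if (rp$period_nm <= 0) stop("ripple period must be > 0")
  if (rp$amplitude < 0) stop("ripple amplitude must be >= 0")
  if (!rp$mode %in% c("additive", "multiplicative"))
    stop("ripple mode must be 'additive' or 'multiplicative'")
  structure(list(excitation_nm = excitation_nm, target_snr = target_snr,
                 fluorescence = fl, ripple = rp),
            class = "acquisition_model")
}

#' Artifact-free acquisition model
#'
#' Convenience preset: fluorescence off, ripple off, noiseless.
#' @export
clean_acquisition <- function() {
  acquisition_model(target_snr = Inf,
                    fluorescence = list(enabled = FALSE, amplitude = 0),
                    ripple = list(enabled = FALSE, amplitude = 0))
}

#' Add a fluorescence background
#'
#' Adds `amplitude * exp(-(nu - min(nu)) / decay)`: smooth, monotone
#' decreasing in wavenumber and non-negative, emulating the broad
#' autofluorescence pedestal that dominates raw in vivo spectra. Its second
#' finite difference is bounded by `amplitude * (step/decay)^2`.
#'
#' @param spectrum intensity vector.
#' @param grid wavenumber axis of `spectrum`, cm^-1.
#' @param acquisition an [acquisition_model].
#' @return intensity vector with background added.
#' @export
add_fluorescence_baseline <- function(spectrum, grid, acquisition) {
  fl <- acquisition$fluorescence
  if (!isTRUE(fl$enabled) || fl$amplitude == 0) return(spectrum)
  spectrum + fluorescence_profile(grid, fl$amplitude, fl$decay)
}

#' Closed-form fluorescence profile (used by the generator and by tests)
#' @param grid wavenumber axis, cm^-1.
#' @param amplitude peak background level.
#' @param decay exponential decay scale, cm^-1.
#' @return non-negative background vector.
#' @export
fluorescence_profile <- function(grid, amplitude, decay = 800) {
  amplitude * exp(-(grid - min(grid)) / decay)
}

#' Add a sinusoidal etalon ripple
#'
#' Interference fringes from a back-thinned CCD are periodic in wavelength;
#' the ripple is generated as a sinusoid of the stated period on the
#' wavelength axis and mapped onto the wavenumber grid. In `"additive"` mode
#' the non-negative waveform `amplitude * (1 + sin(.))/2` is added; in
#' `"multiplicative"` mode the spectrum is scaled by `1 + amplitude*sin(.)`
#' (requires amplitude < 1 so the result stays non-negative).
#'
#' @inheritParams add_fluorescence_baseline
#' @return intensity vector with ripple applied.
#' @export
add_etalon_ripple <- function(spectrum, grid, acquisition) {
  rp <- acquisition$ripple
  if (!isTRUE(rp$enabled) || rp$amplitude == 0) return(spectrum)
  lambda_nm <- raman_shift_to_nm(grid, acquisition$excitation_nm)
  s <- sin(2 * pi * lambda_nm / rp$period_nm + rp$phase)
  if (rp$mode == "additive") {
    spectrum + rp$amplitude * (1 + s) / 2
  } else {
    if (rp$amplitude >= 1)
      stop("multiplicative ripple amplitude must be < 1")
    spectrum * (1 + rp$amplitude * s)
  }
}

#' Add Gaussian noise at a target SNR
#'
#' SNR is defined as (max amplitude of the clean Raman signal) / (noise sd);
#' the definition travels with the result as the `snr_definition` attribute.
#'
#' @param spectrum clean intensity vector (or matrix, one spectrum per row).
#' @param target_snr dimensionless SNR (> 0); `Inf` returns the input.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param reference_peak optional clean peak amplitude to use instead of
#'   `max(spectrum)` (the dataset generator passes the dataset-wide maximum
#'   so all spectra share one noise floor, as a detector would).
#' @return noisy spectrum with attributes `noise_sd` and `snr_definition`.
#' @export
add_noise_to_snr <- function(spectrum, target_snr, seed = NULL,
                             reference_peak = NULL) {
  if (target_snr <= 0) stop("target_snr must be > 0")
  if (is.infinite(target_snr)) return(spectrum)
  peak <- if (is.null(reference_peak)) max(abs(spectrum)) else reference_peak
  if (peak == 0) stop("clean signal is identically zero: SNR undefined")
  if (!is.null(seed)) set.seed(seed)
  sd_noise <- peak / target_snr
  out <- spectrum + stats::rnorm(length(spectrum), 0, sd_noise)
  attr(out, "noise_sd") <- sd_noise
  attr(out, "snr_definition") <- "max_clean_peak_over_noise_sd"
  out
}

draw_truncnorm <- function(n, mean, sd) {
  # normal truncated at zero by rejection; degenerate sd = 0 returns the mean
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

#' Simulate a skin-Raman dataset with known ground truth
#'
#' Draws per-sample concentrations from zero-truncated normals (per class
#' mean and cv), forms the clean bilinear signal C S^T from the rendered
#' component library, then applies fluorescence, etalon ripple and Gaussian
#' noise per the acquisition model. The same seed reproduces the dataset
#' bit for bit.
#'
#' @param profiles named list of [class_profile] objects.
#' @param library named list of rendered component spectra (see
#'   [build_component_library]); names must cover every profile's
#'   concentration entries.
#' @param acquisition an [acquisition_model].
#' @param grid wavenumber axis the library was rendered on.
#' @param seed integer seed controlling all randomness.
#' @return A `synthetic_dataset` list: `spectra` ([raman_spectra]), `c_true`
#'   (samples x components), `s_true` (components x points), `clean`
#'   (noise- and artifact-free C S^T), `seed`, `acquisition`, `noise_sd`.
#' @export
simulate_dataset <- function(profiles, library = NULL,
                             acquisition = acquisition_model(),
                             grid = default_grid(), seed = 1) {
  if (is.null(library)) library <- build_component_library(grid)
  used <- unique(unlist(lapply(profiles,
                               function(pr) names(pr$mean_concentration))))
  missing_c <- setdiff(used, names(library))
  if (length(missing_c) > 0)
    stop("library lacks component(s): ", paste(missing_c, collapse = ", "))
  library <- library[intersect(names(library), used)]
  comp_names <- names(library)
  s_true <- do.call(rbind, library)
  rownames(s_true) <- comp_names
  set.seed(seed)
  c_rows <- list(); labels <- character(0)
  for (pr in profiles) {
    m <- pr$mean_concentration[comp_names]
    m[is.na(m)] <- 0
    cvv <- stats::setNames(rep_len(pr$cv, length(pr$mean_concentration)),
                           names(pr$mean_concentration))[comp_names]
    cvv[is.na(cvv)] <- 0
    cc <- sapply(seq_along(m), function(a)
      draw_truncnorm(pr$n_samples, m[a], m[a] * cvv[a]))
    cc <- matrix(cc, nrow = pr$n_samples)
    c_rows[[length(c_rows) + 1]] <- cc
    labels <- c(labels, rep(pr$class_label, pr$n_samples))
  }
  c_true <- do.call(rbind, c_rows)
  colnames(c_true) <- comp_names
  clean <- c_true %*% s_true
  d <- clean
  for (i in seq_len(nrow(d)))
    d[i, ] <- add_fluorescence_baseline(d[i, ], grid, acquisition)
  for (i in seq_len(nrow(d)))
    d[i, ] <- add_etalon_ripple(d[i, ], grid, acquisition)
  noise_sd <- 0
  if (is.finite(acquisition$target_snr)) {
    peak <- max(clean)
    if (peak == 0) stop("clean signal is identically zero: SNR undefined")
    noise_sd <- peak / acquisition$target_snr
    d <- d + matrix(stats::rnorm(length(d), 0, noise_sd), nrow(d))
  }
  structure(list(
    spectra = raman_spectra(d, grid, axis_kind = "shift_cm1",
                            labels = labels, stage = "raw"),
    c_true = c_true, s_true = s_true, clean = clean,
    seed = as.integer(seed), acquisition = acquisition,
    noise_sd = noise_sd), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d spectra, %d components, seed %d\n",
              nrow(x$c_true), ncol(x$c_true), x$seed))
  print(x$spectra)
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `spectra.csv` (header = wavenumbers), `labels.csv`,
#' `c_true.csv`, `s_true.csv` and a `config.json` echo with the seed and
#' acquisition parameters.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_csv(dataset$spectra, file.path(dir, "spectra.csv"))
  utils::write.csv(data.frame(sample_id = seq_len(nrow(dataset$c_true)),
                              label = dataset$spectra$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(as.data.frame(dataset$c_true),
                   file.path(dir, "c_true.csv"), row.names = FALSE,
                   quote = FALSE)
  s <- data.frame(component = rownames(dataset$s_true), dataset$s_true,
                  check.names = FALSE)
  names(s)[-1] <- format(dataset$spectra$axis, trim = TRUE, digits = 10)
  utils::write.csv(s, file.path(dir, "s_true.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- list(seed = dataset$seed, noise_sd = dataset$noise_sd,
              acquisition = unclass(dataset$acquisition))
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
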