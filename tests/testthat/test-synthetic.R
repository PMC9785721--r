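test_that("component library renders the stated band structure", {
  grid <- default_grid()
  lib <- build_component_library(grid)
  expect_setequal(names(lib),
                  c("melanin", "proteins", "water", "nmf_lipids"))
  step <- diff(grid)[1]
  # melanin: global maximum at one of its two broad bands
  mel_argmax <- grid[which.max(lib$melanin)]
  expect_true(min(abs(mel_argmax - c(1390, 1520))) <= step)
  # proteins: 1450 cm^-1 C-H bending band is the most intense
  expect_lte(abs(grid[which.max(lib$proteins)] - 1450), step)
  # water: single broad band at 1650
  expect_lte(abs(grid[which.max(lib$water)] - 1650), step)
  # everything non-negative and nonzero
  for (s in lib) {
    expect_true(all(s >= 0))
    expect_gt(max(s), 0)
  }
})

test_that("library errors when the grid misses a band", {
  expect_error(build_component_library(seq(1114, 1500, by = 2)),
               "peak")
  expect_error(build_component_library(c(2, 1, 3)), "increasing")
})

test_that("default cohort preset reproduces the class counts", {
  profs <- default_class_profiles()
  expect_equal(vapply(profs, `[[`, 0L, "n_samples"),
               c(NS = 540L, K = 113L, BCC = 122L, MM = 67L, PN = 158L))
  full <- simulate_dataset(default_class_profiles(),
                           acquisition = clean_acquisition(), seed = 3)
  expect_equal(nrow(full$spectra$values), 1000L)
  tab <- table(full$spectra$labels)
  expect_equal(as.integer(tab[c("NS", "K", "BCC", "MM", "PN")]),
               c(540L, 113L, 122L, 67L, 158L))
})

test_that("reconstruction identity holds with artifacts and noise off", {
  ds <- simulate_dataset(default_class_profiles(n_scale = 0.02),
                         acquisition = clean_acquisition(), seed = 5)
  expect_equal(ds$spectra$values, ds$c_true %*% ds$s_true,
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_true(all(ds$c_true >= 0))
  expect_true(all(ds$s_true >= 0))
})

test_that("cv = 0 with artifacts disabled gives identical rows per class", {
  prof <- list(class_profile("A", c(melanin = 1, water = 0.5), cv = 0,
                             n_samples = 4),
               class_profile("B", c(melanin = 0.2, water = 1), cv = 0,
                             n_samples = 3))
  ds <- simulate_dataset(prof, acquisition = clean_acquisition(), seed = 1)
  v <- ds$spectra$values
  for (lab in c("A", "B")) {
    rows <- v[ds$spectra$labels == lab, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
  }
  # and the rows equal the mean-weighted mixture exactly
  expect_equal(v[1, ], as.numeric(c(1, 0.5) %*% ds$s_true),
               ignore_attr = TRUE)
})

test_that("seeded determinism: same seed identical, different seeds differ", {
  acq <- acquisition_model(target_snr = 3)
  a <- simulate_dataset(default_class_profiles(n_scale = 0.02),
                        acquisition = acq, seed = 42)
  b <- simulate_dataset(default_class_profiles(n_scale = 0.02),
                        acquisition = acq, seed = 42)
  c <- simulate_dataset(default_class_profiles(n_scale = 0.02),
                        acquisition = acq, seed = 43)
  expect_identical(a$spectra$values, b$spectra$values)
  expect_identical(a$c_true, b$c_true)
  expect_false(identical(a$spectra$values, c$spectra$values))
})

test_that("mean melanin concentration is elevated in pigmented classes", {
  ds <- simulate_dataset(default_class_profiles(n_scale = 0.2),
                         acquisition = clean_acquisition(), seed = 9)
  mel <- ds$c_true[, "melanin"]
  lab <- ds$spectra$labels
  m_pig <- mean(mel[lab %in% c("K", "MM", "PN")])
  m_rest <- mean(mel[lab %in% c("NS", "BCC")])
  expect_gt(m_pig, m_rest)
})

test_that("fluorescence background is additive, non-negative and smooth", {
  grid <- default_grid()
  acq <- acquisition_model(fluorescence = list(enabled = TRUE,
                                               amplitude = 2, decay = 800))
  y <- rep(1, length(grid))
  out <- add_fluorescence_baseline(y, grid, acq)
  bg <- out - y
  expect_true(all(bg >= 0))
  # closed form: second difference bounded by amplitude * (step/decay)^2
  step <- diff(grid)[1]
  cap <- 2 * (step / 800)^2
  expect_lte(max(abs(diff(bg, differences = 2))), cap)
  # no features narrower than 200 cm^-1: fwhm-scale variation check via
  # the closed form itself
  expect_equal(bg, fluorescence_profile(grid, 2, 800))
  # amplitude 0 -> unchanged
  acq0 <- acquisition_model(fluorescence = list(enabled = TRUE,
                                                amplitude = 0))
  expect_identical(add_fluorescence_baseline(y, grid, acq0), y)
})

test_that("etalon ripple matches the analytic sinusoid on the wavelength axis", {
  grid <- default_grid()
  acq <- acquisition_model(ripple = list(enabled = TRUE, amplitude = 0.4,
                                         period_nm = 3, phase = 1,
                                         mode = "additive"))
  flat <- rep(2, length(grid))
  out <- add_etalon_ripple(flat, grid, acq)
  lambda <- raman_shift_to_nm(grid, 785)
  expected <- 0.4 * (1 + sin(2 * pi * lambda / 3 + 1)) / 2
  expect_equal(out - flat, expected, tolerance = 1e-12)
  expect_true(all(out >= 0))
  # dominant FFT frequency of the ripple matches the configured period
  r <- out - flat - mean(out - flat)
  spec_power <- Mod(stats::fft(r))[2:floor(length(r) / 2)]
  k_peak <- which.max(spec_power)
  cycles_expected <- (max(lambda) - min(lambda)) / 3
  expect_lte(abs((k_peak) - cycles_expected), 2)
  # phase shift by a full period is the identity
  acq2pi <- acquisition_model(ripple = list(enabled = TRUE, amplitude = 0.4,
                                            period_nm = 3,
                                            phase = 1 + 2 * pi,
                                            mode = "additive"))
  expect_equal(add_etalon_ripple(flat, grid, acq2pi), out,
               tolerance = 1e-9)
  # amplitude 0 is the identity
  acq0 <- acquisition_model(ripple = list(amplitude = 0))
  expect_identical(add_etalon_ripple(flat, grid, acq0), flat)
})

test_that("multiplicative ripple keeps spectra non-negative and scales", {
  grid <- default_grid()
  acq <- acquisition_model(ripple = list(enabled = TRUE, amplitude = 0.3,
                                         period_nm = 4, mode =
                                           "multiplicative"))
  y <- seq(0, 2, length.out = length(grid))
  out <- add_etalon_ripple(y, grid, acq)
  expect_true(all(out >= 0))
  expect_equal(out[y == 0], 0)
  bad <- acquisition_model(ripple = list(amplitude = 1.5,
                                         mode = "multiplicative"))
  expect_error(add_etalon_ripple(y, grid, bad), "< 1")
})

test_that("noise scaling matches the SNR definition", {
  # target 3, clean peak 300 -> noise SD 100
  y <- c(rep(0, 10), 300, rep(0, 10))
  out <- add_noise_to_snr(y, 3, seed = 1)
  expect_equal(attr(out, "noise_sd"), 100)
  expect_equal(attr(out, "snr_definition"), "max_clean_peak_over_noise_sd")
  # infinite SNR is the identity
  expect_identical(add_noise_to_snr(y, Inf), y)
  # empirical SD over 1e5 points within 2% of nominal
  big <- rep(300, 1e5)
  noisy <- add_noise_to_snr(big, 3, seed = 7)
  expect_lt(abs(stats::sd(noisy - big) - 100) / 100, 0.02)
  expect_error(add_noise_to_snr(rep(0, 5), 3, seed = 1), "zero")
  expect_error(add_noise_to_snr(y, -1), "target_snr")
})

test_that("generated spectra are non-negative after all artifacts", {
  acq <- acquisition_model(target_snr = Inf)   # artifacts on, noise off
  ds <- simulate_dataset(default_class_profiles(n_scale = 0.05),
                         acquisition = acq, seed = 21)
  expect_true(all(ds$spectra$values >= 0))
})

test_that("profile validation rejects unphysical settings", {
  expect_error(class_profile("X", c(a = -1)), ">= 0")
  expect_error(class_profile("X", c(a = 1), cv = -0.1), ">= 0")
  expect_error(class_profile("X", c(a = 1), n_samples = 0), ">= 1")
  expect_error(simulate_dataset(
    list(class_profile("X", c(nope = 1), n_samples = 2)),
    acquisition = clean_acquisition(), seed = 1), "lacks component")
})

test_that("dataset round-trips through the CSV writer", {
  ds <- simulate_dataset(default_class_profiles(n_scale = 0.02),
                         acquisition = clean_acquisition(), seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("spectra.csv", "labels.csv",
                                               "c_true.csv", "s_true.csv",
                                               "config.json")))))
  back <- read_spectra_csv(file.path(dir, "spectra.csv"))
  expect_equal(back$values, ds$spectra$values, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$labels, ds$spectra$labels)
  expect_equal(back$axis, ds$spectra$axis)
})
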