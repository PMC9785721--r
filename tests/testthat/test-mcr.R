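test_that("simplisma selects the pure rows when they exist", {
  grid <- seq_len(80)
  s1 <- exp(-(grid - 20)^2 / 18)           # disjoint peaks
  s2 <- exp(-(grid - 60)^2 / 18)
  D <- rbind(s1, s2,
             0.5 * s1 + 0.5 * s2,
             0.4 * s1 + 0.6 * s2,
             0.7 * s1 + 0.3 * s2)
  init <- simplisma_init(D, 2, allowed_noise_pct = 10)
  expect_setequal(init$indices, c(1L, 2L))
  expect_true(all(init$spectra >= 0))
  # base case: one component picks the single purest row
  one <- simplisma_init(D, 1)
  expect_length(one$indices, 1)
  expect_error(simplisma_init(D, 10), "exceeds")
})

test_that("large allowed-noise offset orders purity by sigma alone", {
  set.seed(8)
  D <- matrix(abs(rnorm(5 * 40, 1, 0.3)), 5, 40)
  D[3, ] <- D[3, ] * c(rep(0.1, 20), rep(3, 20))   # highest-sigma row
  big <- simplisma_init(D, 1, allowed_noise_pct = 99)
  sig <- apply(D, 1, function(r) sqrt(mean(r^2) - mean(r)^2))
  expect_equal(big$indices, which.max(sig))
})

test_that("closure normalizes free rows and preserves the product", {
  S <- rbind(rep(0.2, 5), c(1, 2, 1, 0.5, 0.5))
  C <- matrix(runif(6, 0.5, 2), 3, 2)
  cl <- apply_closure(S)
  expect_equal(rowSums(cl$spectra), c(1, 1), tolerance = 1e-12)
  expect_equal(cl$factors, c(1, 5))
  C2 <- sweep(C, 2, cl$factors, `*`)
  expect_equal(C2 %*% cl$spectra, C %*% S, tolerance = 1e-12)
  expect_error(apply_closure(rbind(rep(0, 5))), "zero spectral area")
})

test_that("equality constraints overwrite exactly the sentinel-free rows", {
  S <- matrix(runif(12), 3, 4)
  fixedS <- rbind(c(0.1, 0.2, 0.3, 0.4),
                  rep(NA_real_, 4),
                  rep(NA_real_, 4))
  out <- apply_equality(S, fixedS)
  expect_identical(out[1, ], fixedS[1, ])
  expect_identical(out[2:3, ], S[2:3, ])
  # all-sentinel constraint is the identity
  expect_identical(apply_equality(S, matrix(NA_real_, 3, 4)), S)
  expect_error(apply_equality(S, rbind(c(-1, 0, 0, 0), rep(NA, 4),
                                       rep(NA, 4))), "negative")
  expect_error(apply_equality(S, rbind(c(1, NA, 0, 0), rep(NA, 4),
                                       rep(NA, 4))), "mixes")
})

test_that("rank-1 fit reproduces the data exactly", {
  set.seed(5)
  c1 <- runif(15, 0.5, 2)
  s1 <- abs(rnorm(40)) + 0.1
  D <- c1 %*% t(s1)
  m <- fit_mcr(D, mcr_config(1, seed = 1))
  expect_lt(m$metrics$lack_of_fit_pct, 1e-6)
  expect_true(m$converged)
  # oracle: direct alternating projection for the leading nonneg rank-1
  sv <- svd(D)
  r1 <- abs(sv$u[, 1] * sv$d[1]) %*% t(abs(sv$v[, 1]))
  expect_equal(m$concentrations %*% m$spectra, r1, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("noiseless 3-component mixtures are recovered exactly", {
  mix <- tiny_mixture(rank = 3, n = 40, J = 80, seed = 12)
  m <- fit_mcr(mix$D, mcr_config(3, seed = 12))
  mt <- match_components(m$spectra, mix$S)
  expect_true(all(mt$correlations >= 0.999))
  cperm <- m$concentrations[, mt$perm]
  conc_r <- vapply(1:3, function(a) cor(cperm[, a], mix$C[, a]), numeric(1))
  expect_true(all(conc_r >= 0.999))
  expect_lt(m$metrics$lack_of_fit_pct, 0.1)
})

test_that("residual sum of squares is monotone non-increasing", {
  configs <- list(
    mcr_config(3, closure = "equal_area", nonneg = TRUE),
    mcr_config(3, closure = "none", nonneg = TRUE),
    mcr_config(3, closure = "equal_area", nonneg = FALSE),
    mcr_config(3, closure = "none", nonneg = FALSE)
  )
  for (seed in 1:5) {
    mix <- tiny_mixture(rank = 3, n = 25, J = 50, seed = seed)
    D <- mix$D + matrix(abs(rnorm(length(mix$D), 0, 0.02)), nrow(mix$D))
    for (cfg in configs) {
      cfg$conv_tol_pct <- 1e-8          # run long enough to see the trace
      cfg$max_iter <- 40L
      m <- fit_mcr(D, cfg)
      lof <- m$trace$lack_of_fit_pct
      if (length(lof) > 1)
        expect_true(all(diff(lof) <= 1e-9 * lof[-length(lof)] + 1e-12),
                    label = sprintf("monotone lof (seed %d, closure %s, nonneg %s)",
                                    seed, cfg$closure, cfg$nonneg))
    }
  }
})

test_that("stopping rules respect max_iter and the convergence tolerance", {
  mix <- tiny_mixture(rank = 2, n = 20, J = 40, seed = 3)
  D <- mix$D + matrix(abs(rnorm(length(mix$D), 0, 0.05)), nrow(mix$D))
  m <- fit_mcr(D, mcr_config(2, max_iter = 150, conv_tol_pct = 0.1))
  expect_lte(m$n_iter_run, 150)
  expect_equal(nrow(m$trace), m$n_iter_run)
  if (m$converged) {
    sd_tr <- m$trace$residual_sd
    n <- length(sd_tr)
    change <- 100 * abs(sd_tr[n - 1] - sd_tr[n]) / sd_tr[n - 1]
    expect_lte(change, 0.1)
  }
  # hard iteration cap is honored
  m3 <- fit_mcr(D, mcr_config(2, max_iter = 3, conv_tol_pct = 1e-12))
  expect_lte(m3$n_iter_run, 3)
})

test_that("free rows satisfy closure and fixed rows are byte-stable", {
  grid <- default_grid()
  # noise present so the free components have structure to absorb; a fully
  # noiseless basis fit collapses the free rows (tested below as an error)
  ds <- simulate_dataset(default_class_profiles(n_scale = 0.03),
                         acquisition = acquisition_model(target_snr = 10),
                         grid = grid, seed = 17)
  basis <- ds$s_true                     # 4 true spectra as the fixed basis
  m <- fit_with_basis(ds$spectra, basis, n_free = 4, max_iter = 30)
  norm_basis <- apply_closure(basis)$spectra
  # fixed rows identical to the (area-normalized) input, bit for bit
  expect_identical(unname(m$spectra[1:4, ]), unname(norm_basis))
  expect_equal(m$fixed_mask, c(rep(TRUE, 4), rep(FALSE, 4)),
               ignore_attr = TRUE)
  # free rows sum to one within 1e-12
  expect_true(all(abs(rowSums(m$spectra[5:8, ]) - 1) < 1e-12))
})

test_that("regression-only fit with the true basis recovers concentrations", {
  ds <- simulate_dataset(default_class_profiles(n_scale = 0.05),
                         acquisition = clean_acquisition(), seed = 19)
  m <- fit_with_basis(ds$spectra, ds$s_true, n_free = 0, max_iter = 5)
  # recovered C matches c_true up to the per-component closure scale
  for (a in 1:4)
    expect_gt(cor(m$concentrations[, a], ds$c_true[, a]), 0.999)
})

test_that("fit metrics follow the residual definitions and the identity", {
  mix <- tiny_mixture(rank = 2, n = 10, J = 30, seed = 2)
  model0 <- list(concentrations = matrix(0, 10, 2), spectra = mix$S)
  mm <- compute_metrics(mix$D, model0)
  expect_equal(mm$lack_of_fit_pct, 100)
  expect_equal(mm$explained_variation_pct, 0)
  exact <- list(concentrations = mix$C, spectra = mix$S)
  me <- compute_metrics(mix$D, exact)
  expect_equal(me$lack_of_fit_pct, 0, tolerance = 1e-10)
  expect_equal(me$explained_variation_pct, 100, tolerance = 1e-10)
  # consistency identity between the two metrics on a real fit
  m <- fit_mcr(mix$D + 0.05, mcr_config(1, max_iter = 10))
  lof <- m$metrics$lack_of_fit_pct
  expect_equal(m$metrics$explained_variation_pct,
               100 * (1 - (lof / 100)^2), tolerance = 1e-10)
  expect_error(compute_metrics(matrix(0, 10, 30), exact), "zero")
})

test_that("component matching resolves permutations exactly for small A", {
  mix <- tiny_mixture(rank = 4, n = 10, J = 60, seed = 6)
  perm <- c(3, 1, 4, 2)
  mt <- match_components(mix$S[perm, ], mix$S)
  expect_equal(mt$perm, order(perm))
  expect_true(all(mt$correlations > 0.999))
})

test_that("degenerate inputs error clearly", {
  expect_error(fit_mcr(matrix(0, 5, 10), mcr_config(2)), "zero")
  # noiseless data fully explained by the basis: free components collapse
  ds <- simulate_dataset(default_class_profiles(n_scale = 0.02),
                         acquisition = clean_acquisition(), seed = 41)
  expect_error(fit_with_basis(ds$spectra, ds$s_true, n_free = 2,
                              max_iter = 10),
               "component")
  expect_error(mcr_config(0), "n_components")
  expect_error(mcr_config(2, allowed_noise_pct = 0), "allowed_noise_pct")
  expect_error(mcr_config(2, fixed_spectra = matrix(1, 3, 10)),
               "n_components rows")
})
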