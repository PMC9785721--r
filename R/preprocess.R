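#' Asymmetric least squares parameters
#'
#' Eilers-style AsLS baseline: minimize
#' sum_i w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2 with asymmetric weights
#' (p above the baseline, 1 - p below), re-estimated for `n_iter` rounds.
#' Following the R `baseline` package convention, `lam` is the exponent:
#' the effective penalty is `10^lam` when `lam_is_log10 = TRUE` (default),
#' so the conventional printed setting "lambda = 6" means 1e6.
#'
#' @param lam smoothness penalty; interpreted as log10 of the effective
#'   penalty unless `lam_is_log10 = FALSE`.
#' @param p asymmetry weight in (0, 1); small p pushes the baseline under
#'   the peaks.
#' @param n_iter weight re-estimation iterations (>= 1).
#' @param lam_is_log10 interpretation flag for `lam`.
#' @return An `asls_params` list with the resolved `lam_effective`.
#' @export
asls_params <- function(lam = 6, p = 0.1, n_iter = 10, lam_is_log10 = TRUE) {
  if (p <= 0 || p >= 1) stop("p must lie strictly in (0, 1)")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(lam = lam, p = p, n_iter = as.integer(n_iter),
                 lam_is_log10 = isTRUE(lam_is_log10),
                 lam_effective = if (isTRUE(lam_is_log10)) 10^lam else lam),
            class = "asls_params")
}

#' Asymmetric least squares baseline
#'
#' @param y a single spectrum (numeric vector, length >= 3).
#' @param params an [asls_params] object.
#' @return list with `baseline` and `corrected` (= y - baseline).
#' @export
asls_baseline <- function(y, params = asls_params()) {
  n <- length(y)
  if (n < 3) stop("spectrum must have at least 3 points")
  if (!all(is.finite(y))) stop("spectrum must be finite")
  lam <- params$lam_effective
  # second-difference penalty on interior points: (n-2) x n
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lam * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(params$n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, params$p, 1 - params$p)
  }
  list(baseline = z, corrected = y - z)
}

#' Savitzky-Golay parameters
#'
#' @param window odd window width in points (>= 3).
#' @param polyorder polynomial order (< window).
#' @param deriv derivative order (>= 0; 0 returns smoothed intensities).
#' @return A `savgol_params` list.
#' @export
savgol_params <- function(window = 15, polyorder = 1, deriv = 0) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv < 0 || deriv > polyorder)
    stop("deriv must be between 0 and polyorder")
  structure(list(window = window, polyorder = as.integer(polyorder),
                 deriv = as.integer(deriv)), class = "savgol_params")
}

savgol_coefs <- function(window, polyorder, deriv, at = 0) {
  half <- (window - 1) / 2
  x <- (-half):half
  X <- outer(x, 0:polyorder, `^`)
  # row of the projection evaluated at offset `at`, derivative `deriv`
  XtXinvXt <- solve(crossprod(X), t(X))
  dcoef <- numeric(polyorder + 1)
  for (k in deriv:polyorder)
    dcoef[k + 1] <- factorial(k) / factorial(k - deriv) * at^(k - deriv)
  as.numeric(dcoef %*% XtXinvXt)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial fit in a sliding window; edge points are
#' handled by evaluating the polynomial fitted to the first/last full window
#' at the edge offsets (the usual "interp" convention).
#'
#' @param y numeric spectrum, length >= window.
#' @param params a [savgol_params] object.
#' @return smoothed (or differentiated) spectrum of the same length.
#' @export
savgol_smooth <- function(y, params = savgol_params()) {
  n <- length(y)
  w <- params$window
  if (w > n) stop("window (", w, ") exceeds spectrum length (", n, ")")
  half <- (w - 1) / 2
  center <- savgol_coefs(w, params$polyorder, params$deriv, at = 0)
  out <- numeric(n)
  for (i in (half + 1):(n - half))
    out[i] <- sum(center * y[(i - half):(i + half)])
  for (k in 1:half) {
    out[k] <- sum(savgol_coefs(w, params$polyorder, params$deriv,
                               at = k - half - 1) * y[1:w])
    out[n - k + 1] <- sum(savgol_coefs(w, params$polyorder, params$deriv,
                                       at = half - k + 1) * y[(n - w + 1):n])
  }
  out
}

#' Min-max rescaling to [0, 1]
#'
#' @param y numeric vector with max(y) > min(y).
#' @return (y - min) / (max - min).
#' @export
minmax_rescale <- function(y) {
  r <- range(y)
  if (r[1] == r[2]) stop("constant spectrum: zero range, cannot rescale")
  (y - r[1]) / (r[2] - r[1])
}

#' Preprocess a spectra matrix
#'
#' The standard chain for the working range: crop, AsLS baseline removal,
#' Savitzky-Golay smoothing, each applied per spectrum independently.
#' Row order and labels are preserved.
#'
#' @param spectra a [raman_spectra] object on the Raman-shift axis.
#' @param crop length-2 numeric window in cm^-1, or NULL to skip cropping.
#' @param asls an [asls_params] object, or NULL to skip baseline removal.
#' @param savgol a [savgol_params] object, or NULL to skip smoothing.
#' @return a preprocessed [raman_spectra] (stage `"smoothed"`).
#' @export
preprocess_spectra <- function(spectra,
                               crop = c(1114, 1874),
                               asls = asls_params(),
                               savgol = savgol_params()) {
  stopifnot(inherits(spectra, "raman_spectra"))
  out <- spectra
  if (!is.null(crop)) out <- crop_range(out, crop[1], crop[2])
  if (!is.null(asls)) {
    out$values <- t(apply(out$values, 1,
                          function(y) asls_baseline(y, asls)$corrected))
    out$stage <- "baseline_removed"
  }
  if (!is.null(savgol)) {
    out$values <- t(apply(out$values, 1,
                          function(y) savgol_smooth(y, savgol)))
    out$stage <- "smoothed"
  }
  out
}
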