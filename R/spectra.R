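#' Spectra matrix container
#'
#' Bundles a samples-by-points intensity matrix with its spectral axis
#' (wavelength in nm or Raman shift in cm^-1), per-sample class labels and a
#' processing-stage tag. This is the mixture matrix D of the bilinear model
#' D = C S^T + E that all downstream operations consume.
#'
#' @param values numeric matrix, one row per measured spectrum.
#' @param axis strictly increasing numeric vector, one entry per column of
#'   `values`.
#' @param axis_kind `"shift_cm1"` (Raman shift) or `"wavelength_nm"`.
#' @param labels character vector of per-row class tags (recycled if length 1);
#'   defaults to `"unknown"`.
#' @param stage processing stage, one of `"raw"`, `"baseline_removed"`,
#'   `"smoothed"`, `"rescaled"`.
#' @return An object of class `raman_spectra`: a list with elements `values`,
#'   `axis`, `axis_kind`, `labels`, `stage`.
#' @export
raman_spectra <- function(values, axis,
                          axis_kind = c("shift_cm1", "wavelength_nm"),
                          labels = NULL,
                          stage = c("raw", "baseline_removed", "smoothed",
                                    "rescaled")) {
  axis_kind <- match.arg(axis_kind)
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  axis <- as.numeric(axis)
  if (length(axis) != ncol(values))
    stop("axis length (", length(axis), ") != number of columns (",
         ncol(values), ")")
  if (length(axis) > 1 && any(diff(axis) <= 0))
    stop("axis must be strictly increasing")
  if (!all(is.finite(values)))
    stop("spectral intensities must all be finite")
  if (is.null(labels)) labels <- "unknown"
  labels <- as.character(labels)
  if (length(labels) == 1) labels <- rep(labels, nrow(values))
  if (length(labels) != nrow(values))
    stop("labels length (", length(labels), ") != number of rows (",
         nrow(values), ")")
  structure(list(values = values, axis = axis, axis_kind = axis_kind,
                 labels = labels, stage = stage),
            class = "raman_spectra")
}

#' @export
print.raman_spectra <- function(x, ...) {
  cat(sprintf("raman_spectra: %d spectra x %d points [%s %.1f..%.1f, stage %s]\n",
              nrow(x$values), ncol(x$values), x$axis_kind,
              min(x$axis), max(x$axis), x$stage))
  tab <- table(x$labels)
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.raman_spectra <- function(x) dim(x$values)

#' Convert wavelength to Raman shift
#'
#' Stokes shift relative to the excitation line:
#' shift = 1e7 * (1/excitation_nm - 1/wavelength_nm), in cm^-1.
#'
#' @param wavelength_nm detection wavelength(s), nm.
#' @param excitation_nm excitation laser wavelength, nm (default 785).
#' @return Raman shift(s) in cm^-1, monotone increasing in wavelength.
#' @export
nm_to_raman_shift <- function(wavelength_nm, excitation_nm = 785) {
  if (any(excitation_nm <= 0)) stop("excitation wavelength must be positive")
  if (any(wavelength_nm < excitation_nm))
    stop("wavelength below excitation: anti-Stokes range not supported")
  1e7 * (1 / excitation_nm - 1 / wavelength_nm)
}

#' Convert Raman shift back to wavelength
#'
#' Inverse of [nm_to_raman_shift()].
#'
#' @param shift_cm1 Raman shift(s), cm^-1 (non-negative).
#' @param excitation_nm excitation wavelength, nm.
#' @return wavelength(s) in nm.
#' @export
raman_shift_to_nm <- function(shift_cm1, excitation_nm = 785) {
  if (any(shift_cm1 < 0)) stop("negative Raman shift not supported")
  1 / (1 / excitation_nm - shift_cm1 / 1e7)
}

#' Crop a spectra matrix to an axis window
#'
#' Retains the columns whose axis value lies in `[lo, hi]` (inclusive).
#'
#' @param spectra a [raman_spectra] object.
#' @param lo,hi window bounds in the units of `spectra$axis`.
#' @return A cropped `raman_spectra` with labels and stage preserved.
#' @export
crop_range <- function(spectra, lo, hi) {
  stopifnot(inherits(spectra, "raman_spectra"))
  if (lo > hi) stop("crop window has lo > hi")
  keep <- spectra$axis >= lo & spectra$axis <= hi
  if (!any(keep)) stop("crop window [", lo, ", ", hi,
                       "] contains no axis points")
  out <- spectra
  out$axis <- spectra$axis[keep]
  out$values <- spectra$values[, keep, drop = FALSE]
  out
}

#' Write a spectra matrix to CSV
#'
#' First column `sample_id`, second `label`, remaining columns named by their
#' axis value (decimal cm^-1 or nm). The inverse of [read_spectra_csv()].
#'
#' @param spectra a [raman_spectra] object.
#' @param path output file path.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "raman_spectra"))
  df <- data.frame(sample_id = seq_len(nrow(spectra$values)),
                   label = spectra$labels,
                   spectra$values, check.names = FALSE)
  names(df)[-(1:2)] <- format(spectra$axis, trim = TRUE, digits = 10)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an equality-constraint basis from CSV
#'
#' One row per component, first column `component`, remaining columns named
#' by wavenumber. Rows whose cells are all empty (or `NA`/`NaN`) mark free
#' components — the missing-value sentinel convention; numeric rows are
#' held fixed during the fit.
#'
#' @param path CSV path.
#' @return numeric matrix (components x wavenumbers) with all-NA sentinel
#'   rows for free components; wavenumbers in the `"axis"` attribute.
#' @export
read_basis_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.nan(m)] <- NA_real_
  partial <- apply(m, 1, function(r) any(is.na(r)) && !all(is.na(r)))
  if (any(partial))
    stop("basis row(s) ", paste(which(partial), collapse = ", "),
         " mix numbers and missing values; rows must be all-fixed or ",
         "all-missing")
  rownames(m) <- df[[1]]
  attr(m, "axis") <- as.numeric(colnames(df)[-1])
  m
}

#' Read a spectra matrix from CSV
#'
#' @param path CSV written by [write_spectra_csv()].
#' @param axis_kind axis unit tag of the stored columns.
#' @param stage stage tag to attach.
#' @return A [raman_spectra] object.
#' @export
read_spectra_csv <- function(path, axis_kind = "shift_cm1", stage = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  axis <- as.numeric(names(df)[-(1:2)])
  raman_spectra(as.matrix(df[, -(1:2), drop = FALSE]), axis,
                axis_kind = axis_kind, labels = df$label, stage = stage)
}
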