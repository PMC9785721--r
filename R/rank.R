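#' Suggest the number of MCR components by SVD
#'
#' Computes the leading singular values of the (uncentered) data matrix and
#' applies two heuristics: (i) the rank just before the largest consecutive
#' drop ratio sv[k]/sv[k+1], and (ii) the count of singular values above a
#' relative floor (default 1% of the largest). The drop heuristic is used
#' when its best ratio reaches `drop_threshold`, otherwise the floor count;
#' both are reported, since rank choice for real spectra ultimately rests on
#' prior knowledge.
#'
#' @param spectra a [raman_spectra] or numeric matrix (rows = samples).
#' @param max_rank number of leading singular values to examine.
#' @param rel_floor relative floor for the fallback count (default 0.01).
#' @param drop_threshold minimum consecutive-drop ratio for the drop
#'   heuristic to be trusted (default 3).
#' @return A `rank_scan` list: `singular_values`, `drop_ratios`,
#'   `suggested_rank`, `rank_by_drop`, `rank_by_floor`, `method_used`.
#' @export
scan_rank <- function(spectra, max_rank = 30, rel_floor = 0.01,
                      drop_threshold = 3) {
  D <- if (inherits(spectra, "raman_spectra")) spectra$values else
    as.matrix(spectra)
  if (length(D) == 0 || nrow(D) == 0 || ncol(D) == 0)
    stop("empty matrix")
  max_rank <- min(max_rank, nrow(D), ncol(D))
  sv <- svd(D, nu = 0, nv = 0)$d[seq_len(max_rank)]
  ratios <- if (max_rank > 1) sv[-max_rank] / pmax(sv[-1],
                                                   .Machine$double.eps) else
    numeric(0)
  rank_by_floor <- sum(sv > rel_floor * sv[1])
  rank_by_drop <- if (length(ratios) > 0) which.max(ratios) else 1L
  use_drop <- length(ratios) > 0 && max(ratios) >= drop_threshold
  suggested <- if (use_drop) rank_by_drop else rank_by_floor
  structure(list(singular_values = sv, drop_ratios = ratios,
                 suggested_rank = as.integer(suggested),
                 rank_by_drop = as.integer(rank_by_drop),
                 rank_by_floor = as.integer(rank_by_floor),
                 method_used = if (use_drop) "drop_ratio" else
                   "relative_floor"),
            class = "rank_scan")
}

#' @export
print.rank_scan <- function(x, ...) {
  cat(sprintf("rank_scan: suggested rank %d (%s); drop heuristic %d, ",
              x$suggested_rank, x$method_used, x$rank_by_drop))
  cat(sprintf("floor heuristic %d\n", x$rank_by_floor))
  sv <- x$singular_values
  show <- utils::head(sv, 10)
  cat("leading singular values:",
      paste(format(show, digits = 4), collapse = " "),
      if (length(sv) > 10) "...\n" else "\n")
  invisible(x)
}
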