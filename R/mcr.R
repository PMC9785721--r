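#' MCR-ALS configuration
#'
#' All knobs of the constrained alternating-least-squares solver for the
#' bilinear model D = C S^T + E.
#'
#' @param n_components number of components A (>= 1).
#' @param allowed_noise_pct SIMPLISMA purity offset, percent of the maximum
#'   row mean (default 10, the conventional default).
#' @param max_iter maximum ALS iterations (default 150).
#' @param conv_tol_pct convergence threshold: percent change of the residual
#'   standard deviation between consecutive iterations (default 0.1).
#' @param closure `"equal_area"` (each free spectrum scaled to unit sum,
#'   scale absorbed into C) or `"none"`.
#' @param nonneg enforce non-negativity on both C and S via exact NNLS.
#' @param fixed_spectra optional A x J matrix of equality constraints; rows
#'   of all-NA mark free components, numeric rows are held fixed exactly.
#' @param divergence_patience consecutive residual-SD increases tolerated
#'   before stopping with the best model so far.
#' @param seed seed for any stochastic fallback.
#' @return An `mcr_config` list.
#' @export
mcr_config <- function(n_components, allowed_noise_pct = 10, max_iter = 150,
                       conv_tol_pct = 0.1,
                       closure = c("equal_area", "none"), nonneg = TRUE,
                       fixed_spectra = NULL, divergence_patience = 3,
                       seed = 1) {
  closure <- match.arg(closure)
  if (n_components < 1) stop("n_components must be >= 1")
  if (allowed_noise_pct <= 0 || allowed_noise_pct >= 100)
    stop("allowed_noise_pct must lie in (0, 100)")
  if (max_iter < 0) stop("max_iter must be >= 0")
  if (conv_tol_pct <= 0) stop("conv_tol_pct must be > 0")
  if (!is.null(fixed_spectra)) {
    fixed_spectra <- as.matrix(fixed_spectra)
    if (nrow(fixed_spectra) != n_components)
      stop("fixed_spectra must have n_components rows")
  }
  structure(list(n_components = as.integer(n_components),
                 allowed_noise_pct = allowed_noise_pct,
                 max_iter = as.integer(max_iter),
                 conv_tol_pct = conv_tol_pct, closure = closure,
                 nonneg = isTRUE(nonneg), fixed_spectra = fixed_spectra,
                 divergence_patience = as.integer(divergence_patience),
                 seed = as.integer(seed)),
            class = "mcr_config")
}

#' SIMPLISMA initial estimates
#'
#' Selects the "purest" rows of D as initial spectral estimates. Purity of
#' row i is sigma_i / (mu_i + alpha) with offset
#' alpha = (allowed_noise_pct/100) * max(mu); after each selection the
#' purity is re-weighted by the determinant of the correlation-around-origin
#' matrix of the candidate together with the rows already chosen, which
#' drives later picks away from directions already covered.
#'
#' @param spectra a [raman_spectra] object or numeric matrix (rows = samples).
#' @param n_components number of rows to select.
#' @param allowed_noise_pct offset percentage (default 10).
#' @return list with `spectra` (selected rows, negatives clipped to 0,
#'   n_components x J) and `indices` (selected row numbers).
#' @export
simplisma_init <- function(spectra, n_components, allowed_noise_pct = 10) {
  D <- if (inherits(spectra, "raman_spectra")) spectra$values else
    as.matrix(spectra)
  n <- nrow(D); J <- ncol(D)
  if (n_components > n)
    stop("n_components (", n_components, ") exceeds number of rows (", n, ")")
  mu <- rowMeans(D)
  sigma <- sqrt(rowMeans(D^2) - mu^2)
  alpha <- (allowed_noise_pct / 100) * max(mu)
  purity <- sigma / (mu + alpha)
  # length used for the correlation-around-origin scaling
  len <- sqrt(mu^2 + (sigma + alpha)^2)
  Y <- D / len        # rows scaled; COO entries are row dot products / J
  chosen <- integer(0)
  for (k in seq_len(n_components)) {
    if (k == 1) {
      weight <- rep(1, n)
    } else {
      weight <- vapply(seq_len(n), function(i) {
        M <- tcrossprod(Y[c(i, chosen), , drop = FALSE]) / J
        det(M)
      }, numeric(1))
    }
    score <- weight * purity
    score[chosen] <- -Inf
    pick <- which.max(score)
    if (!is.finite(score[pick]) || score[pick] <= 0 && k > 1) {
      # all remaining rows linearly dependent on the chosen set
      if (max(score[setdiff(seq_len(n), chosen)]) <= 0)
        stop("n_components exceeds the number of numerically independent rows")
    }
    chosen <- c(chosen, pick)
  }
  list(spectra = pmax(D[chosen, , drop = FALSE], 0), indices = chosen)
}

#' Equal-area closure
#'
#' Scales each free spectrum row to unit sum and returns the scale factors
#' so the concentration columns can absorb them (C S^T unchanged).
#'
#' @param spectra_rows A x J matrix of component spectra.
#' @param free logical vector marking the rows subject to closure
#'   (default: all).
#' @return list with `spectra` (normalized rows) and `factors` (per-row
#'   scales; 1 for rows left untouched).
#' @export
apply_closure <- function(spectra_rows, free = NULL) {
  spectra_rows <- as.matrix(spectra_rows)
  A <- nrow(spectra_rows)
  if (is.null(free)) free <- rep(TRUE, A)
  factors <- rep(1, A)
  for (a in which(free)) {
    s <- sum(spectra_rows[a, ])
    if (s <= 0)
      stop("component ", a, " has zero spectral area (component collapsed)")
    factors[a] <- s
    spectra_rows[a, ] <- spectra_rows[a, ] / s
  }
  list(spectra = spectra_rows, factors = factors)
}

#' Apply equality constraints to spectra rows
#'
#' Rows of `fixed_spectra` containing numbers overwrite the corresponding
#' rows of `spectra_rows` exactly; all-NA rows (the missing-value sentinel)
#' leave the row free.
#'
#' @param spectra_rows A x J matrix of current spectral estimates.
#' @param fixed_spectra A x J constraint matrix with NA sentinel rows.
#' @param nonneg if TRUE, reject fixed rows containing negative values.
#' @return the constrained A x J matrix.
#' @export
apply_equality <- function(spectra_rows, fixed_spectra, nonneg = TRUE) {
  if (is.null(fixed_spectra)) return(spectra_rows)
  fixed_spectra <- as.matrix(fixed_spectra)
  if (!all(dim(fixed_spectra) == dim(spectra_rows)))
    stop("fixed_spectra dimensions must match the spectra estimate")
  fixed_rows <- which(apply(fixed_spectra, 1, function(r) !all(is.na(r))))
  for (a in fixed_rows) {
    r <- fixed_spectra[a, ]
    if (any(is.na(r)))
      stop("fixed row ", a, " mixes numbers and NA; rows must be all-fixed ",
           "or all-NA")
    if (nonneg && any(r < 0))
      stop("fixed row ", a, " contains negative values")
    spectra_rows[a, ] <- r
  }
  spectra_rows
}

fixed_mask_of <- function(config) {
  if (is.null(config$fixed_spectra)) return(rep(FALSE, config$n_components))
  apply(config$fixed_spectra, 1, function(r) !all(is.na(r)))
}

#' Residual fit metrics
#'
#' lack_of_fit_pct = 100 * sqrt(sum(E^2) / sum(D^2));
#' explained_variation_pct = 100 * (1 - sum(E^2) / sum(D^2)). The two are
#' linked by explained = 100 * (1 - (lof/100)^2).
#'
#' @param spectra a [raman_spectra] or numeric matrix D.
#' @param model a `component_model` (or a list with `concentrations` and
#'   `spectra` matrices).
#' @return list with `lack_of_fit_pct` and `explained_variation_pct`.
#' @export
compute_metrics <- function(spectra, model) {
  D <- if (inherits(spectra, "raman_spectra")) spectra$values else
    as.matrix(spectra)
  S <- model$spectra
  C <- model$concentrations
  if (ncol(C) != nrow(S) || nrow(C) != nrow(D) || ncol(S) != ncol(D))
    stop("model dimensions do not match the data matrix")
  ssd <- sum(D^2)
  if (ssd == 0) stop("data matrix is identically zero")
  sse <- sum((D - C %*% S)^2)
  list(lack_of_fit_pct = 100 * sqrt(sse / ssd),
       explained_variation_pct = 100 * (1 - sse / ssd))
}

#' Constrained MCR-ALS fit
#'
#' Alternates exact constrained least-squares half-steps on the bilinear
#' model D = C S^T + E:
#' (i) C given S (per-sample NNLS), (ii) free rows of S given C (per-column
#' NNLS on the residual after the fixed-row contribution), (iii) equality
#' constraints, (iv) equal-area closure with scale factors absorbed into C.
#' Stops when the relative change of the residual standard deviation falls
#' to `conv_tol_pct` percent, at `max_iter`, or when the residual SD has
#' increased for `divergence_patience` consecutive iterations (the best
#' model so far is returned).
#'
#' @param spectra a [raman_spectra] object or numeric matrix D
#'   (samples x points).
#' @param config an [mcr_config].
#' @param init optional A x J matrix of initial spectral estimates; defaults
#'   to [simplisma_init] on D.
#' @return A `component_model`: list with `concentrations` (n x A),
#'   `spectra` (A x J), `fixed_mask`, `residual`, `n_iter_run`, `converged`,
#'   `diverged`, `trace` (per-iteration residual SD and lack of fit) and
#'   `metrics` (see [compute_metrics]).
#' @export
fit_mcr <- function(spectra, config, init = NULL) {
  D <- if (inherits(spectra, "raman_spectra")) spectra$values else
    as.matrix(spectra)
  if (all(D == 0)) stop("data matrix is identically zero")
  A <- config$n_components
  n <- nrow(D); J <- ncol(D)
  fixed <- fixed_mask_of(config)
  if (is.null(init)) {
    init <- simplisma_init(D, A, config$allowed_noise_pct)$spectra
  } else {
    init <- as.matrix(init)
    if (nrow(init) != A || ncol(init) != J)
      stop("init must be an A x J matrix")
  }
  S <- apply_equality(init, config$fixed_spectra, config$nonneg)
  if (config$closure == "equal_area")
    S <- apply_closure(S, free = !fixed)$spectra
  # guard against an all-zero free initial row
  for (a in which(!fixed)) if (sum(S[a, ]) == 0) S[a, ] <- 1 / J

  solve_C <- function(S) {
    if (config$nonneg) {
      t(nnls_multi(t(S), t(D)))            # rows of D against columns of S^T
    } else {
      t(solve(tcrossprod(S), S %*% t(D)))
    }
  }
  solve_S_free <- function(C, S) {
    if (all(fixed)) return(S)
    freeC <- C[, !fixed, drop = FALSE]
    R <- D
    if (any(fixed))
      R <- D - C[, fixed, drop = FALSE] %*% S[fixed, , drop = FALSE]
    if (config$nonneg) {
      S[!fixed, ] <- nnls_multi(freeC, R)
    } else {
      S[!fixed, ] <- solve(crossprod(freeC), crossprod(freeC, R))
    }
    S
  }

  best <- NULL; best_sd <- Inf
  trace_sd <- numeric(0); trace_lof <- numeric(0)
  prev_sd <- NA_real_; converged <- FALSE; diverged <- FALSE
  n_increase <- 0L; iters <- 0L
  C <- NULL
  ssd <- sum(D^2)
  for (it in seq_len(max(config$max_iter, 1L))) {
    if (it > config$max_iter) break
    iters <- it
    C <- solve_C(S)
    S <- solve_S_free(C, S)
    S <- apply_equality(S, config$fixed_spectra, config$nonneg)
    if (config$closure == "equal_area") {
      cl <- apply_closure(S, free = !fixed)
      S <- cl$spectra
      C <- sweep(C, 2, cl$factors, `*`)
    }
    E <- D - C %*% S
    res_sd <- stats::sd(as.numeric(E))
    trace_sd <- c(trace_sd, res_sd)
    trace_lof <- c(trace_lof, 100 * sqrt(sum(E^2) / ssd))
    if (res_sd < best_sd) {
      best_sd <- res_sd
      best <- list(C = C, S = S)
    }
    # exact fit: residual at numerical zero, nothing left to iterate on
    if (res_sd <= 1e-12 * stats::sd(as.numeric(D))) { converged <- TRUE; break }
    if (!is.na(prev_sd)) {
      if (res_sd > prev_sd) n_increase <- n_increase + 1L else
        n_increase <- 0L
      if (n_increase >= config$divergence_patience) { diverged <- TRUE; break }
      change_pct <- 100 * abs(prev_sd - res_sd) / prev_sd
      if (is.nan(change_pct)) change_pct <- 0
      if (change_pct <= config$conv_tol_pct) { converged <- TRUE; break }
    }
    prev_sd <- res_sd
  }
  if (config$max_iter == 0L) {
    # no iterations requested: report the initial model
    C <- solve_C(S)
    best <- list(C = C, S = S)
    iters <- 0L
  }
  C <- best$C; S <- best$S
  E <- D - C %*% S
  model <- structure(list(
    concentrations = C, spectra = S, fixed_mask = fixed, residual = E,
    n_iter_run = iters, converged = converged, diverged = diverged,
    trace = data.frame(iteration = seq_along(trace_sd),
                       residual_sd = trace_sd, lack_of_fit_pct = trace_lof),
    config = config), class = "component_model")
  model$metrics <- compute_metrics(D, model)
  model
}

#' @export
print.component_model <- function(x, ...) {
  cat(sprintf(paste0("component_model: %d samples x %d components ",
                     "(%d fixed), %d iterations%s\n"),
              nrow(x$concentrations), ncol(x$concentrations),
              sum(x$fixed_mask), x$n_iter_run,
              if (x$converged) ", converged" else
                if (x$diverged) ", diverged" else ""))
  cat(sprintf("lack of fit %.4f%%, explained variation %.4f%%\n",
              x$metrics$lack_of_fit_pct, x$metrics$explained_variation_pct))
  invisible(x)
}

#' MCR-ALS with a fixed spectral basis
#'
#' Convenience wrapper for the basis-constrained design: `basis_spectra`
#' rows are area-normalized once and held exactly during ALS; `n_free`
#' additional components are initialized by SIMPLISMA on the residual of D
#' after a non-negative projection onto the basis.
#'
#' @param spectra a [raman_spectra] or matrix D.
#' @param basis_spectra n_fixed x J non-negative matrix of known spectra.
#' @param n_free number of additional free components (>= 0).
#' @param ... further arguments passed to [mcr_config] (e.g. `max_iter`).
#' @return A `component_model` (fixed components first).
#' @export
fit_with_basis <- function(spectra, basis_spectra, n_free, ...) {
  D <- if (inherits(spectra, "raman_spectra")) spectra$values else
    as.matrix(spectra)
  basis_spectra <- as.matrix(basis_spectra)
  if (any(basis_spectra < 0)) stop("basis spectra must be non-negative")
  n_fixed <- nrow(basis_spectra)
  basis_spectra <- apply_closure(basis_spectra)$spectra
  A <- n_fixed + n_free
  fixed_spectra <- rbind(basis_spectra,
                         matrix(NA_real_, nrow = n_free,
                                ncol = ncol(basis_spectra)))
  config <- mcr_config(n_components = A, fixed_spectra = fixed_spectra, ...)
  if (n_free > 0) {
    Cb <- t(nnls_multi(t(basis_spectra), t(D)))
    R <- pmax(D - Cb %*% basis_spectra, 0)
    free_init <- if (all(R == 0))
      matrix(1 / ncol(D), n_free, ncol(D))
    else
      simplisma_init(R, n_free, config$allowed_noise_pct)$spectra
    init <- rbind(basis_spectra, free_init)
  } else {
    init <- basis_spectra
  }
  model <- fit_mcr(D, config, init = init)
  base_names <- rownames(basis_spectra)
  if (is.null(base_names)) base_names <- paste0("fixed_", seq_len(n_fixed))
  comp_names <- c(base_names,
                  if (n_free > 0) paste0("free_", seq_len(n_free)))
  colnames(model$concentrations) <- comp_names
  rownames(model$spectra) <- comp_names
  model
}

#' Match estimated components to reference components
#'
#' Resolves the permutation ambiguity of bilinear factorizations: finds the
#' component assignment maximizing the total Pearson correlation between
#' estimated and reference spectra (exhaustive over permutations for up to
#' 8 components, greedy beyond).
#'
#' @param s_est,s_ref matrices with one component spectrum per row.
#' @return list with `perm` (for each reference row, the matching estimated
#'   row) and `correlations` (matched spectral Pearson r).
#' @export
match_components <- function(s_est, s_ref) {
  s_est <- as.matrix(s_est); s_ref <- as.matrix(s_ref)
  A <- nrow(s_ref)
  if (nrow(s_est) < A) stop("estimate has fewer components than reference")
  corr <- matrix(0, A, nrow(s_est))
  for (i in seq_len(A)) for (j in seq_len(nrow(s_est)))
    corr[i, j] <- suppressWarnings(stats::cor(s_ref[i, ], s_est[j, ]))
  corr[is.na(corr)] <- 0
  if (A <= 8 && nrow(s_est) == A) {
    perms <- all_permutations(A)
    scores <- vapply(perms, function(p) sum(corr[cbind(seq_len(A), p)]),
                     numeric(1))
    perm <- perms[[which.max(scores)]]
  } else {
    perm <- integer(A)
    avail <- rep(TRUE, nrow(s_est))
    for (i in order(apply(corr, 1, max), decreasing = TRUE)) {
      j <- which.max(ifelse(avail, corr[i, ], -Inf))
      perm[i] <- j; avail[j] <- FALSE
    }
  }
  list(perm = perm, correlations = corr[cbind(seq_len(A), perm)])
}

all_permutations <- function(k) {
  # every permutation of 1..k, built by inserting k into each position
  if (k == 1) return(list(1L))
  out <- vector("list", 0)
  for (p in all_permutations(k - 1)) for (pos in 0:(k - 1))
    out[[length(out) + 1]] <- append(p, k, after = pos)
  out
}
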