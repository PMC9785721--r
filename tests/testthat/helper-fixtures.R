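# Shared fixtures: everything is generated in code at test time.

# exhaustive active-set oracle for min ||Ax - b||, x >= 0 (small p only)
nnls_brute <- function(A, b) {
  p <- ncol(A)
  best <- numeric(p); best_val <- sum(b^2)          # x = 0 candidate
  for (m in seq_len(2^p - 1)) {
    act <- as.logical(bitwAnd(m, 2^(seq_len(p) - 1)))
    G <- crossprod(A[, act, drop = FALSE])
    xa <- tryCatch(solve(G, crossprod(A[, act, drop = FALSE], b)),
                   error = function(e) NULL)
    if (is.null(xa) || any(xa < 0)) next
    x <- numeric(p); x[act] <- xa
    v <- sum((A %*% x - b)^2)
    if (v < best_val) { best_val <- v; best <- x }
  }
  best
}

# small random non-negative bilinear mixture of known rank, with pure rows
# so the factorization is recoverable
tiny_mixture <- function(rank = 3, n = 30, J = 60, seed = 1) {
  set.seed(seed)
  grid <- seq_len(J)
  centers <- seq(J * 0.15, J * 0.85, length.out = rank)
  S <- t(vapply(centers, function(cc) exp(-(grid - cc)^2 / (2 * (J / 25)^2)),
                numeric(J)))
  C <- matrix(stats::runif(n * rank, 0.2, 1), n, rank)
  C[seq_len(rank), ] <- diag(rank)                  # pure leading rows
  list(D = C %*% S, C = C, S = S, grid = grid)
}

# per-component Pearson r between a fitted model and synthetic ground truth,
# after optimal permutation matching on the spectra
matched_recovery <- function(model, dataset) {
  mt <- match_components(model$spectra, dataset$s_true)
  cperm <- model$concentrations[, mt$perm, drop = FALSE]
  conc_r <- vapply(seq_len(ncol(cperm)), function(a)
    stats::cor(cperm[, a], dataset$c_true[, a]), numeric(1))
  list(spectral_r = mt$correlations, conc_r = conc_r, perm = mt$perm)
}

quiet_run_contrasts <- function(...) {
  suppressWarnings(run_contrasts(...))
}
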