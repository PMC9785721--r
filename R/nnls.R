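#' Fast non-negative least squares on normal equations
#'
#' Active-set solver in the Bro & de Jong FNNLS formulation: works from the
#' precomputed cross-products `AtA = t(A) %*% A` and `Atb = t(A) %*% b`, so
#' the ALS inner loops can factor the (small) Gram matrix once per half-step.
#' Returns the exact KKT optimum of min ||A x - b||^2 subject to x >= 0.
#'
#' @param AtA p x p Gram matrix (symmetric positive semi-definite).
#' @param Atb length-p vector.
#' @param tol tolerance on the dual feasibility check.
#' @return non-negative coefficient vector of length p.
#' @export
fnnls <- function(AtA, Atb, tol = NULL) {
  p <- length(Atb)
  if (is.null(tol))
    tol <- 10 * .Machine$double.eps * max(abs(AtA), 1) * p
  x <- numeric(p)
  passive <- logical(p)
  w <- as.numeric(Atb)          # negative gradient at x = 0
  iter <- 0L
  max_iter <- 30L * p + 30L
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    inner <- 0L
    repeat {
      inner <- inner + 1L
      idx <- which(passive)
      s <- numeric(p)
      s[idx] <- solve(AtA[idx, idx, drop = FALSE], Atb[idx])
      if (min(s[idx]) > tol || inner > p + 1L) { x <- pmax(s, 0); break }
      # backtrack along x -> s to the first coefficient hitting zero
      q <- idx[s[idx] <= tol]
      alpha <- x[q] / (x[q] - s[q])
      alpha[!is.finite(alpha)] <- 0
      x <- x + min(alpha) * (s - x)
      passive[idx[x[idx] <= tol]] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- as.numeric(Atb - AtA %*% x)
  }
  pmax(as.numeric(x), 0)
}

#' Non-negative least squares
#'
#' min ||a_matrix %*% x - b_vector||^2 subject to x >= 0, solved exactly by
#' the active-set method (see [fnnls]).
#'
#' @param a_matrix n x p design matrix.
#' @param b_vector length-n response.
#' @return non-negative coefficient vector of length p.
#' @export
nnls <- function(a_matrix, b_vector) {
  a_matrix <- as.matrix(a_matrix)
  if (nrow(a_matrix) != length(b_vector))
    stop("dimension mismatch: nrow(a_matrix) = ", nrow(a_matrix),
         ", length(b_vector) = ", length(b_vector))
  fnnls(crossprod(a_matrix), as.numeric(crossprod(a_matrix, b_vector)))
}

#' NNLS for many right-hand sides sharing one design
#'
#' @param a_matrix n x p design matrix.
#' @param B n x m matrix of right-hand sides.
#' @return p x m matrix of non-negative solutions.
#' @export
nnls_multi <- function(a_matrix, B) {
  AtA <- crossprod(a_matrix)
  AtB <- crossprod(a_matrix, B)
  p <- ncol(a_matrix)
  matrix(vapply(seq_len(ncol(AtB)), function(j) fnnls(AtA, AtB[, j]),
                numeric(p)), nrow = p)
}
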