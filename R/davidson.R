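# Davidson iterative diagonalization for large symmetric operators.

#' Davidson eigensolver
#'
#' Finds the lowest `n_roots` eigenpairs of a symmetric operator given
#' only matrix-vector products and the diagonal (used as a
#' preconditioner with a level shift).  Defaults: residual tolerance
#' 1e-9, subspace capped at `20 * n_roots` vectors before a restart with
#' the current Ritz vectors, deterministic unit-vector initial guess at
#' the smallest diagonal entries unless a warm start is supplied.
#'
#' @param apply_H function(v) returning H v for a numeric vector v.
#' @param dim problem dimension.
#' @param n_roots number of lowest eigenpairs wanted.
#' @param diag numeric vector: diagonal of H.
#' @param guess optional matrix (dim x k) of starting vectors.
#' @param tol residual 2-norm convergence threshold.
#' @param max_iter maximum subspace expansions.
#' @return list with `values` (ascending), `vectors` (dim x n_roots),
#'   `converged` (logical), `residuals`, `iterations`.
#' @export
davidson <- function(apply_H, dim, n_roots = 1L, diag, guess = NULL,
                     tol = 1e-9, max_iter = 200L) {
  stopifnot(length(diag) == dim, n_roots >= 1L, n_roots <= dim)
  max_sub <- min(dim, max(20L * n_roots, n_roots + 10L))
  orthonormalize <- function(V, w) {
    # scale first (correction vectors can be tiny near convergence),
    # then twice-is-enough Gram-Schmidt against the columns of V
    nw0 <- sqrt(sum(w^2))
    if (nw0 == 0) return(NULL)
    w <- w / nw0
    for (rep in 1:2) if (ncol(V)) w <- w - V %*% crossprod(V, w)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-7) return(NULL)
    w / nw
  }
  if (is.null(guess)) {
    ord <- order(diag)[seq_len(n_roots)]
    V <- matrix(0, dim, n_roots)
    V[cbind(ord, seq_len(n_roots))] <- 1
  } else {
    guess <- as.matrix(guess)
    V <- matrix(0, dim, 0)
    for (k in seq_len(ncol(guess))) {
      w <- orthonormalize(V, guess[, k])
      if (!is.null(w)) V <- cbind(V, w)
    }
    while (ncol(V) < n_roots) {           # pad if degenerate guess
      e <- numeric(dim); e[order(diag)[ncol(V) + 1L]] <- 1
      w <- orthonormalize(V, e)
      if (!is.null(w)) V <- cbind(V, w)
    }
  }
  W <- apply(V, 2, apply_H)
  if (is.null(dim(W))) W <- matrix(W, ncol = ncol(V))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    A <- crossprod(V, W)
    A <- (A + t(A)) / 2
    es <- eigen(A, symmetric = TRUE)
    ord <- order(es$values)[seq_len(n_roots)]
    theta <- es$values[ord]
    Y <- es$vectors[, ord, drop = FALSE]
    X <- V %*% Y                          # Ritz vectors
    HX <- W %*% Y
    R <- HX - sweep(X, 2, theta, "*")
    rnorm <- sqrt(colSums(R^2))
    if (all(rnorm <= tol) || iterations >= max_iter) {
      return(list(values = theta, vectors = X,
                  converged = all(rnorm <= tol), residuals = rnorm,
                  iterations = iterations))
    }
    if (ncol(V) + n_roots > max_sub) {    # restart from Ritz vectors
      V <- X
      qrv <- qr(V)
      V <- qr.Q(qrv)
      W <- apply(V, 2, apply_H)
      if (is.null(dim(W))) W <- matrix(W, ncol = ncol(V))
      next
    }
    added <- FALSE
    for (k in seq_len(n_roots)) {
      if (rnorm[k] <= tol) next
      denom <- diag - theta[k]
      # level shift: clipping too aggressively amplifies roundoff in the
      # converged components of the residual
      denom[abs(denom) < 1e-4] <- sign(denom[abs(denom) < 1e-4] + 1e-300) *
        1e-4
      w <- orthonormalize(V, R[, k] / denom)
      if (is.null(w)) next
      V <- cbind(V, w)
      W <- cbind(W, apply_H(as.numeric(w)))
      added <- TRUE
    }
    if (!added) {                         # stagnation: random-free kick
      e <- numeric(dim)
      e[which.max(abs(R[, which.max(rnorm)]))] <- 1
      w <- orthonormalize(V, e)
      if (is.null(w)) {
        return(list(values = theta, vectors = X, converged = FALSE,
                    residuals = rnorm, iterations = iterations))
      }
      V <- cbind(V, w)
      W <- cbind(W, apply_H(as.numeric(w)))
    }
  }
}
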