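# FCI driver: symmetry/Ms-restricted Davidson diagonalization over the
# alpha x beta string grid.

#' Solve the FCI problem for a set of integrals
#'
#' Builds the alpha/beta string spaces with excitation tables, restricts
#' to the symmetry-allowed subset of the determinant grid when a target
#' irrep is given, and converges the lowest `n_roots` eigenstates with
#' the Davidson algorithm driven by the string-based sigma build.
#'
#' @param ints [sfints()] object.
#' @param target_irrep optional irrep code (XOR encoding) of the states.
#' @param ms2 twice the spin projection; defaults to `ints$ms2`.
#' @param n_roots number of states.
#' @param tol Davidson residual tolerance.
#' @param guess optional warm-start matrix (allowed-subspace coordinates,
#'   one column per root).
#' @return list with `energies` (ascending), `states` (list of
#'   [civector()]), `space_a`, `space_b`, `mask`, `converged`.
#' @export
fci_solve <- function(ints, target_irrep = NULL, ms2 = NULL, n_roots = 1L,
                      tol = 1e-9, guess = NULL) {
  stopifnot(inherits(ints, "sfints"))
  ints <- convert_notation(ints, "physicists")
  if (is.null(ms2)) ms2 <- ints$ms2
  na <- (ints$n_elec + ms2) %/% 2L
  nb <- (ints$n_elec - ms2) %/% 2L
  sa <- enumerate_strings(ints$M, na, ints$orbsym, tables = TRUE)
  sb <- if (na == nb) sa else
    enumerate_strings(ints$M, nb, ints$orbsym, tables = TRUE)
  mask <- symmetry_mask(sa, sb, target_irrep)
  nallow <- sum(mask)
  if (nallow == 0L)
    stop("fci_solve: no determinant carries the requested irrep")
  n_roots <- min(n_roots, nallow)
  dg <- hamiltonian_diagonal(sa, sb, ints)
  embed <- function(v) {
    b <- matrix(0, sa$nstr, sb$nstr)
    b[mask] <- v
    b
  }
  apply_H <- function(v) {
    d <- sigma(embed(v), sa, sb, ints, diag = dg)
    d[mask]
  }
  res <- davidson(apply_H, dim = nallow, n_roots = n_roots,
                  diag = dg[mask], guess = guess, tol = tol)
  states <- lapply(seq_len(n_roots), function(k)
    civector(embed(res$vectors[, k]), sa, sb, target_irrep))
  list(energies = res$values, states = states, space_a = sa, space_b = sb,
       mask = mask, converged = res$converged, residuals = res$residuals)
}

#' Flatten a CI vector to a determinant-expansion table
#'
#' @param state [civector()] object.
#' @param drop_zero drop coefficients below `1e-14` in magnitude.
#' @return [wfn_sd()] data frame with columns `alpha`, `beta`, `coef`.
#' @export
civector_to_wfn <- function(state, drop_zero = TRUE) {
  stopifnot(inherits(state, "civector"))
  sa <- state$space_a; sb <- state$space_b
  idx <- which(matrix(TRUE, sa$nstr, sb$nstr), arr.ind = TRUE)
  co <- as.numeric(state$coef)
  keep <- if (drop_zero) abs(co) > 1e-14 else rep(TRUE, length(co))
  wfn_sd(alpha = sa$strings[idx[keep, 1]],
         beta = sb$strings[idx[keep, 2]],
         coef = co[keep], M = sa$M)
}
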