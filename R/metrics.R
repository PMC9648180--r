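# Comparison metrics: multireference character and the unnormalized
# root-sum-of-squares error with global-phase alignment.

#' Multireference character of a CI coefficient vector
#'
#' `sigma_MR = sum_i c_i^2 (1 - c_i^2) = 1 - sum_i c_i^4` for a
#' normalized expansion: 0 for a single-configuration state and
#' approaching 1 as the weight spreads over many important
#' configurations.  The input is normalized internally; the value is
#' invariant under coefficient permutation and global phase.
#'
#' @param coeffs numeric coefficient vector (or a [wfn_sd()]).
#' @return scalar in `[0, 1)`.
#' @export
multireference_character <- function(coeffs) {
  if (inherits(coeffs, "wfn_sd")) coeffs <- coeffs$coef
  nrm2 <- sum(coeffs^2)
  if (nrm2 == 0) stop("multireference_character: zero norm")
  w <- coeffs^2 / nrm2
  1 - sum(w^2)
}

#' Unnormalized root-sum-of-squares error
#'
#' `delta = sqrt(sum_i (A_i - Aref_i)^2)` over all elements of the
#' compared quantity (energy, RDM, or wavefunction coefficients).  With
#' `phase_align = TRUE` the global sign of `A` minimizing delta is
#' applied first (wavefunctions are defined up to a global phase).
#'
#' @param A,A_ref numeric arrays of identical shape.
#' @param phase_align try both global signs of `A`.
#' @return list (class `error_report`) with `delta`, `phase`.
#' @export
error_norm <- function(A, A_ref, phase_align = FALSE) {
  if (length(A) != length(A_ref))
    stop("error_norm: shape mismatch")
  d_plus <- sqrt(sum((A - A_ref)^2))
  phase <- 1
  delta <- d_plus
  if (phase_align) {
    d_minus <- sqrt(sum((-A - A_ref)^2))
    if (d_minus < d_plus) {
      delta <- d_minus
      phase <- -1
    }
  }
  structure(list(delta = delta, phase = phase), class = "error_report")
}

#' Compare two determinant expansions over their union determinant set
#'
#' Embeds both wavefunctions in the union of their determinant sets
#' (missing coefficients are zero) and reports the phase-aligned
#' unnormalized error.
#'
#' @param wfn,wfn_ref [wfn_sd()] objects over the same orbital space.
#' @return `error_report` list.
#' @export
wavefunction_error <- function(wfn, wfn_ref) {
  M <- max(wfn_M(wfn), wfn_M(wfn_ref))
  ka <- wfn_key(wfn$alpha, wfn$beta, M)
  kb <- wfn_key(wfn_ref$alpha, wfn_ref$beta, M)
  keys <- sort(unique(c(ka, kb)))
  va <- numeric(length(keys)); vb <- numeric(length(keys))
  va[match(ka, keys)] <- wfn$coef
  vb[match(kb, keys)] <- wfn_ref$coef
  error_norm(va, vb, phase_align = TRUE)
}
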