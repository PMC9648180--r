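# Spin operators on determinant expansions: S^2 via ladder operators,
# Loewdin projection of a configuration seed onto spin quantum number k,
# and spin-contamination diagnostics.
#
# Fermionic phases follow the canonical spin-then-orbital operator
# order: the position of spin orbital (p, alpha) in a determinant's
# creation string is its rank among occupied alpha orbitals; (p, beta)
# sits after the full alpha block.

# apply annihilation (dagger = FALSE) or creation (TRUE) of spatial
# orbital `orb` with spin `spin` (1 = alpha, 2 = beta) to a determinant;
# returns list(alpha, beta, phase) or NULL if annihilated
apply_ferm_op <- function(alpha, beta, orb, spin, dagger) {
  bit <- bitwShiftL(1L, orb - 1L)
  na <- popcount(alpha)
  if (spin == 1L) {
    occ <- bitwAnd(alpha, bit) != 0L
    if (dagger == occ) return(NULL)
    nbefore <- popcount(bitwAnd(alpha, bit - 1L))
    phase <- if (nbefore %% 2L == 0L) 1 else -1
    list(alpha = bitwXor(alpha, bit), beta = beta, phase = phase)
  } else {
    occ <- bitwAnd(beta, bit) != 0L
    if (dagger == occ) return(NULL)
    nbefore <- na + popcount(bitwAnd(beta, bit - 1L))
    phase <- if (nbefore %% 2L == 0L) 1 else -1
    list(alpha = alpha, beta = bitwXor(beta, bit), phase = phase)
  }
}

# apply S+ = sum_i a+_{i alpha} a_{i beta} (or S- with plus = FALSE) to
# a wavefunction expansion
apply_ladder <- function(wfn, plus = TRUE) {
  M <- wfn_M(wfn)
  outa <- integer(0); outb <- integer(0); outc <- numeric(0)
  for (k in seq_len(nrow(wfn))) {
    a <- wfn$alpha[k]; b <- wfn$beta[k]; c0 <- wfn$coef[k]
    for (i in seq_len(M)) {
      s1 <- apply_ferm_op(a, b, i, if (plus) 2L else 1L, dagger = FALSE)
      if (is.null(s1)) next
      s2 <- apply_ferm_op(s1$alpha, s1$beta, i, if (plus) 1L else 2L,
                          dagger = TRUE)
      if (is.null(s2)) next
      outa <- c(outa, s2$alpha); outb <- c(outb, s2$beta)
      outc <- c(outc, c0 * s1$phase * s2$phase)
    }
  }
  wfn_dedup(wfn_sd(outa, outb, outc, M), tol = 0)
}

#' Apply the total-spin operator S^2 to a determinant expansion
#'
#' Uses `S^2 = S- S+ + S_z (S_z + 1)`, with the ladder operators acting
#' orbital by orbital (flip beta to alpha and back).  The spin
#' projection Ms must be uniform across the expansion and is preserved.
#'
#' @param wfn [wfn_sd()] object.
#' @return `wfn_sd` expansion of `S^2 |Psi>` (duplicates merged).
#' @export
apply_s2 <- function(wfn) {
  if (nrow(wfn) == 0L) return(wfn)
  ms_each <- (popcount(wfn$alpha) - popcount(wfn$beta)) / 2
  if (length(unique(ms_each)) != 1L) stop("apply_s2: mixed Ms input")
  ms <- ms_each[1]
  up <- apply_ladder(wfn, plus = TRUE)
  down <- if (nrow(up)) apply_ladder(up, plus = FALSE) else up
  diag_part <- wfn
  diag_part$coef <- diag_part$coef * ms * (ms + 1)
  M <- wfn_M(wfn)
  wfn_dedup(wfn_sd(c(down$alpha, diag_part$alpha),
                   c(down$beta, diag_part$beta),
                   c(down$coef, diag_part$coef), M), tol = 0)
}

#' Expectation value of S^2
#'
#' @param wfn [wfn_sd()] object (normalized or not; the value is
#'   norm-corrected).
#' @return scalar `<Psi|S^2|Psi> / <Psi|Psi>`.
#' @export
s2_expectation <- function(wfn) {
  nrm2 <- sum(wfn$coef^2)
  if (nrm2 == 0) stop("s2_expectation: zero norm")
  sw <- apply_s2(wfn)
  both <- merge(wfn, sw, by = c("alpha", "beta"), suffixes = c("", ".s2"))
  sum(both$coef * both$coef.s2) / nrm2
}

#' Spin-contamination error
#'
#' `| <S^2> - S(S+1) |`, the deviation of a determinant expansion from
#' a pure spin state.
#'
#' @param wfn [wfn_sd()] object.
#' @param S target total-spin quantum number.
#' @return non-negative scalar.
#' @export
spin_error <- function(wfn, S) {
  abs(s2_expectation(wfn) - S * (S + 1))
}

#' Loewdin spin projection of a seed determinant
#'
#' Projects a seed configuration onto total spin `k` by the product of
#' annihilating factors `(S^2 - r(r+1)) / (k(k+1) - r(r+1))` over every
#' attainable spin quantum number `r != k` (from the minimum compatible
#' with the unpaired-electron count up to half that count), removing
#' duplicate determinants after each factor and normalizing at the end.
#'
#' @param seed [sdet()] or [wfn_sd()] seed configuration (fixed Ms).
#' @param k target spin quantum number (`<S^2> = k(k+1)`).
#' @param M number of spatial orbitals (defaults to the highest occupied
#'   orbital of an `sdet` seed).
#' @return normalized [wfn_sd()] expansion, or an empty `wfn_sd` (0
#'   rows) if the seed has no spin-`k` component.
#' @export
spin_project <- function(seed, k, M = NULL) {
  if (inherits(seed, "sdet")) {
    if (is.null(M)) {
      occ_all <- bitwOr(seed$alpha, seed$beta)
      M <- if (occ_all > 0L) max(occupied_orbitals(occ_all)) else 1L
    }
    wfn <- wfn_sd(seed$alpha, seed$beta, 1, M)
  } else {
    wfn <- seed
  }
  npair_open <- popcount(bitwXor(wfn$alpha[1], wfn$beta[1]))
  smax <- npair_open / 2
  ms <- (popcount(wfn$alpha[1]) - popcount(wfn$beta[1])) / 2
  if (k > smax + 1e-12 || k < abs(ms) - 1e-12)
    stop("spin_project: k outside [|Ms|, n_unpaired/2]")
  rmin <- smax - floor(smax)      # 0 for integer ladder, 1/2 otherwise
  rs <- seq(rmin, smax, by = 1)
  rs <- rs[abs(rs - k) > 1e-12]
  for (r in rs) {
    s2w <- apply_s2(wfn)
    shifted <- wfn
    shifted$coef <- shifted$coef * (-r * (r + 1))
    wfn <- wfn_dedup(wfn_sd(c(s2w$alpha, shifted$alpha),
                            c(s2w$beta, shifted$beta),
                            c(s2w$coef, shifted$coef) /
                              (k * (k + 1) - r * (r + 1)),
                            wfn_M(wfn)), tol = 1e-12)
    if (nrow(wfn) == 0L) return(wfn)
  }
  if (sqrt(sum(wfn$coef^2)) < 1e-10)
    return(wfn[0, , drop = FALSE])
  wfn_sort(wfn_normalize(wfn))
}

#' Expand configuration state functions to a deduplicated SD expansion
#'
#' Applies [spin_project()] to each seed, removes duplicates within each
#' seed's small determinant set as the projector factors are applied,
#' then merges the per-seed expansions and removes duplicates globally.
#'
#' @param seeds list of [sdet()] seed configurations.
#' @param k target spin quantum number.
#' @param coefs per-seed mixing coefficients (default: equal weights).
#' @return normalized [wfn_sd()] over the union determinant set.
#' @export
csfs_to_sd <- function(seeds, k, coefs = NULL) {
  if (is.null(coefs)) coefs <- rep(1, length(seeds))
  parts <- Map(function(s, c0) {
    w <- spin_project(s, k)
    w$coef <- w$coef * c0
    w
  }, seeds, coefs)
  parts <- Filter(function(w) nrow(w) > 0L, parts)
  if (length(parts) == 0L) stop("csfs_to_sd: every seed projects to zero")
  M <- max(vapply(parts, wfn_M, integer(1)))
  all <- wfn_sd(unlist(lapply(parts, `[[`, "alpha")),
                unlist(lapply(parts, `[[`, "beta")),
                unlist(lapply(parts, `[[`, "coef")), M)
  all <- wfn_dedup(all)
  if (nrow(all) == 0L || sum(all$coef^2) < 1e-20)
    stop("csfs_to_sd: seed expansions cancel; check mixing coefficients")
  wfn_sort(wfn_normalize(all))
}
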