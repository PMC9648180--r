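# Truncated CI(n) and Monte Carlo configuration interaction (MCCI).
#
# Both work in explicit determinant subspaces with a stored symmetric
# subspace Hamiltonian.  MCCI grows the space by random single/double
# substitutions of current configurations, diagonalizes (Davidson,
# warm-started from the previous coefficients), and prunes newly added
# configurations whose absolute coefficient falls below c_min; every
# tenth iteration all configurations except the protected reference are
# considered for deletion.

# Aufbau reference determinant for a set of integrals: lowest `na`/`nb`
# orbitals by diagonal one-electron energy order h_pp (ties by index)
reference_determinant <- function(ints, ms2 = NULL) {
  if (is.null(ms2)) ms2 <- ints$ms2
  na <- (ints$n_elec + ms2) %/% 2L
  nb <- (ints$n_elec - ms2) %/% 2L
  ord <- order(diag(ints$h), seq_len(ints$M))
  sdet(orb_mask(ord[seq_len(na)]), orb_mask(ord[seq_len(nb)]))
}

# dense subspace Hamiltonian over a determinant list
subspace_hamiltonian <- function(dets, ints) {
  n <- length(dets)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    v <- hamiltonian_element(dets[[i]], dets[[j]], ints)
    H[i, j] <- v; H[j, i] <- v
  }
  H
}

# lowest eigenpairs of a stored symmetric matrix; Davidson with warm
# start for larger spaces, dense eigen otherwise
subspace_diagonalize <- function(H, n_roots, guess = NULL, tol = 1e-9) {
  n <- nrow(H)
  if (n <= 64L || n_roots > n %/% 4L) {
    es <- eigen((H + t(H)) / 2, symmetric = TRUE)
    ord <- order(es$values)[seq_len(n_roots)]
    return(list(values = es$values[ord],
                vectors = es$vectors[, ord, drop = FALSE]))
  }
  res <- davidson(function(v) as.numeric(H %*% v), dim = n,
                  n_roots = n_roots, diag = diag(H), guess = guess,
                  tol = tol)
  list(values = res$values, vectors = res$vectors)
}

#' Solve truncated CI(n) in the substitution space of a reference
#'
#' Variational eigenstates in the space of determinants at excitation
#' degree at most `level` from the reference determinant, with optional
#' symmetry filtering.  `level = 2` is CISD, `level = 4` CI(4) =
#' CISDTQ, and `level >= N_e` recovers FCI.
#'
#' @param ints [sfints()] object.
#' @param level maximum substitution level (>= 1).
#' @param target_irrep optional irrep code.
#' @param ms2 twice the spin projection (defaults to `ints$ms2`).
#' @param n_roots number of states.
#' @param reference optional [sdet()]; defaults to the Aufbau
#'   determinant of `ints`.
#' @return list with `energies`, `wfns` (list of [wfn_sd()]), `dets`,
#'   `reference`.
#' @export
truncated_ci_solve <- function(ints, level, target_irrep = NULL, ms2 = NULL,
                               n_roots = 1L, reference = NULL) {
  stopifnot(level >= 1L)
  ints <- convert_notation(ints, "physicists")
  if (is.null(ms2)) ms2 <- ints$ms2
  if (is.null(reference)) reference <- reference_determinant(ints, ms2)
  dets <- truncated_det_list(reference, level, ints$M, ints$orbsym,
                             target_irrep)
  if (length(dets) == 0L) stop("truncated_ci_solve: empty space")
  H <- subspace_hamiltonian(dets, ints)
  es <- subspace_diagonalize(H, n_roots)
  wfns <- lapply(seq_len(n_roots), function(k)
    wfn_sort(wfn_sd(vapply(dets, `[[`, integer(1), "alpha"),
                    vapply(dets, `[[`, integer(1), "beta"),
                    es$vectors[, k], ints$M)))
  list(energies = es$values, wfns = wfns, dets = dets,
       reference = reference)
}

# all determinants at total excitation degree <= level from `reference`,
# optionally symmetry filtered; enumerated per-channel by level
truncated_det_list <- function(reference, level, M, orbsym = NULL,
                               target_irrep = NULL) {
  na <- popcount(reference$alpha)
  nb <- popcount(reference$beta)
  if (is.null(orbsym)) orbsym <- integer(M)
  strs_by_level <- function(n, refmask) {
    if (n == 0L) return(list(`0` = 0L))
    cmb <- utils::combn(M, n)
    masks <- vapply(seq_len(ncol(cmb)), function(j) orb_mask(cmb[, j]),
                    integer(1))
    lev <- popcount(bitwAnd(bitwXor(masks, refmask), refmask))
    split(masks, lev)
  }
  la <- strs_by_level(na, reference$alpha)
  lb <- strs_by_level(nb, reference$beta)
  dets <- list()
  for (ka in names(la)) for (kb in names(lb)) {
    if (as.integer(ka) + as.integer(kb) > level) next
    for (a in la[[ka]]) for (b in lb[[kb]]) {
      if (!is.null(target_irrep)) {
        g <- bitwXor(string_irrep(a, orbsym), string_irrep(b, orbsym))
        if (g != target_irrep) next
      }
      dets[[length(dets) + 1L]] <- sdet(a, b)
    }
  }
  # canonical (beta-major) order for reproducibility
  keys <- vapply(dets, function(d) as.numeric(d$beta) * 2^M + d$alpha,
                 numeric(1))
  dets[order(keys)]
}

# ---------------------------------------------------------------------------
# MCCI
# ---------------------------------------------------------------------------

#' Create an MCCI state
#'
#' @param ints [sfints()] object (stored in physicists' notation).
#' @param c_min coefficient-magnitude deletion cutoff.
#' @param target_irrep optional irrep code.
#' @param ms2 twice the spin projection.
#' @param n_roots tracked roots.
#' @param seed RNG seed (all augmentation randomness derives from
#'   `(seed, iteration)`).
#' @return object of class `mcci_state`.
#' @export
mcci_state <- function(ints, c_min, target_irrep = NULL, ms2 = NULL,
                       n_roots = 1L, seed = 1L) {
  ints <- convert_notation(ints, "physicists")
  if (is.null(ms2)) ms2 <- ints$ms2
  ref <- reference_determinant(ints, ms2)
  st <- structure(
    list(ints = ints, c_min = c_min, target_irrep = target_irrep,
         ms2 = ms2, n_roots = n_roots, seed = as.integer(seed),
         dets = list(ref), new_flag = FALSE, reference_key = det_key(ref),
         H_sub = NULL, coeffs = NULL, energies = NULL,
         iteration = 0L, energy_history = numeric(0)),
    class = "mcci_state")
  st$H_sub <- subspace_hamiltonian(st$dets, ints)
  st
}

det_key <- function(d) paste(d$alpha, d$beta)

#' Randomly augment an MCCI configuration space
#'
#' Attempts to add up to `n_add` distinct symmetry/Ms-allowed single or
#' double substitutions of randomly chosen current configurations.
#' Deterministic for a fixed `(seed, iteration)`; a saturated space
#' yields fewer (possibly zero) additions.
#'
#' @param state `mcci_state`.
#' @param n_add number of candidate configurations to attempt.
#' @return state with new configurations appended and flagged.
#' @export
mcci_augment <- function(state, n_add) {
  stopifnot(n_add >= 1L)
  set.seed((state$seed * 7919L + state$iteration * 104729L) %% 2147483647L)
  keys <- vapply(state$dets, det_key, character(1))
  added <- list()
  attempts <- 0L
  max_attempts <- 50L * n_add
  while (length(added) < n_add && attempts < max_attempts) {
    attempts <- attempts + 1L
    base <- state$dets[[sample.int(length(state$dets), 1L)]]
    subs <- enumerate_substitutions(base, 2L, state$ints$M,
                                    state$ints$orbsym, state$target_irrep)
    if (length(subs) == 0L) next
    cand <- subs[[sample.int(length(subs), 1L)]]
    k <- det_key(cand)
    if (k %in% keys) next
    keys <- c(keys, k)
    added[[length(added) + 1L]] <- cand
  }
  if (length(added)) {
    state$dets <- c(state$dets, added)
    state$new_flag <- c(state$new_flag, rep(TRUE, length(added)))
    state <- subspace_hamiltonian_update(
      state, added = length(state$dets) - length(added) + seq_along(added),
      removed = integer(0))
  }
  state
}

#' Incrementally update the stored subspace Hamiltonian
#'
#' Only rows/columns of added or removed configurations are touched; the
#' result is identical to a from-scratch rebuild.
#'
#' @param state `mcci_state` whose `dets` already reflect the edit.
#' @param added integer indices (into the current `dets`) of rows to
#'   compute.
#' @param removed integer indices (into the previous `dets`) of
#'   rows/columns to drop, applied before `added` rows are computed.
#' @return state with updated `H_sub`.
#' @export
subspace_hamiltonian_update <- function(state, added = integer(0),
                                        removed = integer(0)) {
  H <- state$H_sub
  if (length(removed)) {
    if (any(removed < 1L) || any(removed > nrow(H)))
      stop("subspace_hamiltonian_update: unknown configuration in removed")
    H <- H[-removed, -removed, drop = FALSE]
  }
  n <- length(state$dets)
  if (length(added)) {
    stopifnot(nrow(H) + length(added) == n)
    Hnew <- matrix(0, n, n)
    old <- setdiff(seq_len(n), added)
    Hnew[old, old] <- H
    for (i in added) for (j in seq_len(n)) {
      if (j %in% added && j < i) next
      v <- hamiltonian_element(state$dets[[i]], state$dets[[j]], state$ints)
      Hnew[i, j] <- v; Hnew[j, i] <- v
    }
    H <- Hnew
  }
  state$H_sub <- H
  state
}

# diagonalize the current MCCI space, warm-starting from prior coefficients
mcci_diagonalize <- function(state) {
  n <- length(state$dets)
  guess <- NULL
  if (!is.null(state$coeffs) && nrow(state$coeffs) <= n) {
    guess <- matrix(0, n, ncol(state$coeffs))
    guess[seq_len(nrow(state$coeffs)), ] <- state$coeffs
  }
  es <- subspace_diagonalize(state$H_sub, min(state$n_roots, n), guess)
  state$coeffs <- es$vectors
  state$energies <- es$values
  state
}

#' Prune an MCCI configuration space by coefficient magnitude
#'
#' Removes configurations whose maximum absolute coefficient over the
#' tracked roots is below `c_min`.  With `full = FALSE` only
#' newly added configurations are candidates; with `full = TRUE` every
#' configuration except the protected reference is.  The subspace
#' Hamiltonian and coefficients are updated incrementally.
#'
#' @param state diagonalized `mcci_state`.
#' @param full consider all configurations for deletion.
#' @return pruned state (new-flags cleared).
#' @export
mcci_prune <- function(state, full = FALSE) {
  stopifnot(!is.null(state$coeffs))
  cmax <- apply(abs(state$coeffs), 1, max)
  keys <- vapply(state$dets, det_key, character(1))
  candidate <- if (full) rep(TRUE, length(state$dets)) else state$new_flag
  candidate[keys == state$reference_key] <- FALSE
  drop <- which(candidate & cmax < state$c_min)
  if (length(drop)) {
    state$dets <- state$dets[-drop]
    state$new_flag <- state$new_flag[-drop]
    state$coeffs <- state$coeffs[-drop, , drop = FALSE]
    state <- subspace_hamiltonian_update(state, removed = drop)
    nrm <- sqrt(colSums(state$coeffs^2))
    state$coeffs <- sweep(state$coeffs, 2, pmax(nrm, 1e-300), "/")
  }
  state$new_flag <- rep(FALSE, length(state$dets))
  state
}

#' Run the MCCI selected-CI loop
#'
#' Repeats augment / diagonalize / prune, warm-starting Davidson from
#' the previous coefficients, with a full-deletion sweep every 10
#' iterations.  Convergence: the energy change between consecutive
#' full-prune checkpoints stays below `conv_thresh` for `conv_window`
#' consecutive checkpoints.
#'
#' @param ints [sfints()] object.
#' @param c_min coefficient cutoff.
#' @param target_irrep optional irrep code.
#' @param ms2 twice the spin projection.
#' @param n_roots tracked roots (energies reported for root 1).
#' @param seed RNG seed.
#' @param n_add configurations attempted per iteration; default
#'   `max(50, current space size)`.
#' @param max_iter iteration cap.
#' @param conv_thresh checkpoint energy-change threshold (hartree).
#' @param conv_window consecutive converged checkpoints required.
#' @param verbose print one line per iteration.
#' @return list with `wfn` ([wfn_sd()], sorted), `energy`,
#'   `energy_history`, `n_configs`, `converged`, `state`.
#' @export
mcci_run <- function(ints, c_min, target_irrep = NULL, ms2 = NULL,
                     n_roots = 1L, seed = 1L, n_add = NULL,
                     max_iter = 200L, conv_thresh = 5e-4,
                     conv_window = 2L, verbose = FALSE) {
  state <- mcci_state(ints, c_min, target_irrep, ms2, n_roots, seed)
  state <- mcci_diagonalize(state)
  last_checkpoint <- Inf
  hits <- 0L
  converged <- FALSE
  while (state$iteration < max_iter) {
    state$iteration <- state$iteration + 1L
    na_iter <- if (is.null(n_add)) max(50L, length(state$dets)) else n_add
    state <- mcci_augment(state, na_iter)
    state <- mcci_diagonalize(state)
    full <- state$iteration %% 10L == 0L
    state <- mcci_prune(state, full = full)
    state <- mcci_diagonalize(state)
    e <- state$energies[1]
    state$energy_history <- c(state$energy_history, e)
    if (verbose)
      message(sprintf("iter %4d  configs %6d  E = %.10f", state$iteration,
                      length(state$dets), e))
    if (full) {
      if (abs(e - last_checkpoint) < conv_thresh) hits <- hits + 1L
      else hits <- 0L
      last_checkpoint <- e
      if (hits >= conv_window) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("mcci_run: not converged within max_iter; returning best state")
  wfn <- wfn_sort(wfn_normalize(wfn_sd(
    vapply(state$dets, `[[`, integer(1), "alpha"),
    vapply(state$dets, `[[`, integer(1), "beta"),
    state$coeffs[, 1], ints$M)))
  list(wfn = wfn, energy = state$energies[1],
       energy_history = state$energy_history,
       n_configs = length(state$dets), converged = converged, state = state)
}
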