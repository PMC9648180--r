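# Brute-force second-quantization oracle.
#
# Determinants are explicit ordered spin-orbital lists in the canonical
# spin-then-orbital order (alpha block ascending, then beta block); a
# spin orbital is encoded (spin - 1) * 100 + orbital so that numeric
# order coincides with the canonical operator order.  Creation and
# annihilation act by list manipulation with explicit fermionic phases.
# Everything here is independent of the package's bitwise code paths.

so_code <- function(orb, spin) (spin - 1L) * 100L + orb
so_orb <- function(code) code %% 100L
so_spin <- function(code) code %/% 100L + 1L

det_to_solist <- function(d) {
  c(so_code(occupied_orbitals(d$alpha), 1L),
    so_code(occupied_orbitals(d$beta), 2L))
}

solist_to_key <- function(sol) paste(sort(sol), collapse = ",")

# annihilate spin orbital `code` from canonical list; NULL if absent
orc_annihilate <- function(sol, code) {
  pos <- match(code, sol)
  if (is.na(pos)) return(NULL)
  list(sol = sol[-pos], phase = (-1)^(pos - 1L))
}

# create spin orbital `code`; NULL if present
orc_create <- function(sol, code) {
  if (code %in% sol) return(NULL)
  pos <- sum(sol < code)
  list(sol = append(sol, code, after = pos), phase = (-1)^pos)
}

# apply a product of operators, rightmost first; `codes` and `dagger`
# are parallel vectors describing the operator string left-to-right
orc_apply_ops <- function(sol, codes, dagger) {
  phase <- 1
  for (k in rev(seq_along(codes))) {
    r <- if (dagger[k]) orc_create(sol, codes[k]) else
      orc_annihilate(sol, codes[k])
    if (is.null(r)) return(NULL)
    sol <- r$sol
    phase <- phase * r$phase
  }
  list(sol = sol, phase = phase)
}

# <bra| op |ket> for canonical spin-orbital lists
orc_matrix_element <- function(bra_sol, ket_sol, codes, dagger) {
  r <- orc_apply_ops(ket_sol, codes, dagger)
  if (is.null(r)) return(0)
  if (!identical(sort(r$sol), sort(bra_sol))) return(0)
  r$phase
}

# spin-free 2-RDM by brute force: Gamma[p,r,s,q] =
# sum_{spins} sum_{ij} c_i c_j <i| a+_p a+_r a_s a_q |j>
oracle_rdm2 <- function(wfn) {
  M <- attr(wfn, "M")
  sols <- lapply(seq_len(nrow(wfn)), function(k)
    det_to_solist(sdet(wfn$alpha[k], wfn$beta[k])))
  G <- array(0, rep(M, 4))
  for (p in 1:M) for (r in 1:M) for (s in 1:M) for (q in 1:M) {
    val <- 0
    for (s1 in 1:2) for (s2 in 1:2) {
      codes <- c(so_code(p, s1), so_code(r, s2),
                 so_code(s, s2), so_code(q, s1))
      dg <- c(TRUE, TRUE, FALSE, FALSE)
      for (i in seq_along(sols)) for (j in seq_along(sols)) {
        me <- orc_matrix_element(sols[[i]], sols[[j]], codes, dg)
        if (me != 0)
          val <- val + wfn$coef[i] * wfn$coef[j] * me
      }
    }
    G[p, r, s, q] <- val
  }
  G
}

# spin-free 1-RDM by brute force (Eq-6 style direct evaluation)
oracle_rdm1 <- function(wfn) {
  M <- attr(wfn, "M")
  sols <- lapply(seq_len(nrow(wfn)), function(k)
    det_to_solist(sdet(wfn$alpha[k], wfn$beta[k])))
  g <- matrix(0, M, M)
  for (p in 1:M) for (q in 1:M) {
    val <- 0
    for (s1 in 1:2) {
      codes <- c(so_code(p, s1), so_code(q, s1))
      for (i in seq_along(sols)) for (j in seq_along(sols))
        val <- val + wfn$coef[i] * wfn$coef[j] *
          orc_matrix_element(sols[[i]], sols[[j]], codes, c(TRUE, FALSE))
    }
    g[p, q] <- val
  }
  g
}

# dense Hamiltonian over a determinant list from the second-quantized
# operator string of the spatial-orbital Hamiltonian (physicists' eri)
oracle_hamiltonian <- function(dets, ints) {
  ints <- convert_notation(ints, "physicists")
  M <- ints$M
  sols <- lapply(dets, det_to_solist)
  n <- length(sols)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    # a two-body operator touches at most two spin orbitals
    if (length(setdiff(sols[[i]], sols[[j]])) > 2L) next
    val <- if (identical(sols[[i]], sols[[j]])) ints$e_core else 0
    for (p in 1:M) for (q in 1:M) {
      if (ints$h[p, q] == 0) next
      for (s1 in 1:2) {
        val <- val + ints$h[p, q] *
          orc_matrix_element(sols[[i]], sols[[j]],
                             c(so_code(p, s1), so_code(q, s1)),
                             c(TRUE, FALSE))
      }
    }
    for (p in 1:M) for (r in 1:M) for (q in 1:M) for (s in 1:M) {
      g <- ints$eri[p, r, q, s]
      if (g == 0) next
      for (s1 in 1:2) for (s2 in 1:2) {
        me <- orc_matrix_element(sols[[i]], sols[[j]],
                                 c(so_code(p, s1), so_code(r, s2),
                                   so_code(s, s2), so_code(q, s1)),
                                 c(TRUE, TRUE, FALSE, FALSE))
        if (me != 0) val <- val + 0.5 * g * me
      }
    }
    H[i, j] <- val
  }
  H
}

# dense S^2 matrix over a determinant list via ladder operators
oracle_s2_matrix <- function(dets) {
  n <- length(dets)
  sols <- lapply(dets, det_to_solist)
  M <- max(vapply(sols, function(s) max(so_orb(s)), integer(1)))
  S2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ms_j <- (popcount(dets[[j]]$alpha) - popcount(dets[[j]]$beta)) / 2
    val <- if (identical(sols[[i]], sols[[j]])) ms_j * (ms_j + 1) else 0
    # S- S+ = sum_{ab} a+_{b beta} a_{b alpha} a+_{a alpha} a_{a beta}
    for (a in 1:M) for (b in 1:M) {
      val <- val + orc_matrix_element(
        sols[[i]], sols[[j]],
        c(so_code(b, 2L), so_code(b, 1L), so_code(a, 1L), so_code(a, 2L)),
        c(TRUE, FALSE, TRUE, FALSE))
    }
    S2[i, j] <- val
  }
  S2
}

# dense Hamiltonian via the package's Slater-Condon element (distinct
# from oracle_hamiltonian, which uses operator algebra)
dense_hamiltonian <- function(dets, ints) {
  ints <- convert_notation(ints, "physicists")
  n <- length(dets)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    v <- hamiltonian_element(dets[[i]], dets[[j]], ints)
    H[i, j] <- v
    H[j, i] <- v
  }
  H
}

# all determinants of (M, na, nb), beta-major order
all_determinants <- function(M, na, nb) {
  sa <- enumerate_strings(M, na)
  sb <- enumerate_strings(M, nb)
  dets <- list()
  for (b in sb$strings) for (a in sa$strings)
    dets[[length(dets) + 1L]] <- sdet(a, b)
  dets
}

# random normalized wavefunction over a subset of a small space
random_wfn <- function(M, na, nb, n_det = NULL, seed = 1) {
  set.seed(seed)
  dets <- all_determinants(M, na, nb)
  if (!is.null(n_det) && n_det < length(dets))
    dets <- dets[sort(sample.int(length(dets), n_det))]
  co <- stats::rnorm(length(dets))
  co <- co / sqrt(sum(co^2))
  wfn_sort(wfn_sd(vapply(dets, `[[`, integer(1), "alpha"),
                  vapply(dets, `[[`, integer(1), "beta"), co, M))
}
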