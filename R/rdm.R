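# Spin-free reduced density matrices from determinant expansions.
#
# Convention: Gamma_prsq = sum_{sigma,sigma'} <Psi| a+_{p sigma}
# a+_{r sigma'} a_{s sigma'} a_{q sigma} |Psi>, with NO factor 1/2
# absorbed ("eq7-no-half").  The energy is then
#   E = sum h_pq gamma_pq + 1/2 sum <pr|qs> Gamma_prsq + E_core.
#
# All pair updates below derive from the four operator arrangements of
# the two creation / two annihilation indices over the differing spin
# orbitals, gated by Kronecker deltas of the spins; they are certified
# against a brute-force second-quantization oracle in the test suite.

#' Spin-free 2-RDM container
#'
#' @param gamma dense M^4 array `Gamma[p, r, s, q]`.
#' @param n_elec electron count the matrix describes.
#' @return object of class `rdm2` with convention tag `"eq7-no-half"`.
#' @export
rdm2 <- function(gamma, n_elec) {
  stopifnot(length(dim(gamma)) == 4L)
  structure(list(gamma = gamma, M = dim(gamma)[1],
                 n_elec = as.integer(n_elec), convention = "eq7-no-half"),
            class = "rdm2")
}

#' @export
print.rdm2 <- function(x, ...) {
  tr <- rdm2_trace(x)
  cat(sprintf("rdm2 (%s): M = %d, N_e = %d, trace = %.8f\n",
              x$convention, x$M, x$n_elec, tr))
  invisible(x)
}

#' Pair trace of a 2-RDM
#'
#' `sum_pr Gamma_prrp`, which must equal `N_e (N_e - 1)`.
#'
#' @param G [rdm2()] object.
#' @return scalar.
#' @export
rdm2_trace <- function(G) {
  M <- G$M
  idx <- as.matrix(expand.grid(p = seq_len(M), r = seq_len(M)))
  sum(G$gamma[cbind(idx[, 1], idx[, 2], idx[, 2], idx[, 1])])
}

#' Spin-free 1-RDM container
#'
#' @param gamma M x M matrix `gamma[p, q]`.
#' @param n_elec electron count.
#' @return object of class `rdm1`.
#' @export
rdm1 <- function(gamma, n_elec) {
  structure(list(gamma = as.matrix(gamma), M = nrow(gamma),
                 n_elec = as.integer(n_elec)),
            class = "rdm1")
}

# ---------------------------------------------------------------------------
# spin-orbital difference bookkeeping for an ordered determinant pair
# ---------------------------------------------------------------------------

# aligned differences for ordered pair (left = di, right = dj), degree 1 or
# 2.  idiff: spin orbitals in di not dj; jdiff: in dj not di.  Within each
# spin channel holes and particles are ascending and paired in order; the
# combined lists put alpha differences before beta.  `sign` is the
# maximum-coincidence sign Theta of <Phi_i| ... |Phi_j> under the
# spin-then-orbital canonical operator order.
pair_diff_info <- function(di, dj) {
  info <- excitation_info(dj, di)   # holes = in dj, particles = in di
  list(degree = info$degree,
       j_orb = c(info$holes_a, info$holes_b),
       j_spin = c(rep(1L, length(info$holes_a)),
                  rep(2L, length(info$holes_b))),
       i_orb = c(info$particles_a, info$particles_b),
       i_spin = c(rep(1L, length(info$particles_a)),
                  rep(2L, length(info$particles_b))),
       sign = info$sign)
}

# generic permutation-parity sign for the same pair, computed from
# explicit spin-orbital operator lists (no bit tricks); used by the
# "orbital then spin ordering" naive strategy as an independent route
pair_sign_generic <- function(di, dj) {
  # canonical spin-then-orbital list as (spin, orbital) code: spin*64 + orb
  so_list <- function(d)
    c(1L * 64L + occupied_orbitals(d$alpha),
      2L * 64L + occupied_orbitals(d$beta))
  li <- so_list(di)
  lj <- so_list(dj)
  jd <- setdiff(lj, li)   # ascending within alpha block then beta block
  id <- setdiff(li, lj)
  stopifnot(length(jd) == length(id))
  rep_list <- lj
  rep_list[match(jd, lj)] <- id
  # parity of permutation carrying rep_list onto li
  perm <- match(li, rep_list)
  parity_of_permutation(perm)
}

parity_of_permutation <- function(perm) {
  visited <- logical(length(perm))
  sgn <- 1L
  for (s in seq_along(perm)) {
    if (visited[s]) next
    len <- 0L
    k <- s
    while (!visited[k]) {
      visited[k] <- TRUE
      k <- perm[k]
      len <- len + 1L
    }
    if (len %% 2L == 0L) sgn <- -sgn
  }
  sgn
}

# ---------------------------------------------------------------------------
# elementary 2-RDM updates (Kronecker-delta-gated operator arrangements)
# ---------------------------------------------------------------------------

# contributions as a matrix with columns p, r, s, q, v (v excludes c_i c_j)
contrib_two_diff <- function(info) {
  i1o <- info$i_orb[1]; i2o <- info$i_orb[2]
  i1s <- info$i_spin[1]; i2s <- info$i_spin[2]
  j1o <- info$j_orb[1]; j2o <- info$j_orb[2]
  j1s <- info$j_spin[1]; j2s <- info$j_spin[2]
  th <- info$sign
  out <- NULL
  if (i1s == j1s && i2s == j2s)
    out <- rbind(out,
                 c(i1o, i2o, j2o, j1o, th),
                 c(i2o, i1o, j1o, j2o, th))
  if (i1s == j2s && i2s == j1s)
    out <- rbind(out,
                 c(i1o, i2o, j1o, j2o, -th),
                 c(i2o, i1o, j2o, j1o, -th))
  out
}

contrib_one_diff <- function(info, spect_orb, spect_spin) {
  io <- info$i_orb; is_ <- info$i_spin
  jo <- info$j_orb
  th <- info$sign
  out <- matrix(0, 0, 5)
  for (k in seq_along(spect_orb)) {
    n <- spect_orb[k]
    out <- rbind(out,
                 c(io, n, n, jo, th),
                 c(n, io, jo, n, th))
    if (spect_spin[k] == is_)
      out <- rbind(out,
                   c(io, n, jo, n, -th),
                   c(n, io, n, jo, -th))
  }
  out
}

contrib_no_diff <- function(occ_orb, occ_spin) {
  n <- length(occ_orb)
  if (n < 2L) return(matrix(0, 0, 5))
  out <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    out <- rbind(out, c(occ_orb[a], occ_orb[b], occ_orb[b], occ_orb[a], 1))
    if (occ_spin[a] == occ_spin[b])
      out <- rbind(out, c(occ_orb[a], occ_orb[b], occ_orb[a], occ_orb[b], -1))
  }
  out
}

apply_contrib <- function(G, contrib, weight, hermitize = FALSE) {
  if (is.null(contrib) || nrow(contrib) == 0L) return(G)
  M <- dim(G)[1]
  flat <- function(idx)
    idx[, 1] + M * (idx[, 2] - 1) + M^2 * (idx[, 3] - 1) + M^3 * (idx[, 4] - 1)
  ii <- flat(contrib[, 1:4, drop = FALSE])
  vv <- weight * contrib[, 5]
  if (hermitize) {
    ii <- c(ii, flat(contrib[, c(4, 3, 2, 1), drop = FALSE]))
    vv <- c(vv, vv)
  }
  # duplicate index tuples must accumulate, so aggregate before assigning
  acc <- rowsum(vv, ii)
  at <- as.numeric(rownames(acc))
  G[at] <- G[at] + as.numeric(acc)
  G
}

#' Two-difference 2-RDM update
#'
#' Adds the four delta-gated contributions of a degree-2 determinant
#' pair to a 2-RDM accumulator: for aligned left/right spin-orbital
#' differences with maximum-coincidence sign Theta, the straight
#' pairings enter with `+Theta c_i c_j` and the crossed pairings with
#' `-Theta c_i c_j`, each gated by matching spins between the paired
#' creation and annihilation indices.
#'
#' @param G M^4 array accumulator.
#' @param c_i,c_j coefficients of the left / right determinants.
#' @param info [pair difference info][excitation_info()] as produced by
#'   the internal pairing (see `rdm2_naive` source); wrong degree is an
#'   error.
#' @return updated array.
#' @keywords internal
#' @export
rdm2_update_two_diff <- function(G, c_i, c_j, info) {
  if (info$degree != 2L) stop("rdm2_update_two_diff: degree != 2")
  apply_contrib(G, contrib_two_diff(info), c_i * c_j)
}

#' One-difference 2-RDM update
#'
#' Loops over spectator spin orbitals, pairing each with the single
#' difference; same-spin spectators additionally contribute exchange
#' terms with opposite sign.
#'
#' @inheritParams rdm2_update_two_diff
#' @param spect_orb,spect_spin spectator spatial orbitals and spins
#'   (1 = alpha, 2 = beta).
#' @return updated array.
#' @keywords internal
#' @export
rdm2_update_one_diff <- function(G, c_i, c_j, info, spect_orb, spect_spin) {
  if (info$degree != 1L) stop("rdm2_update_one_diff: degree != 1")
  apply_contrib(G, contrib_one_diff(info, spect_orb, spect_spin), c_i * c_j)
}

#' Diagonal (no-difference) 2-RDM update
#'
#' Coulomb-type `+c^2` and same-spin exchange-type `-c^2` contributions
#' for every ordered pair of occupied spin orbitals of one determinant.
#'
#' @param G M^4 array accumulator.
#' @param c2 squared coefficient of the determinant.
#' @param det [sdet()] object.
#' @return updated array.
#' @keywords internal
#' @export
rdm2_update_no_diff <- function(G, c2, det) {
  oa <- occupied_orbitals(det$alpha)
  ob <- occupied_orbitals(det$beta)
  occ_orb <- c(oa, ob)
  occ_spin <- c(rep(1L, length(oa)), rep(2L, length(ob)))
  apply_contrib(G, contrib_no_diff(occ_orb, occ_spin), c2)
}

# ---------------------------------------------------------------------------
# all-pairs builders
# ---------------------------------------------------------------------------

#' 2-RDM by direct loops over determinant pairs
#'
#' Three equivalent strategies: `1` recomputes every maximum-coincidence
#' sign from explicit spin-orbital operator lists (transparent,
#' slowest); `2` uses the bitwise hole/particle/sign machinery; `3`
#' additionally restricts to ordered pairs `i <= j` and adds the
#' hermitian image of each off-diagonal contribution.  All three return
#' identical matrices to machine precision.
#'
#' @param wfn [wfn_sd()] normalized wavefunction.
#' @param strategy 1, 2, or 3.
#' @return [rdm2()] object.
#' @export
rdm2_naive <- function(wfn, strategy = 2L) {
  strategy <- as.integer(strategy)
  stopifnot(strategy %in% 1:3)
  M <- wfn_M(wfn)
  ne <- sum(wfn_nelec(wfn))
  G <- array(0, rep(M, 4))
  n <- nrow(wfn)
  dets <- lapply(seq_len(n), function(k) sdet(wfn$alpha[k], wfn$beta[k]))
  for (jj in seq_len(n)) {
    G <- rdm2_update_no_diff(G, wfn$coef[jj]^2, dets[[jj]])
    ii_range <- if (strategy == 3L) seq_len(jj - 1L) else
      setdiff(seq_len(n), jj)
    for (ii in ii_range) {
      di <- dets[[ii]]; dj <- dets[[jj]]
      deg <- excitation_degree(di, dj)
      if (deg > 2L) next
      info <- pair_diff_info(di, dj)
      if (strategy == 1L) info$sign <- pair_sign_generic(di, dj)
      w <- wfn$coef[ii] * wfn$coef[jj]
      if (deg == 2L) {
        G <- apply_contrib(G, contrib_two_diff(info), w,
                           hermitize = strategy == 3L)
      } else {
        sp <- common_spectators(di, dj)
        G <- apply_contrib(G, contrib_one_diff(info, sp$orb, sp$spin), w,
                           hermitize = strategy == 3L)
      }
    }
  }
  rdm2(G, ne)
}

common_spectators <- function(di, dj) {
  ca <- occupied_orbitals(bitwAnd(di$alpha, dj$alpha))
  cb <- occupied_orbitals(bitwAnd(di$beta, dj$beta))
  list(orb = c(ca, cb), spin = c(rep(1L, length(ca)), rep(2L, length(cb))))
}

# ---------------------------------------------------------------------------
# FCI-structured builder
# ---------------------------------------------------------------------------

#' 2-RDM from a converged FCI vector using the string structure
#'
#' Visits only determinant pairs linked by the precomputed single and
#' double string excitation tables -- O(N_SD M^2) pairs for fixed
#' electron counts -- with fully deterministic serial accumulation.  The
#' number of determinant pairs visited is recorded in attribute
#' `pair_visits`.
#'
#' @param state [civector()] whose string spaces carry excitation tables.
#' @return [rdm2()] object, elementwise equal to [rdm2_naive()] on the
#'   expanded determinant list.
#' @export
rdm2_from_fci <- function(state) {
  stopifnot(inherits(state, "civector"))
  sa <- state$space_a; sb <- state$space_b
  if (is.null(sa$singles) || is.null(sb$singles))
    stop("rdm2_from_fci: string spaces lack excitation tables")
  C <- state$coef
  M <- sa$M
  ne <- sa$n + sb$n
  G <- array(0, rep(M, 4))
  Mi <- as.numeric(M)
  flat <- function(p, r, s, q)
    p + Mi * (r - 1) + Mi^2 * (s - 1) + Mi^3 * (q - 1)
  add_flat <- function(G, idx, val) {
    acc <- rowsum(val, idx)
    ii <- as.numeric(rownames(acc))
    G[ii] <- G[ii] + as.numeric(acc)
    G
  }
  Oa <- channel_occupancy(sa)
  Ob <- channel_occupancy(sb)
  occ_list_a <- lapply(sa$strings, occupied_orbitals)
  occ_list_b <- lapply(sb$strings, occupied_orbitals)
  visits <- 0

  # --- diagonal (no differences) -------------------------------------
  WA <- rowSums(C^2)              # per alpha string
  WB <- colSums(C^2)              # per beta string
  UA <- (C^2) %*% Ob              # alpha string x orbital: beta occupancy wt
  UB <- t(C^2) %*% Oa             # beta string x orbital
  visits <- visits + sa$nstr * sb$nstr
  idx <- numeric(0); val <- numeric(0)
  for (a in seq_len(sa$nstr)) {
    occ <- occ_list_a[[a]]
    if (length(occ) >= 2L) {
      pr <- expand.grid(n = occ, m = occ)
      pr <- pr[pr$n != pr$m, ]
      idx <- c(idx, flat(pr$n, pr$m, pr$m, pr$n), flat(pr$n, pr$m, pr$n, pr$m))
      val <- c(val, rep(WA[a], nrow(pr)), rep(-WA[a], nrow(pr)))
    }
    # alpha-beta cross pairs (Coulomb only)
    gr <- expand.grid(n = occ, m = seq_len(M))
    w <- UA[a, gr$m]
    idx <- c(idx, flat(gr$n, gr$m, gr$m, gr$n), flat(gr$m, gr$n, gr$n, gr$m))
    val <- c(val, w, w)
  }
  for (b in seq_len(sb$nstr)) {
    occ <- occ_list_b[[b]]
    if (length(occ) >= 2L) {
      pr <- expand.grid(n = occ, m = occ)
      pr <- pr[pr$n != pr$m, ]
      idx <- c(idx, flat(pr$n, pr$m, pr$m, pr$n), flat(pr$n, pr$m, pr$n, pr$m))
      val <- c(val, rep(WB[b], nrow(pr)), rep(-WB[b], nrow(pr)))
    }
  }
  G <- add_flat(G, idx, val)

  # --- one-difference and same-spin two-difference ---------------------
  # channel = "a": excitations act on rows of C; "b": on columns
  same_spin_accum <- function(G, sp, occ_list, O_other, channel) {
    S <- sp$singles
    idx <- numeric(0); val <- numeric(0)
    if (nrow(S)) for (k in seq_len(nrow(S))) {
      from <- S$from[k]; to <- S$to[k]
      h <- S$hole[k]; t1 <- S$particle[k]; th <- S$sign[k]
      if (channel == "a") {
        w1 <- th * sum(C[to, ] * C[from, ])
        w2 <- th * as.numeric((C[to, ] * C[from, ]) %*% O_other)
      } else {
        w1 <- th * sum(C[, to] * C[, from])
        w2 <- th * as.numeric((C[, to] * C[, from]) %*% O_other)
      }
      spect <- setdiff(occ_list[[from]], h)
      if (length(spect)) {
        idx <- c(idx, flat(t1, spect, spect, h), flat(spect, t1, h, spect),
                 flat(t1, spect, h, spect), flat(spect, t1, spect, h))
        val <- c(val, rep(w1, length(spect)), rep(w1, length(spect)),
                 rep(-w1, length(spect)), rep(-w1, length(spect)))
      }
      nz <- which(abs(w2) > 0)
      if (length(nz)) {
        idx <- c(idx, flat(t1, nz, nz, h), flat(nz, t1, h, nz))
        val <- c(val, w2[nz], w2[nz])
      }
      if (length(idx) > 200000L) {
        G <- add_flat(G, idx, val); idx <- numeric(0); val <- numeric(0)
      }
    }
    D <- sp$doubles
    if (nrow(D)) for (k in seq_len(nrow(D))) {
      from <- D$from[k]; to <- D$to[k]
      w <- D$sign[k] * (if (channel == "a") sum(C[to, ] * C[from, ]) else
        sum(C[, to] * C[, from]))
      h1 <- D$h1[k]; h2 <- D$h2[k]; t1 <- D$p1[k]; t2 <- D$p2[k]
      idx <- c(idx, flat(t1, t2, h2, h1), flat(t2, t1, h1, h2),
               flat(t1, t2, h1, h2), flat(t2, t1, h2, h1))
      val <- c(val, w, w, -w, -w)
      if (length(idx) > 200000L) {
        G <- add_flat(G, idx, val); idx <- numeric(0); val <- numeric(0)
      }
    }
    if (length(idx)) G <- add_flat(G, idx, val)
    G
  }
  G <- same_spin_accum(G, sa, occ_list_a, Ob, "a")
  G <- same_spin_accum(G, sb, occ_list_b, Oa, "b")
  visits <- visits + nrow(sa$singles) * sb$nstr + nrow(sb$singles) * sa$nstr +
    nrow(sa$doubles) * sb$nstr + nrow(sb$doubles) * sa$nstr

  # --- mixed-spin doubles ----------------------------------------------
  SA <- sa$singles; SB <- sb$singles
  if (nrow(SA) && nrow(SB)) {
    visits <- visits + nrow(SA) * nrow(SB)
    idx <- numeric(0); val <- numeric(0)
    for (k in seq_len(nrow(SA))) {
      ta <- SA$particle[k]; ha <- SA$hole[k]
      w <- SA$sign[k] * SB$sign * C[SA$to[k], SB$to] * C[SA$from[k], SB$from]
      nz <- which(abs(w) > 0)
      if (length(nz)) {
        idx <- c(idx, flat(ta, SB$particle[nz], SB$hole[nz], ha),
                 flat(SB$particle[nz], ta, ha, SB$hole[nz]))
        val <- c(val, w[nz], w[nz])
      }
      if (length(idx) > 200000L) {
        G <- add_flat(G, idx, val); idx <- numeric(0); val <- numeric(0)
      }
    }
    if (length(idx)) G <- add_flat(G, idx, val)
  }
  out <- rdm2(G, ne)
  attr(out, "pair_visits") <- visits
  out
}

# ---------------------------------------------------------------------------
# search-based builder for general (selected) SD wavefunctions
# ---------------------------------------------------------------------------

#' 2-RDM from a general selected-CI determinant list by search
#'
#' For each determinant in the (canonically sorted) expansion, generates
#' its single and double substitutions and locates them in the
#' coefficient list by binary search; only substitutions present in the
#' expansion contribute, plus each determinant's diagonal term.
#'
#' @param wfn [wfn_sd()] sorted with [wfn_sort()] (unsorted input is an
#'   error).
#' @return [rdm2()] object, equal to [rdm2_naive()] to machine precision.
#' @export
rdm2_from_sd_list <- function(wfn) {
  M <- wfn_M(wfn)
  keys <- wfn_key(wfn$alpha, wfn$beta, M)
  if (is.unsorted(keys, strictly = TRUE))
    stop("rdm2_from_sd_list: wavefunction must be wfn_sort()ed")
  ne <- sum(wfn_nelec(wfn))
  G <- array(0, rep(M, 4))
  n <- nrow(wfn)
  for (jj in seq_len(n)) {
    dj <- sdet(wfn$alpha[jj], wfn$beta[jj])
    G <- rdm2_update_no_diff(G, wfn$coef[jj]^2, dj)
    subs <- enumerate_substitutions(dj, 2L, M)
    for (di in subs) {
      k <- wfn_key(di$alpha, di$beta, M)
      pos <- findInterval(k, keys)
      if (pos < 1L || keys[pos] != k) next
      info <- pair_diff_info(di, dj)
      w <- wfn$coef[pos] * wfn$coef[jj]
      if (info$degree == 2L) {
        G <- apply_contrib(G, contrib_two_diff(info), w)
      } else {
        sp <- common_spectators(di, dj)
        G <- apply_contrib(G, contrib_one_diff(info, sp$orb, sp$spin), w)
      }
    }
  }
  rdm2(G, ne)
}

# ---------------------------------------------------------------------------
# 1-RDM and energy
# ---------------------------------------------------------------------------

#' 1-RDM by direct evaluation over determinant pairs
#'
#' `gamma_pq = sum_sigma <Psi| a+_{p sigma} a_{q sigma} |Psi>`; the
#' independent route used to validate the 2-RDM contraction.
#'
#' @param wfn [wfn_sd()] object.
#' @return [rdm1()] object.
#' @export
rdm1_direct <- function(wfn) {
  M <- wfn_M(wfn)
  g <- matrix(0, M, M)
  n <- nrow(wfn)
  dets <- lapply(seq_len(n), function(k) sdet(wfn$alpha[k], wfn$beta[k]))
  for (jj in seq_len(n)) {
    occ <- c(occupied_orbitals(dets[[jj]]$alpha),
             occupied_orbitals(dets[[jj]]$beta))
    for (p in occ) g[p, p] <- g[p, p] + wfn$coef[jj]^2
    for (ii in setdiff(seq_len(n), jj)) {
      if (excitation_degree(dets[[ii]], dets[[jj]]) != 1L) next
      info <- pair_diff_info(dets[[ii]], dets[[jj]])
      g[info$i_orb, info$j_orb] <- g[info$i_orb, info$j_orb] +
        info$sign * wfn$coef[ii] * wfn$coef[jj]
    }
  }
  rdm1(g, sum(wfn_nelec(wfn)))
}

#' Contract a 2-RDM to the 1-RDM
#'
#' `gamma_pq = sum_r Gamma_prrq / (N_e - 1)`.
#'
#' @param G [rdm2()] object.
#' @param n_elec electron count (defaults to the tag stored in `G`).
#' @return [rdm1()] object.
#' @export
rdm1_from_rdm2 <- function(G, n_elec = NULL) {
  stopifnot(inherits(G, "rdm2"))
  if (is.null(n_elec)) n_elec <- G$n_elec
  if (n_elec < 2L) stop("rdm1_from_rdm2 requires N_e >= 2")
  M <- G$M
  g <- matrix(0, M, M)
  for (r in seq_len(M)) g <- g + G$gamma[, r, r, ]
  rdm1(g / (n_elec - 1), n_elec)
}

#' Energy from reduced density matrices
#'
#' `E = sum h_pq gamma_pq + 1/2 sum <pr|qs> Gamma_prsq + E_core`,
#' requiring physicists'-notation integrals and the `"eq7-no-half"`
#' 2-RDM convention.
#'
#' @param ints [sfints()] (converted to physicists' internally).
#' @param g1 [rdm1()] object.
#' @param G [rdm2()] object.
#' @return scalar energy (hartree).
#' @export
energy_from_rdms <- function(ints, g1, G) {
  stopifnot(inherits(ints, "sfints"), inherits(g1, "rdm1"),
            inherits(G, "rdm2"))
  if (!identical(G$convention, "eq7-no-half"))
    stop("energy_from_rdms: unexpected 2-RDM convention tag")
  ints <- convert_notation(ints, "physicists")
  # sum_prsq <pr|qs> Gamma_prsq: align eri[p,r,q,s] with Gamma[p,r,s,q]
  two_e <- sum(ints$eri * aperm(G$gamma, c(1, 2, 4, 3)))
  sum(ints$h * g1$gamma) + 0.5 * two_e + ints$e_core
}

#' Write a 2-RDM as a plain-text sparse dump
#'
#' Self-describing header lines (`# key value`) followed by
#' `p r s q value` records for entries above `tol`.
#'
#' @param G [rdm2()] object.
#' @param path output file.
#' @param tol magnitude threshold for inclusion.
#' @return `path`, invisibly.
#' @export
write_rdm2_sparse <- function(G, path, tol = 1e-12) {
  stopifnot(inherits(G, "rdm2"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rdm2 M %d", G$M),
               sprintf("# n_elec %d", G$n_elec),
               sprintf("# convention %s", G$convention)), con)
  nz <- which(abs(G$gamma) > tol, arr.ind = TRUE)
  if (nrow(nz)) {
    o <- order(nz[, 1], nz[, 2], nz[, 3], nz[, 4])
    nz <- nz[o, , drop = FALSE]
    writeLines(sprintf("%d %d %d %d %.16e", nz[, 1], nz[, 2], nz[, 3],
                       nz[, 4], G$gamma[nz]), con)
  }
  invisible(path)
}

#' Read a sparse 2-RDM dump written by [write_rdm2_sparse()]
#'
#' @param path input file.
#' @return [rdm2()] object.
#' @export
read_rdm2_sparse <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    sub(paste0("^# ", key, " "), "", ln[1])
  }
  M <- as.integer(getv("rdm2 M"))
  ne <- as.integer(getv("n_elec"))
  G <- array(0, rep(M, 4))
  if (length(body)) {
    rec <- do.call(rbind, lapply(strsplit(body, "[ \t]+"), as.numeric))
    G[rec[, 1:4, drop = FALSE]] <- rec[, 5]
  }
  rdm2(G, ne)
}
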