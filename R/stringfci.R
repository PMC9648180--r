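# Alpha/beta-string FCI machinery: string enumeration, excitation
# tables, vector addressing, sigma builds (H b = d), and determinant
# counting by per-irrep string histograms.

#' Enumerate all orbital strings of one spin channel
#'
#' Generates the C(M, n) bitmasks with n of M bits set, in ascending
#' (lexicographic-by-value) order, optionally restricted to one irrep,
#' together with precomputed single- and double-excitation tables used
#' by the sigma build and the structured 2-RDM construction.
#'
#' @param M number of spatial orbitals (<= 31).
#' @param n electrons in this spin channel.
#' @param orbsym optional per-orbital irrep codes.
#' @param irrep_filter optional irrep code: keep only strings of this
#'   irrep.
#' @param tables also build excitation tables (the expensive part;
#'   needed for [sigma()] and [rdm2_from_fci()]).
#' @return object of class `string_space`: list with `M`, `n`, `strings`
#'   (integer bitmask vector), `irreps`, `address` (lookup function),
#'   and if requested `singles` / `doubles` data frames with columns
#'   `from`, `to`, `hole(s)`, `particle(s)`, `sign`.
#' @export
enumerate_strings <- function(M, n, orbsym = NULL, irrep_filter = NULL,
                              tables = FALSE) {
  stopifnot(n >= 0L, n <= M, M <= 31L)
  if (n == 0L) {
    strings <- 0L
  } else {
    cmb <- utils::combn(M, n)
    strings <- vapply(seq_len(ncol(cmb)), function(j) orb_mask(cmb[, j]),
                      integer(1))
    strings <- sort(strings)
  }
  if (is.null(orbsym)) orbsym <- integer(M)
  irr <- string_irrep(strings, orbsym)
  if (!is.null(irrep_filter)) {
    keep <- irr == irrep_filter
    strings <- strings[keep]
    irr <- irr[keep]
  }
  sp <- structure(
    list(M = M, n = n, strings = strings, irreps = irr, orbsym = orbsym,
         nstr = length(strings), singles = NULL, doubles = NULL),
    class = "string_space")
  if (tables && sp$nstr > 0L) sp <- build_excitation_tables(sp)
  sp
}

# index of string bitmasks within a space (0 if absent)
string_address <- function(space, bits) {
  idx <- match(as.integer(bits), space$strings)
  idx[is.na(idx)] <- 0L
  idx
}

# flat singles/doubles tables for every string in the space.  Signs are
# single-channel maximum-coincidence signs; doubles use the sequential
# (hole1->part1 then hole2->part2, ascending) convention.
build_excitation_tables <- function(space) {
  M <- space$M
  n <- space$n
  sF <- sT <- sH <- sP <- sS <- integer(0)
  dF <- dT <- dH1 <- dH2 <- dP1 <- dP2 <- dS <- integer(0)
  for (i in seq_along(space$strings)) {
    s <- space$strings[i]
    occ <- occupied_orbitals(s)
    vir <- setdiff(seq_len(M), occ)
    for (h in occ) for (p in vir) {
      t1 <- bitwXor(s, bitwOr(bitwShiftL(1L, h - 1L),
                              bitwShiftL(1L, p - 1L)))
      j <- string_address(space, t1)
      if (j == 0L) next                     # filtered out by irrep
      sF <- c(sF, i); sT <- c(sT, j); sH <- c(sH, h); sP <- c(sP, p)
      sS <- c(sS, channel_sign(s, t1, h, p))
    }
    if (n >= 2L && length(vir) >= 2L) {
      hp <- utils::combn(occ, 2L)
      pp <- utils::combn(vir, 2L)
      for (a in seq_len(ncol(hp))) for (b in seq_len(ncol(pp))) {
        h1 <- hp[1, a]; h2 <- hp[2, a]
        p1 <- pp[1, b]; p2 <- pp[2, b]
        t2 <- bitwXor(s, Reduce(bitwOr, bitwShiftL(1L, c(h1, h2, p1, p2) - 1L)))
        j <- string_address(space, t2)
        if (j == 0L) next
        dF <- c(dF, i); dT <- c(dT, j)
        dH1 <- c(dH1, h1); dH2 <- c(dH2, h2)
        dP1 <- c(dP1, p1); dP2 <- c(dP2, p2)
        dS <- c(dS, channel_sign(s, t2, c(h1, h2), c(p1, p2)))
      }
    }
  }
  space$singles <- data.frame(from = sF, to = sT, hole = sH, particle = sP,
                              sign = sS)
  space$doubles <- data.frame(from = dF, to = dT, h1 = dH1, h2 = dH2,
                              p1 = dP1, p2 = dP2, sign = dS)
  space
}

#' Map string locations to an FCI vector location
#'
#' The 1-based addressing of the combined determinant grid:
#' `fci_loc = (beta_loc - 1) * alpha_total + alpha_loc`.
#'
#' @param alpha_loc,beta_loc 1-based string locations.
#' @param alpha_total total number of alpha strings.
#' @return 1-based FCI vector location.
#' @export
address_map <- function(alpha_loc, beta_loc, alpha_total) {
  stopifnot(all(alpha_loc >= 1L), all(alpha_loc <= alpha_total),
            all(beta_loc >= 1L))
  (beta_loc - 1L) * alpha_total + alpha_loc
}

#' CI vector over an alpha x beta determinant grid
#'
#' @param coef matrix of coefficients, `dim = c(alpha_total, beta_total)`.
#' @param space_a,space_b [enumerate_strings()] spaces for the two spin
#'   channels.
#' @param target_irrep irrep code of the state (NULL = no symmetry).
#' @return object of class `civector`.
#' @export
civector <- function(coef, space_a, space_b, target_irrep = NULL) {
  coef <- as.matrix(coef)
  stopifnot(nrow(coef) == space_a$nstr, ncol(coef) == space_b$nstr)
  structure(list(coef = coef, space_a = space_a, space_b = space_b,
                 target_irrep = target_irrep),
            class = "civector")
}

# logical grid of symmetry-allowed determinants
symmetry_mask <- function(space_a, space_b, target_irrep) {
  if (is.null(target_irrep))
    return(matrix(TRUE, space_a$nstr, space_b$nstr))
  outer(space_a$irreps, space_b$irreps, function(ga, gb)
    bitwXor(ga, gb) == target_irrep)
}

# per-string one+two electron partial energies and occupation matrix
channel_diag_parts <- function(space, ints) {
  eri <- ints$eri; h <- ints$h
  occm <- matrix(0, space$nstr, space$M)
  evec <- numeric(space$nstr)
  for (i in seq_along(space$strings)) {
    occ <- occupied_orbitals(space$strings[i])
    occm[i, occ] <- 1
    e <- sum(h[cbind(occ, occ)])
    if (length(occ) >= 2L) {
      pr <- utils::combn(occ, 2L)
      for (k in seq_len(ncol(pr))) {
        p <- pr[1, k]; q <- pr[2, k]
        e <- e + eri[p, q, p, q] - eri[p, q, q, p]
      }
    }
    evec[i] <- e
  }
  list(evec = evec, occm = occm)
}

#' Diagonal of the Hamiltonian over the determinant grid
#'
#' @inheritParams sigma
#' @return matrix `alpha_total x beta_total` of diagonal elements
#'   (including `e_core`).
#' @export
hamiltonian_diagonal <- function(space_a, space_b, ints) {
  ints <- convert_notation(ints, "physicists")
  pa <- channel_diag_parts(space_a, ints)
  pb <- channel_diag_parts(space_b, ints)
  M <- ints$M
  # cross Coulomb J[p,q] = <pq|pq>
  J <- matrix(0, M, M)
  for (p in seq_len(M)) for (q in seq_len(M)) J[p, q] <- ints$eri[p, q, p, q]
  outer(pa$evec, pb$evec, "+") + pa$occm %*% J %*% t(pb$occm) + ints$e_core
}

#' Apply the Hamiltonian to a CI trial vector (sigma build)
#'
#' Computes d = H b over the alpha x beta determinant grid using only the
#' precomputed string excitation tables plus the diagonal; the dense
#' Hamiltonian is never formed.  Same-spin double contributions depend
#' only on their own spin channel; single contributions carry a
#' Coulomb coupling to the other channel's occupations; mixed-spin
#' doubles couple one single from each channel.
#'
#' @param b coefficient matrix `alpha_total x beta_total`.
#' @param space_a,space_b string spaces built with `tables = TRUE`.
#' @param ints [sfints()] object (converted to physicists' internally).
#' @param diag optional precomputed [hamiltonian_diagonal()] matrix.
#' @return matrix d of the same shape as `b`.
#' @export
sigma <- function(b, space_a, space_b, ints, diag = NULL) {
  b <- as.matrix(b)
  stopifnot(nrow(b) == space_a$nstr, ncol(b) == space_b$nstr)
  if (is.null(space_a$singles) || is.null(space_b$singles))
    stop("sigma requires string spaces built with tables = TRUE")
  ints <- convert_notation(ints, "physicists")
  eri <- ints$eri; h <- ints$h; M <- ints$M
  if (is.null(diag)) diag <- hamiltonian_diagonal(space_a, space_b, ints)
  d <- diag * b

  occm_a <- channel_occupancy(space_a)
  occm_b <- channel_occupancy(space_b)
  # J3[m,p,n] = <mn|pn>, K3[m,p,n] = <mn|np>
  # flattened lookups below use 1-based arithmetic on array strides
  same_spin_part <- function(space, occm_other, bmat, transposed) {
    # transposed = FALSE: strings index rows of bmat; TRUE: columns
    out <- matrix(0, nrow(bmat), ncol(bmat))
    S <- space$singles
    if (nrow(S)) for (k in seq_len(nrow(S))) {
      i <- S$from[k]; j <- S$to[k]; m <- S$hole[k]; p <- S$particle[k]
      sg <- S$sign[k]
      spect <- setdiff(occupied_orbitals(space$strings[i]), m)
      amp <- h[m, p]
      for (n in spect) amp <- amp + eri[m, n, p, n] - eri[m, n, n, p]
      # other-channel Coulomb: vector over the other channel's strings
      vJ <- occm_other %*% vapply(seq_len(M), function(n) eri[m, n, p, n],
                                  numeric(1))
      if (!transposed) {
        out[j, ] <- out[j, ] + sg * (amp + as.numeric(vJ)) * bmat[i, ]
      } else {
        out[, j] <- out[, j] + sg * (amp + as.numeric(vJ)) * bmat[, i]
      }
    }
    D <- space$doubles
    if (nrow(D)) for (k in seq_len(nrow(D))) {
      m <- D$h1[k]; n <- D$h2[k]; p <- D$p1[k]; q <- D$p2[k]
      val <- D$sign[k] * (eri[m, n, p, q] - eri[m, n, q, p])
      if (!transposed) {
        out[D$to[k], ] <- out[D$to[k], ] + val * bmat[D$from[k], ]
      } else {
        out[, D$to[k]] <- out[, D$to[k]] + val * bmat[, D$from[k]]
      }
    }
    out
  }
  d <- d + same_spin_part(space_a, occm_b, b, transposed = FALSE)
  d <- d + same_spin_part(space_b, occm_a, b, transposed = TRUE)

  # mixed-spin doubles: alpha single (m->p) x beta single (n->q)
  SA <- space_a$singles; SB <- space_b$singles
  if (nrow(SA) && nrow(SB)) {
    # flat physicists' index <m n | p q> = eri[m, n, p, q]
    idx_nq <- function(m, p) {
      # vector over beta singles of eri[m, n_k, p, q_k]
      eri[cbind(m, SB$hole, p, SB$particle)]
    }
    for (k in seq_len(nrow(SA))) {
      m <- SA$hole[k]; p <- SA$particle[k]
      vals <- SA$sign[k] * SB$sign * idx_nq(m, p) *
        b[SA$from[k], SB$from]
      # accumulate into d[SA$to[k], SB$to]; SB$to may repeat
      acc <- rowsum(vals, SB$to)
      d[SA$to[k], as.integer(rownames(acc))] <-
        d[SA$to[k], as.integer(rownames(acc))] + as.numeric(acc)
    }
  }
  d
}

# 0/1 occupancy matrix (nstr x M)
channel_occupancy <- function(space) {
  occm <- matrix(0, space$nstr, space$M)
  for (i in seq_along(space$strings))
    occm[i, occupied_orbitals(space$strings[i])] <- 1
  occm
}

# ---------------------------------------------------------------------------
# Determinant-space counting (no pair enumeration)
# ---------------------------------------------------------------------------

#' Count determinants in a symmetry-adapted FCI space
#'
#' Number of (alpha string, beta string) pairs whose overall irrep
#' product equals `target_irrep`, computed from per-irrep string
#' histograms: `sum_g n_alpha(g) * n_beta(g XOR target)`.  Returned as a
#' double so that spaces beyond 2^31 determinants are representable
#' exactly (counts stay below 2^53).
#'
#' @param M spatial orbitals; `n_alpha`, `n_beta` electrons per channel.
#' @param n_alpha,n_beta electrons per spin channel.
#' @param orbsym per-orbital irrep codes (NULL = no symmetry).
#' @param target_irrep irrep code of the counted space (NULL = all).
#' @return numeric count.
#' @export
count_determinants <- function(M, n_alpha, n_beta, orbsym = NULL,
                               target_irrep = NULL) {
  if (is.null(orbsym) || is.null(target_irrep))
    return(choose(M, n_alpha) * choose(M, n_beta))
  ng <- max_irrep_bins(orbsym)
  ha <- irrep_histogram(M, n_alpha, orbsym, ng)
  hb <- irrep_histogram(M, n_beta, orbsym, ng)
  tot <- 0
  for (g in 0:(ng - 1L))
    tot <- tot + ha[g + 1L] * hb[bitwXor(g, as.integer(target_irrep)) + 1L]
  tot
}

max_irrep_bins <- function(orbsym) {
  ng <- 1L
  while (ng <= max(orbsym)) ng <- ng * 2L
  max(ng, 2L)
}

# histogram over irreps of all C(M, n) strings; numeric to avoid overflow
irrep_histogram <- function(M, n, orbsym, ng) {
  hh <- numeric(ng)
  if (n == 0L) { hh[1] <- 1; return(hh) }
  cmb <- utils::combn(M, n)
  for (j in seq_len(ncol(cmb))) {
    g <- 0L
    for (p in cmb[, j]) g <- bitwXor(g, orbsym[p])
    hh[g + 1L] <- hh[g + 1L] + 1
  }
  hh
}

# joint histogram over (excitation level from reference string, irrep)
level_irrep_histogram <- function(M, n, orbsym, ng, ref_mask) {
  H <- matrix(0, nrow = n + 1L, ncol = ng)
  if (n == 0L) { H[1, 1] <- 1; return(H) }
  cmb <- utils::combn(M, n)
  for (j in seq_len(ncol(cmb))) {
    mask <- orb_mask(cmb[, j])
    lev <- popcount(bitwAnd(bitwXor(mask, ref_mask), ref_mask))
    g <- 0L
    for (p in cmb[, j]) g <- bitwXor(g, orbsym[p])
    H[lev + 1L, g + 1L] <- H[lev + 1L, g + 1L] + 1
  }
  H
}

#' Count determinants in a truncated CI(n) space
#'
#' Number of symmetry/Ms-allowed determinants at excitation degree at
#' most `level` from a reference determinant, via joint
#' (excitation level x irrep) string histograms for each spin channel.
#'
#' @param reference [sdet()] reference determinant.
#' @param level maximum total substitution level (CISD = 2, CI(6) = 6...).
#' @param M spatial orbitals.
#' @param orbsym per-orbital irrep codes (NULL = no symmetry).
#' @param target_irrep irrep code (NULL = all).
#' @return numeric count.
#' @export
count_truncated <- function(reference, level, M, orbsym = NULL,
                            target_irrep = NULL) {
  stopifnot(level >= 0L)
  na <- popcount(reference$alpha)
  nb <- popcount(reference$beta)
  if (is.null(orbsym)) orbsym <- integer(M)
  ng <- max_irrep_bins(orbsym)
  Ha <- level_irrep_histogram(M, na, orbsym, ng, reference$alpha)
  Hb <- level_irrep_histogram(M, nb, orbsym, ng, reference$beta)
  tot <- 0
  for (la in 0:na) for (lb in 0:nb) {
    if (la + lb > level) next
    if (is.null(target_irrep)) {
      tot <- tot + sum(Ha[la + 1L, ]) * sum(Hb[lb + 1L, ])
    } else {
      for (g in 0:(ng - 1L)) {
        g2 <- bitwXor(g, as.integer(target_irrep))
        tot <- tot + Ha[la + 1L, g + 1L] * Hb[lb + 1L, g2 + 1L]
      }
    }
  }
  tot
}
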