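# Determinant algebra: bitset Slater determinants and Slater-Condon rules.
#
# A determinant is a pair of orbital-string bitmasks (alpha, beta).  The
# canonical second-quantized operator order is spin-then-orbital: all
# alpha creation operators (ascending orbital) before all beta
# (ascending).  Every sign below is defined relative to that order.

#' Construct a Slater determinant
#'
#' @param alpha,beta integer bitmasks of the spin-up / spin-down orbital
#'   strings (bit `p - 1` set means spatial orbital `p` occupied), or
#'   vectors of 1-based orbital indices if `from_orbitals = TRUE`.
#' @param from_orbitals interpret inputs as orbital index lists.
#' @return object of class `sdet`: `list(alpha =, beta =)`.
#' @export
sdet <- function(alpha, beta, from_orbitals = FALSE) {
  if (from_orbitals) {
    alpha <- orb_mask(alpha)
    beta <- orb_mask(beta)
  }
  structure(list(alpha = as.integer(alpha), beta = as.integer(beta)),
            class = "sdet")
}

#' @export
print.sdet <- function(x, ...) {
  cat(sprintf("determinant: alpha {%s} beta {%s}\n",
              paste(occupied_orbitals(x$alpha), collapse = ","),
              paste(occupied_orbitals(x$beta), collapse = ",")))
  invisible(x)
}

#' Excitation degree between two determinants
#'
#' Number of spin-orbital substitutions linking `d1` to `d2`: half the
#' popcount of the XOR of the strings, summed over spin channels.
#'
#' @param d1,d2 [sdet()] objects with equal electron counts per
#'   spin channel.
#' @return non-negative integer.
#' @export
excitation_degree <- function(d1, d2) {
  if (popcount(d1$alpha) != popcount(d2$alpha) ||
      popcount(d1$beta) != popcount(d2$beta))
    stop("excitation_degree: electron counts differ")
  (popcount(bitwXor(d1$alpha, d2$alpha)) +
     popcount(bitwXor(d1$beta, d2$beta))) %/% 2L
}

# single-channel excitation data between strings s1 -> s2 (bitmasks):
# holes (in s1 not s2) and particles (in s2 not s1), ascending
channel_diff <- function(s1, s2) {
  d <- bitwXor(s1, s2)
  list(holes = occupied_orbitals(bitwAnd(d, s1)),
       particles = occupied_orbitals(bitwAnd(d, s2)))
}

# maximum-coincidence sign for exciting string s1 to s2 within one spin
# channel, pairing ascending holes with ascending particles and applying
# the substitutions sequentially (intermediate-string bookkeeping)
channel_sign <- function(s1, s2, holes, particles) {
  sgn <- 1L
  cur <- s1
  for (k in seq_along(holes)) {
    h <- holes[k]; p <- particles[k]
    if (bits_between(cur, h, p) %% 2L == 1L) sgn <- -sgn
    cur <- bitwXor(cur, bitwOr(bitwShiftL(1L, h - 1L),
                               bitwShiftL(1L, p - 1L)))
  }
  sgn
}

#' Excitation data between two determinants
#'
#' Holes, particles, and the maximum-coincidence sign Theta for a pair of
#' determinants at excitation degree <= 2.  Holes are orbitals occupied
#' in `d1` but not `d2`; particles the reverse.  The sign is the parity
#' of the permutation aligning the two determinants under the canonical
#' spin-then-orbital operator order, with ascending holes paired to
#' ascending particles within each spin channel.
#'
#' @param d1,d2 [sdet()] objects.
#' @return list with `degree`, `holes_a`, `particles_a`, `holes_b`,
#'   `particles_b`, `sign`.
#' @export
excitation_info <- function(d1, d2) {
  deg <- excitation_degree(d1, d2)
  if (deg > 2L) stop("excitation_info: degree > 2")
  da <- channel_diff(d1$alpha, d2$alpha)
  db <- channel_diff(d1$beta, d2$beta)
  sgn <- channel_sign(d1$alpha, d2$alpha, da$holes, da$particles) *
    channel_sign(d1$beta, d2$beta, db$holes, db$particles)
  list(degree = deg,
       holes_a = da$holes, particles_a = da$particles,
       holes_b = db$holes, particles_b = db$particles,
       sign = sgn)
}

#' Irrep of an orbital string
#'
#' XOR product of the irrep codes of the occupied orbitals (abelian
#' point groups with XOR-multiplicative encoding; the empty string is
#' totally symmetric, code 0).
#'
#' @param bits integer bitmask (or vector of bitmasks).
#' @param orbsym integer vector of per-orbital irrep codes.
#' @return integer irrep code(s).
#' @export
string_irrep <- function(bits, orbsym) {
  vapply(as.integer(bits), function(b) {
    g <- 0L
    for (p in occupied_orbitals(b)) g <- bitwXor(g, orbsym[p])
    g
  }, integer(1))
}

# ---------------------------------------------------------------------------
# Slater-Condon Hamiltonian matrix elements
# ---------------------------------------------------------------------------

# diagonal element for occupied orbital lists occ_a, occ_b (physicists' eri)
sc_diagonal <- function(occ_a, occ_b, h, eri) {
  e <- sum(h[cbind(occ_a, occ_a)]) + sum(h[cbind(occ_b, occ_b)])
  same_spin <- function(occ) {
    val <- 0
    n <- length(occ)
    if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      p <- occ[i]; q <- occ[j]
      val <- val + eri[p, q, p, q] - eri[p, q, q, p]
    }
    val
  }
  e <- e + same_spin(occ_a) + same_spin(occ_b)
  for (p in occ_a) for (q in occ_b) e <- e + eri[p, q, p, q]
  e
}

# single excitation m -> p in one channel; spect_same / spect_other are the
# spectator orbital lists of the same / other spin channel
sc_single <- function(m, p, spect_same, spect_other, h, eri) {
  v <- h[m, p]
  for (n in spect_same) v <- v + eri[m, n, p, n] - eri[m, n, n, p]
  for (n in spect_other) v <- v + eri[m, n, p, n]
  v
}

#' Hamiltonian matrix element between two determinants
#'
#' Slater-Condon rules evaluated with bit operations: degree 0 gives the
#' diagonal (occupied one-electron terms plus Coulomb minus same-spin
#' exchange), degree 1 the signed one-electron plus spectator sum, degree
#' 2 the signed antisymmetrized two-electron integral, and anything
#' higher exactly 0.  `e_core` is included on the diagonal.
#'
#' @param d1,d2 [sdet()] objects.
#' @param ints [sfints()] in physicists' notation.
#' @return scalar energy (hartree).
#' @export
hamiltonian_element <- function(d1, d2, ints) {
  stopifnot(inherits(ints, "sfints"))
  if (ints$notation != "physicists")
    stop("hamiltonian_element requires physicists' notation")
  if (popcount(d1$alpha) != popcount(d2$alpha) ||
      popcount(d1$beta) != popcount(d2$beta))
    stop("hamiltonian_element: electron counts differ")
  deg <- excitation_degree(d1, d2)
  if (deg > 2L) return(0)
  h <- ints$h; eri <- ints$eri
  if (deg == 0L) {
    return(sc_diagonal(occupied_orbitals(d1$alpha),
                       occupied_orbitals(d1$beta), h, eri) + ints$e_core)
  }
  info <- excitation_info(d1, d2)
  if (deg == 1L) {
    if (length(info$holes_a) == 1L) {
      m <- info$holes_a; p <- info$particles_a
      spect_same <- setdiff(occupied_orbitals(d1$alpha), m)
      spect_other <- occupied_orbitals(d1$beta)
    } else {
      m <- info$holes_b; p <- info$particles_b
      spect_same <- setdiff(occupied_orbitals(d1$beta), m)
      spect_other <- occupied_orbitals(d1$alpha)
    }
    return(info$sign * sc_single(m, p, spect_same, spect_other, h, eri))
  }
  # degree 2
  if (length(info$holes_a) == 2L) {         # same-spin alpha
    m <- info$holes_a[1]; n <- info$holes_a[2]
    p <- info$particles_a[1]; q <- info$particles_a[2]
    return(info$sign * (eri[m, n, p, q] - eri[m, n, q, p]))
  }
  if (length(info$holes_b) == 2L) {         # same-spin beta
    m <- info$holes_b[1]; n <- info$holes_b[2]
    p <- info$particles_b[1]; q <- info$particles_b[2]
    return(info$sign * (eri[m, n, p, q] - eri[m, n, q, p]))
  }
  # mixed spin
  m <- info$holes_a; p <- info$particles_a
  n <- info$holes_b; q <- info$particles_b
  info$sign * eri[m, n, p, q]
}

#' Enumerate single and double substitutions of a determinant
#'
#' Yields every distinct determinant at excitation degree 1 (and 2, if
#' `max_level = 2`) from `d`, optionally filtered to a target overall
#' irrep.  Spin projection is preserved by construction (substitutions
#' never move electrons between spin channels).
#'
#' @param d [sdet()] object.
#' @param max_level 1 or 2.
#' @param M number of spatial orbitals.
#' @param orbsym optional per-orbital irrep codes for filtering.
#' @param target_irrep optional irrep code the substituted determinant
#'   must carry overall.
#' @return list of `determinant` objects, each exactly once.
#' @export
enumerate_substitutions <- function(d, max_level, M, orbsym = NULL,
                                    target_irrep = NULL) {
  stopifnot(max_level %in% c(1L, 2L))
  occ_a <- occupied_orbitals(d$alpha)
  occ_b <- occupied_orbitals(d$beta)
  vir_a <- setdiff(seq_len(M), occ_a)
  vir_b <- setdiff(seq_len(M), occ_b)
  res <- list()
  add <- function(a, b) {
    if (!is.null(target_irrep)) {
      g <- bitwXor(string_irrep(a, orbsym), string_irrep(b, orbsym))
      if (g != target_irrep) return()
    }
    res[[length(res) + 1L]] <<- sdet(a, b)
  }
  flip <- function(s, h, p)
    bitwXor(s, bitwOr(bitwShiftL(1L, h - 1L), bitwShiftL(1L, p - 1L)))
  # singles
  for (h in occ_a) for (p in vir_a) add(flip(d$alpha, h, p), d$beta)
  for (h in occ_b) for (p in vir_b) add(d$alpha, flip(d$beta, h, p))
  if (max_level == 2L) {
    pairs <- function(v) if (length(v) >= 2L) utils::combn(v, 2L) else
      matrix(integer(0), 2, 0)
    # same-spin doubles, alpha then beta
    ha <- pairs(occ_a); pa <- pairs(vir_a)
    if (ncol(ha) && ncol(pa))
      for (i in seq_len(ncol(ha))) for (j in seq_len(ncol(pa)))
        add(flip(flip(d$alpha, ha[1, i], pa[1, j]), ha[2, i], pa[2, j]),
            d$beta)
    hb <- pairs(occ_b); pb <- pairs(vir_b)
    if (ncol(hb) && ncol(pb))
      for (i in seq_len(ncol(hb))) for (j in seq_len(ncol(pb)))
        add(d$alpha,
            flip(flip(d$beta, hb[1, i], pb[1, j]), hb[2, i], pb[2, j]))
    # mixed-spin doubles
    for (h1 in occ_a) for (p1 in vir_a)
      for (h2 in occ_b) for (p2 in vir_b)
        add(flip(d$alpha, h1, p1), flip(d$beta, h2, p2))
  }
  res
}
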