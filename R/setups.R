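# Named molecule/basis setups for symmetry-adapted determinant-space
# counting, plus deterministic toy-integral fixture generators.
#
# Determinant-space sizes depend only on the electron counts per spin
# channel and the multiset of irrep labels carried by the active
# orbitals.  Because a symmetry-adapted SCF cannot mix basis functions
# of different irreps, the number of molecular orbitals per irrep equals
# the number of (symmetry-adapted) basis functions per irrep, which
# follows from the angular momenta of the basis shells alone -- no SCF
# or integral evaluation is needed to count.
#
# Irrep codes use the XOR-multiplicative encoding
#   D2h: Ag=0 B1g=1 B2g=2 B3g=3 Au=4 B1u=5 B2u=6 B3u=7
#   C2v: A1=0 B1=1  B2=2  A2=3
# (products of labels correspond to XOR of codes).

d2h_codes <- c(Ag = 0L, B1g = 1L, B2g = 2L, B3g = 3L,
               Au = 4L, B1u = 5L, B2u = 6L, B3u = 7L)
c2v_codes <- c(A1 = 0L, B1 = 1L, B2 = 2L, A2 = 3L)

#' Resolve an irrep label to its XOR code
#'
#' @param label irrep name (e.g. `"Ag"`, `"B1g"`, `"A1"`) or an integer
#'   code passed through unchanged.
#' @param point_group `"D2h"`, `"C2v"`, or `"C1"`.
#' @return integer irrep code.
#' @export
irrep_code <- function(label, point_group) {
  if (is.numeric(label)) return(as.integer(label))
  tab <- switch(toupper(point_group),
                D2H = d2h_codes, C2V = c2v_codes,
                C1 = c(A = 0L),
                stop(sprintf("unsupported point group '%s'", point_group)))
  if (!label %in% names(tab))
    stop(sprintf("unknown irrep '%s' for %s", label, point_group))
  tab[[label]]
}

# orbital irrep multisets per setup.  Atom-centred shells at the origin
# (Ne, D2h): s -> Ag; p -> B3u/B2u/B1u (x/y/z); Cartesian d -> 3 Ag
# (xx,yy,zz) + B1g (xy) + B2g (xz) + B3g (yz).  Heteronuclear diatomic
# along z (CO, C2v): s,pz -> A1; px -> B1; py -> B2; Cartesian d ->
# 3 A1 + A2 (xy) + B1 (xz) + B2 (yz).  Homonuclear diatomic (O2, D2h):
# each shell pair splits into gerade + ungerade partners.
setup_table <- function() {
  rep_codes <- function(pg, ...) {
    spec <- list(...)
    unlist(lapply(names(spec), function(lbl)
      rep(irrep_code(lbl, pg), spec[[lbl]])))
  }
  list(
    # Ne, 6-31G* with 6 Cartesian d components: [3s 2p 1d] = 15 orbitals
    "ne-631gs" = list(
      point_group = "D2h", n_frozen = 1L, n_alpha = 4L, n_beta = 4L,
      frozen_irreps = rep_codes("D2h", Ag = 1),
      active_irreps = rep_codes("D2h", Ag = 5, B1u = 2, B2u = 2, B3u = 2,
                                B1g = 1, B2g = 1, B3g = 1),
      target = "Ag", ref_occ_irreps = NULL),
    # CO, 6-31G: [3s 2p] per atom = 18 orbitals; sigma -> A1, pi -> B1/B2
    "co-631g" = list(
      point_group = "C2v", n_frozen = 2L, n_alpha = 5L, n_beta = 5L,
      frozen_irreps = rep_codes("C2v", A1 = 2),
      active_irreps = rep_codes("C2v", A1 = 8, B1 = 4, B2 = 4),
      target = "A1",
      # active occupied reference: 3sigma 4sigma 1pi_x 1pi_y 5sigma
      ref_occ_irreps = c("A1", "A1", "B1", "B2", "A1")),
    # CO, cc-pVDZ with 6 Cartesian d components: [3s 2p 1d] per atom = 30
    "co-ccpvdz" = list(
      point_group = "C2v", n_frozen = 2L, n_alpha = 5L, n_beta = 5L,
      frozen_irreps = rep_codes("C2v", A1 = 2),
      active_irreps = rep_codes("C2v", A1 = 14, B1 = 6, B2 = 6, A2 = 2),
      target = "A1",
      ref_occ_irreps = c("A1", "A1", "B1", "B2", "A1")),
    # O2, 6-31G, Ms = 1 triplet: gerade/ungerade split of [3s 2p] pairs
    "o2-631g" = list(
      point_group = "D2h", n_frozen = 2L, n_alpha = 7L, n_beta = 5L,
      frozen_irreps = rep_codes("D2h", Ag = 1, B1u = 1),
      active_irreps = rep_codes("D2h", Ag = 4, B1u = 4, B3u = 2, B2g = 2,
                                B2u = 2, B3g = 2),
      target = "B1g", ref_occ_irreps = NULL)
  )
}

#' Named molecule/basis setup for determinant-space counting
#'
#' Returns the active-space definition (electron counts per spin
#' channel and per-orbital irrep codes) for the bundled molecule/basis
#' combinations, derived from basis-set symmetry composition.
#'
#' @param name one of `"ne-631gs"`, `"co-631g"`, `"co-ccpvdz"`,
#'   `"o2-631g"`.
#' @return list with `point_group`, `n_alpha`, `n_beta`,
#'   `active_irreps` (codes), `target` (irrep label),
#'   `target_code`, `M_active`, and for closed-shell CO setups
#'   `reference` (an [sdet()] in the active space, used for CI(n)
#'   counting).
#' @export
molecule_setup <- function(name) {
  tab <- setup_table()
  if (!name %in% names(tab))
    stop(sprintf("unknown setup '%s'; available: %s", name,
                 paste(names(tab), collapse = ", ")))
  s <- tab[[name]]
  s$M_active <- length(s$active_irreps)
  s$target_code <- irrep_code(s$target, s$point_group)
  if (!is.null(s$ref_occ_irreps)) {
    # occupy the first active orbital of each required irrep, in order
    codes <- vapply(s$ref_occ_irreps, irrep_code, integer(1),
                    point_group = s$point_group)
    occ <- integer(0)
    for (cd in codes) {
      cand <- setdiff(which(s$active_irreps == cd), occ)
      occ <- c(occ, cand[1])
    }
    s$reference <- sdet(occ, occ, from_orbitals = TRUE)
  }
  s
}

#' Count the symmetry-adapted FCI determinant space of a named setup
#'
#' @param name setup name (see [molecule_setup()]).
#' @return numeric determinant count.
#' @export
count_setup_fci <- function(name) {
  s <- molecule_setup(name)
  count_determinants(s$M_active, s$n_alpha, s$n_beta, s$active_irreps,
                     s$target_code)
}

# ---------------------------------------------------------------------------
# toy-integral fixtures
# ---------------------------------------------------------------------------

#' Generate deterministic toy integral fixtures
#'
#' All kinds are reproducible from `(kind, seed)` and exercise the full
#' stack with no external integral provider:
#' \describe{
#'   \item{random-hermitian}{random symmetric `h` and random
#'     8-fold-permutation-symmetric eri over `M` orbitals, scaled so the
#'     two-electron part perturbs rather than dominates.}
#'   \item{two-orbital-pair}{closed-shell 2-electron pairing model on 2
#'     orbitals (diagonal h, pair-exchange coupling K) whose singlet
#'     ground energy follows from a 2x2 secular equation.}
#'   \item{hubbard-like}{M-site open chain with hopping `-t` and on-site
#'     repulsion `U` in the site basis.}
#'   \item{named-molecule}{requires an external molecular-integral
#'     provider; not available offline and always an error naming the
#'     dependency.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed RNG seed (used by `random-hermitian`).
#' @param M orbital count (`random-hermitian`, `hubbard-like`).
#' @param n_elec electron count.
#' @param params optional named list: `h11`, `h22`, `K` for
#'   `two-orbital-pair`; `t`, `U` for `hubbard-like`.
#' @return [sfints()] object, chemists' notation.
#' @export
make_fixture <- function(kind, seed = 1L, M = 4L, n_elec = 4L,
                         params = list()) {
  switch(kind,
    "random-hermitian" = {
      set.seed(seed)
      h <- matrix(stats::rnorm(M * M), M)
      h <- (h + t(h)) / 2
      eri <- array(0, rep(M, 4))
      for (i in 1:M) for (j in 1:i) for (k in 1:i) for (l in 1:k) {
        can <- eri_canonical(i, j, k, l)
        if (!identical(can, c(i, j, k, l))) next
        v <- stats::rnorm(1, sd = 0.2)
        for (pp in eri_permutations(i, j, k, l))
          eri[pp[1], pp[2], pp[3], pp[4]] <- v
      }
      sfints(h, eri, e_core = stats::rnorm(1), n_elec = n_elec,
             ms2 = n_elec %% 2L, notation = "chemists")
    },
    "two-orbital-pair" = {
      h11 <- params$h11 %||% -1.2
      h22 <- params$h22 %||% -0.4
      K <- params$K %||% 0.25
      h <- diag(c(h11, h22))
      eri <- array(0, rep(2, 4))
      # only the pair-exchange integral (12|12) couples |11bar> to |22bar>
      for (pp in eri_permutations(1, 2, 1, 2)) eri[rbind(pp)] <- K
      sfints(h, eri, e_core = 0, n_elec = 2L, notation = "chemists")
    },
    "hubbard-like" = {
      t_hop <- params$t %||% 1
      U <- params$U %||% 2
      h <- matrix(0, M, M)
      for (i in seq_len(M - 1L)) h[i, i + 1L] <- h[i + 1L, i] <- -t_hop
      eri <- array(0, rep(M, 4))
      for (i in seq_len(M)) eri[i, i, i, i] <- U
      sfints(h, eri, e_core = 0, n_elec = n_elec, notation = "chemists")
    },
    "named-molecule" = stop(paste(
      "fixture kind 'named-molecule' requires an external molecular",
      "integral provider (e.g. an SCF/integrals program writing FCIDUMP);",
      "none is bundled -- supply an FCIDUMP file instead")),
    stop(sprintf("unknown fixture kind '%s'", kind))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
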