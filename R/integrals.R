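# Spin-free molecular-orbital integrals: container, FCIDUMP I/O,
# notation conversion, frozen-core folding.

#' Spin-free integral container
#'
#' Holds the one- and two-electron molecular-orbital integrals plus core
#' energy that define an electronic Hamiltonian over M real spatial
#' orbitals:
#' \deqn{H = E_core + \sum h_{pq} a^+_{p\sigma} a_{q\sigma}
#'   + 1/2 \sum \langle pr|qs \rangle
#'     a^+_{p\sigma} a^+_{r\sigma'} a_{s\sigma'} a_{q\sigma}}
#'
#' Two-electron integrals are stored as a dense M^4 array under a declared
#' notation: `"chemists"` has `eri[p,q,r,s]` = (pq|rs), `"physicists"` has
#' `eri[p,r,q,s]` = <pr|qs>.  For real orbitals the two are index
#' permutations of one another (see [convert_notation()]).
#'
#' @param h M x M symmetric one-electron integral matrix (hartree).
#' @param eri M^4 array of two-electron integrals (hartree).
#' @param e_core scalar core energy (nuclear repulsion + any folded
#'   frozen-core contribution).
#' @param n_elec number of active electrons.
#' @param ms2 twice the spin projection, `n_alpha - n_beta`.
#' @param notation `"chemists"` or `"physicists"`.
#' @param orbsym integer vector of per-orbital irrep codes in an
#'   XOR-multiplicative abelian encoding (0 = totally symmetric);
#'   defaults to all zero (no symmetry).
#' @param point_group label for the abelian point group of `orbsym`.
#' @return object of class `sfints`.
#' @export
sfints <- function(h, eri, e_core = 0, n_elec, ms2 = 0L,
                   notation = c("chemists", "physicists"),
                   orbsym = NULL, point_group = "C1") {
  notation <- match.arg(notation)
  h <- as.matrix(h)
  M <- nrow(h)
  stopifnot(ncol(h) == M, length(dim(eri)) == 4L, all(dim(eri) == M))
  if (is.null(orbsym)) orbsym <- integer(M)
  orbsym <- as.integer(orbsym)
  stopifnot(length(orbsym) == M, all(orbsym >= 0L))
  n_elec <- as.integer(n_elec)
  ms2 <- as.integer(ms2)
  if ((n_elec + ms2) %% 2L != 0L)
    stop("ms2 parity incompatible with n_elec")
  na <- (n_elec + ms2) %/% 2L
  nb <- (n_elec - ms2) %/% 2L
  if (M < max(na, nb)) stop("fewer orbitals than electrons per spin")
  if (max(abs(h - t(h))) > 1e-10) stop("h is not symmetric")
  obj <- structure(
    list(M = M, n_elec = n_elec, ms2 = ms2, e_core = as.numeric(e_core),
         h = h, eri = eri, notation = notation, orbsym = orbsym,
         point_group = point_group),
    class = "sfints")
  obj
}

#' @export
print.sfints <- function(x, ...) {
  cat(sprintf(
    "sfints: M = %d orbitals, %d electrons (ms2 = %d), %s notation, %s\n",
    x$M, x$n_elec, x$ms2, x$notation, x$point_group))
  cat(sprintf("  e_core = %.10f hartree\n", x$e_core))
  invisible(x)
}

# verify 8-fold permutational symmetry of a chemists' eri array
check_eri_8fold <- function(eri, tol = 1e-10) {
  perms <- list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2))
  for (p in perms)
    if (max(abs(eri - aperm(eri, p))) > tol) return(FALSE)
  TRUE
}

#' Convert two-electron integral notation
#'
#' Reindexes the eri table between chemists' (pq|rs) and physicists'
#' <pr|qs> conventions, valid for real orbitals where
#' <pr|qs> = (pq|rs).  Applying the conversion twice is the identity.
#'
#' @param ints [sfints()] object.
#' @param target `"chemists"` or `"physicists"`.
#' @return converted `sfints`.
#' @export
convert_notation <- function(ints, target = c("physicists", "chemists")) {
  target <- match.arg(target)
  stopifnot(inherits(ints, "sfints"))
  if (ints$notation == target) return(ints)
  # chem[p,q,r,s] -> phys[p,r,q,s]: swap dims 2 and 3 (an involution)
  ints$eri <- aperm(ints$eri, c(1L, 3L, 2L, 4L))
  ints$notation <- target
  ints
}

# ---------------------------------------------------------------------------
# FCIDUMP
# ---------------------------------------------------------------------------

#' Read an FCIDUMP integral file
#'
#' Parses the standard `&FCI` namelist dialect (NORB, NELEC, MS2, ORBSYM,
#' ISYM; 1-based `value i j k l` records; the all-zero index record holds
#' the core energy).  ORBSYM codes are stored as `code - 1`, which for the
#' conventional D2h-and-subgroup irrep ordering is already
#' XOR-multiplicative.  The returned table is in chemists' notation with
#' all eight permutation-equivalent entries filled in.
#'
#' @param path file path.
#' @return [sfints()] object (notation `"chemists"`).
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop(sprintf("FCIDUMP file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  # namelist runs from &FCI to &END or a line starting with /
  m <- regexpr("&FCI", txt, fixed = TRUE)
  if (m < 0) stop("FCIDUMP format error: missing &FCI namelist")
  endm <- regexpr("(&END|\n[ \t]*/)", substring(txt, m), perl = TRUE)
  if (endm < 0) stop("FCIDUMP format error: unterminated namelist")
  head <- substring(txt, m, m + endm + attr(endm, "match.length") - 1L)
  body <- substring(txt, m + endm + attr(endm, "match.length"))

  get_key <- function(key, required = TRUE) {
    pat <- paste0(key, "[ \t]*=[ \t]*([-0-9, \t\n]+)")
    km <- regmatches(head, regexpr(pat, head, perl = TRUE))
    if (length(km) == 0L) {
      if (required) stop(sprintf("FCIDUMP format error: missing key %s", key))
      return(NULL)
    }
    val <- sub(pat, "\\1", km, perl = TRUE)
    as.integer(strsplit(gsub("[ \t\n]", "", val), ",")[[1]])
  }
  norb <- get_key("NORB")[1]
  nelec <- get_key("NELEC")[1]
  ms2v <- get_key("MS2", required = FALSE)
  ms2v <- if (is.null(ms2v)) 0L else ms2v[1]
  orbsym <- get_key("ORBSYM", required = FALSE)
  if (is.null(orbsym)) orbsym <- rep(1L, norb)
  orbsym <- orbsym[!is.na(orbsym)]
  if (length(orbsym) != norb)
    stop("FCIDUMP format error: ORBSYM length != NORB")

  h <- matrix(0, norb, norb)
  eri <- array(0, rep(norb, 4))
  e_core <- 0
  seen_h <- matrix(FALSE, norb, norb)
  seen_g <- array(FALSE, rep(norb, 4))

  recs <- strsplit(trimws(strsplit(body, "\n")[[1]]), "[ \t]+")
  lineno <- 0L
  for (r in recs) {
    lineno <- lineno + 1L
    if (length(r) == 1L && r == "") next
    if (length(r) != 5L)
      stop(sprintf("FCIDUMP format error at record %d", lineno))
    v <- as.numeric(r[1])
    ijkl <- as.integer(r[2:5])
    if (any(is.na(ijkl)) || is.na(v))
      stop(sprintf("FCIDUMP format error at record %d", lineno))
    if (any(ijkl < 0L) || any(ijkl > norb))
      stop(sprintf("FCIDUMP format error: index out of range at record %d",
                   lineno))
    i <- ijkl[1]; j <- ijkl[2]; k <- ijkl[3]; l <- ijkl[4]
    if (all(ijkl == 0L)) {
      e_core <- v
    } else if (k == 0L && l == 0L) {
      if (i == 0L || j == 0L)
        stop(sprintf("FCIDUMP format error at record %d", lineno))
      if (seen_h[i, j] && abs(h[i, j] - v) > 1e-12)
        stop(sprintf("FCIDUMP format error: conflicting h record at line %d",
                     lineno))
      h[i, j] <- v; h[j, i] <- v
      seen_h[i, j] <- seen_h[j, i] <- TRUE
    } else if (any(ijkl == 0L)) {
      stop(sprintf("FCIDUMP format error at record %d", lineno))
    } else {
      perms <- eri_permutations(i, j, k, l)
      if (seen_g[i, j, k, l] && abs(eri[i, j, k, l] - v) > 1e-12)
        stop(sprintf("FCIDUMP format error: conflicting eri record at line %d",
                     lineno))
      for (pp in perms) {
        eri[pp[1], pp[2], pp[3], pp[4]] <- v
        seen_g[pp[1], pp[2], pp[3], pp[4]] <- TRUE
      }
    }
  }
  sfints(h = h, eri = eri, e_core = e_core, n_elec = nelec, ms2 = ms2v,
         notation = "chemists", orbsym = orbsym - 1L,
         point_group = "unknown")
}

# the 8 permutation images of chemists' (ij|kl) for real orbitals
eri_permutations <- function(i, j, k, l) {
  unique(list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
              c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i)))
}

# canonical representative of an (ij|kl) class, for unique output ordering
eri_canonical <- function(i, j, k, l) {
  ij <- sort(c(i, j), decreasing = TRUE)
  kl <- sort(c(k, l), decreasing = TRUE)
  a <- c(ij, kl); b <- c(kl, ij)
  if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2]) ||
      (a[1] == b[1] && a[2] == b[2] && a[3] >= b[3])) a else b
}

#' Write an FCIDUMP integral file
#'
#' Emits only symmetry-unique entries with magnitude above 1e-12, in
#' deterministic order (eri records, then h records, then the core
#' energy).  The integrals must be in chemists' notation; convert first.
#'
#' @param ints [sfints()] object, chemists' notation.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(ints, path) {
  stopifnot(inherits(ints, "sfints"))
  if (ints$notation != "chemists")
    stop("write_fcidump requires chemists' notation; use convert_notation()")
  M <- ints$M
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    " &FCI NORB=%d,NELEC=%d,MS2=%d,\n  ORBSYM=%s,\n  ISYM=1,\n &END",
    M, ints$n_elec, ints$ms2,
    paste(ints$orbsym + 1L, collapse = ",")), con)
  fmt <- function(v, i, j, k, l)
    sprintf("%24.16E %3d %3d %3d %3d", v, i, j, k, l)
  out <- character(0)
  for (i in seq_len(M)) for (j in seq_len(i))
    for (k in seq_len(i)) for (l in seq_len(k)) {
      can <- eri_canonical(i, j, k, l)
      if (!identical(can, c(i, j, k, l))) next
      v <- ints$eri[i, j, k, l]
      if (abs(v) > 1e-12) out <- c(out, fmt(v, i, j, k, l))
    }
  for (i in seq_len(M)) for (j in seq_len(i)) {
    if (abs(ints$h[i, j]) > 1e-12) out <- c(out, fmt(ints$h[i, j], i, j, 0, 0))
  }
  out <- c(out, fmt(ints$e_core, 0, 0, 0, 0))
  writeLines(out, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Frozen core
# ---------------------------------------------------------------------------

#' Fold frozen doubly occupied orbitals into an effective Hamiltonian
#'
#' Removes the listed orbitals from the active space under the standard
#' closed-shell frozen-core approximation: their doubly occupied mean
#' field is absorbed into the effective one-electron integrals and the
#' core energy, and `n_elec` drops by two per frozen orbital.  The FCI
#' energy in the folded space equals the FCI energy of the original
#' problem with those orbitals held doubly occupied.
#'
#' @param ints [sfints()] object (either notation; returned in the same
#'   notation).
#' @param frozen integer vector of 1-based orbitals to freeze.
#' @return active-space `sfints` with `M - length(frozen)` orbitals.
#' @export
fold_frozen_core <- function(ints, frozen) {
  stopifnot(inherits(ints, "sfints"))
  frozen <- sort(unique(as.integer(frozen)))
  if (length(frozen) == 0L) return(ints)
  if (any(frozen < 1L) || any(frozen > ints$M))
    stop("frozen orbital out of range")
  if (2L * length(frozen) > ints$n_elec)
    stop("cannot freeze more electron pairs than electrons present")
  orig_notation <- ints$notation
  ints <- convert_notation(ints, "chemists")
  act <- setdiff(seq_len(ints$M), frozen)
  g <- ints$eri
  h <- ints$h
  # constant shift: sum_f 2 h_ff + sum_fg [2 (ff|gg) - (fg|gf)]
  e_shift <- 2 * sum(diag(h)[frozen])
  for (f in frozen) for (gg in frozen)
    e_shift <- e_shift + 2 * g[f, f, gg, gg] - g[f, gg, gg, f]
  # effective one-electron part over active t,u
  heff <- h[act, act, drop = FALSE]
  for (f in frozen)
    heff <- heff + 2 * g[act, act, f, f] - g[act, f, f, act]
  out <- sfints(h = heff, eri = g[act, act, act, act, drop = FALSE],
                e_core = ints$e_core + e_shift,
                n_elec = ints$n_elec - 2L * length(frozen),
                ms2 = ints$ms2, notation = "chemists",
                orbsym = ints$orbsym[act], point_group = ints$point_group)
  convert_notation(out, orig_notation)
}
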