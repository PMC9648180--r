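# Slater-determinant wavefunction expansions.

#' Determinant-expansion wavefunction
#'
#' A CI wavefunction |Psi> = sum_i c_i |Phi_i> stored as a data frame of
#' (alpha bitmask, beta bitmask, coefficient) rows with uniform electron
#' counts.
#'
#' @param alpha,beta integer bitmask vectors.
#' @param coef numeric coefficients.
#' @param M number of spatial orbitals.
#' @return object of class `wfn_sd` (a data frame with attribute `M`).
#' @export
wfn_sd <- function(alpha, beta, coef, M) {
  alpha <- as.integer(alpha); beta <- as.integer(beta)
  stopifnot(length(alpha) == length(beta),
            length(alpha) == length(coef), M <= 31L)
  if (length(alpha)) {
    if (length(unique(popcount(alpha))) != 1L ||
        length(unique(popcount(beta))) != 1L)
      stop("wfn_sd: non-uniform electron counts")
  }
  w <- data.frame(alpha = alpha, beta = beta, coef = as.numeric(coef))
  attr(w, "M") <- as.integer(M)
  class(w) <- c("wfn_sd", "data.frame")
  w
}

wfn_M <- function(wfn) attr(wfn, "M")

wfn_nelec <- function(wfn) {
  c(na = popcount(wfn$alpha[1]), nb = popcount(wfn$beta[1]))
}

# combined sort key; exact for M <= 26 (fits double mantissa)
wfn_key <- function(alpha, beta, M) {
  stopifnot(M <= 26L)
  as.numeric(beta) * 2^M + as.numeric(alpha)
}

#' Sort a wavefunction by canonical determinant key
#'
#' @param wfn [wfn_sd()] object.
#' @return sorted `wfn_sd` (beta-major, then alpha).
#' @export
wfn_sort <- function(wfn) {
  k <- wfn_key(wfn$alpha, wfn$beta, wfn_M(wfn))
  out <- wfn[order(k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "M") <- wfn_M(wfn)
  class(out) <- c("wfn_sd", "data.frame")
  out
}

#' Merge duplicate determinants and optionally drop near-zero terms
#'
#' @param wfn [wfn_sd()] object.
#' @param tol coefficients with `abs < tol` are dropped after merging.
#' @return deduplicated `wfn_sd`.
#' @export
wfn_dedup <- function(wfn, tol = 1e-12) {
  if (nrow(wfn) == 0L) return(wfn)
  k <- wfn_key(wfn$alpha, wfn$beta, wfn_M(wfn))
  agg <- rowsum(wfn$coef, group = k, reorder = TRUE)
  keys <- as.numeric(rownames(agg))
  co <- as.numeric(agg)
  keep <- abs(co) >= tol
  M <- wfn_M(wfn)
  a <- as.integer(keys[keep] %% 2^M)
  b <- as.integer(keys[keep] %/% 2^M)
  wfn_sd(a, b, co[keep], M)
}

#' Normalize a wavefunction to unit 2-norm
#'
#' @param wfn [wfn_sd()] object.
#' @return normalized `wfn_sd`.
#' @export
wfn_normalize <- function(wfn) {
  nrm <- sqrt(sum(wfn$coef^2))
  if (nrm == 0) stop("wfn_normalize: zero norm")
  wfn$coef <- wfn$coef / nrm
  wfn
}

#' @export
print.wfn_sd <- function(x, ...) {
  cat(sprintf("wfn_sd: %d determinants over M = %d orbitals, |c| = %.6f\n",
              nrow(x), wfn_M(x), sqrt(sum(x$coef^2))))
  if (nrow(x)) {
    show <- utils::head(x[order(-abs(x$coef)), ], 5L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  % .6f  a{%s} b{%s}\n", show$coef[i],
                  paste(occupied_orbitals(show$alpha[i]), collapse = ","),
                  paste(occupied_orbitals(show$beta[i]), collapse = ",")))
  }
  invisible(x)
}
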