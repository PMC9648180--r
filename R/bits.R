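# Bit-level utilities for orbital strings.
#
# An orbital string (the list of spatial orbitals occupied by one spin
# channel) is stored as a non-negative R integer bitmask: bit (p - 1) set
# means spatial orbital p (1-based) is occupied.  R integers are 32-bit,
# so M <= 31 spatial orbitals per string; that covers every space this
# package enumerates (the largest counted space uses M = 28, and counting
# never enumerates determinant pairs).

#' Population count of integer bitmasks
#'
#' Counts set bits in each element of an integer vector, the `popcnt`
#' primitive of hardware-oriented determinant codes.
#'
#' @param x integer vector of non-negative bitmasks.
#' @return integer vector of bit counts.
#' @export
popcount <- function(x) {
  x <- as.integer(x)
  stopifnot(all(x >= 0L))
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Occupied orbitals of an orbital string
#'
#' Unpacks a bitmask into the ascending list of occupied spatial orbitals
#' (1-based), using the trailing-zero / clear-lowest-bit idiom.
#'
#' @param bits single integer bitmask.
#' @return strictly ascending integer vector, length `popcount(bits)`.
#' @export
occupied_orbitals <- function(bits) {
  bits <- as.integer(bits)
  stopifnot(length(bits) == 1L, bits >= 0L)
  out <- integer(0)
  while (bits > 0L) {
    low <- bitwAnd(bits, -bits)      # isolate lowest set bit
    out <- c(out, trailing_zeros(low) + 1L)
    bits <- bitwAnd(bits, bits - 1L) # clear it
  }
  out
}

# trailz for a power-of-two integer (single lowest set bit already isolated)
trailing_zeros <- function(low) {
  tz <- 0L
  while (bitwAnd(low, 1L) == 0L) {
    low <- bitwShiftR(low, 1L)
    tz <- tz + 1L
  }
  tz
}

# bitmask with bits 0..(k-1) set; k = 0 gives 0
mask_below <- function(k) {
  if (k <= 0L) return(0L)
  if (k >= 31L) stop("mask_below: k must be < 31")
  bitwShiftL(1L, k) - 1L
}

# number of set bits of `bits` strictly between (exclusive) orbital
# positions i and j (1-based orbitals)
bits_between <- function(bits, i, j) {
  lo <- min(i, j)
  hi <- max(i, j)
  m <- bitwAnd(mask_below(hi - 1L), bitwNot(mask_below(lo)))
  popcount(bitwAnd(bits, m))
}

# bitmask for a set of 1-based orbitals
orb_mask <- function(orbs) {
  if (length(orbs) == 0L) return(0L)
  stopifnot(all(orbs >= 1L), all(orbs <= 31L))
  Reduce(bitwOr, bitwShiftL(1L, as.integer(orbs) - 1L), 0L)
}
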