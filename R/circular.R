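# Circular mitochondrial coordinate arithmetic.
#
# The human mitochondrial genome is circular (rCRS length 16,569 bp), so a
# fragment may span the replication origin: its end coordinate is then
# numerically smaller than its start.  All mtDNA breakpoints are 1-based
# positions in [1, L]; nuclear intervals elsewhere in the package are 0-based
# half-open internally and rendered 1-based inclusive in files and reports.

MT_GENOME_LENGTH <- 16569L

#' Validate a circular breakpoint pair
#'
#' @param mt_start,mt_end 1-based positions on the circular mitochondrial
#'   genome.
#' @param genome_length Total circular genome length in bp.
#' @return Invisibly `TRUE`; errors on invalid coordinates.
#' @keywords internal
check_circular_pair <- function(mt_start, mt_end, genome_length = MT_GENOME_LENGTH) {
  if (any(genome_length < 1)) {
    stop("genome_length must be >= 1", call. = FALSE)
  }
  bad <- mt_start < 1 | mt_start > genome_length |
    mt_end < 1 | mt_end > genome_length |
    is.na(mt_start) | is.na(mt_end)
  if (any(bad)) {
    stop("invalid circular coordinate: positions must lie in [1, genome_length]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Length of a fragment on the circular mitochondrial genome
#'
#' Computes the length in bp of the fragment running forward (in the
#' direction of increasing coordinate) from `mt_start` to `mt_end`, wrapping
#' through the origin when `mt_end < mt_start`.  A NUMT whose mitochondrial
#' breakpoints are 16,088 and 61 on the 16,569-bp genome therefore has length
#' 542, not -16,027.
#'
#' @inheritParams check_circular_pair
#' @return Integer vector of fragment lengths, each in
#'   `[0, genome_length)`.  A pair with `mt_start == mt_end` has length 0.
#' @examples
#' circular_fragment_length(16088, 61)    # origin-spanning, 542
#' circular_fragment_length(11022, 11188) # plain, 166
#' @export
circular_fragment_length <- function(mt_start, mt_end,
                                     genome_length = MT_GENOME_LENGTH) {
  check_circular_pair(mt_start, mt_end, genome_length)
  as.integer((mt_end - mt_start) %% genome_length)
}

#' Positions covered by a circular fragment
#'
#' Expands a breakpoint pair into the 1-based positions the fragment covers:
#' `mt_start, mt_start + 1, ...` for `circular_fragment_length()` positions,
#' wrapping past `genome_length` to 1.
#'
#' @inheritParams check_circular_pair
#' @return Integer vector of covered positions (empty for a zero-length
#'   fragment).
#' @export
circular_positions <- function(mt_start, mt_end,
                               genome_length = MT_GENOME_LENGTH) {
  len <- circular_fragment_length(mt_start, mt_end, genome_length)
  if (len == 0L) return(integer(0))
  as.integer((as.integer(mt_start) - 1L) + seq_len(len) - 1L) %%
    as.integer(genome_length) + 1L
}

#' Per-base coverage of the circular genome by a set of fragments
#'
#' @param mt_start,mt_end Vectors of breakpoint pairs (recycled together).
#' @param genome_length Circular genome length.
#' @param weights Optional per-fragment weights (default 1 each).
#' @return Numeric vector of length `genome_length`: position i holds the
#'   (weighted) number of fragments covering position i.
#' @export
circular_coverage <- function(mt_start, mt_end,
                              genome_length = MT_GENOME_LENGTH,
                              weights = NULL) {
  check_circular_pair(mt_start, mt_end, genome_length)
  n <- max(length(mt_start), length(mt_end))
  mt_start <- rep_len(as.integer(mt_start), n)
  mt_end <- rep_len(as.integer(mt_end), n)
  if (is.null(weights)) weights <- rep_len(1, n) else weights <- rep_len(weights, n)
  # difference array over [1, L]; wrap fragments split into two linear runs
  len <- (mt_end - mt_start) %% genome_length
  keep <- len > 0L
  s <- mt_start[keep]; l <- len[keep]; w <- weights[keep]
  e <- s + l - 1L                       # may exceed L
  wraps <- e > genome_length
  up_idx <- c(s, rep(1L, sum(wraps)))
  dn_idx <- c(pmin(e, genome_length) + 1L, e[wraps] - genome_length + 1L)
  up_w <- c(w, w[wraps])
  d <- numeric(genome_length + 1L)
  if (length(up_idx)) {
    inc <- rowsum(up_w, up_idx)
    d[as.integer(rownames(inc))] <- d[as.integer(rownames(inc))] + inc[, 1]
    dec <- rowsum(up_w, dn_idx)
    d[as.integer(rownames(dec))] <- d[as.integer(rownames(dec))] - dec[, 1]
  }
  cumsum(d[seq_len(genome_length)])
}
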