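# Consensus NUMT sequence construction and recurrence testing by pairwise
# identity.

#' Per-individual consensus sequence from a pileup
#'
#' Base calling rules, applied per fragment position: bases with phred
#' quality below `min_qual` are discarded; positions with fewer than
#' `min_depth` remaining reads are called `N`; positions where more than one
#' allele is observed and the major allele's fraction is below `min_major`
#' are called `N`; otherwise the major allele is called.
#'
#' @param pileup data.frame `pos` (1-based position within the fragment, 1 ..
#'   fragment length), `base` (A/C/G/T), `qual` (phred).
#' @param fragment_length Length of the fragment; positions without any
#'   pileup row are called `N`.
#' @param min_qual Quality threshold (default 10; a base at exactly 10 is
#'   kept).
#' @param min_depth Minimum post-filter depth (default 3).
#' @param min_major Minimum major-allele fraction at multi-allelic positions
#'   (default 0.75; a fraction of exactly 0.75 is kept).
#' @return Character scalar over `{A,C,G,T,N}` of length `fragment_length`.
#' @export
individual_consensus <- function(pileup, fragment_length,
                                 min_qual = 10, min_depth = 3,
                                 min_major = 0.75) {
  out <- rep("N", fragment_length)
  if (NROW(pileup) > 0) {
    keep <- pileup$qual >= min_qual & pileup$base %in% c("A", "C", "G", "T")
    pileup <- pileup[keep, , drop = FALSE]
    for (p in unique(pileup$pos)) {
      if (p < 1 || p > fragment_length) next
      b <- pileup$base[pileup$pos == p]
      if (length(b) < min_depth) next
      tab <- sort(table(b), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] / length(b) < min_major) next
      # alphabetical tie-break falls out of table()'s name ordering
      out[p] <- names(tab)[1]
    }
  }
  paste(out, collapse = "")
}

#' Representative sequence across individual consensuses
#'
#' Per position, the most frequent non-`N` allele across individuals (`N`
#' calls are ignored; a position that is `N` in every individual stays `N`).
#' Ties break alphabetically.
#'
#' @param consensuses Character vector of equal-length consensus sequences.
#' @return Character scalar representative sequence.
#' @export
representative_sequence <- function(consensuses) {
  stopifnot(length(consensuses) >= 1)
  lens <- nchar(consensuses)
  if (length(unique(lens)) != 1) {
    stop("consensus sequences differ in length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(consensuses, ""))
  apply(m, 2, function(col) {
    col <- col[col != "N"]
    if (!length(col)) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    sort(top)[1]
  }) |> paste(collapse = "")
}

#' Pairwise nucleotide identity with optional masking
#'
#' Identity between two sequences is matches / compared positions, where
#' positions with `N` in either sequence or inside the mask are excluded.
#' Hypervariable control-region positions mutate fast enough to mimic
#' recurrent insertion, so recurrence tests recompute identity with those
#' alignment columns masked.
#'
#' @param consensuses Character vector (>= 2) of equal-length sequences;
#'   names label the matrix.
#' @param mask Optional integer vector of 1-based alignment positions to
#'   exclude.
#' @return List: `matrix` (symmetric pairwise identity, `NA` where no
#'   comparable positions exist), `mean` (mean over all pairs with defined
#'   identity).
#' @export
pairwise_identity <- function(consensuses, mask = NULL) {
  n <- length(consensuses)
  stopifnot(n >= 2)
  lens <- nchar(consensuses)
  if (length(unique(lens)) != 1) {
    stop("sequences differ in length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(consensuses, ""))
  usable <- m != "N"
  if (!is.null(mask) && length(mask)) usable[, mask] <- FALSE
  ids <- matrix(NA_real_, n, n,
                dimnames = list(names(consensuses), names(consensuses)))
  diag(ids) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- usable[i, ] & usable[j, ]
      if (!any(comp)) {
        warning("no comparable positions for pair (", i, ", ", j,
                "); excluded from the mean")
        next
      }
      ids[i, j] <- ids[j, i] <- mean(m[i, comp] == m[j, comp])
    }
  }
  upper <- ids[upper.tri(ids)]
  list(matrix = ids, mean = mean(upper, na.rm = TRUE))
}

#' Alignment-column mask for hypervariable mtDNA intervals
#'
#' Maps hypervariable intervals given in mitochondrial coordinates onto
#' 1-based positions within a circular fragment.
#'
#' @param mt_start,mt_end Fragment breakpoints (1-based circular).
#' @param hv data.frame `start`, `end` (1-based inclusive mtDNA
#'   coordinates); defaults to [hypervariable_default()].
#' @param genome_length Circular genome length.
#' @return Integer vector of fragment positions falling in a hypervariable
#'   interval.
#' @export
hypervariable_mask <- function(mt_start, mt_end, hv = hypervariable_default(),
                               genome_length = MT_GENOME_LENGTH) {
  pos <- circular_positions(mt_start, mt_end, genome_length)
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(NROW(hv))) {
    inside <- inside | (pos >= hv$start[i] & pos <= hv$end[i])
  }
  which(inside)
}

#' Default hypervariable control-region intervals (rCRS coordinates)
#'
#' HVS-I 16,024-16,365 and HVS-II 57-372, 1-based inclusive; override when
#' working with a non-rCRS reference.
#'
#' @return data.frame `name`, `start`, `end`.
#' @export
hypervariable_default <- function() {
  data.frame(name = c("HVS-I", "HVS-II"),
             start = c(16024L, 57L), end = c(16365L, 372L),
             stringsAsFactors = FALSE)
}
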