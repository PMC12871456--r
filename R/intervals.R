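# Interval helpers bridging the package's 0-based half-open data.frames and
# GenomicRanges (1-based closed).

#' Convert an interval data.frame to a GRanges
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return `GenomicRanges::GRanges`; remaining columns become metadata.
#' @keywords internal
as_granges <- function(df, seqlevels = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$end < df$start)) stop("interval with end < start", call. = FALSE)
  if (is.null(seqlevels)) seqlevels <- unique(df$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  extra <- setdiff(names(df), c("chrom", "start", "end"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

# does each query interval intersect any subject interval (>= 1 bp)?
overlaps_any <- function(query, subject) {
  if (NROW(subject) == 0 || NROW(query) == 0) return(rep(FALSE, NROW(query)))
  lv <- unique(c(query$chrom, subject$chrom))
  IRanges::overlapsAny(as_granges(query, lv), as_granges(subject, lv))
}
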