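# Cohort-level merging of per-individual NUMT calls.

#' Cluster nuclear breakpoints across individuals
#'
#' Single-linkage clustering, per chromosome, of per-individual nuclear
#' breakpoint start positions: sorted consecutive starts at most `max_gap` bp
#' apart join one cluster.  The merged nuclear breakpoint interval runs from
#' the smallest to the second-smallest *distinct* member start; a cluster
#' with a single distinct start becomes a point interval.
#'
#' @param calls NUMT call data.frame (`chrom`, `start` 0-based).
#' @param max_gap Maximum bp between consecutive member starts (default 1000).
#' @return `calls` with an integer `locus` column, plus attribute
#'   `"loci"`: data.frame `locus`, `chrom`, `start`, `end` (merged interval,
#'   0-based half-open).
#' @export
merge_nuclear_breakpoints <- function(calls, max_gap = 1000) {
  if (NROW(calls) == 0) {
    calls$locus <- integer(0)
    attr(calls, "loci") <- data.frame(locus = integer(0), chrom = character(0),
                                      start = integer(0), end = integer(0))
    return(calls)
  }
  ord <- order(calls$chrom, calls$start)
  calls <- calls[ord, , drop = FALSE]
  new_chain <- c(TRUE, calls$chrom[-1] != calls$chrom[-NROW(calls)] |
                   diff(calls$start) > max_gap)
  calls$locus <- cumsum(new_chain)
  loci <- do.call(rbind, lapply(split(calls, calls$locus), function(m) {
    starts <- sort(unique(m$start))
    s <- starts[1]
    e <- if (length(starts) >= 2) starts[2] else starts[1]
    data.frame(locus = m$locus[1], chrom = m$chrom[1],
               start = s, end = e + 1L,  # inclusive second start -> half-open
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- rownames(loci) <- NULL
  attr(calls, "loci") <- loci
  calls
}

#' Select merged mitochondrial breakpoints for a locus
#'
#' Start and end are chosen independently as the most frequently observed
#' position among the member calls; ties break toward the smallest
#' coordinate.
#'
#' @param member_calls Calls of one nuclear cluster (`mt_start`, `mt_end`).
#' @return Integer vector `c(mt_start, mt_end)`.
#' @export
select_mt_breakpoints <- function(member_calls) {
  stopifnot(NROW(member_calls) >= 1)
  c(mt_start = modal_position(member_calls$mt_start),
    mt_end = modal_position(member_calls$mt_end))
}

#' Build the merged cohort NUMT table with per-population carrier counts
#'
#' Each individual counts once per locus regardless of how many of its calls
#' fell into the cluster.  Carrier frequency uses the pooled panel size and
#' is classified with [classify_frequency()]; per-population counts are one
#' column per panel population.
#'
#' @param clustered Output of [merge_nuclear_breakpoints()].
#' @param panel [population_panel()] data.frame.
#' @param individuals data.frame `individual_id`, `population` mapping every
#'   calling individual to a panel population.
#' @param genome_length Circular mtDNA length for the `length` column.
#' @return Merged NUMT data.frame: `locus_id`, `chrom`, `start`, `end`,
#'   `mt_start`, `mt_end`, `length`, one `n_<population>` column per
#'   population, `carriers_total`, `freq_pct`, `freq_class`; attribute
#'   `"panel"` carries the panel.
#' @export
assign_population_counts <- function(clustered, panel, individuals,
                                     genome_length = MT_GENOME_LENGTH) {
  loci <- attr(clustered, "loci")
  stopifnot(!is.null(loci))
  pop <- individuals$population[match(clustered$individual_id,
                                      individuals$individual_id)]
  if (anyNA(pop)) {
    stop("individual(s) without a panel population: ",
         paste(unique(clustered$individual_id[is.na(pop)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(unique(pop) %in% panel$name)) {
    stop("population(s) not in panel", call. = FALSE)
  }
  total <- sum(panel$size)
  rows <- lapply(seq_len(NROW(loci)), function(i) {
    m <- clustered[clustered$locus == loci$locus[i], , drop = FALSE]
    mpop <- pop[clustered$locus == loci$locus[i]]
    carriers <- tapply(m$individual_id, mpop, function(x) length(unique(x)))
    cnt <- stats::setNames(integer(NROW(panel)), panel$name)
    cnt[names(carriers)] <- as.integer(carriers)
    mt <- select_mt_breakpoints(m)
    n_tot <- length(unique(m$individual_id))
    row <- data.frame(
      locus_id = sprintf("%s_%dM", loci$chrom[i],
                         (loci$start[i] + 1L) %/% 1000000L),
      chrom = loci$chrom[i], start = loci$start[i], end = loci$end[i],
      mt_start = mt[["mt_start"]], mt_end = mt[["mt_end"]],
      length = circular_fragment_length(mt[["mt_start"]], mt[["mt_end"]],
                                        genome_length),
      stringsAsFactors = FALSE)
    for (p in panel$name) row[[paste0("n_", p)]] <- cnt[[p]]
    row$carriers_total <- n_tot
    row$freq_pct <- 100 * n_tot / total
    row
  })
  out <- do.call(rbind, rows)
  out <- out[out$carriers_total > 0, , drop = FALSE]
  # disambiguate duplicate locus_ids within the same megabase
  dup <- duplicated(out$locus_id) | duplicated(out$locus_id, fromLast = TRUE)
  out$locus_id[dup] <- sprintf("%s_%d", out$locus_id[dup], out$start[dup] + 1L)
  out$freq_class <- classify_frequency(out$carriers_total, total)
  rownames(out) <- NULL
  attr(out, "panel") <- panel
  out
}

#' Merge per-individual calls into cohort loci
#'
#' Convenience wrapper: [merge_nuclear_breakpoints()] then
#' [assign_population_counts()].
#'
#' @inheritParams merge_nuclear_breakpoints
#' @inheritParams assign_population_counts
#' @return See [assign_population_counts()].
#' @export
merge_cohort_calls <- function(calls, panel, individuals, max_gap = 1000,
                               genome_length = MT_GENOME_LENGTH) {
  assign_population_counts(merge_nuclear_breakpoints(calls, max_gap),
                           panel, individuals, genome_length)
}
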