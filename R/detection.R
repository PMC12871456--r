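# Per-individual NUMT calling from abstracted read evidence.
#
# Alignment and BLAT realignment are upstream of this package: evidence
# arrives as records already typed as discordant pairs (one mate nuclear, one
# mitochondrial) or split reads assigned to a nuclear or mitochondrial side.
#
# Evidence table columns (one row per read observation):
#   read_id, kind ("pair"/"split"), side ("nuclear"/"mt"; NA for pairs),
#   chrom (nuclear chromosome of the read's nuclear anchor),
#   pos (nuclear position for pairs and nuclear-side splits; mtDNA
#        breakpoint position for mt-side splits),
#   anchor_pos (nuclear anchor position; equals pos for pairs and
#        nuclear-side splits, locates mt-side splits in the nuclear genome),
#   strand, mt_pos (mate mtDNA position, pairs only), mapq

#' Drop evidence records with zero mapping quality
#'
#' @param evidence Evidence data.frame with a `mapq` column.
#' @return The rows with `mapq > 0`.
#' @export
filter_evidence <- function(evidence) {
  stopifnot(is.data.frame(evidence), "mapq" %in% names(evidence))
  evidence[!is.na(evidence$mapq) & evidence$mapq > 0, , drop = FALSE]
}

#' Cluster discordant pairs by orientation and proximity
#'
#' Single-linkage clustering of nuclear anchor positions within each
#' (chromosome, strand) stratum: sorted consecutive anchors at most `max_gap`
#' bp apart chain into one cluster.  Clusters supported by fewer than
#' `min_pairs` pairs are discarded (their members keep `cluster_id = NA`), so
#' the returned ids partition the retained pairs.
#'
#' @param pairs Evidence rows with `kind == "pair"` (columns `chrom`, `pos`,
#'   `strand`).
#' @param max_gap Maximum bp between consecutive anchors in a cluster
#'   (default 500).
#' @param min_pairs Minimum pairs per retained cluster (default 2).
#' @return `pairs` with an integer `cluster_id` column (NA = discarded),
#'   rows ordered by chromosome, strand, position.
#' @export
cluster_discordant_pairs <- function(pairs, max_gap = 500, min_pairs = 2) {
  if (NROW(pairs) == 0) {
    pairs$cluster_id <- integer(0)
    return(pairs)
  }
  ord <- order(pairs$chrom, pairs$strand, pairs$pos)
  pairs <- pairs[ord, , drop = FALSE]
  key <- paste(pairs$chrom, pairs$strand)
  new_chain <- c(TRUE, key[-1] != key[-length(key)] |
                   diff(pairs$pos) > max_gap)
  chain <- cumsum(new_chain)
  keep <- table(chain)[as.character(chain)] >= min_pairs
  ids <- rep(NA_integer_, length(chain))
  retained <- unique(chain[keep])
  ids[keep] <- match(chain[keep], retained)
  pairs$cluster_id <- ids
  rownames(pairs) <- NULL
  pairs
}

# smallest modal value of an integer vector (deterministic tie-break)
modal_position <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])  # which.max takes first = smallest
}

# top-k distinct positions by frequency, ties broken toward the smaller
# coordinate
modal_positions <- function(x, k) {
  if (length(x) == 0) return(integer(0))
  tab <- sort(table(x), decreasing = TRUE)
  vals <- as.integer(names(tab))
  ord <- order(-as.integer(tab), vals)
  utils::head(vals[ord], k)
}

# Orient two mtDNA breakpoint positions into (mt_start, mt_end): of the two
# circular readings, prefer the one containing more of the discordant mates'
# mtDNA positions; break ties toward the shorter fragment.
orient_mt_pair <- function(a, b, pair_mt_pos, genome_length = MT_GENOME_LENGTH) {
  if (a == b) return(c(a, b))
  inside <- function(s, e) {
    len <- (e - s) %% genome_length
    off <- (pair_mt_pos - s) %% genome_length
    sum(off < len)
  }
  n1 <- inside(a, b); n2 <- inside(b, a)
  if (n1 > n2) return(c(a, b))
  if (n2 > n1) return(c(b, a))
  if ((b - a) %% genome_length <= (a - b) %% genome_length) c(a, b) else c(b, a)
}

#' Resolve breakpoints of one evidence cluster into a NUMT call
#'
#' A call needs a nuclear breakpoint and two mitochondrial breakpoints.  In
#' `modern` mode every breakpoint must be split-read supported: at least one
#' nuclear-side split and at least two mt-side splits at two distinct
#' positions (>= 3 split reads in total).  `archaic` mode -- for short-insert
#' degraded libraries where split reads are scarce -- relaxes this to at
#' least one supporting split read overall; breakpoints without split support
#' fall back to discordant-pair evidence (modal anchor position for the
#' nuclear side, extreme mate positions for the mitochondrial side).
#'
#' Breakpoints are the modal observed positions; ties break toward the
#' smallest coordinate.  The two mitochondrial positions are oriented into a
#' (start, end) pair by placing the fragment interior where the discordant
#' mates map.
#'
#' @param cluster_pairs Discordant-pair rows of one cluster.
#' @param splits Split-read evidence rows (any cluster; selected by nuclear
#'   anchor within the cluster region extended by `flank`).
#' @param mode `"modern"` or `"archaic"`.
#' @param flank Extension of the cluster region when collecting splits
#'   (default 500 bp).
#' @param genome_length Circular mtDNA length.
#' @param individual_id Sample label attached to the call.
#' @return One-row NUMT call data.frame, or `NULL` when split support is
#'   insufficient for the mode.
#' @export
resolve_breakpoints <- function(cluster_pairs, splits,
                                mode = c("modern", "archaic"),
                                flank = 500,
                                genome_length = MT_GENOME_LENGTH,
                                individual_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(NROW(cluster_pairs) >= 1)
  chrom <- cluster_pairs$chrom[1]
  lo <- min(cluster_pairs$pos) - flank
  hi <- max(cluster_pairs$pos) + flank
  sel <- splits[splits$chrom == chrom &
                  splits$anchor_pos >= lo & splits$anchor_pos <= hi, ,
                drop = FALSE]
  nuc <- sel[sel$side == "nuclear", , drop = FALSE]
  mts <- sel[sel$side == "mt", , drop = FALSE]
  n_distinct_mt <- length(unique(mts$pos))

  if (mode == "modern") {
    if (NROW(nuc) < 1 || NROW(mts) < 2 || n_distinct_mt < 2) return(NULL)
  } else {
    if (NROW(nuc) + NROW(mts) < 1) return(NULL)
  }

  nuclear_pos <- if (NROW(nuc) >= 1) modal_position(nuc$pos) else
    modal_position(cluster_pairs$pos)

  if (n_distinct_mt >= 2) {
    mp <- modal_positions(mts$pos, 2)
  } else if (n_distinct_mt == 1) {
    other <- cluster_pairs$mt_pos[cluster_pairs$mt_pos != mts$pos[1]]
    mp <- c(mts$pos[1],
            if (length(other)) modal_position(other) else mts$pos[1])
  } else {
    mp <- range(cluster_pairs$mt_pos)
  }
  mt <- orient_mt_pair(mp[1], mp[2], cluster_pairs$mt_pos, genome_length)

  data.frame(individual_id = individual_id,
             chrom = chrom,
             start = nuclear_pos - 1L,      # 0-based half-open point
             end = nuclear_pos,
             mt_start = as.integer(mt[1]),
             mt_end = as.integer(mt[2]),
             n_discordant_pairs = NROW(cluster_pairs),
             n_split_nuclear = NROW(nuc),
             n_split_mt = NROW(mts),
             stringsAsFactors = FALSE)
}

#' Filter calls by local coverage and a reference-NUMT mask
#'
#' Breakpoints in regions of extreme read depth are collapsed repeats or
#' reference-embedded NUMT copies, not segregating insertions: calls whose
#' local coverage strictly exceeds `max_coverage` are removed, as are calls
#' whose nuclear breakpoint falls inside an optional mask of NUMTs already
#' present in the reference assembly.
#'
#' @param calls NUMT call data.frame.
#' @param coverage_lookup Function `(chrom, start, end) -> mean depth` over
#'   the breakpoint region (0-based half-open), or `NULL` to skip the depth
#'   filter.
#' @param max_coverage Exclusive upper bound on retained local coverage
#'   (default 200; a call at exactly 200x is retained).
#' @param ref_numt_mask Optional data.frame `chrom`, `start`, `end` (0-based
#'   half-open) of reference-genome NUMTs.
#' @param missing_coverage What to do when the lookup returns `NA`:
#'   `"drop"` (default, with a warning), `"keep"`, or `"error"`.
#' @return The retained calls.
#' @export
coverage_filter <- function(calls, coverage_lookup = NULL, max_coverage = 200,
                            ref_numt_mask = NULL,
                            missing_coverage = c("drop", "keep", "error")) {
  missing_coverage <- match.arg(missing_coverage)
  if (NROW(calls) == 0) return(calls)
  keep <- rep(TRUE, NROW(calls))
  if (!is.null(coverage_lookup)) {
    cov <- mapply(coverage_lookup, calls$chrom, calls$start, calls$end)
    if (anyNA(cov)) {
      if (missing_coverage == "error") {
        stop("coverage missing for one or more calls", call. = FALSE)
      }
      if (missing_coverage == "drop") {
        warning("dropping ", sum(is.na(cov)), " call(s) with missing coverage")
        keep <- keep & !is.na(cov)
      }
    }
    keep <- keep & (is.na(cov) | cov <= max_coverage)
    if (missing_coverage == "drop") keep <- keep & !is.na(cov)
  }
  if (!is.null(ref_numt_mask) && NROW(ref_numt_mask) > 0) {
    hit <- overlaps_any(calls, ref_numt_mask)
    keep <- keep & !hit
  }
  calls[keep, , drop = FALSE]
}

#' Call NUMTs for one individual from an evidence table
#'
#' Runs the full per-individual chain: MAPQ filtering, discordant-pair
#' clustering, breakpoint resolution per cluster, and (optionally) the local
#' coverage filter.
#'
#' @param evidence Evidence table (see module header for columns).
#' @param individual_id Sample label.
#' @param mode `"modern"` (>= 3 split reads, one per breakpoint) or
#'   `"archaic"` (>= 1 split read, pair-evidence fallback).
#' @param max_gap,min_pairs Clustering parameters (500 bp, 2 pairs).
#' @param flank Split-read collection flank around each cluster.
#' @param coverage_lookup,max_coverage,ref_numt_mask Passed to
#'   [coverage_filter()].
#' @return NUMT call data.frame (possibly empty).
#' @export
call_numts <- function(evidence, individual_id, mode = "modern",
                       max_gap = 500, min_pairs = 2, flank = 500,
                       coverage_lookup = NULL, max_coverage = 200,
                       ref_numt_mask = NULL) {
  ev <- filter_evidence(evidence)
  pairs <- ev[ev$kind == "pair", , drop = FALSE]
  splits <- ev[ev$kind == "split", , drop = FALSE]
  clustered <- cluster_discordant_pairs(pairs, max_gap = max_gap,
                                        min_pairs = min_pairs)
  ids <- unique(clustered$cluster_id[!is.na(clustered$cluster_id)])
  calls <- lapply(ids, function(id) {
    resolve_breakpoints(clustered[!is.na(clustered$cluster_id) &
                                    clustered$cluster_id == id, , drop = FALSE],
                        splits, mode = mode, flank = flank,
                        individual_id = individual_id)
  })
  calls <- do.call(rbind, c(calls[!vapply(calls, is.null, logical(1))],
                            list(empty_call_table())))
  coverage_filter(calls, coverage_lookup, max_coverage, ref_numt_mask)
}

empty_call_table <- function() {
  data.frame(individual_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             mt_start = integer(0), mt_end = integer(0),
             n_discordant_pairs = integer(0), n_split_nuclear = integer(0),
             n_split_mt = integer(0), stringsAsFactors = FALSE)
}
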