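# Permutation enrichment of NUMT insertion sites against nuclear annotation
# tracks, and sliding-window hotspot detection of NUMT origins on the
# circular mitochondrial genome.

#' Count NUMTs whose flanked insertion site intersects a track
#'
#' Each NUMT's nuclear interval is extended by `flank` bp on both sides; the
#' count is the number of NUMTs (each at most once) whose extended interval
#' intersects any interval of the annotation track.
#'
#' @param numts data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param track data.frame `chrom`, `start`, `end`.
#' @param flank Flank in bp (default 100, i.e. a 200-bp flanking area around
#'   a point insertion).
#' @return Integer count.
#' @export
flank_overlap_count <- function(numts, track, flank = 100) {
  if (NROW(numts) == 0) return(0L)
  ext <- numts
  ext$start <- pmax(0L, ext$start - as.integer(flank))
  ext$end <- ext$end + as.integer(flank)
  sum(overlaps_any(ext, track))
}

# closure counting random 0-based points whose +/-flank window touches the
# track; merged flanked intervals per chromosome make each replicate a
# findInterval lookup
flanked_point_counter <- function(track, flank) {
  bounds <- lapply(split(track, track$chrom), function(tr) {
    s <- tr$start - flank; e <- tr$end + flank
    o <- order(s); s <- s[o]; e <- e[o]
    grp <- cumsum(c(TRUE, s[-1] > cummax(e)[-length(e)]))
    as.numeric(rbind(tapply(s, grp, min), tapply(e, grp, max)))
  })
  function(chrom, pos) {
    cnt <- 0L
    for (ch in unique(chrom)) {
      b <- bounds[[ch]]
      if (is.null(b)) next
      idx <- findInterval(pos[chrom == ch], b)
      cnt <- cnt + sum(idx %% 2L == 1L)  # odd index = inside an interval
    }
    cnt
  }
}

# add-one two-tailed empirical p from a null vector and an observed value
two_tailed_empirical_p <- function(null_values, observed) {
  ge <- sum(null_values >= observed)
  le <- sum(null_values <= observed)
  n <- length(null_values)
  min(1, 2 * min(ge + 1, le + 1) / (n + 1))
}

#' Permutation test for NUMT insertion-site enrichment in a nuclear track
#'
#' Each replicate draws as many random insertion points as there are NUMTs
#' -- chromosome chosen proportional to length, position uniform -- and
#' recomputes [flank_overlap_count()].  The two-tailed empirical p-value is
#' `min(1, 2 * min(#\{null >= obs\} + 1, #\{null <= obs\} + 1) / (n_perm + 1))`;
#' the raw one-sided exceedance fractions are reported alongside.
#'
#' @inheritParams flank_overlap_count
#' @param genome data.frame `chrom`, `length` giving chromosome sizes.
#' @param n_perm Number of replicates (default 1000).
#' @param seed Optional RNG seed.
#' @return List of class `"numt_enrichment_test"`: `observed`, `null_counts`,
#'   `p_two_tailed`, `frac_ge`, `frac_le`, `n_perm`, `seed`.
#' @export
nuclear_permutation_test <- function(numts, track, genome, n_perm = 1000,
                                     flank = 100, seed = NULL) {
  if (NROW(track) == 0) {
    warning("empty annotation track: p undefined")
    return(structure(list(observed = 0L, null_counts = integer(0),
                          p_two_tailed = NA_real_, frac_ge = NA_real_,
                          frac_le = NA_real_, n_perm = n_perm, seed = seed),
                     class = "numt_enrichment_test"))
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  obs <- flank_overlap_count(numts, track, flank)
  n <- NROW(numts)
  counter <- flanked_point_counter(track, flank)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    ci <- sample.int(NROW(genome), n, replace = TRUE,
                     prob = genome$length)
    pos <- floor(stats::runif(n) * genome$length[ci])  # 0-based point
    counter(genome$chrom[ci], pos)
  }, integer(1))
  structure(list(observed = obs, null_counts = null_counts,
                 p_two_tailed = two_tailed_empirical_p(null_counts, obs),
                 frac_ge = mean(null_counts >= obs),
                 frac_le = mean(null_counts <= obs),
                 n_perm = n_perm, seed = seed),
            class = "numt_enrichment_test")
}

#' @export
print.numt_enrichment_test <- function(x, ...) {
  cat("NUMT insertion-site permutation enrichment test\n")
  cat(sprintf("  observed overlap count : %d\n", x$observed))
  cat(sprintf("  replicates             : %d\n", x$n_perm))
  cat(sprintf("  two-tailed P = %g  (frac >= obs: %g, frac <= obs: %g)\n",
              x$p_two_tailed, x$frac_ge, x$frac_le))
  invisible(x)
}

#' Sliding-window start positions on the circular mitochondrial genome
#' @keywords internal
mt_window_starts <- function(genome_length = MT_GENOME_LENGTH, width = 50,
                             overlap = 10) {
  step <- width - overlap
  seq.int(1L, genome_length, by = step)
}

#' Per-window mean NUMT coverage of the circular mitochondrial genome
#'
#' Windows of `width` bp slide with `overlap` bp shared between adjacent
#' windows (step = width - overlap), wrapping through the origin so every
#' position is covered.  A window's value is the mean, over its `width`
#' positions, of the number of NUMT fragments covering each position
#' (optionally weighted, e.g. by cohort frequency).
#'
#' @param numts data.frame with `mt_start`, `mt_end` (1-based circular
#'   breakpoints).
#' @param genome_length Circular genome length (default 16,569).
#' @param width,overlap Window geometry (defaults 50 and 10).
#' @param weights Optional per-fragment weights (default: each fragment
#'   counts 1).
#' @return data.frame `win_start`, `win_end` (1-based circular, `win_end`
#'   may wrap below `win_start`), `coverage`.
#' @export
mt_coverage_windows <- function(numts, genome_length = MT_GENOME_LENGTH,
                                width = 50, overlap = 10, weights = NULL) {
  cov <- circular_coverage(numts$mt_start, numts$mt_end, genome_length,
                           weights)
  starts <- mt_window_starts(genome_length, width, overlap)
  vals <- window_means(cov, starts, width)
  data.frame(win_start = starts,
             win_end = (starts - 1L + width - 1L) %% genome_length + 1L,
             coverage = vals)
}

# mean of a circular per-base vector over windows of `width` starting at
# `starts` (1-based), via a cumulative sum over the wrapped vector
window_means <- function(cov, starts, width) {
  L <- length(cov)
  cs <- cumsum(c(0, cov, cov[seq_len(min(width, L))]))
  (cs[starts + width] - cs[starts]) / width
}

#' Hotspot detection of NUMT origins on the mitochondrial genome
#'
#' Compares observed per-window NUMT coverage against a null in which the
#' same number of fragments, with identical lengths, are placed at uniform
#' random starts on the circle (so total covered base pairs are conserved in
#' every replicate).  Per-window two-tailed empirical p-values use the
#' add-one convention; windows with `p < alpha` in the enrichment direction
#' (observed above the null median) that overlap or abut are merged into
#' hotspot intervals.
#'
#' @inheritParams mt_coverage_windows
#' @param n_sim Number of simulation replicates (default 5000).
#' @param seed Optional RNG seed.
#' @param alpha Window significance threshold for merging (default 0.05).
#' @return List of class `"mt_hotspot_test"`: `windows` (per-window
#'   data.frame with `coverage`, `null_mean`, `p`, `enriched`,
#'   `significant`), `hotspots` (merged circular intervals `start`, `end`,
#'   `min_p`), `n_sim`, `seed`.
#' @export
mt_hotspot_permutation <- function(numts, genome_length = MT_GENOME_LENGTH,
                                   width = 50, overlap = 10, n_sim = 5000,
                                   seed = NULL, alpha = 0.05,
                                   weights = NULL) {
  stopifnot(NROW(numts) >= 1)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  obs <- mt_coverage_windows(numts, genome_length, width, overlap, weights)
  lens <- circular_fragment_length(numts$mt_start, numts$mt_end,
                                   genome_length)
  starts_grid <- mt_window_starts(genome_length, width, overlap)
  n_frag <- length(lens)
  null_mat <- matrix(0, n_sim, length(starts_grid))
  for (s in seq_len(n_sim)) {
    rs <- sample.int(genome_length, n_frag, replace = TRUE)
    re <- (rs - 1L + lens) %% genome_length + 1L
    cov <- circular_coverage(rs, re, genome_length, weights)
    null_mat[s, ] <- window_means(cov, starts_grid, width)
  }
  ge <- colSums(null_mat >= rep(obs$coverage, each = n_sim) - 1e-12)
  le <- colSums(null_mat <= rep(obs$coverage, each = n_sim) + 1e-12)
  p <- pmin(1, 2 * pmin(ge + 1, le + 1) / (n_sim + 1))
  null_mean <- colMeans(null_mat)
  win <- obs
  win$null_mean <- null_mean
  win$p <- p
  win$enriched <- win$coverage > apply(null_mat, 2, stats::median)
  win$significant <- win$p < alpha
  hotspots <- merge_circular_windows(win[win$significant & win$enriched, ,
                                         drop = FALSE],
                                     genome_length)
  structure(list(windows = win, hotspots = hotspots, n_sim = n_sim,
                 seed = seed),
            class = "mt_hotspot_test")
}

# merge overlapping/adjacent significant windows into circular intervals
merge_circular_windows <- function(sig, genome_length) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      min_p = numeric(0))
  if (NROW(sig) == 0) return(empty)
  covered <- rep(FALSE, genome_length)
  pmin_track <- rep(Inf, genome_length)
  for (i in seq_len(NROW(sig))) {
    pos <- circular_positions(sig$win_start[i],
                              (sig$win_end[i] %% genome_length) + 1L,
                              genome_length)
    covered[pos] <- TRUE
    pmin_track[pos] <- pmin(pmin_track[pos], sig$p[i])
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # stitch a run touching position L to one starting at position 1
  if (NROW(runs) >= 2 && runs$start[1] == 1 &&
      runs$end[NROW(runs)] == genome_length) {
    runs$start[1] <- runs$start[NROW(runs)]
    runs <- runs[-NROW(runs), , drop = FALSE]
  }
  runs$min_p <- vapply(seq_len(NROW(runs)), function(i) {
    pos <- circular_positions(runs$start[i],
                              (runs$end[i] %% genome_length) + 1L,
                              genome_length)
    min(pmin_track[pos])
  }, numeric(1))
  rownames(runs) <- NULL
  runs
}

#' @export
print.mt_hotspot_test <- function(x, ...) {
  cat("Mitochondrial NUMT-origin hotspot scan\n")
  cat(sprintf("  windows    : %d (width %d)\n", NROW(x$windows),
              x$windows$win_end[1] - x$windows$win_start[1] + 1L))
  cat(sprintf("  replicates : %d\n", x$n_sim))
  cat(sprintf("  hotspots   : %d merged region(s)\n", NROW(x$hotspots)))
  invisible(x)
}
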