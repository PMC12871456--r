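# Population branch statistic (PBS) selection scan over NUMT loci, with
# z-score outliers, block jackknife stability, nearest-gene assignment and a
# carrier-based expression association test.

#' Hudson's two-population F_ST estimator
#'
#' Sample-size-corrected Hudson estimator from allele frequencies:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`.  Estimates are clamped to `[0, 1 - cap_eps]` so
#' the branch-length transform `-log(1 - F_ST)` stays finite.
#'
#' @param p1,p2 Allele frequencies in `[0, 1]`.
#' @param n1,n2 Sample sizes in haplotypes (> 1).
#' @param cap_eps Distance kept below 1 (default 1e-9).
#' @return F_ST estimate(s) in `[0, 1 - cap_eps]`.
#' @export
hudson_fst <- function(p1, n1, p2, n2, cap_eps = 1e-9) {
  if (any(n1 <= 1 | n2 <= 1)) stop("sample sizes must exceed 1", call. = FALSE)
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den <= 0, 0, num / den)
  pmin(pmax(fst, 0), 1 - cap_eps)
}

#' Population branch statistic from three pairwise F_ST values
#'
#' Branch lengths are `T = -log(1 - F_ST)`; the branch private to population
#' A is `PBS_A = (T_AB + T_AC - T_BC) / 2`.  F_ST values of 1 are capped
#' just below 1 (with a warning) to keep T finite.
#'
#' @param fst_ab,fst_ac,fst_bc Pairwise F_ST values in `[0, 1]`.
#' @param cap_eps Cap distance below 1.
#' @return PBS value(s) for population A.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc, cap_eps = 1e-9) {
  f <- cbind(fst_ab, fst_ac, fst_bc)
  if (any(f < 0 | f > 1)) stop("F_ST must lie in [0, 1]", call. = FALSE)
  if (any(f >= 1)) {
    warning("F_ST of 1 capped at 1 - cap_eps before log transform")
    f <- pmin(f, 1 - cap_eps)
  }
  t_ <- -log(1 - f)
  unname((t_[, 1] + t_[, 2] - t_[, 3]) / 2)
}

#' Best PBS triplet for one locus
#'
#' The focal population is the one with the highest allele frequency at the
#' locus (ties break toward the larger sample size, then alphabetically).
#' Sister populations come from the focal population's continent -- except
#' for an Oceanian (Papuan) focal population, whose sisters are drawn from
#' East Asia -- and outgroups from any continent different from both.  All
#' (sister, outgroup) pairs are enumerated and the triplet maximising the
#' focal branch is returned.
#'
#' @param freqs Per-population frequency table for the locus: data.frame
#'   `population`, `continent`, `p` (allele frequency), `n` (haplotypes).
#' @param oceania_label,east_asia_label Continent labels driving the Papuan
#'   ingroup rule (defaults `"Oceania"`, `"EastAsia"`).
#' @return One-row data.frame `focal`, `sister`, `outgroup`, `fst_fs`,
#'   `fst_fo`, `fst_so`, `pbs`, or `NULL` (with a warning) when no valid
#'   triplet exists.
#' @export
triplet_scan <- function(freqs, oceania_label = "Oceania",
                         east_asia_label = "EastAsia") {
  stopifnot(all(c("population", "continent", "p", "n") %in% names(freqs)))
  ord <- order(-freqs$p, -freqs$n, freqs$population)
  focal <- freqs[ord[1], ]
  sister_cont <- if (focal$continent == oceania_label) east_asia_label
                 else focal$continent
  sisters <- freqs[freqs$continent == sister_cont &
                     freqs$population != focal$population, , drop = FALSE]
  outs <- freqs[!(freqs$continent %in% c(focal$continent, sister_cont)), ,
                drop = FALSE]
  if (NROW(sisters) == 0 || NROW(outs) == 0) {
    warning("no valid (sister, outgroup) pair for focal population ",
            focal$population)
    return(NULL)
  }
  grid <- expand.grid(s = seq_len(NROW(sisters)), o = seq_len(NROW(outs)))
  fst_fs <- hudson_fst(focal$p, focal$n, sisters$p[grid$s], sisters$n[grid$s])
  fst_fo <- hudson_fst(focal$p, focal$n, outs$p[grid$o], outs$n[grid$o])
  fst_so <- hudson_fst(sisters$p[grid$s], sisters$n[grid$s],
                       outs$p[grid$o], outs$n[grid$o])
  val <- pbs(fst_fs, fst_fo, fst_so)
  best <- which.max(val)
  data.frame(focal = focal$population,
             sister = sisters$population[grid$s[best]],
             outgroup = outs$population[grid$o[best]],
             fst_fs = fst_fs[best], fst_fo = fst_fo[best],
             fst_so = fst_so[best], pbs = val[best],
             stringsAsFactors = FALSE)
}

#' PBS scan over a set of loci
#'
#' Applies [triplet_scan()] to every locus of a long-format frequency table.
#'
#' @param freq_table data.frame `locus_id`, `population`, `continent`, `p`,
#'   `n`.
#' @param ... Passed to [triplet_scan()].
#' @return data.frame with one row per locus that admitted a triplet:
#'   `locus_id` plus the [triplet_scan()] columns.
#' @export
pbs_scan <- function(freq_table, ...) {
  rows <- lapply(split(freq_table, freq_table$locus_id), function(f) {
    r <- triplet_scan(f, ...)
    if (is.null(r)) return(NULL)
    cbind(data.frame(locus_id = f$locus_id[1], stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Flag z-score outliers among per-locus maximum PBS values
#'
#' @param pbs_values Numeric vector of per-locus max PBS (>= 3 values).
#' @param z_cut Threshold on `|Z|` (default 2).
#' @return data.frame `pbs`, `z`, `outlier`.
#' @export
zscore_outliers <- function(pbs_values, z_cut = 2) {
  if (length(pbs_values) < 3) stop("need >= 3 loci", call. = FALSE)
  s <- stats::sd(pbs_values)
  if (!is.finite(s) || s == 0) {
    warning("zero variance among PBS values; no outliers flagged")
    z <- rep(0, length(pbs_values))
  } else {
    z <- (pbs_values - mean(pbs_values)) / s
  }
  data.frame(pbs = pbs_values, z = z, outlier = abs(z) > z_cut)
}

#' Block jackknife stability of PBS z-score outliers
#'
#' The genome is tiled into nonoverlapping windows of `window` bp; every
#' window containing at least one locus is removed in turn and z-scores are
#' recomputed over the remaining loci.  For each locus the report gives the
#' fraction of iterations (among those in which the locus survives) where
#' its `|Z| > z_cut` status matches the full-data status.
#'
#' @param loci data.frame `locus_id`, `chrom`, `start` (0-based), `pbs`.
#' @param window Window size in bp (500 kb or 1 Mb in practice).
#' @param z_cut Outlier threshold (default 2).
#' @return data.frame `locus_id`, `z_full`, `outlier_full`, `n_iter`,
#'   `stability`; attribute `"n_windows"` gives the number of removable
#'   windows.  When all loci share one window the single iteration is
#'   degenerate and `stability` is `NA`.
#' @export
block_jackknife <- function(loci, window = 500000, z_cut = 2) {
  stopifnot(all(c("locus_id", "chrom", "start", "pbs") %in% names(loci)))
  win <- paste(loci$chrom, loci$start %/% window)
  wins <- unique(win)
  full <- zscore_outliers(loci$pbs, z_cut)
  match_cnt <- integer(NROW(loci))
  iter_cnt <- integer(NROW(loci))
  if (length(wins) > 1) {
    for (w in wins) {
      keep <- win != w
      if (sum(keep) < 3) next
      zi <- zscore_outliers(loci$pbs[keep], z_cut)
      iter_cnt[keep] <- iter_cnt[keep] + 1L
      match_cnt[keep] <- match_cnt[keep] +
        (zi$outlier == full$outlier[keep])
    }
  }
  data.frame(locus_id = loci$locus_id, z_full = full$z,
             outlier_full = full$outlier, n_iter = iter_cnt,
             stability = ifelse(iter_cnt > 0, match_cnt / iter_cnt, NA_real_),
             stringsAsFactors = FALSE) -> out
  attr(out, "n_windows") <- length(wins)
  out
}

#' Nearest gene to an extended NUMT breakpoint
#'
#' Extends the nuclear breakpoint interval by `flank` bp on both sides and
#' reports the gene at minimal distance from the extended region (0 when
#' overlapping).  Ties break alphabetically by gene name.
#'
#' @param locus One-row data.frame `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes data.frame `chrom`, `start`, `end`, `name` (0-based
#'   half-open).
#' @param flank Extension in bp (default 5000).
#' @return One-row data.frame `gene`, `distance`, or `NULL` when the
#'   annotation is empty or lacks the chromosome.
#' @export
nearest_gene <- function(locus, genes, flank = 5000) {
  g <- genes[genes$chrom == locus$chrom[1], , drop = FALSE]
  if (NROW(g) == 0) return(NULL)
  lo <- locus$start[1] - flank
  hi <- locus$end[1] + flank
  d <- pmax(0, pmax(g$start - hi, lo - g$end))
  ord <- order(d, g$name)
  data.frame(gene = g$name[ord[1]], distance = d[ord[1]],
             stringsAsFactors = FALSE)
}

#' Carrier vs non-carrier expression comparison around a NUMT
#'
#' For a NUMT with at least `min_carriers` carriers, compares expression of
#' every gene whose annotated interval lies within `window` bp of the NUMT
#' between carrier and non-carrier individuals with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param locus One-row data.frame `chrom`, `start`, `end`.
#' @param expression Matrix/data.frame of expression values, genes in rows
#'   (rownames = gene names), individuals in columns.
#' @param carriers Character vector of carrier individual ids (columns of
#'   `expression`).
#' @param genes Gene annotation data.frame `chrom`, `start`, `end`, `name`.
#' @param window Flank in bp (default 2e5).
#' @param min_carriers Minimum carriers to test (default 10).
#' @param alpha Significance threshold recorded in the output (default 0.05).
#' @return data.frame `gene`, `n_carrier`, `n_noncarrier`, `p_value`,
#'   `significant`, or `NULL` when the locus is skipped (too few carriers or
#'   no gene in the window).
#' @export
expression_association <- function(locus, expression, carriers, genes,
                                   window = 200000, min_carriers = 10,
                                   alpha = 0.05) {
  samples <- colnames(expression)
  carriers <- intersect(carriers, samples)
  if (length(carriers) < min_carriers) return(NULL)
  noncar <- setdiff(samples, carriers)
  g <- genes[genes$chrom == locus$chrom[1] &
               genes$start < locus$end[1] + window &
               genes$end > locus$start[1] - window, , drop = FALSE]
  g <- g[g$name %in% rownames(expression), , drop = FALSE]
  if (NROW(g) == 0) return(NULL)
  res <- lapply(g$name, function(gene) {
    x <- as.numeric(expression[gene, carriers])
    y <- as.numeric(expression[gene, noncar])
    p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    data.frame(gene = gene, n_carrier = length(carriers),
               n_noncarrier = length(noncar), p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
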