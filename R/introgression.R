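# Archaic introgressed segments: reconstruction from Sprime-style output,
# per-individual NUMT/segment overlap rates, the cohort permutation test, and
# haplotype colocalization classes.

#' Reconstruct per-individual introgressed segments from Sprime-style sites
#'
#' Sprime-style output lists candidate segments and the putative
#' archaic-specific allele at each member site.  For each individual
#' haplotype, maximal runs of consecutive sites (within one segment id)
#' carrying the archaic allele become introgressed segments spanning the
#' first to last site of the run.  Runs shorter than `min_run` are dropped: a
#' single archaic-like allele does not define a span.
#'
#' @param sites data.frame `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `archaic_allele`, `segment_id`.
#' @param genotypes data.frame `chrom`, `pos`, plus one column per individual
#'   holding phased GT strings (`"0|1"`); rows aligned to `sites` by
#'   (chrom, pos).
#' @param min_run Minimum consecutive archaic-allele sites per segment
#'   (default 2).
#' @param source Callset label stored on the output (default `"Sprime"`).
#' @return data.frame `individual_id`, `haplotype` (0/1), `chrom`, `start`,
#'   `end` (0-based half-open span of the run), `segment_id`, `n_sites`,
#'   `source`.
#' @export
reconstruct_individual_segments <- function(sites, genotypes, min_run = 2,
                                            source = "Sprime") {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "archaic_allele",
                  "segment_id") %in% names(sites)))
  key <- paste(sites$chrom, sites$pos)
  gkey <- paste(genotypes$chrom, genotypes$pos)
  idx <- match(key, gkey)
  if (anyNA(idx)) stop("genotypes missing for some sites", call. = FALSE)
  samples <- setdiff(names(genotypes), c("chrom", "pos", "ref", "alt", "id"))
  out <- list()
  for (ind in samples) {
    gt <- genotypes[[ind]][idx]
    if (any(grepl("/", gt, fixed = TRUE))) {
      stop("unphased genotype for individual ", ind,
           ": segment reconstruction requires phased haplotypes",
           call. = FALSE)
    }
    alleles <- strsplit(gt, "|", fixed = TRUE)
    a0 <- vapply(alleles, `[`, "", 1)
    a1 <- vapply(alleles, `[`, "", 2)
    for (hap in 0:1) {
      code <- if (hap == 0) a0 else a1
      base <- ifelse(code == "0", sites$ref, sites$alt)
      carries <- !is.na(base) & base == sites$archaic_allele
      for (seg in unique(sites$segment_id)) {
        in_seg <- sites$segment_id == seg
        ord <- order(sites$pos[in_seg])
        pos <- sites$pos[in_seg][ord]
        hit <- carries[in_seg][ord]
        r <- rle(hit)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values & r$lengths >= min_run)) {
          out[[length(out) + 1L]] <- data.frame(
            individual_id = ind, haplotype = hap,
            chrom = sites$chrom[in_seg][1],
            start = pos[starts[k]] - 1L, end = pos[ends[k]],
            segment_id = seg, n_sites = r$lengths[k],
            source = source, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(individual_id = character(0), haplotype = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), segment_id = character(0),
                      n_sites = integer(0), source = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-individual overlap rate between NUMTs and introgressed segments
#'
#' R = (number of the individual's NUMTs whose nuclear interval intersects
#' any of the individual's segments by >= 1 bp) / (total NUMTs).  Intervals
#' are 0-based half-open, so a shared boundary base counts only when the
#' intersection is nonempty.
#'
#' @param calls One individual's NUMT calls (`chrom`, `start`, `end`).
#' @param segments That individual's segments (`chrom`, `start`, `end`).
#' @return Overlap rate in `[0, 1]`; `NA` when the individual has no NUMTs.
#' @export
overlap_rate <- function(calls, segments) {
  if (NROW(calls) == 0) return(NA_real_)
  mean(overlaps_any(calls, segments))
}

# Matrix R[i, j]: overlap rate of analysis individual i's NUMTs against pool
# individual j's segment set (segments kept at their own coordinates).
overlap_rate_matrix <- function(calls, segments, analysis_ids, pool_ids) {
  R <- matrix(0, length(analysis_ids), length(pool_ids),
              dimnames = list(analysis_ids, pool_ids))
  calls_a <- calls[calls$individual_id %in% analysis_ids, , drop = FALSE]
  n_i <- table(factor(calls_a$individual_id, levels = analysis_ids))
  if (NROW(calls_a) == 0 || NROW(segments) == 0) return(R)
  lv <- unique(c(calls_a$chrom, segments$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(calls_a, lv),
                                      as_granges(segments, lv))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    j <- segments$individual_id[S4Vectors::subjectHits(hits)]
    uq <- !duplicated(paste(q, j))
    cnt <- table(factor(calls_a$individual_id[q[uq]], levels = analysis_ids),
                 factor(j[uq], levels = pool_ids))
    R <- sweep(unclass(cnt), 1, pmax(as.numeric(n_i), 1), "/")
    dimnames(R) <- list(analysis_ids, pool_ids)
  }
  R
}

#' Permutation test for NUMT / introgressed-segment co-occurrence
#'
#' The empirical statistic is the mean per-individual overlap rate over the
#' analysis set.  Each of `n_perm` replicates reassigns to every analysis
#' individual the complete segment set of a uniformly drawn *different*
#' individual from the cohort pool (segments keep their genomic coordinates),
#' recomputes the mean overlap rate, and the one-sided enrichment p-value is
#' the fraction of replicate means greater than or equal to the empirical
#' mean.  When no replicate reaches it the result is reported as the bound
#' `p < 1/n_perm`.
#'
#' @param calls Cohort NUMT calls (`individual_id`, `chrom`, `start`, `end`).
#' @param segments Cohort segments (`individual_id`, `chrom`, `start`,
#'   `end`).
#' @param n_perm Number of replicates (default 5000).
#' @param seed Optional RNG seed for reproducibility.
#' @param analysis_set `"overlapping"` (default): individuals whose own
#'   NUMTs overlap their own segments at least once; `"all"`: every
#'   individual with >= 1 NUMT.
#' @param pool_ids Individuals whose segment sets form the reassignment
#'   pool; defaults to every individual present in `calls` or `segments`.
#' @return List of class `"numt_overlap_test"`: `r_emp` (named
#'   per-individual rates over NUMT carriers), `r_mean`, `analysis_ids`,
#'   `n_analysis`, `n_exceed`, `p_value` (= `n_exceed / n_perm`), `p_bound`
#'   (`1/n_perm` when `n_exceed` is 0, else `p_value`), `p_label`, `n_perm`,
#'   `seed`, `null_means`.
#' @export
permutation_overlap_test <- function(calls, segments, n_perm = 5000,
                                     seed = NULL,
                                     analysis_set = c("overlapping", "all"),
                                     pool_ids = NULL) {
  analysis_set <- match.arg(analysis_set)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  carriers <- unique(calls$individual_id)
  if (is.null(pool_ids)) {
    pool_ids <- unique(c(calls$individual_id, segments$individual_id))
  }
  if (length(pool_ids) < 2) {
    stop("permutation needs a cohort of >= 2 individuals", call. = FALSE)
  }
  r_emp <- vapply(carriers, function(ind) {
    overlap_rate(calls[calls$individual_id == ind, , drop = FALSE],
                 segments[segments$individual_id == ind, , drop = FALSE])
  }, numeric(1))
  names(r_emp) <- carriers
  analysis_ids <- if (analysis_set == "overlapping") {
    carriers[r_emp > 0]
  } else carriers
  if (!length(analysis_ids)) {
    stop("analysis set is empty (no individual has an overlapping NUMT)",
         call. = FALSE)
  }
  r_mean <- mean(r_emp[analysis_ids])

  R <- overlap_rate_matrix(calls, segments, analysis_ids, pool_ids)
  sums <- numeric(n_perm)
  P <- length(pool_ids)
  for (k in seq_along(analysis_ids)) {
    self <- match(analysis_ids[k], pool_ids)
    if (is.na(self)) {
      draw <- sample.int(P, n_perm, replace = TRUE)
    } else {
      draw <- sample.int(P - 1L, n_perm, replace = TRUE)
      draw <- draw + (draw >= self)  # skip the individual's own set
    }
    sums <- sums + R[k, draw]
  }
  null_means <- sums / length(analysis_ids)
  n_exceed <- sum(null_means >= r_mean - 1e-12)
  p_value <- n_exceed / n_perm
  p_bound <- if (n_exceed == 0) 1 / n_perm else p_value
  structure(list(r_emp = r_emp, r_mean = r_mean,
                 analysis_ids = analysis_ids,
                 n_analysis = length(analysis_ids),
                 n_exceed = n_exceed, p_value = p_value, p_bound = p_bound,
                 p_label = if (n_exceed == 0) sprintf("< %g", 1 / n_perm)
                           else sprintf("= %g", p_value),
                 n_perm = n_perm, seed = seed, null_means = null_means),
            class = "numt_overlap_test")
}

#' @export
print.numt_overlap_test <- function(x, ...) {
  cat("NUMT / introgressed-segment permutation overlap test\n")
  cat(sprintf("  analysis individuals : %d\n", x$n_analysis))
  cat(sprintf("  mean overlap rate    : %.4f\n", x$r_mean))
  cat(sprintf("  replicates           : %d\n", x$n_perm))
  cat(sprintf("  P %s (one-sided, enrichment)\n", x$p_label))
  invisible(x)
}

#' Classify NUMT / segment haplotype colocalization
#'
#' Given per-individual genotype classes for a NUMT and an overlapping
#' introgressed segment (and, for double heterozygotes, the phased haplotype
#' index each lies on), classifies the configuration:
#' \describe{
#'   \item{same-haplotype}{het NUMT and het segment phased to the same
#'     haplotype.}
#'   \item{different-haplotype}{both het, phased to opposite haplotypes.}
#'   \item{consistent-coinheritance}{hom NUMT with het segment or het NUMT
#'     with hom segment: every haplotype carrying the rarer state also
#'     carries the other.}
#'   \item{shared}{homozygous for both.}
#'   \item{uninformative}{missing genotype, or double het without phase.}
#' }
#'
#' @param numt_gt,seg_gt Genotype classes, `"het"` or `"hom"` (NA allowed).
#' @param numt_hap,seg_hap Haplotype index (0/1) for phased heterozygotes;
#'   NA when unphased.
#' @return Character vector of classifications.
#' @export
haplotype_colocalization <- function(numt_gt, seg_gt,
                                     numt_hap = NA, seg_hap = NA) {
  n <- max(length(numt_gt), length(seg_gt))
  numt_gt <- rep_len(as.character(numt_gt), n)
  seg_gt <- rep_len(as.character(seg_gt), n)
  numt_hap <- rep_len(numt_hap, n)
  seg_hap <- rep_len(seg_hap, n)
  vapply(seq_len(n), function(i) {
    if (is.na(numt_gt[i]) || is.na(seg_gt[i])) return("uninformative")
    if (numt_gt[i] == "hom" && seg_gt[i] == "hom") return("shared")
    if (xor(numt_gt[i] == "hom", seg_gt[i] == "hom")) {
      return("consistent-coinheritance")
    }
    if (is.na(numt_hap[i]) || is.na(seg_hap[i])) return("uninformative")
    if (numt_hap[i] == seg_hap[i]) "same-haplotype" else "different-haplotype"
  }, character(1))
}
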