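# Cohort-level domain types and summary statistics.
#
# Containers are plain data.frames with documented columns:
#   population panel : name, continent, size
#   NUMT call        : individual_id, chrom, start, end (0-based half-open),
#                      mt_start, mt_end (1-based circular),
#                      n_discordant_pairs, n_split_nuclear, n_split_mt
#   merged NUMT      : locus_id, chrom, start, end, mt_start, mt_end, length,
#                      one carrier-count column per population, carriers_total,
#                      freq_pct, freq_class

#' Construct a population panel
#'
#' @param name Population labels (unique).
#' @param continent Continental group per population.
#' @param size Number of sampled individuals per population (> 0).
#' @return data.frame with columns `name`, `continent`, `size`.
#' @export
population_panel <- function(name, continent, size) {
  if (anyDuplicated(name)) stop("population names must be unique", call. = FALSE)
  if (any(size <= 0)) stop("panel sizes must be > 0", call. = FALSE)
  data.frame(name = as.character(name), continent = as.character(continent),
             size = as.integer(size), stringsAsFactors = FALSE)
}

#' Round half-up to a given number of digits
#'
#' Base `round()` rounds half-to-even; cohort summary statistics are reported
#' with the conventional half-up rule (162.5 -> 163).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Frequency classes for cohort carrier frequency
#'
#' Carrier frequency F (percent) partitions into: prevalent (F > 10%),
#' common (1% <= F <= 10%), rare (0.1% <= F < 1%) and ultrarare (F < 0.1%).
#'
#' @return Character vector of the four class labels, most to least frequent.
#' @export
frequency_classes <- function() c("prevalent", "common", "rare", "ultrarare")

#' Classify a carrier frequency
#'
#' @param carriers Number of carrier individuals (0 <= carriers <= panel_total).
#' @param panel_total Total individuals in the panel (> 0).
#' @return Factor with levels `frequency_classes()`.
#' @examples
#' classify_frequency(336, 504)  # 66.6% -> prevalent
#' classify_frequency(1, 100)    # 1%    -> common (boundary inclusive)
#' @export
classify_frequency <- function(carriers, panel_total) {
  if (any(panel_total <= 0)) stop("panel_total must be > 0", call. = FALSE)
  if (any(carriers < 0 | carriers > panel_total)) {
    stop("carriers must lie in [0, panel_total]", call. = FALSE)
  }
  f <- 100 * carriers / panel_total
  cls <- ifelse(f > 10, "prevalent",
         ifelse(f >= 1, "common",
         ifelse(f >= 0.1, "rare", "ultrarare")))
  factor(cls, levels = frequency_classes())
}

#' Fragment-length summary over a merged NUMT table
#'
#' Mean, median and sample standard deviation (n - 1 denominator) of the
#' mitochondrial fragment lengths of a set of loci, with half-up-rounded
#' display values alongside the exact ones.
#'
#' @param loci data.frame with either a `length` column or `mt_start` /
#'   `mt_end` columns (lengths then computed circularly).
#' @param genome_length Circular genome length used when lengths must be
#'   derived from breakpoints.
#' @return List with `mean`, `median`, `sd` (exact) and `mean_display`,
#'   `median_display`, `sd_display` (half-up integers), plus `n`.
#' @export
cohort_length_stats <- function(loci, genome_length = MT_GENOME_LENGTH) {
  if (NROW(loci) == 0) stop("no loci supplied", call. = FALSE)
  if (!is.null(loci$length)) {
    len <- as.numeric(loci$length)
  } else {
    len <- as.numeric(circular_fragment_length(loci$mt_start, loci$mt_end,
                                               genome_length))
  }
  if (length(len) < 2) stop("need >= 2 loci for a sample SD", call. = FALSE)
  out <- list(mean = mean(len), median = stats::median(len),
              sd = stats::sd(len), n = length(len))
  out$mean_display <- round_half_up(out$mean)
  out$median_display <- round_half_up(out$median)
  out$sd_display <- round_half_up(out$sd)
  out
}

#' Archaic/modern sharing summary for an archaic NUMT table
#'
#' Summarises a table of NUMT loci detected in archaic genomes: how many of
#' the loci are also observed in modern populations (any nonzero modern
#' carrier count), and the mean number of NUMTs per archaic genome, counting
#' (locus, genome) presence pairs and dividing by the number of genomes
#' analysed -- genomes in which no NUMT was found still count in the
#' denominator.
#'
#' @param archaic_genomes Character vector (one element per locus) listing
#'   carrying archaic genomes separated by `/`, or a list of character
#'   vectors.
#' @param modern_counts data.frame/matrix of per-population modern carrier
#'   counts, one row per locus.
#' @param n_genomes Total archaic genomes analysed (>= 1), including any with
#'   zero calls.
#' @return List with `n_shared_with_modern` and `mean_per_archaic_genome`.
#' @export
archaic_sharing_summary <- function(archaic_genomes, modern_counts, n_genomes) {
  if (n_genomes < 1) stop("n_genomes must be >= 1", call. = FALSE)
  if (is.character(archaic_genomes)) {
    archaic_genomes <- strsplit(archaic_genomes, "/", fixed = TRUE)
  }
  if (length(archaic_genomes) != NROW(modern_counts)) {
    stop("one archaic-genome entry per locus required", call. = FALSE)
  }
  cnt <- as.matrix(modern_counts)
  storage.mode(cnt) <- "numeric"
  shared <- sum(apply(cnt, 1, function(r) any(r > 0)))
  pairs <- sum(lengths(lapply(archaic_genomes, function(g) g[nzchar(trimws(g))])))
  list(n_shared_with_modern = as.integer(shared),
       mean_per_archaic_genome = pairs / n_genomes)
}
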