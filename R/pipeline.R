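# End-to-end pipeline over a synthetic cohort: detect -> merge -> overlap
# test -> PBS scan -> nuclear enrichment -> mtDNA hotspot -> consensus ->
# reading-frame classification.

#' Run the full NUMT analysis pipeline on a synthetic cohort
#'
#' Generates a cohort and its read evidence from `config`, calls NUMTs per
#' individual, merges them, and runs every downstream analysis stage.
#' All stage outputs are returned and, when `out_dir` is given, written as
#' TSV/JSON files; the summary is machine-readable and byte-reproducible for
#' a fixed config.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param n_perm_overlap Replicates for the segment-overlap permutation test
#'   (default 1000).
#' @param n_perm_enrich Replicates for the nuclear annotation enrichment
#'   test (default 500).
#' @param n_sim_hotspot Replicates for the mtDNA hotspot scan (default 500).
#' @param mode Detection mode, `"modern"` or `"archaic"`.
#' @return List of class `"numt_pipeline"`: `truth`, `calls`, `merged`,
#'   `overlap`, `pbs`, `jackknife`, `enrichment`, `hotspot`, `consensus`
#'   (per-locus representative sequences), `orf`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_perm_overlap = 1000,
                         n_perm_enrich = 500, n_sim_hotspot = 500,
                         mode = "modern") {
  truth <- generate_cohort(config)
  evidence <- generate_read_evidence(truth)

  calls <- do.call(rbind, lapply(split(evidence, evidence$individual_id),
                                 function(ev) {
    call_numts(ev[, setdiff(names(ev), "individual_id")],
               individual_id = ev$individual_id[1], mode = mode)
  }))
  if (is.null(calls)) calls <- empty_call_table()
  rownames(calls) <- NULL

  merged <- merge_cohort_calls(calls, truth$panel, truth$individuals)

  overlap <- permutation_overlap_test(calls, truth$segments,
                                      n_perm = n_perm_overlap,
                                      seed = config$seed + 10L,
                                      analysis_set = "all")

  # carrier-frequency proxy per population for the PBS scan
  freq_long <- do.call(rbind, lapply(seq_len(NROW(merged)), function(i) {
    data.frame(locus_id = merged$locus_id[i],
               population = truth$panel$name,
               continent = truth$panel$continent,
               p = pmin(1, vapply(truth$panel$name, function(p)
                 merged[[paste0("n_", p)]][i], numeric(1)) /
                 truth$panel$size),
               n = 2L * truth$panel$size, stringsAsFactors = FALSE)
  }))
  pbs_res <- pbs_scan(freq_long)
  jack <- NULL
  if (!is.null(pbs_res) && NROW(pbs_res) >= 3) {
    z <- zscore_outliers(pbs_res$pbs)
    pbs_res$z <- z$z
    pbs_res$outlier <- z$outlier
    jl <- merge(pbs_res[, c("locus_id", "pbs")],
                merged[, c("locus_id", "chrom", "start")], by = "locus_id")
    jack <- block_jackknife(jl, window = 500000)
  }

  enrich <- nuclear_permutation_test(
    merged, truth$segments[, c("chrom", "start", "end")], config$genome,
    n_perm = n_perm_enrich, seed = config$seed + 11L)

  hotspot <- mt_hotspot_permutation(merged, genome_length = config$mt_length,
                                    n_sim = n_sim_hotspot,
                                    seed = config$seed + 12L)

  mt_ref <- synthetic_mt_genome(config$seed + 13L,
                                mt_length = config$mt_length)
  piles <- generate_pileups(truth, mt_ref)
  consensus <- vapply(names(piles$pileups), function(lid) {
    pl <- piles$pileups[[lid]]
    if (!length(pl)) return(NA_character_)
    li <- match(lid, truth$loci$locus_id)
    cs <- vapply(pl, individual_consensus,
                 fragment_length = truth$loci$length[li], character(1))
    representative_sequence(cs)
  }, character(1))

  orf <- do.call(rbind, lapply(names(consensus)[!is.na(consensus)],
                               function(lid) {
    li <- match(lid, truth$loci$locus_id)
    res <- mito_orf_classify(consensus[[lid]], truth$loci$mt_start[li],
                             truth$loci$mt_end[li], mt_ref)
    cbind(locus_id = lid, res)
  }))

  summary <- list(
    seed = config$seed,
    n_individuals = NROW(truth$individuals),
    n_calls = NROW(calls),
    n_merged_loci = NROW(merged),
    overlap_r_mean = overlap$r_mean,
    overlap_p_label = overlap$p_label,
    overlap_p_bound = overlap$p_bound,
    max_pbs = if (!is.null(pbs_res)) max(pbs_res$pbs) else NA,
    n_pbs_outliers = if (!is.null(pbs_res) && "outlier" %in% names(pbs_res))
      sum(pbs_res$outlier) else 0L,
    enrichment_p = enrich$p_two_tailed,
    n_hotspots = NROW(hotspot$hotspots),
    n_intact_frames = if (!is.null(orf)) sum(orf$status == "intact") else 0L)

  out <- structure(list(truth = truth, calls = calls, merged = merged,
                        overlap = overlap, pbs = pbs_res, jackknife = jack,
                        enrichment = enrich, hotspot = hotspot,
                        consensus = consensus, orf = orf, summary = summary),
                   class = "numt_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calls(calls, file.path(out_dir, "calls.tsv"))
    write_merged(merged, file.path(out_dir, "merged.tsv"))
    if (!is.null(pbs_res)) {
      utils::write.table(pbs_res, file.path(out_dir, "pbs.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    utils::write.table(hotspot$windows, file.path(out_dir, "mt_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    seqs <- consensus[!is.na(consensus)]
    if (length(seqs)) write_fasta(seqs, file.path(out_dir, "consensus.fasta"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  out
}

#' @export
print.numt_pipeline <- function(x, ...) {
  cat("NUMT pipeline run\n")
  str(x$summary, give.attr = FALSE)
  invisible(x)
}
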