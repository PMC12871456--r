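# Readers and writers for the pipeline's file formats.
#
# Internal coordinates are 0-based half-open; every TSV rendered for human
# consumption (call and merged-locus tables) uses 1-based inclusive
# positions.  BED files are 0-based half-open by definition and pass through
# unchanged.

stop_at_line <- function(path, i, msg) {
  stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
}

#' Read a BED file
#'
#' @param path BED path (tab-separated, no header; track/browser lines are
#'   skipped).
#' @param extra_cols Names for columns beyond chrom/start/end (default
#'   `name`, `score`, `strand`, ... as many as present).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open) plus any
#'   extra columns.
#' @export
read_bed <- function(path, extra_cols = c("name", "score", "strand",
                                          "col7", "col8", "col9")) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  idx <- which(keep)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(rows)
  if (length(rows) && any(n_col < 3)) {
    stop_at_line(path, idx[which(n_col < 3)[1]], "BED line has < 3 fields")
  }
  out <- data.frame(
    chrom = vapply(rows, `[`, "", 1),
    start = suppressWarnings(as.integer(vapply(rows, `[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(rows, `[`, "", 3))),
    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) {
    stop_at_line(path, idx[which(is.na(out$start) | is.na(out$end))[1]],
                 "non-numeric BED coordinate")
  }
  if (any(out$end < out$start)) {
    stop_at_line(path, idx[which(out$end < out$start)[1]],
                 "BED interval with start > end")
  }
  extra_n <- max(0, max(c(n_col, 3L)) - 3L)
  for (k in seq_len(extra_n)) {
    out[[extra_cols[k]]] <- vapply(rows, function(r) {
      if (length(r) >= k + 3L) r[k + 3L] else NA_character_
    }, "")
  }
  out
}

#' Write a BED file
#'
#' @param df data.frame `chrom`, `start`, `end` (0-based half-open) plus
#'   optional extra columns written in order.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting a named character
#' vector.
#'
#' @param path FASTA path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unlist(sequences))
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write per-individual NUMT call tables
#'
#' TSV with header `individual_id`, `chrom`, `nu_start`, `nu_end`
#' (1-based inclusive), `mt_start`, `mt_end`, `n_discordant_pairs`,
#' `n_split_nuclear`, `n_split_mt`.
#'
#' @param path TSV path.
#' @return `read_calls`: internal call data.frame (0-based half-open).
#' @export
read_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "chrom", "nu_start", "nu_end", "mt_start",
            "mt_end", "n_discordant_pairs", "n_split_nuclear", "n_split_mt")
  if (!all(need %in% names(df))) {
    stop(path, ": missing call-table column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (any(df$nu_end < df$nu_start)) {
    stop(path, ": call with nu_end < nu_start", call. = FALSE)
  }
  data.frame(individual_id = df$individual_id, chrom = df$chrom,
             start = df$nu_start - 1L, end = df$nu_end,
             mt_start = df$mt_start, mt_end = df$mt_end,
             n_discordant_pairs = df$n_discordant_pairs,
             n_split_nuclear = df$n_split_nuclear,
             n_split_mt = df$n_split_mt, stringsAsFactors = FALSE)
}

#' @rdname read_calls
#' @param calls Internal call data.frame.
#' @export
write_calls <- function(calls, path) {
  out <- data.frame(individual_id = calls$individual_id, chrom = calls$chrom,
                    nu_start = calls$start + 1L, nu_end = calls$end,
                    mt_start = calls$mt_start, mt_end = calls$mt_end,
                    n_discordant_pairs = calls$n_discordant_pairs,
                    n_split_nuclear = calls$n_split_nuclear,
                    n_split_mt = calls$n_split_mt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write merged cohort NUMT tables
#'
#' TSV in the archaic-table layout: `locus_id`, `nu_chrom`, `nu_start`,
#' `nu_end` (1-based inclusive), `mt_start`, `mt_end`, `length`, one
#' `n_<population>` column per population, `carriers_total`, `freq_pct`,
#' `freq_class`.
#'
#' @param path TSV path.
#' @return `read_merged`: internal merged data.frame.
#' @export
read_merged <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("locus_id", "nu_chrom", "nu_start", "nu_end", "mt_start",
            "mt_end", "length")
  if (!all(need %in% names(df))) {
    stop(path, ": missing merged-table column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(locus_id = df$locus_id, chrom = df$nu_chrom,
                    start = df$nu_start - 1L, end = df$nu_end,
                    mt_start = df$mt_start, mt_end = df$mt_end,
                    length = df$length, stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), c(need, "freq_class"))) out[[nm]] <- df[[nm]]
  if ("freq_class" %in% names(df)) {
    out$freq_class <- factor(df$freq_class, levels = frequency_classes())
  }
  out
}

#' @rdname read_merged
#' @param merged Internal merged data.frame.
#' @export
write_merged <- function(merged, path) {
  out <- data.frame(locus_id = merged$locus_id, nu_chrom = merged$chrom,
                    nu_start = merged$start + 1L, nu_end = merged$end,
                    mt_start = merged$mt_start, mt_end = merged$mt_end,
                    length = merged$length, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (nm in setdiff(names(merged),
                     c("locus_id", "chrom", "start", "end", "mt_start",
                       "mt_end", "length"))) {
    out[[nm]] <- merged[[nm]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF-like phased genotype table
#'
#' TSV with header `CHROM`, `POS`, `REF`, `ALT` followed by one column per
#' sample holding GT strings (`"0|1"` phased, `"0/1"` unphased).
#'
#' @param path TSV path.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, plus sample columns.
#' @export
read_vcf_like <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  need <- c("CHROM", "POS", "REF", "ALT")
  if (!all(need %in% names(df))) {
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  names(df)[match(need, names(df))] <- c("chrom", "pos", "ref", "alt")
  df$pos <- as.integer(df$pos)
  df
}

#' Read a Sprime-style site table
#'
#' TSV with header `CHROM`, `POS`, `REF`, `ALT`, `ARCHAIC`, `SEGMENT`.
#'
#' @param path TSV path.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `archaic_allele`,
#'   `segment_id`.
#' @export
read_sprime <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("CHROM", "POS", "REF", "ALT", "ARCHAIC", "SEGMENT")
  if (!all(need %in% names(df))) {
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  data.frame(chrom = df$CHROM, pos = as.integer(df$POS), ref = df$REF,
             alt = df$ALT,
             archaic_allele = df$ARCHAIC, segment_id = df$SEGMENT,
             stringsAsFactors = FALSE)
}

#' Bundled archaic NUMT locus table
#'
#' Ten NUMT loci detected in four high-coverage archaic hominin genomes
#' (two Neanderthals with calls, one without, and one Denisovan), with
#' nuclear and mitochondrial breakpoints, fragment lengths, the carrying
#' genomes, and carrier counts in six modern population panels
#' (EUR 503, AFR 504, AMR 347, EAS 504, SAS 489, Papua 15 individuals).
#' Used by the worked examples and the reproduction script.
#'
#' @return data.frame with columns `nu_chrom`, `nu_start`, `nu_end`
#'   (1-based inclusive), `mt_start`, `mt_end`, `length`,
#'   `archaic_genomes` (slash-separated), and the six panel counts.
#' @export
archaic_numt_table <- function() {
  utils::read.delim(system.file("extdata", "archaic_numts.tsv",
                                package = "numtkit"),
                    stringsAsFactors = FALSE)
}

#' Bundled table of NUMTs overlapping Neanderthal introgressed segments
#'
#' Twenty-two NUMT loci whose carriers also carry an overlapping Neanderthal
#' introgressed segment, with per-population counts of such individuals.
#'
#' @return data.frame with columns `nu_chrom`, `nu_start`, `nu_end`,
#'   `mt_start`, `mt_end`, `in_archaic` (logical), `EUR`, `AFR`, `AMR`,
#'   `SAS`, `EAS`.
#' @export
neanderthal_overlap_table <- function() {
  utils::read.delim(system.file("extdata", "neanderthal_overlap_numts.tsv",
                                package = "numtkit"),
                    stringsAsFactors = FALSE)
}

#' Panel sizes accompanying [archaic_numt_table()]
#'
#' @return A [population_panel()] of the six modern panels.
#' @export
archaic_numt_panel <- function() {
  population_panel(
    name = c("EUR", "AFR", "AMR", "EAS", "SAS", "Papua"),
    continent = c("Europe", "Africa", "America", "EastAsia", "SouthAsia",
                  "Oceania"),
    size = c(503L, 504L, 347L, 504L, 489L, 15L))
}
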