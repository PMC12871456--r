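# Mitochondrial genome container and reading-frame classification of NUMT
# sequences under the vertebrate mitochondrial genetic code.

#' Construct a circular mitochondrial genome object
#'
#' @param sequence Character scalar (A/C/G/T) of the circular reference
#'   sequence.
#' @param cds data.frame `gene`, `start`, `end`, `strand` (1-based inclusive
#'   coordinates; `strand` `"+"` or `"-"`) for the protein-coding genes.
#' @param hypervariable data.frame `name`, `start`, `end` of hypervariable
#'   control-region intervals (default [hypervariable_default()]).
#' @return List of class `"mt_genome"`: `sequence`, `length`, `cds`,
#'   `hypervariable`.
#' @export
mt_genome <- function(sequence, cds, hypervariable = hypervariable_default()) {
  L <- nchar(sequence)
  if (any(cds$start < 1 | cds$end > L | cds$start > cds$end)) {
    stop("CDS annotation outside [1, genome length]", call. = FALSE)
  }
  if (NROW(cds) != 13) {
    warning("expected the 13 mitochondrial protein-coding genes; got ",
            NROW(cds))
  }
  structure(list(sequence = toupper(sequence), length = L, cds = cds,
                 hypervariable = hypervariable),
            class = "mt_genome")
}

#' Canonical human mitochondrial protein-coding gene coordinates
#'
#' rCRS coordinates (1-based inclusive) of the 13 protein-coding genes; ND6
#' is the single light-strand gene.
#'
#' @return data.frame `gene`, `start`, `end`, `strand`.
#' @export
mt_cds_default <- function() {
  data.frame(
    gene = c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3", "ND3",
             "ND4L", "ND4", "ND5", "ND6", "CYTB"),
    start = c(3307L, 4470L, 5904L, 7586L, 8366L, 8527L, 9207L, 10059L,
              10470L, 10760L, 12337L, 14149L, 14747L),
    end = c(4262L, 5511L, 7445L, 8269L, 8572L, 9207L, 9990L, 10404L,
            10766L, 12137L, 14148L, 14673L, 15887L),
    strand = c(rep("+", 11), "-", "+"),
    stringsAsFactors = FALSE)
}

# vertebrate mitochondrial code (NCBI translation table 2)
mito_code <- function() Biostrings::getGeneticCode("2")

translate_codons <- function(codons) {
  code <- mito_code()
  aa <- code[codons]
  aa[is.na(aa)] <- "X"  # codons containing N or gaps
  unname(aa)
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
  rev(unname(comp[x]))
}

#' Classify mitochondrial reading-frame integrity of a NUMT sequence
#'
#' Aligns a NUMT-derived mtDNA fragment to each overlapping protein-coding
#' gene by coordinate, trims the overlap to complete codons of the gene's
#' reading frame (incomplete terminal codons are dropped), and classifies:
#' the frame is intact when the compared length is a positive multiple of
#' three, no internal gap breaks the codon structure (a codon that is
#' entirely `-` counts as an in-frame codon deletion; a partial-codon gap is
#' a frameshift), and translation under the vertebrate mitochondrial code
#' yields no premature stop codon.  For intact frames, every codon that
#' differs from the reference is classified by its translated amino acid:
#' unchanged amino acid adds the codon's nucleotide differences to the
#' synonymous count, a changed amino acid adds them to the nonsynonymous
#' count.  Codons containing `N` are excluded from comparison.
#'
#' @param numt_seq Character scalar over `{A,C,G,T,N,-}` covering the
#'   fragment `mt_start` -> `mt_end` (length must equal the circular
#'   fragment length).
#' @param mt_start,mt_end Fragment breakpoints (1-based circular).
#' @param genome An [mt_genome()] object.
#' @return data.frame with one row per overlapping CDS (`gene`, `status`
#'   in `intact`/`not-intact`, `reason`, `n_codons`, `n_diff_nt`, `syn`,
#'   `nonsyn`), or a single row with `status = "not-applicable"` when the
#'   fragment overlaps no protein-coding gene.
#' @export
mito_orf_classify <- function(numt_seq, mt_start, mt_end, genome) {
  stopifnot(inherits(genome, "mt_genome"))
  L <- genome$length
  fp <- circular_positions(mt_start, mt_end, L)
  fs <- toupper(strsplit(numt_seq, "")[[1]])
  if (length(fs) != length(fp)) {
    stop("sequence length does not match the circular fragment length",
         call. = FALSE)
  }
  ref <- strsplit(genome$sequence, "")[[1]]
  rows <- list()
  for (i in seq_len(NROW(genome$cds))) {
    cds <- genome$cds[i, ]
    g_pos <- if (cds$strand == "+") cds$start:cds$end else cds$end:cds$start
    idx <- match(g_pos, fp)
    if (!any(!is.na(idx))) next
    rows[[length(rows) + 1L]] <-
      classify_one_cds(cds, g_pos, idx, fs, ref)
  }
  if (!length(rows)) {
    return(data.frame(gene = NA_character_, status = "not-applicable",
                      reason = "fragment overlaps no protein-coding gene",
                      n_codons = 0L, n_diff_nt = 0L, syn = 0L, nonsyn = 0L,
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

classify_one_cds <- function(cds, g_pos, idx, fs, ref) {
  res <- function(status, reason, n_codons = 0L, n_diff = 0L,
                  syn = 0L, nonsyn = 0L) {
    data.frame(gene = cds$gene, status = status, reason = reason,
               n_codons = n_codons, n_diff_nt = n_diff, syn = syn,
               nonsyn = nonsyn, stringsAsFactors = FALSE)
  }
  covered <- !is.na(idx)
  # coding-space positions 1..len; require one contiguous aligned block
  r <- rle(covered)
  if (sum(r$values) > 1) {
    blocks <- which(r$values)
    lens <- r$lengths[blocks]
    keep_block <- blocks[which.max(lens)]
    ends <- cumsum(r$lengths)
    sel <- (ends[keep_block] - r$lengths[keep_block] + 1L):ends[keep_block]
    covered <- rep(FALSE, length(covered))
    covered[sel] <- TRUE
  }
  ci <- (seq_along(g_pos) - 1L) %/% 3L
  full <- covered & stats::ave(covered, ci, FUN = all)
  if (!any(full)) {
    return(res("not-intact", "aligned length shorter than one codon"))
  }
  # query bases in coding orientation
  qb <- rep(NA_character_, length(g_pos))
  qb[covered] <- fs[idx[covered]]
  if (cds$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")
    qb <- unname(comp[qb])
  }
  codons <- sort(unique(ci[full]))
  q_cod <- vapply(codons, function(k) paste(qb[ci == k], collapse = ""),
                  character(1))
  r_cod <- vapply(codons, function(k) {
    b <- ref[g_pos[ci == k]]
    if (cds$strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      b <- unname(comp[b])
    }
    paste(b, collapse = "")
  }, character(1))

  has_gap <- grepl("-", q_cod, fixed = TRUE)
  full_del <- q_cod == "---"
  if (any(has_gap & !full_del)) {
    return(res("not-intact", "internal gap inconsistent with codon structure"))
  }
  keep <- !full_del & !grepl("N", q_cod, fixed = TRUE)
  if (!any(keep)) {
    return(res("not-intact", "no comparable codon after gap/N exclusion"))
  }
  q_aa <- translate_codons(q_cod[keep])
  r_aa <- translate_codons(r_cod[keep])
  last_cds_codon <- (length(g_pos) - 1L) %/% 3L
  premature <- q_aa == "*" & codons[keep] != last_cds_codon
  if (any(premature)) {
    return(res("not-intact", "premature stop codon"))
  }
  diff_nt <- mapply(function(q, r) {
    sum(strsplit(q, "")[[1]] != strsplit(r, "")[[1]])
  }, q_cod[keep], r_cod[keep])
  changed <- diff_nt > 0
  syn <- sum(diff_nt[changed & q_aa == r_aa])
  nonsyn <- sum(diff_nt[changed & q_aa != r_aa])
  res("intact", "", n_codons = sum(keep), n_diff = sum(diff_nt),
      syn = as.integer(syn), nonsyn = as.integer(nonsyn))
}
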