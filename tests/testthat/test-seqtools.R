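# Consensus construction, pairwise identity, and reading-frame
# classification.

pile <- function(bases, quals = 30, pos = 1L) {
  data.frame(pos = pos, base = bases, qual = rep_len(quals, length(bases)),
             stringsAsFactors = FALSE)
}

test_that("consensus base-calling follows quality/depth/majority rules", {
  expect_identical(individual_consensus(pile(rep("A", 5)), 1L), "A")
  # fewer than three reads -> N
  expect_identical(individual_consensus(pile(rep("A", 2)), 1L), "N")
  # 7 A / 3 G: major fraction 0.70 < 0.75 -> N
  expect_identical(individual_consensus(pile(c(rep("A", 7), rep("G", 3))),
                                        1L), "N")
  # exactly 0.75 is callable
  expect_identical(individual_consensus(pile(c(rep("A", 9), rep("G", 3))),
                                        1L), "A")
  # quality below 10 is discarded; exactly 10 is kept
  expect_identical(individual_consensus(pile(rep("A", 5), quals = 9), 1L),
                   "N")
  expect_identical(individual_consensus(pile(rep("A", 3), quals = 10), 1L),
                   "A")
  # uncovered positions and empty pileups are N
  expect_identical(individual_consensus(pile(rep("C", 4)), 3L), "CNN")
  empty <- data.frame(pos = integer(0), base = character(0),
                      qual = numeric(0))
  expect_identical(individual_consensus(empty, 2L), "NN")
})

test_that("single-allele consensus is monotone in both thresholds", {
  set.seed(41)
  for (i in 1:20) {
    depth <- sample(1:6, 1)
    quals <- sample(5:40, depth, replace = TRUE)
    p <- pile(rep("T", depth), quals = quals)
    lo <- individual_consensus(p, 1L, min_qual = 10)
    hi <- individual_consensus(p, 1L, min_qual = 25)
    if (lo == "N") expect_identical(hi, "N")
    d_hi <- individual_consensus(p, 1L, min_depth = 5)
    if (lo == "N") expect_identical(d_hi, "N")
  }
})

test_that("representative sequence takes the majority non-N allele", {
  expect_identical(representative_sequence(c("A", "A", "G")), "A")
  expect_identical(representative_sequence(c("A", "N", "N")), "A")
  expect_identical(representative_sequence(c("A", "A", "G", "G")), "A")
  expect_identical(representative_sequence(c("N", "N")), "N")
  expect_identical(representative_sequence(c("ACG", "ANG", "GCG")), "ACG")
  expect_error(representative_sequence(c("AC", "A")), "length")
})

test_that("pairwise identity excludes N and masked columns, symmetric", {
  seqs <- c(s1 = paste(rep("A", 1000), collapse = ""),
            s2 = paste(c(rep("A", 999), "G"), collapse = ""))
  r <- pairwise_identity(seqs)
  expect_equal(r$matrix["s1", "s2"], 0.999)
  expect_equal(r$matrix["s2", "s1"], 0.999)
  expect_equal(pairwise_identity(c(a = "ACGT", b = "ACGT"))$mean, 1)
  # N columns drop out of the denominator
  r <- pairwise_identity(c(a = "ANGT", b = "ATGT"))
  expect_equal(r$mean, 1)
  # mismatches confined to the mask: masked identity 1, unmasked below 1
  s <- c(a = "AAAACCCC", b = "AAAAGGGG")
  expect_lt(pairwise_identity(s)$mean, 1)
  expect_equal(pairwise_identity(s, mask = 5:8)$mean, 1)
  expect_gte(pairwise_identity(s, mask = 5:8)$mean,
             pairwise_identity(s)$mean)
})

test_that("hypervariable mask maps mtDNA intervals into fragment columns", {
  # fragment wrapping the origin: 16,000 -> 300 covers HVS-I tail and HVS-II
  m <- hypervariable_mask(16000, 300)
  pos <- circular_positions(16000, 300)
  expect_true(all(pos[m] >= 16024 | pos[m] <= 372))
  expect_true(25 %in% m)          # position 16,024 is the 25th column
  expect_false(1 %in% m)          # position 16,000 is not hypervariable
})

# -- reading-frame classification ------------------------------------------

genome <- synthetic_mt_genome(97)
ref <- strsplit(genome$sequence, "")[[1]]
nd1 <- genome$cds[genome$cds$gene == "ND1", ]
# fragment of 30 complete ND1 codons, starting at codon 11
frag_s <- nd1$start + 10L * 3L
frag_e <- frag_s + 90L
frag_ref <- paste(ref[frag_s:(frag_e - 1L)], collapse = "")
codon_of <- function(k) substr(frag_ref, 3 * k - 2, 3 * k)  # k in 1..30
fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

test_that("a reference-identical in-frame fragment is intact with (0, 0)", {
  r <- mito_orf_classify(frag_ref, frag_s, frag_e, genome)
  expect_identical(r$status, "intact")
  expect_identical(r$gene, "ND1")
  expect_identical(c(r$syn, r$nonsyn), c(0L, 0L))
  expect_identical(r$n_codons, 30L)
})

test_that("third-position change in a fourfold codon is synonymous", {
  k <- which(vapply(1:30, function(k)
    substr(codon_of(k), 1, 2) %in% fourfold, logical(1)))[1]
  expect_false(is.na(k))  # 30 random codons essentially always include one
  cod <- codon_of(k)
  alt <- setdiff(c("A", "C", "G", "T"), substr(cod, 3, 3))[1]
  q <- frag_ref
  substr(q, 3 * k, 3 * k) <- alt
  r <- mito_orf_classify(q, frag_s, frag_e, genome)
  expect_identical(r$status, "intact")
  expect_identical(c(r$syn, r$nonsyn), c(1L, 0L))
})

test_that("first-position Ala->Thr change is nonsynonymous", {
  k <- which(vapply(1:30, function(k)
    substr(codon_of(k), 1, 2) == "GC", logical(1)))[1]
  expect_false(is.na(k))
  q <- frag_ref
  substr(q, 3 * k - 2, 3 * k - 2) <- "A"   # GCx -> ACx, never a stop
  r <- mito_orf_classify(q, frag_s, frag_e, genome)
  expect_identical(r$status, "intact")
  expect_identical(c(r$syn, r$nonsyn), c(0L, 1L))
  expect_identical(r$n_diff_nt, 1L)
})

test_that("syn + nonsyn equals differing nucleotides; AAs check out", {
  ks <- which(vapply(1:30, function(k)
    substr(codon_of(k), 1, 2) %in% fourfold, logical(1)))[1:2]
  expect_false(anyNA(ks))
  q <- frag_ref
  for (k in ks) {
    alt <- setdiff(c("A", "C", "G", "T"), substr(q, 3 * k, 3 * k))[1]
    substr(q, 3 * k, 3 * k) <- alt
  }
  kn <- which(vapply(1:30, function(k)
    substr(codon_of(k), 1, 2) == "GC", logical(1)))
  kn <- setdiff(kn, ks)[1]
  expect_false(is.na(kn))
  substr(q, 3 * kn - 2, 3 * kn - 2) <- "A"
  r <- mito_orf_classify(q, frag_s, frag_e, genome)
  expect_identical(r$status, "intact")
  expect_identical(r$syn + r$nonsyn, r$n_diff_nt)
  # independent translation check via Biostrings on both sequences
  aa_q <- as.character(Biostrings::translate(
    Biostrings::DNAString(q), genetic.code = Biostrings::getGeneticCode("2")))
  aa_r <- as.character(Biostrings::translate(
    Biostrings::DNAString(frag_ref),
    genetic.code = Biostrings::getGeneticCode("2")))
  n_aa_diff <- sum(strsplit(aa_q, "")[[1]] != strsplit(aa_r, "")[[1]])
  expect_identical(n_aa_diff, 1L)  # only the Ala->Thr codon changes the AA
})

test_that("gaps and premature stops break the frame", {
  # 1-bp internal gap -> frameshift
  q <- frag_ref
  substr(q, 10, 10) <- "-"
  r <- mito_orf_classify(q, frag_s, frag_e, genome)
  expect_identical(r$status, "not-intact")
  expect_match(r$reason, "gap")
  # a whole-codon gap is an in-frame deletion: frame survives
  q <- frag_ref
  substr(q, 4, 6) <- "---"
  r <- mito_orf_classify(q, frag_s, frag_e, genome)
  expect_identical(r$status, "intact")
  expect_identical(r$n_codons, 29L)
  # planted TAA mid-fragment -> premature stop
  q <- frag_ref
  substr(q, 31, 33) <- "TAA"
  r <- mito_orf_classify(q, frag_s, frag_e, genome)
  expect_identical(r$status, "not-intact")
  expect_match(r$reason, "stop")
})

test_that("fragments outside every CDS are not applicable", {
  r <- mito_orf_classify(paste(ref[100:199], collapse = ""), 100, 200,
                         genome)
  expect_identical(r$status, "not-applicable")
})

test_that("incomplete terminal codons are trimmed, not padded", {
  # shift the fragment by one base: first/last partial codons drop
  q <- paste(ref[(frag_s + 1L):frag_e], collapse = "")
  r <- mito_orf_classify(q, frag_s + 1L, frag_e + 1L, genome)
  expect_identical(r$status, "intact")
  expect_identical(r$n_codons, 29L)
})
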