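# Synthetic-data generators: determinism, planted truth, analytic checks.

test_that("the same seed reproduces the cohort and its evidence exactly", {
  cfg <- sim_config(seed = 50, theta = 0.5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$loci, b$loci)
  expect_identical(a$carriers, b$carriers)
  expect_identical(a$segments, b$segments)
  expect_identical(generate_read_evidence(a), generate_read_evidence(b))
  sp_a <- generate_sprime_output(a)
  expect_identical(sp_a, generate_sprime_output(b))
})

test_that("theta = 1 embeds every carried NUMT in a carrier tract", {
  cfg <- sim_config(seed = 51, theta = 1, background_tracts = 0)
  tr <- generate_cohort(cfg)
  expect_gt(nrow(tr$carriers), 0)
  for (k in seq_len(nrow(tr$carriers))) {
    li <- match(tr$carriers$locus_id[k], tr$loci$locus_id)
    segs <- tr$segments[
      tr$segments$individual_id == tr$carriers$individual_id[k] &
        tr$segments$haplotype == tr$carriers$haplotype[k] &
        tr$segments$chrom == tr$loci$chrom[li], , drop = FALSE]
    covered <- any(segs$start <= tr$loci$start[li] &
                     segs$end >= tr$loci$end[li])
    expect_true(covered)
  }
})

test_that("theta = 0 overlap matches the random-coverage expectation", {
  cfg <- sim_config(seed = 52, theta = 0, background_tracts = 4,
                    tract_length_range = c(50000L, 100000L),
                    populations = data.frame(name = "P1", continent = "C1",
                                             size = 150L),
                    n_loci = 10, locus_freq = matrix(0.4, 10, 1))
  tr <- generate_cohort(cfg)
  calls <- data.frame(individual_id = tr$carriers$individual_id,
                      tr$loci[match(tr$carriers$locus_id, tr$loci$locus_id),
                              c("chrom", "start", "end")])
  rates <- vapply(unique(calls$individual_id), function(i)
    overlap_rate(calls[calls$individual_id == i, ],
                 tr$segments[tr$segments$individual_id == i, ]), numeric(1))
  n_numts <- nrow(calls)
  obs <- sum(rates * table(calls$individual_id)[unique(calls$individual_id)])
  # analytic expectation: P(point in >= 1 of N ~ Pois(4) uniform tracts)
  q <- mean(c(50000, 100000)) / sum(cfg$genome$length)
  expected <- (1 - exp(-4 * q)) * n_numts
  expect_lt(abs(obs - expected), 4 * sqrt(expected) + 2)
})

test_that("empirical carrier frequencies converge to the configuration", {
  f <- matrix(c(0.1, 0.4, 0.25), 3, 1)
  cfg <- sim_config(seed = 53, n_loci = 3,
                    populations = data.frame(name = "P1", continent = "C1",
                                             size = 400L),
                    locus_freq = f, background_tracts = 0)
  tr <- generate_cohort(cfg)
  emp <- table(factor(tr$carriers$locus_id,
                      levels = tr$loci$locus_id)) / 400
  se <- sqrt(f[, 1] * (1 - f[, 1]) / 400)
  z <- abs(as.numeric(emp) - f[, 1]) / se
  # simultaneous binomial draws: allow one marginal ~3-SE fluctuation
  expect_lte(sum(z > 3), 1)
  expect_true(all(z <= 4))
})

test_that("planted evidence respects its own guarantees", {
  cfg <- sim_config(seed = 54, noise_pair_rate = 0, noise_mapq0_rate = 0)
  tr <- generate_cohort(cfg)
  ev <- generate_read_evidence(tr)
  pr <- ev[ev$kind == "pair", ]
  key <- paste(pr$individual_id, pr$chrom)
  for (k in seq_len(nrow(tr$carriers))) {
    li <- match(tr$carriers$locus_id[k], tr$loci$locus_id)
    bp <- tr$loci$start[li] + 1L
    own <- pr[pr$individual_id == tr$carriers$individual_id[k] &
                pr$chrom == tr$loci$chrom[li] &
                abs(pr$pos - bp) <= 500, , drop = FALSE]
    expect_gte(nrow(own), 2L)
  }
})

test_that("zero-error pileups reproduce the planted sequence; depth 2 is N", {
  g <- synthetic_mt_genome(5)
  cfg <- sim_config(seed = 55, error_rate = 0, depth = 30, n_loci = 3,
                    populations = data.frame(name = "P1", continent = "C1",
                                             size = 6L),
                    locus_freq = matrix(0.9, 3, 1))
  tr <- generate_cohort(cfg)
  pl <- generate_pileups(tr, g)
  for (lid in names(pl$pileups)) {
    li <- match(lid, tr$loci$locus_id)
    for (p in pl$pileups[[lid]]) {
      cons <- individual_consensus(p, tr$loci$length[li])
      expect_identical(cons, pl$planted[[lid]])
    }
  }
  # planted sequences carry the configured substitutions vs the reference
  refseq <- strsplit(g$sequence, "")[[1]]
  for (lid in names(pl$planted)) {
    li <- match(lid, tr$loci$locus_id)
    frag <- refseq[circular_positions(tr$loci$mt_start[li],
                                      tr$loci$mt_end[li], g$length)]
    expect_identical(sum(strsplit(pl$planted[[lid]], "")[[1]] != frag), 2L)
  }

  cfg2 <- sim_config(seed = 56, depth = 2, qual_sd = 0, n_loci = 1,
                     populations = data.frame(name = "P1", continent = "C1",
                                              size = 2L),
                     locus_freq = matrix(1, 1, 1))
  tr2 <- generate_cohort(cfg2)
  pl2 <- generate_pileups(tr2, g)
  cons <- individual_consensus(pl2$pileups[[1]][[1]], tr2$loci$length[1])
  # Poisson(2) depth: the large majority of positions fall below 3 reads
  expect_gt(mean(strsplit(cons, "")[[1]] == "N"), 0.6)
})

test_that("low error rate keeps consensus mismatches rare", {
  g <- synthetic_mt_genome(6)
  cfg <- sim_config(seed = 57, error_rate = 0.01, depth = 30, n_loci = 4,
                    numt_length_range = c(400L, 600L),
                    populations = data.frame(name = "P1", continent = "C1",
                                             size = 8L),
                    locus_freq = matrix(0.8, 4, 1))
  tr <- generate_cohort(cfg)
  pl <- generate_pileups(tr, g)
  total <- 0L; mismatch <- 0L
  for (lid in names(pl$pileups)) {
    li <- match(lid, tr$loci$locus_id)
    for (p in pl$pileups[[lid]]) {
      cons <- strsplit(individual_consensus(p, tr$loci$length[li]), "")[[1]]
      truth <- strsplit(pl$planted[[lid]], "")[[1]]
      ok <- cons != "N"
      total <- total + sum(ok)
      mismatch <- mismatch + sum(cons[ok] != truth[ok])
    }
  }
  expect_gt(total, 1000)
  expect_lt(mismatch / total, 0.001)
})

test_that("sprime output round-trips and non-carriers yield nothing", {
  cfg <- sim_config(seed = 58, theta = 1, background_tracts = 1)
  tr <- generate_cohort(cfg)
  sp <- generate_sprime_output(tr)
  rec <- reconstruct_individual_segments(sp$sites, sp$genotypes)
  a <- tr$segments[order(tr$segments$individual_id, tr$segments$chrom,
                         tr$segments$start),
                   c("individual_id", "haplotype", "chrom", "start", "end")]
  b <- rec[order(rec$individual_id, rec$chrom, rec$start),
           c("individual_id", "haplotype", "chrom", "start", "end")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  no_seg <- setdiff(tr$individuals$individual_id,
                    tr$segments$individual_id)
  expect_true(all(!rec$individual_id %in% no_seg))
})
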