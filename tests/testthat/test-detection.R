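# Per-individual NUMT calling from abstracted evidence.

pair_rec <- function(pos, strand = "+", mapq = 40, chrom = "chr1",
                     mt_pos = 5000L) {
  data.frame(read_id = sprintf("p%04d", seq_along(pos)), kind = "pair",
             side = NA_character_, chrom = chrom, pos = as.integer(pos),
             anchor_pos = as.integer(pos), strand = strand,
             mt_pos = as.integer(mt_pos), mapq = mapq,
             stringsAsFactors = FALSE)
}

split_rec <- function(pos, side, anchor, mapq = 40, chrom = "chr1") {
  data.frame(read_id = sprintf("s%04d", seq_along(pos)), kind = "split",
             side = side, chrom = chrom, pos = as.integer(pos),
             anchor_pos = as.integer(anchor), strand = "+",
             mt_pos = NA_integer_, mapq = mapq, stringsAsFactors = FALSE)
}

test_that("MAPQ-zero records are excluded, boundary MAPQ 1 kept", {
  ev <- pair_rec(c(100, 200, 300), mapq = c(0, 1, 40))
  kept <- filter_evidence(ev)
  expect_identical(nrow(kept), 2L)
  expect_true(all(kept$mapq > 0))
  expect_identical(nrow(filter_evidence(ev)), sum(ev$mapq > 0))
})

test_that("pair clustering follows the 500-bp single-linkage rule", {
  # two pairs 400 bp apart, same orientation -> one cluster
  cl <- cluster_discordant_pairs(pair_rec(c(1000, 1400)))
  expect_identical(unique(cl$cluster_id), 1L)
  # a lone pair never forms a cluster
  cl <- cluster_discordant_pairs(pair_rec(5000))
  expect_true(all(is.na(cl$cluster_id)))
  # 0 / 400 / 900: chained by single linkage into one cluster of 3
  cl <- cluster_discordant_pairs(pair_rec(c(1, 401, 901)))
  expect_identical(cl$cluster_id, rep(1L, 3))
  # 501-bp gap breaks the chain
  cl <- cluster_discordant_pairs(pair_rec(c(1000, 1400, 2000, 2400)))
  expect_identical(unique(cl$cluster_id[cl$pos <= 1400]), 1L)
  expect_identical(unique(cl$cluster_id[cl$pos >= 2000]), 2L)
  # opposite orientation never co-clusters
  ev <- rbind(pair_rec(c(1000, 1100)), pair_rec(c(1050, 1150), strand = "-"))
  cl <- cluster_discordant_pairs(ev)
  expect_identical(length(unique(cl$cluster_id)), 2L)
})

test_that("clustering partitions its input", {
  set.seed(5)
  ev <- pair_rec(sort(sample.int(50000, 200, replace = TRUE)))
  cl <- cluster_discordant_pairs(ev)
  expect_identical(nrow(cl), nrow(ev))
  expect_setequal(cl$read_id, ev$read_id)
  expect_false(anyDuplicated(cl$read_id) > 0)
  # every retained cluster has >= 2 members; each member in exactly one
  tab <- table(cl$cluster_id[!is.na(cl$cluster_id)])
  expect_true(all(tab >= 2))
})

test_that("breakpoint resolution enforces mode-specific split support", {
  pairs <- cluster_discordant_pairs(pair_rec(c(1000, 1100),
                                             mt_pos = c(5100, 5400)))
  sp3 <- rbind(split_rec(1150, "nuclear", 1150),
               split_rec(c(5000, 5000, 5500), "mt", 1150))
  call <- resolve_breakpoints(pairs, sp3, mode = "modern")
  expect_identical(call$start + 1L, 1150L)
  expect_identical(sort(c(call$mt_start, call$mt_end)), c(5000L, 5500L))
  # interior evidence at 5100/5400 orients the fragment as 5000 -> 5500
  expect_identical(c(call$mt_start, call$mt_end), c(5000L, 5500L))

  # one nuclear + one mt split is not enough in modern mode
  sp2 <- rbind(split_rec(1150, "nuclear", 1150), split_rec(5000, "mt", 1150))
  expect_null(resolve_breakpoints(pairs, sp2, mode = "modern"))
  # ... but archaic mode emits a call with one split per breakpoint
  sp_arch <- rbind(split_rec(1150, "nuclear", 1150),
                   split_rec(c(5000, 5500), "mt", 1150))
  call <- resolve_breakpoints(pairs, sp_arch, mode = "archaic")
  expect_identical(call$start + 1L, 1150L)
  expect_identical(c(call$mt_start, call$mt_end), c(5000L, 5500L))
  # archaic mode with no split read at all still returns nothing
  expect_null(resolve_breakpoints(pairs, sp_arch[0, ], mode = "archaic"))
})

test_that("modal breakpoints break ties toward the smaller coordinate", {
  pairs <- cluster_discordant_pairs(pair_rec(c(1000, 1100),
                                             mt_pos = c(5100, 5400)))
  sp <- rbind(split_rec(c(1150, 1150, 1152, 1152), "nuclear", 1150),
              split_rec(c(5000, 5000, 5500, 5500), "mt", 1150))
  call <- resolve_breakpoints(pairs, sp, mode = "modern")
  expect_identical(call$start + 1L, 1150L)
})

test_that("coverage filter excludes only strictly above 200x", {
  calls <- data.frame(individual_id = "i1", chrom = "chr1",
                      start = c(10L, 20L, 30L), end = c(11L, 21L, 31L),
                      mt_start = 1L, mt_end = 100L,
                      n_discordant_pairs = 2L, n_split_nuclear = 1L,
                      n_split_mt = 2L)
  cov <- c(250, 200, 30)
  lookup <- function(chrom, s, e) cov[match(s, calls$start)]
  kept <- coverage_filter(calls, lookup)
  expect_identical(kept$start, c(20L, 30L))
  # missing coverage drops with a warning by default
  lookup_na <- function(chrom, s, e) NA_real_
  expect_warning(kept <- coverage_filter(calls, lookup_na), "missing")
  expect_identical(nrow(kept), 0L)
  # reference-NUMT mask removes overlapping calls
  mask <- data.frame(chrom = "chr1", start = 25L, end = 35L)
  kept <- coverage_filter(calls, NULL, ref_numt_mask = mask)
  expect_identical(kept$start, c(10L, 20L))
})

test_that("zero-noise evidence yields exact planted breakpoints", {
  cfg <- sim_config(seed = 21, n_loci = 6, noise_pair_rate = 0,
                    noise_mapq0_rate = 0, error_rate = 0,
                    locus_freq = matrix(0.4, 6, 3))
  tr <- generate_cohort(cfg)
  ev <- generate_read_evidence(tr)
  calls <- do.call(rbind, lapply(split(ev, ev$individual_id), function(e)
    call_numts(e, individual_id = e$individual_id[1])))
  expect_gt(nrow(calls), 0)
  key_call <- paste(calls$chrom, calls$start, calls$mt_start, calls$mt_end)
  key_true <- paste(tr$loci$chrom, tr$loci$start, tr$loci$mt_start,
                    tr$loci$mt_end)
  expect_true(all(key_call %in% key_true))
  # every planted locus with >= 1 carrier recovered
  carried <- unique(tr$carriers$locus_id)
  expect_setequal(unique(key_call),
                  key_true[match(carried, tr$loci$locus_id)])
})

test_that("archaic profile: archaic mode recovers at least what modern does", {
  extra_modern <- 0L; extra_archaic <- 0L
  for (seed in 1:8) {
    cfg <- sim_config(seed = seed, n_loci = 6, archaic_profile = TRUE,
                      locus_freq = matrix(0.5, 6, 3),
                      noise_pair_rate = 0, noise_mapq0_rate = 0)
    tr <- generate_cohort(cfg)
    ev <- generate_read_evidence(tr)
    for (ind in unique(ev$individual_id)) {
      e <- ev[ev$individual_id == ind, ]
      n_mod <- nrow(call_numts(e, ind, mode = "modern"))
      n_arc <- nrow(call_numts(e, ind, mode = "archaic"))
      expect_gte(n_arc, n_mod)
      extra_archaic <- extra_archaic + (n_arc - n_mod)
    }
  }
  # thinned split support makes the relaxed mode strictly more sensitive
  expect_gt(extra_archaic, 0)
})
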