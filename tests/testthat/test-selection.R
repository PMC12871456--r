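# PBS scan components.

test_that("Hudson F_ST matches the direct formula and clamps correctly", {
  # direct textbook computation, written out independently
  p1 <- 0.8; p2 <- 0.2; n1 <- 100; n2 <- 100
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(hudson_fst(p1, n1, p2, n2), num / den)
  expect_equal(hudson_fst(0.5, 1000, 0.5, 1000), 0)  # clamped negative
  expect_equal(hudson_fst(1, 100, 0, 100), 1 - 1e-9)  # fixed difference cap
  expect_error(hudson_fst(0.5, 1, 0.5, 100), "sample sizes")
})

test_that("PBS closed forms and the branch-length identity hold", {
  expect_equal(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.5, 0.5, 0), log(2))
  set.seed(13)
  for (i in 1:50) {
    f <- runif(3, 0, 0.95)
    t_ab <- -log(1 - f[1])
    pbs_a <- pbs(f[1], f[2], f[3])
    pbs_b <- pbs(f[1], f[3], f[2])
    expect_lt(abs(pbs_a + pbs_b - t_ab), 1e-12)
  }
  expect_warning(pbs(1, 0.5, 0), "capped")
})

test_that("PBS is monotone in the focal branches", {
  grid <- seq(0.05, 0.9, by = 0.05)
  base <- pbs(grid, 0.3, 0.3)
  expect_true(all(diff(base) > 0))                 # increasing in fst_ab
  expect_true(all(diff(pbs(0.3, grid, 0.3)) > 0))  # increasing in fst_ac
  expect_true(all(diff(pbs(0.3, 0.3, grid)) < 0))  # decreasing in fst_bc
})

test_that("triplet scan picks the max-frequency focal and obeys the Papuan rule", {
  freqs <- data.frame(population = c("X", "Y", "Z"),
                      continent = c("ContA", "ContA", "ContB"),
                      p = c(0.6, 0.1, 0.1), n = c(100, 100, 100))
  r <- triplet_scan(freqs)
  expect_identical(r$focal, "X")
  expect_identical(r$sister, "Y")
  expect_identical(r$outgroup, "Z")
  expect_gt(r$pbs, 0)

  pap <- data.frame(population = c("Papuan", "CHB", "CEU"),
                    continent = c("Oceania", "EastAsia", "Europe"),
                    p = c(0.5, 0.05, 0.05), n = c(30, 100, 100))
  r <- triplet_scan(pap)
  expect_identical(r$focal, "Papuan")
  expect_identical(r$sister, "CHB")  # East Asia serves as the ingroup
  expect_identical(r$outgroup, "CEU")
  # no sister on the focal continent -> skipped with warning
  lonely <- data.frame(population = c("A", "B"),
                       continent = c("ContA", "ContB"),
                       p = c(0.5, 0.1), n = c(50, 50))
  expect_warning(expect_null(triplet_scan(lonely)), "no valid")
})

test_that("z-score outliers flag only extreme loci", {
  expect_warning(z0 <- zscore_outliers(rep(1, 5)), "zero variance")
  expect_false(any(z0$outlier))
  z <- zscore_outliers(c(rep(0.1, 20), 3))
  expect_true(z$outlier[21])
  expect_false(any(z$outlier[1:20]))
  expect_error(zscore_outliers(c(1, 2)), "3 loci")
})

test_that("block jackknife matches manual recomputation on two windows", {
  loci <- data.frame(locus_id = c("l1", "l2", "l3", "l4"),
                     chrom = c("chr1", "chr1", "chr2", "chr2"),
                     start = c(1000L, 2000L, 1000L, 2000L),
                     pbs = c(0.1, 0.2, 0.15, 3))
  jk <- block_jackknife(loci, window = 500000)
  expect_identical(attr(jk, "n_windows"), 2L)
  # manual: removing chr1's window leaves l3/l4 -> too few loci (< 3)
  # removing chr2's window leaves l1/l2 -> too few; no usable iteration
  expect_true(all(jk$n_iter == 0))

  loci6 <- data.frame(locus_id = sprintf("l%d", 1:6),
                      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2",
                                "chr2"),
                      start = c(1e3, 2e3, 3e3, 1e3, 2e3, 3e3),
                      pbs = c(0.1, 0.2, 0.12, 0.18, 0.15, 3))
  jk <- block_jackknife(loci6, window = 500000)
  # manual recomputation of the single informative iteration per locus
  z_no_chr1 <- (3 - mean(c(0.18, 0.15, 3))) / sd(c(0.18, 0.15, 3))
  expect_identical(jk$n_iter, rep(1L, 6))
  expect_true(jk$outlier_full[6])
  expect_identical(jk$stability[6], as.numeric(abs(z_no_chr1) > 2))
})

test_that("an outlier spread across many windows is fully stable", {
  set.seed(9)
  loci <- data.frame(locus_id = sprintf("l%02d", 1:30),
                     chrom = "chr1",
                     start = as.integer(seq(0, 29) * 600000),
                     pbs = c(rep(0.1, 29) + rnorm(29, 0, 0.01), 5))
  loci$pbs[30] <- 5
  jk <- block_jackknife(loci, window = 500000)
  expect_equal(jk$stability[jk$locus_id == "l30"], 1.0)
})

test_that("nearest gene uses the 5-kb extension and alphabetical ties", {
  genes <- data.frame(chrom = "chr1",
                      start = c(1000L, 20000L, 40001L),
                      end = c(2000L, 21000L, 41001L),
                      name = c("GENEC", "GENEA", "GENEB"))
  inside <- data.frame(chrom = "chr1", start = 1500L, end = 1501L)
  r <- nearest_gene(inside, genes)
  expect_identical(r$gene, "GENEC")
  expect_identical(r$distance, 0)
  near <- data.frame(chrom = "chr1", start = 30000L, end = 30001L)
  r <- nearest_gene(near, genes)  # 4 kb beyond the extension from GENEA
  expect_identical(r$gene, "GENEA")
  expect_identical(r$distance, 4000)
  tie <- data.frame(chrom = "chr1", start = 30500L, end = 30501L)
  r <- nearest_gene(tie, genes)   # 4500 bp to both GENEA and GENEB
  expect_identical(r$gene, "GENEA")
  expect_null(nearest_gene(inside, genes[0, ]))
})

test_that("expression association respects the window and carrier floor", {
  set.seed(17)
  inds <- sprintf("i%03d", 1:100)
  carriers <- inds[1:50]
  expr <- generate_expression_matrix(inds, carriers,
                                     gene_names = c("NEAR", "FAR"),
                                     effect = 2, seed = 17)
  locus <- data.frame(chrom = "chr1", start = 500000L, end = 500001L)
  genes <- data.frame(chrom = "chr1",
                      start = c(450000L, 760000L), end = c(460000L, 770000L),
                      name = c("NEAR", "FAR"))
  res <- expression_association(locus, expr, carriers, genes)
  expect_identical(res$gene, "NEAR")          # FAR is 250 kb away
  expect_true(res$significant)
  expect_null(expression_association(locus, expr, carriers[1:5], genes))
})

test_that("a planted carrier shift is detected in nearly all seeds", {
  sig <- 0L
  locus <- data.frame(chrom = "chr1", start = 500000L, end = 500001L)
  genes <- data.frame(chrom = "chr1", start = 450000L, end = 460000L,
                      name = "NEAR")
  inds <- sprintf("i%03d", 1:100)
  for (seed in 1:20) {
    expr <- generate_expression_matrix(inds, inds[1:50],
                                       gene_names = "NEAR",
                                       effect = 2, sd = 1, seed = seed)
    res <- expression_association(locus, expr, inds[1:50], genes)
    if (res$significant) sig <- sig + 1L
  }
  expect_gte(sig, 19L)
})
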