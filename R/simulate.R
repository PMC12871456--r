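# Seeded synthetic-data generators producing every input the pipeline
# consumes, with planted ground truth for recovery and calibration tests.
#
# One master seed drives fixed per-stage substreams (seed, seed + 1, ...) so
# any stage can be regenerated in isolation.

#' Simulation configuration
#'
#' Defaults describe a toy cohort small enough for sub-minute tests: five
#' 1-Mb chromosomes, a 16,569-bp circular mtDNA, three populations on two
#' continents.  `theta` is the probability that a carried NUMT lies inside an
#' introgressed tract on the carrying haplotype (1 = always embedded, 0 =
#' tracts placed independently).
#'
#' @param seed Master RNG seed.
#' @param populations data.frame `name`, `continent`, `size`.
#' @param genome data.frame `chrom`, `length`.
#' @param mt_length Circular mtDNA length.
#' @param n_loci Number of planted NUMT loci.
#' @param numt_length_range Fragment length range in bp.
#' @param freq_range Per-population carrier-frequency range from which locus
#'   frequencies are drawn (overridden by `locus_freq`).
#' @param locus_freq Optional `n_loci x n_population` matrix of carrier
#'   frequencies.
#' @param theta NUMT-in-tract probability in `[0, 1]`.
#' @param tract_length_range Introgressed tract length range in bp.
#' @param background_tracts Poisson mean of NUMT-independent tracts per
#'   individual.
#' @param depth Mean pileup depth per position.
#' @param error_rate Per-base sequencing error probability.
#' @param qual_mean,qual_sd Phred quality distribution of pileup bases.
#' @param n_pairs_mean Mean discordant pairs emitted per planted NUMT
#'   (minimum 2 always emitted).
#' @param splits_per_breakpoint Split reads emitted at each of the three
#'   breakpoints (default 3).
#' @param noise_pair_rate Poisson mean of background discordant pairs per
#'   individual.
#' @param noise_mapq0_rate Fraction of evidence records emitted with MAPQ 0
#'   (removed by filtering).
#' @param numt_substitutions Substitutions planted per locus sequence
#'   relative to the mtDNA reference.
#' @param archaic_profile When `TRUE`, every split read is independently
#'   dropped with probability 1/2, emulating short degraded ancient-DNA
#'   libraries.
#' @param expr_baseline,expr_effect,expr_sd Expression model: baseline mean,
#'   additive carrier effect on the affected gene, residual SD.
#' @return List of class `"numt_sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       populations = data.frame(
                         name = c("POPA1", "POPA2", "POPB1"),
                         continent = c("ContA", "ContA", "ContB"),
                         size = c(20L, 20L, 20L),
                         stringsAsFactors = FALSE),
                       genome = data.frame(
                         chrom = paste0("chr", 1:5),
                         length = rep(1000000L, 5),
                         stringsAsFactors = FALSE),
                       mt_length = 16569L,
                       n_loci = 10L,
                       numt_length_range = c(60L, 600L),
                       freq_range = c(0.05, 0.5),
                       locus_freq = NULL,
                       theta = 0,
                       tract_length_range = c(20000L, 60000L),
                       background_tracts = 2,
                       depth = 30,
                       error_rate = 0.01,
                       qual_mean = 35,
                       qual_sd = 4,
                       n_pairs_mean = 6,
                       splits_per_breakpoint = 3L,
                       noise_pair_rate = 1,
                       noise_mapq0_rate = 0.05,
                       numt_substitutions = 2L,
                       archaic_profile = FALSE,
                       expr_baseline = 10,
                       expr_effect = 2,
                       expr_sd = 1) {
  cfg <- as.list(environment())
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]", call. = FALSE)
  if (any(populations$size <= 0)) stop("population sizes must be > 0",
                                       call. = FALSE)
  if (max(numt_length_range) >= min(tract_length_range) && theta > 0) {
    stop("tracts too short to contain a NUMT fragment's breakpoint region",
         call. = FALSE)
  }
  class(cfg) <- "numt_sim_config"
  cfg
}

# union overlapping/abutting tracts per individual, haplotype and
# chromosome, as a segment caller would report them
merge_tracts <- function(segments) {
  key <- paste(segments$individual_id, segments$haplotype, segments$chrom)
  out <- lapply(split(segments, key), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, s$start[-1] > cummax(s$end)[-NROW(s)]))
    do.call(rbind, lapply(split(s, grp), function(g) {
      ll <- unique(g$linked_locus[!is.na(g$linked_locus)])
      data.frame(individual_id = g$individual_id[1],
                 haplotype = g$haplotype[1], chrom = g$chrom[1],
                 start = min(g$start), end = max(g$end),
                 linked_locus = if (length(ll)) paste(ll, collapse = ",")
                                else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$individual_id, res$haplotype, res$chrom, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic cohort with planted NUMTs and introgressed tracts
#'
#' Draws NUMT carrier status per individual from the per-population locus
#' frequencies; for each carried NUMT, with probability `theta`, places an
#' introgressed tract containing the insertion point on the carrying
#' haplotype; adds NUMT-independent background tracts per individual.
#'
#' @param config A [sim_config()].
#' @return List of class `"numt_truth"`: `config`, `individuals`
#'   (`individual_id`, `population`), `panel`, `loci` (`locus_id`, `chrom`,
#'   `start`, `end` 0-based, `mt_start`, `mt_end`, `length`), `freq`
#'   (locus x population carrier-frequency matrix), `carriers`
#'   (`individual_id`, `locus_id`, `haplotype`), `segments`
#'   (`individual_id`, `haplotype`, `chrom`, `start`, `end`, `linked_locus`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "numt_sim_config"))
  with_seed(config$seed, {
    pops <- config$populations
    individuals <- do.call(rbind, lapply(seq_len(NROW(pops)), function(i) {
      data.frame(
        individual_id = sprintf("%s_%03d", pops$name[i],
                                seq_len(pops$size[i])),
        population = pops$name[i], stringsAsFactors = FALSE)
    }))
    n_ind <- NROW(individuals)

    g <- config$genome
    ci <- sample.int(NROW(g), config$n_loci, replace = TRUE, prob = g$length)
    pos <- vapply(ci, function(k) {
      sample.int(g$length[k] - 2000L, 1) + 1000L  # keep away from edges
    }, integer(1))
    frag_len <- sample(seq(config$numt_length_range[1],
                           config$numt_length_range[2]),
                       config$n_loci, replace = TRUE)
    mt_s <- sample.int(config$mt_length, config$n_loci, replace = TRUE)
    mt_e <- (mt_s - 1L + frag_len) %% config$mt_length + 1L
    loci <- data.frame(
      locus_id = sprintf("L%02d", seq_len(config$n_loci)),
      chrom = g$chrom[ci], start = pos - 1L, end = pos,
      mt_start = mt_s, mt_end = mt_e, length = frag_len,
      stringsAsFactors = FALSE)

    if (is.null(config$locus_freq)) {
      freq <- matrix(stats::runif(config$n_loci * NROW(pops),
                                  config$freq_range[1], config$freq_range[2]),
                     config$n_loci, NROW(pops))
    } else {
      freq <- config$locus_freq
      stopifnot(all(dim(freq) == c(config$n_loci, NROW(pops))))
    }
    dimnames(freq) <- list(loci$locus_id, pops$name)

    pop_idx <- match(individuals$population, pops$name)
    carry <- matrix(stats::runif(n_ind * config$n_loci) <
                      t(freq)[cbind(rep(pop_idx, each = config$n_loci),
                                    rep(seq_len(config$n_loci), n_ind))],
                    nrow = config$n_loci)
    carriers <- which(carry, arr.ind = TRUE)
    carriers <- data.frame(
      individual_id = individuals$individual_id[carriers[, "col"]],
      locus_id = loci$locus_id[carriers[, "row"]],
      haplotype = sample(0:1, NROW(carriers), replace = TRUE),
      stringsAsFactors = FALSE)

    segs <- list()
    if (config$theta > 0 && NROW(carriers) > 0) {
      linked <- stats::runif(NROW(carriers)) < config$theta
      for (k in which(linked)) {
        li <- match(carriers$locus_id[k], loci$locus_id)
        tl <- sample(seq(config$tract_length_range[1],
                         config$tract_length_range[2]), 1)
        p0 <- loci$start[li]
        lo <- max(0L, p0 - tl + 1L)
        s <- sample(seq(lo, p0), 1)
        chrom_len <- g$length[g$chrom == loci$chrom[li]]
        e <- min(chrom_len, s + tl)
        segs[[length(segs) + 1L]] <- data.frame(
          individual_id = carriers$individual_id[k],
          haplotype = carriers$haplotype[k],
          chrom = loci$chrom[li], start = as.integer(s), end = as.integer(e),
          linked_locus = carriers$locus_id[k], stringsAsFactors = FALSE)
      }
    }
    n_bg <- stats::rpois(n_ind, config$background_tracts)
    for (i in which(n_bg > 0)) {
      for (b in seq_len(n_bg[i])) {
        k <- sample.int(NROW(g), 1, prob = g$length)
        tl <- sample(seq(config$tract_length_range[1],
                         config$tract_length_range[2]), 1)
        s <- sample.int(max(1L, g$length[k] - tl), 1)
        segs[[length(segs) + 1L]] <- data.frame(
          individual_id = individuals$individual_id[i],
          haplotype = sample(0:1, 1),
          chrom = g$chrom[k], start = as.integer(s),
          end = as.integer(s + tl), linked_locus = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    segments <- if (length(segs)) merge_tracts(do.call(rbind, segs)) else
      data.frame(individual_id = character(0), haplotype = integer(0),
                 chrom = character(0), start = integer(0), end = integer(0),
                 linked_locus = character(0))
    structure(list(config = config, individuals = individuals,
                   panel = population_panel(pops$name, pops$continent,
                                            pops$size),
                   loci = loci, freq = freq, carriers = carriers,
                   segments = segments),
              class = "numt_truth")
  })
}

#' Generate abstracted read evidence for every individual
#'
#' Each planted NUMT of a carrier emits at least two discordant pairs whose
#' nuclear anchors fall within 500 bp upstream of the breakpoint and whose
#' mates map inside the mtDNA fragment, plus `splits_per_breakpoint` split
#' reads at the exact nuclear breakpoint and at each of the two mtDNA
#' breakpoints.  Background noise pairs land uniformly; a configured
#' fraction of all records carries MAPQ 0.  With `archaic_profile = TRUE`
#' every split read is independently dropped with probability 1/2.
#'
#' @param truth A [generate_cohort()] bundle.
#' @return data.frame of evidence records for all individuals (columns
#'   `individual_id`, `read_id`, `kind`, `side`, `chrom`, `pos`,
#'   `anchor_pos`, `strand`, `mt_pos`, `mapq`).
#' @export
generate_read_evidence <- function(truth) {
  config <- truth$config
  with_seed(config$seed + 1L, {
    rows <- list()
    rid <- 0L
    add <- function(df) rows[[length(rows) + 1L]] <<- df
    for (k in seq_len(NROW(truth$carriers))) {
      ind <- truth$carriers$individual_id[k]
      li <- match(truth$carriers$locus_id[k], truth$loci$locus_id)
      bp <- truth$loci$start[li] + 1L  # 1-based breakpoint
      chrom <- truth$loci$chrom[li]
      frag <- circular_positions(truth$loci$mt_start[li],
                                 truth$loci$mt_end[li], config$mt_length)
      n_pairs <- max(2L, stats::rpois(1, config$n_pairs_mean))
      anchor <- bp - sample.int(450L, n_pairs, replace = TRUE)
      add(data.frame(individual_id = ind,
                     read_id = sprintf("p%06d", rid + seq_len(n_pairs)),
                     kind = "pair", side = NA_character_, chrom = chrom,
                     pos = anchor, anchor_pos = anchor, strand = "+",
                     mt_pos = sample(frag, n_pairs, replace = TRUE),
                     mapq = sample(30:60, n_pairs, replace = TRUE),
                     stringsAsFactors = FALSE))
      rid <- rid + n_pairs
      nsp <- config$splits_per_breakpoint
      sp <- data.frame(
        individual_id = ind,
        read_id = sprintf("s%06d", rid + seq_len(3L * nsp)),
        kind = "split",
        side = rep(c("nuclear", "mt", "mt"), each = nsp),
        chrom = chrom,
        pos = rep(c(bp, truth$loci$mt_start[li], truth$loci$mt_end[li]),
                  each = nsp),
        anchor_pos = bp, strand = "+", mt_pos = NA_integer_,
        mapq = sample(30:60, 3L * nsp, replace = TRUE),
        stringsAsFactors = FALSE)
      rid <- rid + 3L * nsp
      if (config$archaic_profile) {
        sp <- sp[stats::runif(NROW(sp)) < 0.5, , drop = FALSE]
      }
      if (NROW(sp)) add(sp)
    }
    n_ind <- NROW(truth$individuals)
    n_noise <- stats::rpois(n_ind, config$noise_pair_rate)
    for (i in which(n_noise > 0)) {
      g <- config$genome
      ci <- sample.int(NROW(g), n_noise[i], replace = TRUE, prob = g$length)
      pos <- vapply(ci, function(k) sample.int(g$length[k], 1), integer(1))
      add(data.frame(individual_id = truth$individuals$individual_id[i],
                     read_id = sprintf("n%06d", rid + seq_len(n_noise[i])),
                     kind = "pair", side = NA_character_,
                     chrom = g$chrom[ci], pos = pos, anchor_pos = pos,
                     strand = sample(c("+", "-"), n_noise[i], replace = TRUE),
                     mt_pos = sample.int(config$mt_length, n_noise[i],
                                         replace = TRUE),
                     mapq = sample(30:60, n_noise[i], replace = TRUE),
                     stringsAsFactors = FALSE))
      rid <- rid + n_noise[i]
    }
    ev <- do.call(rbind, rows)
    if (is.null(ev)) {
      return(data.frame(individual_id = character(0), read_id = character(0),
                        kind = character(0), side = character(0),
                        chrom = character(0), pos = integer(0),
                        anchor_pos = integer(0), strand = character(0),
                        mt_pos = integer(0), mapq = integer(0)))
    }
    if (config$noise_mapq0_rate > 0) {
      drop <- stats::runif(NROW(ev)) < config$noise_mapq0_rate
      ev$mapq[drop] <- 0L
    }
    rownames(ev) <- NULL
    ev
  })
}

#' Generate a synthetic circular mitochondrial genome
#'
#' Random sequence of the configured length carrying the canonical 13
#' protein-coding gene annotation; each CDS is overwritten with a valid open
#' reading frame under the vertebrate mitochondrial code (start codon,
#' non-stop interior codons, terminal stop), so reading-frame classification
#' behaves as on a real reference.  Synthetic stand-in for an rCRS-like
#' reference; it is not the rCRS sequence.
#'
#' @param seed RNG seed.
#' @param mt_length Genome length (default 16,569; must fit the default CDS
#'   annotation).
#' @return An [mt_genome()] object.
#' @export
synthetic_mt_genome <- function(seed = 1, mt_length = 16569L) {
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    s <- sample(bases, mt_length, replace = TRUE)
    code <- mito_code()
    all_cod <- names(code)
    stops <- all_cod[code == "*"]
    interior <- setdiff(all_cod, stops)
    cds <- mt_cds_default()
    for (i in seq_len(NROW(cds))) {
      n <- cds$end[i] - cds$start[i] + 1L
      n_cod <- n %/% 3L
      codons <- c("ATG", sample(interior, max(0L, n_cod - 2L), replace = TRUE),
                  sample(c("TAA", "TAG"), 1))
      coding <- strsplit(paste(codons, collapse = ""), "")[[1]]
      coding <- c(coding, sample(bases, n - 3L * n_cod, replace = TRUE))
      if (cds$strand[i] == "-") coding <- revcomp_chars(coding)
      s[cds$start[i]:cds$end[i]] <- coding
    }
    mt_genome(paste(s, collapse = ""), cds)
  })
}

#' Generate pileups for every carrier of every locus
#'
#' Each locus receives a planted sequence: the mtDNA reference fragment with
#' `numt_substitutions` random substitutions.  Carrier pileups draw
#' per-position depth from Poisson(`depth`), flip bases to a random other
#' base with probability `error_rate`, and draw phred qualities from a
#' clipped normal.
#'
#' @param truth A [generate_cohort()] bundle.
#' @param genome An [mt_genome()] (e.g. [synthetic_mt_genome()]).
#' @return List: `planted` (named character vector of locus sequences),
#'   `pileups` (nested list `[[locus_id]][[individual_id]]` of pileup
#'   data.frames `pos`, `base`, `qual`).
#' @export
generate_pileups <- function(truth, genome) {
  config <- truth$config
  stopifnot(inherits(genome, "mt_genome"))
  with_seed(config$seed + 2L, {
    bases <- c("A", "C", "G", "T")
    ref <- strsplit(genome$sequence, "")[[1]]
    planted <- character(NROW(truth$loci))
    names(planted) <- truth$loci$locus_id
    pileups <- stats::setNames(vector("list", NROW(truth$loci)),
                               truth$loci$locus_id)
    for (li in seq_len(NROW(truth$loci))) {
      frag_pos <- circular_positions(truth$loci$mt_start[li],
                                     truth$loci$mt_end[li], genome$length)
      seq_chars <- ref[frag_pos]
      n_sub <- min(config$numt_substitutions, length(seq_chars))
      if (n_sub > 0) {
        at <- sample(seq_along(seq_chars), n_sub)
        for (a in at) {
          seq_chars[a] <- sample(setdiff(bases, seq_chars[a]), 1)
        }
      }
      planted[li] <- paste(seq_chars, collapse = "")
      inds <- truth$carriers$individual_id[
        truth$carriers$locus_id == truth$loci$locus_id[li]]
      pileups[[li]] <- stats::setNames(lapply(inds, function(ind) {
        depth <- stats::rpois(length(seq_chars), config$depth)
        pos <- rep(seq_along(seq_chars), depth)
        b <- rep(seq_chars, depth)
        err <- stats::runif(length(b)) < config$error_rate
        if (any(err)) {
          b[err] <- vapply(b[err],
                           function(x) sample(setdiff(bases, x), 1), "")
        }
        qual <- pmin(41, pmax(2, round(stats::rnorm(length(b),
                                                    config$qual_mean,
                                                    config$qual_sd))))
        data.frame(pos = pos, base = b, qual = qual,
                   stringsAsFactors = FALSE)
      }), inds)
    }
    list(planted = planted, pileups = pileups)
  })
}

#' Generate Sprime-style site files and phased genotypes from true segments
#'
#' Every true segment emits archaic-specific sites on the carrying
#' haplotype: one at each segment boundary plus interior sites every ~10 kb,
#' so [reconstruct_individual_segments()] round-trips to the true spans.
#'
#' @param truth A [generate_cohort()] bundle.
#' @return List: `sites` (data.frame `chrom`, `pos`, `ref`, `alt`,
#'   `archaic_allele`, `segment_id`), `genotypes` (data.frame `chrom`,
#'   `pos`, one phased-GT column per individual).
#' @export
generate_sprime_output <- function(truth) {
  config <- truth$config
  with_seed(config$seed + 3L, {
    segs <- truth$segments
    sites <- list()
    for (k in seq_len(NROW(segs))) {
      first <- segs$start[k] + 1L
      last <- segs$end[k]
      interior <- if (last - first > 2L) {
        n_int <- max(0L, (last - first) %/% 10000L)
        if (n_int > 0) sort(sample(seq(first + 1L, last - 1L), n_int))
        else integer(0)
      } else integer(0)
      pos <- unique(c(first, interior, last))
      sites[[k]] <- data.frame(chrom = segs$chrom[k], pos = pos,
                               ref = "A", alt = "T", archaic_allele = "T",
                               segment_id = sprintf("seg%04d", k),
                               stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, sites)
    if (is.null(sites)) {
      sites <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          archaic_allele = character(0),
                          segment_id = character(0))
    }
    usite <- unique(sites[, c("chrom", "pos")])
    gt <- data.frame(chrom = usite$chrom, pos = usite$pos,
                     stringsAsFactors = FALSE)
    ukey <- paste(usite$chrom, usite$pos)
    for (ind in truth$individuals$individual_id) {
      a0 <- rep("0", NROW(usite))
      a1 <- rep("0", NROW(usite))
      own <- which(segs$individual_id == ind)
      for (k in own) {
        skey <- paste(sites$chrom, sites$pos)[
          sites$segment_id == sprintf("seg%04d", k)]
        at <- match(skey, ukey)
        if (segs$haplotype[k] == 0) a0[at] <- "1" else a1[at] <- "1"
      }
      gt[[ind]] <- paste(a0, a1, sep = "|")
    }
    list(sites = sites, genotypes = gt)
  })
}

#' Generate a three-population frequency model with one differentiated locus
#'
#' Null loci share an ancestral frequency drawn per locus, with per-population
#' binomial sampling noise; one planted locus is strongly differentiated in
#' the focal population.  Recovery of that locus as the top PBS z-score is
#' the module's parameter-recovery check.
#'
#' @param seed RNG seed.
#' @param n_null Number of undifferentiated loci (default 50).
#' @param populations data.frame `name`, `continent`, `size` (>= 3
#'   populations on >= 2 continents).
#' @param focal_p,base_p Frequencies of the differentiated locus in the
#'   focal population and elsewhere (defaults 0.6 and 0.05).
#' @param null_range Range of ancestral frequencies for null loci.
#' @return data.frame `locus_id`, `population`, `continent`, `p`, `n`
#'   (haplotypes); attribute `"planted"` names the differentiated locus and
#'   `"focal"` its focal population.
#' @export
generate_pbs_frequencies <- function(seed = 1, n_null = 50,
                                     populations = data.frame(
                                       name = c("POPA1", "POPA2", "POPB1"),
                                       continent = c("ContA", "ContA",
                                                     "ContB"),
                                       size = c(50L, 50L, 50L),
                                       stringsAsFactors = FALSE),
                                     focal_p = 0.6, base_p = 0.05,
                                     null_range = c(0.1, 0.5)) {
  with_seed(seed, {
    n_hap <- 2L * populations$size
    rows <- list()
    for (l in seq_len(n_null)) {
      p0 <- stats::runif(1, null_range[1], null_range[2])
      p_hat <- stats::rbinom(NROW(populations), n_hap, p0) / n_hap
      rows[[l]] <- data.frame(locus_id = sprintf("null%03d", l),
                              population = populations$name,
                              continent = populations$continent,
                              p = p_hat, n = n_hap, stringsAsFactors = FALSE)
    }
    focal <- populations$name[1]
    p_sel <- ifelse(populations$name == focal, focal_p, base_p)
    p_hat <- stats::rbinom(NROW(populations), n_hap, p_sel) / n_hap
    rows[[n_null + 1L]] <- data.frame(locus_id = "planted",
                                      population = populations$name,
                                      continent = populations$continent,
                                      p = p_hat, n = n_hap,
                                      stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    attr(out, "planted") <- "planted"
    attr(out, "focal") <- focal
    out
  })
}

#' Generate an expression matrix with a planted carrier effect
#'
#' @param individual_ids Sample labels (columns).
#' @param carrier_ids Subset of `individual_ids` carrying the NUMT.
#' @param gene_names Gene labels (rows); the first gene receives the carrier
#'   effect.
#' @param baseline,effect,sd Normal expression model parameters.
#' @param seed RNG seed.
#' @return Numeric matrix genes x individuals.
#' @export
generate_expression_matrix <- function(individual_ids, carrier_ids,
                                       gene_names = c("GENE1", "GENE2"),
                                       baseline = 10, effect = 2, sd = 1,
                                       seed = 1) {
  with_seed(seed, {
    m <- matrix(stats::rnorm(length(gene_names) * length(individual_ids),
                             baseline, sd),
                nrow = length(gene_names),
                dimnames = list(gene_names, individual_ids))
    m[1, individual_ids %in% carrier_ids] <-
      m[1, individual_ids %in% carrier_ids] + effect
    m
  })
}
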