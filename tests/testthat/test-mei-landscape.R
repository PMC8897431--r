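mk_call <- function(sample_id = "S1", element_class = "Alu",
                    chrom = "chr1", pos = 1000, filter = "PASS",
                    assess = 5L, tsd = TRUE, split_reads = 4L,
                    discordant_pairs = 1L, genotype = "0/1") {
  data.frame(sample_id, element_class, chrom, pos, filter, assess,
             tsd, split_reads, discordant_pairs, genotype,
             stringsAsFactors = FALSE)
}

test_that("base and private filters implement the stated rules", {
  calls <- rbind(mk_call(filter = "lc"),
                 mk_call(assess = 4L),
                 mk_call(split_reads = 2L),
                 mk_call(split_reads = 3L),
                 mk_call(tsd = FALSE),
                 mk_call(discordant_pairs = 50L))
  cfg <- mei_filter_config(max_discordant_pairs = 10)
  base <- filter_mei_calls(calls, cfg, "base")
  expect_identical(nrow(base), 4L)          # non-PASS and high-DPR out
  priv <- filter_mei_calls(calls, cfg, "private")
  # only assess==5, TSD defined, split reads > 2 survive
  expect_identical(nrow(priv), 1L)
  expect_identical(priv$split_reads, 3L)
  # low-complexity mask removes in-mask insertion points
  mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
  cfgm <- mei_filter_config(low_complexity_mask = mask,
                            max_discordant_pairs = 10)
  expect_identical(nrow(filter_mei_calls(mk_call(), cfgm, "base")), 0L)
  expect_error(filter_mei_calls(mk_call(element_class = "LTR"), cfg),
               "unknown element class")
})

test_that("merging links same-class calls within tolerance only", {
  two <- rbind(mk_call("S1", pos = 1000), mk_call("S2", pos = 1019))
  loci <- merge_mei_loci(two, n_samples = 2)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$representative_pos, 1000L)
  expect_identical(loci$n_carriers, 2L)
  # 21 bp apart: two events
  apart <- rbind(mk_call("S1", pos = 1000), mk_call("S2", pos = 1021))
  expect_identical(nrow(merge_mei_loci(apart, n_samples = 2)), 2L)
  # different element classes never merge
  mixed <- rbind(mk_call("S1", element_class = "Alu"),
                 mk_call("S2", element_class = "L1"))
  expect_identical(nrow(merge_mei_loci(mixed, n_samples = 2)), 2L)
  # zero tolerance equals exact-coordinate grouping
  near <- rbind(mk_call("S1", pos = 1000), mk_call("S2", pos = 1001),
                mk_call("S3", pos = 1001))
  expect_identical(nrow(merge_mei_loci(near, n_samples = 3,
                                       tolerance_bp = 0)), 2L)
  # allele counts use genotype dosage
  doso <- rbind(mk_call("S1", genotype = "1/1"),
                mk_call("S2", genotype = "0/1"))
  expect_identical(merge_mei_loci(doso, n_samples = 2)$allele_count, 3L)
})

test_that("merging is invariant to input row order", {
  withr::with_seed(5, {
    calls <- do.call(rbind, lapply(1:40, function(i)
      mk_call(sample_id = sprintf("S%02d", sample(8, 1)),
              element_class = sample(c("Alu", "L1"), 1),
              chrom = sample(c("chr1", "chr2"), 1),
              pos = sample(c(1000, 1015, 1030, 5000, 5010), 1))))
    base <- merge_mei_loci(calls, n_samples = 8)
    for (k in 1:5) {
      perm <- merge_mei_loci(calls[sample(nrow(calls)), ],
                             n_samples = 8)
      expect_identical(perm, base)
    }
  })
})

test_that("database matching respects class, chromosome and tolerance", {
  locus <- data.frame(element_class = "Alu", chrom = "chr2",
                      representative_pos = 5000L)
  db <- data.frame(element_class = "Alu", chrom = "chr2", pos = 5020L)
  expect_true(match_mei_database(locus, db)$db_matched)
  expect_false(match_mei_database(locus, db[0, ])$db_matched)
  dbsva <- data.frame(element_class = "SVA", chrom = "chr2", pos = 5000L)
  expect_false(match_mei_database(locus, dbsva)$db_matched)
  db21 <- data.frame(element_class = "Alu", chrom = "chr2", pos = 5021L)
  expect_false(match_mei_database(locus, db21)$db_matched)
})

test_that("classification partitions loci with database precedence", {
  loci <- data.frame(db_matched = c(TRUE, FALSE, FALSE),
                     n_carriers = c(1L, 3L, 1L))
  got <- classify_mei_loci(loci)$classification
  expect_identical(got, c("Shared", "CohortPrivate", "Singleton"))
  # partition property on random inputs
  withr::with_seed(9, {
    rand <- data.frame(db_matched = runif(200) < 0.5,
                       n_carriers = sample(1:10, 200, replace = TRUE))
    cls <- classify_mei_loci(rand)$classification
    expect_true(all(cls %in% c("Shared", "CohortPrivate", "Singleton")))
    expect_identical(sum(cls == "Shared"), sum(rand$db_matched))
  })
})

test_that("planted classes are recovered exactly on a jittered synthetic cohort", {
  cfg <- toy_config(seed = 81, n_samples = 60, n_mei_loci = 250,
                    positional_jitter_bp = 20,
                    chromosome_lengths = c(chr1 = 400000, chr2 = 300000))
  sim <- generate_mei_callset(cfg)
  calls <- filter_mei_calls(sim$calls, stage = "private")
  loci <- classify_mei_loci(
    match_mei_database(merge_mei_loci(calls, cfg$n_samples), sim$dgv))
  m <- match(paste(loci$chrom, loci$representative_pos,
                   loci$element_class),
             paste(sim$truth$chrom, sim$truth$pos,
                   sim$truth$element_class))
  expect_false(anyNA(m))
  expect_identical(loci$classification, sim$truth$truth_class[m])
})

test_that("context annotation applies CDS > UTR > IntronFlank > Intergenic", {
  gm <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(10000, 10000, 10150, 12000, 10000,
                               20000, 20000, 20000),
                     end = c(13000, 10149, 11000, 13000, 10149,
                             22000, 20400, 20100)),
    type = c("mRNA", "five_prime_UTR", "CDS", "CDS", "UTR",
             "mRNA", "exon", "CDS"))
  loci <- data.frame(
    chrom = "chr1",
    representative_pos = c(10500, 10050, 11500, 14500, 16000,
                           20050))
  got <- annotate_mei_context(loci, gm)$context
  # 1500 bp downstream of a transcription end is still flank
  expect_identical(got,
                   c("CDS", "UTR", "IntronFlank", "IntronFlank",
                     "Intergenic", "CDS"))
  # UTR in one transcript, CDS in another: CDS wins
  overlap <- data.frame(chrom = "chr1", representative_pos = 20050)
  expect_identical(annotate_mei_context(overlap, gm)$context, "CDS")
})

test_that("context precedence matches exhaustive overlap enumeration", {
  ref <- generate_reference(toy_config(seed = 91))
  gm <- ref$genes
  type <- S4Vectors::mcols(gm)$type
  positions <- seq(500, 140000, by = 777)
  loci <- data.frame(chrom = "chr1", representative_pos = positions)
  got <- annotate_mei_context(loci, gm, flank_bp = 2000)$context
  oracle <- vapply(positions, function(p) {
    hit <- function(t, pad = 0)
      any(GenomicRanges::start(gm[type %in% t]) - pad <= p &
            GenomicRanges::end(gm[type %in% t]) + pad >= p &
            as.character(GenomicRanges::seqnames(gm[type %in% t])) ==
              "chr1")
    if (hit("CDS")) "CDS"
    else if (hit(c("five_prime_UTR", "three_prime_UTR", "UTR"))) "UTR"
    else if (hit(c("mRNA", "transcript"), pad = 2000)) "IntronFlank"
    else "Intergenic"
  }, character(1))
  expect_identical(got, oracle)
})

test_that("KS machinery matches the brute-force sup distance", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      x <- round(runif(sample(3:12, 1)), 2)
      y <- round(runif(sample(3:12, 1)), 2)
      expect_equal(unname(suppressWarnings(ks.test(x, y))$statistic),
                   brute_ks_statistic(x, y), tolerance = 1e-12)
    }
  })
})

test_that("GC bias test flags AT-biased insertions and not uniform ones", {
  cfg <- toy_config(seed = 101)
  ref <- generate_reference(cfg)
  genome <- ref$genome
  # uniform insertions: no signal expected at alpha = 0.01 mostly
  withr::with_seed(15, {
    pvals <- vapply(1:20, function(r) {
      pos <- sample.int(140000, 300) + 50
      loci <- data.frame(element_class = "Alu", chrom = "chr1",
                         representative_pos = pos)
      mei_gc_bias(loci, genome, n_windows = 2000, seed = r)$per_class$p_value
    }, numeric(1))
  })
  expect_gte(mean(pvals > 0.01), 0.9)
  # insertions planted in the most AT-rich windows: strong signal
  starts <- seq(1, length(genome[["chr1"]]) - 99, by = 100)
  v <- Biostrings::Views(genome[["chr1"]], starts, width = 100)
  gc <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
  at_rich <- order(gc)[1:300]
  loci <- data.frame(element_class = "L1", chrom = "chr1",
                     representative_pos = (at_rich - 1L) * 100L + 50L)
  res <- mei_gc_bias(loci, genome, n_windows = 2000, seed = 3)
  expect_lt(res$per_class$p_value, 0.01)
  # degenerate: identical GC in both groups gives statistic 0
  expect_equal(brute_ks_statistic(rep(0.5, 5), rep(0.5, 7)), 0)
})

test_that("landscape summary reproduces printed-count arithmetic and U statistic", {
  # class proportions from the printed counts 5571 / 1501 / 418
  loci <- data.frame(
    classification = rep(c("Shared", "CohortPrivate", "Singleton"),
                         c(5571, 1501, 418)),
    element_class = "Alu", carriers = "S1",
    allele_frequency = 0.1, stringsAsFactors = FALSE)
  s <- mei_landscape_summary(loci)
  expect_identical(sum(s$class_counts), 7490L)
  expect_equal(round(100 * s$class_proportions[["Singleton"]], 1), 5.6)
  # Mann-Whitney U equals brute-force pair counting
  sh <- c(0.5, 0.4, 0.3)
  pr <- c(0.1, 0.05, 0.2)
  loci2 <- data.frame(
    classification = rep(c("Shared", "CohortPrivate"), each = 3),
    element_class = "Alu", carriers = "S1",
    allele_frequency = c(sh, pr), stringsAsFactors = FALSE)
  s2 <- mei_landscape_summary(loci2)
  expect_identical(s2$af_comparison$U, 9)
  expect_identical(s2$af_comparison$U, brute_mann_whitney_u(sh, pr))
  # burden proportional to chromosome length gives r = 1
  loci3 <- data.frame(
    classification = "Shared", element_class = "Alu", carriers = "S1",
    allele_frequency = 0.1,
    chrom = rep(c("chr1", "chr2", "chr3"), c(30, 20, 10)),
    stringsAsFactors = FALSE)
  s3 <- mei_landscape_summary(loci3,
    chromosome_lengths = c(chr1 = 3e6, chr2 = 2e6, chr3 = 1e6))
  expect_equal(s3$chrom_correlation$r, 1)
  # a class with zero loci yields an undefined AF comparison
  s4 <- mei_landscape_summary(loci3)
  expect_true(is.na(s4$af_comparison$U))
  # high-AF private flag counts AF > 0.20
  loci5 <- data.frame(
    classification = "CohortPrivate", element_class = "Alu",
    carriers = "S1", allele_frequency = c(0.25, 0.1, 0.21, 0.2),
    stringsAsFactors = FALSE)
  expect_identical(mei_landscape_summary(loci5)$high_af_private$count, 2L)
})

test_that("Mann-Whitney U equals brute force on random small inputs", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      x <- sample(seq(0, 1, by = 0.05), sample(2:12, 1), replace = TRUE)
      y <- sample(seq(0, 1, by = 0.05), sample(2:12, 1), replace = TRUE)
      expect_equal(unname(suppressWarnings(wilcox.test(x, y))$statistic),
                   brute_mann_whitney_u(x, y))
    }
  })
})
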