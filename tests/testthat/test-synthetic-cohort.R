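test_that("config validation rejects malformed parameters", {
  expect_error(sim_config(chromosome_lengths = c(chr1 = 0)),
               "length")
  expect_error(sim_config(truth_class_mix = c(Shared = 0.6,
                                              CohortPrivate = 0.2,
                                              Singleton = 0.1)),
               "sum to 1")
  expect_error(sim_config(mask_fraction = 1.5), "rates outside")
  expect_error(sim_config(pathogenic_allele_freqs = list(G = c(0.8, 0.7))),
               "> 1")
})

test_that("reference generation is seed-deterministic with nested gene models", {
  cfg <- toy_config(seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- generate_reference(cfg, d1)
  r2 <- generate_reference(cfg, d2)
  expect_identical(readLines(r1$paths[["fasta"]]),
                   readLines(r2$paths[["fasta"]]))
  expect_identical(as.character(r1$genome), as.character(r2$genome))

  type <- S4Vectors::mcols(r1$genes)$type
  parent <- S4Vectors::mcols(r1$genes)$Parent
  id <- S4Vectors::mcols(r1$genes)$ID
  for (tx in id[type == "mRNA"]) {
    tx_rng <- r1$genes[id == tx]
    kids <- r1$genes[parent == tx]
    exons <- kids[S4Vectors::mcols(kids)$type == "exon"]
    cds <- kids[S4Vectors::mcols(kids)$type == "CDS"]
    # CDS within exons within the transcript span
    expect_true(all(IRanges::overlapsAny(cds, exons, type = "within")))
    expect_true(all(IRanges::overlapsAny(exons, tx_rng, type = "within")))
  }
})

test_that("zero mask fraction yields an empty mask", {
  cfg <- toy_config(mask_fraction = 0)
  ref <- generate_reference(cfg)
  expect_length(ref$mask, 0)
})

test_that("cohort VCF plants single-cause FD/FB truth at the configured rates", {
  cfg <- toy_config(seed = 21, n_samples = 40, n_sites = 200,
                    allele_balance_error_rate = 0.1,
                    low_depth_error_rate = 0)
  sim <- generate_cohort_vcf(cfg)
  g <- sim$genotypes
  expect_identical(nrow(g), 40L * 200L)
  het <- g$gt == "0/1"
  n_fb <- sum(g$truth_flag == "FB")
  interval <- qbinom(c(0.005, 0.995), sum(het), 0.1)
  expect_gte(n_fb, interval[1])
  expect_lte(n_fb, interval[2])
  # planted violations are single-cause
  fb <- g[g$truth_flag == "FB", ]
  expect_true(all(fb$dp >= 8))
  expect_true(all(fb$ad_alt / fb$dp < 0.2 | fb$ad_alt / fb$dp > 0.8))
  pass <- g[g$truth_flag == "PASS", ]
  expect_true(all(pass$dp >= 8))
})

test_that("zero error rates give an all-PASS truth table", {
  cfg <- toy_config(low_depth_error_rate = 0,
                    allele_balance_error_rate = 0)
  sim <- generate_cohort_vcf(cfg)
  expect_true(all(sim$truth$flag == "PASS"))
})

test_that("same seed gives a byte-identical VCF body", {
  cfg <- toy_config(seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_cohort_vcf(cfg, out_dir = d1)
  s2 <- generate_cohort_vcf(cfg, out_dir = d2)
  expect_identical(readLines(gzfile(s1$paths[["vcf"]])),
                   readLines(gzfile(s2$paths[["vcf"]])))
})

test_that("MEI truth-class counts follow the configured mix", {
  cfg <- toy_config(seed = 31, n_samples = 50, n_mei_loci = 200,
                    chromosome_lengths = c(chr1 = 400000, chr2 = 300000))
  sim <- generate_mei_callset(cfg)
  counts <- table(factor(sim$truth$truth_class,
                         c("Shared", "CohortPrivate", "Singleton")))
  for (k in names(counts)) {
    p <- cfg$truth_class_mix[[k]]
    iv <- qbinom(c(0.005, 0.995), 200, p)
    expect_gte(counts[[k]], iv[1])
    expect_lte(counts[[k]], iv[2])
  }
  # structural truth: carrier counts per class
  carr <- tapply(sim$calls$sample_id, sim$calls$locus_id,
                 function(s) length(unique(s)))
  tc <- sim$truth$truth_class[match(names(carr), sim$truth$locus_id)]
  expect_true(all(carr[tc == "Singleton"] == 1))
  expect_true(all(carr[tc == "CohortPrivate"] >= 2))
  # Shared loci in table, others absent (same class within tolerance)
  shared <- sim$truth[sim$truth$truth_class == "Shared", ]
  for (i in seq_len(nrow(shared))) {
    hit <- sim$dgv$element_class == shared$element_class[i] &
      sim$dgv$chrom == shared$chrom[i] &
      abs(sim$dgv$pos - shared$pos[i]) <= cfg$positional_jitter_bp
    expect_true(any(hit))
  }
})

test_that("degenerate MEI mixes behave as stated", {
  cfg <- toy_config(truth_class_mix = c(Shared = 0, CohortPrivate = 0,
                                        Singleton = 1),
                    n_mei_loci = 30)
  sim <- generate_mei_callset(cfg)
  expect_true(all(table(sim$calls$locus_id) == 1))
  cfg0 <- toy_config(positional_jitter_bp = 0, n_mei_loci = 30)
  sim0 <- generate_mei_callset(cfg0)
  shared <- sim0$truth[sim0$truth$truth_class == "Shared", ]
  key <- paste(sim0$dgv$element_class, sim0$dgv$chrom, sim0$dgv$pos)
  expect_true(all(paste(shared$element_class, shared$chrom,
                        shared$pos) %in% key))
})

test_that("MEI generator rejects private loci in a 1-sample cohort", {
  expect_error(
    generate_mei_callset(toy_config(n_samples = 1)),
    "CohortPrivate")
})

test_that("HWE generator matches closed-form genotype expectations", {
  cfg <- toy_config(pathogenic_allele_freqs = list(G = c(0.006, 0.004)))
  sim <- generate_hwe_genotypes(cfg, n = 200000)
  aff <- sum(sim$genotypes$a1 > 0 & sim$genotypes$a2 > 0)
  iv <- qbinom(c(0.005, 0.995), 200000, 1e-4)
  expect_gte(aff, iv[1])
  expect_lte(aff, iv[2])
  # zero-frequency gene has zero carriers
  sim0 <- generate_hwe_genotypes(
    toy_config(pathogenic_allele_freqs = list(G = numeric(0))), n = 1000)
  expect_true(all(sim0$genotypes$a1 == 0 & sim0$genotypes$a2 == 0))
  # deterministic given the seed
  s1 <- generate_hwe_genotypes(cfg, n = 500)
  s2 <- generate_hwe_genotypes(cfg, n = 500)
  expect_identical(s1$genotypes, s2$genotypes)
})

test_that("HLA registry withholding marks novelty at the right level", {
  cfg <- toy_config(n_samples = 60, registry_withheld_fraction = 0.2)
  sim <- generate_hla_cohort(cfg)
  expect_true(all(sim$truth$level %in% c("sequence_novel",
                                         "protein_novel")))
  # the intron-variant twin is sequence-novel only
  for (l in names(cfg$hla_allele_freqs)) {
    ids <- sim$catalog$allele_id[sim$catalog$locus == l]
    twin <- ids[length(ids)]
    lvl <- sim$truth$level[sim$truth$locus == l &
                             sim$truth$allele_id == twin]
    expect_identical(lvl, "sequence_novel")
  }
  # withheld alleles absent from registry
  expect_false(any(paste(sim$truth$locus, sim$truth$allele_id) %in%
                     paste(sim$registry$locus, sim$registry$allele_id)))
  # withholding nothing leaves an empty truth table
  sim0 <- generate_hla_cohort(toy_config(registry_withheld_fraction = 0))
  expect_identical(nrow(sim0$truth), 0L)
})

test_that("HLA haplotype frequencies follow the configured spectrum", {
  k <- 5
  freqs <- setNames(rep(1 / k, k), sprintf("HLA-A*%02d", 1:k))
  cfg <- toy_config(n_samples = 400,
                    hla_allele_freqs = list("HLA-A" = freqs))
  sim <- generate_hla_cohort(cfg)
  counts <- table(c(sim$genotypes$allele_1, sim$genotypes$allele_2))
  n <- 2 * 400
  for (cnt in counts) {
    iv <- qbinom(c(0.005, 0.995), n, 1 / k)
    expect_gte(cnt, iv[1])
    expect_lte(cnt, iv[2])
  }
})

test_that("every emitted record has exactly one truth entry and vice versa", {
  cfg <- toy_config(seed = 41)
  mei <- generate_mei_callset(cfg)
  expect_setequal(unique(mei$calls$locus_id), mei$truth$locus_id)
  expect_identical(anyDuplicated(mei$truth$locus_id), 0L)
  nrs <- generate_nrs_evidence(cfg)
  expect_setequal(nrs$contigs$contig_id, nrs$truth$contig_id)
  expect_identical(anyDuplicated(nrs$truth$contig_id), 0L)
  vcf <- generate_cohort_vcf(cfg)
  expect_identical(nrow(vcf$truth), nrow(vcf$genotypes))
})

test_that("the orchestrator writes a complete manifest deterministically", {
  cfg <- toy_config(seed = 51, n_sites = 40, n_mei_loci = 20,
                    n_nrs_contigs = 3)
  d1 <- withr::local_tempdir()
  sim <- generate_synthetic_cohort(cfg, d1)
  expect_true(all(file.exists(sim$manifest$file)))
  expect_setequal(unique(sim$manifest$component),
                  c("reference", "cohort_vcf", "mei", "nrs", "hwe", "hla"))
})
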