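#' Simulation configuration for a synthetic WGS cohort
#'
#' Bundles every parameter of the synthetic-cohort generator.  Defaults
#' describe the study conditions the pipeline is exercised under: a
#' cohort of 500 individuals genotyped at negative-binomial depth with
#' mean 38.65x (the real cohort's average coverage), 2000 MEI loci whose
#' truth-class mix (74.3% shared / 20.1% cohort-private / 5.6%
#' singleton) and element mix (Alu / L1 / SVA / HERV) mirror the
#' observed landscape, a +/-20 bp positional tolerance, and pathogenic
#' allele frequencies that reproduce the printed carrier frequencies of
#' the five curated recessive-disease genes.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_samples Number of cohort individuals.
#' @param chromosome_lengths Named numeric vector of chromosome sizes in
#'   bp (each >= 10 kb).
#' @param n_sites Number of biallelic SNV sites in the cohort VCF.
#' @param n_mei_loci Number of planted MEI loci.
#' @param mei_class_mix Named proportions over the four element classes
#'   `Alu`, `L1`, `SVA`, `HERV`; must sum to 1.
#' @param truth_class_mix Named proportions over the truth classes
#'   `Shared`, `CohortPrivate`, `Singleton`; must sum to 1.
#' @param positional_jitter_bp Maximum absolute positional jitter (bp)
#'   applied to reference-database MEI coordinates.  Must not exceed the
#'   +/-20 bp matching tolerance used downstream.
#' @param depth_mean,depth_dispersion Mean and dispersion (negative
#'   binomial `size`) of per-genotype sequencing depth.
#' @param low_depth_error_rate Fraction of genotypes planted as
#'   fail-depth (FD): depth drawn below the depth cutoff.
#' @param allele_balance_error_rate Fraction of heterozygous genotypes
#'   planted as fail-balance (FB): allele fraction outside the balance
#'   interval.
#' @param n_nrs_contigs Number of truth-anchored non-reference contigs.
#' @param barcode_noise_rate Fraction of barcode evidence records placed
#'   in random (wrong) 1-kb windows.
#' @param pathogenic_allele_freqs Named list: gene -> numeric vector of
#'   per-allele pathogenic frequencies (each gene's sum <= 0.5).
#' @param hla_allele_freqs Named list: HLA locus -> numeric frequency
#'   vector over that locus' alleles (sums to 1).
#' @param registry_withheld_fraction Fraction of HLA alleles withheld
#'   from the emulated allele registry (these become "novel").
#' @param mask_fraction Fraction of each chromosome covered by the
#'   low-complexity mask BED.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_samples = 20, n_sites = 50)
#' cfg$n_samples
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 500L,
                       chromosome_lengths = c(chr1 = 500000, chr2 = 300000),
                       n_sites = 1000L,
                       n_mei_loci = 2000L,
                       mei_class_mix = c(Alu = 5971, L1 = 1131, SVA = 375,
                                         HERV = 13) / 7490,
                       truth_class_mix = c(Shared = 0.743,
                                           CohortPrivate = 0.201,
                                           Singleton = 0.056),
                       positional_jitter_bp = 20L,
                       depth_mean = 38.65,
                       depth_dispersion = 10,
                       low_depth_error_rate = 0.02,
                       allele_balance_error_rate = 0.02,
                       n_nrs_contigs = 30L,
                       barcode_noise_rate = 0,
                       pathogenic_allele_freqs = list(
                         CFTR = c(0.006, 0.003),
                         HBB  = c(0.012, 0.0075),
                         GJB2 = c(0.010, 0.0032),
                         MEFV = c(0.003, 0.0013),
                         HFE  = c(0.03)),
                       hla_allele_freqs = default_hla_freqs(),
                       registry_withheld_fraction = 0.1,
                       mask_fraction = 0.05) {
  cfg <- list(seed = as.integer(seed),
              n_samples = as.integer(n_samples),
              chromosome_lengths = chromosome_lengths,
              n_sites = as.integer(n_sites),
              n_mei_loci = as.integer(n_mei_loci),
              mei_class_mix = mei_class_mix,
              truth_class_mix = truth_class_mix,
              positional_jitter_bp = as.integer(positional_jitter_bp),
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              low_depth_error_rate = low_depth_error_rate,
              allele_balance_error_rate = allele_balance_error_rate,
              n_nrs_contigs = as.integer(n_nrs_contigs),
              barcode_noise_rate = barcode_noise_rate,
              pathogenic_allele_freqs = pathogenic_allele_freqs,
              hla_allele_freqs = hla_allele_freqs,
              registry_withheld_fraction = registry_withheld_fraction,
              mask_fraction = mask_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default HLA class I allele frequency spectra
#'
#' Six loci with 12 alleles each; frequencies decay as 1/rank
#' (normalised), a crude stand-in for the skewed allele spectra of HLA
#' class I genes.
#'
#' @return Named list of frequency vectors, one per locus.
#' @export
default_hla_freqs <- function() {
  loci <- c("HLA-A", "HLA-B", "HLA-C", "HLA-E", "HLA-F", "HLA-G")
  f <- (1 / seq_len(12)) / sum(1 / seq_len(12))
  setNames(lapply(loci, function(l) {
    setNames(f, sprintf("%s*%02d", l, seq_along(f)))
  }), loci)
}

#' @rdname sim_config
#' @param cfg A `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$chromosome_lengths) == 0)
    stop("chromosome_lengths must be nonempty")
  if (any(cfg$chromosome_lengths <= 0))
    stop("zero- or negative-length chromosome in chromosome_lengths")
  if (is.null(names(cfg$chromosome_lengths)))
    stop("chromosome_lengths must be named")
  check_mix <- function(p, what, labels) {
    if (abs(sum(p) - 1) > 1e-9)
      stop(what, " must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop(what, " has negative entries")
    if (!setequal(names(p), labels))
      stop(what, " must be named over {", paste(labels, collapse = ", "), "}")
  }
  check_mix(cfg$mei_class_mix, "mei_class_mix",
            c("Alu", "L1", "SVA", "HERV"))
  check_mix(cfg$truth_class_mix, "truth_class_mix",
            c("Shared", "CohortPrivate", "Singleton"))
  if (cfg$positional_jitter_bp < 0 || cfg$positional_jitter_bp > 20)
    stop("positional_jitter_bp must be in [0, 20], the matching tolerance")
  rates <- c(low_depth_error_rate = cfg$low_depth_error_rate,
             allele_balance_error_rate = cfg$allele_balance_error_rate,
             barcode_noise_rate = cfg$barcode_noise_rate,
             registry_withheld_fraction = cfg$registry_withheld_fraction,
             mask_fraction = cfg$mask_fraction)
  bad <- rates < 0 | rates > 1
  if (any(bad))
    stop("rates outside [0,1]: ", paste(names(rates)[bad], collapse = ", "))
  for (g in names(cfg$pathogenic_allele_freqs)) {
    q <- cfg$pathogenic_allele_freqs[[g]]
    if (any(q < 0 | q > 1)) stop("pathogenic frequencies outside [0,1] for ", g)
    if (sum(q) > 1) stop("sum of pathogenic allele frequencies > 1 for ", g)
  }
  for (l in names(cfg$hla_allele_freqs)) {
    f <- cfg$hla_allele_freqs[[l]]
    if (abs(sum(f) - 1) > 1e-9) stop("HLA frequencies for ", l, " must sum to 1")
    if (any(f < 0)) stop("negative HLA frequency for ", l)
  }
  invisible(cfg)
}
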