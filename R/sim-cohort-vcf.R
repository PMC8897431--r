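#' Generate a multi-sample cohort VCF with planted genotype-quality truth
#'
#' Simulates biallelic SNV genotypes under Hardy-Weinberg at random
#' allele frequencies, with per-genotype depth drawn from a negative
#' binomial (overdispersed, as in real WGS).  A configured fraction of
#' genotypes is planted as fail-depth (FD: depth below `min_depth`) and
#' a configured fraction of heterozygotes as fail-balance (FB: alternate
#' allele fraction outside `het_balance`).  Every planted violation is
#' single-cause — a genotype fails depth or balance, never both — so the
#' emitted truth table is unambiguous and downstream flag recovery can
#' be scored exactly.
#'
#' @param cfg A [sim_config()] object.
#' @param min_depth Depth cutoff the FD plants fall below (default 8,
#'   matching [flag_config()]).
#' @param het_balance Heterozygote balance interval the FB plants fall
#'   outside (default `c(0.2, 0.8)`).
#' @param out_dir Optional output directory; writes `cohort.vcf.gz` and
#'   `genotype_flag_truth.tsv`.
#' @return List with `genotypes` (long data.frame: site_id, chrom, pos,
#'   sample_id, gt, dp, ad_ref, ad_alt, truth_flag), `vcf` (a
#'   [vcfR::vcfR] object), `truth` (data.frame site_id, sample_id,
#'   flag), and `paths` when `out_dir` is given.
#' @examples
#' sim <- generate_cohort_vcf(sim_config(seed = 1, n_samples = 4,
#'   n_sites = 10))
#' table(sim$truth$flag)
#' @export
generate_cohort_vcf <- function(cfg, min_depth = 8L,
                                het_balance = c(0.2, 0.8),
                                out_dir = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_samples < 2) stop("n_samples must be >= 2")
  r_fd <- cfg$low_depth_error_rate
  r_fb <- cfg$allele_balance_error_rate
  if (r_fd + r_fb > 1) stop("error rates sum above 1")
  if (min_depth >= cfg$depth_mean)
    warning("depth cutoff >= mean depth: most genotypes will fail depth")

  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  withr::with_seed(cfg$seed + 202L, {
    sites <- sim_site_positions(cfg$chromosome_lengths, cfg$n_sites)
    n <- cfg$n_sites * cfg$n_samples
    af <- rep(runif(cfg$n_sites, 0.05, 0.5), each = cfg$n_samples)
    a1 <- rbinom(n, 1, af)
    a2 <- rbinom(n, 1, af)
    gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    is_het <- a1 != a2

    u <- runif(n)
    flag <- rep("PASS", n)
    flag[u < r_fd] <- "FD"
    flag[is_het & u >= r_fd & u < r_fd + r_fb] <- "FB"

    dp <- rnbinom(n, size = cfg$depth_dispersion, mu = cfg$depth_mean)
    # PASS/FB genotypes must not fail depth: redraw the stragglers
    need <- which(flag != "FD" & dp < min_depth)
    for (i in seq_len(50)) {
      if (length(need) == 0) break
      dp[need] <- rnbinom(length(need), size = cfg$depth_dispersion,
                          mu = cfg$depth_mean)
      need <- need[dp[need] < min_depth]
    }
    dp[flag != "FD" & dp < min_depth] <- min_depth
    fd <- which(flag == "FD")
    dp[fd] <- sample.int(min_depth, length(fd), replace = TRUE) - 1L

    lo <- het_balance[1]; hi <- het_balance[2]
    frac <- numeric(n)
    safe <- is_het & flag != "FB"
    frac[safe] <- runif(sum(safe), lo + 0.1, hi - 0.1)
    fb <- which(flag == "FB")
    low_side <- runif(length(fb)) < 0.5
    ad_alt <- integer(n)
    ad_alt[safe] <- round(dp[safe] * frac[safe])
    ad_alt[fb[low_side]] <-
      floor(dp[fb[low_side]] * runif(sum(low_side), 0.02, lo - 0.02))
    ad_alt[fb[!low_side]] <-
      ceiling(dp[fb[!low_side]] * runif(sum(!low_side), hi + 0.02, 0.98))
    hom_alt <- !is_het & a1 == 1
    ad_alt[hom_alt] <- dp[hom_alt]
    ad_ref <- dp - ad_alt
  })

  genotypes <- data.frame(
    site_id = rep(sites$site_id, each = cfg$n_samples),
    chrom = rep(sites$chrom, each = cfg$n_samples),
    pos = rep(sites$pos, each = cfg$n_samples),
    sample_id = rep(samples, times = cfg$n_sites),
    gt = gt, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
    truth_flag = flag, stringsAsFactors = FALSE)
  truth <- genotypes[, c("site_id", "sample_id", "truth_flag")]
  names(truth)[3] <- "flag"
  vcf <- genotypes_to_vcfR(sites, genotypes, samples,
                           cfg$chromosome_lengths)
  out <- list(genotypes = genotypes, vcf = vcf, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(vcf = file.path(out_dir, "cohort.vcf.gz"),
               truth = file.path(out_dir, "genotype_flag_truth.tsv"))
    vcfR::write.vcf(vcf, paths[["vcf"]])
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

sim_site_positions <- function(lens, n_sites) {
  chrom <- sample(names(lens), n_sites, replace = TRUE,
                  prob = lens / sum(lens))
  pos <- vapply(chrom, function(ch) sample.int(lens[[ch]], 1), integer(1))
  ord <- order(match(chrom, names(lens)), pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(site_id = sprintf("site%05d", seq_len(n_sites)),
             chrom = chrom[ord], pos = pos[ord],
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

genotypes_to_vcfR <- function(sites, genotypes, samples, lens) {
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", names(lens),
                    as.integer(lens)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                   "Description=\"Allele depths\">"))
  fix <- cbind(CHROM = sites$chrom, POS = as.character(sites$pos),
               ID = sites$site_id, REF = sites$ref, ALT = sites$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  cell <- sprintf("%s:%d:%d,%d", genotypes$gt, genotypes$dp,
                  genotypes$ad_ref, genotypes$ad_alt)
  gt <- matrix(cell, nrow = nrow(sites), ncol = length(samples),
               byrow = TRUE, dimnames = list(NULL, samples))
  gt <- cbind(FORMAT = "GT:DP:AD", gt)
  methods::new("vcfR", meta = meta, fix = fix, gt = gt)
}
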