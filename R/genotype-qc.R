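#' Configuration for two-step genotype and site quality flagging
#'
#' The filter flags individual genotypes on depth of coverage and
#' allele balance, then flags each site on the proportion of flagged
#' genotypes.  The cutoffs are deliberate defaults, every one
#' configurable: a genotype fails depth (FD) below 8 reads; a
#' heterozygote fails balance (FB) when its alternate allele fraction
#' leaves [0.2, 0.8]; sites tier as vSR (reliable, <= 5% flagged
#' genotypes), vMR (<= 20%) or vUR (above).
#'
#' @param min_depth Minimum genotype depth (FD below this).
#' @param het_balance Numeric length-2: allowed heterozygote alternate
#'   allele fraction interval, inclusive at both ends.
#' @param site_tiers Named numeric vector of strictly increasing
#'   maximum flagged-genotype fractions, best tier first; the last tier
#'   must reach 1.
#' @param missingness_max Maximum tolerated fraction of missing
#'   genotypes per site; sites strictly above are removed.
#' @return A `flag_config` list.
#' @examples
#' flag_config()$site_tiers
#' @export
flag_config <- function(min_depth = 8L,
                        het_balance = c(0.2, 0.8),
                        site_tiers = c(vSR = 0.05, vMR = 0.20, vUR = 1),
                        missingness_max = 0.05) {
  stopifnot(length(het_balance) == 2,
            het_balance[1] >= 0, het_balance[1] < het_balance[2],
            het_balance[2] <= 1)
  if (any(diff(site_tiers) <= 0))
    stop("site_tiers thresholds must be strictly increasing")
  if (site_tiers[length(site_tiers)] < 1)
    stop("the worst tier must have threshold 1")
  structure(list(min_depth = as.integer(min_depth),
                 het_balance = het_balance,
                 site_tiers = site_tiers,
                 missingness_max = missingness_max),
            class = "flag_config")
}

#' Flag genotypes on depth of coverage and allele balance
#'
#' Vectorised first step of the two-step filter: a genotype is flagged
#' `FD` when its depth is below `cfg$min_depth` (missing depth counts
#' as FD), `FB` when it is heterozygous and its alternate allele
#' fraction `ad_alt / dp` lies outside the balance interval, and `PASS`
#' otherwise.  FD takes precedence over FB: without adequate depth the
#' balance evidence is meaningless.
#'
#' @param gt Character vector of diploid genotypes (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `"./."`; phased separators accepted).
#' @param dp Integer depth per genotype.
#' @param ad_alt Integer alternate-allele read count per genotype.
#' @param cfg A [flag_config()].
#' @return Character vector over `{"PASS", "FD", "FB"}`.
#' @examples
#' flag_genotypes(c("0/1", "0/1", "0/0"), dp = c(30, 30, 40),
#'                ad_alt = c(15, 2, 0), cfg = flag_config())
#' @export
flag_genotypes <- function(gt, dp, ad_alt, cfg = flag_config()) {
  n <- length(gt)
  stopifnot(length(dp) == n, length(ad_alt) == n)
  if (any(dp < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE))
    stop("negative DP or AD: malformed genotype record")
  flag <- rep("PASS", n)
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  het <- alleles1 != alleles2 & alleles1 != "." & alleles2 != "."
  het[is.na(het)] <- FALSE
  frac <- ad_alt / dp
  fb <- het & !is.na(frac) &
    (frac < cfg$het_balance[1] | frac > cfg$het_balance[2])
  flag[fb] <- "FB"
  fd <- is.na(dp) | dp < cfg$min_depth
  flag[fd] <- "FD"
  flag
}

#' Assign a site-quality tier from genotype flags
#'
#' Second step of the filter: the fraction of flagged (FD or FB)
#' genotypes at the site is mapped to the first tier whose threshold is
#' greater than or equal to it.  A clean site (no flagged genotypes)
#' gets the best tier (`vSR` by default); the mapping is monotone — a
#' larger flagged fraction never earns a better tier.
#'
#' @param flags Character vector of per-genotype flags at one site
#'   (output of [flag_genotypes()]).
#' @param cfg A [flag_config()].
#' @return Single tier label (name from `cfg$site_tiers`).
#' @examples
#' flag_site(c(rep("PASS", 94), rep("FD", 6)))
#' @export
flag_site <- function(flags, cfg = flag_config()) {
  if (length(flags) == 0) stop("empty call list at site")
  f <- mean(flags != "PASS")
  names(cfg$site_tiers)[which(cfg$site_tiers >= f)[1]]
}

#' Set flagged genotypes missing and drop high-missingness sites
#'
#' Applies the downstream filtering rule used before phasing: every FD
#' or FB genotype becomes missing (`"./."`), and a site is removed when
#' its resulting missing fraction strictly exceeds
#' `cfg$missingness_max` (5% by default).  Retained sites keep their
#' input order; the operation is idempotent.
#'
#' @param genotypes Long data.frame with columns `site_id`, `gt` and a
#'   flag column (default `flag`); one row per site x sample.
#' @param cfg A [flag_config()].
#' @param flag_col Name of the flag column.
#' @return List with `genotypes` (filtered data.frame; FD/FB rows now
#'   `gt == "./."` and flag `"PASS"` with missing genotype),
#'   `removed_sites` (character vector of dropped site ids).
#' @export
apply_missingness <- function(genotypes, cfg = flag_config(),
                              flag_col = "flag") {
  stopifnot(all(c("site_id", "gt", flag_col) %in% names(genotypes)))
  flagged <- genotypes[[flag_col]] %in% c("FD", "FB")
  genotypes$gt[flagged] <- "./."
  genotypes[[flag_col]][flagged] <- "PASS"
  miss <- genotypes$gt == "./."
  frac <- tapply(miss, genotypes$site_id, mean)
  drop <- names(frac)[frac > cfg$missingness_max]
  list(genotypes = genotypes[!(genotypes$site_id %in% drop), ,
                             drop = FALSE],
       removed_sites = drop)
}

#' Flag all genotypes and sites of a VCF
#'
#' Reads a multi-sample VCF (FORMAT fields GT, DP, AD), computes
#' per-genotype FD/FB/PASS flags and per-site tiers, and returns the
#' flat genotype table the rest of the filtering pipeline consumes.
#'
#' @param vcf Path to a VCF file, or a [vcfR::vcfR] object.
#' @param cfg A [flag_config()].
#' @return List with `genotypes` (data.frame: site_id, sample_id, gt,
#'   dp, ad_alt, flag) and `sites` (data.frame: site_id, tier).
#' @export
qc_flag_vcf <- function(vcf, cfg = flag_config()) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multiallelic records found: split sites into one ALT per line ",
         "before flagging")
  site_id <- fix[, "ID"]
  if (any(site_id == "." | is.na(site_id)))
    site_id <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad_alt <- matrix(as.integer(sub(".*,", "", ad)), nrow = nrow(ad))
  samples <- colnames(gt)
  long <- data.frame(
    site_id = rep(site_id, times = length(samples)),
    sample_id = rep(samples, each = length(site_id)),
    gt = gsub("|", "/", as.vector(gt), fixed = TRUE),
    dp = as.vector(dp), ad_alt = as.vector(ad_alt),
    stringsAsFactors = FALSE)
  long$flag <- flag_genotypes(long$gt, long$dp, long$ad_alt, cfg)
  tiers <- tapply(long$flag, long$site_id, flag_site, cfg = cfg)
  sites <- data.frame(site_id = site_id,
                      tier = unname(tiers[site_id]),
                      stringsAsFactors = FALSE)
  list(genotypes = long, sites = sites)
}

#' Configuration and inference for read-count based sex checks
#'
#' Sex is inferred from reads-per-million (CPM) mapped to the X
#' chromosome and to the male-specific region of Y (MSY), relative to
#' autosomal reads.  Reference levels: females cluster around 55,000
#' X CPM with MSY below 200 CPM; males around 27,500 X CPM with MSY
#' above 550 CPM.  Calls falling between the two MSY regimes are
#' returned as `ambiguous` rather than forced.
#'
#' @param female_x_cpm,male_x_cpm Reference X CPM levels.
#' @param female_msy_cpm_max Upper MSY CPM bound for a female call.
#' @param male_msy_cpm_min Lower MSY CPM bound for a male call.
#' @return A `sex_call_config` list.
#' @export
sex_call_config <- function(female_x_cpm = 55000, male_x_cpm = 27500,
                            female_msy_cpm_max = 200,
                            male_msy_cpm_min = 550) {
  stopifnot(female_msy_cpm_max < male_msy_cpm_min)
  structure(list(female_x_cpm = female_x_cpm, male_x_cpm = male_x_cpm,
                 female_msy_cpm_max = female_msy_cpm_max,
                 male_msy_cpm_min = male_msy_cpm_min),
            class = "sex_call_config")
}

#' @rdname sex_call_config
#' @param x_cpm,msy_cpm Non-negative CPM values (vectorised).
#' @param cfg A [sex_call_config()].
#' @return `infer_sex` returns a character vector over
#'   `{"female", "male", "ambiguous"}`.
#' @examples
#' infer_sex(c(55000, 27500, 40000), c(150, 600, 400))
#' @export
infer_sex <- function(x_cpm, msy_cpm, cfg = sex_call_config()) {
  stopifnot(all(x_cpm >= 0), all(msy_cpm >= 0))
  nearer_female <- abs(x_cpm - cfg$female_x_cpm) <
    abs(x_cpm - cfg$male_x_cpm)
  out <- rep("ambiguous", length(x_cpm))
  out[msy_cpm < cfg$female_msy_cpm_max & nearer_female] <- "female"
  out[msy_cpm > cfg$male_msy_cpm_min] <- "male"
  out
}
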