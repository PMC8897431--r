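#' Nei's unbiased gene diversity
#'
#' `H = n / (n - 1) * (1 - sum p_i^2)` for allele counts summing to
#' `n` gene copies: the probability that two gene copies drawn without
#' replacement differ, with the small-sample correction.
#'
#' @param counts Integer vector of allele counts (n = sum >= 2), or a
#'   table.
#' @return Gene diversity in `[0, 1]`; 0 for monomorphic data.
#' @examples
#' gene_diversity(c(50, 50))   # (100/99) * 0.5
#' @export
gene_diversity <- function(counts) {
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("gene diversity needs at least 2 gene copies")
  p <- counts / n
  h <- n / (n - 1) * (1 - sum(p^2))
  min(max(h, 0), 1)
}

#' Expected rarefied allele richness (hypergeometric closed form)
#'
#' Expected number of distinct alleles in a subsample of `m` gene
#' copies drawn without replacement from counts `n_a`:
#' `E[k] = sum_a (1 - C(n - n_a, m) / C(n, m))`.
#'
#' @param counts Allele counts (total `n >= m`).
#' @param m Standardised subsample size in gene copies.
#' @return Expected richness (numeric).
#' @export
rarefied_richness <- function(counts, m) {
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  n <- sum(counts)
  stopifnot(m >= 1, m <= n)
  sum(1 - exp(lchoose(n - counts, m) - lchoose(n, m)))
}

#' Resampled diversity statistics for one HLA locus
#'
#' Draws `n_batches` batches of `batch_size` individuals without
#' replacement from the cohort and averages, across batches, the
#' number of distinct alleles (allele richness), the number of
#' distinct full-sequence haplotypes, and Nei's unbiased gene
#' diversity.  With a fixed seed the result is reproducible.
#'
#' @param genotypes data.frame with `sample_id`, `locus`, `allele_1`,
#'   `allele_2` (one row per sample per locus).
#' @param locus Locus to resample.
#' @param batch_size Individuals per batch (default 50, i.e. 100 gene
#'   copies).
#' @param n_batches Number of batches (default 5000).
#' @param seed Seed for the resampling stream.
#' @param catalog Optional data.frame mapping `allele_id` to
#'   `sequence` (see [generate_hla_cohort()]); when given, haplotype
#'   counts are at full-sequence identity, otherwise alleles and
#'   haplotypes coincide.
#' @return List: `locus`, `gene_diversity`, `allele_richness`,
#'   `allele_richness_sd` (between-batch standard deviation),
#'   `mean_haplotypes`, `n_batches`, `batch_size`, `seed`.
#' @export
resample_diversity <- function(genotypes, locus, batch_size = 50,
                               n_batches = 5000, seed = 1L,
                               catalog = NULL) {
  g <- genotypes[genotypes$locus == locus, , drop = FALSE]
  if (nrow(g) == 0) stop("no genotypes for locus ", locus)
  if (nrow(g) < batch_size)
    stop("cohort smaller than batch_size at ", locus)
  alleles <- cbind(g$allele_1, g$allele_2)
  if (!is.null(catalog)) {
    seq_of <- setNames(catalog$sequence, catalog$allele_id)
    haps <- matrix(seq_of[alleles], nrow = nrow(alleles))
  } else {
    haps <- alleles
  }
  withr::with_seed(seed, {
    rich <- numeric(n_batches)
    nhap <- numeric(n_batches)
    div <- numeric(n_batches)
    for (b in seq_len(n_batches)) {
      i <- sample.int(nrow(g), batch_size)
      a <- c(alleles[i, ])
      rich[b] <- length(unique(a))
      nhap[b] <- length(unique(c(haps[i, ])))
      div[b] <- gene_diversity(table(a))
    }
  })
  list(locus = locus, gene_diversity = mean(div),
       allele_richness = mean(rich),
       allele_richness_sd = stats::sd(rich),
       mean_haplotypes = mean(nhap),
       n_batches = n_batches, batch_size = batch_size, seed = seed)
}

#' Detect cohort alleles absent from a reference registry
#'
#' An allele is full-sequence novel when its normalised full sequence
#' (uppercased, gaps removed) is absent from the registry, and protein
#' novel when its CDS translation is absent from the registry's
#' translations.  A novel protein implies a novel full sequence, so
#' the protein-novel set is nested in the full-sequence-novel set.
#' When genotypes are supplied, the fractions of individuals carrying
#' at least one novel allele at each level are reported.
#'
#' @param catalog data.frame of cohort alleles: `locus`, `allele_id`,
#'   `sequence`, `protein`.
#' @param registry data.frame of known alleles: `locus`, `sequence`,
#'   `protein`.
#' @param genotypes Optional data.frame (`sample_id`, `locus`,
#'   `allele_1`, `allele_2`) for carrier fractions.
#' @return List: `full_sequence_novel` and `protein_novel`
#'   (data.frames `locus`, `allele_id`), `fraction_sequence_novel`
#'   and `fraction_protein_novel` (or `NA` without genotypes).
#' @export
novel_alleles <- function(catalog, registry, genotypes = NULL) {
  norm <- function(s) toupper(gsub("[-.*]", "", s))
  if (nrow(registry) == 0)
    warning("empty registry: every cohort allele is reported novel")
  seq_novel <- logical(nrow(catalog))
  prot_novel <- logical(nrow(catalog))
  for (l in unique(catalog$locus)) {
    i <- catalog$locus == l
    reg <- registry[registry$locus == l, , drop = FALSE]
    seq_novel[i] <- !(norm(catalog$sequence[i]) %in% norm(reg$sequence))
    prot_novel[i] <- !(norm(catalog$protein[i]) %in% norm(reg$protein))
  }
  # a known full sequence implies a known protein
  prot_novel <- prot_novel & seq_novel
  res <- list(
    full_sequence_novel = catalog[seq_novel, c("locus", "allele_id")],
    protein_novel = catalog[prot_novel, c("locus", "allele_id")],
    fraction_sequence_novel = NA_real_,
    fraction_protein_novel = NA_real_)
  if (!is.null(genotypes)) {
    carrier_frac <- function(novel) {
      key <- paste(novel$locus, novel$allele_id)
      hit <- paste(genotypes$locus, genotypes$allele_1) %in% key |
        paste(genotypes$locus, genotypes$allele_2) %in% key
      carriers <- unique(genotypes$sample_id[hit])
      length(carriers) / length(unique(genotypes$sample_id))
    }
    res$fraction_sequence_novel <- carrier_frac(res$full_sequence_novel)
    res$fraction_protein_novel <- carrier_frac(res$protein_novel)
  }
  res
}

#' Known vs newly described variants across the MAF spectrum
#'
#' Bins variants by minor allele frequency and reports, per bin, the
#' proportions of previously described and newly described variants.
#'
#' @param variants data.frame with `variant_id` and `maf` (in
#'   `[0, 0.5]`).
#' @param known_ids Character vector of previously described variant
#'   ids.
#' @param maf_bins Bin edges over `[0, 0.5]`.
#' @return data.frame: `bin`, `n`, `n_known`, `n_new`,
#'   `proportion_known`, `proportion_new`.
#' @export
variant_spectrum <- function(variants, known_ids,
                             maf_bins = c(0, 0.01, 0.05, 0.1, 0.25,
                                          0.5)) {
  if (any(variants$maf < 0 | variants$maf > 0.5))
    stop("MAF outside [0, 0.5]: not a minor allele frequency")
  bin <- cut(variants$maf, maf_bins, include.lowest = TRUE)
  known <- variants$variant_id %in% known_ids
  do.call(rbind, lapply(levels(bin), function(b) {
    i <- bin == b
    n <- sum(i)
    data.frame(bin = b, n = n, n_known = sum(known[i]),
               n_new = sum(!known[i]),
               proportion_known = if (n == 0) NA_real_
                                  else sum(known[i]) / n,
               proportion_new = if (n == 0) NA_real_
                                else sum(!known[i]) / n,
               stringsAsFactors = FALSE)
  }))
}
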