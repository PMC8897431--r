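#' Simulate genotypes at pathogenic sites under Hardy-Weinberg
#'
#' Draws, for each gene in `cfg$pathogenic_allele_freqs` and each of `n`
#' individuals, two independent haplotypes.  Each haplotype carries at
#' most one pathogenic allele of the gene (alleles are mutually
#' exclusive on a haplotype, as in a curated panel): allele `i` with
#' probability `q_i`, otherwise the benign reference allele.  Compound
#' heterozygotes (two different pathogenic alleles) arise naturally.
#' Alleles are coded as integers, 0 for the reference, so tables of
#' millions of draws stay small.
#'
#' @param cfg A [sim_config()] object (uses `pathogenic_allele_freqs`).
#' @param n Number of diploid individuals to draw per gene (defaults to
#'   `cfg$n_samples`).
#' @param genes Genes to simulate (default: all configured genes).
#' @param out_dir Optional output directory; writes
#'   `hwe_genotypes.tsv`.
#' @return List with `genotypes` (data.frame: gene, individual, a1, a2
#'   integer allele codes), `allele_ids` (named list gene -> allele
#'   labels), `truth` (data.frame gene, q_total) and `paths` when
#'   `out_dir` is given.
#' @examples
#' sim <- generate_hwe_genotypes(sim_config(seed = 1, n_samples = 100),
#'                               genes = "CFTR")
#' mean(sim$genotypes$a1 > 0 & sim$genotypes$a2 > 0)
#' @export
generate_hwe_genotypes <- function(cfg, n = cfg$n_samples,
                                   genes = names(cfg$pathogenic_allele_freqs),
                                   out_dir = NULL) {
  validate_sim_config(cfg)
  freqs <- cfg$pathogenic_allele_freqs[genes]
  for (g in genes) {
    qt <- sum(freqs[[g]])
    if (qt > 1) stop("total pathogenic frequency > 1 for ", g)
    if (qt > 0.5)
      warning("total pathogenic frequency above 0.5 for ", g,
              "; incidence math assumes rare alleles")
  }
  withr::with_seed(cfg$seed + 505L, {
    genotypes <- do.call(rbind, lapply(genes, function(g) {
      q <- freqs[[g]]
      p <- c(1 - sum(q), q)
      a1 <- sample.int(length(p), n, replace = TRUE, prob = p) - 1L
      a2 <- sample.int(length(p), n, replace = TRUE, prob = p) - 1L
      data.frame(gene = g, individual = seq_len(n), a1 = a1, a2 = a2,
                 stringsAsFactors = FALSE)
    }))
  })
  truth <- data.frame(gene = genes,
                      q_total = vapply(freqs, sum, numeric(1)),
                      stringsAsFactors = FALSE)
  out <- list(genotypes = genotypes,
              allele_ids = lapply(freqs, function(q)
                if (is.null(names(q))) as.character(seq_along(q))
                else names(q)),
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genotypes = file.path(out_dir, "hwe_genotypes.tsv"))
    write.table(genotypes, paths[["genotypes"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$paths <- paths
  }
  out
}
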