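#' Generate a synthetic HLA cohort with a partially withheld registry
#'
#' Builds, for each configured locus, an allele pool of full gene
#' sequences (two exons flanking an intron plus a trailing UTR; the
#' exons form the CDS) where each allele differs from the locus base
#' sequence by allele-specific substitutions.  The last two alleles of
#' every locus are an engineered pair that is identical in CDS
#' translation but differs by one intronic base, so full-sequence and
#' protein novelty can diverge.  Per-sample two-allele genotypes are
#' drawn from the configured frequency spectra.  A configurable
#' fraction of whole alleles — always including the intron-variant twin
#' — is withheld from the emulated registry and marked in the truth
#' table as `protein_novel` (its translation is absent from the
#' registry) or `sequence_novel` (translation present, full sequence
#' absent).
#'
#' @param cfg A [sim_config()] object (uses `hla_allele_freqs` and
#'   `registry_withheld_fraction`).
#' @param out_dir Optional output directory; writes
#'   `hla_genotypes.tsv`, `hla_alleles.fa`, `hla_registry.fa` and
#'   `hla_novel_truth.tsv`.
#' @return List with `genotypes` (data.frame: sample_id, locus,
#'   allele_1, allele_2), `catalog` (data.frame: locus, allele_id,
#'   sequence, cds, protein, frequency), `registry` (catalog subset
#'   present in the registry), `truth` (data.frame: locus, allele_id,
#'   level), and `paths` when `out_dir` is given.
#' @examples
#' sim <- generate_hla_cohort(sim_config(seed = 1, n_samples = 30))
#' table(sim$truth$level)
#' @export
generate_hla_cohort <- function(cfg, out_dir = NULL) {
  validate_sim_config(cfg)
  loci <- names(cfg$hla_allele_freqs)
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  exon_len <- 300L   # two exons of 300 nt -> 600 nt CDS, 200 aa
  intron_len <- 300L
  utr_len <- 200L

  withr::with_seed(cfg$seed + 606L, {
    catalog <- do.call(rbind, lapply(loci, function(l) {
      f <- cfg$hla_allele_freqs[[l]]
      k <- length(f)
      ids <- if (is.null(names(f))) sprintf("%s*%02d", l, seq_len(k))
             else names(f)
      L <- 2L * exon_len + intron_len + utr_len
      base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      cds_idx <- c(seq_len(exon_len),
                   exon_len + intron_len + seq_len(exon_len))
      intron_idx <- exon_len + seq_len(intron_len)
      seqs <- character(k)
      seqs[1] <- paste(base, collapse = "")
      for (j in seq_len(k)[-1]) {
        if (j < k || k == 2) {
          seqs[j] <- make_allele(base, cds_idx, j)
        } else {
          # intron-variant twin of allele k-1: same CDS, one intron change
          s <- strsplit(seqs[k - 1L], "")[[1]]
          at <- sample(intron_idx, 1)
          s[at] <- sample(setdiff(c("A", "C", "G", "T"), s[at]), 1)
          seqs[j] <- paste(s, collapse = "")
        }
      }
      cds <- substr_idx(seqs, cds_idx)
      protein <- vapply(cds, function(x)
        as.character(Biostrings::translate(Biostrings::DNAString(x))),
        character(1), USE.NAMES = FALSE)
      data.frame(locus = l, allele_id = ids, sequence = seqs, cds = cds,
                 protein = protein, frequency = as.numeric(f),
                 stringsAsFactors = FALSE)
    }))

    genotypes <- do.call(rbind, lapply(loci, function(l) {
      f <- cfg$hla_allele_freqs[[l]]
      ids <- catalog$allele_id[catalog$locus == l]
      data.frame(sample_id = rep(samples, each = 1),
                 locus = l,
                 allele_1 = sample(ids, cfg$n_samples, replace = TRUE,
                                   prob = f),
                 allele_2 = sample(ids, cfg$n_samples, replace = TRUE,
                                   prob = f),
                 stringsAsFactors = FALSE)
    }))

    withheld <- do.call(rbind, lapply(loci, function(l) {
      ids <- catalog$allele_id[catalog$locus == l]
      n_wh <- round(cfg$registry_withheld_fraction * length(ids))
      if (n_wh == 0) return(NULL)
      twin <- ids[length(ids)]
      # the twin's CDS partner stays in the registry so the twin is
      # sequence-novel, never protein-novel
      partner <- ids[length(ids) - 1L]
      extra <- setdiff(ids, c(twin, partner))
      n_extra <- min(n_wh - 1L, length(extra))
      wh <- c(twin, sample(extra, n_extra))
      data.frame(locus = l, allele_id = wh, stringsAsFactors = FALSE)
    }))
  })

  is_wh <- interaction(catalog$locus, catalog$allele_id) %in%
    (if (is.null(withheld)) character(0)
     else interaction(withheld$locus, withheld$allele_id))
  registry <- catalog[!is_wh, ]
  truth <- if (is.null(withheld)) {
    data.frame(locus = character(0), allele_id = character(0),
               level = character(0), stringsAsFactors = FALSE)
  } else {
    wh_cat <- catalog[is_wh, ]
    lvl <- vapply(seq_len(nrow(wh_cat)), function(i) {
      reg_prot <- registry$protein[registry$locus == wh_cat$locus[i]]
      if (wh_cat$protein[i] %in% reg_prot) "sequence_novel"
      else "protein_novel"
    }, character(1))
    data.frame(locus = wh_cat$locus, allele_id = wh_cat$allele_id,
               level = lvl, stringsAsFactors = FALSE)
  }

  out <- list(genotypes = genotypes, catalog = catalog,
              registry = registry, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genotypes = file.path(out_dir, "hla_genotypes.tsv"),
               alleles = file.path(out_dir, "hla_alleles.fa"),
               registry = file.path(out_dir, "hla_registry.fa"),
               truth = file.path(out_dir, "hla_novel_truth.tsv"))
    write.table(genotypes, paths[["genotypes"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_hla_fasta(catalog, paths[["alleles"]])
    write_hla_fasta(registry, paths[["registry"]])
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

make_allele <- function(base, cds_idx, j) {
  if (j > 1) {
    at <- sample(cds_idx, j)
    base[at] <- vapply(base[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(base, collapse = "")
}

substr_idx <- function(seqs, idx) {
  vapply(seqs, function(s)
    paste(strsplit(s, "")[[1]][idx], collapse = ""),
    character(1), USE.NAMES = FALSE)
}

write_hla_fasta <- function(catalog, path) {
  seqs <- Biostrings::DNAStringSet(catalog$sequence)
  names(seqs) <- sprintf("%s|%s", catalog$locus, catalog$allele_id)
  Biostrings::writeXStringSet(seqs, path)
}
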