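#' Generate a toy reference genome, gene models and low-complexity mask
#'
#' Emits a random DNA reference (one sequence per configured
#' chromosome), GENCODE-style gene models with proper feature nesting
#' (CDS within exon within transcript, UTRs at both ends), and a BED
#' mask covering `mask_fraction` of each chromosome in 1-kb blocks.
#' Everything is deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Optional directory; when given, writes `reference.fa`,
#'   `genes.gff3` and `mask.bed` there.
#' @return List with `genome` (a [Biostrings::DNAStringSet]), `genes`
#'   (a [GenomicRanges::GRanges] of GFF3 features), `mask` (GRanges),
#'   and `paths` (named character, when `out_dir` given).
#' @examples
#' ref <- generate_reference(sim_config(seed = 1, n_samples = 5,
#'   chromosome_lengths = c(chr1 = 20000)))
#' names(ref$genome)
#' @export
generate_reference <- function(cfg, out_dir = NULL) {
  validate_sim_config(cfg)
  lens <- cfg$chromosome_lengths
  if (any(lens < 10000))
    stop("chromosome lengths must be >= 10 kb for the toy reference")
  withr::with_seed(cfg$seed + 101L, {
    genome <- Biostrings::DNAStringSet(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1)))
    names(genome) <- names(lens)
    genes <- sim_gene_models(lens)
    mask <- sim_mask(lens, cfg$mask_fraction)
  })
  out <- list(genome = genome, genes = genes, mask = mask)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(out_dir, "reference.fa"),
               gff3 = file.path(out_dir, "genes.gff3"),
               bed = file.path(out_dir, "mask.bed"))
    Biostrings::writeXStringSet(genome, paths[["fasta"]])
    rtracklayer::export.gff3(genes, paths[["gff3"]])
    rtracklayer::export.bed(mask, paths[["bed"]])
    out$paths <- paths
  }
  out
}

# One gene per ~50 kb slot; 3 exons, UTRs at both CDS ends.  Intervals
# are built so that CDS subset-of exon subset-of transcript holds by
# construction.
sim_gene_models <- function(lens) {
  feats <- list()
  gi <- 0L
  for (chrom in names(lens)) {
    L <- lens[[chrom]]
    n_genes <- max(1L, floor(L / 50000))
    slot <- floor(L / n_genes)
    for (k in seq_len(n_genes)) {
      gi <- gi + 1L
      gene_id <- sprintf("GENE%04d", gi)
      tx_id <- sprintf("TX%04d", gi)
      s <- (k - 1L) * slot + sample(500:2000, 1)
      exon_w <- sample(300:700, 3, replace = TRUE)
      intron_w <- sample(500:1200, 2, replace = TRUE)
      e1s <- s
      e1e <- e1s + exon_w[1] - 1L
      e2s <- e1e + intron_w[1] + 1L
      e2e <- e2s + exon_w[2] - 1L
      e3s <- e2e + intron_w[2] + 1L
      e3e <- e3s + exon_w[3] - 1L
      utr5 <- 150L
      utr3 <- 150L
      df <- data.frame(
        start = c(e1s, e1s, e1s, e2s, e3s,
                  e1s, e1s + utr5, e2s, e3s, e3e - utr3 + 1L),
        end = c(e3e, e3e, e1e, e2e, e3e,
                e1s + utr5 - 1L, e1e, e2e, e3e - utr3, e3e),
        type = c("gene", "mRNA", "exon", "exon", "exon",
                 "five_prime_UTR", "CDS", "CDS", "CDS", "three_prime_UTR"),
        stringsAsFactors = FALSE)
      df$chrom <- chrom
      df$ID <- c(gene_id, tx_id, paste0(tx_id, ".e", 1:3),
                 paste0(tx_id, ".u5"), paste0(tx_id, ".c", 1:3),
                 paste0(tx_id, ".u3"))
      df$Parent <- c(NA, gene_id, rep(tx_id, 8))
      df$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
      feats[[length(feats) + 1L]] <- df
    }
  }
  all <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(all$chrom,
                               IRanges::IRanges(all$start, all$end),
                               strand = "+")
  S4Vectors::mcols(gr)$type <- all$type
  S4Vectors::mcols(gr)$ID <- all$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(all$Parent), "", all$Parent)
  S4Vectors::mcols(gr)$phase <- all$phase
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr
}

sim_mask <- function(lens, fraction) {
  if (fraction == 0) {
    return(GenomicRanges::GRanges(seqlengths = lens))
  }
  pieces <- lapply(names(lens), function(chrom) {
    L <- lens[[chrom]]
    n_blocks <- floor(fraction * L / 1000)
    if (n_blocks == 0) return(NULL)
    starts <- sort(sample(seq(1L, L - 1000L, by = 1000L), n_blocks))
    data.frame(chrom = chrom, start = starts, stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, Filter(Negate(is.null), pieces))
  gr <- GenomicRanges::GRanges(blocks$chrom,
                               IRanges::IRanges(blocks$start,
                                                width = 1000))
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr
}
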