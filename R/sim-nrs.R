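#' Generate synthetic non-reference contigs with anchoring evidence
#'
#' Emits `n_nrs_contigs` truth-anchored contigs, each supported by one
#' of the three localization evidence sources (partial reference
#' alignment, discordant read pairs, linked-read barcodes, assigned
#' round-robin), plus planted negatives: a contig shorter than the
#' 200-bp retention cutoff, a contig with a >= 95%-identity reference
#' alignment, a contig whose read coverage is out of the 7.5-100x
#' presence range in every sample, a contig supported by a single
#' barcode (which the >= 2-barcode rule must leave unplaced), and a
#' contig whose only anchor target is the mitochondrial sequence.
#' Barcode evidence follows the 1-kb window model: supporting barcodes
#' fall in the window containing the true anchor, and a configurable
#' fraction (`barcode_noise_rate`) is displaced to random windows.
#'
#' Partial-map alignments are emitted with 90% block identity so that
#' genuinely non-reference contigs survive the library's >= 95%-identity
#' redundancy filter; the planted redundant decoy aligns at 96%.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Optional output directory; writes `nrs_contigs.fa`,
#'   `nrs_alignments.paf`, `nrs_coverage.tsv`, `nrs_evidence.tsv` and
#'   `nrs_anchor_truth.tsv`.
#' @return List with `contigs` (data.frame contig_id, length),
#'   `sequences` (DNAStringSet), `paf` (data.frame, PAF columns),
#'   `coverage` (long data.frame contig_id, sample_id, depth),
#'   `evidence` (data.frame contig_id, kind, sample_id, chrom, pos,
#'   barcode), `truth` (data.frame contig_id, label, chrom, pos,
#'   evidence_kind), and `paths` when `out_dir` is given.
#' @examples
#' sim <- generate_nrs_evidence(sim_config(seed = 1, n_samples = 5,
#'   n_nrs_contigs = 6))
#' table(sim$truth$label)
#' @export
generate_nrs_evidence <- function(cfg, out_dir = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_nrs_contigs < 1) stop("n_nrs_contigs must be >= 1")
  lens <- cfg$chromosome_lengths
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  n <- cfg$n_nrs_contigs
  kinds <- rep(c("partial_map", "discordant_pair", "barcode"),
               length.out = n)

  withr::with_seed(cfg$seed + 404L, {
    anchors <- sim_grid_positions(lens, n + 2L)
    mito_anchor <- anchors[n + 1L, ]
    single_anchor <- anchors[n + 2L, ]
    contigs <- data.frame(
      contig_id = sprintf("nrs%04d", seq_len(n)),
      length = sample(600:2000, n, replace = TRUE),
      stringsAsFactors = FALSE)
    extras <- data.frame(
      contig_id = c("decoy_short", "decoy_identity", "decoy_coverage",
                    "single_barcode", "mito_target"),
      length = c(180L, 400L, 500L, 700L, 650L),
      stringsAsFactors = FALSE)
    all_contigs <- rbind(contigs, extras)
    sequences <- Biostrings::DNAStringSet(vapply(all_contigs$length,
      function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""),
      character(1)))
    names(sequences) <- all_contigs$contig_id

    # coverage: each real contig present (7.5-100x) in >= 1 sample
    cov <- do.call(rbind, lapply(seq_len(nrow(all_contigs)), function(i) {
      id <- all_contigs$contig_id[i]
      if (id == "decoy_coverage") {
        depth <- rep(3, cfg$n_samples)
      } else {
        k <- sample.int(cfg$n_samples, 1)
        depth <- runif(cfg$n_samples, 0, 5)
        depth[sample.int(cfg$n_samples, k)] <- runif(k, 10, 60)
      }
      data.frame(contig_id = id, sample_id = samples,
                 depth = round(depth, 2), stringsAsFactors = FALSE)
    }))

    paf <- NULL
    evidence <- NULL
    for (i in seq_len(n)) {
      id <- contigs$contig_id[i]
      L <- contigs$length[i]
      ch <- anchors$chrom[i]
      pos <- anchors$pos[i]
      if (kinds[i] == "partial_map") {
        paf <- rbind(paf, sim_partial_paf(id, L, ch, lens[[ch]], pos))
      } else if (kinds[i] == "discordant_pair") {
        mates <- pmax(1L, pos + sample(-400:400, 5, replace = TRUE))
        evidence <- rbind(evidence, data.frame(
          contig_id = id, kind = "discordant_pair",
          sample_id = sample(samples, 5, replace = TRUE),
          chrom = ch, pos = mates, barcode = NA_character_,
          stringsAsFactors = FALSE))
      } else {
        nb <- sample(3:5, 1)
        bpos <- floor((pos - 1) / 1000) * 1000 +
          sample.int(1000L, nb, replace = TRUE)
        noisy <- runif(nb) < cfg$barcode_noise_rate
        bpos[noisy] <- vapply(which(noisy), function(z)
          sample.int(lens[[ch]], 1), integer(1))
        evidence <- rbind(evidence, data.frame(
          contig_id = id, kind = "barcode",
          sample_id = sample(samples, nb, replace = TRUE),
          chrom = ch, pos = bpos,
          barcode = sprintf("%s_bc%02d", id, seq_len(nb)),
          stringsAsFactors = FALSE))
      }
    }
    # planted negatives
    paf <- rbind(paf,
      data.frame(query_id = "decoy_identity", query_len = 400L,
                 query_start = 0L, query_end = 400L, strand = "+",
                 chrom = names(lens)[1], target_len = lens[[1]],
                 target_start = 5000L, target_end = 5400L,
                 matching_bases = 384L, block_len = 400L, mapq = 60L,
                 stringsAsFactors = FALSE),
      sim_partial_paf("mito_target", 650L, "chrM", 16569, mito_anchor$pos))
    evidence <- rbind(evidence, data.frame(
      contig_id = "single_barcode", kind = "barcode",
      sample_id = samples[1], chrom = single_anchor$chrom,
      pos = single_anchor$pos, barcode = "single_bc01",
      stringsAsFactors = FALSE))
  })

  truth <- rbind(
    data.frame(contig_id = contigs$contig_id, label = "anchored",
               chrom = anchors$chrom[seq_len(n)],
               pos = anchors$pos[seq_len(n)], evidence_kind = kinds,
               stringsAsFactors = FALSE),
    data.frame(contig_id = c("decoy_short", "decoy_identity",
                             "decoy_coverage", "single_barcode",
                             "mito_target"),
               label = c("discard_too_short", "discard_reference_identity",
                         "discard_coverage", "unplaced",
                         "suppressed_target"),
               chrom = NA, pos = NA,
               evidence_kind = c(NA, NA, NA, "barcode", "partial_map"),
               stringsAsFactors = FALSE))

  out <- list(contigs = all_contigs, sequences = sequences, paf = paf,
              coverage = cov, evidence = evidence, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(fasta = file.path(out_dir, "nrs_contigs.fa"),
               paf = file.path(out_dir, "nrs_alignments.paf"),
               coverage = file.path(out_dir, "nrs_coverage.tsv"),
               evidence = file.path(out_dir, "nrs_evidence.tsv"),
               truth = file.path(out_dir, "nrs_anchor_truth.tsv"))
    Biostrings::writeXStringSet(sequences, paths[["fasta"]])
    write_paf(paf, paths[["paf"]])
    write.table(cov, paths[["coverage"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(evidence, paths[["evidence"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

# Head of the contig aligns (at 90% block identity), the >= 200 bp tail
# does not; the clip boundary on the target is the planted anchor.
sim_partial_paf <- function(id, L, chrom, chrom_len, anchor) {
  qend <- L - max(200L, round(0.4 * L))
  tstart <- max(0L, anchor - qend)
  data.frame(query_id = id, query_len = L, query_start = 0L,
             query_end = qend, strand = "+", chrom = chrom,
             target_len = chrom_len, target_start = tstart,
             target_end = anchor, matching_bases = round(0.9 * qend),
             block_len = qend, mapq = 60L, stringsAsFactors = FALSE)
}

#' Read and write PAF alignment tables
#'
#' Minimal readers/writers for the 12 mandatory PAF columns (tab
#' separated, no header).
#'
#' @param path File path.
#' @return `read_paf` returns a data.frame with columns `query_id`,
#'   `query_len`, `query_start`, `query_end`, `strand`, `chrom`,
#'   `target_len`, `target_start`, `target_end`, `matching_bases`,
#'   `block_len`, `mapq`.
#' @export
read_paf <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:12]
  names(df) <- c("query_id", "query_len", "query_start", "query_end",
                 "strand", "chrom", "target_len", "target_start",
                 "target_end", "matching_bases", "block_len", "mapq")
  df
}

#' @rdname read_paf
#' @param paf A PAF data.frame as returned by [read_paf()].
#' @export
write_paf <- function(paf, path) {
  write.table(paf, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}
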