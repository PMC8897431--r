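MEI_CLASSES <- c("Alu", "L1", "SVA", "HERV")

#' Filter configuration for MEI calls
#'
#' Two filtering stages are applied to MELT-style calls.  The base
#' stage drops calls (i) not marked PASS by the caller, (ii) inserted
#' in a low-complexity region, and (iii) showing more discordant read
#' pairs than expected — operationalised as an absolute cap, defaulting
#' to twice the median discordant-pair count of the input calls.  The
#' private stage, applied to candidate cohort-private and singleton
#' events, additionally requires the top evidence tier (ASSESS 5), a
#' defined target-site duplication, and more than 2 split reads
#' defining the insertion point.
#'
#' @param require_pass Drop non-PASS calls in the base stage.
#' @param low_complexity_mask `GRanges` of masked regions (e.g. an
#'   imported BED), or `NULL` for no mask.
#' @param max_discordant_pairs Absolute cap on discordant pairs;
#'   `NULL` means 2 x median of the calls being filtered.
#' @param assess_equals,tsd_required,min_split_reads_exclusive
#'   Private-stage rules: required ASSESS score, whether a TSD must be
#'   defined, and the exclusive lower bound on split reads.
#' @return A `mei_filter_config` list.
#' @export
mei_filter_config <- function(require_pass = TRUE,
                              low_complexity_mask = NULL,
                              max_discordant_pairs = NULL,
                              assess_equals = 5L,
                              tsd_required = TRUE,
                              min_split_reads_exclusive = 2L) {
  structure(list(require_pass = require_pass,
                 low_complexity_mask = low_complexity_mask,
                 max_discordant_pairs = max_discordant_pairs,
                 assess_equals = as.integer(assess_equals),
                 tsd_required = tsd_required,
                 min_split_reads_exclusive =
                   as.integer(min_split_reads_exclusive)),
            class = "mei_filter_config")
}

#' Filter MEI calls (base or private stage)
#'
#' @param calls data.frame of calls: `sample_id`, `element_class`,
#'   `chrom`, `pos` (1-based insertion point), `filter`, `assess`,
#'   `tsd`, `split_reads`, `discordant_pairs`, `genotype`.
#' @param cfg A [mei_filter_config()].
#' @param stage `"base"` or `"private"` (private implies base).
#' @return The retained subset of `calls`.
#' @examples
#' calls <- data.frame(sample_id = "S1", element_class = "Alu",
#'   chrom = "chr1", pos = 100, filter = c("PASS", "lc"), assess = 5,
#'   tsd = TRUE, split_reads = 4, discordant_pairs = 1,
#'   genotype = "0/1")
#' nrow(filter_mei_calls(calls, stage = "base"))
#' @export
filter_mei_calls <- function(calls, cfg = mei_filter_config(),
                             stage = c("base", "private")) {
  stage <- match.arg(stage)
  unknown <- setdiff(unique(calls$element_class), MEI_CLASSES)
  if (length(unknown) > 0)
    stop("unknown element class: ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(calls))
  if (cfg$require_pass) keep <- keep & calls$filter == "PASS"
  if (!is.null(cfg$low_complexity_mask) &&
      length(cfg$low_complexity_mask) > 0) {
    pts <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$pos, calls$pos))
    keep <- keep & !IRanges::overlapsAny(pts, cfg$low_complexity_mask)
  }
  cap <- cfg$max_discordant_pairs
  if (is.null(cap)) cap <- 2 * median(calls$discordant_pairs)
  keep <- keep & calls$discordant_pairs <= cap
  if (stage == "private") {
    keep <- keep & calls$assess == cfg$assess_equals
    if (cfg$tsd_required) keep <- keep & calls$tsd
    keep <- keep & calls$split_reads > cfg$min_split_reads_exclusive
  }
  calls[keep, , drop = FALSE]
}

#' Merge per-sample MEI calls into nonredundant cohort loci
#'
#' Single-linkage clustering per (chromosome, element class): two calls
#' belong to one event when they are the same element type on the same
#' chromosome within `tolerance_bp` of each other (chains longer than
#' the tolerance are allowed).  Only like elements merge — an Alu and
#' an L1 at the same position are separate events.  The representative
#' position is the minimum position in the cluster; allele counts use
#' genotype dosage (het = 1, hom = 2, maximum per carrier).  The
#' result is invariant to the input row order.
#'
#' @param calls Filtered call data.frame (see [filter_mei_calls()]).
#' @param n_samples Cohort size, for allele frequencies.
#' @param tolerance_bp Positional tolerance in bp (default 20).
#' @return data.frame of loci: `locus_index`, `element_class`, `chrom`,
#'   `representative_pos`, `carriers` (comma-joined sample ids),
#'   `n_carriers`, `allele_count`, `allele_frequency`.
#' @examples
#' calls <- data.frame(sample_id = c("S1", "S2"),
#'   element_class = "Alu", chrom = "chr1", pos = c(1000, 1019),
#'   genotype = "0/1")
#' merge_mei_loci(calls, n_samples = 2)
#' @export
merge_mei_loci <- function(calls, n_samples, tolerance_bp = 20) {
  stopifnot(all(c("sample_id", "element_class", "chrom", "pos",
                  "genotype") %in% names(calls)))
  if (nrow(calls) == 0) stop("no calls to merge")
  ord <- order(calls$element_class, calls$chrom, calls$pos,
               calls$sample_id)
  x <- calls[ord, , drop = FALSE]
  grp <- paste(x$element_class, x$chrom, sep = "\r")
  new_cluster <- c(TRUE, grp[-1] != grp[-nrow(x)] |
                     diff(x$pos) > tolerance_bp)
  cl <- cumsum(new_cluster)
  dosage <- ifelse(x$genotype == "1/1", 2L, 1L)
  idx <- split(seq_len(nrow(x)), factor(cl, levels = sort(unique(cl))))
  loci <- do.call(rbind, lapply(idx, function(i) {
    # allele count: max dosage per carrier, summed over carriers
    ac <- sum(tapply(dosage[i], x$sample_id[i], max))
    data.frame(element_class = x$element_class[i[1]],
               chrom = x$chrom[i[1]],
               representative_pos = as.integer(min(x$pos[i])),
               carriers = paste(sort(unique(x$sample_id[i])),
                                collapse = ","),
               n_carriers = length(unique(x$sample_id[i])),
               allele_count = as.integer(ac),
               stringsAsFactors = FALSE)
  }))
  loci <- cbind(locus_index = seq_len(nrow(loci)), loci)
  rownames(loci) <- NULL
  loci$allele_frequency <- loci$allele_count / (2 * n_samples)
  loci
}

#' Match cohort MEI loci against a reference database
#'
#' A locus matches when the database holds a record of the same element
#' class, on the same chromosome, within `tolerance_bp` of the
#' representative position (symmetric +/- window).
#'
#' @param loci Locus data.frame from [merge_mei_loci()].
#' @param db data.frame with columns `element_class`, `chrom`, `pos`.
#' @param tolerance_bp Positional tolerance in bp (default 20).
#' @return `loci` with a logical `db_matched` column added.
#' @export
match_mei_database <- function(loci, db, tolerance_bp = 20) {
  key <- function(class, chrom) paste(class, chrom, sep = "\r")
  db_split <- split(db$pos, key(db$element_class, db$chrom))
  k <- key(loci$element_class, loci$chrom)
  loci$db_matched <- vapply(seq_len(nrow(loci)), function(i) {
    p <- db_split[[k[i]]]
    !is.null(p) && any(abs(p - loci$representative_pos[i]) <= tolerance_bp)
  }, logical(1))
  loci
}

#' Classify MEI loci as Shared, CohortPrivate or Singleton
#'
#' Database presence dominates: a locus found in the reference database
#' is `Shared` regardless of carrier count.  Otherwise a locus carried
#' by two or more cohort individuals is `CohortPrivate`, and a locus
#' carried by exactly one is a `Singleton`.  The three classes
#' partition the loci.
#'
#' @param loci Locus data.frame with `db_matched` and `n_carriers`
#'   (from [match_mei_database()]).
#' @return `loci` with a `classification` column added.
#' @examples
#' loci <- data.frame(db_matched = c(TRUE, FALSE, FALSE),
#'                    n_carriers = c(1, 3, 1))
#' classify_mei_loci(loci)$classification
#' @export
classify_mei_loci <- function(loci) {
  stopifnot(all(c("db_matched", "n_carriers") %in% names(loci)))
  loci$classification <- ifelse(loci$db_matched, "Shared",
                                ifelse(loci$n_carriers >= 2,
                                       "CohortPrivate", "Singleton"))
  loci
}

#' Annotate the genomic context of MEI loci
#'
#' Assigns each insertion point one context with precedence
#' CDS > UTR > IntronFlank > Intergenic across all overlapping
#' transcripts.  Genic territory is the transcript span extended by
#' `flank_bp` (2 kb by default) up- and downstream of the
#' transcription start/end.
#'
#' @param loci Locus data.frame with `chrom` and `representative_pos`.
#' @param gene_models `GRanges` of GFF3 features with a `type` column
#'   (`CDS`, `five_prime_UTR`/`three_prime_UTR`/`UTR`,
#'   `mRNA`/`transcript`), e.g. from `rtracklayer::import`.
#' @param flank_bp Flank width around transcripts (default 2000).
#' @return `loci` with a `context` column over
#'   `{CDS, UTR, IntronFlank, Intergenic}`.
#' @export
annotate_mei_context <- function(loci, gene_models, flank_bp = 2000) {
  type <- S4Vectors::mcols(gene_models)$type
  if (is.null(type)) stop("gene_models lacks a 'type' column")
  pts <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$representative_pos,
                                                 loci$representative_pos))
  tx <- gene_models[type %in% c("mRNA", "transcript")]
  tx_flank <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tx),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(tx) - flank_bp),
                     GenomicRanges::end(tx) + flank_bp))
  utr <- gene_models[type %in% c("five_prime_UTR", "three_prime_UTR",
                                 "UTR")]
  cds <- gene_models[type == "CDS"]
  ctx <- rep("Intergenic", nrow(loci))
  ctx[IRanges::overlapsAny(pts, tx_flank)] <- "IntronFlank"
  ctx[IRanges::overlapsAny(pts, utr)] <- "UTR"
  ctx[IRanges::overlapsAny(pts, cds)] <- "CDS"
  loci$context <- ctx
  loci
}
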