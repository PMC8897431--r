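#' Generate a synthetic cohort MEI callset with planted class truth
#'
#' Plants `n_mei_loci` mobile-element insertion events across the toy
#' genome, each assigned an element class (Alu/L1/SVA/HERV) and a truth
#' class: `Shared` (also present in the DGV-style reference table),
#' `CohortPrivate` (carried by >= 2 cohort individuals, absent from the
#' table) or `Singleton` (one carrier, absent from the table).  Loci are
#' placed on a 1-kb grid so that distinct events are always farther
#' apart than the +/-20 bp merge tolerance.  All carrier calls of one
#' event share the insertion coordinate (a MELT-style caller reports a
#' single breakpoint per event); the configured positional jitter is
#' applied to the reference-table entry, emulating coordinate
#' discrepancies between databases.  Every planted call carries
#' MELT-style quality fields chosen to survive the private-event filter
#' (PASS, ASSESS 5, TSD defined, > 2 split reads), so downstream class
#' recovery is limited only by the matching logic.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Optional output directory; writes one
#'   `mei_calls/<sample>.vcf.gz` per carrier sample, `dgv_table.tsv` and
#'   `mei_class_truth.tsv`.
#' @return List with `calls` (data.frame: sample_id, element_class,
#'   chrom, pos, filter, assess, tsd, split_reads, discordant_pairs,
#'   genotype, locus_id), `dgv` (data.frame element_class, chrom, pos),
#'   `truth` (data.frame locus_id, element_class, chrom, pos,
#'   truth_class), and `paths` when `out_dir` is given.
#' @examples
#' sim <- generate_mei_callset(sim_config(seed = 1, n_samples = 10,
#'   n_mei_loci = 50))
#' table(sim$truth$truth_class)
#' @export
generate_mei_callset <- function(cfg, out_dir = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_samples < 2 && cfg$truth_class_mix[["CohortPrivate"]] > 0)
    stop("CohortPrivate loci require n_samples >= 2")
  n <- cfg$n_mei_loci
  n_decoy <- round(0.2 * n)
  lens <- cfg$chromosome_lengths
  n_slots <- sum(floor(lens / 1000)) - length(lens)
  if (n + n_decoy > n_slots)
    stop("too many MEI loci for the configured genome size")
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))

  withr::with_seed(cfg$seed + 303L, {
    pos_tab <- sim_grid_positions(lens, n + n_decoy)
    locus <- pos_tab[seq_len(n), ]
    decoy <- pos_tab[seq_len(n_decoy) + n, , drop = FALSE]
    locus$locus_id <- sprintf("mei%05d", seq_len(n))
    locus$element_class <- sample(names(cfg$mei_class_mix), n,
                                  replace = TRUE, prob = cfg$mei_class_mix)
    locus$truth_class <- sample(names(cfg$truth_class_mix), n,
                                replace = TRUE, prob = cfg$truth_class_mix)

    n_car <- integer(n)
    shared <- locus$truth_class == "Shared"
    priv <- locus$truth_class == "CohortPrivate"
    n_car[shared] <- pmax(1L, rbinom(sum(shared), cfg$n_samples,
                                     runif(sum(shared), 0.02, 0.6)))
    n_car[priv] <- pmax(2L, rbinom(sum(priv), cfg$n_samples,
                                   runif(sum(priv), 0.004, 0.3)))
    n_car[locus$truth_class == "Singleton"] <- 1L

    calls <- do.call(rbind, lapply(seq_len(n), function(i) {
      car <- sample(samples, n_car[i])
      data.frame(sample_id = car,
                 element_class = locus$element_class[i],
                 chrom = locus$chrom[i], pos = locus$pos[i],
                 filter = "PASS", assess = 5L, tsd = TRUE,
                 split_reads = sample(3:8, length(car), replace = TRUE),
                 discordant_pairs = sample(1:4, length(car), replace = TRUE),
                 genotype = ifelse(runif(length(car)) < 0.1, "1/1", "0/1"),
                 locus_id = locus$locus_id[i],
                 stringsAsFactors = FALSE)
    }))

    j <- cfg$positional_jitter_bp
    dgv_rows <- locus[shared, c("element_class", "chrom", "pos")]
    if (nrow(dgv_rows) > 0 && j > 0)
      dgv_rows$pos <- dgv_rows$pos +
        sample(seq(-j, j), nrow(dgv_rows), replace = TRUE)
    dgv_extra <- data.frame(
      element_class = sample(names(cfg$mei_class_mix), n_decoy,
                             replace = TRUE, prob = cfg$mei_class_mix),
      chrom = decoy$chrom, pos = decoy$pos, stringsAsFactors = FALSE)
    dgv <- rbind(dgv_rows, dgv_extra)
    dgv <- dgv[order(match(dgv$chrom, names(lens)), dgv$pos), ]
    rownames(dgv) <- NULL
  })

  truth <- locus[, c("locus_id", "element_class", "chrom", "pos",
                     "truth_class")]
  out <- list(calls = calls, dgv = dgv, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "mei_calls"), showWarnings = FALSE,
               recursive = TRUE)
    for (s in unique(calls$sample_id)) {
      write_mei_vcf(calls[calls$sample_id == s, ], lens,
                    file.path(out_dir, "mei_calls", paste0(s, ".vcf.gz")))
    }
    paths <- c(calls_dir = file.path(out_dir, "mei_calls"),
               dgv = file.path(out_dir, "dgv_table.tsv"),
               truth = file.path(out_dir, "mei_class_truth.tsv"))
    write.table(dgv, paths[["dgv"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}

# Distinct 1-kb slots with a random offset in [1, 980]: consecutive
# positions are always > 20 bp apart.
sim_grid_positions <- function(lens, n) {
  slots <- do.call(rbind, lapply(names(lens), function(ch) {
    k <- floor(lens[[ch]] / 1000) - 1L
    data.frame(chrom = ch, slot = seq_len(k), stringsAsFactors = FALSE)
  }))
  pick <- slots[sample.int(nrow(slots), n), ]
  pick$pos <- (pick$slot - 1L) * 1000L + sample.int(980L, n, replace = TRUE)
  ord <- order(match(pick$chrom, names(lens)), pick$pos)
  out <- pick[ord, c("chrom", "pos")]
  rownames(out) <- NULL
  out
}

write_mei_vcf <- function(calls, lens, path) {
  calls <- calls[order(match(calls$chrom, names(lens)), calls$pos), ]
  meta <- c("##fileformat=VCFv4.2",
            sprintf("##contig=<ID=%s,length=%d>", names(lens),
                    as.integer(lens)),
            "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Element class\">",
            "##INFO=<ID=ASSESS,Number=1,Type=Integer,Description=\"Evidence tier\">",
            "##INFO=<ID=TSD,Number=1,Type=String,Description=\"Target site duplication\">",
            "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
            "##INFO=<ID=DPR,Number=1,Type=Integer,Description=\"Discordant pairs\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  info <- sprintf("CLASS=%s;ASSESS=%d;TSD=%s;SR=%d;DPR=%d",
                  calls$element_class, calls$assess,
                  ifelse(calls$tsd, "yes", "null"), calls$split_reads,
                  calls$discordant_pairs)
  fix <- cbind(CHROM = calls$chrom, POS = as.character(calls$pos),
               ID = calls$locus_id, REF = "N", ALT = "<INS:ME>",
               QUAL = ".", FILTER = calls$filter, INFO = info)
  gt <- cbind(FORMAT = "GT",
              matrix(calls$genotype, ncol = 1,
                     dimnames = list(NULL, calls$sample_id[1])))
  vcfR::write.vcf(methods::new("vcfR", meta = meta, fix = fix, gt = gt),
                  path)
}

#' Read MELT-style per-sample MEI VCFs back into a call table
#'
#' Inverse of the files written by [generate_mei_callset()]: parses the
#' `CLASS`, `ASSESS`, `TSD`, `SR` and `DPR` INFO keys of each
#' single-sample VCF in `dir` into the flat call data.frame the MEI
#' landscape operations consume.
#'
#' @param dir Directory of `<sample>.vcf.gz` files.
#' @return data.frame with one row per call (see
#'   [generate_mei_callset()]).
#' @export
read_mei_calls <- function(dir) {
  files <- list.files(dir, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0) stop("no VCF files under ", dir)
  do.call(rbind, lapply(files, function(f) {
    v <- vcfR::read.vcfR(f, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    key <- function(k) vcfR::extract.info(v, element = k)
    data.frame(sample_id = colnames(v@gt)[2],
               element_class = key("CLASS"),
               chrom = fix$CHROM, pos = as.integer(fix$POS),
               filter = fix$FILTER,
               assess = as.integer(key("ASSESS")),
               tsd = key("TSD") == "yes",
               split_reads = as.integer(key("SR")),
               discordant_pairs = as.integer(key("DPR")),
               genotype = sub(":.*", "", v@gt[, 2]),
               locus_id = fix$ID, stringsAsFactors = FALSE)
  }))
}
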