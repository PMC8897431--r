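#' GC-content bias test for MEI insertion sites
#'
#' Compares, per element class, the GC content of 100-bp windows
#' centred on the insertion points against the GC content of windows
#' drawn uniformly at random from the reference (10,000 windows of
#' 100 bp by default), using a two-sample two-sided
#' Kolmogorov-Smirnov test.  Windows extending past a chromosome end
#' are clipped and counted in `n_clipped`.
#'
#' @param loci Locus data.frame with `element_class`, `chrom`,
#'   `representative_pos`.
#' @param genome A [Biostrings::DNAStringSet] reference.
#' @param n_windows Number of random control windows.
#' @param window_bp Window width in bp.
#' @param seed Seed for the control-window draw.
#' @return List with `control_gc` (numeric vector), `per_class`
#'   (data.frame: element_class, n, n_clipped, ks_statistic, p_value)
#'   and `insertion_gc` (named list of numeric vectors).
#' @export
mei_gc_bias <- function(loci, genome, n_windows = 10000,
                        window_bp = 100, seed = 1L) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  bad <- !(loci$chrom %in% names(lens))
  if (any(bad))
    stop("loci on chromosomes absent from the reference: ",
         paste(unique(loci$chrom[bad]), collapse = ", "))
  withr::with_seed(seed, {
    ctrl_chrom <- sample(names(lens), n_windows, replace = TRUE,
                         prob = lens / sum(lens))
    ctrl_start <- vapply(ctrl_chrom, function(ch)
      sample.int(lens[[ch]] - window_bp + 1L, 1), integer(1))
  })
  control_gc <- window_gc(genome, ctrl_chrom, ctrl_start, window_bp)

  half <- floor(window_bp / 2)
  start <- loci$representative_pos - half
  end <- start + window_bp - 1L
  clipped <- start < 1 | end > lens[loci$chrom]
  start <- pmax(1L, start)
  w <- pmin(lens[loci$chrom], end) - start + 1L
  ins_gc <- vapply(seq_len(nrow(loci)), function(i) {
    window_gc(genome, loci$chrom[i], start[i], w[i])
  }, numeric(1))

  classes <- unique(loci$element_class)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    g <- ins_gc[loci$element_class == cl]
    ks <- suppressWarnings(ks.test(g, control_gc))
    data.frame(element_class = cl, n = length(g),
               n_clipped = sum(clipped[loci$element_class == cl]),
               ks_statistic = unname(ks$statistic),
               p_value = ks$p.value, stringsAsFactors = FALSE)
  }))
  list(control_gc = control_gc,
       per_class = per_class,
       insertion_gc = split(ins_gc, loci$element_class))
}

window_gc <- function(genome, chrom, start, width) {
  width <- rep_len(width, length(chrom))
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    v <- Biostrings::Views(genome[[ch]],
                           start = start[i], width = width[i])
    out[i] <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
  }
  out
}

#' Summarise the cohort MEI landscape
#'
#' Computes the headline landscape statistics from a classified locus
#' table: class counts and proportions, element counts, per-individual
#' burden by class and element (carrier status: number of loci
#' carried), the allele-frequency comparison between Shared and
#' CohortPrivate loci (two-sided Mann-Whitney), the Pearson
#' correlation of per-chromosome locus count with chromosome length,
#' and the count of cohort-private loci at unexpectedly high allele
#' frequency (> 20% by default).  Statistics whose inputs are empty
#' (e.g. the AF comparison when a class has no loci) are reported as
#' `NA`, not zero.
#'
#' @param loci Classified, annotated locus data.frame (needs
#'   `classification`, `element_class`, `carriers`,
#'   `allele_frequency`; `context` used when present).
#' @param samples Optional character vector of all cohort sample ids;
#'   individuals carrying no locus then appear in the burden table
#'   with zero counts.  Defaults to the union of carriers.
#' @param chromosome_lengths Optional named vector for the
#'   chromosome-length correlation.
#' @param high_af_threshold AF threshold for the high-AF private flag.
#' @return List with components `class_counts`, `class_proportions`,
#'   `element_counts`, `n_loci`, `burden` (per-individual data.frame),
#'   `burden_means`, `alu_l1_share_pct`, `af_comparison` (U statistic
#'   and p), `chrom_correlation` (r and p, or NULL), `high_af_private`
#'   (count and proportion), `context_counts` (when annotated).
#' @export
mei_landscape_summary <- function(loci, samples = NULL,
                                  chromosome_lengths = NULL,
                                  high_af_threshold = 0.2) {
  stopifnot(all(c("classification", "element_class", "carriers",
                  "allele_frequency") %in% names(loci)))
  cls <- factor(loci$classification,
                levels = c("Shared", "CohortPrivate", "Singleton"))
  class_counts <- table(cls)
  elem_counts <- table(factor(loci$element_class, levels = MEI_CLASSES))

  carrier_list <- strsplit(loci$carriers, ",", fixed = TRUE)
  long <- data.frame(
    sample_id = unlist(carrier_list),
    classification = rep(loci$classification,
                         lengths(carrier_list)),
    element_class = rep(loci$element_class, lengths(carrier_list)),
    stringsAsFactors = FALSE)
  if (is.null(samples)) samples <- sort(unique(long$sample_id))
  burden <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  burden$total <- as.integer(table(factor(long$sample_id,
                                          levels = samples)))
  for (k in levels(cls))
    burden[[k]] <- as.integer(table(factor(
      long$sample_id[long$classification == k], levels = samples)))
  for (k in MEI_CLASSES)
    burden[[k]] <- as.integer(table(factor(
      long$sample_id[long$element_class == k], levels = samples)))
  burden_means <- colMeans(burden[, -1, drop = FALSE])
  alu_l1_share_pct <- 100 *
    (burden_means[["Alu"]] + burden_means[["L1"]]) /
    burden_means[["total"]]

  af_sh <- loci$allele_frequency[loci$classification == "Shared"]
  af_pr <- loci$allele_frequency[loci$classification == "CohortPrivate"]
  af_comparison <- if (length(af_sh) == 0 || length(af_pr) == 0) {
    list(U = NA_real_, p_value = NA_real_)
  } else {
    w <- suppressWarnings(wilcox.test(af_sh, af_pr))
    list(U = unname(w$statistic), p_value = w$p.value)
  }

  chrom_correlation <- NULL
  if (!is.null(chromosome_lengths)) {
    counts <- table(factor(loci$chrom, levels = names(chromosome_lengths)))
    r <- cor(as.numeric(counts), as.numeric(chromosome_lengths))
    chrom_correlation <- list(r = r, n_chrom = length(chromosome_lengths))
  }

  n_priv <- sum(loci$classification == "CohortPrivate")
  n_high <- sum(loci$classification == "CohortPrivate" &
                  loci$allele_frequency > high_af_threshold)
  high_af_private <- list(
    count = n_high,
    proportion = if (n_priv == 0) NA_real_ else n_high / n_priv)

  out <- list(class_counts = as.integer(class_counts),
              class_proportions =
                as.numeric(class_counts) / sum(class_counts),
              element_counts = as.integer(elem_counts),
              n_loci = nrow(loci),
              burden = burden,
              burden_means = burden_means,
              alu_l1_share_pct = unname(alu_l1_share_pct),
              af_comparison = af_comparison,
              chrom_correlation = chrom_correlation,
              high_af_private = high_af_private)
  names(out$class_counts) <- levels(cls)
  names(out$class_proportions) <- levels(cls)
  names(out$element_counts) <- MEI_CLASSES
  if ("context" %in% names(loci)) {
    ctx <- table(factor(loci$context,
                        levels = c("CDS", "UTR", "IntronFlank",
                                   "Intergenic")))
    out$context_counts <- setNames(as.integer(ctx), names(ctx))
    out$genic_total <- sum(out$context_counts[c("CDS", "UTR",
                                                "IntronFlank")])
  }
  out
}
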