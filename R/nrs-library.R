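#' Build the nonredundant non-reference segment library
#'
#' Applies the library retention rules to candidate contigs: only
#' sequences longer than 200 bp are retained, and any contig with a
#' reference alignment of 95% identity or higher (identity =
#' matching bases / alignment block length, the PAF convention) is
#' dropped as redundant with the reference.  Every input contig
#' appears in the output exactly once with a reason code.
#'
#' @param contigs data.frame with `contig_id` and `length` (bp).
#' @param alignments PAF data.frame (see [read_paf()]) of
#'   contig-vs-reference alignments; may be `NULL`.
#' @param min_length_exclusive Retention length cutoff (strict;
#'   default 200).
#' @param max_identity Identity at or above which a contig is dropped
#'   (default 0.95).
#' @return `contigs` with logical `retained` and character `reason`
#'   (`ok`, `too_short`, `reference_identity`) columns.
#' @examples
#' build_nrs_library(data.frame(contig_id = c("a", "b"),
#'                              length = c(180, 250)), NULL)
#' @export
build_nrs_library <- function(contigs, alignments,
                              min_length_exclusive = 200,
                              max_identity = 0.95) {
  stopifnot(all(c("contig_id", "length") %in% names(contigs)))
  if (!is.null(alignments) && nrow(alignments) > 0) {
    unknown <- setdiff(alignments$query_id, contigs$contig_id)
    if (length(unknown) > 0)
      stop("alignments refer to unknown contigs: ",
           paste(head(unknown, 5), collapse = ", "))
    identity <- alignments$matching_bases / alignments$block_len
    hi <- unique(alignments$query_id[identity >= max_identity])
  } else {
    hi <- character(0)
  }
  reason <- rep("ok", nrow(contigs))
  reason[contigs$contig_id %in% hi] <- "reference_identity"
  reason[contigs$length <= min_length_exclusive] <- "too_short"
  contigs$retained <- reason == "ok"
  contigs$reason <- reason
  contigs
}

#' Per-sample presence calls from contig coverage
#'
#' A contig is present in a sample when its mean read depth (restricted
#' upstream to reads with mapping quality above 20) lies in the closed
#' interval [7.5, 100]; depths outside mark contamination or
#' misassembly.  Contigs present in no sample are discarded with
#' reason `coverage_out_of_range`.
#'
#' @param contigs Retained contig data.frame (from
#'   [build_nrs_library()], rows with `retained == TRUE`).
#' @param coverage Long data.frame: `contig_id`, `sample_id`, `depth`.
#' @param range Closed presence interval (default `c(7.5, 100)`).
#' @return List with `matrix` (logical sample x contig matrix),
#'   `contigs` (input with `retained`/`reason` updated).
#' @export
nrs_presence_matrix <- function(contigs, coverage,
                                range = c(7.5, 100)) {
  if (any(coverage$depth < 0)) stop("negative depth in coverage table")
  cov <- coverage[coverage$contig_id %in% contigs$contig_id, ]
  present <- cov$depth >= range[1] & cov$depth <= range[2]
  samples <- sort(unique(cov$sample_id))
  m <- matrix(FALSE, nrow = length(samples), ncol = nrow(contigs),
              dimnames = list(samples, contigs$contig_id))
  m[cbind(match(cov$sample_id, samples),
          match(cov$contig_id, contigs$contig_id))] <- present
  absent <- colSums(m) == 0
  contigs$retained <- contigs$retained & !absent[contigs$contig_id]
  contigs$reason[contigs$reason == "ok" & absent[contigs$contig_id]] <-
    "coverage_out_of_range"
  list(matrix = m, contigs = contigs)
}

#' Anchor evidence from a partial reference alignment
#'
#' A contig whose alignment leaves at least 200 bp of the query
#' unaligned is anchored at the clip boundary on the target: the
#' target coordinate of the aligned block adjacent to the unaligned
#' tail.  Fully (or nearly fully) aligned contigs yield no evidence.
#' Among multiple qualifying alignments of one contig the one with the
#' most matching bases wins; ties break to the lowest target
#' coordinate.
#'
#' @param alignments PAF data.frame rows for retained contigs.
#' @param min_clip_bp Minimum unaligned portion (default 200).
#' @return data.frame of evidence: `contig_id`, `kind`
#'   (`"partial_map"`), `chrom`, `pos`, `support` (matching bases); no
#'   row for contigs without qualifying alignments.
#' @export
anchor_partial <- function(alignments, min_clip_bp = 200) {
  head_clip <- alignments$query_start
  tail_clip <- alignments$query_len - alignments$query_end
  qual <- pmax(head_clip, tail_clip) >= min_clip_bp
  a <- alignments[qual, , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(contig_id = character(0), kind = character(0),
                      chrom = character(0), pos = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  # clip boundary: block edge next to the larger unaligned portion,
  # on the target strand
  tail_bigger <- (a$query_len - a$query_end) >= a$query_start
  plus <- a$strand == "+"
  pos <- ifelse(tail_bigger == plus, a$target_end, a$target_start)
  ev <- data.frame(contig_id = a$query_id, kind = "partial_map",
                   chrom = a$chrom, pos = as.integer(pos),
                   support = a$matching_bases, stringsAsFactors = FALSE)
  ev <- ev[order(ev$contig_id, -ev$support, ev$pos), ]
  ev[!duplicated(ev$contig_id), , drop = FALSE]
}

#' Best barcode window for each contig
#'
#' Bins linked-read barcode observations into 1-kb windows and, per
#' contig, picks the window with the highest cross-sample number of
#' distinct barcodes.  A contig is localized only when that count is
#' at least `min_barcodes` (two chromium barcodes, in the same or
#' different individuals); ties break to the first chromosome in
#' `chrom_order` (alphabetical when omitted), then the lowest window
#' start.
#'
#' @param evidence data.frame: `contig_id`, `chrom`, `pos`, `barcode`
#'   (sample ids may be present but counting is cross-sample).
#' @param min_barcodes Minimum distinct barcodes (default 2).
#' @param window_bp Window size (default 1000).
#' @param chrom_order Optional chromosome ordering for tie-breaks.
#' @return data.frame of evidence calls: `contig_id`, `kind`
#'   (`"barcode"`), `chrom`, `pos` (window start), `support`
#'   (distinct barcodes); contigs below `min_barcodes` are absent.
#' @export
anchor_barcode <- function(evidence, min_barcodes = 2,
                           window_bp = 1000, chrom_order = NULL) {
  if (nrow(evidence) == 0)
    return(data.frame(contig_id = character(0), kind = character(0),
                      chrom = character(0), pos = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  win <- (evidence$pos - 1) %/% window_bp * window_bp + 1
  key <- paste(evidence$contig_id, evidence$chrom, win, sep = "\r")
  support <- tapply(evidence$barcode, key, function(b)
    length(unique(b)))
  parts <- do.call(rbind, strsplit(names(support), "\r", fixed = TRUE))
  tab <- data.frame(contig_id = parts[, 1], chrom = parts[, 2],
                    pos = as.integer(parts[, 3]),
                    support = as.integer(support),
                    stringsAsFactors = FALSE)
  chrom_rank <- if (is.null(chrom_order))
    match(tab$chrom, sort(unique(tab$chrom)))
  else match(tab$chrom, chrom_order)
  tab <- tab[order(tab$contig_id, -tab$support, chrom_rank, tab$pos), ]
  best <- tab[!duplicated(tab$contig_id), , drop = FALSE]
  best <- best[best$support >= min_barcodes, , drop = FALSE]
  if (nrow(best) == 0)
    return(data.frame(contig_id = character(0), kind = character(0),
                      chrom = character(0), pos = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  data.frame(contig_id = best$contig_id, kind = "barcode",
             chrom = best$chrom, pos = best$pos,
             support = best$support, stringsAsFactors = FALSE)
}

#' Anchor evidence from discordant read pairs
#'
#' Read-pair mates mapping to the reference are binned into 1-kb
#' windows like barcodes; per contig the best-supported window wins
#' (ties as in [anchor_barcode()]) and the anchor position is the
#' median mate coordinate within that window.
#'
#' @param evidence data.frame: `contig_id`, `chrom`, `pos` (mate
#'   coordinates), one row per read pair.
#' @param window_bp Window size (default 1000).
#' @param chrom_order Optional chromosome ordering for tie-breaks.
#' @return data.frame of evidence calls: `contig_id`, `kind`
#'   (`"discordant_pair"`), `chrom`, `pos`, `support` (read pairs in
#'   the winning window).
#' @export
anchor_discordant <- function(evidence, window_bp = 1000,
                              chrom_order = NULL) {
  if (nrow(evidence) == 0)
    return(data.frame(contig_id = character(0), kind = character(0),
                      chrom = character(0), pos = integer(0),
                      support = integer(0), stringsAsFactors = FALSE))
  win <- (evidence$pos - 1) %/% window_bp * window_bp + 1
  key <- paste(evidence$contig_id, evidence$chrom, win, sep = "\r")
  support <- vapply(split(evidence$pos, key), length, integer(1))
  med <- vapply(split(evidence$pos, key), function(p)
    as.integer(round(median(p))), integer(1))
  parts <- do.call(rbind, strsplit(names(support), "\r", fixed = TRUE))
  tab <- data.frame(contig_id = parts[, 1], chrom = parts[, 2],
                    win = as.integer(parts[, 3]),
                    pos = med, support = as.integer(support),
                    stringsAsFactors = FALSE)
  chrom_rank <- if (is.null(chrom_order))
    match(tab$chrom, sort(unique(tab$chrom)))
  else match(tab$chrom, chrom_order)
  tab <- tab[order(tab$contig_id, -tab$support, chrom_rank, tab$win), ]
  best <- tab[!duplicated(tab$contig_id), , drop = FALSE]
  data.frame(contig_id = best$contig_id, kind = "discordant_pair",
             chrom = best$chrom, pos = best$pos,
             support = best$support, stringsAsFactors = FALSE)
}

#' Resolve the final anchor call for each contig
#'
#' Combines the three evidence sources with the stated precedence:
#' partial-map coordinates first, then discordant read pairs, then
#' barcode windows (the first two give base-precise coordinates).
#' Anchors whose target is the mitochondrial sequence or a decoy are
#' suppressed; contigs without evidence are unplaced.
#'
#' @param contig_ids Character vector of retained contig ids.
#' @param evidence data.frame of evidence calls (rows from
#'   [anchor_partial()], [anchor_discordant()], [anchor_barcode()]).
#' @param suppressed_chroms Chromosome names (or regular expression
#'   matches) whose anchors are not reported.
#' @return data.frame of anchor calls: `contig_id`, `chrom`, `pos`,
#'   `evidence_kind`, `support`, `status` over
#'   `{localized, unplaced, suppressed_target}`.
#' @export
resolve_anchor <- function(contig_ids, evidence,
                           suppressed_chroms = c("chrM", "MT",
                                                 "chrEBV", "decoy")) {
  precedence <- c(partial_map = 1L, discordant_pair = 2L, barcode = 3L)
  out <- data.frame(contig_id = contig_ids, chrom = NA_character_,
                    pos = NA_integer_, evidence_kind = NA_character_,
                    support = NA_integer_, status = "unplaced",
                    stringsAsFactors = FALSE)
  if (nrow(evidence) > 0) {
    ev <- evidence[order(evidence$contig_id,
                         precedence[evidence$kind]), ]
    ev <- ev[!duplicated(ev$contig_id), , drop = FALSE]
    i <- match(out$contig_id, ev$contig_id)
    hit <- !is.na(i)
    out$chrom[hit] <- ev$chrom[i[hit]]
    out$pos[hit] <- ev$pos[i[hit]]
    out$evidence_kind[hit] <- ev$kind[i[hit]]
    out$support[hit] <- ev$support[i[hit]]
    suppressed <- hit & (out$chrom %in% suppressed_chroms |
                           grepl("decoy", out$chrom, ignore.case = TRUE))
    out$status[hit] <- "localized"
    out$status[suppressed] <- "suppressed_target"
  }
  out
}

#' Run the full NRS pipeline on generated or loaded inputs
#'
#' Library filtering, presence calling and anchoring in one call;
#' convenience wrapper used by the worked examples and the acceptance
#' runs.
#'
#' @param contigs,alignments,coverage,evidence Inputs as documented in
#'   the individual steps ([build_nrs_library()],
#'   [nrs_presence_matrix()], [anchor_partial()],
#'   [anchor_discordant()], [anchor_barcode()]).
#' @param min_barcodes Passed to [anchor_barcode()].
#' @return List with `library` (contig table with reason codes),
#'   `presence` (logical matrix) and `anchors` (anchor-call
#'   data.frame for retained contigs).
#' @export
nrs_pipeline <- function(contigs, alignments, coverage, evidence,
                         min_barcodes = 2) {
  lib <- build_nrs_library(contigs, alignments)
  pres <- nrs_presence_matrix(lib, coverage)
  lib <- pres$contigs
  kept <- lib$contig_id[lib$retained]
  aln_kept <- alignments[alignments$query_id %in% kept, , drop = FALSE]
  ev <- rbind(
    anchor_partial(aln_kept),
    anchor_discordant(evidence[evidence$kind == "discordant_pair" &
                                 evidence$contig_id %in% kept, ,
                               drop = FALSE]),
    anchor_barcode(evidence[evidence$kind == "barcode" &
                              evidence$contig_id %in% kept, ,
                            drop = FALSE],
                   min_barcodes = min_barcodes))
  list(library = lib, presence = pres$matrix,
       anchors = resolve_anchor(kept, ev))
}
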