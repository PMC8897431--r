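#' Expected incidence of a recessive disorder from allele frequencies
#'
#' Under random mating (panmixia), an affected offspring carries two
#' pathogenic alleles of the gene: either the same allele on both
#' haplotypes (homozygote) or two different ones (compound
#' heterozygote).  With per-allele frequencies `q_i` and alleles
#' mutually exclusive on a haplotype, the expected birth incidence is
#' `(sum q_i)^2`, decomposing into `sum q_i^2` homozygotes and
#' `sum_{i != j} q_i q_j` compound heterozygotes.
#'
#' @param q Numeric vector of pathogenic allele frequencies for one
#'   gene (each in `[0, 1]`; the sum should not exceed 0.5 — a warning
#'   is raised above, an error above 1).
#' @return List: `incidence`, `homozygous`, `compound_het`, `q_total`.
#' @examples
#' expected_incidence(c(0.006, 0.004))
#' @export
expected_incidence <- function(q) {
  if (length(q) == 0)
    return(list(incidence = 0, homozygous = 0, compound_het = 0,
                q_total = 0))
  if (any(q < 0)) stop("negative allele frequency")
  if (any(q > 1)) stop("allele frequency above 1")
  qt <- sum(q)
  if (qt > 1) stop("total allele frequency above 1")
  if (qt > 0.5)
    warning("total pathogenic frequency above 0.5; ",
            "rare-allele assumptions are strained")
  hom <- sum(q^2)
  list(incidence = qt^2, homozygous = hom,
       compound_het = qt^2 - hom, q_total = qt)
}

#' Carrier frequency and its inverse
#'
#' The heterozygous-carrier frequency under Hardy-Weinberg is
#' `c = 2 q (1 - q)` for total pathogenic frequency `q`.
#' `q_from_carrier` inverts it: the exact smaller root
#' `(1 - sqrt(1 - 2c)) / 2`, or the rare-allele approximation `c / 2`
#' commonly used when reporting incidences from carrier screens.
#'
#' @param q Total pathogenic allele frequency.
#' @return `carrier_frequency` returns `2 q (1 - q)`.
#' @examples
#' carrier_frequency(0.01)
#' q_from_carrier(0.02)
#' q_from_carrier(0.02, method = "approximate")
#' @export
carrier_frequency <- function(q) {
  stopifnot(all(q >= 0), all(q <= 1))
  2 * q * (1 - q)
}

#' @rdname carrier_frequency
#' @param carrier Observed carrier frequency (`[0, 0.5]`).
#' @param method `"exact"` (smaller quadratic root) or
#'   `"approximate"` (`carrier / 2`).
#' @export
q_from_carrier <- function(carrier, method = c("exact", "approximate")) {
  method <- match.arg(method)
  if (any(carrier < 0 | carrier > 0.5))
    stop("carrier frequency must be in [0, 0.5] (no real root above)")
  if (method == "approximate") return(carrier / 2)
  (1 - sqrt(1 - 2 * carrier)) / 2
}

#' Render an incidence as "1 in N"
#'
#' @param incidence Expected incidence per birth (`> 0`; an incidence
#'   of exactly 0 renders the sentinel `"0 expected"`).
#' @param big_mark Thousands separator.
#' @return List: `n` (integer `round(1 / incidence)`, or `NA` at 0)
#'   and `label`.
#' @examples
#' one_in_n(1e-4)$label
#' @export
one_in_n <- function(incidence, big_mark = ",") {
  if (incidence < 0) stop("negative incidence")
  if (incidence == 0)
    return(list(n = NA_integer_, label = "0 expected"))
  n <- round(1 / incidence)
  list(n = n,
       label = paste0("1 in ", formatC(n, format = "d",
                                       big.mark = big_mark)))
}

#' Compare carrier frequencies between two cohorts
#'
#' 2x2 chi-square test (1 degree of freedom, no continuity
#' correction) of carriers vs non-carriers across two cohorts.
#'
#' @param carriers_a,total_a Carrier count and cohort size, cohort A.
#' @param carriers_b,total_b Same for cohort B.
#' @return List: `statistic`, `df` (1), `p_value`, `proportions`.
#' @examples
#' compare_carriers(21, 1171, 40, 2000)
#' @export
compare_carriers <- function(carriers_a, total_a, carriers_b, total_b) {
  stopifnot(carriers_a >= 0, carriers_b >= 0,
            carriers_a <= total_a, carriers_b <= total_b,
            total_a > 0, total_b > 0)
  tab <- matrix(c(carriers_a, total_a - carriers_a,
                  carriers_b, total_b - carriers_b),
                nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("zero margin in the 2x2 table")
  if (carriers_a / total_a == carriers_b / total_b) {
    # identical proportions: the statistic is exactly 0
    return(list(statistic = 0, df = 1L, p_value = 1,
                proportions = c(a = carriers_a / total_a,
                                b = carriers_b / total_b)))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = ct$p.value,
       proportions = c(a = carriers_a / total_a,
                       b = carriers_b / total_b))
}

#' Per-gene incidence report from a pathogenic allele panel
#'
#' @param panel data.frame with columns `gene`, `variant_id`,
#'   `frequency` (and optionally `classification`).
#' @return data.frame, one row per gene: `gene`, `n_alleles`,
#'   `q_total`, `carrier_frequency`, `incidence`, `homozygous`,
#'   `compound_het`, `one_in_n`.
#' @export
incidence_report <- function(panel) {
  stopifnot(all(c("gene", "variant_id", "frequency") %in% names(panel)))
  dup <- tapply(panel$variant_id, panel$gene,
                function(v) any(duplicated(v)))
  if (any(dup)) stop("duplicate variant ids within a gene")
  do.call(rbind, lapply(split(panel, panel$gene), function(p) {
    inc <- expected_incidence(p$frequency)
    data.frame(gene = p$gene[1], n_alleles = nrow(p),
               q_total = inc$q_total,
               carrier_frequency = carrier_frequency(inc$q_total),
               incidence = inc$incidence,
               homozygous = inc$homozygous,
               compound_het = inc$compound_het,
               one_in_n = one_in_n(inc$incidence)$n,
               stringsAsFactors = FALSE)
  }))
}
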