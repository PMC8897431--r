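---
title: "Models and methods behind the admixkit cohort pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the admixkit cohort pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixkit)
```

`admixkit` implements the downstream, cohort-level stages of a
population WGS study: genotype quality flagging, mobile element
insertion (MEI) landscape analysis, non-reference segment (NRS)
library construction and anchoring, recessive-disorder incidence
estimation, and resampled HLA diversity statistics. This vignette
explains the models behind each stage, the parameters that matter and
why their defaults are what they are, what the synthetic-cohort
generator does and does not emulate, and the numerical and design
choices made where the problem left them open.

## The synthetic cohort: planted truth as the testing substrate

Real inputs for this kind of study are access-restricted individual
level data, so every pipeline stage in this package is validated
against a generator that emits the same file formats (VCF 4.2 with
GT/DP/AD, FASTA, GFF3, BED, PAF, TSV evidence tables) with known
ground truth. Two principles govern the generator:

* **Single-cause planting.** Every planted violation has exactly one
  cause — a genotype fails depth *or* balance, a contig is discarded
  for exactly one reason — so truth labels are unambiguous and
  recovery can be scored as exact precision/recall rather than fuzzy
  agreement.
* **Determinism.** Each generator draws from a stream derived from
  `sim_config()$seed` (per-component offsets keep the streams
  independent), and identical configurations produce byte-identical
  output files.

Default study conditions follow the quantities the cohort study
reports where it reports them: per-genotype depth is negative binomial
with mean 38.65× (the cohort's average coverage; the dispersion
parameter, `size = 10`, is a choice — the study reports only
per-sample means, and WGS per-site depth is overdispersed relative to
Poisson); the MEI truth-class mix is 74.3% shared / 20.1%
cohort-private / 5.6% singleton and the element mix follows the
reported 5971/1131/375/13 Alu/L1/SVA/HERV split; pathogenic allele
frequencies for the five curated recessive-disease genes reproduce the
published carrier frequencies (e.g. CFTR q ≈ 0.009 for a 1.8%
carrier rate). Where no value is stated we fixed one realistic value
once: 2% planted FD and FB rates, 10% of HLA alleles withheld from
the registry, a 5% low-complexity mask.

Three deliberate simplifications matter when interpreting green
tests:

* **No read-level simulation.** Depths and allele depths are drawn
  directly; there are no reads, no mapping errors, no reference bias.
  Passing recovery tests shows the *decision logic* is correct, not
  that the upstream callers it consumes are.
* **Shared breakpoints within an event.** All carrier calls of one
  MEI event share a single insertion coordinate, as a MELT-style
  caller reports one breakpoint per event; the configured positional
  jitter (uniform on [−j, +j], j ≤ 20 bp) is applied to the
  reference-database entry instead, emulating coordinate discrepancies
  between databases (TSD-length and alignment-adjustment effects). If
  both the per-sample calls and the database entry jittered
  independently, the representative-to-database distance could exceed
  the ±20 bp tolerance by construction and no matching rule could
  recover 100% of planted classes; merging of positionally scattered
  calls is exercised separately in unit tests.
* **Spacing.** Planted MEI loci sit on a 1-kb grid (offsets within
  980 bp of a slot start), so distinct events are always farther apart
  than the merge tolerance and never chain. Real genomes have
  insertion hotspots where ±20 bp single-linkage can chain distinct
  events; that limitation is inherent to the published rule, not to
  the implementation.

## Genotype flagging

The filter is two-step. Step one flags genotypes: `FD` when
DP < `min_depth` (default 8; missing DP counts as FD), `FB` when a
heterozygote's alternate fraction AD~alt~/DP falls outside
`het_balance` (default [0.2, 0.8], inclusive ends). FD takes
precedence when both hold: without adequate depth, the balance
evidence is not meaningful. Step two maps the per-site flagged
fraction *f* to the first tier whose threshold is ≥ *f*: `vSR` up to
0.05, `vMR` up to 0.20, `vUR` above. Only the `vSR` label and the
FD/FB semantics are fixed by the published description; the exact
cutoffs and the intermediate tier name are defaults in
`flag_config()` and every one is configurable. The downstream rule
is literal: FD/FB genotypes become missing and a site is removed when
its missing fraction **strictly** exceeds 5% (59/1171 = 5.04% is
removed; 58/1171 is kept).

Records with more than one ALT allele are rejected: the filter is
defined on biallelic lines, and multiallelic sites are expected to be
split upstream into one ALT per line.

Sex inference uses the two reported CPM regimes (female ≈ 55,000 X
CPM with MSY < 200; male ≈ 27,500 with MSY > 550). Values between
the MSY thresholds return `ambiguous` rather than a forced label —
only the two clear regimes are defined, and a gap call is exactly the
case a human would review. "Near the female X level" is implemented
as closer to 55,000 than to 27,500.

## MEI landscape

Filtering has two stages because the evidence bar differs: every call
must be caller-PASS, outside the low-complexity mask, and below a
discordant-pair cap; candidate private/singleton events — which
cannot be corroborated by other datasets — additionally need the top
evidence tier (ASSESS 5), a defined target-site duplication and more
than 2 split reads. The discordant-pair rule ("more than the expected
number") comes with no published number; it is operationalised as a
configurable absolute cap defaulting to twice the median
discordant-pair count of the calls being filtered. Mask BED files are
0-based half-open and converted to 1-based coordinates at the
boundary; insertion points are 1-based throughout.

Merging treats two calls as the same event iff they are the same
element class on the same chromosome within ±20 bp — the tolerance
published for the database comparison, reused intra-cohort because no
separate intra-cohort tolerance is stated. Clustering is
single-linkage with the minimum position as representative:
deterministic and invariant to input order, at the cost that chains
longer than the tolerance are possible (documented above). Allele
counts use genotype dosage (het 1, hom 2; maximum per carrier when a
sample contributes several calls to one cluster), and
AF = AC / (2N).

Classification makes the three classes a partition: database presence
dominates (a database-matched locus is `Shared` even with one
carrier), then carrier count separates `CohortPrivate` (≥ 2) from
`Singleton` (1). The alternative reading — shared requires two or
more cohort carriers *and* database presence — leaves
one-carrier-but-known loci unclassifiable, so the
database-presence-dominates definition is adopted.

Context annotation applies CDS > UTR > intron/flank > intergenic
across *all* overlapping transcripts (a UTR of one transcript inside
the CDS of another is CDS), with genic territory the transcript span
±2 kb. GC bias compares insertion-centred 100-bp windows against
10,000 uniformly drawn 100-bp control windows by two-sample
two-sided KS test; windows clipped at chromosome ends are kept and
counted. The AF comparison between Shared and CohortPrivate uses the
two-sided Mann-Whitney test (exact for small untied samples, normal
approximation with tie correction otherwise — the behaviour of R's
`wilcox.test`). Statistics over empty classes are reported `NA`, not
zero.

## NRS library and anchoring

Boundary conventions are read literally from the published
procedure: "longer than 200 bp" is strict (a 200-bp contig drops),
"identity of 95% or higher" drops at exactly 0.95, the presence range
7.5–100× is closed at both ends, and "mapping quality above 20" is
strict (enforced upstream of the coverage table). Identity is
matching bases / alignment block length — the PAF convention; the
identity denominator is otherwise unspecified. Whether presence uses
mean or median per-contig depth is also unspecified; mean is used.

Anchoring combines three evidence types. Partial alignments anchor at
the clip boundary: the target coordinate of the aligned block edge
adjacent to the unaligned portion (strand-aware), requiring ≥ 200 bp
unaligned; among several qualifying alignments the most matching
bases win, ties to the lowest target coordinate. Barcode evidence is
binned into 1-kb windows; the best window is the one with the highest
cross-sample count of distinct barcodes, requires ≥ 2 barcodes, and
ties break to the first chromosome then the lowest window start —
any fixed rule works, this one is deterministic and
permutation-invariant. Discordant pairs get no published aggregation
rule; they are binned like barcodes with the anchor at the median
mate coordinate of the winning window, which keeps the anchor within
the insert-size scatter of the true position. Resolution prefers
partial mapping, then discordant pairs, then barcodes (the published
preference sentence says "partial mapping or discordant paired
reads"; partial mapping is ranked first as the more precise of the
two). Mitochondrial and decoy targets are suppressed rather than
reported; contigs without evidence are `unplaced`.

The generator emits partial alignments at 90% block identity so that
genuinely non-reference contigs survive the 95% redundancy filter —
under the per-block identity definition, a genuine NRS flank
alignment at ~100% identity would otherwise discard its own contig.

## Recessive incidence

With pathogenic allele frequencies $q_i$ mutually exclusive on a
haplotype (the standard curated-panel assumption) and random mating,
the probability a birth carries two pathogenic alleles is

$$\Big(\sum_i q_i\Big)^2 \;=\; \underbrace{\sum_i q_i^2}_{\text{homozygous}}
\;+\; \underbrace{\sum_{i\neq j} q_i q_j}_{\text{compound het}}$$

The identity holds to 10^−12 by construction and is property-tested
on 1000 random panels. Carrier frequency is $c = 2q(1-q)$; its exact
inverse (the smaller quadratic root) and the rare-allele
approximation $q \approx c/2$ are both exposed, because published
incidences computed from carrier screens conventionally use the
approximation (a 2% carrier frequency gives q = 0.01 and "1 in
10,000"). Rendering rounds the reciprocal to the nearest integer.

Cohort carrier comparisons use the 2×2 chi-square with 1 d.f. and no
continuity correction. The p-value is always the exactly computed
chi-square survival function — for a statistic of 0.26 with 1 d.f.
that is p ≈ 0.61, and no attempt is made to reproduce any differently
rounded published p for the same statistic.

## HLA diversity

Gene diversity uses Nei's unbiased estimator
$H = \frac{n}{n-1}(1 - \sum_i p_i^2)$ over gene copies ($n \ge 2$).
Resampling draws batches of 50 **individuals** (100 gene copies)
without replacement — the published procedure says "50 samples" and
does not distinguish individuals from gene copies; individuals are the
natural sampling unit of a cohort — in 5000 batches, averaging
distinct-allele counts (richness), distinct full-sequence counts
(haplotypes) and per-batch gene diversity. The Monte-Carlo mean is
validated against the hypergeometric rarefaction closed form
$E[k] = \sum_a \big(1 - \binom{n-n_a}{m}/\binom{n}{m}\big)$ at
$m = 100$ within three standard errors.

Novelty detection is exact string matching on normalised (uppercased,
gap-free) sequences at two levels: full sequence and translated CDS.
A known full sequence implies a known protein, so the protein-novel
set is nested in the full-sequence-novel set — the generator plants
an intron-variant twin per locus (same CDS translation, one intronic
substitution) precisely to exercise the sequence-novel-only case, and
withholding operates on whole alleles, never single variants,
mirroring allele-level novelty reporting. Partial or ambiguous
registry matches are out of scope.

## Problem sizes and runtime

The validation suites run at sizes chosen to make the statistical
checks sharp while staying desk-scale: genotype-flag recovery on
10^5 genotypes (500 samples × 200 sites), MEI class recovery on
500 samples × 2000 loci over a 3-Mb toy genome, NRS recovery on 30
anchored contigs plus planted negatives, Hardy-Weinberg calibration
on 10^6 diploid draws (99% binomial interval around the expected
10^−4), and rarefaction agreement at the published 5000 × 50
resampling depth. Exact multinomial/binomial 99% intervals are used
for all stochastic count checks, so a correctly calibrated generator
fails any single check with probability ≤ 1%, at fixed seeds.

## Known limitations

* The per-individual MEI burden counts loci carried (carrier status),
  not allele dosage; the published per-individual averages do not
  state which was used.
* The denominator behind the published count of high-AF
  cohort-private events is not reconstructible; the summary reports
  both the count and its proportion over all cohort-private loci.
* Single-linkage merging can chain dense insertion clusters; the
  generator avoids this by construction, real data may not.
* The sex caller returns `ambiguous` between the MSY regimes instead
  of modelling aneuploidies.
* The NRS module consumes precomputed assemblies, alignments and
  coverage; it is the decision logic only, and no contamination
  screening is performed.
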