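---
title: "Detecting extrachromosomal circular DNA with eccscout: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extrachromosomal circular DNA with eccscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccscout)
```

## The detection problem

Extrachromosomal circular DNA (eccDNA) is enriched experimentally by
digesting linear DNA with exonucleases and amplifying the surviving circles
by random rolling-circle amplification (rRCA) with phi29 polymerase. rRCA is
the key to everything downstream: it turns each circular template into a
long head-to-tail tandem concatemer, so every circle boundary in the
amplified material is a copy of the circular junction, and the circle's
sequence becomes strongly over-represented relative to residual linear DNA.

`eccscout` exploits this in two independent ways and intersects the results:

* **Mapping route.** circSeq reads aligned to a linear reference show three
  signatures at a circle locus: wrap-around split reads at the junction,
  outward-facing (discordant) mate pairs straddling it, and a block of
  locally high coverage. Each signature is called separately; regions with
  all three are high-confidence candidates, two out of three give low
  confidence, and low-confidence calls enter further analysis only when no
  high-confidence call exists.
* **Clustering route.** Without any reference, comparative clustering of
  equal-sized circSeq and control subsamples groups reads from the same
  (amplified, hence effectively repetitive) sequence; clusters dominated by
  circSeq reads (> 80%) indicate enrichment that a genomic repeat, present
  equally in both libraries, cannot produce.
* **Comparative route.** Contigs assembled from candidate clusters are
  aligned to the candidate regions and to their *rotated* sequences; a
  candidate confirmed by both routes is reported with very high confidence.

## The wrap-around split rule

A split read has two aligned segments. We call it circular evidence only
when both segments are on one chromosome and strand and the segment
occupying the *later* part of the stored (reference-forward) sequence aligns
*upstream* of the earlier one. Reads crossing a deletion breakpoint produce
the colinear order and are ignored. Working in stored-sequence coordinates
(leading-clip offsets) rather than sequencing order makes the rule
strand-symmetric: a minus-strand junction read reverse-complements into
exactly the same layout, which the test suite verifies explicitly. The
junction interval is (upstream segment start, downstream segment end);
junctions agreeing within `breakpoint_tolerance` (5 bp, absorbing clip
placement ambiguity at homologous junction bases) are pooled, and pooled
support must reach `min_split = 5` reads.

## Coverage, BPM and prominence

Depth counts every reference-consuming base of primary and supplementary
alignments (secondary alignments are excluded). Normalization to bases per
million bases, $\mathrm{BPM}_i = d_i \cdot 10^6 / \sum_j d_j$, makes tracks
with different read lengths and library sizes directly comparable; every
normalized track sums to $10^6$ by construction, which the suite asserts to
a relative $10^{-6}$.

Peaks are local maxima (plateaus allowed, apex at the leftmost plateau
position; plateaus touching a chromosome end are not maxima) filtered on
topographic prominence: apex height minus the higher of the two bases,
where each base is the minimum between the apex and the nearest strictly
higher position (or the boundary). The minimum prominence is 1 BPM. One
practical caveat: BPM units depend on library size, so in very shallow
libraries a single read can exceed 1 BPM of prominence and peaks lose
selectivity — peaks alone, however, never make a candidate (two evidence
types are always required). The peak's reported extent, the maximal
interval with depth above (apex − prominence), is this package's own
definition; boundaries of final candidates come from split junctions
anyway. The implementation is validated against an independent brute-force
prominence oracle on hundreds of random tracks.

## The enrichment score

The score of region $R$ is
$\overline{\mathrm{BPM}}_{circ}(R) / \max(\overline{\mathrm{BPM}}_{ctrl}(R), \epsilon)$
with $\epsilon = 0.1$ BPM guarding empty control regions; without a control
the denominator is the global mean BPM of the circSeq track ("enrichment
relative to a uniform library"). The ratio-of-region-means form is this
package's concrete choice; it is dimensionless, scale-free (independent of
read counts), and on the simulated benchmark reproduces the expected
geometry: with half the circSeq pairs drawn from the concatemer of a
6,695 bp element in a 0.6 Mb genome, the expected score is
$1 + f\,(L_{ref}/L_{elem} - 1) \approx 45$, and measured runs give ~45-47.
Because rRCA amplification is biased, the score ranks candidates by
estimated abundance but is not a quantitative copy-number estimate.

## Comparative clustering: similarity graph and defaults

Reads are prepared by seeded subsampling of the same number of pairs per
dataset (default 6,000, i.e. ~4x coverage of the benchmark genome;
`pairs_for_coverage()` converts a coverage target), dataset name prefixes,
truncation to the minimum sampled read length, and interlacing. The cluster
graph joins two reads when they share at least `min_shared` distinct
canonical k-mers (k = 15, strand-collapsed); clusters are connected
components of at least `min_cluster` reads.

The two defaults are deliberately *scale-aware* rather than fixed:

* `min_shared = round(0.3 * L)` (60 at L = 200). Two error-free reads
  overlapping by $v$ bases share $v - k + 1$ k-mers, so a tiny fixed
  threshold (say 3) links reads overlapping by only ~17 bp. At 4x
  clustering coverage the genomic background then chains into a single
  genome-wide component (the probability of a chain-breaking gap is
  $e^{-\rho \cdot 183} \approx 10^{-3}$ at background read-start density
  $\rho \approx 0.03$/bp), which would fold the enriched element into a
  ~50% mixed cluster and defeat the 80% filter. Requiring ~0.3 L shared
  k-mers demands roughly half-read overlap at the default 1% error rate —
  the same idea as the majority-overlap (≥ 55% of read length) similarity
  rule used by established comparative clustering engines — and confines
  chance background chains to a few hundred bases.
* `min_cluster = max(10, 0.0025 * n_reads)` (60 at 24,000 clustered reads).
  The 80% proportion filter is only meaningful when a cluster is large
  enough that its dataset composition is not binomial noise; a cutoff of
  0.25% of the clustered reads corresponds to the size scale at which
  comparative clustering outputs are conventionally treated as reportable
  top clusters (the benchmark's true cluster holds ~25% of all clustered
  reads).

Cluster granularity differs from graph-refinement engines: single-linkage
components typically merge what such engines split into several clusters of
one supercluster, so the benchmark element appears as one large cluster
rather than ~a dozen linked ones. Mate-pair links (≥ 2 pairs) still join
any split clusters into superclusters. The component semantics are verified
against a brute-force all-pairs shared-k-mer oracle.

Selection is strict: proportion $> 0.8$, so exactly 80% is rejected.
Proportions count individual reads, not pairs (the convention here; mates
usually co-cluster anyway).

## Contigs and the rotated-junction test

Per-cluster contigs come from greedy overlap-layout assembly: repeatedly
merge the pair of sequences with the longest exact suffix-prefix overlap
≥ 31 bp, trying both orientations. With sequencing errors, exact overlaps
fragment the assembly — contigs are then pieces of the element, which is
sufficient because linking only needs 50 aligned bases at 80% identity.
Clusters above 300 reads are subsampled (seeded) before assembly to bound
the quadratic overlap search; at default coverage this still tiles the
element many times over.

A contig crossing the circular breakpoint cannot match the linear region
sequence contiguously. Each region is therefore also searched in rotated
form (end half concatenated with start half); a match crossing the seam
marks the cluster as junction-spanning. This rotated-sequence mechanism is
this package's concrete realization of breakpoint-covering cluster
detection.

## The internal similarity search

Annotation and linking share one ungapped seed-and-extend engine: exact
13-mer seeds on both strands define diagonals, and on each seeded diagonal
the *exact* maximum-scoring segment under +1 match / −2 mismatch is
computed (Kadane scan on the score profile). This dominates an X-drop
extension from the same seeds while staying simple and deterministic. Hits
need identity ≥ 0.8 over ≥ 3 seed lengths (annotation) or ≥ 50 bp
(linking); gapped alignment and e-values are out of scope — candidates and
databases here are close homologs or exact copies.

## What the simulator emulates — and what it does not

`simulate_circseq()` reproduces the geometry of the semi-artificial
benchmark: a ~0.6 Mb reference in three chromosomes, one 6,695 bp planted
element recorded as ground truth, a 9-copy head-to-tail concatemer, 50,000
pairs of 200 bp per dataset, and a matched control from the reference only.
Since no benchmark sequence is published and recovery behavior depends on
geometry rather than composition, sequences are seeded i.i.d. random DNA;
junction variants of the real element (solo-LTR / LTR-LTR) are modeled as
plain copy boundaries, whose split signature is identical. Fragments are
uniform with truncated-normal inserts (mean 500 bp, SD 50 — declared
defaults, not inferred from any published simulation parameters), errors
are substitution-only at 1%, and qualities are constant. The
`enrichment_fraction` default of 0.5 makes the circle the majority species
and lands the enrichment score in the observed ~45-fold range.

The oracle SAM emitter converts read provenance into the alignments a
split-aware mapper would produce (soft clips, `SA:Z:` partner anchors,
proper-pair flags unset for fragments crossing copy boundaries). A green
end-to-end test therefore establishes that the *evidence integration* is
correct given faithful alignments; it does not test a real mapper's
behavior on repeats, indels, quality trimming, or amplification bias —
which is also why the false-positive control simulates flag-clean
background rather than mapper artifacts.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in all BED output; SAM
  input/output converts at the boundary. Strand is collapsed for all
  region evidence (circles are strand-symmetric).
* Split boundaries are consensus medians, rounded to integers.
* `max_insert` defaults to mean + 3 SD of proper-pair |TLEN| from the first
  100,000 pairs; with fewer than two proper pairs it degrades to infinity.
* Empty inputs: no alignments give an all-zero track whose normalization
  errors (no enrichment computable); empty evidence lists yield empty
  candidate sets, not errors.
* Discordant-peak candidates without split support use intersection (not
  union) boundaries — the conservative choice.
* Reported low-confidence candidates are capped at 10,000.
* Ties in ranking break by length (longer first), then chromosome/start,
  making every output table deterministic; reruns with one seed are
  byte-identical, which the suite checksums.

## Known limitations

Quality trimming is out of scope (reads are expected pre-trimmed). No
external mapper is wrapped: mode `map`/`all` consumes SAM produced by the
simulator's oracle or by the user's aligner of choice. The enrichment score
is comparable in spirit, not bit-identical, to other tools' scores (no
published formula exists to match). Indel errors, quality models and
amplification bias are not simulated, and cluster counts are not comparable
to graph-modularity engines (one component here may correspond to several
clusters there).
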