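---
title: "Quantifying and correcting TE expression: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and correcting TE expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecoex)
```

This vignette is the package's own account of the statistical machinery it
implements: the multi-mapping read-assignment model, the
pre-mRNA/retained-intron correction, the normalization and clustering
conventions, the consensus co-expression network, the association screens,
and — because every one of these is validated on simulated data — what the
synthetic-data generator does and does not emulate.

## The quantification problem

Young TE families consist of near-identical genomic copies, so a short read
from one copy aligns equally well to many. Aligners report up to a
multiplicity cap (200 here, matching common practice for TE work) and tag
each read with its alignment count (`NH`). Summing only uniquely mapped
reads systematically under-counts the youngest, least diverged copies —
precisely the biologically interesting ones. A second, independent error
source is genomic position: a TE inside an intron receives reads from
pre-mRNA and retained introns of its host gene, inflating apparent TE
expression with signal that is really host-gene transcription.

`tecoex` addresses the first problem with an EM mixture model and the
second with a read-depth discount, in that order — EM first, correction
after — because correcting before assignment would require the effective
uniquely-mappable length of every locus, which is itself what makes TE
quantification hard.

## EM assignment

Each fragment contributes one counting unit (pairs collapse to one
fragment). Fragment `r` has a candidate set `A_r`: the TE loci its
alignments overlap by at least one base. Any-overlap is the simplest rule
that is fully testable; alignments landing in a gene exon without touching
a TE contribute no candidates, and fragments with only such alignments are
excluded so that ordinary mRNA reads never enter the TE model. With locus
abundances `pi` the complete-data model is a multinomial mixture; the
E-step computes `w_rl = pi_l / sum(pi_l')` over `l'` in `A_r`, the M-step
re-estimates `pi` from the summed weights. Initialization is uniform.

Two properties are enforced and tested: total EM mass equals the ingested
fragment count exactly (the E-step weights of each fragment sum to 1), and
the observed-data log-likelihood is non-decreasing over iterations. The
log-likelihood is concave in `pi` (a sum of logs of linear functions), so
the EM fixed point is a global maximum; the test suite and the acceptance
script verify agreement with a direct grid-plus-quasi-Newton maximizer on
every two-locus configuration up to 20 fragments and sampled three-locus
configurations. Configurations in which several abundance vectors achieve
the same likelihood (e.g. all fragments shared between two loci) have no
unique ML count vector; these are detected by multi-start probing and
compared on likelihood only.

*Stopping rule.* Production defaults stop when the largest per-locus count
change falls below 1e-3 or after 100 iterations — adequate for counting,
where downstream noise dwarfs the residual. When EM is compared against
the independent ML oracle the iteration is run to `tol = 1e-9`, because the
comparison is about the fixed point, not the stopping rule: near a
degenerate optimum the count change per iteration can be an order of
magnitude smaller than the remaining distance to the optimum, so a loose
tolerance would measure the stopping rule rather than the estimator.

*Unique-only mode* implements single-best-alignment semantics: any
fragment with multiplicity above 1 is discarded entirely. Per-locus unique
counts can never exceed EM counts, which is asserted as an invariant.

## The read-through correction

For an intronic TE, the flanking intron portions (the intron interval left
of the TE and right of it) see read depth only from pre-mRNA/retained
introns, while the TE interval sees that depth plus autonomous TE
transcription. Depth is reads per effective base, `count / (len -
read_len)`, the effective length discounting positions where a read can no
longer start inside the interval. The corrected count subtracts the
read-through share:

```
count'_TE = count_TE * (1 - (R_IL + R_IR) / (2 R_TE))    if the ratio < 1, else 0
```

Choices the formula leaves open, and how this package resolves them:

- `count_TE` is the EM-weighted count (correction runs after assignment).
- Flank counts tally fragments by any-overlap, regardless of multiplicity;
  a fragment crossing the TE/flank boundary counts for the flank.
- A TE abutting one end of its intron has a single flank; its depth stands
  in for both sides and the locus is flagged `single_flank`.
- A flank not longer than the read falls back to `count / len` so the
  depth stays finite.
- Corrected counts may be fractional; downstream stages accept reals.
- Exonic TEs (any exon overlap, including non-coding genes) are zeroed and
  excluded from family totals; intergenic TEs (at least 1000 bases from
  every gene boundary) pass through uncorrected; loci outside genes but
  closer than 1000 bases are labeled `proximal` and kept out of intergenic
  analysis sets.

The correction is deliberately one-sided: it can only reduce counts, and
`0 <= corrected <= raw` is asserted everywhere. It is also known to be
imperfect at interval edges: reads overhanging a locus boundary are counted
for both the TE and the flank, so even with no read-through a short TE in a
long intron loses a few percent (bounded by roughly `read_len / len_TE`).
The recovery simulations quantify this bias rather than hide it: with a
2 kb TE the mean recovered autonomous count sits a few percent below truth.

## Normalization

Size factors come from gene counts only and are applied unchanged to TE
matrices: TE counts are too sparse and too family-correlated to anchor a
median-ratio estimator. The two-step DEGES scheme guards the median-ratio
assumption (most genes not DE) against multi-tissue panels where it fails:
step 1 normalizes with plain median ratios over genes positive in every
sample; genes are then ranked by a one-way F-statistic across sample groups
on step-1-normalized `log2(x+1)` counts (across-sample variance when no
groups are given), the top 30% are eliminated, and step 2 recomputes median
ratios on the remainder. The eliminated fraction and the ranking statistic
are configurable; 30% with an F ranking recovers known simulated depths to
about 1% with 30% planted 4-fold DE genes, where one-step normalization is
off by about 7%. With `drop_fraction = 0` the two steps coincide exactly.

Size factors are defined up to a common scale; equivariance holds for
factor ratios (scaling one sample's counts by `c` moves its factor ratio
against every other sample by exactly `c`). The median over an even number
of reference genes is the arithmetic midpoint.

The log transform is `log2(x + 1)`. A dispersion-fitted variance
stabilizing transform would differ in the low-count range, but every
downstream analysis here is correlation- or rank-based, and the planted
structure recovery results are insensitive to this choice.

## Clustering and NMI

Features are locus-level by default: loci with fewer than 5 raw counts in
every sample are removed, X/Y-chromosome features excluded, and the top 150
by variance of the log2 values retained (ties broken by feature id so
selection is deterministic). Samples are clustered by average-linkage
(UPGMA) on Euclidean distances — the dissimilarity is configurable,
Euclidean being the package default — and the tree is cut at `k` clusters.
Each cluster takes the majority true label; agreement is scored by
normalized mutual information, `I(U;V)` divided by the arithmetic mean of
the two partition entropies (a geometric-mean variant is available). NMI is
0 whenever either partition is a single cluster. Baselines permute the true
labels with and without replacement 100 times and report the mean NMI;
between random partitions NMI has a positive small-sample bias, which is
why the packaged clustering scenario uses 60 samples (3 tissues of 20) —
large enough that the baseline settles near 0.03 while the planted
clustering reaches 1.

## Consensus co-expression networks

Per tissue: signed adjacency `a_ij = ((1 + cor_ij)/2)^beta` with `beta =
14` by default (a scale-free-fit selector over candidate powers is
provided, falling back to 14 when no fit is defined), then the topological
overlap matrix

```
TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
```

Consensus across tissues is the element-wise minimum — an edge is only as
strong as its weakest tissue. Modules come from average-linkage clustering
of `1 - TOM` with a *static* cut (height 0.995, minimum size 30):
deterministic and sufficient for planted-block recovery, in place of
dynamic tree cutting, whose exact behavior is not reproduced here. Module
eigengenes are first principal components of the standardized member
submatrix, unit-norm, oriented to correlate positively with their members
on average. Membership (kME) is the feature-eigengene correlation; strict
members exceed 0.6 in every tissue, anti-correlated module pairs fall
below -0.7 in every tissue, TE modules contain more than 10 TE features,
and core TE modules are majority-TE.

## Association screens

The KZFP x TE family screen computes Pearson correlations per tissue,
two-sided t-distribution p-values, and Benjamini-Hochberg q-values within
each tissue batch; a pair is co-expressed at `q < 0.05` (the significance
measure is configurable; BH is the default adjustment), and replication
counts tissues with a consistent sign. Locus-level follow-up re-tests each
significant family's loci in the hit tissue with BH over the follow-up
batch. Binding overlap builds the 2x2 co-expressed x bound table over the
shared (KZFP, family) universe — binding-assayed KZFPs crossed with
families present in both datasets — and applies Fisher's exact test. Peaks
bind a locus when, after 250-base extension, they reach it; a peak exactly
250 bases away binds, 251 does not. A locus is expressed when some sample
exceeds 5 reads, strictly.

The L1HS 5' screen regresses log2 L1HS 5'-end signal on log2 gene
expression with optional covariates (log2 effective library size — the sum
of normalized counts —, batch, radiation, and the intronic-TE module
eigengene). All `2^4` covariate subsets are fitted with the gene term
always included (its coefficient is the reported quantity, so it is not
subject to selection); the model minimizing `AICc = AIC + 2k(k+1)/(n-k-1)`
wins, models with `n - k - 1 <= 0` being excluded. Reported per gene:
coefficient, p, partial eta-squared (`t^2 / (t^2 + df)`), BH q within
tissue; genes replicate at `q < 1e-4` in at least two tissues with
consistent sign. L1HS 5' regions themselves come from local alignment
(match +1, mismatch -1, gap -2) of each locus against the first 300
consensus bases, accepted at 60% identity over 50+ aligned bases with a
minimum score of 30 — the score floor screens out the short chance local
alignments that unrelated sequence produces at the identity/length
thresholds alone. 5'-truncated copies yield no region.

## The synthetic-data generator

The generator emulates the data properties the methods are sensitive to:

- *Multi-mappability with a dial.* TE copies are a family consensus
  mutated at a per-base divergence; at divergence 0 all copies are
  identical (every read multi-maps), by 0.2 essentially every 48-mer is
  copy-specific. Alignment discovery is exact sequence match on both
  strands via a genome k-mer index — reads are error-free, so simulated NH
  values are exact.
- *Read-through.* Per gene, an expected `retention_fraction` of its mature
  fragments are re-emitted as intron-contained fragments tiling introns
  uniformly, covering any embedded TE. There is no literature value for
  this fraction; the default 0.3 is a free parameter of the simulation,
  not a biological claim.
- *Planted co-expression.* Feature groups (TE families; named gene groups
  such as KZFP-like, immune-like, mitochondrial-like) load on latent
  factors; per-sample factor values are tissue means plus unit Gaussian
  noise; expected abundance is `exp(baseline + loadings x factors)` scaled
  to the target library size; counts are negative binomial with variance
  `mu + mu^2/dispersion`. Anti-correlated structure (a TE module against
  an immune-like module, intronic TEs against mitochondrial-like genes) is
  planted by opposite-sign loadings on one factor.

What it does not emulate — and what passing tests therefore do not show —
includes sequencing error and quality, GC and positional bias, splice
isoforms, polymorphic (non-reference) TE insertions, paired-end fragment
geometry, and aligner-specific artifacts such as soft-clipped spliced
reads. Results on real data additionally depend on annotation quality and
on the aligner's multimapping behavior, neither of which the simulation
stresses.

## Scenario geometry and problem sizes

The packaged validation scenarios fix their own study conditions:

- *Mappability bias*: 200 intergenic loci (20 families of 10) with family
  divergence graded 0 to 0.25, equal true abundance (baseline spread 0),
  3 samples of 20k fragments. Unique-only counts correlate strongly with
  uniquely-mappable length; EM counts do not.
- *Read-through removal*: full-length 2 kb TEs almost filling a 2.4 kb
  intron (flanks of a few hundred bases). Short flanks make the flank
  depth estimate conservative (effective-length inflation), so with zero
  autonomous transcription the discount ratio sits well above 1 and
  corrected counts collapse to zero with a wide noise margin.
- *Recovery*: the same TEs in a roomier 3.2 kb intron with moderate
  retention (0.3) and reduced baseline spread, 50 replicate simulations.
  Roomier flanks shrink the overhang bias described above; the mean
  recovered-to-true ratio is about 0.9, reflecting the correction's known
  conservative bias.
- *Tissue clustering*: 3 tissues of 20 samples; tissue factor means are
  separated by 8 noise standard deviations, emulating the dominant,
  cleanly separable tissue signal of large normal-tissue panels.
- *Networks*: 2 tissues x 50 samples x 300 features in two planted blocks
  at within-block correlation 0.9.
- *Screen calibration*: 1000 null and 50 planted (r = 0.6) pairs at n =
  50, 30 replicates, for FDR and power; 150 replicates of n = 100
  regressions with three active covariates of four and residual SD half
  the signal SD, for AICc subset recovery.

These sizes keep the full validation under a minute of compute apiece
while leaving each criterion a comfortable noise margin.

## Known limitations

- The correction cannot distinguish autonomous transcription of an
  intronic TE from read-through confined to the TE itself (e.g. an
  alternatively processed transcript ending inside it); it only uses flank
  depth.
- Edge effects at locus boundaries bias the correction a few percent
  conservative; the bias grows as `read_len / len_TE`.
- Static tree cutting will split or merge modules differently from
  dynamic methods on real, unevenly sized modules.
- The family-level screen inherits whatever bias remains in family
  aggregation after exonic exclusion; locus follow-up mitigates but does
  not remove this.
- NMI's small-sample bias makes permutation baselines at a few dozen
  samples noticeably positive; compare clusterings at matched sample
  sizes.
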