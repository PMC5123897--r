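---
title: "Statistical methods for promoter capture Hi-C interactomes"
author: "chicogs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for promoter capture Hi-C interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chicogs)
```

## The setting

Promoter capture Hi-C (PCHi-C) enriches a Hi-C library for ligation
products involving baited restriction fragments that contain annotated
promoters. After interaction calling, the data are a *peak matrix*: one row
per (bait fragment, other-end fragment) pair, with one CHiCAGO interaction
confidence score per cell type. A score of at least 5 in a cell type marks
a high-confidence interaction there, and the other end of such a pair is a
promoter-interacting region (PIR). Everything in this package starts from
such a matrix, plus the standard companions of a regulatory-genomics
analysis: per-cell-type regulatory feature activity states, gene
expression, GWAS summary statistics, a reference haplotype panel for
linkage disequilibrium (LD), a recombination map, eQTL tables and a coding
consequence annotation.

The package implements the bespoke statistics such an interactome
analysis needs — specificity scores, distance-matched and bait-shift
randomizations, an overdispersion-adjusted contingency test, a
directionality-index TAD caller, single-causal-variant fine mapping, the
COGS gene score, a TAD-based baseline score, and the blockshifter
tissue-set enrichment test — together with a synthetic-data generator that
produces every input with the statistical structure these methods assume,
so that the whole pipeline is testable without any external download.

## Specificity scores

For a quantitative profile $x_i$ over cell types $i \in I$ (a CHiCAGO
score, or asinh-transformed expression), the specificity score of cell
type $c$ is a weighted mean of differences,

$$ s_c = \frac{\sum_{i \neq c} d_{c,i}\,(x_c - x_i)}{\sum_{i \neq c} d_{c,i}}, $$

where the weights $d_{c,i}$ are Euclidean distances between the cell-type
columns of the *complete* dataset. The weighting prevents panels that
over-represent a lineage (several macrophage preparations, multiple CD4
subsets) from deflating each other's scores: near-duplicate cell types
receive little weight in each other's sums. The score is translation
invariant, scales linearly with $x$, and is identically zero for a
constant profile.

Gene-level scores restrict to interactions whose bait maps exclusively to
one protein-coding promoter and which have, in at least one cell type,
both a score $\ge 5$ and an active enhancer at the other end. Scores are
zeroed where the enhancer is not active, asinh-transformed, and capped at
4.3 (a raw score of about 36.8) so that extreme scores do not dominate;
the per-interaction specificity vectors are averaged within genes. Gene
partitions use `stats::kmeans` with many random restarts (default 12
clusters, 10,000 restarts); cluster enrichment for the most specifically
expressed genes is the proportion difference $e_{c,k} = p_{c,k} - q_k$,
whose expectation is zero for a random gene draw.

The per-bait variance test asks whether a promoter's interactions share
cell-type specificity: each interaction inherits the maximum cluster
specificity score of its cluster, the statistic is the variance of these
values within baits (single-interaction baits drop out), and the null
permutes the interaction-to-cluster labels.

## Chromatin: TADs, randomized PIRs, coupling tests

The directionality index contrasts, for a 25 kb sliding window stepped at
the matrix resolution (5 kb), the contact sums $A$ (upstream flank, up to
1 Mb) and $B$ (downstream flank): $\mathrm{DI} = \mathrm{sign}(B-A)\,
[(A-E)^2/E + (B-E)^2/E]$ with $E=(A+B)/2$. Flanks are truncated
*symmetrically* near chromosome ends so a symmetric contact matrix scores
exactly zero everywhere. The track is smoothed (±25 kb running mean) and
standardized; boundaries are placed at the sign change between a
qualifying negative local extremum followed by a qualifying positive one
(|z| > 0.5), i.e. where upstream bias gives way to downstream bias.
Replicate TAD sets are merged by reciprocal-overlap matching (≥ 75% of
both lengths, a design choice — nearest-boundary matching would be the
alternative) with boundary positions averaged.

TAD-crossing statistics classify high-confidence cis interactions whose
bait lies inside a TAD by whether the other end leaves the bait's TAD. The
null reshuffles the (left flank, right flank) bait-to-boundary distance
pairs across baits — jointly, preserving each bait's relative position in
a domain of the permuted size — and re-classifies each interaction by its
signed distance.

Feature enrichment at PIRs uses distance-matched randomization: each cis
PIR is reassigned to a random non-PIR fragment in the same log2 distance
bin (width 0.25; widened once when empty) from its bait, preserving the
binned distance histogram and set size exactly; 100 draws give the null
mean and sd from which fold enrichment and a z-score are computed.

Activity-coupling analyses build 2×2 tables over (interaction, cell type)
records — promoter activity × enhancer activity at linked ends, or
enhancer activity × interaction presence — pooling poised, repressed and
inactive states as "non-active". Because interactions sharing a bait are
correlated, the Pearson chi-square is overdispersed; baited fragments are
resampled with replacement (block bootstrap), and the observed statistic
is scaled by $\sqrt{2}$ divided by the sd of the 1000 bootstrap
statistics, with the p-value from the 1-df upper tail. A caveat worth
knowing: the bootstrap sd equals $\sqrt{2}$ only when the observed table
sits exactly at independence; at a noisy null draw the bootstrap
distribution is non-central and the adjustment deflates the statistic
further, which makes the procedure conservative but not exactly
chi-square calibrated — a property of the procedure itself, visible in
the package's calibration tests.

## GWAS preparation, fine mapping, COGS

GWAS summary statistics pass a spurious-association filter: a SNP with
p < 5×10⁻⁸ is dropped unless some other SNP with p < 10⁻⁵ is within 50 kb
or in LD (r² > 0.6) with it. The grammar of the rule leaves open whether
the p < 10⁻⁵ condition binds both arms; we apply it to both. The MHC
(GRCh37 chr6:25–35 Mb) is masked throughout for its extreme LD.

The genome is partitioned into recombination blocks by cutting the
cumulative genetic map every 0.1 cM (the last block may be short). Within
each block, untyped panel SNPs (MAF > 1%) receive the p-value of their
maximal-r² typed partner when that maximum exceeds 0.6, and are flagged
imputed; unmatched panel SNPs and study SNPs absent from the panel are
discarded.

Fine mapping assumes at most one causal variant per block. For each SNP,
$z$ is recovered from the two-sided p-value (only $|z|$ is identifiable,
which suffices since the Bayes factor depends on $z^2$), the effect
variance is $V = 1/(2 n f (1-f))$ — times $1/(s(1-s))$ for case-control
traits with case proportion $s$ — and the approximate Bayes factor is
$\sqrt{V/(V+W)}\,\exp[z^2 W / (2(V+W))]$ with prior effect variance
$W = 0.2^2 = 0.04$ by default (the prior sd of 0.2 on the standardized
effect is conventional; the value is configurable). Posterior
probabilities of causality normalize the ABFs within the block (in log
space); an `include_null` option adds a null model to the denominator but
is off by default, matching the single-causal-variant synthesis.

COGS aggregates these posteriors per gene: within each block, the block
gene score sums the posteriors over three disjoint SNP sets — coding SNPs
of the gene; promoter SNPs (bait fragment ± one flanking fragment,
a reading of "bait and flanking fragments" since the flank count is a
design choice); and PIR SNPs for the tissue set (fragments with a score
≥ 5 interaction in at least one tissue of the set), with precedence
coding > promoter > PIR. Blocks combine under independence:
$\mathrm{genescore} = 1 - \prod_b (1 - \mathrm{genescore}_b)$. Genes with
score > 0.5 are reported as prioritized. The TAD-based baseline replaces
interaction information with TAD colocation: posterior mass of each
block restricted to the TAD (coding SNPs removed), combined the same way,
assigned to genes by TSS, maximized over cell types.

Because posteriors are normalized within every block regardless of
signal, blocks with no association still carry unit mass; genes whose
regulatory footprint covers much of a block inherit that mass. This is
inherent to the method, and it is why the synthetic genetic map matters
(below).

## Blockshifter

The blockshifter is a competitive test for GWAS posterior mass at PIRs of
a test tissue set against a control set. Fragments in both sets, or
overlapping no GWAS signal, are discarded; remaining fragments form runs
("blocks") separated by at most one non-PIR fragment. The statistic is
$\delta$, the difference of mean per-fragment posterior mass between test
and control fragments. Spatial correlation (LD and fragment adjacency)
inflates the variance of $\delta$, so the null is built by permuting
whole blocks: unmixed blocks have their block-level labels re-dealt
(preserving the observed label counts; implemented as a permutation of
the label multiset, which makes the scheme label-symmetric, so swapping
test and control negates Z exactly), and mixed blocks are circularized
and their label sequence rotated by a uniform random offset (the identity
rotation is allowed; a flag excludes it). The result is the empirical
z-score $Z = (\delta - \bar\delta_{null}) / \mathrm{sd}(\delta_{null})$,
with a degenerate (zero-variance) null reported as $Z = 0$ and flagged.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with planted
truth returned for recovery tests. Its defaults are the package's frozen
study conditions:

* **Fragments.** Exponential cut spacing with mean 4096 bp — the expected
  HindIII fragment length — tiling each chromosome.
* **Panel and clusters.** 17 blood cell types in two lineages (myeloid
  and lymphoid); each interaction belongs to a lineage-specific or
  invariant cluster, with scores ≥ 5 in member cell types and sub-5
  elsewhere. Interaction distances are lognormal (median 300 kb, log-sd
  0.9), matching the long-tailed distance profile of promoter
  interactions.
* **Enhancer coupling.** A fraction (0.9) of other ends carries a distal
  enhancer; with coupling strength 0.8, activity follows high-confidence
  interaction status; otherwise it is an independent Bernoulli(0.3).
  Expression is additive in the number of interacting active enhancers
  (+1.5 per enhancer, Gaussian noise sd 1).
* **Haplotypes.** Mosaic copying: founders drawn from per-SNP frequencies,
  each further haplotype copying a random predecessor and switching
  template at intensity 30 per cM. This produces r² decaying with genetic
  distance (half-distance a few kb, the fast end of European-ancestry
  panels) without claiming any population-genetic model. Panel density
  defaults to one SNP per 3 kb — dense-array rather than sequencing
  density.
* **Genetic map.** Piecewise-constant background rates (gamma-distributed
  around 1 cM/Mb). Narrow (~2 kb) hotspots are available but off by
  default: hotspot-scale 0.1-cM blocks are smaller than one restriction
  fragment, and a block fully contained in a single fragment hands its
  entire normalized posterior to whichever gene touches that fragment —
  a degeneracy of block-normalized posteriors that the smooth default
  avoids.
* **GWAS.** z-scores are drawn per block from $N(\Sigma\lambda, \Sigma)$
  with $\Sigma$ the block LD matrix (ridge-regularized when needed) and
  $\lambda$ non-zero only at a planted causal SNP (non-centrality 6 by
  default); no phenotypes are simulated.
* **eQTLs.** For a configured fraction of genes the lead eQTL SNP sits
  inside a true PIR; background genes receive leads at distances drawn
  from the pooled bait-to-PIR distance distribution, independent of PIR
  status, so they overlap PIRs only at the chance rate. Each lead is
  accompanied by its r² ≥ 0.5 partners as FDR-significant rows, mimicking
  the multi-SNP footprint of real eQTL signals.

What passing tests on these data do *not* show: the generator has no
trans-chromosomal structure beyond labels, no coverage or visibility
biases, Gaussian (not count-based) expression noise, and LD without
population history; real-data behavior on those axes is untested.

## Numerical and inferential choices

* Coordinates are 0-based half-open internally; peak-matrix text files
  are 1-based inclusive at the start coordinate, BED-like files stay
  0-based. Trans pairs carry an undefined (`NA`) distance and are
  excluded from distance-conditioned operations (they still contribute
  PIR SNPs to COGS).
* Posterior normalization is done in log space (log-sum-exp); p = 0 is
  clamped to the smallest positive double and logged, zero MAF is an
  error.
* Empirical permutation p-values use $(1 + \#\{perm \ge obs\})/(1 +
  n_{perm})$. On discrete overlap counts this is conservative
  (super-uniform) because ties with the observed value count in full;
  alongside it the package reports the tie-randomized exact p, which is
  uniform under exchangeability. Calibration tests assert uniformity of
  the randomized version and validity (no excess of small values) of the
  conservative one.
* Ties in argmax specificity are broken by panel order; ranking ties in
  gene prioritization by gene id.
* k-means restarts, bootstrap counts (1000), randomization draws (100)
  and permutation counts (1000 or 10,000) default to the conventional
  values; every stochastic function takes an explicit seed.

## Problem sizes

The test-suite and acceptance experiments run at desk scale, chosen so
each recovery or calibration study completes in minutes on one core:
regions of 2–4 Mb, 6–50 captured genes, panels of about 60–1300 SNPs and
40–100 haplotypes, 100–200 simulation seeds per calibration, and 199–1000
permutations per test. The end-to-end COGS recovery study uses a 4 Mb
region with 8 genes; the eQTL calibration uses 50 genes with about 20
interactions each (the real interactome averages ~31 unique interactions
per bait).

## Known limitations

* COGS inherits the block-normalized posterior: genes spanning many
  blocks accumulate score even for traits with no signal near them, so
  scores are comparable within a trait but are not error probabilities.
* Fragment-level attribution blurs when LD extends beyond one fragment:
  posterior mass leaks from a causal PIR into adjacent fragments, which
  weakens gene recovery as LD lengthens.
* The overdispersion adjustment is exactly calibrated only at
  independence (see above).
* `run_pipeline()` orchestrates the synthetic route end to end; on real
  data the individual stage functions are the interface, with the same
  defaults.

## A short worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, chrom_lengths = c(chr1 = 3e6), n_genes = 10)
res <- run_pipeline(pipeline_config(seed = 7, sim = cfg), "pipeline-out")
res$blockshifter
head(res$prioritized)
```

The run writes the imputed GWAS table, per-gene COGS scores, prioritized
genes, gene specificity matrix, the blockshifter comparison of the two
lineages, and a JSON manifest (seeds, thresholds, versions) sufficient to
reproduce the outputs byte-wise.
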