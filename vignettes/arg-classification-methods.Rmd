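---
title: "Methods: genome-wide ARG-based classification of STR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide ARG-based classification of STR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argstr)
```

## The problem

Microsatellite (STR) panels used for germplasm classification are often
genome-wide but extremely sparse: on the order of a hundred multi-allelic
loci spread over ten linkage groups, with a few percent missing data.
Classical clustering of raw allele codes with Euclidean-style distances
treats alleles as coordinates and ignores how variation is actually
generated — by coalescence, mutation and recombination. `argstr`
implements an alternative: estimate a simplified ancestral recombination
graph (ARG) from the panel, read pairwise relatedness off the graph as
the age of most recent common ancestors (MRCAs), and summarize the
resulting distance matrix as a classification tree and k-cluster
partition. The cacao germplasm panel — 952 samples, 96 STR loci over 10
chromosomes, allele counts of 3 to 30 per locus, ~2.8% missing — is the
motivating shape, and the package's evaluation stack reproduces the
published contingency-table metrics for that panel exactly.

## Pipeline overview

1. **Imputation** (`impute_missing`) — missing genotypes are filled from
   the most frequent complete per-chromosome haplotype compatible with
   the sample's observed alleles; per-locus modal allele as fallback;
   seeded random tie-breaks.
2. **Staging** — either each chromosome separately (*solo*,
   `stage_solo`) or all chromosomes concatenated into one sequence after
   a random circular arrangement (*ensemble*, `build_ensemble` +
   `stage_ensemble`): uniform random chromosome order on a ring,
   independent fair-coin flips of chromosome orientation, and a uniform
   random cut of the ring.
3. **Recombination detection** (`detect_recombinations`) — a
   multi-allelic generalization of the four-gamete test produces a
   *recomatrix* of per-sample, per-boundary breakpoint support.
4. **subARG construction** (`build_subarg`) — the staged loci are
   segmented at supported boundaries; identical haplotypes within each
   segment coalesce; flagged recombinants receive genetic-exchange
   nodes.
5. **Age estimation and distances** (`estimate_ages`,
   `pairwise_distances`) — node ages from carrier counts; the distance
   between two samples is the mean MRCA age over non-mixing segments.
6. **Consolidation** (`average_distances`) — the elementwise mean over
   N randomized ensemble iterations (default N = 25) or over the solo
   per-chromosome matrices.
7. **Classification** (`nnj_tree`, `cut_to_k`, `linkage_partition`,
   `mds_embed`) and **evaluation** (`contingency`, `assign_labels`,
   `precision_recall`, `f_index`, `partition_metric`,
   `agreement_index`).

`run_pipeline()` orchestrates all of this from a single config with one
master seed; per-iteration seeds are derived by a counter scheme so
increasing N never reshuffles earlier iterations.

## The recombination detector

For every inter-locus boundary and every consensus setting (a window
*grain* and an *offset*), haplotype classes are counted over the
flanking windows: `L` classes on the left, `R` on the right, `J`
jointly. Two multi-state characters are consistent with a single tree
only if `J <= L + R - 1`, so the incompatibility evidence is

    ev = J - (L + R - 1),   when positive.

The samples charged are the members of the `ev` smallest joint classes
(ties resolved toward the lexicographically smallest joint haplotype),
and each receives score `ev` for that setting. Scoring by the evidence
magnitude rather than a flat count makes the consensus threshold
meaningful on multi-allelic data, where strong breakpoints produce
large excesses: with the default four-setting consensus
(grains {g, g+1} x offsets {0, 1}) and the default threshold of 5, an
entry survives only when the summed evidence across settings is
substantial. After thresholding, non-maximal boundaries within
`peak_distance` (default 2) of a stronger one are suppressed, ties
keeping the leftmost — accepted breakpoints are therefore at least
`peak_distance` apart.

Defaults are `grain_size = 1`, `peak_distance = 2`, `threshold = 5`,
matching the validated operating point for sparse STR panels. The
threshold is a consensus score, so it scales with the information
content of the panel: small toy panels (tens of samples) legitimately
use `threshold` 1-2, and the package's oracle tests do so explicitly.

A structural caveat: a *single* recombinant between two otherwise
tree-like parental lineages produces only three of the four gametes and
is mathematically indistinguishable from a third lineage; detection
requires both exchange directions or homoplasy in the window. The
planted-recombinant fixture in the test suite is constructed
accordingly.

## subARG structure, ages and distances

Within each non-mixing segment, samples carrying identical haplotypes
are merged under a coalescent node (largest class first, ties by
lexicographic haplotype); the remaining lineage roots are joined under
a single segment root, so the per-segment structure is a two-level
forest plus root. A sample flagged at a boundary is routed through a
genetic-exchange node whose two parents carry the material on either
side of the breakpoint. The result is deliberately a *subgraph-style*
estimate — only events with direct pattern support appear.

The age of a node on a segment is the expected standard-coalescent
depth for its carrier count `k`:

    f(k) = sum_{j=2..k} 2 / (j (j-1)) = 2 (1 - 1/k)

in coalescent units, with `f(1) = 0`. Any strictly increasing function
of `k` would preserve the downstream rank structure; this choice has
testable closed forms (`f(2) = 1`, `f(4) = 1.5`) and saturates at 2,
mirroring the expected TMRCA of a large panmictic sample. Two
consequences worth noting:

* ages are **non-decreasing** (not strictly increasing) toward the
  roots, because a genetic-exchange node has a single carrier and
  therefore age 0, equal to its leaf child;
* two samples with identical profiles sit at distance `f(2) = 1`, the
  minimum attainable — an MRCA age is never 0 for distinct samples.

The pairwise distance is the mean over segments of the age of the
pair's lowest common ancestor on that segment. If a segment leaves a
pair un-joined (possible only in degenerate graphs, since a segment
root is always added), the oldest age on the segment plus one
coalescent unit is used as a finite "beyond the graph" value.

## Why ensemble staging helps

A single sparse chromosome carries too few loci to resolve ten
populations. Concatenating all chromosomes lets the detector and the
identity-class structure exploit associations *between* physically
unlinked loci — exactly the linkage disequilibrium that domestication
bottlenecks and multi-genic selection induce in crop panels. Randomized
order, orientation and cut ensure that chromosome adjacencies are not
fixed artifacts of one arrangement; averaging distances over N
iterations integrates out the arrangement noise. The consolidation
change decays as O(1/N), and the running-mean change at N = 25 is well
below 20% of its N = 2 value, which is why N = 25 is the default and
larger N buys little.

## Classification and evaluation

* **Tree**: standard neighbor joining on the consolidated matrix with
  negative branch lengths clamped to zero (the "relaxed" variant).
* **Partition** (`cut_to_k`): the tree is pruned at its internal edges
  into local subtrees, which are merged by smallest average inter-part
  distance until k clusters remain. An earlier design — removing only
  the k-1 longest internal edges — proved degenerate on noisy
  neighbor-joining trees, where a handful of outlier clades absorb
  every cut and leave one giant cluster; pruning to local subtrees
  first makes the merge step do the work and recovers the same blocks
  on clean inputs (the exhaustive two-block oracle in the tests).
* **Alternative partitions**: average/complete-linkage `hclust` cuts,
  and classical (Torgerson) MDS for visualization, with negative
  eigenvalue mass reported as a non-Euclidean-ness diagnostic.
* **Labeling** (`assign_labels`): the computed clusters are matched to
  the reference clusters by the column permutation maximizing the
  contingency-table diagonal — solved exactly by dynamic programming
  over column subsets, with lexicographically smallest permutation on
  ties.
* **Metrics**: per-pair precision `m[i,j]/p_j` and recall
  `m[i,j]/c_i`; per-pair F as their weighted harmonic mean with weight
  `alpha2` (1 = equal weighting); overall
  `F = sum_i (c_i/n) max_j F[i,j]`. Tree agreement uses the partition
  metric `d_p = E(T1) + E(T2) - 2 v` over non-leaf edges and identical
  splits, normalized to the agreement index `A = 1 - d_p/(E1+E2)`;
  classes split across subtrees are reduced to their largest subset
  before comparison. Empty clusters score 0 with a warning rather than
  erroring, so degenerate clusterings remain comparable. Display
  rounding is half-up to two decimals; all internal comparisons are
  exact.

## The synthetic panel generator

`simulate_panel()` provides ground truth the real panel cannot: a known
partition and true pairwise TMRCAs.

* **Demography**: populations evolve as independent Kingman coalescents
  until the divergence depth (default 5 coalescent units), then merge
  into one ancestral pool.
* **Mutation**: stepwise (allele +/- 1, reflecting at 0), the standard
  STR model, at `mutation_rate` per locus per coalescent unit of
  branch. The default 0.35 was chosen once, by pilot simulation, as the
  rate at which realized distinct-allele counts at panel scale fall
  inside the target 3-30 band for at least 90% of loci.
* **Linkage**: within a chromosome the genealogy switches between loci
  with probability `recombination_rate` (default 0.1); across
  chromosomes, each chromosome reuses one shared genome-wide genealogy
  with probability `bottleneck` (default 0.5), which induces the
  between-chromosome LD that motivates ensemble staging.
* **Panel shape defaults**: 10 populations with the published panel's
  composition (952 samples), 96 loci over 10 chromosomes with the
  largest linkage groups first, third and fifth, and a missing fraction
  of 2562/91392.

What the generator does **not** emulate: diploid unphased genotypes,
selfing/outcrossing dynamics, selection, allele-length constraints
beyond reflection at zero, and non-random missingness. Passing tests on
synthetic panels therefore demonstrate recoverability of clean
population structure under the stated model, not performance on real
germplasm with admixture or genotyping artifacts.

## Numerical and design choices at genuinely open points

* Imputation haplotypes are defined per chromosome — the largest span
  over which "haplotype" is meaningful in a linkage map — and
  "most common" counts only complete haplotypes compatible with the
  sample's observed alleles; all ties are seeded-uniform.
* The ring cut may fall inside a chromosome block, not only between
  blocks; a cut index of 0 reproduces the uncut ring.
* Chromosome "length" for solo selection is locus count; explicit
  chromosome lists are also accepted.
* Deterministic tie-breaks everywhere (leftmost boundary, lexicographic
  haplotype, lowest index), so one seed fully determines a run; the
  run manifest records per-file checksums and derived seeds, and
  re-running a config reproduces artifacts bit-identically.
* Degenerate inputs: an all-zero distance matrix embeds at the origin;
  a locus missing in every sample is an imputation error; fewer than 2
  loci cannot be staged for detection; n < 3 cannot form a tree.

## Problem sizes used by the test suite

The suite exercises the full ensemble pipeline (N = 25, k = 10) on a
10-population x 20-sample panel with the 96-locus map, small-panel
property checks on hundreds of randomized subARGs, and exhaustive
oracles (all k! label assignments up to k = 8, all 4- and 5-taxon
topologies, all splits on trees up to 6 leaves). These sizes keep the
default check fast while covering every operation; the same pipeline
runs unchanged at the full 952-sample shape.

## Known limitations

* The detector's consensus settings are a configurable approximation of
  a multi-run statistical consensus; only the headline parameters
  (grain 1, peak distance 2, threshold 5) are pinned.
* Per-segment coalescence is resolved only to identity classes plus a
  segment root, so between-class relatedness within a segment is not
  graded — discrimination comes from averaging many segments and
  layouts.
* The age function is a rank-preserving convention, not a calibrated
  estimator of time; distances are comparable within a run, not across
  mutation-rate regimes.
* Agreement-index comparisons against external reference trees require
  those trees; the package computes the index but ships no external
  reference.
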