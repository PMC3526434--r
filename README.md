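# argstr

Genome-wide, ARG-based population classification from sparse,
multi-allelic STR (microsatellite) panels.

Germplasm collections are routinely genotyped at ~100 STR loci spread
over all chromosomes — far too sparse for dense-marker methods, and
multi-allelic in a way that defeats SNP-oriented tools. `argstr`
classifies such panels by estimating a simplified ancestral
recombination graph (ARG): chromosomes are staged either separately
("solo") or concatenated after a random circular ordering, flipping and
cutting ("ensemble"); a pattern-based recombination detector with a
multi-setting consensus produces a recomatrix of high-confidence
breakpoints; a subARG is built from it; node ages are estimated from
carrier counts over non-mixing segments; and the distance between two
samples is the mean age of their most recent common ancestor (MRCA)
across segments,

    d(x, y) = mean over segments s of age( MRCA_s(x, y) ),
    age of a k-carrier node = f(k) = sum_{j=2..k} 2/(j(j-1)) = 2(1 - 1/k)

in coalescent units. Distances from N randomized ensemble iterations
(default N = 25) are averaged into one consolidated matrix, summarized
as a relaxed neighbor-joining classification tree, a k-cluster
partition, average/complete-linkage alternatives and a classical MDS
embedding.

Against a reference partition, the contingency table `m[i,j]` (rows =
reference clusters with sums `c_i`, columns = computed clusters with
sums `p_j`, total `n`) is labeled by the diagonal-maximizing column
permutation and scored with

    Prec[i,j] = m[i,j]/p_j,   Rec[i,j] = m[i,j]/c_i,
    F[i,j]    = (a2+1) Prec Rec / (a2 Prec + Rec),
    F         = sum_i (c_i/n) max_j F[i,j]          (a2 = alpha^2, 1 by default)

and trees are compared by the partition metric
`d_p(T1,T2) = E(T1)+E(T2)-2v` (non-leaf edges, identical splits) and
the agreement index `A = 1 - d_p/(E1+E2)`.

A coalescent STR panel simulator (stepwise mutation, population
divergence, within-chromosome recombination, bottleneck-induced
between-chromosome LD, injected missingness) supplies ground-truth
panels shaped like the cacao germplasm set (952 samples, 96 loci over
10 chromosomes, 3-30 alleles per locus, ~2.8% missing).

## Worked example 1: metrics on a published contingency table

The package ships the published 10x10 reference-vs-computed tables for
the cacao panel as worked-example inputs:

```r
library(argstr)
tab <- cacao_contingency("complete")   # 952 samples, ensemble method
lab <- assign_labels(tab)              # diagonal-maximizing labeling
fx  <- f_index(lab, alpha2 = 1.0)
round(fx$F, 4)
#> [1] 0.9184
data.frame(cluster   = rownames(lab),
           precision = round_half_up(diag(fx$precision)),
           recall    = round_half_up(diag(fx$recall)))
#>    cluster precision recall
#>  Amelonado      0.94   0.72
#>  Contamana      0.94   0.91
#>    Criollo      0.93   1.00
#>    Curaray      0.97   0.97
#>     Guiana      0.91   0.98
#>    Iquitos      0.97   0.85
#>    Maranon      0.95   0.97
#>   Nacional      0.78   0.88
#>      Nanay      0.95   0.99
#>      Purus      0.79   0.90
```

Curaray is the strongest group (0.97/0.97); Amelonado's recall (0.72)
reflects its samples assigned to Guiana and Purus, and Nacional's
precision (0.78) the few Purus samples assigned to it.

## Worked example 2: full pipeline on a simulated panel

```r
pack <- simulate_panel(sim_config(n_populations = 3,
                                  samples_per_population = 12,
                                  loci_per_chromosome = rep(12, 4),
                                  seed = 42))
out <- tempfile()
run_pipeline(run_config(genotypes = pack$genotypes, map = pack$map,
                        reference = pack$truth, method = "ensemble",
                        n_iterations = 10, k = 3, threshold = 3, seed = 7,
                        out_dir = out))
cat(report_run(out))
#> # Classification run summary
#>
#> - method: ensemble (N = 10 iterations), k = 3 clusters
#> - seed: 7
#> - panel: 36 samples x 48 loci; 2.78% missing on input
#> - distinct alleles per locus: 2-8
#> - tree: 36 leaves, 33 internal edges
#> - partition: 3 clusters, sizes 12, 12, 12
#> - consolidation change at N = 10: 0.03564 (vs 0.2237 at N = 2)
#>
#> ## Agreement with the reference
#>
#> - overall F-index (alpha^2 = 1): 1.0000
```

The run directory also contains the consolidated PHYLIP distance
matrix, the Newick tree, the partition and MDS coordinates as TSV, the
labeled contingency CSV, a metrics JSON and a manifest with per-file
checksums — re-running the same config reproduces every artifact
bit-identically.

A thin command-line front-end is installed with the package
(`system.file("cli", "argstr", package = "argstr")`) with subcommands
`run --config cfg.yaml`, `simulate --config sim.yaml`,
`evaluate --table M.csv` and `report RUNDIR`.

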