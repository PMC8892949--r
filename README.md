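# cladescape

Phylogenomic support is usually reported on a single preferred tree.
`cladescape` maps it across *all* candidate trees: for a set of named major
clades it enumerates every rooted arrangement — 105 for five clades, the
double factorial (2k−3)!! in general — re-estimates per-branch **gene
concordance factors** (gCF) and **site concordance factors** (sCF) on each
arrangement against a fixed set of gene trees and a partitioned
supermatrix, and embeds the resulting landscape in treespace by
Robinson–Foulds distance. It is built for the situation typical of rapid
radiations (the motivating system is the Hawaiian Drosophilidae), where
short basal internodes make bootstrap values saturate while genuine
gene-tree and site-level conflict remains.

The quantities at the core:

* `gCF` = 100 × (decisive gene trees containing the branch) / (decisive
  gene trees); a gene tree is decisive iff it touches all four subtrees
  adjacent to the branch.
* `sCF` = mean over sampled quartets (one taxon per adjacent subtree) of
  100 × s₁/(s₁+s₂+s₃), where the sᵢ count clean binary site patterns
  supporting each of the three quartet arrangements; chance level is
  100/3 ≈ 33.3.
* Landscape = one record per clade arrangement with means over the k−2
  clade-level branches, plus a principal-coordinates embedding of the
  pairwise Robinson–Foulds matrix.

Around that core the package implements the rest of the same study design:
quartet likelihood mapping (JC69 pruning likelihood, 3- and 7-region
simplex census), the SOWH parametric-bootstrap topology test, Mk-model
fitting with stochastic character mapping and transition censuses for
discrete traits classified from rearing records (specialist/generalist
rule: generalist iff two substrates each exceed 1/4 of records or none
exceeds 2/3), and a multispecies-coalescent simulator that produces
complete fixtures with known truth (gene trees, alignments, partition
files, clade maps, traits with their true histories).

## Worked example

```r
library(cladescape)

bundle <- make_fixture(list(n_genes = 80, sites_per_gene = 200), seed = 11)
bundle
#> Synthetic fixture: 24 taxa, 80 genes x 200 sites
#> Planted clade topology: (((((cladeA,cladeB),cladeC),cladeD),cladeE),outgroup);
#> True trait transitions: 2

landscape <- scan_landscape(bundle$gene_trees, bundle$alignment,
                            bundle$clade_map, n_quartets = 50, seed = 11)
glance(landscape)
#> # A tibble: 1 x 7
#>   n_topologies branches_per_topology top_gcf_id top_gcf top_scf_id top_scf  seed
#>          <int>                 <dbl> <chr>        <dbl> <chr>        <dbl> <dbl>
#> 1          105                     3 aa            29.2 aa            40.1    11

head(tidy(landscape)[order(-tidy(landscape)$mean_gcf), ], 3)
#> # A tibble: 3 x 6
#>   topology_id newick                         mean_gcf mean_scf    axis1    axis2
#> 1 aa          (((((cladeA,cladeB),cladeC),c…     29.2     40.1 -0.00160 -1.68e-4
#> 2 ag          (((((cladeA,cladeC),cladeB),c…     25.8     36.8 -2.11     8.84e-1
#> 3 bn          ((((cladeA,cladeB),cladeC),(c…     25.8     38.1  1.88    -4.60e-2
```

The arrangement with the highest mean gCF and sCF (`aa`) is the planted
topology, recovered from 80 genes despite per-branch gCF values of only
25–35 — exactly the short-internode regime the landscape is designed to
expose (`autoplot(landscape)` draws the treespace map, point size = mean
gCF, color = mean sCF). Bipartition-level summaries show *which* clades
carry the signal; here the planted `cladeA+cladeB` pairing leads:

```r
bs <- bipartition_summary(landscape)
head(bs[order(-bs$gcf), ], 3)
#> # A tibble: 3 x 5
#>   clade_split           size n_topologies   gcf per_topology
#> 1 cladeA+cladeB            2           15  35   <tibble [15 x 3]>
#> 2 cladeA+cladeB+cladeC     3            9  28.8 <tibble [9 x 3]>
#> 3 cladeA+cladeC            2           15  25   <tibble [15 x 3]>
```

The trait layer runs from rearing records to transition censuses:

```r
calls <- classify_substrates(bundle$rearing)
states <- setNames(calls$state, calls$species)
fit <- fit_mk(bundle$species_tree, states, "ER")
maps <- stochastic_maps(bundle$species_tree, states, fit,
                        n_maps = 200, seed = 11)
count_transitions(maps, generalist_state = "generalist")
#> Mean transitions per map: 3.18 (terminal 0.72, internal 2.46)
```

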