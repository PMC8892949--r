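---
title: "Concordance landscapes across clade arrangements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance landscapes across clade arrangements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladescape)
```

# The problem

Rapid radiations — the Hawaiian Drosophilidae are the motivating example —
leave short internodes at the base of the tree. Across thousands of gene
trees, lineage sorting under the multispecies coalescent then produces
genuine conflict: a branch can carry a bootstrap of 100 while only a fifth
of the informative gene trees actually contain it. Support measures built
for this situation are the **gene concordance factor** (gCF: the percentage
of decisive gene trees whose bipartition set contains a branch) and the
**site concordance factor** (sCF: the mean, over quartets drawn around a
branch, of the percentage of decisive sites supporting the branch's
arrangement; chance level is 100/3 because a clean binary site pattern can
support exactly one of the three arrangements of a quartet).

`cladescape` treats these factors not as decoration on one preferred tree
but as a **landscape**: every possible rooted arrangement of the named
major clades is enumerated — 105 arrangements for five clades, the double
factorial (2k−3)!! in general — and gCF/sCF are re-evaluated on every
clade-level branch of every arrangement, against the *same* fixed gene
trees and supermatrix. The result is embedded in treespace by
Robinson–Foulds distance so hotspots of genic and site support can be seen,
and compared with the maximum-likelihood topology. Around that core sit the
supporting analyses from the same study design: quartet likelihood mapping,
the SOWH parametric-bootstrap topology test, and stochastic character
mapping of a discrete ecological trait (oviposition substrate) under an Mk
model.

# Concordance definitions and their edge cases

A branch of a binary unrooted tree touches four subtrees; their taxon sets
form the branch's quadripartition. The definitions implemented are the
standard ones from the concordance-factor literature:

* a gene tree is **decisive** for a branch iff it contains at least one
  taxon from each of the four adjacent sets; a decisive gene tree is
  **concordant** iff its bipartition set, restricted to the shared taxa,
  contains the branch's induced bipartition;
* a site is **decisive** for a sampled quartet iff all four characters are
  unambiguous nucleotides forming a clean binary pattern (`xxyy`, `xyxy`,
  `xyyx`); gaps, `N`, and 3- or 4-state sites are ignored. Ambiguity codes
  other than `N` are collapsed to `N` on input, mirroring the practice of
  replacing non-nucleotide characters with missing data.

Two conventions matter and are deliberate:

* quartets with zero decisive sites are *skipped*, not scored zero, so sCF
  is an unweighted mean over informative quartets ("average proportion of
  informative sites");
* a branch with no decisive gene trees (or no informative quartets) has an
  *undefined* factor, reported as `NA` and printed as `NA`, never 0.

Decisiveness depends on the full quadripartition, not just the
bipartition. When gene trees contain every taxon the distinction vanishes
and gCF is a function of the bipartition alone — the property the
bipartition-level summary (`bipartition_summary()`) relies on — but with
genes missing whole clades, two arrangements sharing a bipartition can
disagree on which genes are decisive. `cladescape` computes gCF per
quadripartition and caches on the full four-set context, so the output is
correct in both regimes.

# The landscape scan

`scan_landscape()` enumerates rooted arrangements of the ingroup clades by
recursive leaf insertion, de-duplicated and ordered by a canonical form
(children sorted by smallest descendant label), then attaches the outgroup
at the root. Enumerating rooted k-clade topologies and rooting between the
ingroup and the outgroup is equivalent to enumerating unrooted (k+1)-leaf
trees; both give 105 at k = 5. Each arrangement gets a deterministic
two-letter identifier (`aa`, `ab`, ...) in canonical order; a seeded
shuffle is available for cosmetic parity with randomly labeled figures,
but reproducible identifiers are the default.

Per arrangement, the scanned branches are exactly the k−2 clade-level
internal branches (3 for k = 5). The ingroup/outgroup split and all
within-clade branches are shared by every arrangement, so they are excluded
from the per-arrangement means — including them would shrink all contrasts
toward a common constant. Clade-level branches are expanded to full-taxon
quadripartitions by pooling clade members; sCF quartets draw one taxon
uniformly from each pooled set.

The pairwise Robinson–Foulds matrix over the (k+1)-leaf skeletons is
embedded by classical multidimensional scaling (principal coordinates,
`cmdscale`), truncating negative eigenvalues to zero. One caveat is
inherent to the geometry: the RF matrix over a complete, highly symmetric
set of skeletons has repeated eigenvalues, so the two plotted axes are an
arbitrary basis of a degenerate eigenspace — the embedded *distances* and
the spectrum are reproducible, the axes only up to rotation within that
subspace. Plots (`autoplot()`) encode mean gCF as point size and mean sCF
as color.

# Likelihood core

Quartet likelihood mapping and the SOWH test both need maximized
log-likelihoods on fixed topologies. The scoring model is JC69 by default,
computed by Felsenstein pruning over compressed site patterns with
per-pattern scaling; a GTR model (no rate heterogeneity) is available. The
JC69 path runs in compiled code and is tested equal to a generic R
implementation and to an exhaustive sum over ancestral states. Keeping the
default model this simple is a deliberate trade: every number the likelihood
core produces can be verified against closed forms and enumeration, and the
model is a logged, flagged parameter rather than a hidden default.

Numerical choices:

* branch lengths are optimized cyclically, one branch at a time by
  golden-section search on the log scale, bounded in [1e−8, 10], starting
  from 0.1, sweeping until the log-likelihood gain falls below 1e−6 (or 100
  sweeps, flagged as non-convergence); ascent is monotone because an update
  is kept only if it does not lower the likelihood;
* likelihood-mapping weights are `exp(lnL_i − max lnL)` normalized to sum
  to one, which cannot underflow;
* the seven simplex regions use a dominance rule with threshold 2 (corner
  i iff `p_i > 2 p_j` and `p_i > 2 p_k`; else side ij iff both beat
  `2 p_k`; else center), with ties resolved toward the lower-numbered
  region. The original likelihood-mapping partition is geometric and its
  exact boundaries are not restated here; the threshold is a parameter so
  the census can be recomputed under a different convention;
* the SOWH p-value uses the add-one estimator `(1 + #{Δ_rep ≥ Δ_obs}) /
  (1 + n_reps)`, so it is never exactly zero.

# The SOWH test at quartet scale: a known limitation

`sowh_test()` follows the standard prescription: optimize branch lengths
for both fixed topologies, take Δ = lnL\*(best) − lnL\*(null), simulate
replicates under the *null topology with its fitted branch lengths*, and
recompute Δ per replicate. The package's own calibration experiments (see
the test suite) show that at quartet scale with a few hundred sites this
plug-in test is markedly **conservative**: the fitted internal branch
length nearly determines Δ, so replicate Δ values center on the observed
one and small p-values are almost never produced (rejection rate 0 out of
200 at α = 0.05 under the null in the suite's calibration run). The same
experiment with replicates drawn under the *true* generating tree — which
breaks the coupling between the statistic and the simulation parameters —
is well calibrated, confirming that the behavior is a finite-sample
property of the plug-in bootstrap, not an implementation defect. Users
should read small-sample SOWH p-values as conservative bounds; power
against well-separated topologies is unaffected (the power checks in the
suite reach the minimum attainable p).

# Discrete-trait layer

Rearing records are classified per species by the generalist rule: a
species is a generalist if any two substrate categories each exceed 1/4 of
its records, or if no category exceeds 2/3; otherwise it is a specialist in
the unique category above 2/3; species without records are unknown.

The trait model is Mk with ER/SYM/ARD structures; the default is ER with a
flat root prior, both recorded in every output, since nothing in the study
design pins them down. Likelihoods use pruning over matrix exponentials
(closed form for ER, `ape::matexpo` otherwise); rates are maximized on the
log scale. Stochastic maps sample node states from their joint conditional
distribution and then sample each branch path conditional on its endpoints
by **uniformization** with dominating rate μ = max |Q_ii|. Uniformization
was chosen over rejection sampling because its runtime is bounded even for
short branches with unlikely endpoint combinations. Transition censuses
report the per-map mean, the split between terminal and internal branches,
the state-pair matrix, and the fraction of changes involving the
generalist state; the max-posterior summary tree marks branches where
parent and child summary states disagree. The per-map mean and the
summary-tree change count are different accountings and are both exposed
without any claim that they agree.

# What the synthetic data emulate — and what they do not

`make_fixture()` generates the complete study shape with known truth: 24
taxa in five ingroup clades (6/5/4/4/2) plus a 3-taxon outgroup on an
ultrametric species tree in coalescent units; 200 genes of 300 sites each,
simulated as multispecies-coalescent gene trees (one lineage per taxon,
exponential coalescence at rate k(k−1)/2 per branch) scaled to 0.03
substitutions per coalescent unit and evolved under JC69; a partitioned
supermatrix; and an ER trait with its full true character history.

The internode lengths are calibrated to the two concordance regimes the
design requires: radiation-base internodes of 0.25 coalescent units (the
planted ladder joins at 3.5, 3.75, 4.0, 4.25 CU), which put clade-level
branch gCF in the 15–40 band, and clade stems of at least 2.5 CU plus a
3-CU ingroup stem, which keep clades monophyletic in well over 85% of gene
trees. These values were fixed once against those target bands and are
defaults, not fitted quantities. The closed form for gene-tree concordance
across an internode of T coalescent units, 1 − (2/3)e^(−T), is exposed as
`expected_concordance()` and anchors the simulator's validation.

Real transcriptome supermatrices differ from this fixture in ways that
matter for interpretation: missing data are pervasive (the fixture's genes
are complete), substitution processes are heterogeneous across genes and
sites (the fixture is homogeneous JC69), alignment error exists, and
discordance can also come from introgression, which the simulator does not
model. Passing tests therefore demonstrate that the *estimators and the
scan* behave correctly under clean coalescent variation — not that any
empirical number from a particular data set will be reproduced.

# Problem sizes used in the checks

The test suite exercises the pipeline at sizes chosen to make the
statistical tolerances meaningful on a single CPU: exhaustive oracles on
trees of up to 4 tips (likelihoods) and 8 tips / 50 genes (gCF); 2,000
gene trees per internode length for the coalescent closed form (3 binomial
standard errors); a 10-taxon × 50,000-site signal-free alignment for the
sCF null (3 Monte-Carlo standard errors around 33.3); 200 meta-replicates
of 20 bootstrap replicates for SOWH calibration; the full default fixture
(105 arrangements × 3 branches, 100 quartets per branch) for the
end-to-end landscape run; and 8,000 stochastic maps against brute-force
node conditionals on 4-tip trees.

# Other limitations

* The conservation score is a transparent mean pairwise-identity statistic
  per column, averaged over columns — a stand-in with the same intent as,
  but not bit-compatible with, trimming-tool similarity scores.
* Gene/site discordance factors for the two specific alternative quartet
  arrangements are not computed (only the three-way classification of
  gene support via `classify_gene_support()`).
* No rate heterogeneity, no partitioned models, no amino-acid alphabets,
  and no topology search: trees are inputs, never estimated here.
* Concordance is re-evaluated on fixed gene trees and sites under each
  constraint arrangement; gene trees are not re-estimated per constraint.
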