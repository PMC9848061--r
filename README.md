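# orthosignal

Orthologous-signal enrichment and model-fit diagnostics for phylogenomic
datasets.

Deep phylogenomic conflicts — the textbook case is whether sponges
(Porifera) or comb jellies (Ctenophora) branch first in the animal
tree — are fought over supermatrices of hundreds of orthogroups. Many of
those orthogroups cannot even recover uncontroversial groups (the major
phyla) as monophyletic in their own gene trees, a symptom of hidden
paralogy and gene–species tree conflict. `orthosignal` is for
phylogeneticists who want to *measure* that problem and *filter* on it:

* **Clan testing and filtering.** A clan is the unrooted analogue of a
  clade: a taxon set separable from all other leaves by removing one
  edge. For each gene tree and each user-defined clan with members
  `P` present (`|P| >= 2`), the clan is *recovered* iff some single edge
  separates exactly `P` from the rest, *violated* otherwise, and
  *insufficient* when `|P| < 2`. Orthogroups are retained when they
  recover at least `min_clans` (default 3) of the countable clans.
* **Supermatrix assembly** with partition bookkeeping, constant-site
  removal, occupancy and outgroup-restricted subsetting.
* **Information metrics** per orthogroup: variable and
  parsimony-informative sites, mean bipartition support, long-branch
  scores, saturation, treeness, RCV, RCFV
  (`sum_j sum_i |f_ij - fbar_j| / n`), chi-square compositional
  homogeneity, plus Wilcoxon comparisons between filter-passing and
  filter-failing orthogroups.
* **Concordance factors.** Gene concordance factor of a branch `x`:
  `gCF = 100 * concordant / decisive`, where a gene tree is decisive iff
  the branch restricted to its taxa keeps >= 2 taxa on both sides; site
  concordance from seeded quartet sampling.
* **Posterior-predictive adequacy.** PPA-DIV / PPA-MAX / PPA-MEAN with
  `|Z| = |obs - mean(rep)| / sd(rep)` and the strict verdicts
  `|Z| < 2` adequate, `|Z| > 5` rejected.
* **Chain diagnostics**: bpcomp-style per-bipartition `maxdiff` /
  `meandiff` between two tree samples, normalized Robinson–Foulds
  distances.
* **Alignment choice**: the three-aligner rule — agreement iff all
  pairwise distances < 0.15, else argmax column similarity, else seeded
  random pick.
* **Synthetic data**: seeded generators for species trees with clan
  structure, gene trees with dropout and clan-violating relocations,
  alignments with gamma rates and lineage compositional shifts, and
  exact-profile constructors for worked examples.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a
simulated 70-taxon, 100-orthogroup dataset and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_clan_filter.R
Rscript analysis/03_supermatrix.R
Rscript analysis/04_information_metrics.R
Rscript analysis/05_concordance.R
Rscript analysis/06_model_fit.R
```

Stage 2 prints, for the simulated dataset:

```
recovered-clan histogram (n = 5..0): 21 0 1 24 45 9
retained 22 / 100 orthogroups at min_clans = 3 (22%)
```

i.e. 21 orthogroups recover all five countable clans, 45 recover just
one, and the >= 3-clan filter keeps 22% — inside the 17–33% band the
published datasets show. It also rebuilds the five published per-n
recovery profiles and refilters them:

```
        dataset orthogroups retained retained_pct
      Chang2015         200       34         17.0
 Whelan2015_D10         210       40         19.0
 Whelan2015_D20         178       29         16.3
     Simion2017        1719      457         26.6
 Whelan2017MCRS         127       42         33.1
```

Stage 5 shows the filter's effect on concordance (gene trees that pass
the filter agree with the species tree far more often):

```
original: mean gCF 70.6, mean sCF 61.8 over 67 branches
filtered: mean gCF 98.7, mean sCF 71.9 over 67 branches
gCF increased on 67 / 67 comparable branches after filtering
```

and stage 6 scores model adequacy of both supermatrices against a
homogeneous null — the filtered matrix fits better on the
lineage-heterogeneity statistics (PPA-MEAN drops from `|Z| = 21.3`,
rejected, to `|Z| = 2.8`, intermediate) — and summarizes two simulated
chains (`maxdiff 0.067`, converged by the `maxdiff < 0.3` rule).

In code, the core loop is three calls:

```r
library(orthosignal)
trees  <- read_tree_list("results/synthetic/gene_trees.nwk")
clans  <- read_clans("results/synthetic/clans.tsv")
report <- check_clans(trees, clans)
filter_orthogroups(report, min_clans = 3)
```

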