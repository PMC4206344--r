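# phylocover

Does a conservation site network chosen for *threatened* species also
capture above-average taxonomic and phylogenetic diversity? `phylocover`
answers that question for gridded presence/absence data and a rooted,
branch-length phylogeny, the setting of regional analyses such as Important
Bird Area (IBA) networks. It is aimed at conservation biogeographers and
community phylogeneticists who want the full chain — per-cell diversity
surfaces, null models, effectiveness statistics, hotspot maps — as tested,
scriptable R functions.

## What it computes

For each grid cell and season the four standard diversity measures:

* taxonomic richness *S*;
* red-list richness (number of flagged taxa);
* phylogenetic richness — Faith's PD, root-inclusive:
  `PD(A) = sum of branch lengths on the union of root-to-tip paths of A`,
  so `PD(all taxa) = total tree length`;
* phylogenetic distinctiveness — mean pairwise patristic distance,
  `MPD(A) = mean over unordered pairs {i,j} in A of d(i,j)` (undefined for
  fewer than two taxa).

Two resampling analyses on top of them:

* **Tip-shuffle null** — is the branch length spanned by the flagged taxa
  different from that of a random equally sized set? Labels are shuffled
  across the fixed tree 1,000 times; the 2.5%/97.5% percentiles of the
  replicate PD form the null interval.
* **Effectiveness** — for a site set of *k* distinct cells with diversity
  `D_site`, each replicate draws *k* cells uniformly without replacement
  and scores `E(r) = (D_site − D_rand(r)) / D_site`; the network is
  effective for a measure when the 2.5–97.5% interval of `E(r)` excludes 0.
  `D` is either the per-cell mean (*average* mode) or the measure of the
  union of taxa over the set (*total*, complementarity mode).

Plus top-decile hotspot masks per measure with Jaccard overlaps, species /
branch-length coverage summaries, maximum clade credibility consensus from
a Newick tree sample, taxon lumping, and a synthetic scenario generator
(Yule tree, spreading-dye ranges on a gradient landscape, seasonal range
shifts, flagged subsets, focal sites) so the entire pipeline runs and is
tested without any external data. See the vignette in `vignettes/` for the
methods in full.

## Worked example

```r
library(phylocover)

report <- run_analysis(list(
  seed = 42, n_reps = 1000,
  scenario = list(seed = 42)   # standard synthetic scenario:
))                             # 200 species, 60x60 grid, sites in
print(report)                  # cells holding flagged species
```

```
Site-network diversity analysis

Tip-shuffle null for flagged-subset branch length
  flagged tips: 10   replicates: 1000
  observed: 7.328   null 95% CI: [5.686, 7.753]
  observed is inside the interval (no departure from random placement)

                metric    season    mode   observed mean_effectiveness ci_lower ci_upper significant
              richness  breeding average  10.350000             0.1979  -0.0075   0.3841       FALSE
           rl_richness  breeding average   1.275000             0.6742   0.5098   0.8039        TRUE
        phylo_richness  breeding average   6.648353             0.1798   0.0228   0.3189        TRUE
 phylo_distinctiveness  breeding average   1.647059            -0.0037  -0.0430   0.0412       FALSE
 ...
```

Reading the output: the flagged ("red-list") taxa span 7.33 units of
branch length, inside the null interval — they sit randomly on the tree,
exactly as simulated. The site network nonetheless holds 67% more flagged
species and 18% more summed branch length per cell than random networks
(intervals exclude 0), while mean pairwise distance shows no effect — the
spatial side of the argument, recovered on synthetic data with known truth.
`plot(report)` draws the dot-and-interval panels; `effectiveness_table()`,
`coverage_summary()` and the written `report.json` / `*.tsv` / hotspot
rasters expose everything programmatically.

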