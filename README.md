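# microassembly

Null-model analysis of microbial community assembly from 16S rRNA gene
amplicon data. Given an ASV (amplicon sequence variant) count table, a
rooted phylogeny whose tips are the ASVs, a taxonomy and sample metadata,
the package quantifies which ecological processes — selection, dispersal,
or drift — structured the observed communities, and detects clade-level
competitive exclusion. It was built for engineered microbiomes such as
anaerobic granular sludge, where floating and settled biofilm granules
from replicated bioreactors are contrasted, but the statistics are general.

## The statistics

Four complementary null models are implemented, each authored in this
package and validated against brute-force oracles and self-calibration
simulations:

* **NTI** (nearest taxon index). For each sample, the observed mean
  nearest taxon distance `MNTD = mean_k min_{l != k} d_kl` over patristic
  distances `d` is compared with a richness null that redraws the sample's
  membership uniformly from the observed taxa pool (999 randomisations,
  presence/absence only). `NTI = -(MNTD_obs - mean_null) / sd_null`;
  NTI > +2 indicates phylogenetic clustering driven by environmental
  filtering, NTI < -2 overdispersion driven by competition.
* **βNTI + RC-bray → QPE** (quantitative process estimates). For every
  sample pair the abundance-weighted between-community nearest taxon
  distance `βMNTD = 0.5 (Σ_k f_xk min_{l∈y} d_kl + Σ_k f_yk min_{l∈x} d_kl)`
  is z-scored against a null that shuffles taxa across all tips of the
  phylogeny. Pairs with βNTI > +2 are assembled by variable selection,
  < -2 by homogeneous selection. Remaining pairs are passed to an
  abundance-based Raup–Crick null on Bray–Curtis: each community is
  reassembled at its observed richness (membership ∝ occupancy, reads ∝
  pool relative abundance) and `RC = 2 Pr(null < obs) - 1` with half
  weight on ties. RC > +0.95 means dispersal limitation (+drift),
  RC < -0.95 homogenizing dispersal, otherwise undominated turnover.
* **NST** (normalised stochasticity ratio), with Jaccard (incidence) and
  Ružička (abundance) dissimilarity under proportional-proportional (PP)
  and proportional-fixed (PF) taxa-richness constraints. Pairwise observed
  dissimilarity `D` is compared with the null expectation `E`; NST is 1
  when turnover sits at the null expectation (fully stochastic) and 0 at
  the attainable extreme (fully deterministic); group means are reported
  as percentages and compared between groups with a permutation test
  ("PANOVA").
* **Competitive lottery model**. ASVs are binned into family-level clades;
  in each sample a clade's top ASV is a lottery "winner" when it captures
  strictly more than 90% of the clade's reads. Winner prevalence (fraction
  of eligible samples with a winner) and winner diversity (normalised
  entropy of winner identities) summarise each clade, and winner status is
  compared across sample categories.

A synthetic-community generator (`simulate_dataset()`, `simulate_community()`)
produces phylogenies, clade-conserved niche traits and ASV tables under six
known assembly regimes, so every inference stage can be validated against
ground truth.

## Worked example

```r
library(microassembly)

ds  <- simulate_dataset(n_taxa_pool = 256, depth = 2000, seed = 42)
res <- run_pipeline(ds$table, ds$tree, ds$taxonomy, ds$metadata,
                    seed = 42, reps = 199, nst_reps = 100,
                    permutations = 199)
```

The preset emulates a 24-sample study — 2 positions (floating/settled) x
2 nucleic-acid types (DNA/cDNA) x 3 reactors x 2 replicates — with settled
granules assembled under homogeneous selection and floating granules under
drift. The pipeline filters contaminant lineages, rarefies to the minimum
depth, and runs every model:

```
> res$table
ASV abundance table: 248 taxa x 24 samples, total reads 48,000

> head(res$alpha, 3)
           sample_id richness  shannon
1  floating_DNA_R1_a      187 4.268547
2 floating_cDNA_R1_a      182 4.230397
3  floating_DNA_R2_a      183 4.254574

> subset(res$qpe_summary, group == "settled.DNA")
         group                process   fraction n_pairs
16 settled.DNA     variable_selection 0.00000000       0
17 settled.DNA  homogeneous_selection 0.46666667       7
18 settled.DNA   dispersal_limitation 0.06666667       1
19 settled.DNA homogenizing_dispersal 0.00000000       0
20 settled.DNA            undominated 0.46666667       7

> res$panova[["jaccard.PF"]]
PANOVA (floating vs settled): statistic 0.6321, p = 0.0050 (199 permutations)
```

Homogeneous selection is the modal defined process in the selected
(settled) category and absent from the drift-assembled floating one, the
per-position NST group means differ (Jaccard/PF: 69.7% floating vs 64.5%
settled), and every metric-constraint combination separates the two
positions decisively (PANOVA p = 0.005 at 199 permutations).
`res$winner_changes` lists clades that win the lottery in some categories
only:

```
    clade                                      categories_won           status
4  Fam004                            settled.cDNA,settled.DNA winner in subset
14 Fam014 floating.cDNA,floating.DNA,settled.cDNA,settled.DNA    winner in all
```

`plot_qpe_fractions()` draws the stacked process bars per category and
`plot_lottery()` the winner prevalence x diversity scatter. A thin
command-line wrapper over `run_pipeline()`/`simulate_dataset()` ships in
`inst/scripts/assembly-pipeline.R`.

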