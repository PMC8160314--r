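---
title: "Null models for microbial community assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models for microbial community assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microassembly)
```

# The problem

Microbial communities assemble through a mixture of deterministic
processes (environmental selection) and stochastic ones (dispersal and
ecological drift). For engineered systems such as anaerobic granular
sludge — where floating versus settled granules, DNA- versus cDNA-derived
profiles, and replicate reactors define natural sample categories — knowing
*which* process dominates each category tells an operator whether a
disturbance like granule flotation reflects a changed selective
environment or random washout. None of these processes is observable
directly; all are inferred by comparing observed community structure with
explicit null models. This vignette documents the models as implemented
here, the tunable parameters, the synthetic benchmark, and the design
decisions taken where the methodology left genuine choices.

# Preprocessing

Contaminant lineages (`Chloroplast`, `Mitochondria` by default) are removed
by case-insensitive substring match at *any* taxonomic rank, because
reference taxonomies place chloroplasts at order level and mitochondria at
family level. Samples are then rarefied to a common depth (default: the
minimum sample total) by uniform subsampling *without* replacement
(multivariate hypergeometric), the convention of mainstream amplicon
pipelines; the scheme matters for the variance of rare-taxon counts, and
the hypergeometric choice never inflates a count above its observed value.
Taxa left with zero reads everywhere are dropped: unobserved taxa would
otherwise enter occupancy-weighted nulls with weight zero and only
destabilise membership draws. Equal post-rarefaction totals also mean the
abundance-weighted statistics below can work directly on counts.

# The four null models

## Nearest taxon index (alpha phylogenetic structure)

For a sample with at least two taxa, `MNTD` is the mean distance from each
present taxon to its nearest present relative (patristic distances, i.e.
summed branch lengths). The null redraws the sample's membership at its
observed richness, uniformly without replacement from the taxa pool —
defined as all taxa present in at least one sample of the analysed table,
not all tips of the tree, so the null conditions on what the study
actually observed. With 999 randomisations (default), `NTI` is the
negative z-score; samples whose null standard deviation is zero are
flagged undefined rather than silently zeroed. Presence/absence only: the
index deliberately asks a membership question.

## betaNTI and the tip-shuffling null

`betaMNTD` weights, by relative abundance, the distance from each taxon of
one sample to its nearest relative in the other; a shared taxon finds
itself at distance zero. The null permutes taxon identities across *all*
tips of the phylogeny, not merely the observed taxa: a community confined
to one clade must be compared against placements over the whole tree, or
the null could never detect the confinement. One permutation per
randomisation is applied to every sample pair — the standard choice for
matrix-wide turnover nulls, and an order of magnitude cheaper than
per-pair permutation streams. Pairs with identical membership have a
degenerate null (observed and every permutation give zero) and are
reported as undefined; downstream summaries exclude and count them.

## RC-bray and the five-way classification

For pairs without a selection verdict (|betaNTI| <= 2), the Raup–Crick
null reassembles each community independently: membership is drawn at the
observed richness, without replacement, with probability proportional to
occupancy in the regional pool; the observed read total is then allocated
by a multinomial proportional to pool-wide relative abundance over the
drawn taxa, after every drawn taxon receives one read so that realised
richness equals drawn richness. `RC` locates the observed Bray–Curtis
value in that null distribution, rescaled to [-1, 1] with half weight on
ties (Bray–Curtis on counts is discrete; without the tie rule RC would be
biased outward on small communities). The regional pool defaults to the
analysed group's samples, matching per-category process profiles; a flag
widens it to the whole table.

The classification is strict at every boundary: betaNTI > +2 variable
selection, < -2 homogeneous selection, then RC > +0.95 dispersal
limitation, RC < -0.95 homogenizing dispersal, else undominated. Boundary
values fall through to the weaker category.

## Normalised stochasticity ratio

The NST null randomises a table under a taxa-richness constraint:
membership proportional to occurrence frequency, richness either fixed at
the observed value (PF) or binomial with the observed expectation (PP);
read totals are preserved by the same one-read-then-multinomial
allocation. For each pair, the observed dissimilarity `D` (Jaccard or
Ružička) is compared with the null mean `E`:

* `D = E` — turnover is exactly as expected by chance: `ST = NST = 1`.
* `D > E`: `ST = E/D`, `NST = (ST - E)/(1 - E)`.
* `D < E`: `ST = (1-E)/(1-D)`, `NST = (ST - (1-E))/E`.

Both branches are continuous at `D = E` and reach 0 when `D` attains its
extreme (0 or 1) away from `E`. Degenerate cases are defined by limits:
`D = E = 0` gives 1; `E` exactly 0 or 1 with `D != E` gives 0. This
normalisation satisfies the framework's contract (1 at the null
expectation, 0 at maximal deviation, branch-symmetric) and is isolated in
a single internal function so an alternative convention can be swapped in
and cross-checked; published NST implementations differ in details of the
normalisation, so numerical comparisons across software should be made
with care.

Group NST is the mean over within-group pairs, reported as a percentage.
Significance between groups uses a permutation test on the pairwise NST
values: the statistic is the absolute difference of within-group means
(for more than two groups, the pair-count-weighted variance of group
means), sample-to-group labels are permuted, and
`p = (1 + #null >= obs)/(1 + permutations)`. The permutation null needs
NST values for *all* sample pairs, so the test runs on a pooled
stochasticity analysis across the compared groups. With two groups of six
samples the attainable p-value floor is about 0.003; smaller designs
cannot reach p <= 0.01 at all, which is worth knowing before interpreting
a non-significant result.

## Competitive lottery model

Families (or any rank) define clades of presumed nearest competitors. In
each sample where a clade carries at least `min_clade_reads` reads
(default 10 — without a floor, a clade seen as a single read would
trivially produce a "winner"), the top member wins iff its share strictly
exceeds 0.90. Winner prevalence divides winning samples by *eligible*
samples, since absence of the clade says nothing about competition within
it. Winner diversity is the Shannon entropy of winner identities across
winning samples, normalised by `log` of the number of winning samples; it
is 0 when one ASV always wins and approaches 1 when every sample crowns a
different winner. The entropy form reproduces the intended qualitative
reading (low diversity = one dominant competitor everywhere); other
formalisations exist, so the function is kept isolated and small.

# The synthetic benchmark

`simulate_community()` generates ASV tables under six regimes on a
simulated pure-birth (Yule) phylogeny with log-normal pool abundances
(`sdlog = 1.75`; heavy-tailed rank-abundance as in real amplicon surveys).
Defaults — 128-tip tree, 10 samples, depth 2000 — keep a full recovery
study of all six regimes within minutes on one CPU while leaving each
statistic enough taxa and pairs to work with; the paper-shaped
`simulate_dataset()` preset scales the same machinery to 24 samples and an
~1,800-taxon pool.

**The niche trait.** Selection acts through a Gaussian kernel on a
heritable niche trait. Plain Brownian motion at the tip level turns out to
be the wrong conservatism model on Yule trees: most trait variance
accumulates on the long pendant branches, so the set of taxa within a
niche window is phylogenetically almost random and trait-mediated
selection produces *no* clade clustering for the nearest-taxon statistics
to find. The package therefore models the niche as the Brownian value of
each tip's ancestor at the depth where the tree had exactly `n_lineages`
(default 10) lineages: whole "niche guilds" share one value, guilds
diverge by Brownian motion on the deep branches (`conserved_trait()`).
Pure tip-level Brownian motion remains available (`evolve_trait()`) and is
what the trait-covariance oracle tests exercise.

**Selection regimes.** The homogeneous-selection environment centres on
the dominant (largest) niche guild; the niche window is
`min(w, gap/6)` where `gap` is the trait distance to the nearest other
guild, so neighbouring guilds are excluded rather than leaving straggler
taxa at the window edge — stragglers from distant clades register as
phylogenetic *over*dispersion and cancel the clustering signal. Each
sample is founded by a finite inoculum (`founder_size = 60` cells) drawn
from the selected pool and grown multinomially to depth. The bottleneck
matters: with infinite inocula all samples share essentially identical
membership, pair turnover consists only of selection *rejects*, and
betaNTI cannot fall below -2; finite founding creates within-guild
membership turnover — close relatives replacing one another — which is
precisely the signature homogeneous selection leaves in real data.
Variable selection applies the same machinery to the two most
niche-separated guilds with at least 8 members, on two sample blocks.

**Dispersal and drift regimes.** Dispersal limitation splits the taxa pool
into disjoint subpools, assigns samples to subpools, and iterates
Wright–Fisher multinomial resampling (20 generations) with migration
`m = 0.001` from the full pool. Homogenizing dispersal draws one deep
"mother" community (10x sample depth) and resamples every sample from it:
the shared source is richer than any one sample captures, which gives the
Raup–Crick null the occupancy freedom it needs to register the excess
similarity. Pure drift draws samples i.i.d. from the pool, and `nst_null`
emits tables generated by the PF stochasticity null itself, for
self-calibration.

**What passing recovery tests does and does not show.** The generator
emulates phylogenetically structured selection, founder drift, disjoint
dispersal pools and mass effects, under even sampling depth and a perfect
phylogeny. It does not emulate sequencing error, compositional biases,
copy-number variation, tree estimation error, or temporal autocorrelation;
recovery of the six regimes therefore validates the statistics and their
nulls, not robustness to those measurement artefacts.

**Known tension.** On a 128-tip Yule tree the detectability ceiling for
homogeneous selection is modest: nearest-taxon distances of random subsets
are within a small factor of within-clade distances (real 16S trees are
far more scale-heterogeneous), so per-study betaNTI recovery fluctuates
around 70–95% across random phylogenies. Moreover the membership turnover
that betaNTI requires is exactly what the (phylogeny-blind, per-group)
NST null reproduces, so a selection regime detectable by betaNTI scores a
*high* NST (~0.7) in every metric-constraint combination — the two
statistics answer different questions, and on clade-structured selection
with founder drift they legitimately disagree. Group NST contrasts between
regimes (e.g. drift vs selection categories) remain informative, as the
worked example in the README shows.

# Numerical and reproducibility choices

* Every randomised function takes a `seed`; RNG state is restored
  afterwards, so seeded calls never perturb the caller's stream.
* Pipeline stage seeds derive from one global seed as a hash of the stage
  name (`stage_seed()`), so adding a stage never changes earlier stages'
  randomness; reruns with the same global seed are byte-identical, which
  the test suite asserts on the full report bundle.
* Null z-scores with zero null standard deviation (identical-membership
  pairs, single-taxon degeneracies) propagate as explicit `NA` with an
  `undefined` flag and are excluded-and-counted downstream, never coerced
  to zero.
* Raup–Crick ties get half weight; the classification thresholds are
  strict inequalities; both choices are exercised by boundary tests.
* Default randomisation counts (999 for the phylogenetic nulls, 1000 for
  NST) follow field convention; the validation suite and the acceptance
  script run the same machinery at 199–299 randomisations, which leaves
  z-score Monte-Carlo noise well under 0.1 while keeping a full
  six-regime recovery study within a few minutes.

# Limitations

* Per-group regional pools make QPE fractions comparable across categories
  but mean that processes operating *between* categories (e.g. mass
  effects from floating to settled biomass) are not directly tested.
* The NST normalisation reconstructs the framework's contract; numerical
  equality with other NST software is not guaranteed (see above).
* The lottery model's winner-diversity entropy is one of several possible
  formalisations of "how spread out the winners are".
* The synthetic benchmark's Yule + clade-anchored-trait world is a
  deliberately minimal ecology; effect sizes measured there do not
  transfer to real data, only the validity of the decision rules does.
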