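---
title: "Quantifying community assembly processes with phylogenetic null models"
author: "PhyloAssembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly processes with phylogenetic null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhyloAssembly)
```

## The model

Microbial community composition is shaped by a mixture of deterministic
processes (environmental selection) and stochastic ones (dispersal and
ecological drift). Because many bacterial traits are phylogenetically
conserved, the phylogeny of a community carries a signal of selection:
communities filtered by similar environments retain phylogenetically
similar taxa, while random birth–death–immigration dynamics do not care
about the tree. The framework implemented here reads that signal with
null models.

For a single sample with relative abundances $f_i$ on a tree with
patristic distances $d_{ij}$:

- the abundance-weighted **mean pairwise distance** is
  $\mathrm{MPD} = \sum_{i \ne j} f_i f_j d_{ij} \big/ \sum_{i \ne j} f_i f_j$;
- the **mean nearest taxon distance** is
  $\mathrm{MNTD} = \sum_i f_i \min_{j \ne i} d_{ij} \big/ \sum_i f_i$.

Each observed value is standardized against a null distribution obtained
by shuffling taxon labels across the pool's distance matrix
("taxa-labels" null, 999 iterations by default):
$\mathrm{SES} = (\mathrm{obs} - \mu_{\mathrm{null}})/\sigma_{\mathrm{null}}$,
and the reported indices are $\mathrm{NRI} = -\mathrm{SES_{MPD}}$ and
$\mathrm{NTI} = -\mathrm{SES_{MNTD}}$, so values above $+2$ indicate
significant phylogenetic clustering and below $-2$ overdispersion.

Between samples, $\beta\mathrm{MNTD}$ averages the two directional
abundance-weighted means of each taxon's distance to its nearest relative
in the *other* community, and $\beta\mathrm{NTI}$ is its standardized
effect size under the same joint taxa shuffle (one permutation per
iteration applied to the whole pool, so all pairs see the same null
stream). $\mathrm{RC}_{\mathrm{bray}}$ compares the observed Bray–Curtis
dissimilarity of a pair with nulls that preserve each sample's richness
and total abundance: species are drawn without replacement with
probability proportional to occupancy across the pool, and individuals
are then allocated proportionally to pool-wide relative abundance;
$\mathrm{RC} = 2\,\big(\tfrac{n_{<} + 0.5\,n_{=}}{n_{\mathrm{iter}}}\big) - 1 \in [-1, 1]$.

Pairs are classified with strict thresholds, deterministic tests first:
$\beta\mathrm{NTI} > 2$ heterogeneous selection;
$\beta\mathrm{NTI} < -2$ homogeneous selection; otherwise
$\mathrm{RC} > 0.95$ dispersal limitation, $\mathrm{RC} < -0.95$
homogenizing dispersal, and anything inside both bands drift /
diversification. Boundary-exact values fall to the stochastic/drift side
and are logged.

## Parameters that matter

- **nIter** (999): null iterations for every standardized statistic. The
  granularity of RC is $1/999$; fewer iterations coarsen both βNTI and RC.
- **Pooling** (`groupBy = c("compartment", "week")`): nulls are generated
  per pool, so SES values are always relative to the taxa present in that
  compartment-week. A whole-compartment pooling is available for
  sensitivity analysis.
- **Thresholds** (βNTI ±2, RC ±0.95): the conventional two-standard-
  deviation / 5% significance bands; configurable but defaulted to the
  field's values.
- **weighted** (`TRUE`): abundance weighting throughout, matching the
  `abundance.weighted = TRUE` convention of the picante toolkit. The
  unweighted variants are available everywhere.
- **betaMetric** (`"bmntd"`): the turnover SES is based on βMNTD
  (nearest-taxon semantics). A between-community MPD variant
  (`"bmpd"`, the comdist-style statistic) is provided behind this flag
  because the two are sometimes conflated in methods sections; they answer
  different questions (tip-level vs tree-wide turnover).
- **abundanceFloor** (1000): RC_bray allocates discrete individuals, so
  spike-normalized (non-integer) tables are rescaled so each sample totals
  at least this many individuals and rounded, keeping originally present
  taxa at count ≥ 1 so richness is preserved.
- **RNG**: one master seed; each pool derives a deterministic 32-bit
  sub-seed from (seed, compartment, week), so results do not depend on the
  order pools are executed in.

Two algebraic conventions are worth stating because toolkits differ. Our
weighted MPD excludes self-pairs from the weights (the denominator sums
$f_i f_j$ over $i \ne j$); picante's `mpd(..., abundance.weighted = TRUE)`
includes the zero-distance diagonal, and the two differ exactly by the
factor $1 - \sum_i f_i^2$. That factor is invariant under taxa shuffles,
so NRI is identical either way. Our unweighted βMNTD averages the two
directional means (so a singleton vs its superset gives 0.5); picante's
`comdistnt` pools all minima instead. The abundance-weighted βMNTD — the
form used everywhere in this framework — coincides with `comdistnt`
exactly, which the test suite verifies.

## Preprocessing

The pipeline fixes the preprocessing order as: dataset-wide singleton and
zero-sum removal on raw counts, then internal-standard (spike)
normalization, then table/tree alignment. Filtering raw counts first
keeps the "represented once in the entire data set" criterion meaningful
on integer reads; normalizing before alignment lets the spike taxon (a
foreign organism, absent from the community phylogeny) do its job and
then disappear. Samples without the spike (e.g. leaf samples in a design
that spikes only root and rhizosphere) are left on the read scale — pools
never mix compartments, so units never mix within a null model. Alpha
diversity is computed on the singleton-filtered counts before spike
scaling because ACE is defined on integer counts. Missing branch lengths
in Newick input are rejected by default (a config flag can default them)
because silently imputed branch lengths corrupt every distance-based
statistic downstream.

Pielou's evenness returns `NaN` for single-taxon samples (the index is
0/0 there) rather than 0, so weekly means are not biased downward;
group summaries drop non-finite values and report how many were dropped.
Simpson diversity defaults to the complement form $1 - \sum p_i^2$ with
the inverse form behind a switch, since reports often omit which variant
they used. ACE uses the classic rare/abundant cutoff at 10 and falls back
to bias-corrected Chao1 with a warning when the coverage estimate is zero
(all rare taxa singletons).

## The synthetic-data generator

`simulateScenario()` builds a pure-birth (Yule) tree, evolves a Brownian
trait along it (the heritable niche axis selection acts on), draws a
lognormal metacommunity, and assembles communities of
$n_{\mathrm{individuals}}$ multinomial draws with weights
$(1-m)\cdot w_{\mathrm{local}} + m \cdot w_{\mathrm{meta}}$, where the
local term encodes the regime:

- **homogeneous selection** — one shared environment maintains a set of
  phylogenetically tight niches (the fittest taxa clustered into groups of
  near relatives); each sample drifts to a different representative per
  niche. Turnover therefore happens between close relatives, which is
  exactly the signature βMNTD reads as "less phylogenetic turnover than
  the null". A plain shared Gaussian filter is *not* enough: samples then
  share most taxa outright, shared taxa contribute zero to βMNTD under
  both the observed and any jointly relabeled configuration, and the
  standardized effect plateaus well above the −2 band.
- **heterogeneous selection** — contrasting environments select deeply
  diverged lineages: patches are anchored on maximally separated tips
  (greedy max–min patristic choice) and each sample founds from the tips
  nearest its anchor; the anchor's trait value is the recorded optimum.
  We anchor on lineages rather than raw trait bands because Brownian
  traits converge: a single trait-convergent taxon inside the partner's
  clade collapses the pair's nearest-taxon distances (the min is not
  robust), erasing the intended signal.
- **dispersal limitation** — no filter, near-zero immigration, each
  sample drifting from its own sparse concentrated founder draw:
  compositional turnover beyond what the richness-preserving RC null
  expects.
- **homogenizing dispersal** — no filter, immigration near one from a
  single realized source community plus a little per-sample founder
  noise: pairs are less dissimilar than the null.
- **drift/diversification** — no filter, intermediate immigration with
  weakly perturbed local copies of the metacommunity: turnover
  statistically indistinguishable from the null.

The per-regime parameter defaults live in
`inst/extdata/regime_defaults.json` and are calibrated so each regime's
intended process is recovered as the dominant classification at the
reference scale of 10 samples × 200 taxa × 1000 individuals with 999
iterations — the scale the acceptance tests run at. `simulateStudy()`
replicates the field design shape (three compartments × ten weeks ×
lines × blocks, with an internal-standard spike taxon added to root and
rhizosphere samples and a fixed week-to-BBCH map) at configurable scale,
one pool per compartment-week, each generated from a deterministic
sub-seed.

What the generator does *not* emulate: sequencing noise (chimeras, primer
bias, variable depth), taxonomically realistic tree shapes (real ASV
trees have many near-zero terminal branches), co-occurrence networks, or
temporal autocorrelation between weeks. Passing the recovery tests shows
the statistics respond to the right mechanisms, not that any particular
real dataset will partition the same way.

## Numerical choices and degenerate inputs

- SES values with a zero null standard deviation (e.g. star phylogenies,
  or identical communities whose βMNTD is zero under every relabeling)
  are `NA` with a warning, never ±∞. Identical communities are a genuinely
  degenerate pool for βNTI: a joint relabeling keeps them identical, so
  the null collapses at zero.
- RC ties are counted at half weight; Bray–Curtis equality uses a 1e-10
  tolerance.
- The βMNTD inner loops (column minima over present taxa) are compiled
  (Rcpp) because they sit inside a 999-iteration × all-pairs loop; the
  R-level functions are the reference semantics and the compiled path is
  tested against naive loop oracles to 1e-12.
- Problem sizes in the test suite: oracle equivalence enumerates all
  nonempty subsets of 20 random ≤6-tip trees; self-calibration uses 1000
  standardized effect sizes (5 replicate 64-tip pools × 200 samples) and
  ~1100 null-generated pairs for the false-positive rate; regime recovery
  runs all five regimes × five seeds at the reference scale.

## Known limitations

- The taxa-shuffle null is the picante default but not the only null
  family; independent-swap and trial-swap nulls are out of scope.
- βNTI under the joint pool shuffle cannot detect clustering shared
  *identically* by both members of a pair (shared taxa are inert); this
  is a property of the statistic, not an implementation artifact, and is
  why the homogeneous-selection simulator models turnover among close
  relatives.
- RC_bray's two-stage null assumes discrete individuals; heavily
  normalized tables are integerized, which is an approximation.
- Process fractions treat pairs as independent observations, as the
  source framework does; pairs sharing a sample are in fact correlated.
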