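---
title: "Signature-reversal drug repositioning with network filtering: methods"
author: "DrugSigNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug repositioning with network filtering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DrugSigNet)
```

## The problem and the model

Transcriptome-based drug repositioning rests on a simple premise: if a
disease pushes a set of genes up and another set down, a drug whose
perturbation signature pushes those same genes in the *opposite*
directions may be therapeutic. DrugSigNet implements a two-step version
of this idea for case/control cohorts (its motivating application is
heart failure, where multiple public left-ventricle expression cohorts
exist), combining connectivity-map-style reversal scoring with a
protein–protein-interaction (PPI) network filter, followed by
mode-of-action (MOA) subnetwork construction, pathway
over-representation, and a meta-analytic drug-set enrichment check of
the whole ranking.

### Step 1: reversal scoring

For each cohort a differential-expression (DE) table is computed and
four *disease signatures* are formed: the top-K genes by fold change for
K in {150, 250, 350} (split K/2 up-regulated, K/2 down-regulated) and
the *articulation genes* of the PPI subgraph induced by all significant
DEGs — vertices whose removal disconnects the subgraph, a
graph-theoretic notion of load-bearing genes.

Each drug signature is a genome-wide z-score vector per (drug, cell
line); genes are sorted by descending z so up-regulated genes sit at the
top. For a query list of t genes occupying sorted positions $V(j)$ in a
signature of n genes, the enrichment statistic is

$$a = \max_{1\le j\le t}\left[\tfrac{j}{t} - \tfrac{V(j)}{n}\right],
\qquad
b = \max_{1\le j\le t}\left[\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right],
\qquad
KS = \begin{cases} a & a > b\\ -b & \text{otherwise.}\end{cases}$$

The weighted connectivity score is $W = KS_{up} - KS_{down}$ when the
two directional scores disagree in sign and 0 otherwise; $W<0$ means the
disease's up genes sit at the bottom of the drug signature and vice
versa — a reversal. W values are normalized within each (cell line,
perturbation type) stratum by the magnitude of their sign-group mean
(NCS), and each NCS is converted to a signed percentile $\tau \in
[-100, 100]$ against all drug signatures for the same query; $\tau=-90$
means only 10% of the library reverses this disease signature more
strongly. Per drug and cohort, the minimum $\tau$ over cell lines is
taken per signature variant and the per-variant minima are averaged
into the final score. Per cohort the most-negative 5% of drugs
(floor(0.05·N)) are selected, and the most frequently recurring drugs
across cohorts (up to 38) become the preliminary candidates.

A note on the NCS normalization: dividing a negative W by the signed
(negative) group mean would flip its sign and corrupt the subsequent
signed percentile; DrugSigNet therefore divides by the *absolute value*
of the group mean, which preserves sign while making magnitudes
comparable across cell lines — the stated purpose of the normalization.

### Step 2: network filtering and MOA networks

Consensus DEGs — genes significant in at least 3 cohorts, irrespective
of direction — induce a disease subnetwork from the global PPI graph.
Each preliminary candidate is classified by the relation of its targets
to that subnetwork: *inside* (some target is a node), *boundary* (a
target interacts with a node), or *outside*. Only *inside* drugs become
final candidates. The direction-free consensus rule is a deliberate
choice: a gene robustly perturbed in either direction across cohorts is
disease-associated for network purposes.

For each final candidate, the MOA network is the union of all shortest
paths of length ≤ 2 edges ("fewer than three steps") between the drug's
in-network targets and known disease genes, within the disease
subnetwork. Both the step bound and the pairing rule are configurable
(`maxSteps`, `allPairs`): the default pairs targets with disease genes
only, matching the drug–disease reading of the construct; `allPairs`
admits any endpoints from the union of the two sets. MOA genes are then
tested for pathway over-representation by one-sided Fisher's exact test
(hypergeometric upper tail) with Benjamini–Hochberg adjustment, ranked
by a combined score $-\ln(p)\times(\text{observed}/\text{expected
overlap})$, and the top 10 significant sets reported. The combined
score is a self-contained analogue of popular enrichment-tool scores
(which mix log-p with a rank-deviation z computed against a precomputed
background); it retains the same monotone intent without an external
background.

### Validation: drug-set enrichment

Whether a reference drug set (e.g. drugs in clinical use) concentrates
at the reversal end of the ranking is tested per cohort by a rank-sum
test on the $\tau$-ranked drug list, using the difference in mean ranks
as the effect with null variance $N(N+1)/12\,(1/n_1+1/n_2)$
(tie-corrected). Evidence is pooled by fixed-effect inverse-variance
meta-analysis (with Cochran's Q and I² reported) and by Fisher's and
Tippett's p-value combinations. Tests are one-sided in the enrichment
direction by default — the hypothesis is directional — with a two-sided
switch. Fixed-effect pooling (not random-effects) is the default because
the per-cohort effects share one data-generating protocol; Q and I²
expose heterogeneity when that assumption fails. The choice of the
mean-rank difference as the pooled effect is this package's decision;
published descriptions of the approach do not pin down the effect
metric, and the per-cohort forest columns (effect, CI, weight) expose
everything needed to audit it.

Two numerical details. The approximate rank-sum p-value carries a
continuity correction of half the lattice step of the mean-rank
difference plus an Edgeworth term for the (negative) excess kurtosis of
the rank-sum null, keeping it within 0.02 of exact enumeration even at
N = 6; below N = 13 the implementation enumerates exactly by default.
Zero p-values entering Fisher's method are clipped to the smallest
positive double with a warning.

## The synthetic world

Because the real inputs (GEO cohorts, perturbation libraries, drug
target databases, PPI repositories, curated disease genes) cannot be
bundled, the package ships a generator whose output exercises every
stage with known ground truth. A world consists of:

* a scale-free PPI backbone (preferential attachment, connected by
  construction) with extra edges planted inside the disease module so
  the induced disease subnetwork is non-trivial;
* `nDatasets` case/control cohorts in which a planted module of
  `diseaseModuleSize` genes is shifted in cases by per-gene signed
  log2 fold changes (signs fixed across cohorts, so consensus DEGs
  exist by construction; magnitudes `effectSize` ± 20%), all on a
  shared uniform(5,9) log-intensity baseline with within-group
  standard deviation `noiseSd`. A counts mode draws
  Poisson(2^intensity) to exercise the RNA-seq branch (log2-CPM with
  pseudocount 0.5 before testing);
* a signature library in which planted "therapeutic" drugs have
  z-scores negatively proportional to the planted fold changes plus
  Gaussian noise (`reversalNoise`), and all other drugs are independent
  standard-normal noise — the minimal construction under which KS-based
  reversal detection should succeed;
* target maps giving therapeutic drugs a fraction
  `fracTargetsInModule` of targets inside the module, decoys uniform
  targets; and reference exports: the module as the known-disease-gene
  set, the planted drugs (plus optional decoy padding) as the known
  drug set, and a pathway collection that always contains the module
  itself among random decoy sets.

One RNG stream is seeded once per world and sub-generators draw in a
fixed order, so an identical configuration reproduces a bit-identical
world.

The reference configuration — used by the package's own recovery
experiments and the acceptance script — is 1000 genes, five cohorts of
10 vs 10, a 200-gene module with effect size 3 and noise 0.5, 200 drugs
in 3 cell lines with 3 planted therapeutics, 5 targets per drug with
80% of planted drugs' targets in-module, reversal noise 0.3, known set
equal to the planted drugs, and PPI mean degree 6. Cohort sizes, effect
and noise match what typical public case/control expression cohorts of
this kind support; the library size is scaled down from the hundreds of
drugs of a real screen to keep simulation-based tests fast while
leaving the 5% selection rule meaningful (floor gives 10 drugs per
cohort). For synthetic worlds `runPipelineOnWorld` defaults the top-K
list to {0.5, 0.75, 1}×module size rather than {150, 250, 350}: a
200-gene module cannot fill a 350-gene signature, and identical
truncated variants would be pointless; the standard K list remains the
default of `runPipeline` for real-scale data.

What passing on this world shows — and what it does not: the generator
plants clean Gaussian shifts, independent genes, a perfectly shared
module across cohorts, and reversal proportional to the truth. Real
cohorts have correlated genes, platform and batch structure, partial
module overlap, and drug signatures whose reversal is at best rank-level.
Recovery here validates the machinery (formulas, orderings, filters,
calibration), not performance on real data.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | BH-adjusted significance cutoff for DEGs |
| `Ks` | 150, 250, 350 | top-K signature sizes (total, split K/2 per direction; `split = "each"` for K per direction) |
| `minSupport` | 3 | cohorts a gene must be significant in to enter the disease network |
| `fraction` | 0.05 | per-cohort candidate fraction (floor) |
| `consensusSize` | 38 | cross-cohort preliminary candidate count |
| `maxSteps` | 2 | MOA shortest-path bound (edges) |
| `topN` | 10 | pathways reported per candidate |

Degenerate inputs are handled without failure: zero-variance genes get
p = 1 and a flag; requesting more signature genes than there are
significant DEGs truncates with a warning; query genes missing from a
signature's universe shrink the query (an empty intersection yields an
undefined score, excluded downstream with a warning); one-signed
normalization strata warn and pass the absent branch through; ties are
broken deterministically (fold-change ties by raw p then gene id,
selection ties by drug id, z-score ties by gene id).

## Known limitations

* The DE stage is a Welch t-test on (transformed) values — deliberately
  pluggable, not a moderated or count-model fit; with very few samples
  per group it is underpowered relative to shrinkage-based methods.
* The 5% selection uses floor and lexicographic tie-breaks; with very
  small libraries the per-cohort lists can be empty.
* Pathway enrichment is over-representation only; no topology or
  rank-based (GSEA-style) statistics.
* "Top-K" is read as K total (K/2 per direction) with a switch for
  K-per-direction; whether articulation genes should enter the KS scan
  ordered by |fold change| (as here) or unordered is a convention, not
  an identity — KS itself only uses membership and signature positions,
  so the choice affects nothing numerically.

## A worked run

```{r run, eval = FALSE}
cfg <- syntheticConfig(seed = 1)
world <- generateWorld(cfg)
res <- runPipelineOnWorld(world, consensusSize = 38L)

world@therapeuticDrugs
res$candidates[res$candidates$finalFlag, ]
res$enrichment$meta[c("pooled", "p", "fisherP", "tippettP", "Q", "I2")]
head(res$pathwayReports[[world@therapeuticDrugs[1]]], 3)
```

On the reference world every planted drug is recovered among the final
candidates, the three meta-analytic p-values reject comfortably, and
the planted module ranks first in each planted drug's pathway report;
the test suite repeats this over 20 seeds and requires at least 90%
success per property (95% for the separation of planted mean tau below
the decoy median).
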