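---
title: "Ontology-driven analysis of marine metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven analysis of marine metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomarine)
```

## The discovery model

The engine treats an ontology as a queryable index into annotated data.
Classes are CURIE-identified terms linked by is\_a edges; asking for a
class implicitly asks for its entire recursive-subclass closure, because
any datum annotated with a subclass is, semantically, an instance of the
superclass. A query therefore proceeds in three steps:

1. **closure** — all descendants of the feature class (including
   itself), computed by breadth-first traversal of the is\_a DAG;
2. **sample filtering** — metadata constraints evaluated per sample:
   project identity, environment class (by default itself expanded over
   the environment ontology's subclasses), required measurements, and
   half-open depth or measurement windows;
3. **intersection** — samples must carry at least one nonzero count on
   a closure term; returned terms are the closure members with at least
   one nonzero count among the matched samples.

Only is\_a edges define the hierarchy. part\_of, regulates and other
relationship types are ignored: a recursive *subclass* query over the
class hierarchy is exactly transitive is\_a closure, and mixing in other
relations would silently change what "descendant" means. Obsolete terms
are parsed but excluded from every closure; parents that do not resolve
inside the loaded graph are retained in a report rather than dropped or
fatal, since published ontology subsets legitimately reference classes
outside the subset.

## Preprocessing

Counts are compositional twice over: sequencing depth is arbitrary, and
annotation yield varies by sample. The pipeline therefore:

* divides function counts by the sample's ORF total and taxon counts by
  its post-QC read total (`relativize_*`), giving relative abundances;
* optionally sums a clade's subtree ("genus level and below"), which is
  double-count free because the upstream annotators assign each read or
  ORF to exactly one node — stated here as a data contract;
* for taxonomic regressions, keeps only species-ranked terms and their
  descendants (strains, subspecies), then removes likely contaminants
  with a prevalence rule: a term must reach ≥ 1 count per million in
  ≥ 5% of samples. The CPM denominator is the per-sample total *of the
  table being filtered*, not the read total — "counts per million" is a
  table-relative notion; users who prefer the read denominator can
  relativize first;
* applies the centered log-ratio transform per sample,
  `clr_i = ln x_i − mean_j ln x_j`, after zero handling.

**Zero handling.** Two policies are provided and must be chosen
explicitly for reproducibility: a pseudocount added to zero cells only
(default: half the smallest nonzero value of the matrix), or
multiplicative replacement (zeros set to a small delta, nonzero parts
scaled down to preserve the unit sum). Pseudocount is the default
because it perturbs only the zeros. A sample with no nonzero parts has
no composition and is an error; the packaged recipes drop such samples
from the analysis rather than fabricating data for them.

**Variance exclusion.** Regression recipes drop the top 30% of features
by across-sample variance before model fitting, the standard guard
against hypervariable features dominating penalized fits on genomic
data. Whether this happens before or after CLR is a genuinely open
choice; the packaged recipes apply it to the *relative-abundance*
matrix, before CLR, and record the choice in every run manifest. Ties in
the variance ranking are broken lexicographically by term id (the later
id drops first), so the filter is deterministic.

**Binning.** All threshold binning uses half-open intervals
`[t_{i−1}, t_i)`: a value exactly at a cut point falls in the upper bin.
Default cut points are package choices, documented because the relevant
literature values are context-dependent: oxic/anoxic at 20 µmol/kg
dissolved O₂, high/low dissolved inorganic carbon at 1975 µmol/kg, and
shallow/intermediate/deep depth bins at 200 m and 1000 m.

## Statistics

* **Spearman** is the Pearson correlation of average-ranked values with
  pairwise deletion of incomplete pairs; fewer than three complete pairs
  or zero rank variance are errors, not NA.
* **PERMANOVA** uses Euclidean distances. With
  `SS_T = Σ_{i<j} d²_ij / n` and within-group
  `SS_W = Σ_g Σ_{i<j∈g} d²_ij / n_g`, the statistic is
  `F = ((SS_T − SS_W)/(k−1)) / (SS_W/(n−k))`. In one dimension this is
  algebraically the classical one-way ANOVA F, which the tests assert to
  1e-10 against `aov`.
* **Dispersion test**: each sample's Euclidean distance to its own group
  centroid; the statistic is the one-way ANOVA F of those distances, and
  the p-value permutes group labels over the fixed distances. With raw
  Euclidean coordinates no negative-eigenvalue correction arises, and
  centroids (not spatial medians) are used.
* **Permutation p-values** use the add-one convention
  `p = (1 + b)/(1 + m)`: never zero, and the floor at 999 permutations
  is exactly 0.001.
* **IndVal.g**: specificity `A_g` is the group's mean abundance over the
  sum of per-group means (the group-size-corrected form), fidelity `B_g`
  is occupancy, and the statistic is their geometric mean. Each feature
  is tested for its best (argmax) group against the permutation
  distribution of the permuted best-group statistic. Only single groups
  are scored; site-group *combinations* are out of scope. Features
  absent everywhere are reported with NA, not dropped silently.
* **Elastic net** is fitted by `glmnet::cv.glmnet` behind a seeded
  surface: folds come from a seeded permutation (stratified by class for
  the binomial family), the default selection rule is the largest lambda
  within one standard error of the CV minimum, and coefficients are
  reported on the original scale. The mixing parameter defaults to
  `alpha = 1`. This is a deliberate resolution of a tension: the method
  is called elastic net, but the toolchain's *default* mixing is pure
  lasso, and defaults are what the packaged recipes declare; `alpha` is
  a first-class knob recorded in every manifest.
* **Coefficient z-scaling** uses the sample standard deviation over the
  selected (nonzero) coefficients; the absolute z-scores of the
  negative-coefficient features are reported separately, since those are
  the features that *increase* as the response decreases. Scaling is
  per-regression; pooling across regressions is left to the caller.

## What the synthetic cohorts emulate

`sim_design()` defaults describe a single vertical-profile cohort:
40 samples on an even depth grid over 5–1000 m; post-QC read totals on
the 10⁷ scale and ORF totals on the 10⁶ scale with 5% lognormal jitter;
an exponentially declining oxygen profile (230·exp(−depth/250) µmol/kg
plus noise, so the anoxic bin at 20 µmol/kg captures the deepest ~40%);
phosphate and DIC increasing with depth; mesopelagic/mixed-layer
environment tags by depth.

Count tables are multinomial draws over softmax log-abundance weights.
Three weight components matter:

* a per-term baseline `a ~ N(0, 1.2²)` (lognormal abundance spectrum);
* per-term *patchiness*: each term has a lognormal noise SD drawn from a
  capped exponential (mean 1, cap 2.5). This heavy-but-bounded tail is
  the design's key realism choice: in real water-column data the most
  variable features are blooming, patchy taxa and families, not the
  steady gradient followers, so a variance-based exclusion removes
  mostly noise. With pure multinomial noise the planted gradient terms
  would always top the variance ranking and the 30% exclusion would
  delete exactly the signal — unrepresentative of the corpus this
  emulates, where gradient-associated genes demonstrably survive that
  exclusion. The cap prevents a single term from swallowing a whole
  sample's reads;
* planted effects: gradient terms get slope ±1 per SD of depth at a
  fixed moderate baseline (a = −0.5) with small noise (sd 0.3, enough to
  decorrelate co-planted terms so a lasso does not collapse them onto
  one representative); indicator terms get a high baseline, small noise,
  and a hard zero in the non-target group (exclusivity with full
  occupancy by construction).

The ledger returned with every simulation records depths, oxygen, group
labels, totals, planted terms and the expected (pre-multinomial)
relative abundances, so tests can compare realized against constructed
values.

**What passing tests do not show.** The generator draws independent
per-term noise: no phylogenetic covariance, no co-occurring guilds, no
read-level errors, no chimeric annotations, and an annotation model in
which every read/ORF is classified. Recovery rates measured here
therefore bound what the same pipeline would achieve on real data only
loosely; they validate the *mechanics* (closure, intersection,
normalization, selection), not field performance.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 6–50 samples
with 80–120 random ontology terms, totals between 2·10⁴ and the default
10⁷, 999 permutations where a floor of 0.001 is asserted and 99–199
where only calibration matters; the elastic-net benchmark is n = 200
with 100 features over ten seeds. These sizes were chosen so the whole
suite exercises every code path in well under the time a desk check
should take, while keeping every statistical assertion comfortably away
from its threshold.

Other numerical decisions, in one place: CLR row sums are asserted to
zero within 1e-9; `stat² = A·B` within 1e-12; QC thresholds are
inclusive at the boundary; depth/measurement windows are half-open;
N-Triples output is sorted lexicographically and doubles are printed
with `%.15g`, making repeated exports byte-identical; all permutation
machinery derives from a single integer seed via `set.seed`.

## Known limitations

* Only is\_a closure; no OWL reasoning, no existential axioms.
* Euclidean distances only in the multivariate tests (appropriate after
  CLR, not before).
* Gaussian and binomial elastic-net families only; no coefficient
  inference (no p-values on selections).
* The RDF vocabulary is this package's own minimal namespace —
  structurally faithful to a count/measurement-node triplestore layout
  but not byte-compatible with any external deployment.
* The taxonomy generator produces trees; the code nowhere assumes single
  parents, but multi-parent taxonomies are only exercised through the
  GO-like DAGs.
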