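---
title: "Phylogeny-guided ctDNA marker selection: models and methods"
author: "phyloMarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-guided ctDNA marker selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloMarkers)
```

## The problem

Liquid biopsy assays read tumor-derived DNA circulating in blood (ctDNA).
Because tumor DNA is a small fraction of total cell-free DNA, quantitative
work relies on a *small* panel of pre-selected somatic mutations assayed at
high precision (droplet digital PCR or deep targeted sequencing) rather than
genome-wide sequencing. This package addresses the design question that
panel size forces: **which few mutations should be assayed**, given that the
goal is to track the tumor's clonal structure and dynamics over time?

The package works on *clonal trees*: rooted trees whose nodes are tumor
clones, with each somatic mutation originating at one node and inherited by
the subtree below it. Tree inference from bulk sequencing is uncertain, so
the central object is not a single tree but an empirical **tree density** —
a weighted collection of candidate trees, here estimated by bootstrapping
sequence reads and inferring one tree per replicate. On top of that density
the package poses three coupled tasks:

1. **Structure-discriminating marker selection** — choose markers whose
   high-precision read counts best distinguish the candidate trees.
2. **Bayesian density refinement** — update the tree weights from observed
   marker counts.
3. **Clone-tracking marker selection and quantification** — choose markers
   that cover the clones carrying the most cell mass, and convert marker
   VAFs into per-clone fraction estimates at each time point.

## Data model

A `ClonalTree` stores a parent vector (the tree), a mutation-to-clone
assignment, and a frequency matrix `F` (samples x clones) on the
*subtree-sum* scale: `F[s, i]` is the frequency at which a mutation
originating in clone `i` is observed in sample `s`, i.e. the summed fraction
of all cells in the subtree rooted at `i`. Validity enforces the **sum
rule**: a clone's frequency is at least the sum of its children's
frequencies in every sample (tolerance `1e-6`; smaller excursions are
clipped, larger ones are errors). The *exclusive* fraction of a clone is
`cloneFractions()`: `F[i] - sum(F[children])`.

Throughout, marker VAF is treated as directly comparable to `F` with no
purity or ploidy correction: panels are assumed to be drawn from
copy-number-neutral regions, where VAF is a proxy for the cancer cell
fraction. This is a deliberate simplification; panels in copy-number-altered
regions would need an explicit correction the package does not model.

Mutation-pair structure is encoded by the ancestor matrix `A`:
`A[i, j] = 1` when mutation `i`'s clone is a proper ancestor of `j`'s.
Mutations of one clone are recorded as *mutual* ancestors, so the pair
`(A[i,j], A[j,i])` distinguishes all four relationships — ancestor `(1,0)`,
descendant `(0,1)`, same clone `(1,1)`, branched `(0,0)`. The literature
defines `A` only for proper ancestry; the mutual-1 convention was chosen so
the update machinery can recover the relationship from the matrix alone.

## Structure-discriminating selection

For a candidate panel, each tree implies Gaussian read counts per marker
(`mu = D F`, `sigma^2 = D F (1 - F)` at assay depth `D`; the variance is
floored at `1e-6 D` so frequencies of exactly 0 or 1 stay regular), and a
projected ancestor matrix over the panel. For an ordered pair of trees
`(q, k)` the package evaluates the cross-tree read likelihood

```
log I = -1/2 sum_j log(2 pi (s2_jq + s2_jk)) - 1/2 sum_j (mu_jk - mu_jq)^2 / (s2_jq + s2_jk)
```

and the structure term `log(lambda) * sum |A_k - A_q|` over the projected
matrices, with `lambda >= 1` the regularization factor per unit of
ancestor-structure difference. The selection score sums these over all
ordered pairs of distinct trees, weighted by the product of their density
weights.

**Sign convention.** Minimizing the expected cross-tree likelihood means
*maximizing separation*. As printed in the source formulation the global
sign makes the structure term pull against that goal, so the default
objective (`objectiveSign = "discriminative"`) maximizes

```
sum_{q != k} w_q w_k [ 1/2 sum_j (mu_jk - mu_jq)^2/(s2_jq + s2_jk)
                     + 1/2 sum_j log(2 pi (s2_jq + s2_jk))
                     + log(lambda) sum |A_k - A_q| ]
```

i.e. read-model divergence plus structure difference. The literal form is
available as `objectiveSign = "literal"`, and the panel-dependent Gaussian
normalization term can be excluded with `includeConstant = FALSE`.

**The role of lambda.** At realistic high-precision depths (`D ~ 10^4`) the
read-divergence term is of order `D (dF)^2 / F(1-F)` — hundreds per marker —
while one unit of ancestor-structure difference contributes only
`log(lambda)`. The downstream Bayesian update (next section), however, sees
*only* pairwise lineage relationships: a panel with large read divergence
but identical relationships across all trees provably leaves the weights
unchanged. For tree refinement one should therefore run selection in the
**structure-dominant regime**, where `log(lambda)` is large enough that
relationship diversity drives the choice and read divergence acts as a
tie-breaker. Since such `lambda` can overflow `exp()`, `structureParams()`
accepts the factor directly on the log scale; the refinement experiments in
this package use `logLambda = 1e4`. With the default `lambda = 2` the
objective instead favors panels that separate the trees' expected read
counts — appropriate when the assay itself, not the pairwise update, is the
discriminator.

**Optimization.** The score decomposes into per-marker linear coefficients
plus nonnegative marker-pair coefficients, a binary quadratic program under
a cardinality constraint (in the ILP view, pair products are linearized with
the standard three inequalities). The package solves it *exactly*:
mutations with identical clone assignments in every candidate tree are
interchangeable, so the search runs over profile groups by capped
enumeration of group count vectors; instances too large for that fall back
to depth-first branch-and-bound whose admissible bound adds the top
remaining linear terms plus half of each candidate's largest pairwise
masses. Exhaustive enumeration (`solverMode = "exhaustive"`) is retained
for small instances and serves as the independent oracle in the test suite;
the test suite and acceptance checks verify solver-oracle agreement on
hundreds of random instances. Among equal-scoring optima the
lexicographically smallest index set is returned.

## Bayesian refinement from marker counts

High-precision counts for a marker pair `(r1, d1, r2, d2)` are modeled as
binomial draws from latent frequencies `(f1, f2)` constrained by the pair's
relationship on a given tree: `f1 >= f2` (ancestor), `f1 <= f2`
(descendant), `f1 = f2` (same clone), `f1 + f2 <= 1` (branched). Each
tree's weight is multiplied by the marginal likelihood of the counts with
the frequencies integrated uniformly over the corresponding region, and the
weights are renormalized. The same-clone case is the closed form
`B(r1 + r2 + 1, d1 + d2 - r1 - r2 + 1)`; the region cases reduce to
one-dimensional integrals of a beta density times a regularized incomplete
beta function, evaluated by adaptive quadrature (relative tolerance
`1e-8`). For counts so extreme that the linear-scale integral underflows,
evaluation switches to log-space Gauss–Legendre panels placed by beta
quantiles, so strongly contradicted relationships get a very negative but
finite log-likelihood rather than breaking normalization. All weight
arithmetic is in log space with max-shifted exponentiation; a posterior in
which every tree underflows is reported as a degenerate-posterior error.

For panels larger than two, markers are paired into a disjoint matching
(`choosePairs()`): the default greedy strategy repeatedly takes the pair
whose relationship is most heterogeneous across the density (weighted Gini
impurity), one marker staying unpaired for odd panels. Disjoint pairs keep
each marker's reads used once; the per-pair multipliers commute, so the
update order is irrelevant. An all-pairs update would reuse each marker's
evidence several times and overstate confidence, which is why it is not the
default.

## Clone tracking and quantification

Under the **partial information** assumption a clone is trackable when some
panel marker originates in it — its subtree mass is then measurable. Under
**complete information** the clone *and all its children* must carry
markers, so the clone's own exclusive fraction can be isolated by
subtraction. Selection maximizes the weighted mass of tracked clones, in
expectation over the density; weights default to the previous time point's
exclusive clone fractions (blood sample), with a uniform option for cold
starts. The printed source expression for the complete-information
indicator evaluates to values `>= 1` for untracked clones and cannot be
maximized as written; the implementation uses the evident intent — an AND
over the clone and its children — via the standard linearization.

The partial-mode objective is a weighted coverage function — monotone and
submodular — so the exact solver uses enumeration over mutation profile
groups for small instances and, for larger ones, branch-and-bound with the
top-`t`-marginal-gains bound that submodularity licenses. Complete-mode
instances too large to enumerate use the weaker add-all-remaining monotone
bound and can be slower; at the study sizes used here this path is rarely
taken.

`estimateFractions()` converts measured VAFs into clone fractions on a
chosen tree: a clone's estimate is the mean VAF of its markers minus the
sum of its measured children's mean VAFs. Negative estimates — possible
when child markers are observed above the parent's, an impossibility for
exact frequencies but a real occurrence under assay noise or topology error
— are **retained and flagged**, because they are diagnostic of exactly such
error; an optional simplex projection is off by default. Clones with
unmeasured children are flagged as quantified at subtree level (only
measured children are subtracted); clones with no marker are omitted and
listed in an attribute rather than zero-filled.

## The synthetic-data generator

`simulateTree()` emulates the study conditions used throughout: 7 clones
(uniform random attachment), a Poisson(50) mutation count assigned uniformly
with every clone guaranteed one mutation, flat-Dirichlet exclusive clone
fractions per sample, one blood plus two tissue samples, and per-clone
tissue dropout with probability 0.5 followed by renormalization ("mutation
rate 50" is read as the expected mutation count, and the mask proportion as
a per-clone dropout probability; both are config parameters).
`simulateReads()` draws binomial read counts at the bulk depth;
`simulateDdpcr()` draws binomial counts at the assay depth from the blood
frequencies, with an optional Dirichlet drift step (concentration
parameter; drift redistributes mass within the tumor fraction) to emulate
longitudinal change. All stages derive independent named streams from one
master seed.

`bootstrapDensity()` supplies the tree-inference step so the pipeline runs
without an external tumor-phylogeny engine: per replicate it resamples each
mutation's reads binomially around the observed VAF, clusters mutations by
their multi-sample VAF profiles (k-means with silhouette-chosen k), orders
clusters by mean VAF and greedily attaches each to the most specific parent
compatible with the sum rule (within an attachment tolerance of 0.05,
absorbing binomial noise at the default depth), then repairs residual
violations by capping to [0, 1] and rescaling children top-down. Distinct
replicate topologies accumulate bootstrap counts; replicates of one
topology merge with count-weighted frequency averaging after canonical
clone reordering. This builder is a deliberately lightweight heuristic: it
recovers well-separated clonal structure but is not a substitute for a full
phylogeny engine, and externally inferred replicate trees (e.g. converted
from a PhyloWGS-style summary with `readPhyloWGS()`) can be supplied
instead.

What passing the simulation-based checks shows — and what it does not: the
generator produces exact binomial noise around exactly valid trees, with no
sequencing error model, no overdispersion, no copy-number effects, and no
tumor-purity dilution. Results on real ctDNA, where all four are present,
will be noisier than the synthetic summaries suggest; the workflow is the
same, but the numbers are not transferable.

## Evaluating refinement: tree distances

`treeDistance()` implements CASet and DISC. For every unordered mutation
pair, CASet takes the Jaccard distance between the pair's common-ancestor
sets in the two trees; DISC does the same over ordered pairs for the set of
ancestors of the first mutation not shared with the second. Ancestor sets
include the mutation itself and its same-clone companions, consistent with
the package's ancestor-matrix convention. When bootstrap universes differ,
comparison restricts to the shared mutation set and reports its size.
`weightedDistance()` and `bestTreeWeight()` summarize a density against a
reference tree (ties at the minimal distance pool their weights and are
flagged).

## Study design reproduced by the experiment harness

`runRefinementStudy()` runs the full loop on seeded cases (defaults: 10
cases, 7 clones, ~50 mutations, 1 blood + 2 tissue samples, mask 0.5, bulk
depth 1000, 100 bootstrap replicates, panels of 5, ddPCR depth 10^4,
structure selection at `logLambda = 1e4`): it reports weighted CASet/DISC
distances to the ground truth and the best tree's weight before and after
updating, for structure-selected versus random panels.
`runTrackingStudy()` sweeps panel sizes 1–8 and reports the trackable
fraction of tracking-optimized versus random panels, both in expectation
over the density (the selection objective, monotone in panel size by
construction) and evaluated on the ground-truth tree. These problem sizes
are the package's chosen desk-scale study conditions; both studies complete
in minutes on one CPU.

```{r example, eval = FALSE}
cfg <- simConfig(seed = 11)
cs <- simulateCase(cfg)
params <- structureParams(depth = cfg$ddpcrDepth, logLambda = 1e4)
panel <- selectStructureMarkers(cs$density, 5, params)
counts <- simulateDdpcr(cs$truth, panel, cfg$ddpcrDepth, cfg$seed)
posterior <- updateWeights(cs$density, panel, counts)
weightedDistance(cs$density, cs$truth, "CASet")   # before
weightedDistance(posterior, cs$truth, "CASet")    # after
```

## Numerical choices and limitations

- Sum-rule tolerance `1e-6` absolute; clipping inside, hard error outside.
- Variance floor `1e-6 * depth` in the Gaussian read model.
- Pair-integral quadrature at relative tolerance `1e-8`, with the log-space
  Gauss-Legendre fallback for underflowing regions; the same-clone case is
  closed-form.
- Branch-and-bound accepts improvements beyond `1e-9`; reported optima are
  exact up to that tolerance, with lexicographic tie-breaking on the
  enumeration paths.
- The bootstrap tree builder assumes mutation clusters are separable in VAF
  space; heavily masked tissue samples with shallow depth can merge adjacent
  clones, which then appears as same-clone relationships in the density.
- No CNA/SV awareness anywhere; marker panels are assumed copy-number
  neutral. ddPCR droplet counts are treated as plain binomial reads with no
  droplet-volume correction and no overdispersion.
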