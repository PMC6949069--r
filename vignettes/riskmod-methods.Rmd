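---
title: "Methods: integrated risk-module identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated risk-module identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(riskmod)
```

This vignette documents the statistical model behind `riskmod`, the
assumptions it makes, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical/design choices taken where the method left
room for interpretation.

## The model

The method assumes that disease-relevant gene modules in a
protein-interaction network are (i) anchored on known disease genes
("seed genes"), (ii) enriched for genes whose expression differs between
tumor and normal tissue in mean or in variance, (iii) internally
coherent — non-seed members are statistically similar to the seed
members — and (iv) jointly perturbed: high seed differential signal,
shared function annotations, and rewired co-expression between
conditions. Each pipeline stage operationalises one of these
assumptions.

### Differential screening

Two complementary screens run on a paired tumor/normal log2 expression
matrix.

*Mean shifts.* A paired SAM-style statistic: per gene, within-pair
differences `z_j = tumor_j − normal_j`, `d = z̄ / (se(z̄) + s₀)`, with the
fudge factor `s₀` set to the median of all genes' standard errors. `s₀`
stabilises genes whose tiny variance would otherwise produce huge `d`
from negligible effects; the median (rather than the full quantile
search of the original SAM) keeps the statistic deterministic and
dependency-free. The FDR is estimated by sign-flip permutations of the
pairs, which is the exact group of symmetries of the paired null: for
gene ranked `r` by |d|, the q-value is the median across permutations of
the count of permuted |d| values at least as large, divided by `r`,
clipped to [0, 1] and made monotone. A gene is a DEG when q < 0.05 and
|log2FC| > 1, where log2FC is the mean paired difference (the input is
already log2).

*Variance shifts.* `V = |S²_normal − S²_tumor|` with `S²` the unbiased
sample variance. The null draws a uniformly random gene, swaps its
tumor/normal values within a random subset of pairs, and recomputes V;
1000 such draws form one shared null. Swapping within pairs rather than
resampling observed V across genes matters: an observed-V null would
confound genome-wide variance heterogeneity with condition effects,
whereas label swapping removes exactly the condition association while
preserving each gene's marginal distribution. Empirical p-values use the
add-one convention `(1 + #{null ≥ V}) / (n_null + 1)` so no p is exactly
zero, and are Benjamini–Hochberg adjusted. Note the practical floor this
implies: with `n_null = 1000` the smallest attainable p is ~0.001, so on
a ~550-gene study BH can only call a DEVG set of size ~20 or more;
shrinking `n_null` below ~1000 makes the DEVG screen silently
conservative, which is why 1000 is both the default and the recommended
minimum for real use (the validator refuses < 100 outright).

The screens run on whatever scale the input is on; the package assumes
already-normalized log2 intensities and does no normalization of its
own. Whether the upstream study ran its screens on log or linear scale
is not recoverable; log2 is the field convention for the variance
statistic to be comparable across intensity ranges.

### Primary modules: clique mining and Simpson merging

Maximal cliques with 5–8 genes are enumerated from the seed-centered
network (igraph's maximal-clique search); maximal cliques larger than 8
contribute all their 8-gene subsets, because the size window is a size
filter, not a maximality requirement — silently dropping a 12-clique
would discard exactly the densest region of the network. The window can
be widened to [4, 8], but 4-cliques are so abundant that merging them
produces uselessly large modules; 5 is the default minimum. Only cliques
containing at least one seed gene and at least one differential gene are
kept.

Cliques are merged bottom-up: the pair of subgraphs whose **seed-gene
subsets** have the largest Simpson overlap `S = |A∩B| / min(|A|,|B|)` is
merged (gene union, induced edges recomputed) while `S > 0.8`, strictly.
The Simpson index is computed on seed subsets, not full gene sets,
because the merge is meant to coalesce cliques anchored on the same
disease genes. Merging is deterministic: highest S first, ties broken by
the lexicographically smallest combined gene set. Cliques with
*identical* seed subsets are coalesced in a single pre-pass — such pairs
always have S = 1 and their merge cannot change any other pair's S
(which depends on seed sets only), so the pre-pass provably reaches the
same fixpoint while collapsing the combinatorial explosion of 8-gene
subsets inside dense regions. Termination is guaranteed because every
merge reduces the subgraph count by one.

### Candidate modules: similarity pruning

For each non-seed gene y of a primary module, two objectives are
computed over all pooled samples: `mi_sum = Σ_x MI(x, y)` over the
module's measured seed genes x, and `pcc_avg`, the mean absolute Pearson
correlation with them. MI uses the Kraskov–Stögbauer–Grassberger k-NN
estimator (first variant, max-norm, k = 3): for each joint point the
distance ε to its k-th neighbor is found, and
`MI = ψ(k) − ⟨ψ(n_x+1) + ψ(n_y+1)⟩ + ψ(N)` with `n_x`, `n_y` the
marginal neighbor counts strictly within ε. Two typesetting ambiguities
in the source description were resolved toward the canonical estimator:
the printed formula shows a spurious `−1/k` and a `+` sign before the
averaged digamma term, and drops the `+1` in the digamma arguments;
as printed, the estimator would be biased by roughly −1/k everywhere and
would not converge to the analytic value `−½ ln(1−ρ²)` for bivariate
Gaussians, which the test suite checks at ρ ∈ {0, 0.4, 0.8}. Exactly
repeated values (ties) would break the neighbor counts, so a
deterministic jitter of magnitude 1e-10, seeded by `rng_seed`, is always
added; negative estimates (possible by sampling noise) are floored at 0
wherever MI acts as a weight. |PCC| rather than signed PCC is used
because the working hypothesis is *similarity*; strongly anti-correlated
partners are still informative partners. Both options are exposed.

Pruning retains the seeds unconditionally and keeps non-seed genes that
are jointly large in both objectives. The optimisation is specified only
as simultaneous maximisation of the two criteria, so the package
implements Pareto dominance with a tolerance: iteratively remove the
gene strictly dominated (worse in *both* objectives) by the most
retained genes, until every retained gene is dominated by at most
`dominance_tol` others. The strict front (`dominance_tol = 0`) is
available but is **not** the default, for a structural reason: among k
genes that are genuinely exchangeable (equally similar to the seeds),
the expected front size is only the harmonic number H(k) ≈ log k, so a
strict front arbitrarily discards most of a coherent gene group on
sampling noise alone. The default `dominance_tol = 4` was calibrated on
a constructed module of 5 seed-correlated genes (ρ = 0.8) and 10
independent decoys: decoys are dominated by essentially all 5 coherent
genes, so any tolerance below 5 removes every decoy, while a tolerance
of 4 retains the full coherent set. A quantile strategy (keep genes at
or above the module's q-quantile in both objectives) is provided as a
fallback. Modules left with no non-seed gene carry no new candidates
and are dropped.

### Risk modules: three scores and a permutation null

*W (MRF score).* Treating the per-gene differential statistic `f`
(absolute paired t) as a Markov random field on the module graph, the
score rewards differential seed genes and penalises rough variation of
the degree-normalized field across strongly dependent non-seed
neighbors:
`W = (1/m) Σ_{i∈C1} f_i − (1/k) Σ_{(u,v)} (f_u/d_u − f_v/d_v)² · MI(u,v)`,
the pair sum running over module edges with both endpoints non-seed.
Both normalizers come from the module as a whole: `m` is the module's
gene count and `k` its edge count. Three readings were fixed: (i) the
compact typesetting `(f_u d_u − f_v d_v)² MI` is read as division by
degree — degree normalization is what makes the fields of a hub and a
leaf comparable; (ii) MI multiplies the squared difference rather than
dividing it, because division would explode the penalty precisely for
*unrelated* gene pairs (MI → 0), inverting the stated intent of
penalising discordance between similar genes; the divide variant is
still available (`mi_role = "divide"`, MI floored at 1e-6); (iii) `f` is
|t|, since the seed term rewards differential magnitude regardless of
direction. The Gibbs normalisation constant and temperature of the full
random-field distribution are never needed: only W itself is scored.
Degenerate cases are defined, not fatal: a module with no edges gets
penalty 0 with a warning, an all-non-seed module gets seed term 0 with a
warning, and a gene with zero-variance paired differences gets t capped
at 100 (warning) or 0 if the differences are identically zero.

*F (functional consistency).* Mean Jaccard index of annotation sets over
(seed, non-seed) pairs where both genes carry at least one annotation;
pairs with an unannotated member are excluded rather than counted as
zero, so sparse annotation coverage does not masquerade as functional
incoherence. No eligible pair gives F = 0.

*ΔPCC (rewiring).* Sum over unordered measured gene pairs of
|PCC_tumor − PCC_normal|. Absolute differences are the default (the sum
of signed differences could cancel genuine rewiring of mixed sign);
signed summation is available.

*Null model.* For each candidate, 1,000 (default; tests and the
acceptance script use 200 for runtime, which leaves the smallest
attainable p at 1/201 ≈ 0.005, still well below α = 0.05) random modules
with the same gene count **and the same seed count** are drawn uniformly
from the measured subnetwork, and each score's upper-tail permutation
p-value is computed with the add-one convention. Matching the seed count
as well as the size matters for W, whose first term sums over seeds.
Random modules are node-set samples, not connected subgraphs — the null
asks "is this score surprising for an arbitrary same-composition gene
set", which is the comparison the permutation test describes. Candidates
are each tested at α = 0.05 with no cross-candidate multiplicity
correction, mirroring the original procedure; with three independent
score tests the compound false-positive rate per candidate is at most
α³ under the global null. A candidate significant in all three scores is
a risk module.

### Validation

Classification uses a linear-kernel SVM (cost 1) under leave-one-out
cross-validation: per fold, features are standardized with statistics
fit on the training fold only, and the left-out sample's decision value
is recorded; the AUC is the trapezoidal area under the ROC of the pooled
decision values (per-fold AUC is undefined for single-sample test
folds). The kernel and cost are the smallest-assumption deterministic
defaults, since the original classifier is unspecified beyond "SVM".
Pairing is ignored at classification time — samples are independent
instances labelled tumor/normal. The observed AUC is judged against 100
random gene sets of the same size drawn from the measured network. A
hypergeometric enrichment test (BH-adjusted, universe defaulting to the
measured network genes) provides offline gene-set enrichment; stability
is assessed by rerunning the entire pipeline on random subsets of whole
tumor/normal pairs (default 90%) and counting re-identified risk-module
genes.

## The synthetic study

The generator emulates the structure the method consumes: a paired
tumor/normal log2 intensity matrix, a seed-centered interaction network,
and GMT-style annotations, with known ground truth. Defaults were fixed
once, from the study design being emulated and the log2-microarray
scale, and define the package's reference conditions:

- 32 seed genes (the size of a two-database-supported disease-gene
  catalogue), 43 tumor/normal pairs, background intensities N(8, 0.5²) —
  a typical log2 microarray scale.
- 500 independent background genes, each attached to at least one seed
  (the structural contract of a seed-centered network) plus sparse
  random edges (p = 0.02). The background must be large enough that a
  size-matched random gene set is usually uninformative; with only a
  couple hundred genes, random feature sets contain planted genes so
  often that the classification baseline saturates.
- One **coherent planted module**: 6 seeds + 10 non-seeds forming a
  near-clique (edge probability 0.95), equicorrelated at ρ = 0.3 in
  tumors but 0.05 in normals (condition rewiring that drives ΔPCC),
  mean-shifted +1.2 log2 units in tumors with tumor variance ×4, and
  90% of its genes sharing a module-specific annotation set. The shift
  is deliberately moderate: each gene alone is a mediocre classifier,
  and it is the module's aggregation of 16 partially independent genes
  that separates the classes — which is exactly the property the
  random-feature-set comparison should detect.
- One **decoy module**: 3 seeds + 6 non-seeds, variance-inflated (×6)
  but unshifted, uncorrelated and unannotated. It enters the pipeline
  through the DEVG channel and survives to candidacy, but fails the
  risk scores — a negative control inside every end-to-end run.
- Equicorrelated Gaussian blocks were chosen over factor models because
  they give closed-form control of both PCC and Gaussian MI
  (`−½ ln(1−ρ²)`), so every estimator in the package has an analytic
  reference.

What the generator does **not** emulate: probe-level effects, batch
effects, intensity-dependent variance, non-Gaussian marginals, scale-free
network topology, or annotation hierarchies. Passing tests on this
fixture therefore demonstrate correctness of the statistical machinery
and recoverability of planted structure — not performance on real
microarray data, where preprocessing and network quality dominate.

Problem sizes in the test-suite and acceptance runs (548 genes, 43
pairs, 200 random modules per candidate, 20 resampling replicates, 100
baseline feature sets) are the package's chosen desk-scale defaults;
every size is a visible parameter and scales up unchanged.

## Known limitations

- The DEVG permutation null is shared across genes; p-values of
  different genes are therefore weakly dependent, which the BH
  adjustment tolerates but a strict FDR proof does not cover.
- The clique window plus subset expansion can still be combinatorially
  heavy on very dense networks; the seed-set pre-merge absorbs the
  common case, but pathological inputs (near-complete graphs over
  hundreds of nodes) remain expensive.
- KSG MI at 86 samples has noticeable variance; `mi_sum` rankings
  between near-tied genes are not stable across seeds, which is the
  reason the pruning tolerance exists.
- Risk calls at α = 0.05 with 200-module nulls have a granularity of
  1/201; borderline candidates can flip between neighboring seeds.
- Seed genes are trusted as given; no attempt is made to model
  uncertainty in the seed catalogue itself.
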