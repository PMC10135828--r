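---
title: "quadnet: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadnet: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

quadnet reconstructs ligand → receptor → TF → target ("quad-chain")
regulatory networks linking a sender cell population to a receiver
population across disease stages, by consensus over four independent
lines of evidence. The guiding idea is that any single
cell-communication tool over-calls interactions; a chain reported by
quadnet must simultaneously (i) be constructible from a prior signaling
network with high diffusion support, (ii) have a ligand–receptor pair
expressed in the sender/receiver clusters, (iii) have co-expression
support for its TF → target link in the receiver, and (iv) be anchored in
differential expression between the two stages being compared.

Conditions are a fixed vocabulary: `nLung` (distant normal lung),
`tLung` (early tumor), `tL/B` (advanced tumor). Networks are oriented as
(reference, interest) pairs, by default (nLung, tLung) and
(tLung, tL/B). "Signals" of a network are its distinct
receptor/TF/target genes — ligands are the sender-side stimulus and are
excluded from the signal count.

# Stage-by-stage assumptions and parameters

## Preprocessing

* QC (all bounds inclusive): mitochondrial fraction ≤ `mito_max` = 0.20,
  UMIs ∈ [100, 150000], detected genes ∈ [200, 10000]. The two printed
  ranges are assigned to UMIs and genes respectively — the only
  biologically sensible pairing (a cell with 100 genes and 150,000 UMIs
  does not occur). Mitochondrial genes are recognized by the `MT-`
  prefix; covariates are recomputed from the matrix, which makes the
  filter idempotent. Removals are tallied by first failing criterion in
  the fixed order mito, UMI, genes.
* Normalization: `ln(1 + count · 10⁴ / depth)`. Exactly invertible given
  depths; zeros stay zeros.
* HVG selection: dispersion (variance/mean of normalized values)
  z-scored within 20 equal-frequency mean bins; top `n` (default 3000)
  with lexicographic tie-break. This is the classic binned-dispersion
  heuristic; the upstream literature names only a function, not a
  method, so the classic variant was chosen for determinism and
  testability.

## Differential expression and enrichment

Two-sided Wilcoxon rank-sum with the normal approximation, tie
correction and continuity correction; genes are prefiltered by
expressing fraction (`min_pct` = 0.1 in at least one group) and
`|log2fc|` ≥ 0.25 computed on expm1-mean expression with pseudocount 1
(the conventions of the popular marker-finding function; no published
values exist for this pipeline). BH adjustment is applied to the tested
set only. Gene-set enrichment is the exact hypergeometric upper tail
against a user-supplied background, BH across sets; no ontology
databases are bundled or downloaded.

## Ligand–receptor verification

The interaction score of a pair is ½(mean ligand in sender cluster +
mean receptor in receiver cluster) on normalized values, set to 0 when
either cluster mean is 0 (both-expressed convention). Retention is
strictly `mean > 0` — deliberately permissive, mirroring the published
procedure; the permutation p-value (cell-type labels shuffled within the
sender + receiver pool, `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, never
exactly 0) is computed and carried as metadata for users who want a
stricter rule. Labels are shuffled only within the sender + receiver
pool, the smallest exchangeable set.

## Diffusion potential and path extraction

Regulatory potential is personalized PageRank from the ligand over the
lr + signaling layers (damping 0.85, power iteration to 1e-10), with
**absorbing** dangling nodes: mass reaching a node without out-edges
leaves the walk rather than being redistributed to the restart vector.
Absorbing semantics make scores monotone under edge deletion (removing a
route can never raise another gene's score), which restart-redistribution
violates. TF mass is spread over its out-weight-normalized
`gene_regulatory` edges. Ligand activity is the Pearson correlation
between the potential over the target-gene universe and the 0/1
receiver-DEG indicator; top 30 ligands are kept by default. Path
extraction is exact dynamic programming over the layered DAG with at
most one signaling intermediate (receptor → TF or receptor → signaling →
TF), matching the layered generator; deeper signaling cascades are out
of scope.

## Regulons

Default method: |Spearman| between TF and target across receiver cells —
deterministic and directly checkable against hand-computed rank
correlations. A seeded gradient-boosted-stump ensemble
(`method = "tree_ensemble"`, 50 rounds, shrinkage 0.1, 80% row
subsampling, importance = share of squared-error reduction) is available
for nonlinear dependence. Regulons keep targets with importance ≥
`min_importance` (default 0.1 — a weak-evidence floor on |rho|; the
source procedure does not state its thresholds), truncated to `top_k` =
50, ties broken by gene name. Motif/cis-regulatory pruning is omitted
(it requires external motif databases); a user-supplied allowlist can
stand in for it by intersecting regulons beforehand.

## Consensus filtering

Chains (not edges) are the unit of filtering. The DEG filter — the least
specified step in the source procedure — keeps a chain iff its ligand is
DE in the sender (adjusted p < 0.05) AND at least one of its
receptor/TF/target is DE in the receiver, because ligands are
sender-cell signals while downstream elements are receiver responses.
Direction is annotated from the receiver-side sign, preferring the
target, then the TF, then the receptor. Whether adjusted or raw p was
used upstream is unstated; adjusted p was chosen as the conservative
reading. Monotonicity 1.0 ⊇ 2.0 ⊇ 3.0 ⊇ 4.0 holds by construction and is
asserted on every pipeline run in the tests.

## Trajectory

DDRTree is replaced by a transparent surrogate: PCA to 2 components,
seeded k-means into `n_states` (default 7, mirroring the scale of
published macrophage state counts, but a free parameter), minimum
spanning tree on state centroids, and pseudotime as the along-tree
distance from the root centroid to each cell's projection onto its
nearest tree segment. The root state is the state with the largest
fraction of root-condition (`nLung`) cells, and pseudotime is anchored
so that the earliest root-condition cell sits at 0. The scientific claim
this supports — tumor-stage receiver states separate from normal states
along the tree — is testable under either reduction; exact DDRTree is
out of scope. Nearest-segment projection was chosen over
"offset along the state's incoming edge" after the latter was observed
to scramble orderings when k-means splits a 1-D manifold across the
noise component.

## Survival

Native product-limit curves and the standard two-group log-rank test
(hypergeometric variance per event time, χ² with 1 df); verified against
the survival package and against hand-worked arithmetic in the tests.
`optimal_cutpoint` scans all biomarker midpoints keeping both groups ≥
`minprop`·n (default 0.1) and maximizes the log-rank statistic. The
returned p is the naive p at the selected cutoff and is flagged
`selection_biased = TRUE`; it is not corrected, matching common practice
with maximally selected statistics, and should be treated as descriptive.
Proportion comparisons use Welch's t on per-patient fractions (patients,
not samples, as the unit), BH across cell types.

# The synthetic world: what it emulates and what it does not

`simulate_counts` draws counts from a negative binomial,
`NB(mean μ, size = dispersion)` — the standard overdispersed model for
UMI data. All genes sit at `baseline_mean` (default 1) scaled by a
lognormal(0, 0.25) per-cell depth factor; 500 background genes and 10
`MT-` genes (tuned to ~5% mitochondrial fraction) make QC and
normalization meaningful. For a cascade active in condition c, the
ligand mean is multiplied by `2^effect_log2fc` in sender cells of c and
the receptor/TF/targets jointly in receiver cells of c — the coordinated
sender/receiver pattern the consensus method is designed to detect. The
published study gives no effect-size or noise values; `effect_log2fc` =
2 and `dispersion` = 2 are calibration choices fixed once. Not emulated:
transcriptome-wide covariance, doublets, ambient RNA; a green test
therefore demonstrates correctness of the machinery on an idealized
world, not performance on real tissue.

## Identifiability of the planted truth

The recovery benchmark must have a ground truth that is recoverable *in
principle*. Unconstrained cascade sampling does not guarantee that:

* cascades sharing a ligand or TF across different active stages cancel
  each other's differential expression;
* alternate-receptor routes and cross-cascade routes in the prior create
  "phantom" chains, every gene of which is genuinely perturbed — no
  expression-based method can reject them;
* a ligand whose diffusion mass mostly flows to other TFs has near-zero
  activity against its own targets, so ranking it above decoys is not a
  statistical question at all;
* shared signaling hubs entangle all ligands with all TFs.

`generate_truth(identifiable = TRUE)` therefore samples *dedicated
axes*: gene-disjoint cascades in which the TF is reachable from exactly
one ligand through exactly one receptor, the ligand has a single lr
edge, the receptor a single signaling out-edge, and the target set is
restricted to genes regulated by no other TF. `simulate_dataset` (the
benchmark entry point) combines this with a direct receptor → TF prior
(12 ligands / 15 receptors / 15 TFs / 60 targets, density 0.04) and a
deterministic rejection ladder over prior seeds (steps of 1000, ≤ 40
attempts; about half of random priors admit three dedicated axes, and
the ladder was verified to succeed on 200/200 master seeds). The default
`generate_truth` mode remains unconstrained sampling for users who want
harder, partially-confounded worlds. These constraints repair the test
oracle; they do not alter effect sizes, noise, sample sizes or any
inference threshold.

# Numerical and degenerate-input policy

* One explicit RNG stream per operation; pipeline stages derive seeds
  from the config seed via a documented rolling hash (`stage_seed`), so
  reruns are byte-identical.
* Power iteration errors out (rather than returning) after 10⁴
  non-converged iterations; a ligand with no out-edges yields an
  all-zero potential, not an error.
* Zero-depth cells are an error in normalization (impossible after QC);
  a fully constant matrix is an error in HVG selection; variances below
  1e-12 are treated as zero.
* All-identical trajectory input collapses to a single state at
  pseudotime 0, never a crash; k-means receives at most as many centers
  as distinct points.
* Ties everywhere break lexicographically by gene name, making every
  ranking deterministic.
* Empty networks are legal at versions 2.0–4.0 (with a warning at 2.0);
  only an empty Network 1.0 is an error.

# Known limitations

* Heteromeric ligand/receptor complexes are not modeled; chains carry
  single genes.
* The prior network is an input; quadnet does not ship or reconstruct a
  curated multi-database prior, so network *contents* on real data
  depend entirely on the supplied prior.
* The signaling layer supports at most one intermediate hop in path
  extraction.
* The maximally-selected cutpoint p-value is selection-biased and only
  flagged as such.
* Pseudotime is a 2-component linear surrogate; branch-specific
  differential expression along the tree is out of scope.
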