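---
title: "Methods: network propagation, immune scoring and balanced classification for chemoresistance discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation, immune scoring and balanced classification for chemoresistance discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(resistnet)
```

`resistnet` is a discovery pipeline for genes that mediate chemotherapy
resistance through the tumor immune microenvironment. This vignette
documents the statistical machinery stage by stage: the model behind
each operation, the tunable parameters and their defaults, the numerical
choices, what the synthetic generators emulate, and the known
limitations.

## Study design assumed by the pipeline

The expected input is a log2-scale expression matrix over four sample
arms: drug-**resistant** and drug-**sensitive** patients (in the
breast-cancer setting that motivated the pipeline, Miller–Payne grades
1–2 and 4–5 respectively), each sampled **pre** and **post**
chemotherapy. Annotations travel with the matrix as a
`sample_id`/`group`/`timepoint` data frame. Probe-level arrays are first
collapsed to gene level by averaging each gene's probes on the log2
scale (`collapse_probes`). Gene identifiers are matched as exact,
case-sensitive strings throughout; alias resolution is deliberately out
of scope because alias maps are database-versioned.

Missing values are rejected at load time; `impute = "row-mean"` is an
explicit opt-in because silent imputation would bias the downstream
permutation nulls.

## Differential expression screen

For a contrast of groups $A$ and $B$,
$\mathrm{logFC}_g = \bar{x}_{gA} - \bar{x}_{gB}$ on the log2 scale, with
a two-sided p-value from Welch's unequal-variance $t$ (the default).
Genes pass when $|\mathrm{logFC}| > 0.585$ (a 1.5-fold change; the
threshold is kept as the literal conventional value, not recomputed) and
raw $p < 0.05$. No multiple-testing correction is applied at the
screening stage — the filter is intentionally on the raw p-value, and a
Benjamini–Hochberg FDR column is emitted for information only.

Four contrasts are screened: (a) resistant-vs-sensitive pre-treatment —
survivors are the *potential drug-resistance genes* (PDRGs); (b) the
same post-treatment; (c) pre-vs-post within the resistant group; (d)
pre-vs-post within the sensitive group — survivors are the *potential
drug-induced genes* (PDIGs). Pre-vs-post contrasts are unpaired: patient
pairing information is not part of the input contract, and an unpaired
test remains valid (if conservative) when samples are in fact paired.

An optional `test = "moderated"` shrinks the per-gene pooled variance
toward the grand mean variance, $\tilde{s}^2_g = (d_0\bar{s}^2 +
d_g s^2_g)/(d_0 + d_g)$ with prior weight $d_0 = 4$, and refers the
statistic to $t_{d_0+d_g}$ — a lightweight empirical-Bayes variant for
very small arms. It is not the default because the Welch test makes the
fewest assumptions and is exactly testable against `stats::t.test`.

Degenerate genes: zero variance in both groups yields $p = 1$ when the
means are equal and $p \to 0$ when they differ.

## Network permutation tests

`connectivity_permutation_test` asks whether a gene set induces more
edges in the interaction network than chance. The null is the induced
edge count of `n_perm` uniform same-size node draws (without
replacement, from all network nodes — not degree-matched, since the
question is about the set as found, not about its degree sequence).
`enrichment_permutation_test` is the analogous random-comparison version
of over-representation: observed overlap versus overlaps of random
same-size query draws from the universe; it converges to the
hypergeometric tail as `n_perm` grows.

All permutation p-values in the package use add-one smoothing,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$, so
$p$ is never 0 and is floored at $1/(n_{\text{perm}}+1)$.

## Random walk with restart and its rewired null

Gene relevance to a seed set is scored by network propagation. With $A$
the (optionally weighted) adjacency matrix, $D = \mathrm{diag}(A
\mathbf{1})$ and $M = A D^{-1}$ the column-stochastic transition matrix,
the walk iterates

$$ p^{(t+1)} = (1 - r)\, M p^{(t)} + r\, p_0 $$

with $p_0$ uniform over the seed genes present in the network, stopping
when the L1 change falls below `tol` ($10^{-10}$ by default; the
spectral radius of $(1-r)M$ is at most $1-r$, so convergence is
geometric). The fixed point equals the direct solve
$p = r\,(I - (1-r)M)^{-1} p_0$, which the test suite verifies to
$10^{-8}$ on random graphs; the two-node chain with $r = 0.5$ has the
closed form $(2/3, 1/3)$. Scores are non-negative and sum to 1; nodes
unreachable from the seeds score 0. Zero-degree nodes are made
self-absorbing so $M$ stays stochastic. The restart probability defaults
to $r = 0.7$, the conventional value in network-propagation gene
prioritization; edge weights are used in $M$ by default with an
unweighted mode available.

**Null model.** Walk scores scale strongly with node degree, so
significance is assessed against *degree-preserving* rewired networks:
`10 · |E|` attempted double-edge swaps per replicate, rejecting
self-loops and parallel edges, which leaves every node's degree exactly
unchanged (asserted on every replicate). The rewiring engine is
`igraph::rewire(keeping_degseq())`; because it does not carry edge
attributes, the original weight multiset is reassigned to the rewired
edges in random order, preserving both the degree and the weight
distributions. A uniform node-relabeling null (`null_model =
"label-shuffle"`) is available for comparison. A graph admitting no
legal swap (e.g. a triangle) is returned unchanged with a warning.

**Per-gene null.** Each candidate's observed score is compared only
against *its own* scores across the rewired replicates, never against a
pooled score distribution — pooling would confound degree with
significance. This choice matters: hub genes have systematically larger
scores under any seeding.

**Combination rule.** A gene is promoted to the candidate resistance set
when significant at `alpha = 0.01` for at least `min_sets = 2` seed
sets. The threshold of two is the default rather than three because the
biological claim being encoded is "related to multiple independent
resistance-gene collections"; both are one-argument changes.

## Immune microenvironment scoring

**Geometric-mean signatures.** On log2 data the score is the arithmetic
mean over the set's genes, i.e. the log2 of the geometric mean of the
linear-scale values; it is translation-equivariant on the log2 scale.

**ssGSEA.** Per sample, genes are ranked by expression (descending,
average ranks on ties). Walking down the ranked list, the in-set
weighted ECDF (weights $r_g^\alpha$ with $r_g$ the rank value, top gene
$= n$) and the uniform out-set ECDF are accumulated, and the enrichment
score is the sum of their differences over all positions — the integral
form of the running sum. $\alpha = 0.25$ is the standard single-sample
exponent. Because only ranks enter, the score is invariant under any
strictly monotone per-sample transform (tested to $10^{-12}$), which is
also why no cross-sample rescaling of the ES is applied — the background
z-normalization below plays that role.

**Random-background z-normalization.** Raw ssGSEA scores are not
comparable across samples. Each replicate shuffles the gene-to-value
assignment within every sample's expression vector (preserving each
sample's value distribution; per-gene shuffling across samples is
available as an option), re-scores the panel, and repeats `n_perm = 100`
times. Per signature, the null scores are pooled over replicates *and*
samples, and $z = (\text{real} - \mu_{\text{null}})/\sigma_{\text{null}}$;
a per-sample pooling mode is provided since either reading of
"integrate real and random data" is defensible. A minimum of 10
replicates is enforced — the standard deviation of fewer values is too
unstable to divide by. On self-null data the per-signature mean z is
within three standard errors of 0 (tested).

**Group comparison.** Two-sided Wilcoxon rank-sum per feature via
`stats::wilcox.test` (exact for small untied samples: $\{1,2\}$ vs
$\{3,4\}$ gives exactly $p = 1/3$), with the direction taken from the
sign of the median difference. Externally computed 22-cell-type
deconvolution fractions enter through `read_cell_fractions`, which only
enforces the contract (entries in $[0,1]$, rows summing to 1).

## Consensus immune subtyping

For each candidate $k$, `n_reps = 1000` replicates subsample 80% of the
samples and run k-means on standardized features; the consensus entry
for a pair is the fraction of co-sampled replicates in which it was
co-clustered. The classical model-selection indicators — the empirical
CDF of consensus entries, its area, and the delta-area across $k$ — are
computed and reported. For choosing $k$ itself the package uses the
ambiguity of the same CDF: the proportion of ambiguous entries
$\mathrm{PAC}(k) = \mathrm{CDF}(0.9) - \mathrm{CDF}(0.1)$, selecting the
smallest $k$ with $\mathrm{PAC} \le 0.1$. The delta-area elbow alone was
measured to be unreliable here: under subsampled k-means the CDF area
keeps growing well past the true $k$ (on clean two-cluster data the
relative delta-area at $k = 3$ was still $\approx 0.23$), whereas PAC is
essentially 0 at the true $k$ and large elsewhere. When no $k$ is
unambiguous the rule falls back to the smallest $k$ in the range and
raises a `low_confidence` flag (also raised whenever the chosen $k$'s
ambiguous fraction exceeds 0.3). Final labels cut an average-linkage
hierarchical tree of $1 - \text{consensus}$.

## Balanced random forest

The 15-feature matrix (five drug-resistance pathways, seven immune
signatures, ABC transporters, cancer stemness, and the walk-derived
`Potential_Set`; all geometric-mean scores, columns in panel order) is
classified by a 1000-tree random forest in which each tree is trained on
*all* minority-class samples plus an equal-size uniform draw (without
replacement) of the majority class — implemented through
`randomForest`'s `strata`/`sampsize`/`replace = FALSE` mechanism and
asserted tree by tree on the in-bag matrix. The balancing rule is
applied symmetrically (downsample whichever class is larger) with
`resistant` as the positive class. Tree hyperparameters beyond the count
(`mtry`, node size) stay at library defaults and are recorded in the
fitted object. Importances are mean decrease in Gini impurity,
normalized to sum to 1.

Evaluation is stratified 5-fold cross-validation; AUC-ROC (via `pROC`)
and AUC-PR are reported per fold and pooled over held-out predictions.
AUC-PR uses step interpolation over the ranked predictions
($\sum_i (R_i - R_{i-1}) P_i$, i.e. average precision); under a random
classifier it concentrates near the prevalence, which the tests assert.

The published panel discloses set names, categories and sizes but not
the member genes, so `default_feature_panel()` constructs a synthetic
stand-in with the documented layout by drawing members from a supplied
universe; it exists for testing and simulation, and real analyses load
their own GMT.

## Synthetic generators and what they do (not) show

All generators are pure functions of their arguments including `seed`.

* `simulate_cohort` — per-gene baselines $\sim N(7, 2)$ clipped at 0 on
  the log2 scale (microarray-like dynamic range; the exact values are
  immaterial to the tests), i.i.d. Gaussian noise (`noise_sd = 0.5`),
  and the first `n_de_genes = 100` of `n_genes = 2000` genes shifted by
  `de_logfc = 1.0` in the resistant-pre arm with alternating sign, so
  both the up and the down accounting branches are exercised;
  15 samples per arm.
* `simulate_network` — a preferential-attachment backbone
  (`n_nodes = 500`, `attachment = 2`; the construction yields exactly
  $m(n-m) + \binom{m}{2}$ edges, asserted), four disjoint 20-gene seed
  sets, and `n_planted = 20` planted genes each gaining independent
  edges with probability `planted_link_prob = 0.8` to every member of
  two randomly chosen seed sets — the wiring pattern the walk stage is
  designed to detect. At `planted_link_prob = 0` the planted genes are
  ordinary backbone nodes and recovery must (and does) fall to chance.
* `simulate_signatures` — disjoint random gene sets with a `+shift`
  planted into the member genes of the first `shifted_sets` sets in one
  annotation group.

These generators validate *recovery and calibration*, not realism: they
contain no batch effects, no correlated gene modules outside the planted
structure, no probe-level artifacts, and expression noise is homoscedastic
Gaussian. Passing the suite therefore demonstrates that the machinery is
correct and calibrated under its own assumptions — not that any
particular real cohort will yield a reliable classifier (on real
validation cohorts of this design, modest AUCs are the documented
outcome).

## Validation problem sizes

The packaged validation (test suite and `scripts/acceptance.R`) runs at
desk scale, chosen so each property is measured with useful precision:
2000-gene cohorts with 15 samples per arm for DE power/calibration; 100
random graphs of up to 50 nodes for the propagation-vs-solve check;
walk-null calibration from ~285 candidate genes at 200 rewirings;
planted-gene recovery on the default 500-node network at 1000 rewirings
against 200 degree-matched decoys; 50 background replicates for ssGSEA
self-null centering; 200 consensus replicates; and 1000-tree forests,
with the label-permuted AUC averaged over several permutations because a
single 60-sample CV AUC has Monte-Carlo standard deviation near 0.09.
Production analyses would typically raise `n_perm` and `n_reps` to the
stage defaults (1000 walk rewirings, 100 background replicates, 1000
consensus replicates).

## Known limitations

* Pre-vs-post contrasts are unpaired even when the design is paired.
* The moderated test is a fixed-prior shrinkage, not a full
  empirical-Bayes fit of the prior degrees of freedom.
* The connectivity null draws node sets uniformly, not degree-matched;
  for degree-driven questions use the walk stage, whose null preserves
  degree exactly.
* ssGSEA scores are reported unrescaled; cross-sample comparability is
  delegated entirely to the background z-normalization.
* Consensus clustering uses k-means replicates; strongly non-convex
  cluster shapes would need a different base clusterer.
* The classifier's feature panel on real data depends on user-supplied
  gene sets; the built-in panel is a synthetic stand-in with the
  documented layout only.
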