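# resistnet

Network-based discovery of immune-mediated chemotherapy-resistance genes
from tumor expression cohorts.

## The problem

In cohorts of cancer patients treated with chemotherapy (e.g. breast
cancer graded by Miller–Payne response, where grades 1–2 define a
drug-resistant group and grades 4–5 a drug-sensitive group), the genes
that separate resistant from sensitive tumors *before* treatment are
candidate drivers of resistance — and a growing body of evidence places
many of them in the tumor immune microenvironment rather than in
tumor-cell-intrinsic pathways. `resistnet` implements the full discovery
pipeline for this setting:

1. **Differential expression screen** — per-gene log2 fold change and
   Welch *t* p-value over the four standard contrasts
   (resistant-vs-sensitive pre and post chemotherapy; pre-vs-post within
   each group), filtered at `|logFC| > 0.585` and raw `p < 0.05`.
   Survivors of the pre-treatment contrast are the potential
   drug-resistance genes (PDRGs); survivors of the sensitive pre-vs-post
   contrast are the potential drug-induced genes (PDIGs).
2. **Network permutation tests** — is the PDRG interaction subnetwork
   more densely connected than same-size random node sets
   (`connectivity_permutation_test`), and does a gene list overlap an
   annotation set beyond chance (`enrichment_permutation_test`)? Both use
   add-one empirical p-values, `p = (1 + #{null ≥ obs}) / (n_perm + 1)`.
3. **Random-walk prioritization** — relevance of every gene to curated
   seed sets (drug-resistance genes, cancer-stemness markers, ABC
   transporters) by random walk with restart,
   `p ← (1 − r)·W·p + r·p₀` with `W` the column-stochastic transition
   matrix and restart `r = 0.7`; per-gene significance against the same
   walk on degree-preserving rewired networks, and a candidate is kept
   when significant (`p < 0.01`) for ≥ 2 seed sets (`combine_walks`).
4. **Immune microenvironment scoring** — per-sample geometric-mean
   signature scores and single-sample gene-set enrichment (ssGSEA,
   `α = 0.25`), the latter z-normalized against a shuffled-matrix random
   background; two-group Wilcoxon comparisons; consensus clustering
   (subsampled k-means, consensus CDF) into immune subtypes.
5. **Resistance classifier** — a 15-dimensional per-patient feature
   matrix (5 drug-resistance pathways, 7 immune signatures, ABC
   transporters, cancer stemness, and the prioritized gene set), fed to a
   1000-tree random forest in which *every tree* is trained
   class-balanced (all minority-class samples plus an equal-size draw of
   the majority class), evaluated by stratified 5-fold cross-validated
   AUC-ROC and AUC-PR.

A synthetic-data module (`simulate_cohort`, `simulate_network`,
`simulate_signatures`) generates cohorts, scale-free interaction networks
and signature panels with *planted* signal, so every stage can be
validated against known ground truth.

## Worked example

```r
library(resistnet)

## a cohort with 50 planted DE genes (|logFC| = 1) out of 1000
cohort <- simulate_cohort(n_genes = 1000, n_per_arm = 15, n_de_genes = 50,
                          de_logfc = 1.0, noise_sd = 0.5, seed = 42)
screen <- screen_contrasts(cohort$expr)
screen$counts
#>                      contrast up down total
#> 1  resistant_vs_sensitive_pre 25   25    50
#> 2 resistant_vs_sensitive_post  2    1     3
#> 3       resistant_pre_vs_post 27   25    52
#> 4       sensitive_pre_vs_post  0    1     1
mean(cohort$truth$gene %in% screen$pdrg)   # PDRG recall of planted genes
#> [1] 1
```

The pre-treatment contrast recovers all 50 planted genes (25 up, 25
down); the post-treatment and within-group contrasts show only the
handful of false positives expected at raw `p < 0.05`.

```r
## a network with 10 planted resistance genes wired near 4 seed sets
net <- simulate_network(n_nodes = 300, seed_set_sizes = rep(15, 4),
                        n_planted = 10, planted_link_prob = 0.8, seed = 42)
walks <- lapply(names(net$seed_sets), function(nm)
  walk_significance(net$network, net$seed_sets[[nm]], n_perm = 200,
                    seed = 42, seed_set_name = nm))
hits <- combine_walks(walks, alpha = 0.01, min_sets = 2)
sum(net$planted %in% hits$gene)
#> [1] 10        # all 10 planted genes recovered
head(hits, 2)
#>       gene n_sets      best_p
#> 1 node0075      2 0.004975124
#> 2 node0151      2 0.004975124
```

`best_p = 1/201` is the add-one floor at 200 permutations: the planted
genes outscore every rewired replicate.

```r
## background-normalized ssGSEA finds the two planted signature shifts
sig <- simulate_signatures(cohort$expr, n_sets = 6, set_size = 15,
                           shifted_sets = 2, shift = 1, seed = 42)
z <- score_signature_panel(sig$expr, sig$sets, method = "ssgsea_z",
                           n_perm = 20, seed = 42)
compare_groups(z, sig$expr$samples$group)[1:3, 1:3]
#>        feature      p_value direction
#> 1 signature_01 1.691123e-17        up
#> 2 signature_02 1.691123e-17        up
#> 3 signature_03 3.581014e-01      down

## 15-feature balanced random forest
panel <- default_feature_panel(gene_ids(sig$expr), seed = 42)
fm <- build_feature_matrix(sig$expr, panel)
cross_validate(fm, k = 5, n_trees = 1000, seed = 42)
#> ClassifierReport: 5-fold CV, pooled AUC-ROC = 1.000, AUC-PR = 1.000
```

Only the two shifted signatures separate the groups (direction `up` =
higher in the resistant group), and the forest separates the planted
cohort perfectly — on a null cohort the same code path returns AUCs near
0.5 (see the test suite).

Real data enter through `read_expression_matrix()` (TSV/GCT, with
`collapse_probes()` for probe-level arrays), `read_gene_sets()` (GMT),
`read_network()` (STRING-style edge lists, combined-score threshold 0.4
by default) and `read_cell_fractions()` (externally computed 22-cell-type
deconvolution tables).

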