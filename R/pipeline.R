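#' End-to-end synthetic discovery run
#'
#' Exercises the whole pipeline on generated data with planted signal:
#' simulate a cohort, screen the four differential-expression contrasts,
#' simulate a seeded network and prioritize planted resistance genes by
#' random walk against rewired nulls, plant signature shifts and score
#' them (geometric mean and background-normalized ssGSEA), compare groups,
#' derive consensus immune subtypes from the scores, and cross-validate
#' the balanced random forest on the 15-feature matrix. Everything is a
#' deterministic function of `seed`.
#'
#' The generator defaults are the study conditions the synthetic modules
#' document; the `n_perm_*`, `n_reps` and `n_trees` arguments only set
#' how much Monte-Carlo effort each stage spends and default to the
#' stage-level defaults (1000 walk permutations, 100 background
#' replicates, 1000 clustering replicates, 1000 trees).
#'
#' @param seed Master seed; per-stage streams are derived as
#'   `seed + 1 ... seed + 7`.
#' @param n_perm_walk Rewired-network replicates for walk significance.
#' @param n_perm_bg Background replicates for ssGSEA z-normalization.
#' @param n_reps Consensus-clustering replicates.
#' @param n_trees Trees per forest.
#' @param cohort,network,signatures Optional lists of argument overrides
#'   for [simulate_cohort()], [simulate_network()],
#'   [simulate_signatures()].
#' @return A list with elements `cohort`, `screen`, `network`, `walks`,
#'   `candidates`, `signatures`, `scores_gm`, `scores_z`,
#'   `group_comparison`, `subtypes`, `features`, `classifier`.
#' @export
run_synthetic_pipeline <- function(seed = 1, n_perm_walk = 1000,
                                   n_perm_bg = 100, n_reps = 1000,
                                   n_trees = 1000,
                                   cohort = list(), network = list(),
                                   signatures = list()) {
  seed <- as.integer(seed)

  ## 1. cohort + differential expression screen
  cohort_sim <- do.call(simulate_cohort, c(cohort, list(seed = seed + 1L)))
  screen <- screen_contrasts(cohort_sim$expr)

  ## 2. network + random-walk prioritization
  net_sim <- do.call(simulate_network, c(network, list(seed = seed + 2L)))
  walks <- lapply(names(net_sim$seed_sets), function(nm) {
    walk_significance(net_sim$network, net_sim$seed_sets[[nm]],
                      n_perm = n_perm_walk, seed = seed + 3L,
                      seed_set_name = nm)
  })
  candidates <- combine_walks(walks)

  ## 3. signature scoring + group comparison + subtyping
  sig_sim <- do.call(simulate_signatures,
                     c(signatures, list(expr = cohort_sim$expr,
                                        seed = seed + 4L)))
  scores_gm <- score_signature_panel(sig_sim$expr, sig_sim$sets,
                                     method = "geometric_mean")
  scores_z <- score_signature_panel(sig_sim$expr, sig_sim$sets,
                                    method = "ssgsea_z",
                                    n_perm = n_perm_bg, seed = seed + 5L)
  grp <- sig_sim$expr$samples$group
  comparison <- compare_groups(scores_z, grp)
  subtypes <- consensus_cluster(unclass(scores_gm), k_range = 2:5,
                                n_reps = n_reps, seed = seed + 6L)

  ## 4. feature matrix + balanced forest
  panel <- default_feature_panel(gene_ids(sig_sim$expr), seed = seed + 7L)
  features <- build_feature_matrix(sig_sim$expr, panel)
  classifier <- cross_validate(features, k = 5, n_trees = n_trees,
                               seed = seed + 7L)

  list(cohort = cohort_sim, screen = screen, network = net_sim,
       walks = walks, candidates = candidates, signatures = sig_sim,
       scores_gm = scores_gm, scores_z = scores_z,
       group_comparison = comparison, subtypes = subtypes,
       features = features, classifier = classifier)
}
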