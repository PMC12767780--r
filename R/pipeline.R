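# End-to-end NPR-bias pipeline on synthetic data: simulate -> importance
# -> motif-pruned regulons -> activity -> exclusive cells -> class
# networks -> complexity comparison.

#' Run the full NPR-bias recovery pipeline on synthetic data
#'
#' One pass of the whole analysis at desk scale: simulate an expression
#' matrix with planted class-asymmetric regulation, infer TF-to-target
#' importance for the panel genes, prune into motif-supported regulons,
#' score and binarize regulon activity, split cells into NP- and
#' NPR-exclusive sets, build the two class networks, and compare their
#' complexity (per-gene TF in-degree).
#'
#' The default configuration (500 cells, 100 genes, 20 TFs, sparse panel
#' expression: baseline mean 0.1 UMI, TFs active in 10% of cells) is sized
#' so that the TF axis is not saturated -- with only a handful of TFs
#' almost every TF regulates at least one gene of either class and the
#' TF-count contrast degenerates to a tie -- and so that class-exclusive
#' cell populations exist, which requires panel genes to be silent in
#' most cells.
#'
#' @param config A [sim_config()]; `NULL` uses the pipeline default above.
#' @param seed Integer seed (overrides `config$seed`).
#' @param top_fraction,n_null,act_quantile Activity-scoring settings
#'   passed to [aucell_score()] / [binarize_activity()].
#' @param top_k_per_tf Regulon pruning depth ([build_regulons()]).
#' @return List: `dataset`, `importance`, `regulons`, `activity`,
#'   `cells` (exclusive sets), `networks` (`np`, `npr`), `stats` (per
#'   class [network_stats()]), `comparison` (the in-degree comparison
#'   row from [compare_tissue_networks()]).
#' @export
run_bias_pipeline <- function(config = NULL, seed = 1, top_fraction = 0.3,
                              n_null = 100, act_quantile = 0.99,
                              top_k_per_tf = 50) {
  if (is.null(config)) {
    config <- sim_config(n_cells = 500, n_genes = 100, n_tfs = 20,
                         baseline_mean = 0.1, tf_active_prob = 0.1, seed = seed)
  } else {
    config$seed <- seed
  }
  ds <- simulate_expression(config)
  m <- ds$matrix
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  np_genes <- panel_genes(config$panel, "NP", network = TRUE)
  npr_genes <- panel_genes(config$panel, "NPR", network = TRUE)

  imp <- genie3_importance(m, tfs, targets = c(np_genes, npr_genes),
                           seed = seed)
  regulons <- build_regulons(imp, ds$motif_support,
                             top_k_per_tf = top_k_per_tf,
                             rank_by = "importance_raw")
  ranks <- cell_ranks(m$counts)
  target_universe <- setdiff(colnames(m$counts), tfs)
  activity <- stats::setNames(lapply(seq_along(regulons), function(i) {
    r <- regulons[[i]]
    auc <- aucell_score(m, r, top_fraction = top_fraction, ranks = ranks)
    binarize_activity(auc, m, r, n_null = n_null, quantile = act_quantile,
                      top_fraction = top_fraction, seed = seed + i,
                      ranks = ranks, universe = target_universe)
  }), vapply(regulons, `[[`, character(1), "tf"))

  cells <- select_exclusive_cells(m, np_genes, npr_genes)
  np_net <- build_class_network(regulons, activity, cells$np_cells,
                                np_genes, class = "NP")
  npr_net <- build_class_network(regulons, activity, cells$npr_cells,
                                 npr_genes, class = "NPR")
  comparison <- compare_tissue_networks(list(list(
    group = "all",
    np = tf_indegree(np_net, np_genes),
    npr = tf_indegree(npr_net, npr_genes))), seed = seed)
  list(dataset = ds, importance = imp, regulons = regulons,
       activity = activity, cells = cells,
       networks = list(np = np_net, npr = npr_net),
       stats = list(np = network_stats(np_net), npr = network_stats(npr_net)),
       comparison = comparison)
}
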