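test_that("exclusive-cell selection partitions cells as specified", {
  counts <- rbind(c(5, 0),   # NP only -> NP-exclusive
                  c(2, 1),   # both -> excluded
                  c(0, 4),   # NPR only -> NPR-exclusive
                  c(0, 0))   # neither -> excluded
  colnames(counts) <- c("np1", "npr1")
  m <- toy_matrix(counts)
  sel <- select_exclusive_cells(m, "np1", "npr1")
  expect_equal(sel$np_cells, "c1")
  expect_equal(sel$npr_cells, "c3")
  # a sub-threshold receptor count does not disqualify the cell
  sel2 <- select_exclusive_cells(m, "np1", "npr1", min_count = 2)
  expect_true("c2" %in% sel2$np_cells)
  expect_length(intersect(sel2$np_cells, sel2$npr_cells), 0)
  expect_error(select_exclusive_cells(m, character(), "npr1"), "non-empty")
})

test_that("exclusive sets are always disjoint on simulated data", {
  for (s in 1:5) {
    d <- simulate_expression(sim_config(n_cells = 100, n_genes = 50,
                                        n_tfs = 5, seed = 800 + s))
    np <- panel_genes(d$config$panel, "NP", network = TRUE)
    npr <- panel_genes(d$config$panel, "NPR", network = TRUE)
    sel <- select_exclusive_cells(d$matrix, np, npr)
    expect_length(intersect(sel$np_cells, sel$npr_cells), 0)
  }
})

toy_activity <- function(tfs, cells, on = TRUE) {
  stats::setNames(lapply(tfs, function(tf) {
    list(active = stats::setNames(rep(on, length(cells)), cells))
  }), tfs)
}

test_that("class networks count TFs, nodes and edges as in the worked example", {
  regs <- list(new_regulon("TF1", "r1"), new_regulon("TF2", c("r1", "r2")))
  act <- toy_activity(c("TF1", "TF2"), c("c1", "c2"))
  net <- build_class_network(regs, act, c("c1", "c2"), c("r1", "r2"),
                             class = "NPR")
  s <- network_stats(net)
  expect_equal(s$n_tfs, 2)
  expect_equal(s$n_nodes, 4)
  expect_equal(s$n_edges, 3)
  # no active regulons: empty network
  act_off <- toy_activity(c("TF1", "TF2"), c("c1", "c2"), on = FALSE)
  net0 <- build_class_network(regs, act_off, c("c1", "c2"), c("r1", "r2"))
  expect_equal(network_stats(net0)$n_edges, 0)
  expect_error(build_class_network(regs, act, "c9", c("r1", "r2")), "absent")
})

test_that("shared-TF removal empties overlaps and is idempotent", {
  a <- structure(list(class = "NP", group = "all",
                      edges = data.frame(tf = c("T1", "T2"), gene = c("x", "y")),
                      tf_set = c("T1", "T2"), gene_set = c("x", "y")),
                 class = "tf_network")
  b <- structure(list(class = "NPR", group = "all",
                      edges = data.frame(tf = c("T2", "T3"), gene = c("u", "v")),
                      tf_set = c("T2", "T3"), gene_set = c("u", "v")),
                 class = "tf_network")
  out <- remove_shared_tfs(a, b)
  expect_equal(out$shared, "T2")
  expect_false("T2" %in% out$a$tf_set)
  expect_false("T2" %in% out$b$tf_set)
  again <- remove_shared_tfs(out$a, out$b)
  expect_equal(again$a, out$a)
  expect_equal(again$b, out$b)
  expect_length(again$shared, 0)
  # identical networks cancel entirely
  both <- remove_shared_tfs(a, a)
  expect_length(both$a$tf_set, 0)
  expect_equal(nrow(both$a$edges), 0)
  # disjoint networks pass through unchanged
  dis <- remove_shared_tfs(out$a, out$b)
  expect_equal(dis$a$edges, out$a$edges)
})

test_that("cascade counting matches hand enumeration on a toy regulon set", {
  regs <- list(new_regulon("A", c("B", "x"), motif = "m1", context = "head"),
               new_regulon("B", c("y"), motif = "m2", context = "head"),
               new_regulon("C", c("A", "B"), motif = "m3", context = "body"))
  cc <- cascade_counts(regs, c("A", "B", "C"), group_by = "motif")
  # A targets TF B (under m1); C targets TFs A and B (under m3)
  expect_equal(unname(cc$counts[c("m1", "m3")]), c(1, 2))
  expect_false("m2" %in% names(cc$counts))
  by_tissue <- cascade_counts(regs, c("A", "B", "C"), group_by = "tissue")
  expect_equal(unname(by_tissue$counts[c("body", "head")]), c(2, 1))
  # restricting the upstream set drops cascades
  cc2 <- cascade_counts(regs, "B", group_by = "motif")
  expect_equal(nrow(cc2$incidences), 0)
  expect_length(cc2$counts, 0)
})

test_that("group comparisons skip undersized groups with a warning", {
  nets <- list(list(group = "tiny", np = c(1, 2), npr = c(3, 4)),
               list(group = "ok", np = c(1, 2, 3, 2), npr = c(5, 6, 7, 8)))
  expect_warning(res <- compare_tissue_networks(nets), "tiny")
  expect_equal(res$group, "ok")
  expect_gt(res$dbm, 0)
})

test_that("the end-to-end pipeline recovers the planted receptor bias", {
  res <- run_bias_pipeline(seed = 17)
  expect_gt(res$stats$npr$n_tfs, res$stats$np$n_tfs)
  expect_lt(res$comparison$p, 0.05)
  expect_gt(res$comparison$dbm, 0)
  # node accounting: disjoint gene and TF sets
  s <- res$stats$npr
  expect_equal(s$n_nodes,
               length(res$networks$npr$tf_set) + length(res$networks$npr$gene_set))
})
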