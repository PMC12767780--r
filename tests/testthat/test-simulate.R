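small_cfg <- function(...) {
  sim_config(n_cells = 120, n_genes = 50, n_tfs = 10, ...)
}

test_that("expression simulation is bit-for-bit reproducible from its seed", {
  cfg <- small_cfg(seed = 11)
  d1 <- simulate_expression(cfg)
  d2 <- simulate_expression(cfg)
  expect_identical(as.matrix(d1$matrix$counts), as.matrix(d2$matrix$counts))
  expect_identical(d1$truth_edges, d2$truth_edges)
  expect_identical(d1$motif_support, d2$motif_support)
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_expression(sim_config(n_genes = 10, n_tfs = 10)),
               "invalid config")
  expect_error(simulate_expression(sim_config(n_genes = 25, n_tfs = 5)),
               "invalid config")
  expect_error(sim_config(effect_size = 0.5), "effect_size")
  expect_error(sim_config(tf_active_prob = 0), "tf_active_prob")
})

test_that("counts are non-negative integers and truth edges live in the matrix", {
  d <- simulate_expression(small_cfg(seed = 2))
  counts <- as.matrix(d$matrix$counts)
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_true(all(d$truth_edges$tf %in% colnames(counts)))
  expect_true(all(d$truth_edges$target %in% colnames(counts)))
})

test_that("effect size 1 leaves targets indistinguishable from background", {
  # oracle: per-gene two-sample t-test of each panel gene against a
  # matched background gene, alpha = 0.01
  fails_to_reject <- 0; total <- 0
  for (s in 1:20) {
    d <- simulate_expression(small_cfg(effect_size = 1, seed = 100 + s))
    counts <- as.matrix(d$matrix$counts)
    panel <- unique(d$truth_edges$target)
    bg <- grep("^BG", colnames(counts), value = TRUE)
    for (i in seq_along(panel)) {
      x <- counts[, panel[i]]
      y <- counts[, bg[(i - 1) %% length(bg) + 1]]
      if (sd(x) == 0 && sd(y) == 0) next
      p <- tryCatch(t.test(x, y)$p.value, error = function(e) 1)
      fails_to_reject <- fails_to_reject + (p >= 0.01)
      total <- total + 1
    }
  }
  expect_gte(fails_to_reject / total, 0.95)
})

test_that("planted fan-in asymmetry is recovered from the truth edges", {
  diffs <- vapply(1:20, function(s) {
    d <- simulate_expression(sim_config(n_cells = 30, n_genes = 60, n_tfs = 20,
                                        fanin_np = 3, fanin_npr = 8,
                                        seed = 200 + s))
    deg <- truth_indegree(d)
    mean(deg$npr) - mean(deg$np)
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 5), 1)
})

test_that("cis-regulatory annotation recovers planted class means", {
  panel <- load_panel("packaged")
  np_means <- npr_means <- numeric(0)
  for (s in 1:50) {
    ann <- simulate_cisreg_annotation(panel, count_mean = c(NP = 5, NPR = 12),
                                      seed = 300 + s)
    fs <- summarize_features(ann, genes = c(panel_genes(panel, "NP"),
                                            panel_genes(panel, "NPR")))
    np_means <- c(np_means, mean(fs$count[fs$gene %in% panel_genes(panel, "NP")]))
    npr_means <- c(npr_means, mean(fs$count[fs$gene %in% panel_genes(panel, "NPR")]))
  }
  se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(np_means) - 5), 3 * se(np_means))
  expect_lt(abs(mean(npr_means) - 12), 3 * se(npr_means))
  # identical class means: paired count difference compatible with zero
  diffs <- vapply(1:50, function(s) {
    ann <- simulate_cisreg_annotation(panel, count_mean = c(NP = 6, NPR = 6),
                                      seed = 400 + s)
    fs <- summarize_features(ann, genes = c(panel_genes(panel, "NP"),
                                            panel_genes(panel, "NPR")))
    mean(fs$count[fs$gene %in% panel_genes(panel, "NPR")]) -
      mean(fs$count[fs$gene %in% panel_genes(panel, "NP")])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * se(diffs))
  # determinism
  expect_identical(simulate_cisreg_annotation(panel, seed = 5),
                   simulate_cisreg_annotation(panel, seed = 5))
})

test_that("annotation generator validates its class means", {
  panel <- load_panel("packaged")
  expect_error(simulate_cisreg_annotation(panel, count_mean = c(NP = 5)),
               "unknown gene class")
})

test_that("Ct generator plants exact folds at zero noise", {
  genes <- c("AstA-R1", "GAPDH")
  fold <- data.frame(gene = "AstA-R1", temperature_c = 37, log2_fold = 2)
  ct <- simulate_ct_table(genes, fold, noise_sd = 0, seed = 1)
  rel <- relative_expression(ct, "AstA-R1")
  expect_equal(unique(rel$fold[rel$temperature_c == 37]), 4)
  expect_equal(unique(rel$fold[rel$temperature_c == 25]), 1)
  expect_equal(unique(rel$fold[rel$temperature_c == 29]), 1)
  expect_error(simulate_ct_table("AstA"), "missing reference gene")
})

test_that("importance series plants class lifts and is seed-stable", {
  panel <- load_panel("packaged")
  ages <- c(5, 30, 50, 70)
  lifted <- simulate_importance_series(ages, npr_lift = 0.05, seed = 4)
  by_age <- split(lifted, lifted$age_days)
  for (a in by_age) {
    expect_gt(mean(a$importance[a$class == "NPR"]),
              mean(a$importance[a$class == "NP"]))
  }
  expect_identical(simulate_importance_series(ages, seed = 4),
                   simulate_importance_series(ages, seed = 4))
  expect_error(simulate_importance_series(numeric(0)), "non-empty")
  # no lift: class means equal within 3 SE (pooled over seeds)
  d <- vapply(1:30, function(s) {
    imp <- simulate_importance_series(30, npr_lift = 0, seed = 500 + s)
    mean(imp$importance[imp$class == "NPR"]) -
      mean(imp$importance[imp$class == "NP"])
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})
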