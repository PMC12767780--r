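test_that("rank-AUC score matches worked examples", {
  # 1 cell, 10 genes; targets at ranks 2 and 4; top fraction 0.5
  counts <- matrix(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), 1, 10)
  m <- toy_matrix(counts)
  reg <- list(targets = c("g2", "g4"))
  expect_equal(unname(aucell_score(m, reg, top_fraction = 0.5)), 6 / 9)
  # all targets at the top of the ranking: maximal recovery
  expect_equal(unname(aucell_score(m, list(targets = c("g1", "g2")),
                                   top_fraction = 0.5)), 1)
  # all targets outside the scored window
  expect_equal(unname(aucell_score(m, list(targets = c("g9", "g10")),
                                   top_fraction = 0.5)), 0)
})

test_that("rank-AUC equals the brute-force recovery-curve oracle", {
  for (s in 1:20) {
    set.seed(s)
    counts <- matrix(rpois(20 * 50, 3), 20, 50)
    m <- toy_matrix(counts)
    size <- sample(2:10, 1)
    targets_idx <- sample(50, size)
    f <- runif(1, 0.05, 1)
    got <- aucell_score(m, list(targets = colnames(m$counts)[targets_idx]),
                        top_fraction = f)
    want <- vapply(seq_len(20), function(i)
      oracle_aucell(counts[i, ], targets_idx, f), numeric(1))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("rank-AUC input contracts are enforced", {
  m <- toy_matrix(matrix(1:4, 2, 2))
  expect_error(aucell_score(m, list(targets = "nope")), "present")
  expect_error(aucell_score(m, list(targets = "g1"), top_fraction = 0), "top_fraction")
  expect_error(aucell_score(m, list(targets = "g1"), top_fraction = 1.2), "top_fraction")
})

test_that("a target that copies a TF attracts almost all importance", {
  set.seed(1)
  n <- 100
  tf_counts <- matrix(rpois(n * 6, 5), n, 6,
                      dimnames = list(NULL, sprintf("TF%02d", 1:6)))
  counts <- cbind(tf_counts, target = tf_counts[, 1])
  m <- toy_matrix(counts)
  imp <- genie3_importance(m, sprintf("TF%02d", 1:6), targets = "target",
                           seed = 1)
  expect_gt(imp$importance[imp$tf == "TF01"], 0.9)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
})

test_that("importance on an independent target stays near uniform", {
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    counts <- cbind(matrix(rpois(80 * 6, 5), 80, 6,
                           dimnames = list(NULL, sprintf("TF%02d", 1:6))),
                    target = rpois(80, 5))
    m <- toy_matrix(counts)
    imp <- genie3_importance(m, sprintf("TF%02d", 1:6), targets = "target",
                             seed = s)
    if (max(imp$importance) < 3 / 6) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("importance tables are deterministic and normalized per target", {
  d <- simulate_expression(sim_config(n_cells = 60, n_genes = 40, n_tfs = 5,
                                      seed = 9))
  tfs <- sprintf("TF%02d", 1:5)
  i1 <- genie3_importance(d$matrix, tfs, seed = 42)
  i2 <- genie3_importance(d$matrix, tfs, seed = 42)
  expect_identical(i1, i2)
  sums <- tapply(i1$importance, i1$target, sum)
  split_happened <- tapply(i1$importance_raw, i1$target, sum) > 0
  expect_true(all(abs(sums[split_happened] - 1) < 1e-9))
})

test_that("constant targets are flagged with zero importances", {
  counts <- cbind(matrix(rpois(60 * 3, 5), 60, 3,
                         dimnames = list(NULL, c("TF01", "TF02", "TF03"))),
                  flat = rep(2, 60))
  m <- toy_matrix(counts)
  imp <- genie3_importance(m, c("TF01", "TF02", "TF03"), targets = "flat")
  expect_true(all(imp$constant_target))
  expect_true(all(imp$importance == 0))
  expect_error(genie3_importance(m, "TF01", targets = "flat"), "2 TFs")
})

test_that("regulon pruning keeps top targets with motif support", {
  imp <- data.frame(tf = "TF1", target = c("a", "b", "c"),
                    importance = c(0.5, 0.3, 0.2))
  motifs <- data.frame(tf = "TF1", motif_id = "m1", gene = c("a", "c"))
  regs <- build_regulons(imp, motifs, top_k_per_tf = 2)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$targets, "a")  # b unsupported, c outside top 2
  expect_equal(regs[[1]]$motif, "m1")
  # tie at rank 1 resolves toward the lexicographically smaller gene
  imp2 <- data.frame(tf = "TF1", target = c("zz", "aa"),
                     importance = c(0.5, 0.5))
  motifs2 <- data.frame(tf = "TF1", motif_id = "m1", gene = c("zz", "aa"))
  regs2 <- build_regulons(imp2, motifs2, top_k_per_tf = 1)
  expect_equal(regs2[[1]]$targets, "aa")
  # a TF absent from the motif table yields no regulon
  expect_length(build_regulons(imp, motifs[0, ], top_k_per_tf = 2), 0)
  expect_error(build_regulons(imp[0, ], motifs), "empty")
})

test_that("planted regulons are recovered with high Jaccard overlap", {
  # sparse-regime dataset scored over panel plus background targets;
  # ranking by the cross-target raw importance, pruning depth 20
  jac <- c()
  for (s in 1:2) {
    d <- simulate_expression(sim_config(seed = 700 + s))
    tfs <- sprintf("TF%02d", 1:10)
    imp <- genie3_importance(d$matrix, tfs, seed = s)
    regs <- build_regulons(imp, d$motif_support, top_k_per_tf = 20,
                           rank_by = "importance_raw")
    truth <- d$truth_regulons
    names(truth) <- vapply(truth, `[[`, character(1), "tf")
    jac <- c(jac, vapply(regs, function(r) {
      tt <- truth[[r$tf]]$targets
      length(intersect(r$targets, tt)) / length(union(r$targets, tt))
    }, numeric(1)))
  }
  expect_gte(mean(jac), 0.8)
})

test_that("binarization is calibrated on an exchangeable null", {
  d <- simulate_expression(sim_config(n_cells = 1000, n_genes = 100,
                                      n_tfs = 10, seed = 21))
  m <- d$matrix
  bg <- grep("^BG", colnames(m$counts), value = TRUE)
  reg <- list(targets = sample(bg, 10), tf = "none")
  ranks <- pepregnet:::cell_ranks(m$counts)
  auc <- aucell_score(m, reg, top_fraction = 0.3, ranks = ranks)
  b <- binarize_activity(auc, m, reg, n_null = 200, quantile = 0.95,
                         top_fraction = 0.3, seed = 8, ranks = ranks,
                         universe = bg)
  frac <- mean(b$active)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("binarized activity recovers the cells where the planted TF is on", {
  # clean condition: 4 TFs, one regulator per target, strong effect
  cfg <- sim_config(n_cells = 500, n_genes = 60, n_tfs = 4,
                    fanin_np = 1, fanin_npr = 1, effect_size = 16,
                    seed = 31)
  d <- simulate_expression(cfg)
  m <- d$matrix
  ranks <- pepregnet:::cell_ranks(m$counts)
  universe <- setdiff(colnames(m$counts), sprintf("TF%02d", 1:4))
  f1s <- vapply(d$truth_regulons, function(r) {
    if (length(r$targets) < 3) return(NA_real_)
    auc <- aucell_score(m, r, top_fraction = 0.3, ranks = ranks)
    b <- binarize_activity(auc, m, r, n_null = 100, quantile = 0.99,
                           top_fraction = 0.3, seed = 5, ranks = ranks,
                           universe = universe)
    truth_on <- d$tf_activity[, r$tf] == 1
    tp <- sum(b$active & truth_on)
    if (tp == 0) return(0)
    2 * tp / (sum(b$active) + sum(truth_on))
  }, numeric(1))
  expect_gte(mean(f1s, na.rm = TRUE), 0.8)
})

test_that("binarization is reproducible and validates inputs", {
  m <- toy_matrix(matrix(rpois(100, 2), 20, 5))
  reg <- list(targets = c("g1", "g2"), tf = "g5")
  auc <- aucell_score(m, reg, top_fraction = 0.5)
  b1 <- binarize_activity(auc, m, reg, n_null = 20, top_fraction = 0.5, seed = 3)
  b2 <- binarize_activity(auc, m, reg, n_null = 20, top_fraction = 0.5, seed = 3)
  expect_identical(b1, b2)
  expect_error(binarize_activity(auc, m, reg, n_null = 5), "n_null")
  expect_error(binarize_activity(auc, m, list(targets = letters, tf = "x"),
                                 n_null = 20), "universe|present|size")
})
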