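# Small fixtures and independent oracles shared across test files.

# Hand-buildable expression matrix: counts given as cells x genes.
toy_matrix <- function(counts, tissues = NULL, ages = NULL) {
  n <- nrow(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("c", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  expression_matrix(counts, data.frame(
    cell_id = rownames(counts),
    tissue = if (is.null(tissues)) "head" else tissues,
    annotation = "ann1",
    age_days = if (is.null(ages)) 5 else ages,
    sex = "female"))
}

# A minimal 3-pair panel for arithmetic-level comparisons.
toy_panel <- function() {
  pairs <- data.frame(
    np_symbol = c("npA", "npB", "npC"),
    np_flybase_id = sprintf("FBgn%07d", 1:3),
    npr_symbol = c("nprA", "nprB", "nprC"),
    npr_flybase_id = sprintf("FBgn%07d", 101:103),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, network_pairs = NULL), class = "gene_panel")
}

# Brute-force recovery-curve oracle for the rank-AUC score: walks the
# ranking position by position and accumulates the recovery curve.
oracle_aucell <- function(counts_row, target_idx, top_fraction) {
  G <- length(counts_row)
  T_top <- ceiling(top_fraction * G)
  m <- length(target_idx)
  ord <- order(-counts_row, seq_along(counts_row))
  recovery <- numeric(T_top)
  hits <- 0
  for (i in seq_len(T_top)) {
    if (ord[i] %in% target_idx) hits <- hits + 1
    recovery[i] <- hits
  }
  max_recovery <- pmin(seq_len(T_top), m)
  sum(recovery) / sum(max_recovery)
}

# Truth in-degree vectors of a synthetic dataset, per class.
truth_indegree <- function(ds) {
  te <- ds$truth_edges
  np <- panel_genes(ds$config$panel, "NP", network = TRUE)
  npr <- panel_genes(ds$config$panel, "NPR", network = TRUE)
  list(np = vapply(np, function(g) sum(te$target == g), numeric(1)),
       npr = vapply(npr, function(g) sum(te$target == g), numeric(1)))
}
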