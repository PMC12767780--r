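# Desk-scale regulon machinery: tree-ensemble TF-to-target importance,
# motif pruning into regulons, per-cell rank-AUC activity scoring, and
# null-calibrated activity binarization.

#' Construct a regulon
#'
#' A regulon is one TF together with the target gene set it is inferred to
#' regulate, the motif backing the inference, and a tissue context.
#'
#' @param tf TF gene symbol.
#' @param targets Non-empty character vector of target genes (not
#'   containing `tf`).
#' @param motif Motif identifier.
#' @param context Tissue label, or `"all"`.
#' @return A `regulon` object.
#' @export
new_regulon <- function(tf, targets, motif = NA_character_, context = "all") {
  targets <- unique(as.character(targets))
  if (length(targets) == 0) stop("regulon targets must be non-empty")
  if (tf %in% targets) stop("a regulon must not target its own TF")
  structure(list(tf = tf, targets = targets, motif = motif,
                 context = context), class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat("<regulon> ", x$tf, " (", x$motif, ", ", x$context, "): ",
      length(x$targets), " targets\n", sep = "")
  invisible(x)
}

# Regression-ready expression transform: log1p of counts, optionally
# depth-normalized per cell (scaling to 1e4). Depth normalization is only
# appropriate when library size varies for technical reasons; when depth
# covaries with the biology (as in data where a few regulators dominate
# the library), it leaks signal out of every gene.
normalize_log1p <- function(counts, depth_normalize = FALSE, scale = 1e4) {
  counts <- as.matrix(counts)
  if (!depth_normalize) return(log1p(counts))
  depth <- rowSums(counts)
  depth[depth == 0] <- 1
  log1p(counts * (scale / depth))
}

#' Tree-ensemble TF-to-target importance
#'
#' For each target gene, a random-forest regression of the target's
#' log1p-normalized expression (standardized to unit variance) on the
#' TF expressions assigns every TF an importance: its total impurity
#' reduction across the ensemble. Two scores are reported per (TF,
#' target) pair: `importance_raw`, the impurity reduction on the
#' unit-variance target (comparable across targets and used for edge
#' ranking), and `importance`, the per-target share normalized to sum to
#' 1 over TFs.
#'
#' The ensemble uses `n_trees` trees with the full TF set as the
#' candidate set at every split, and a minimum node size of
#' `min_node_frac` of the cells so that fully-grown trees do not convert
#' residual noise into importance. Deterministic given `seed`.
#'
#' @param m An `expr_matrix`.
#' @param tfs Candidate regulator genes (>= 2, present in the matrix).
#' @param targets Target genes to score (default: all non-TF genes). A
#'   target that is itself a TF is regressed on the remaining TFs.
#' @param n_trees Trees per target ensemble (default 200).
#' @param min_node_frac Minimum terminal-node size as a fraction of cells
#'   (default 0.1, floor 5).
#' @param depth_normalize Normalize each cell to a common library size
#'   before the log1p transform? Off by default: it is only appropriate
#'   when library size varies technically, and it removes real signal
#'   when depth covaries with regulator activity.
#' @param seed Integer seed.
#' @return An importance data frame: `tf`, `target`, `importance`,
#'   `importance_raw`, `constant_target` (flag: the target had no
#'   variance, all importances zero).
#' @export
genie3_importance <- function(m, tfs, targets = NULL, n_trees = 200,
                              min_node_frac = 0.1, depth_normalize = FALSE,
                              seed = 1) {
  genes <- colnames(m$counts)
  tfs <- intersect(tfs, genes)
  if (length(tfs) < 2) stop("need at least 2 TFs present in the matrix")
  if (nrow(m$counts) < 20) stop("need at least 20 cells")
  if (is.null(targets)) targets <- setdiff(genes, tfs)
  if (!all(targets %in% genes)) {
    stop("targets absent from matrix: ",
         paste(setdiff(targets, genes), collapse = ", "))
  }
  expr <- normalize_log1p(m$counts, depth_normalize = depth_normalize)
  min_node <- max(5L, ceiling(min_node_frac * nrow(expr)))
  out <- lapply(seq_along(targets), function(ti) {
    tg <- targets[ti]
    preds <- setdiff(tfs, tg)
    y <- expr[, tg]
    if (stats::sd(y) == 0) {
      return(data.frame(tf = preds, target = tg, importance = 0,
                        importance_raw = 0, constant_target = TRUE,
                        stringsAsFactors = FALSE))
    }
    y <- (y - mean(y)) / stats::sd(y)
    fit <- ranger::ranger(
      y = y, x = as.data.frame(expr[, preds, drop = FALSE]),
      num.trees = n_trees, mtry = length(preds),
      min.node.size = min_node, importance = "impurity",
      seed = as.integer(seed) + ti, num.threads = 1,
      verbose = FALSE)
    raw <- pmax(fit$variable.importance, 0)
    tot <- sum(raw)
    data.frame(tf = preds, target = tg,
               importance = if (tot > 0) unname(raw / tot) else 0,
               importance_raw = unname(raw),
               constant_target = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Edge-recovery AUROC against a truth set
#'
#' Area under the ROC curve of the cross-target importance ranking
#' (`importance_raw`) against a set of true regulatory edges.
#'
#' @param imp Importance table from [genie3_importance()].
#' @param truth_edges Data frame with columns `tf`, `target`.
#' @return AUROC in `[0, 1]`.
#' @export
edge_auroc <- function(imp, truth_edges) {
  lab <- paste(imp$tf, imp$target) %in% paste(truth_edges$tf, truth_edges$target)
  if (!any(lab) || all(lab)) stop("truth must contain both edges and non-edges")
  score <- if ("importance_raw" %in% names(imp)) imp$importance_raw else imp$importance
  as.numeric(pROC::auc(pROC::roc(response = lab, predictor = score,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Prune an importance table into motif-supported regulons
#'
#' For each TF, keeps its `top_k_per_tf` targets by importance (ties
#' broken toward the lexicographically smaller gene), then drops targets
#' lacking motif support for that TF. TFs absent from the motif table, or
#' left with no supported target, yield no regulon. The regulon's motif is
#' the TF's motif supporting the most retained targets (lexicographic
#' tie-break).
#'
#' @param imp Importance table (`tf`, `target`, `importance`, optionally
#'   `importance_raw`).
#' @param motifs Motif-support data frame: `tf`, `motif_id`, `gene`.
#' @param top_k_per_tf Targets kept per TF before motif pruning
#'   (default 50).
#' @param rank_by Importance column used for the per-TF ranking
#'   (default `"importance"`).
#' @param context Context label stored on the regulons.
#' @return List of `regulon` objects, ordered by TF.
#' @export
build_regulons <- function(imp, motifs, top_k_per_tf = 50,
                           rank_by = c("importance", "importance_raw"),
                           context = "all") {
  rank_by <- match.arg(rank_by)
  if (nrow(imp) == 0) stop("importance table is empty")
  if (!rank_by %in% names(imp)) stop("missing column: ", rank_by)
  regs <- lapply(sort(unique(imp$tf)), function(tf) {
    rows <- imp[imp$tf == tf, , drop = FALSE]
    rows <- rows[order(-rows[[rank_by]], rows$target), , drop = FALSE]
    kept <- utils::head(rows$target, top_k_per_tf)
    sup <- motifs[motifs$tf == tf, , drop = FALSE]
    kept <- kept[kept %in% sup$gene]
    if (length(kept) == 0) return(NULL)
    sup <- sup[sup$gene %in% kept, , drop = FALSE]
    motif_votes <- sort(table(sup$motif_id), decreasing = TRUE)
    motif <- names(motif_votes)[order(-motif_votes, names(motif_votes))][1]
    new_regulon(tf = tf, targets = kept, motif = motif, context = context)
  })
  Filter(Negate(is.null), regs)
}

# Per-cell gene ranks by decreasing count; ties broken by stable gene
# order (the column order of the matrix).
cell_ranks <- function(counts) {
  counts <- as.matrix(counts)
  t(apply(counts, 1, function(v) {
    o <- order(-v, seq_along(v))
    r <- integer(length(v)); r[o] <- seq_along(v); r
  }))
}

#' Rank-AUC activity of a gene set per cell
#'
#' AUCell-style score: per cell, genes are ranked by decreasing count
#' (ties broken by stable gene order); the score is the area under the
#' target-set recovery curve within the top `top_fraction` of the
#' ranking, normalized by the maximal achievable area, giving a value in
#' `[0, 1]`.
#'
#' With `T = ceiling(top_fraction * n_genes)` and `m` targets present in
#' the matrix, the recovery curve is `y(i)` = number of targets ranked at
#' or above `i`, and the score is
#' `sum(y(1..T)) / sum(pmin(1..T, m))`.
#'
#' @param m An `expr_matrix`.
#' @param regulon A `regulon` (or any list with a `targets` element).
#' @param top_fraction Fraction of the ranking scored (in `(0, 1]`,
#'   default 0.05).
#' @param ranks Optional precomputed [cell x gene] rank matrix (from
#'   `cell_ranks`), to amortize ranking across many regulons.
#' @return Named numeric vector of per-cell scores.
#' @export
aucell_score <- function(m, regulon, top_fraction = 0.05, ranks = NULL) {
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]")
  }
  genes <- colnames(m$counts)
  targets <- intersect(regulon$targets, genes)
  n_t <- length(targets)
  if (n_t == 0) stop("no regulon target is present in the matrix")
  if (is.null(ranks)) ranks <- cell_ranks(m$counts)
  G <- length(genes)
  T_top <- ceiling(top_fraction * G)
  denom <- sum(pmin(seq_len(T_top), n_t))
  r <- ranks[, match(targets, genes), drop = FALSE]
  # sum over i<=T of y(i) equals sum over targets of (T - rank + 1)+
  contrib <- pmax(T_top - r + 1, 0)
  scores <- rowSums(contrib) / denom
  stats::setNames(as.numeric(scores), rownames(m$counts))
}

#' Binarize regulon activity against a size-matched random-set null
#'
#' Scores `n_null` random gene sets of the same size as the regulon on
#' the same cells, takes the `quantile` of the pooled null scores as the
#' activity threshold, and calls a cell active when its regulon score
#' exceeds it.
#'
#' @param auc Per-cell scores from [aucell_score()] for the regulon.
#' @param m The `expr_matrix` the scores were computed on.
#' @param regulon The scored `regulon` (its size fixes the null sets).
#' @param n_null Number of random gene sets (>= 20, default 200).
#' @param quantile Null quantile used as threshold (default 0.99).
#' @param top_fraction Must match the fraction used for `auc`.
#' @param seed Integer seed.
#' @param ranks Optional precomputed rank matrix.
#' @param universe Genes the null sets are sampled from. The default (all
#'   genes except the regulon's TF) is only well calibrated when the
#'   regulon's targets are statistically exchangeable with the rest of
#'   the matrix; when the matrix mixes broadly expressed regulators with
#'   sparse targets, pass the target universe explicitly.
#' @return List with `active` (named logical per cell), `threshold`, and
#'   `null_quantile`.
#' @export
binarize_activity <- function(auc, m, regulon, n_null = 200, quantile = 0.99,
                              top_fraction = 0.05, seed = 1, ranks = NULL,
                              universe = NULL) {
  if (n_null < 20) stop("n_null must be >= 20")
  genes <- colnames(m$counts)
  if (is.null(universe)) universe <- setdiff(genes, regulon$tf)
  if (!all(universe %in% genes)) stop("universe genes absent from the matrix")
  size <- length(intersect(regulon$targets, genes))
  if (size == 0 || size > length(universe)) {
    stop("regulon size must be between 1 and the size of the universe")
  }
  if (is.null(ranks)) ranks <- cell_ranks(m$counts)
  null_scores <- local_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      rnd <- list(targets = sample(universe, size))
      aucell_score(m, rnd, top_fraction = top_fraction, ranks = ranks)
    }, numeric(nrow(m$counts)))
  })
  thr <- stats::quantile(null_scores, quantile, names = FALSE)
  list(active = auc > thr, threshold = thr, null_quantile = quantile)
}
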