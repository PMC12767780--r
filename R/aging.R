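# Age- and cell-type-stratified comparison of TF-gene pair importance,
# and regulon activity profiles across ages.

classify_pairs <- function(imp, panel) {
  np <- unique(c(panel_genes(panel, "NP"),
                 if (!is.null(panel$network_pairs)) panel_genes(panel, "NP", network = TRUE)))
  npr <- unique(c(panel_genes(panel, "NPR"),
                  if (!is.null(panel$network_pairs)) panel_genes(panel, "NPR", network = TRUE)))
  cls <- rep(NA_character_, nrow(imp))
  cls[imp$target %in% np] <- "NP"
  cls[imp$target %in% npr] <- "NPR"
  cls
}

topk_class <- function(rows, k) {
  rows <- rows[order(-rows$importance, rows$tf, rows$target), , drop = FALSE]
  utils::head(rows, k)
}

#' Compare top-k TF--NP vs TF--NPR pair importance per age
#'
#' Per age (and optional cell-type stratum), ranks each class's TF--gene
#' pairs by importance (ties broken lexicographically on TF then target),
#' takes the top `k` per class, and compares the two k-vectors with the
#' normality-gated test. A class with fewer than `k` pairs contributes
#' all it has, with a warning.
#'
#' @param imp Importance data frame with columns `tf`, `target`,
#'   `importance`, `age_days`, optionally `cell_type`.
#' @param panel A `gene_panel` used to class targets as NP or NPR.
#' @param k Pairs per class (>= 2, default 50).
#' @param cell_type Optional stratum; `NULL` uses all records.
#' @return Data frame per age: `age_days`, `cell_type`, `k_np`, `k_npr`,
#'   `mean_np`, `mean_npr`, `dbm`, `method`, `p`, `label`.
#' @export
topk_importance_compare <- function(imp, panel, k = 50, cell_type = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (!"age_days" %in% names(imp)) stop("importance table must have age labels")
  if (!is.null(cell_type)) imp <- imp[imp$cell_type %in% cell_type, , drop = FALSE]
  imp$.class <- classify_pairs(imp, panel)
  imp <- imp[!is.na(imp$.class), , drop = FALSE]
  ages <- sort(unique(imp$age_days))
  rows <- lapply(ages, function(a) {
    sub <- imp[imp$age_days == a, , drop = FALSE]
    np <- topk_class(sub[sub$.class == "NP", ], k)
    npr <- topk_class(sub[sub$.class == "NPR", ], k)
    if (nrow(np) < k || nrow(npr) < k) {
      warning("age ", a, ": fewer than k = ", k,
              " pairs in a class; using all available")
    }
    test <- route_and_test(np$importance, npr$importance)
    data.frame(age_days = a,
               cell_type = if (is.null(cell_type)) "all" else cell_type,
               k_np = nrow(np), k_npr = nrow(npr),
               mean_np = mean(np$importance), mean_npr = mean(npr$importance),
               dbm = mean(npr$importance) - mean(np$importance),
               method = test$method, p = test$p, label = test$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Class membership of the pooled top-k pairs
#'
#' Ranks TF--NP and TF--NPR pairs together in a single importance order
#' (lexicographic tie-break) and reports how many of the pooled top `k`
#' belong to each class, with the class mean importances within the top
#' `k`.
#'
#' @inheritParams topk_importance_compare
#' @param k Pooled ranking depth (default 100).
#' @return Data frame per age: `age_days`, `n_np`, `n_npr`, `mean_np`,
#'   `mean_npr` (class means within the pooled top k; `NA` for an absent
#'   class).
#' @export
pooled_topk <- function(imp, panel, k = 100, cell_type = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (!"age_days" %in% names(imp)) stop("importance table must have age labels")
  if (!is.null(cell_type)) imp <- imp[imp$cell_type %in% cell_type, , drop = FALSE]
  imp$.class <- classify_pairs(imp, panel)
  imp <- imp[!is.na(imp$.class), , drop = FALSE]
  ages <- sort(unique(imp$age_days))
  rows <- lapply(ages, function(a) {
    sub <- imp[imp$age_days == a, , drop = FALSE]
    if (nrow(sub) < k) {
      warning("age ", a, ": fewer than k = ", k, " pooled pairs; using all")
    }
    top <- topk_class(sub, k)
    m <- function(cls) if (any(top$.class == cls))
      mean(top$importance[top$.class == cls]) else NA_real_
    data.frame(age_days = a,
               n_np = sum(top$.class == "NP"),
               n_npr = sum(top$.class == "NPR"),
               mean_np = m("NP"), mean_npr = m("NPR"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean regulon activity per age
#'
#' Builds the regulons x ages matrix of mean per-cell activity scores,
#' the data behind a regulon age-profile heatmap.
#'
#' @param auc Cells x regulons matrix (or data frame) of activity scores,
#'   cells in rows (named).
#' @param cell_ages Named numeric vector of ages per cell, covering the
#'   matrix rows.
#' @param ages Ages to report; every one must be present among the cells.
#' @return Regulons x ages numeric matrix, row order as in `auc`.
#' @export
regulon_age_profile <- function(auc, cell_ages, ages = sort(unique(cell_ages))) {
  auc <- as.matrix(auc)
  if (is.null(rownames(auc))) stop("activity matrix must have cell names")
  cell_ages <- cell_ages[rownames(auc)]
  missing <- setdiff(ages, unique(cell_ages))
  if (length(missing) > 0) {
    stop("no cells at age(s): ", paste(missing, collapse = ", "))
  }
  out <- vapply(ages, function(a) {
    colMeans(auc[which(cell_ages == a), , drop = FALSE])
  }, numeric(ncol(auc)))
  out <- matrix(out, nrow = ncol(auc),
                dimnames = list(colnames(auc), as.character(ages)))
  out
}
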