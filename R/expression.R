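# Pooled per-group expression level (TPM) and expressing-cell counts
# (TCC), and their correlation.

#' Per-group TPM and expressing-cell counts
#'
#' Pools cells by tissue or annotation label and computes, per group and
#' gene, the pooled pseudobulk expression on the transcripts-per-million
#' scale (UMI data, so no gene-length normalization: TPM of a gene is its
#' pooled count x 1e6 / the group's total pooled count over all genes) and
#' the total cell count (TCC): the number of cells in the group expressing
#' the gene at `min_count` UMIs or more.
#'
#' @param m An `expr_matrix`.
#' @param group_by `"tissue"` or `"annotation"`.
#' @param min_count Detection threshold in UMIs for a cell to count as
#'   expressing (default 1).
#' @return Data frame with columns `group`, `gene`, `tpm`, `tcc`,
#'   `n_cells`. Per group, `sum(tpm)` is 1e6.
#' @export
tissue_expression <- function(m, group_by = c("tissue", "annotation"),
                              min_count = 1) {
  group_by <- match.arg(group_by)
  labels <- m$cell_meta[[group_by]]
  groups <- unique(labels)
  empty <- groups[is.na(groups) | !nzchar(as.character(groups))]
  if (length(empty) > 0 || anyNA(labels)) {
    stop("empty or missing ", group_by, " label for some cells")
  }
  out <- lapply(groups, function(g) {
    rows <- which(labels == g)
    if (length(rows) == 0) stop("empty group: ", g)
    sub <- m$counts[rows, , drop = FALSE]
    pooled <- Matrix::colSums(sub)
    total <- sum(pooled)
    if (total == 0) stop("group ", g, " has zero total counts")
    data.frame(group = g, gene = colnames(m$counts),
               tpm = as.numeric(pooled) * 1e6 / total,
               tcc = as.numeric(Matrix::colSums(sub >= min_count)),
               n_cells = length(rows),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Pearson correlation between TPM and TCC
#'
#' Product-moment correlation of the (tpm, tcc) points of a
#' [tissue_expression()] table, optionally restricted to a gene subset
#' and/or one group.
#'
#' @param te Output of [tissue_expression()].
#' @param genes Optional gene subset.
#' @param group Optional single group label.
#' @return List with `r` (Pearson R), `n` (number of points).
#' @export
correlate_tpm_tcc <- function(te, genes = NULL, group = NULL) {
  if (!is.null(genes)) te <- te[te$gene %in% genes, , drop = FALSE]
  if (!is.null(group)) te <- te[te$group %in% group, , drop = FALSE]
  if (nrow(te) < 3) stop("need at least 3 (tpm, tcc) points")
  if (stats::sd(te$tpm) == 0 || stats::sd(te$tcc) == 0) {
    stop("undefined correlation: zero variance in tpm or tcc")
  }
  list(r = stats::cor(te$tpm, te$tcc, method = "pearson"), n = nrow(te))
}
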