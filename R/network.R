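# TF-NP / TF-NPR network construction with exclusive-cell selection,
# shared-TF removal, cascade counting, and per-tissue class comparison.

#' Select cells expressing exclusively one gene class
#'
#' Splits cells into NP-exclusive (at least one NP gene at `min_count` or
#' more UMIs and every NPR gene below it) and NPR-exclusive cells
#' (symmetric). Cells co-expressing both classes are excluded from both
#' sets, maximizing the distinction between the two regulatory contexts;
#' the two sets are disjoint by construction.
#'
#' @param m An `expr_matrix`.
#' @param np_genes,npr_genes Panel gene symbols (non-empty; genes absent
#'   from the matrix are ignored).
#' @param min_count Detection threshold in UMIs (default 1).
#' @return List with `np_cells` and `npr_cells` (character vectors of
#'   cell ids).
#' @export
select_exclusive_cells <- function(m, np_genes, npr_genes, min_count = 1) {
  if (length(np_genes) == 0 || length(npr_genes) == 0) {
    stop("both gene panels must be non-empty")
  }
  genes <- colnames(m$counts)
  np_genes <- intersect(np_genes, genes)
  npr_genes <- intersect(npr_genes, genes)
  has_np <- Matrix::rowSums(m$counts[, np_genes, drop = FALSE] >= min_count) > 0
  has_npr <- Matrix::rowSums(m$counts[, npr_genes, drop = FALSE] >= min_count) > 0
  cells <- rownames(m$counts)
  list(np_cells = cells[has_np & !has_npr],
       npr_cells = cells[has_npr & !has_np])
}

#' Build a TF--gene network for one gene class
#'
#' An edge (TF, gene) is included when the gene belongs to the TF's
#' regulon and to the class panel, and the TF's regulon is active
#' (per binarized activity) in at least `min_active_cells` of the given
#' cells.
#'
#' @param regulons List of `regulon` objects.
#' @param activity Named list per regulon TF, each with an `active`
#'   named-logical vector over cells (as from [binarize_activity()]).
#' @param cells Cell ids defining the context (e.g. the exclusive cells
#'   of the class, within one tissue).
#' @param class_genes Panel genes of the class.
#' @param class `"NP"` or `"NPR"`.
#' @param group Group label (tissue/annotation or `"all"`).
#' @param min_active_cells Minimum active cells for a regulon to
#'   contribute edges (default 1).
#' @return A `tf_network` list: `class`, `group`, `edges` (data frame
#'   `tf`, `gene`), `tf_set`, `gene_set`.
#' @export
build_class_network <- function(regulons, activity, cells, class_genes,
                                class = "NP", group = "all",
                                min_active_cells = 1) {
  edges <- list()
  for (r in regulons) {
    act <- activity[[r$tf]]
    if (is.null(act)) next
    if (!all(cells %in% names(act$active))) {
      stop("cells absent from the activity matrix")
    }
    if (sum(act$active[cells]) < min_active_cells) next
    tg <- intersect(r$targets, class_genes)
    if (length(tg) > 0) {
      edges[[length(edges) + 1]] <- data.frame(tf = r$tf, gene = tg,
                                               stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(tf = character(), gene = character(), stringsAsFactors = FALSE)
  structure(list(class = class, group = group, edges = edges,
                 tf_set = unique(edges$tf), gene_set = unique(edges$gene)),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  s <- network_stats(x)
  cat("<tf_network> ", x$class, " @ ", x$group, ": ", s$n_tfs, " TFs, ",
      s$n_nodes, " nodes, ", s$n_edges, " edges\n", sep = "")
  invisible(x)
}

#' Complexity metrics of a TF--gene network
#'
#' @param net A `tf_network`.
#' @param regulons Optional regulon list; when given, `n_cascade_tfs`
#'   counts the network's TFs that are themselves targets of another
#'   network TF's regulon (the TF-TF cascade vertices).
#' @return List `n_tfs`, `n_nodes`, `n_edges`, `n_cascade_tfs` (`NA`
#'   without regulons).
#' @export
network_stats <- function(net, regulons = NULL) {
  n_casc <- NA_integer_
  if (!is.null(regulons)) {
    casc <- cascade_counts(regulons, net$tf_set)
    n_casc <- length(unique(casc$target_tf))
  }
  list(n_tfs = length(net$tf_set),
       n_nodes = length(net$tf_set) + length(net$gene_set),
       n_edges = nrow(net$edges),
       n_cascade_tfs = n_casc)
}

#' Remove TFs shared between two networks
#'
#' Drops every TF present in both networks' TF sets from both, along with
#' its edges; the operation is idempotent.
#'
#' @param a,b `tf_network` objects with the same group label.
#' @return List `a`, `b` (pruned networks), `shared` (removed TFs).
#' @export
remove_shared_tfs <- function(a, b) {
  if (!identical(a$group, b$group)) stop("networks must share a group label")
  shared <- intersect(a$tf_set, b$tf_set)
  prune <- function(net) {
    keep <- !net$edges$tf %in% shared
    net$edges <- net$edges[keep, , drop = FALSE]
    net$tf_set <- setdiff(net$tf_set, shared)
    net$gene_set <- unique(net$edges$gene)
    net
  }
  list(a = prune(a), b = prune(b), shared = shared)
}

#' Count cascade TFs per motif or tissue
#'
#' A TF is a cascade TF when it is itself a target of another TF's
#' regulon. Each (regulon, target TF) incidence with the regulon's TF in
#' `tf_set` is recorded and counted under the regulon's motif or context.
#'
#' @param regulons List of `regulon` objects.
#' @param tf_set TFs considered as potential upstream regulators.
#' @param group_by `"motif"` or `"tissue"` (the regulon's context).
#' @return List with `incidences` (data frame `upstream_tf`,
#'   `target_tf`, `group`) and `counts` (distinct cascade TFs per group).
#' @export
cascade_counts <- function(regulons, tf_set, group_by = c("motif", "tissue")) {
  group_by <- match.arg(group_by)
  all_tfs <- unique(c(tf_set, vapply(regulons, `[[`, character(1), "tf")))
  inc <- list()
  for (r in regulons) {
    if (!r$tf %in% tf_set) next
    hits <- setdiff(intersect(r$targets, all_tfs), r$tf)
    if (length(hits) > 0) {
      inc[[length(inc) + 1]] <- data.frame(
        upstream_tf = r$tf, target_tf = hits,
        group = if (group_by == "motif") r$motif else r$context,
        stringsAsFactors = FALSE)
    }
  }
  inc <- if (length(inc) > 0) do.call(rbind, inc) else
    data.frame(upstream_tf = character(), target_tf = character(),
               group = character(), stringsAsFactors = FALSE)
  counts <- if (nrow(inc) > 0) {
    tapply(inc$target_tf, inc$group, function(t) length(unique(t)))
  } else integer()
  list(incidences = inc, counts = c(counts))
}

#' Per-gene TF in-degree of a network
#'
#' The comparison unit for class complexity: for every class gene in the
#' network's panel, the number of distinct TFs with an edge to it (0 for
#' panel genes without edges).
#'
#' @param net A `tf_network`.
#' @param class_genes The class's full panel (genes without edges count 0).
#' @return Named integer vector over `class_genes`.
#' @export
tf_indegree <- function(net, class_genes) {
  deg <- table(factor(net$edges$gene, levels = class_genes))
  stats::setNames(as.integer(deg), class_genes)
}

#' Compare NP vs NPR network complexity across groups
#'
#' Per group (tissue or annotation), compares the per-gene TF in-degree
#' vectors of the NP and NPR networks with the normality-gated test and
#' estimation statistics. Groups where either class has fewer than 2
#' observations are skipped with a warning.
#'
#' @param networks Data-free interface: a list of lists, each with
#'   elements `group`, `np` (named in-degree vector) and `npr`.
#' @param n_boot,seed Passed to [estimation_stats()].
#' @return Data frame per group: `group`, `n_np`, `n_npr`, `mean_np`,
#'   `mean_npr`, `dbm`, `method`, `p`, `label`, `ci_low`, `ci_high`.
#' @export
compare_tissue_networks <- function(networks, n_boot = 2000, seed = 1) {
  rows <- lapply(networks, function(x) {
    if (length(x$np) < 2 || length(x$npr) < 2) {
      warning("group ", x$group, " skipped: fewer than 2 genes in a class")
      return(NULL)
    }
    if (length(x$np) < 3 || length(x$npr) < 3) {
      warning("group ", x$group, " skipped: test needs n >= 3 per class")
      return(NULL)
    }
    test <- route_and_test(x$np, x$npr)
    est <- estimation_stats(x$np, x$npr, n_boot = n_boot, seed = seed)
    data.frame(group = x$group, n_np = length(x$np), n_npr = length(x$npr),
               mean_np = mean(x$np), mean_npr = mean(x$npr),
               dbm = est$dbm, method = test$method, p = test$p,
               label = test$label, ci_low = est$ci_low,
               ci_high = est$ci_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
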