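# Per-gene regulatory-feature summaries (TFBS hotspot areas, CRMs, ChIP
# peaks) and NP-vs-NPR class comparisons in paired and unpaired modes.

feature_kinds <- c("TFBS_HSA", "CRM", "PEAK")

validate_annotation <- function(ann) {
  need <- c("gene", "kind", "start", "end")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(ann$kind %in% feature_kinds)) {
    stop("unknown feature kind: ",
         paste(setdiff(unique(ann$kind), feature_kinds), collapse = ", "))
  }
  if (any(ann$end <= ann$start)) stop("intervals must satisfy end > start")
  if (any(ann$start < 0)) stop("interval starts must be non-negative")
  ann
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  keep_s <- start[1]; keep_e <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= keep_e) keep_e <- max(keep_e, end[i])
    else { out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
           keep_s <- start[i]; keep_e <- end[i] }
  }
  data.frame(start = c(out_s, keep_s), end = c(out_e, keep_e))
}

#' Summarize regulatory features per gene
#'
#' For every (gene, kind) combination, counts the annotated intervals and
#' sums their lengths in kilobase pairs. Genes in `genes` that carry no
#' feature of a kind get count 0, total 0 and a missing mean. Overlapping
#' intervals are, by default, summed as listed (each annotated element
#' contributes its own length); set `merge_overlaps = TRUE` to collapse
#' overlaps before measuring.
#'
#' @param ann Annotation data frame (`gene`, `kind`, `start`, `end`),
#'   0-based half-open coordinates in bp.
#' @param genes Gene universe to report (default: genes present in `ann`).
#' @param kinds Feature kinds to report (default: kinds present in `ann`).
#' @param merge_overlaps Merge overlapping intervals per gene before
#'   counting/measuring?
#' @return Data frame with columns `gene`, `kind`, `count`, `total_kb`,
#'   `mean_kb` (`NA` when count is 0).
#' @export
#' @examples
#' ann <- data.frame(gene = "g", kind = "CRM",
#'                   start = c(100, 2000), end = c(1100, 2500))
#' summarize_features(ann)  # count 2, total 1.5 kb, mean 0.75 kb
summarize_features <- function(ann, genes = NULL, kinds = NULL,
                               merge_overlaps = FALSE) {
  ann <- validate_annotation(ann)
  if (is.null(genes)) genes <- unique(ann$gene)
  if (is.null(kinds)) kinds <- intersect(feature_kinds, unique(ann$kind))
  out <- expand.grid(gene = genes, kind = kinds, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    sel <- ann[ann$gene == out$gene[i] & ann$kind == out$kind[i], , drop = FALSE]
    if (merge_overlaps && nrow(sel) > 1) {
      sel <- merge_intervals(sel$start, sel$end)
    }
    n <- nrow(sel)
    total <- if (n > 0) sum(sel$end - sel$start) / 1000 else 0
    c(count = n, total_kb = total,
      mean_kb = if (n > 0) total / n else NA_real_)
  })
  cbind(out, do.call(rbind, res))
}

feature_value <- function(summary, gene, kind, feature, strict = FALSE) {
  row <- summary[summary$gene == gene & summary$kind == kind, , drop = FALSE]
  if (nrow(row) == 0) {
    if (strict) return(NULL)
    # absent gene: zero features of this kind
    return(switch(feature, count = 0, total_kb = 0, mean_kb = NA_real_))
  }
  row[[feature]][1]
}

#' Compare a regulatory feature between NP and NPR gene classes
#'
#' Extracts one feature (`count`, `total_kb` or `mean_kb`) of one kind for
#' the NP and NPR genes of a panel and compares the classes. In paired
#' mode the unit is one published NP--NPR pairing row, so genes appearing
#' in several rows contribute once per row (set `collapse = TRUE` to use
#' unique genes instead, dropping the pairing); in unpaired mode the unit
#' is the unique gene. Genes with a missing mean (no features) are dropped
#' from `mean_kb` comparisons and kept as 0 for `count`/`total_kb`.
#'
#' @param summary Output of [summarize_features()].
#' @param panel A `gene_panel`.
#' @param kind Feature kind (`"TFBS_HSA"`, `"CRM"`, `"PEAK"`).
#' @param feature `"count"`, `"total_kb"` or `"mean_kb"`.
#' @param mode `"paired"` or `"unpaired"`.
#' @param collapse In paired mode, collapse repeated genes to one entry
#'   (turning the comparison unpaired in structure but keeping unique
#'   genes matched by first pairing).
#' @param n_boot,seed Passed to [estimation_stats()].
#' @return A `class_comparison` list: `np`, `npr` (the two value vectors),
#'   `dbm` (mean NPR - mean NP), `test` ([route_and_test()] result),
#'   `estimation` ([estimation_stats()] result), plus the call settings.
#' @export
compare_classes <- function(summary, panel, kind, feature = c("count", "total_kb", "mean_kb"),
                            mode = c("unpaired", "paired"), collapse = FALSE,
                            n_boot = 5000, seed = 1) {
  feature <- match.arg(feature)
  mode <- match.arg(mode)
  if (mode == "paired") {
    pairs <- panel$pairs
    if (collapse) pairs <- pairs[!duplicated(pairs$np_symbol) &
                                   !duplicated(pairs$npr_symbol), ]
    grab <- function(sym, i) {
      v <- feature_value(summary, sym, kind, feature, strict = TRUE)
      if (is.null(v)) {
        stop("paired mode: row ", i, " (", sym,
             ") is missing from the summary")
      }
      v
    }
    np <- vapply(seq_len(nrow(pairs)), function(i)
      grab(pairs$np_symbol[i], i), numeric(1))
    npr <- vapply(seq_len(nrow(pairs)), function(i)
      grab(pairs$npr_symbol[i], i), numeric(1))
    if (feature == "mean_kb") {
      keep <- !is.na(np) & !is.na(npr)
      np <- np[keep]; npr <- npr[keep]
    }
  } else {
    np <- vapply(panel_genes(panel, "NP"), function(g)
      feature_value(summary, g, kind, feature), numeric(1))
    npr <- vapply(panel_genes(panel, "NPR"), function(g)
      feature_value(summary, g, kind, feature), numeric(1))
    if (feature == "mean_kb") {
      np <- np[!is.na(np)]; npr <- npr[!is.na(npr)]
    }
  }
  test <- route_and_test(np, npr, paired = (mode == "paired"))
  est <- estimation_stats(np, npr, paired = (mode == "paired"),
                          n_boot = n_boot, seed = seed)
  structure(list(np = unname(np), npr = unname(npr),
                 dbm = mean(npr) - mean(np),
                 test = test, estimation = est,
                 kind = kind, feature = feature, mode = mode),
            class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat("<class_comparison> ", x$kind, " ", x$feature, " (", x$mode, "): ",
      "NP n=", length(x$np), " mean=", signif(mean(x$np), 4),
      "; NPR n=", length(x$npr), " mean=", signif(mean(x$npr), 4),
      "; DBM=", signif(x$dbm, 4), ", p=", signif(x$test$p, 4),
      " (", x$test$label, ")\n", sep = "")
  invisible(x)
}
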