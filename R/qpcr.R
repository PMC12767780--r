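# 2^-ddCt relative quantification with reference-gene normalization,
# per-replicate fold computation, and condition contrasts.

ct_condition_key <- function(ct) {
  paste(ct$sex, ct$age_days, ct$tissue_part, sep = "|")
}

#' Relative expression by the 2^-ddCt method
#'
#' Within each (sex, age, tissue part) stratum, each replicate's
#' delta-Ct is the target Ct minus the reference-gene Ct of the same
#' replicate; the delta-delta-Ct subtracts the stratum's mean control
#' (25 degree) delta-Ct, and the replicate fold is `2^-ddCt`. Amplification
#' efficiency is taken as exactly 2 and folds are summarized as mean and
#' SEM over replicates; the control condition is reported the same way
#' (its mean fold is ~1, exactly 1 at zero noise with one replicate
#' pattern). The whole computation is invariant to adding a constant to
#' every Ct value.
#'
#' @param ct Ct data frame (`gene`, `sex`, `age_days`, `temperature_c`,
#'   `tissue_part`, `replicate_id`, `ct`).
#' @param target_gene Gene to quantify.
#' @param reference_gene Internal reference gene (default `"GAPDH"`).
#' @param control_temperature Control condition (default 25 degrees).
#' @return Data frame per condition: `gene`, `sex`, `age_days`,
#'   `temperature_c`, `tissue_part`, `fold` (mean of replicate folds),
#'   `sem`, `n_reps`, plus a `fold_reps` list-column of the per-replicate
#'   folds.
#' @export
#' @examples
#' ct <- simulate_ct_table(c("AstA-R1", "GAPDH"), noise_sd = 0, seed = 1)
#' head(relative_expression(ct, "AstA-R1"))
relative_expression <- function(ct, target_gene, reference_gene = "GAPDH",
                                control_temperature = 25) {
  tgt <- ct[ct$gene == target_gene, , drop = FALSE]
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (nrow(tgt) == 0) stop("target gene absent from the Ct table")
  if (nrow(ref) == 0) stop("missing reference gene: ", reference_gene)
  full_key <- function(d) paste(ct_condition_key(d), d$temperature_c,
                                d$replicate_id, sep = "|")
  idx <- match(full_key(tgt), full_key(ref))
  if (anyNA(idx)) {
    stop("unmatched replicate ids between target and reference gene")
  }
  tgt$dct <- tgt$ct - ref$ct[idx]
  strata <- unique(ct_condition_key(tgt))
  out <- lapply(strata, function(s) {
    sub <- tgt[ct_condition_key(tgt) == s, , drop = FALSE]
    ctrl <- sub$dct[sub$temperature_c == control_temperature]
    if (length(ctrl) == 0) {
      stop("no control (", control_temperature, " degree) condition in stratum ", s)
    }
    do.call(rbind, lapply(unique(sub$temperature_c), function(tc) {
      reps <- sub[sub$temperature_c == tc, , drop = FALSE]
      folds <- 2^-(reps$dct - mean(ctrl))
      data.frame(gene = target_gene, sex = reps$sex[1],
                 age_days = reps$age_days[1], temperature_c = tc,
                 tissue_part = reps$tissue_part[1],
                 fold = mean(folds),
                 sem = if (length(folds) > 1)
                   stats::sd(folds) / sqrt(length(folds)) else NA_real_,
                 n_reps = length(folds),
                 fold_reps = I(list(folds)),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Panel-wide temperature contrasts with a class responsiveness summary
#'
#' Quantifies every panel gene found in the Ct table with
#' [relative_expression()], tests each non-control condition's replicate
#' folds against the control condition's replicate folds
#' ([route_and_test()]), and summarizes per class (NP vs NPR) the
#' fraction of conditions with a significant change. Design cells with
#' fewer than 2 replicates are skipped with a warning.
#'
#' @param ct Ct data frame.
#' @param panel A `gene_panel`; targets are the panel genes (full pairing
#'   table plus network panel symbols) present in the table.
#' @param reference_gene,control_temperature As in
#'   [relative_expression()].
#' @param alpha Significance level for the class summary (default 0.05).
#' @return List with `results` (per gene x condition: fold, sem, p,
#'   label, class) and `class_summary` (per class: conditions tested,
#'   significant count, fraction).
#' @export
contrast_panel <- function(ct, panel, reference_gene = "GAPDH",
                           control_temperature = 25, alpha = 0.05) {
  pool_np <- unique(c(panel_genes(panel, "NP"),
                      if (!is.null(panel$network_pairs))
                        panel_genes(panel, "NP", network = TRUE)))
  pool_npr <- unique(c(panel_genes(panel, "NPR"),
                       if (!is.null(panel$network_pairs))
                         panel_genes(panel, "NPR", network = TRUE)))
  genes <- intersect(unique(ct$gene), c(pool_np, pool_npr))
  if (length(genes) == 0) stop("no panel gene present in the Ct table")
  rows <- list()
  for (g in genes) {
    rel <- relative_expression(ct, g, reference_gene = reference_gene,
                               control_temperature = control_temperature)
    strata <- unique(ct_condition_key(rel))
    for (s in strata) {
      sub <- rel[ct_condition_key(rel) == s, , drop = FALSE]
      ctrl <- sub[sub$temperature_c == control_temperature, , drop = FALSE]
      for (i in which(sub$temperature_c != control_temperature)) {
        fr <- sub$fold_reps[[i]]
        cr <- ctrl$fold_reps[[1]]
        if (length(fr) < 2 || length(cr) < 2) {
          warning("condition with < 2 replicates skipped: ", g, " ", s)
          next
        }
        p <- if (length(fr) >= 3 && length(cr) >= 3) {
          route_and_test(cr, fr)$p
        } else {
          stats::t.test(cr, fr, var.equal = TRUE)$p.value
        }
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, class = if (g %in% pool_np) "NP" else "NPR",
          sex = sub$sex[i], age_days = sub$age_days[i],
          temperature_c = sub$temperature_c[i],
          tissue_part = sub$tissue_part[i],
          fold = sub$fold[i], sem = sub$sem[i], p = p,
          label = significance_label(p), stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  class_summary <- do.call(rbind, lapply(split(results, results$class), function(d) {
    data.frame(class = d$class[1], n_conditions = nrow(d),
               n_significant = sum(d$p < alpha),
               fraction_significant = mean(d$p < alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(class_summary) <- NULL
  list(results = results, class_summary = class_summary)
}
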