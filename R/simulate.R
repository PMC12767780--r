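# Seeded synthetic-data generators with planted ground truth. These stand
# in for the large public single-cell atlases: they emulate the statistical
# structure the downstream analyses rely on (negative-binomial UMI counts,
# latent TF activity driving target co-expression, class-asymmetric TF
# fan-in, planted motif support, temperature-responsive receptor Ct
# values), so every stage of the pipeline can be verified offline against
# known truth.

#' Simulation configuration
#'
#' Bundles every knob of the expression simulator. The defaults define the
#' reference condition used throughout the package's own validation:
#' 1000 cells, 100 genes, 10 TFs, a four-fold expression lift on targets of
#' active TFs on top of negative-binomial noise, and a receptor-biased
#' regulator fan-in (mean 8 TFs per NPR vs 3 per NP) encoding the
#' hypothesis that receptors sit under broader transcriptional control.
#'
#' @param n_cells,n_genes,n_tfs Matrix dimensions; `n_genes` includes the
#'   TFs and the panel genes.
#' @param panel A `gene_panel`; its network pairs name the NP/NPR genes
#'   planted in the matrix (defaults to the packaged panel).
#' @param fanin_np,fanin_npr Mean number of regulator TFs per NP / NPR gene
#'   (Poisson, truncated below at 1 and above at `n_tfs`).
#' @param tf_active_prob Per-cell probability that a TF is active.
#' @param effect_size Multiplicative lift on a target's NB mean per active
#'   regulator (>= 1; 1 disables the signal).
#' @param baseline_mean NB mean of background and panel-gene expression
#'   (default 0.5: a detectable but noisy co-expression regime). Lower it
#'   (e.g. 0.1) for a sparse regime where panel genes are off in most
#'   cells, as in real atlases -- the regime [run_bias_pipeline()] uses so
#'   that class-exclusive cell populations exist.
#' @param tf_baseline_mean NB mean of TF expression when inactive (TFs are
#'   broadly expressed, so their transcript level can carry the activity
#'   signal co-expression methods rely on).
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param tissues,ages,sexes Label pools sampled uniformly per cell.
#' @param n_decoy_support Background genes per TF given spurious motif
#'   support, so motif pruning is exercised against non-edges.
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells = 1000, n_genes = 100, n_tfs = 10,
                       panel = load_panel("packaged"),
                       fanin_np = 3, fanin_npr = 8,
                       tf_active_prob = 0.2, effect_size = 4,
                       baseline_mean = 0.5, tf_baseline_mean = 5,
                       nb_dispersion = 0.5,
                       tissues = c("head", "body"),
                       ages = c(5, 30, 50, 70),
                       sexes = c("female", "male"),
                       n_decoy_support = 2,
                       seed = 1) {
  cfg <- list(n_cells = n_cells, n_genes = n_genes, n_tfs = n_tfs,
              panel = panel, fanin_np = fanin_np, fanin_npr = fanin_npr,
              tf_active_prob = tf_active_prob, effect_size = effect_size,
              baseline_mean = baseline_mean, tf_baseline_mean = tf_baseline_mean,
              nb_dispersion = nb_dispersion,
              tissues = tissues, ages = ages, sexes = sexes,
              n_decoy_support = n_decoy_support, seed = seed)
  stopifnot(n_cells >= 1, n_genes >= 1, n_tfs >= 1,
            fanin_np >= 0, fanin_npr >= 0, effect_size >= 1,
            tf_active_prob > 0, tf_active_prob < 1,
            baseline_mean > 0, tf_baseline_mean > 0, nb_dispersion >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cells, " cells x ", x$n_genes, " genes (",
      x$n_tfs, " TFs); fan-in NP ", x$fanin_np, " / NPR ", x$fanin_npr,
      "; effect ", x$effect_size, "x; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# NB with mean mu and dispersion phi; phi = 0 degenerates to Poisson.
rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a single-cell expression dataset with planted regulation
#'
#' The generative model: each TF is independently active per cell with
#' probability `tf_active_prob` (a latent Bernoulli). Every NP/NPR panel
#' gene is assigned a random set of regulator TFs (truncated Poisson
#' fan-in, receptor-biased by default). A gene's NB mean is
#' `baseline_mean * effect_size^(number of its active regulators)`; a TF's
#' own transcript is lifted the same way when the TF is active, so that TF
#' expression carries the activity signal co-expression methods need.
#' Background genes are pure NB noise.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_dataset` list: `matrix` (an `expr_matrix`),
#'   `truth_edges` (data frame `tf`, `target`, `class`), `truth_regulons`
#'   (list of `regulon` objects, one per TF with targets), `motif_support`
#'   (data frame `tf`, `motif_id`, `gene`: truth edges plus planted
#'   decoys), `tf_activity` (cells x TFs 0/1 matrix of the latent state),
#'   and `config`.
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  np_genes <- panel_genes(config$panel, "NP", network = TRUE)
  npr_genes <- panel_genes(config$panel, "NPR", network = TRUE)
  if (config$n_tfs >= config$n_genes) {
    stop("invalid config: n_tfs must be smaller than n_genes")
  }
  n_panel <- length(np_genes) + length(npr_genes)
  if (config$n_tfs + n_panel > config$n_genes) {
    stop("invalid config: panel genes (", n_panel, ") plus TFs (",
         config$n_tfs, ") exceed n_genes (", config$n_genes, ")")
  }
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
  n_bg <- config$n_genes - config$n_tfs - n_panel
  bg <- if (n_bg > 0) sprintf("BG%03d", seq_len(n_bg)) else character()
  genes <- c(tfs, np_genes, npr_genes, bg)

  local_seed(config$seed, {
    # planted regulator sets: truncated-Poisson fan-in per panel gene
    draw_regs <- function(gene_set, lambda) {
      lapply(gene_set, function(g) {
        k <- min(max(stats::rpois(1, lambda), 1L), config$n_tfs)
        sample(tfs, k)
      })
    }
    regs <- c(stats::setNames(draw_regs(np_genes, config$fanin_np), np_genes),
              stats::setNames(draw_regs(npr_genes, config$fanin_npr), npr_genes))

    truth_edges <- do.call(rbind, lapply(names(regs), function(g) {
      data.frame(tf = regs[[g]], target = g,
                 class = if (g %in% np_genes) "NP" else "NPR",
                 stringsAsFactors = FALSE)
    }))

    # latent per-cell TF activity and the resulting NB means
    act <- matrix(stats::rbinom(config$n_cells * config$n_tfs, 1,
                                config$tf_active_prob),
                  nrow = config$n_cells, dimnames = list(NULL, tfs))
    log_eff <- log(config$effect_size)
    mu <- matrix(config$baseline_mean, nrow = config$n_cells,
                 ncol = config$n_genes, dimnames = list(NULL, genes))
    for (tf in tfs) mu[, tf] <- config$tf_baseline_mean * exp(act[, tf] * log_eff)
    for (g in names(regs)) {
      n_active <- rowSums(act[, regs[[g]], drop = FALSE])
      mu[, g] <- mu[, g] * exp(n_active * log_eff)
    }
    counts <- matrix(rnb(length(mu), as.vector(mu), config$nb_dispersion),
                     nrow = config$n_cells, dimnames = dimnames(mu))

    cell_ids <- sprintf("cell%05d", seq_len(config$n_cells))
    rownames(counts) <- cell_ids
    rownames(act) <- cell_ids
    cell_meta <- data.frame(
      cell_id = cell_ids,
      tissue = sample(config$tissues, config$n_cells, replace = TRUE),
      annotation = NA_character_,
      age_days = sample(config$ages, config$n_cells, replace = TRUE),
      sex = sample(config$sexes, config$n_cells, replace = TRUE),
      stringsAsFactors = FALSE)
    # annotations refine tissues: two per tissue
    cell_meta$annotation <- paste0(cell_meta$tissue, "_ann",
                                   sample(1:2, config$n_cells, replace = TRUE))

    # planted motif support: every truth edge is supported, plus decoy
    # background genes per TF so motif pruning has negatives to reject
    support <- truth_edges[, c("tf", "target")]
    names(support) <- c("tf", "gene")
    if (config$n_decoy_support > 0 && length(bg) > 0) {
      decoys <- do.call(rbind, lapply(tfs, function(tf) {
        data.frame(tf = tf,
                   gene = sample(bg, min(config$n_decoy_support, length(bg))),
                   stringsAsFactors = FALSE)
      }))
      support <- rbind(support, decoys)
    }
    support$motif_id <- paste0("motif_", support$tf)
    motif_support <- support[, c("tf", "motif_id", "gene")]

    truth_regulons <- lapply(tfs, function(tf) {
      tg <- truth_edges$target[truth_edges$tf == tf]
      if (length(tg) == 0) return(NULL)
      new_regulon(tf = tf, targets = sort(tg), motif = paste0("motif_", tf),
                  context = "all")
    })
    truth_regulons <- Filter(Negate(is.null), truth_regulons)

    structure(list(matrix = expression_matrix(counts, cell_meta),
                   truth_edges = truth_edges,
                   truth_regulons = truth_regulons,
                   motif_support = motif_support,
                   tf_activity = act,
                   config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ")
  print(x$matrix)
  cat("  ", nrow(x$truth_edges), " planted edges from ",
      length(unique(x$truth_edges$tf)), " TFs\n", sep = "")
  invisible(x)
}

#' Simulate a regulatory-feature annotation with planted class bias
#'
#' Per panel gene, the number of regulatory features (TFBS hotspot areas,
#' CRMs or peaks) is Poisson with a class-specific mean, and feature
#' lengths are log-normal with a class-specific mean length. Interval
#' starts are uniform in a 100 kb window; coordinates are 0-based
#' half-open.
#'
#' @param panel A `gene_panel`; unique NP and NPR symbols from the pairing
#'   table are annotated.
#' @param count_mean Named vector `c(NP = , NPR = )` of mean feature
#'   counts per gene (both > 0).
#' @param length_mean_bp Named vector `c(NP = , NPR = )` of mean feature
#'   lengths in bp (both > 0).
#' @param kind Feature kind: `"TFBS_HSA"`, `"CRM"` or `"PEAK"`.
#' @param sdlog Log-normal shape parameter for lengths.
#' @param seed Integer seed.
#' @return Annotation data frame (`gene`, `kind`, `start`, `end`) as
#'   accepted by [summarize_features()].
#' @export
simulate_cisreg_annotation <- function(panel,
                                       count_mean = c(NP = 5, NPR = 12),
                                       length_mean_bp = c(NP = 1000, NPR = 1000),
                                       kind = c("TFBS_HSA", "CRM", "PEAK"),
                                       sdlog = 0.5, seed = 1) {
  kind <- match.arg(kind)
  if (!all(c("NP", "NPR") %in% names(count_mean)) ||
      !all(c("NP", "NPR") %in% names(length_mean_bp))) {
    stop("unknown gene class: count_mean and length_mean_bp need NP and NPR entries")
  }
  stopifnot(all(count_mean > 0), all(length_mean_bp > 0))
  genes <- data.frame(
    gene = c(panel_genes(panel, "NP"), panel_genes(panel, "NPR")),
    class = rep(c("NP", "NPR"),
                c(length(panel_genes(panel, "NP")),
                  length(panel_genes(panel, "NPR")))),
    stringsAsFactors = FALSE)
  local_seed(seed, {
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      cls <- genes$class[i]
      n <- stats::rpois(1, count_mean[[cls]])
      if (n == 0) return(NULL)
      # meanlog chosen so the log-normal mean equals the requested mean
      len <- stats::rlnorm(n, meanlog = log(length_mean_bp[[cls]]) - sdlog^2 / 2,
                           sdlog = sdlog)
      start <- sample.int(100000L, n, replace = TRUE) - 1L
      data.frame(gene = genes$gene[i], kind = kind, start = start,
                 end = start + pmax(1L, as.integer(ceiling(len))),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, Filter(Negate(is.null), rows))
    validate_annotation(ann)
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Builds threshold-cycle replicates over a full condition design
#' (temperature x age x sex x tissue part) such that the true
#' `2^-ddCt` fold of each gene, relative to the 25 degree control in the
#' same (sex, age, tissue part) stratum and normalized to the reference
#' gene, equals the planted fold exactly at zero noise. The reference
#' gene's fold is 1 everywhere by construction.
#'
#' @param genes Character vector of target genes; must include
#'   `reference_gene`.
#' @param log2_fold `NULL` (all folds 1) or a data frame with column
#'   `log2_fold` plus any subset of the design keys (`gene`,
#'   `temperature_c`, `age_days`, `sex`, `tissue_part`); rows matched on
#'   the keys present, everything else defaults to 0. Folds at 25 degrees
#'   are control-anchored and must be absent or 0.
#' @param temperatures,ages,sexes,tissue_parts The condition design
#'   (defaults: 25/29/37 degrees, days 1/3/5, both sexes, head and body).
#' @param reference_gene Internal reference gene (default `"GAPDH"`).
#' @param noise_sd SD of Gaussian measurement noise added to every Ct.
#' @param n_reps Replicates per condition (>= 2).
#' @param seed Integer seed.
#' @return A Ct data frame as accepted by [relative_expression()].
#' @export
simulate_ct_table <- function(genes, log2_fold = NULL,
                              temperatures = c(25, 29, 37),
                              ages = c(1, 3, 5),
                              sexes = c("female", "male"),
                              tissue_parts = c("head", "body"),
                              reference_gene = "GAPDH",
                              noise_sd = 0.2, n_reps = 3, seed = 1) {
  stopifnot(n_reps >= 2, noise_sd >= 0)
  if (!reference_gene %in% genes) {
    stop("missing reference gene in design: add '", reference_gene,
         "' to `genes`")
  }
  if (!25 %in% temperatures) stop("design must include the 25 degree control")
  design <- expand.grid(gene = genes, sex = sexes, age_days = ages,
                        temperature_c = temperatures,
                        tissue_part = tissue_parts,
                        replicate_id = seq_len(n_reps),
                        stringsAsFactors = FALSE)
  design$log2_fold <- 0
  if (!is.null(log2_fold)) {
    keys <- intersect(names(log2_fold),
                      c("gene", "temperature_c", "age_days", "sex", "tissue_part"))
    if (length(keys) == 0 || !"log2_fold" %in% names(log2_fold)) {
      stop("log2_fold needs a log2_fold column and at least one design key")
    }
    if (any(log2_fold$gene %in% reference_gene & log2_fold$log2_fold != 0)) {
      stop("the reference gene cannot have a planted fold")
    }
    if ("temperature_c" %in% keys &&
        any(log2_fold$temperature_c == 25 & log2_fold$log2_fold != 0)) {
      stop("folds at the 25 degree control must be 0")
    }
    key_str <- function(d) do.call(paste, c(d[keys], sep = "\r"))
    idx <- match(key_str(design), key_str(log2_fold))
    design$log2_fold[!is.na(idx)] <- log2_fold$log2_fold[idx[!is.na(idx)]]
  }
  local_seed(seed, {
    # deterministic per-gene baseline Ct; reference amplifies earliest
    base <- 22 + (seq_along(genes) - 1) %% 5
    names(base) <- genes
    base[reference_gene] <- 16
    ct <- base[design$gene] - design$log2_fold +
      stats::rnorm(nrow(design), sd = noise_sd)
    out <- design[, c("gene", "sex", "age_days", "temperature_c",
                      "tissue_part", "replicate_id")]
    out$ct <- as.numeric(ct)
    out
  })
}

#' Simulate an age-stratified TF--gene importance table
#'
#' Per age (and class), TF--target pair importances are drawn from a
#' Gamma(2, rate 40) baseline (mean 0.05), with an additive lift on
#' TF--NPR pairs and an optional additive per-age drift, floored at 0.
#'
#' @param ages Ages in days (non-empty).
#' @param n_pairs_per_class Pairs planted per class per age.
#' @param npr_lift Additive importance lift on TF--NPR pairs (>= 0).
#' @param drift Additive importance change per successive age.
#' @param panel A `gene_panel` supplying the NP/NPR target names.
#' @param n_tfs Number of distinct TFs to draw from.
#' @param cell_type Cell-type label stored on every record.
#' @param seed Integer seed.
#' @return Importance data frame (`tf`, `target`, `class`, `importance`,
#'   `age_days`, `cell_type`), unique on (tf, target, age, cell_type).
#' @export
simulate_importance_series <- function(ages, n_pairs_per_class = 100,
                                       npr_lift = 0, drift = 0,
                                       panel = load_panel("packaged"),
                                       n_tfs = 20, cell_type = "all",
                                       seed = 1) {
  if (length(ages) == 0) stop("ages must be non-empty")
  stopifnot(npr_lift >= 0, n_pairs_per_class >= 1)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  pools <- list(NP = panel_genes(panel, "NP", network = TRUE),
                NPR = panel_genes(panel, "NPR", network = TRUE))
  local_seed(seed, {
    out <- lapply(seq_along(ages), function(ai) {
      do.call(rbind, lapply(names(pools), function(cls) {
        combos <- expand.grid(tf = tfs, target = pools[[cls]],
                              stringsAsFactors = FALSE)
        k <- min(n_pairs_per_class, nrow(combos))
        pick <- combos[sample.int(nrow(combos), k), ]
        imp <- stats::rgamma(k, shape = 2, rate = 40) +
          (if (cls == "NPR") npr_lift else 0) + drift * (ai - 1)
        data.frame(tf = pick$tf, target = pick$target, class = cls,
                   importance = pmax(imp, 0), age_days = ages[ai],
                   cell_type = cell_type, stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, out)
  })
}
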