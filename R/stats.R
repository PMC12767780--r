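# Two-group statistical toolkit: normality-gated test routing and
# bootstrap estimation statistics.

#' Significance label for a p-value
#'
#' Conventional star labels: `****` p < 0.0001, `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p A p-value.
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}

# One-sample KS normality screen. Default is the Lilliefors-corrected
# test (parameters estimated from the sample, critical values corrected
# accordingly); the naive variant standardizes the sample and compares
# against the standard normal, which is markedly conservative about
# declaring non-normality. Constant samples cannot be standardized and
# are scored as maximally non-normal; the Lilliefors tables need n >= 5,
# below which the naive variant is used.
ks_normal_p <- function(x, variant = c("lilliefors", "naive")) {
  variant <- match.arg(variant)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  if (variant == "lilliefors" && length(x) >= 5) {
    return(suppressWarnings(nortest::lillie.test(x)$p.value))
  }
  z <- (x - mean(x)) / s
  suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
}

#' Normality-gated two-group test
#'
#' Routes a two-group comparison the way the source analyses do: each
#' sample is screened with a Kolmogorov--Smirnov test against the normal
#' distribution (standardized sample vs the standard normal); if both pass
#' at `alpha_ks` a two-sided Student's t-test is used (pooled-variance
#' unpaired, or paired), otherwise a two-sided Mann--Whitney U test.
#' A paired request on non-normal data falls back to the unpaired
#' Mann--Whitney test with a warning.
#'
#' @param a,b Numeric samples (each n >= 3; equal lengths when paired).
#' @param paired Pair observations by position?
#' @param alpha_ks Normality-screen level (default 0.05).
#' @param ks_variant `"lilliefors"` (default; corrected for estimating
#'   the mean and SD from the sample) or `"naive"` (standardized sample
#'   against the standard normal, conservative about non-normality).
#' @return A `test_result` list: `method` (`t_unpaired`, `t_paired` or
#'   `mann_whitney`), `statistic`, `p`, `n_a`, `n_b`, `ks_p_a`, `ks_p_b`,
#'   `degenerate` (both samples constant), and `label`
#'   (see [significance_label()]).
#' @export
#' @examples
#' route_and_test(c(1, 2, 3), c(4, 5, 6))
route_and_test <- function(a, b, paired = FALSE, alpha_ks = 0.05,
                           ks_variant = c("lilliefors", "naive")) {
  ks_variant <- match.arg(ks_variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  if (paired && length(a) != length(b)) stop("paired samples must have equal length")
  out <- list(n_a = length(a), n_b = length(b),
              ks_p_a = ks_normal_p(a, ks_variant),
              ks_p_b = ks_normal_p(b, ks_variant),
              degenerate = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # no variation anywhere: nothing to test
    out$method <- "t_unpaired"
    out$statistic <- 0
    out$p <- 1
    out$degenerate <- TRUE
  } else if (paired && stats::sd(b - a) == 0) {
    # a perfectly constant pairwise shift: no within-pair variance to
    # test against; report the limiting p-value
    out$method <- "t_paired"
    out$statistic <- sign(mean(b - a)) * Inf
    out$p <- if (mean(b - a) == 0) 1 else 0
    out$degenerate <- TRUE
  } else if (out$ks_p_a > alpha_ks && out$ks_p_b > alpha_ks) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
    out$method <- if (paired) "t_paired" else "t_unpaired"
    out$statistic <- unname(tt$statistic)
    out$p <- tt$p.value
  } else {
    if (paired) {
      warning("non-normal paired samples: falling back to unpaired Mann-Whitney U")
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    out$method <- "mann_whitney"
    out$statistic <- unname(wt$statistic)
    out$p <- wt$p.value
  }
  out$label <- significance_label(out$p)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$method, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p, 4), " (", x$label, "), n = ", x$n_a, "/", x$n_b,
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Bootstrap estimation statistics for a mean difference
#'
#' Effect-size-first companion to [route_and_test()]: reports the
#' difference between means (DBM, `mean(b) - mean(a)`) with a percentile
#' bootstrap confidence interval. In paired mode the per-pair differences
#' are resampled; in unpaired mode the two groups are resampled
#' independently.
#'
#' @param a,b Numeric samples (n >= 3; equal lengths when paired).
#' @param paired Resample per-pair differences instead of groups?
#' @param n_boot Number of bootstrap resamples (>= 100; default 5000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed; the resampling is deterministic given it.
#' @return An `estimation_result` list: `dbm`, `ci_low`, `ci_high`,
#'   `n_boot`, `conf`, `seed`.
#' @export
estimation_stats <- function(a, b, paired = FALSE, n_boot = 5000,
                             conf = 0.95, seed = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (paired && length(a) != length(b)) stop("paired samples must have equal length")
  dbm <- mean(b) - mean(a)
  boots <- local_seed(seed, {
    if (paired) {
      d <- b - a
      idx <- matrix(sample.int(length(d), n_boot * length(d), replace = TRUE),
                    nrow = n_boot)
      rowMeans(matrix(d[idx], nrow = n_boot))
    } else {
      ia <- matrix(sample.int(length(a), n_boot * length(a), replace = TRUE),
                   nrow = n_boot)
      ib <- matrix(sample.int(length(b), n_boot * length(b), replace = TRUE),
                   nrow = n_boot)
      rowMeans(matrix(b[ib], nrow = n_boot)) -
        rowMeans(matrix(a[ia], nrow = n_boot))
    }
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(dbm = dbm, ci_low = qs[1], ci_high = qs[2],
                 n_boot = n_boot, conf = conf, seed = seed),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("<estimation_result> DBM = ", signif(x$dbm, 4), " [",
      signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "] (",
      100 * x$conf, "% percentile bootstrap, ", x$n_boot, " resamples)\n",
      sep = "")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All package randomness funnels through this.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
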