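# Curated NP / NPR gene panels and their validation.

#' Load an NP--NPR gene panel
#'
#' A gene panel holds the curated table of neuropeptide (NP) genes paired
#' with their receptors (NPRs), one row per published NP--NPR pairing, plus
#' the smaller network panel of pairs used for TF-network analyses.
#'
#' The packaged panel ships with the package (use `path = "packaged"`); it
#' reproduces the published pairing table row for row, including its known
#' quirks (genes appearing in several rows, one FlyBase ID printed for two
#' different receptor rows). Those quirks are surfaced by
#' [validate_panel()] rather than silently resolved.
#'
#' @param path Path to a tab-separated pairing table with columns
#'   `np_symbol`, `np_flybase_id`, `npr_symbol`, `npr_flybase_id`
#'   (an optional leading `row` column is accepted), or the string
#'   `"packaged"` for the curated table shipped with the package.
#' @param network_path Optional path to a two-column (`np_symbol`,
#'   `npr_symbol`) network-panel table; defaults to the packaged one when
#'   `path = "packaged"`, otherwise `NULL`.
#' @return An object of class `gene_panel`: a list with `pairs` (the
#'   pairing table, row order preserved) and `network_pairs` (the network
#'   panel, or `NULL`).
#' @export
#' @examples
#' panel <- load_panel("packaged")
#' nrow(panel$pairs)
load_panel <- function(path = "packaged", network_path = NULL) {
  if (identical(path, "packaged")) {
    path <- system.file("extdata", "np_npr_pairs.tsv", package = "pepregnet")
    if (is.null(network_path)) {
      network_path <- system.file("extdata", "network_panel.tsv",
                                  package = "pepregnet")
    }
  }
  pairs <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("row" %in% names(pairs)) pairs$row <- NULL
  need <- c("np_symbol", "np_flybase_id", "npr_symbol", "npr_flybase_id")
  if (!all(need %in% names(pairs))) {
    stop("panel table must have columns: ", paste(need, collapse = ", "))
  }
  pairs <- pairs[, need]
  for (col in c("np_flybase_id", "npr_flybase_id")) {
    bad <- !grepl("^FBgn[0-9]{7}$", pairs[[col]])
    if (any(bad)) {
      stop("malformed FlyBase ID in column ", col, ": ",
           paste(unique(pairs[[col]][bad]), collapse = ", "))
    }
  }
  network_pairs <- NULL
  if (!is.null(network_path) && nzchar(network_path)) {
    network_pairs <- utils::read.delim(network_path, stringsAsFactors = FALSE)
    if (!all(c("np_symbol", "npr_symbol") %in% names(network_pairs))) {
      stop("network panel must have columns np_symbol, npr_symbol")
    }
  }
  structure(list(pairs = pairs, network_pairs = network_pairs),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", nrow(x$pairs), " NP-NPR pairing rows; ",
      length(panel_genes(x, "NP")), " NP / ",
      length(panel_genes(x, "NPR")), " NPR unique symbols", sep = "")
  if (!is.null(x$network_pairs)) {
    cat("; network panel: ", length(unique(x$network_pairs$np_symbol)),
        " NPs x ", length(unique(x$network_pairs$npr_symbol)), " NPRs",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Unique panel genes of one class
#'
#' @param panel A `gene_panel`.
#' @param class `"NP"` or `"NPR"`.
#' @param network If `TRUE`, take genes from the network panel instead of
#'   the full pairing table.
#' @return Character vector of unique gene symbols, in first-appearance order.
#' @export
panel_genes <- function(panel, class = c("NP", "NPR"), network = FALSE) {
  class <- match.arg(class)
  if (network) {
    if (is.null(panel$network_pairs)) stop("panel has no network pairs")
    col <- if (class == "NP") "np_symbol" else "npr_symbol"
    return(unique(panel$network_pairs[[col]]))
  }
  col <- if (class == "NP") "np_symbol" else "npr_symbol"
  unique(panel$pairs[[col]])
}

# Symbol normalization used when cross-referencing the network panel (whose
# symbols follow current FlyBase casing, e.g. Crz, Pdf, FMRFa) against the
# pairing table (which keeps the published spelling, e.g. CRZ, PDF,
# FMRFamide). Case-insensitive, and FMRFa is accepted as a prefix of
# FMRFamide.
normalize_symbol <- function(x) {
  x <- tolower(x)
  x[x == "fmrfa"] <- "fmrfamide"
  x
}

#' Validate a gene panel and report its quirks
#'
#' Checks FlyBase ID format, cross-references the network panel against the
#' pairing table (case-insensitively, with known synonym spellings), and
#' reports duplicate gene/ID usages instead of resolving them: the packaged
#' table intentionally reproduces its published source verbatim.
#'
#' @param panel A `gene_panel`.
#' @return A list with `ok` (logical), `duplicate_ids` (FlyBase IDs printed
#'   for more than one distinct receptor symbol), `repeated_genes` (symbols
#'   appearing in more than one pairing row), and `unmatched_network`
#'   (network-panel symbols with no counterpart in the pairing table).
#' @export
validate_panel <- function(panel) {
  pairs <- panel$pairs
  id2sym <- unique(rbind(
    data.frame(id = pairs$np_flybase_id, sym = pairs$np_symbol),
    data.frame(id = pairs$npr_flybase_id, sym = pairs$npr_symbol)))
  dup <- names(which(tapply(id2sym$sym, id2sym$id, function(s) length(unique(s))) > 1))
  rep_genes <- c(
    names(which(table(pairs$np_symbol) > 1)),
    names(which(table(pairs$npr_symbol) > 1)))
  unmatched <- character()
  if (!is.null(panel$network_pairs)) {
    known <- normalize_symbol(c(pairs$np_symbol, pairs$npr_symbol))
    net <- unique(c(panel$network_pairs$np_symbol, panel$network_pairs$npr_symbol))
    unmatched <- net[!normalize_symbol(net) %in% known]
  }
  # duplicates are reported, not treated as failures: the packaged table
  # keeps its published quirks on purpose
  list(ok = length(unmatched) == 0,
       duplicate_ids = dup,
       repeated_genes = unique(rep_genes),
       unmatched_network = unmatched)
}
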