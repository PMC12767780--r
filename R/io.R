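# Expression-matrix container and readers/writers for the on-disk formats:
# MTX triplet (+ cells.tsv/genes.tsv), dense TSV, GMT-like regulon files,
# annotation and Ct tables.

#' Construct an expression matrix with per-cell metadata
#'
#' Cells-by-genes matrix of non-negative integer UMI counts, with one
#' metadata row per cell (tissue, annotation, age in days, sex).
#'
#' @param counts Cells x genes matrix (dense or `Matrix` sparse) of
#'   non-negative integers; dimnames give cell and gene identifiers.
#' @param cell_meta Data frame with columns `cell_id`, `tissue`,
#'   `annotation`, `age_days`, `sex`, aligned with the matrix rows.
#' @return An object of class `expr_matrix` with elements `counts`
#'   (a sparse `dgCMatrix`) and `cell_meta`.
#' @export
expression_matrix <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("negative counts are not allowed")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have cell and gene dimnames")
  }
  if (anyDuplicated(rownames(counts))) stop("cell_ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("gene_ids must be unique")
  need <- c("cell_id", "tissue", "annotation", "age_days", "sex")
  if (!all(need %in% names(cell_meta))) {
    stop("cell_meta must have columns: ", paste(need, collapse = ", "))
  }
  cell_meta <- as.data.frame(cell_meta)[, need]
  if (!identical(as.character(cell_meta$cell_id), rownames(counts))) {
    stop("cell_meta$cell_id must match the matrix rows in order")
  }
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " genes; tissues: ", paste(unique(x$cell_meta$tissue), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Write an expression matrix to disk
#'
#' `mtx` writes a MatrixMarket triplet `matrix.mtx` plus `cells.tsv` and
#' `genes.tsv`; `dense_tsv` writes one tab-separated table with cells as
#' rows, genes as columns, and the metadata columns first.
#'
#' @param m An `expr_matrix`.
#' @param dir Output directory (created if missing).
#' @param format `"mtx"` or `"dense_tsv"`.
#' @return `dir`, invisibly.
#' @export
write_expression <- function(m, dir, format = c("mtx", "dense_tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
    utils::write.table(m$cell_meta, file.path(dir, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = colnames(m$counts)),
                       file.path(dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dense <- cbind(m$cell_meta, as.data.frame(as.matrix(m$counts),
                                              check.names = FALSE))
    utils::write.table(dense, file.path(dir, "matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read an expression matrix from disk
#'
#' Inverse of [write_expression()]: reading back what was written yields an
#' identical object. The MTX header is checked against the number of
#' triplet lines before parsing, so a truncated or padded file fails with a
#' format error instead of silently mis-reading.
#'
#' @param dir Directory written by [write_expression()].
#' @param format `"mtx"` or `"dense_tsv"`.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(dir, format = c("mtx", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx_path <- file.path(dir, "matrix.mtx")
    lines <- readLines(mtx_path)
    body <- lines[!startsWith(lines, "%")]
    header <- as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]])
    if (length(header) != 3) stop("format error: malformed MTX size header")
    if (length(body) - 1L != header[3]) {
      stop("format error: MTX header declares ", header[3],
           " entries but file has ", length(body) - 1L)
    }
    counts <- as(Matrix::readMM(mtx_path), "CsparseMatrix")
    cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                               stringsAsFactors = FALSE)
    genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                               stringsAsFactors = FALSE)
    if (nrow(cells) != nrow(counts) || nrow(genes) != ncol(counts)) {
      stop("format error: dimension mismatch between matrix and index files")
    }
    dimnames(counts) <- list(as.character(cells$cell_id),
                             as.character(genes$gene_id))
    expression_matrix(counts, cells)
  } else {
    dense <- utils::read.delim(file.path(dir, "matrix.tsv"),
                               stringsAsFactors = FALSE, check.names = FALSE)
    meta_cols <- c("cell_id", "tissue", "annotation", "age_days", "sex")
    counts <- as.matrix(dense[, setdiff(names(dense), meta_cols), drop = FALSE])
    if (any(counts < 0)) stop("validation error: negative count in dense TSV")
    rownames(counts) <- as.character(dense$cell_id)
    expression_matrix(counts, dense[, meta_cols])
  }
}

#' Write regulons in a GMT-like format
#'
#' One regulon per line: TF, then `motif|context` as the description field,
#' then the tab-separated target genes.
#'
#' @param regulons List of `regulon` objects (see [build_regulons()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regulons <- function(regulons, path) {
  lines <- vapply(regulons, function(r) {
    paste(c(r$tf, paste0(r$motif, "|", r$context), r$targets), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read regulons written by [write_regulons()]
#'
#' @param path GMT-like regulon file.
#' @return List of `regulon` objects.
#' @export
read_regulons <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("format error: regulon line with < 3 fields")
    desc <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    new_regulon(tf = f[1], targets = f[-(1:2)],
                motif = desc[1],
                context = if (length(desc) > 1) desc[2] else "all")
  })
}

#' Read a regulatory-feature annotation table
#'
#' BED-like TSV with columns `gene`, `kind` (one of `TFBS_HSA`, `CRM`,
#' `PEAK`), `start`, `end`; coordinates are 0-based half-open.
#'
#' @param path TSV file.
#' @return Validated annotation data frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `gene`, `sex`, `age_days`, `temperature_c`,
#' `tissue_part`, `replicate_id`, `ct`.
#'
#' @param path CSV file.
#' @return Data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "sex", "age_days", "temperature_c", "tissue_part",
            "replicate_id", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(ct$ct <= 0)) stop("validation error: Ct values must be positive")
  ct
}
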