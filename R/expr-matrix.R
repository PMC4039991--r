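#' Expression matrix container
#'
#' A light wrapper around a genes x cells (or genes x conditions) numeric
#' matrix with optional per-cell metadata. Single-cell values are on a
#' non-negative log2-expression scale where 0 encodes "undetected";
#' condition-level values are FPKM.
#'
#' @param values Numeric matrix, genes in rows, cells/conditions in columns.
#'   Row and column names are required and must be unique.
#' @param cell_meta Optional data frame with one row per cell and a
#'   `cell_id` column; may carry `gate_label` and `generation` columns.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, cell_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells).", call. = FALSE)
  }
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("`values` must have row (gene) and column (cell) names.", call. = FALSE)
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g) > 0) {
    stop("Duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  dup_c <- cell_ids[duplicated(cell_ids)]
  if (length(dup_c) > 0) {
    stop("Duplicate cell identifier(s): ", paste(unique(dup_c), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("Missing value at gene '%s', cell '%s'.",
                 gene_ids[idx[1]], cell_ids[idx[2]]), call. = FALSE)
  }
  if (any(values < 0)) {
    stop("Expression values must be non-negative (0 encodes undetected).",
         call. = FALSE)
  }
  if (!is.null(cell_meta)) {
    cell_meta <- tibble::as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) {
      stop("`cell_meta` must contain a `cell_id` column.", call. = FALSE)
    }
    missing <- setdiff(cell_ids, cell_meta$cell_id)
    if (length(missing) > 0) {
      stop("`cell_meta` lacks rows for cell(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  }
  structure(list(values = values, cell_meta = cell_meta), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' Gene and cell identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells\n", nrow(x$values), ncol(x$values)))
  cat("genes: ", paste(utils::head(gene_ids(x), 4), collapse = ", "),
      if (nrow(x$values) > 4) ", ..." else "", "\n", sep = "")
  cat("cells: ", paste(utils::head(cell_ids(x), 4), collapse = ", "),
      if (ncol(x$values) > 4) ", ..." else "", "\n", sep = "")
  if (!is.null(x$cell_meta)) {
    cat("cell_meta: ", paste(setdiff(names(x$cell_meta), "cell_id"),
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.expr_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$values, rownames = "gene")
  out <- tidyr::pivot_longer(out, -"gene", names_to = "cell",
                             values_to = "expression")
  if (!is.null(x$cell_meta)) {
    out <- dplyr::left_join(out, x$cell_meta, by = c(cell = "cell_id"))
  }
  out
}

# case-insensitive gene lookup; returns index or NA
match_gene <- function(symbol, pool) {
  hit <- match(symbol, pool)
  if (is.na(hit)) hit <- match(tolower(symbol), tolower(pool))
  hit
}

#' Read a gene x cell expression table
#'
#' Reads a delimited text table into an [expr_matrix()]. The first column
#' (or row, see `layout`) carries identifiers; the body must be fully
#' numeric. Missing cells are a hard error, never silently imputed, because
#' downstream rank statistics would be corrupted.
#'
#' @param path Path to a TSV/CSV file.
#' @param layout `"genes_in_rows"` (default) or `"cells_in_rows"`; the
#'   result is always genes x cells.
#' @param delim Field delimiter; if `NULL` it is sniffed from the header
#'   line (tab wins over comma).
#' @return An [expr_matrix()].
#' @export
read_expression_table <- function(path,
                                  layout = c("genes_in_rows", "cells_in_rows"),
                                  delim = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !(is.na(col) | trimws(as.character(col)) == "NA"))
      if (length(bad) > 0 || anyNA(num)) {
        row_bad <- if (length(bad) > 0) bad[1] else which(is.na(num))[1]
        stop(sprintf("Non-numeric or empty cell at row '%s', column '%s'.",
                     ids[row_bad], names(body)[j]), call. = FALSE)
      }
      body[[j]] <- num
    }
    if (anyNA(body[[j]])) {
      row_bad <- which(is.na(body[[j]]))[1]
      stop(sprintf("Missing value at row '%s', column '%s'.",
                   ids[row_bad], names(body)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (layout == "cells_in_rows") m <- t(m)
  expr_matrix(m)
}

#' Read a MatrixMarket expression matrix with id sidecars
#'
#' Reads coordinate-format MTX plus two plain-text sidecar files listing the
#' gene and cell identifiers (one per line, in matrix order). Entries absent
#' from the MTX file are 0 by format convention.
#'
#' @param mtx_path Path to the `.mtx` file (genes in rows).
#' @param genes_path,cells_path Paths to the id sidecars.
#' @return An [expr_matrix()].
#' @export
read_expression_mtx <- function(mtx_path, genes_path, cells_path) {
  for (p in c(mtx_path, genes_path, cells_path)) {
    if (!file.exists(p)) stop("File not found: ", p, call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  genes <- genes[nzchar(genes)]
  cells <- cells[nzchar(cells)]
  if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
    stop(sprintf(
      "Sidecar lengths (%d genes, %d cells) do not match matrix dimensions (%d x %d).",
      length(genes), length(cells), nrow(m), ncol(m)), call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  expr_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, identifier column `gene` first; numbers written at 10
#' significant digits so a write/read round trip is exact at that precision.
#'
#' @param x An [expr_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = gene_ids(x), fmt_num(x$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", cell_ids(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed-precision number formatting shared by all writers (10 significant
# digits, no scientific notation surprises); keeps reports byte-deterministic
fmt_num <- function(x) {
  out <- formatC(signif(x, 10), format = "g", digits = 10, width = 1)
  dim(out) <- dim(x)
  out
}
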