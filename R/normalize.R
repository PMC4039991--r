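#' qPCR cycle-threshold matrix
#'
#' Container for raw single-cell qPCR Ct values. Undetected reactions are
#' encoded as `NA` — an explicit sentinel, never a fabricated number.
#'
#' @param ct Numeric matrix of Ct values (genes x cells, units cycles) with
#'   row/column names; `NA` marks undetected reactions.
#' @return An object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop("`ct` must be a numeric matrix.", call. = FALSE)
  }
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("`ct` must have gene (row) and cell (column) names.", call. = FALSE)
  }
  detected <- ct[!is.na(ct)]
  if (any(!is.finite(detected))) {
    stop("Detected Ct values must be finite.", call. = FALSE)
  }
  if (any(detected <= 0)) {
    stop("Detected Ct values must be positive (cycles).", call. = FALSE)
  }
  structure(list(ct = ct), class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d genes x %d cells, %d undetected entries\n",
              nrow(x$ct), ncol(x$ct), sum(is.na(x$ct))))
  invisible(x)
}

#' Normalize qPCR Ct values to log2-expression above detection limit
#'
#' Applies the standard limit-of-detection transform of single-cell qPCR
#' protocols: expression `e = max(0, lod_ct - Ct)` for detected reactions,
#' and 0 for undetected reactions. Because one PCR cycle is one doubling,
#' the result is on a log2 scale anchored at the detection limit; `Ct`
#' equal to `lod_ct` maps to 0 (the boundary of detection).
#'
#' @param ct A [ct_matrix()] (or bare named numeric matrix; `NA` =
#'   undetected).
#' @param lod_ct Limit-of-detection cycle number (default 28 cycles).
#' @return An [expr_matrix()] of log2-expression; attribute `n_undetected`
#'   carries the count of undetected entries set to 0.
#' @export
normalize_ct <- function(ct, lod_ct = 28) {
  if (!inherits(ct, "ct_matrix")) ct <- ct_matrix(ct)
  if (!is.numeric(lod_ct) || length(lod_ct) != 1 || lod_ct <= 0) {
    stop("`lod_ct` must be a single positive number of cycles.", call. = FALSE)
  }
  m <- ct$ct
  n_over <- sum(m > lod_ct, na.rm = TRUE)
  if (n_over > 0) {
    warning(sprintf("%d detected Ct value(s) exceed lod_ct = %g; set to 0.",
                    n_over, lod_ct), call. = FALSE)
  }
  expr <- pmax(lod_ct - m, 0)
  n_undet <- sum(is.na(m))
  expr[is.na(m)] <- 0
  out <- expr_matrix(expr)
  attr(out, "n_undetected") <- n_undet
  attr(out, "lod_ct") <- lod_ct
  out
}

#' Gene annotation table
#'
#' Maps gene symbols to one of four functional categories used by the
#' correlation screen: `cytokine`, `surface_receptor`,
#' `transcription_factor`, `other`. Lookup is case-insensitive and any
#' unannotated gene resolves to `"other"`.
#'
#' @param df Data frame with columns `gene`, `category`, and optionally
#'   `is_suppressor` (logical).
#' @return A tibble of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("gene", "category") %in% names(df))) {
    stop("Annotation needs `gene` and `category` columns.", call. = FALSE)
  }
  valid <- c("cytokine", "surface_receptor", "transcription_factor", "other")
  bad <- setdiff(unique(df$category), valid)
  if (length(bad) > 0) {
    stop("Invalid annotation category value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tolower(df$gene))) {
    stop("Duplicate gene symbol(s) in annotation.", call. = FALSE)
  }
  if (!"is_suppressor" %in% names(df)) df$is_suppressor <- FALSE
  class(df) <- c("gene_annotation", class(df))
  df
}

#' Read a gene annotation TSV (columns gene, category[, is_suppressor])
#' @param path Path to a TSV/CSV file.
#' @return A [gene_annotation()] tibble.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE)
  if ("is_suppressor" %in% names(df)) {
    df$is_suppressor <- as.logical(df$is_suppressor)
  }
  gene_annotation(df)
}

#' Look up annotation categories for gene symbols
#'
#' @param annotation A [gene_annotation()] or `NULL` (everything `"other"`).
#' @param genes Character vector of gene symbols.
#' @return Character vector of categories, `"other"` for unannotated genes.
#' @export
annotation_category <- function(annotation, genes) {
  if (is.null(annotation)) return(rep("other", length(genes)))
  idx <- match(tolower(genes), tolower(annotation$gene))
  out <- annotation$category[idx]
  out[is.na(out)] <- "other"
  out
}
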