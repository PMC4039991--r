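#' Write a pipeline result as a JSON report with a TSV twin
#'
#' Serialises any pipeline result to `<stem>.json` and writes its main
#' tabular component to `<stem>.tsv`. Field order is deterministic and all
#' floating-point numbers are written at 10 significant digits, so reloading
#' reproduces the values bit-identically at that precision and repeated runs
#' are byte-identical.
#'
#' @param result A screen, module, clustering, proliferation, or plain
#'   tibble/list result.
#' @param stem Output path without extension (`.json`/`.tsv` are appended).
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_report <- function(result, stem) {
  dir <- dirname(stem)
  if (!dir.exists(dir)) {
    stop("Output directory does not exist: ", dir, call. = FALSE)
  }
  payload <- report_payload(result)
  json_path <- paste0(stem, ".json")
  tsv_path <- paste0(stem, ".tsv")
  jsonlite::write_json(round_floats(payload$json), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  tab <- payload$table
  if (is.null(tab)) tab <- tibble::tibble()
  tab <- dplyr::mutate(tibble::as_tibble(tab),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ signif(.x, 10)))
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

# recursively fix float precision so JSON bytes are stable
round_floats <- function(x) {
  if (is.list(x)) return(lapply(x, round_floats))
  if (is.double(x)) return(signif(x, 10))
  x
}

# dispatchable mapping from result objects to {json payload, main table}
report_payload <- function(result) UseMethod("report_payload")

#' @export
report_payload.default <- function(result) {
  if (is.data.frame(result)) {
    list(json = list(records = df_records(result)), table = result)
  } else if (is.list(result)) {
    list(json = result, table = NULL)
  } else {
    list(json = list(value = result), table = NULL)
  }
}

#' @export
report_payload.anchor_screen <- function(result) {
  list(json = list(
    anchor = result$anchor,
    config = result$config[c("screen_threshold", "cell_cluster_threshold",
                             "min_detected_cells", "p_method", "fdr_alpha")],
    records = df_records(result$records),
    screened_genes = as.list(result$screened_genes),
    cell_cluster_genes = as.list(result$cell_cluster_genes),
    excluded = df_records(result$excluded)
  ), table = result$records)
}

#' @export
report_payload.gene_modules <- function(result) {
  list(json = list(
    anchor = result$anchor,
    anchor_module = as.list(result$anchor_module),
    modules = df_records(result$modules)
  ), table = result$modules)
}

#' @export
report_payload.cell_clusters <- function(result) {
  list(json = list(
    anchor = result$anchor,
    k = result$k,
    anchor_cell_cluster = result$anchor_cell_cluster,
    fraction_anchor_in_cluster = result$fraction_anchor_in_cluster,
    partition = df_records(result$partition)
  ), table = result$partition)
}

#' @export
report_payload.generation_fit <- function(result) {
  list(json = list(
    g0_center = result$g0_center,
    sigma = result$sigma,
    n_events = result$n_events,
    method = result$method,
    counts = df_records(result$counts)
  ), table = result$counts)
}

#' @export
report_payload.division_index <- function(result) {
  list(json = list(
    di = result$di,
    condition = result$condition,
    replicate = result$replicate,
    precursor_counts = df_records(result$precursors)
  ), table = result$precursors)
}

#' @export
report_payload.suppression_assay <- function(result) {
  list(json = list(
    reference_condition = result$reference_condition,
    summary = df_records(result$summary),
    replicates = df_records(result$replicates)
  ), table = result$summary)
}

# data frame -> list of row records (deterministic field order, lists kept)
df_records <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(list())
  df <- tibble::as_tibble(df)
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df, function(col) {
      v <- col[[i]]
      if (is.list(col)) as.list(v) else v
    })
    row
  })
}
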