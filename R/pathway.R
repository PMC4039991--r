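#' Pathway definition: ordered metabolite steps with required genes
#'
#' Describes an ordered enzymatic pathway (here, steroidogenesis from
#' cholesterol to pregnenolone and beyond). Each step yields a metabolite
#' and requires a set of gene symbols; with `any_of = TRUE` a single
#' detected gene from the set suffices (redundant transporters/sources),
#' otherwise all are required.
#'
#' @param steps Data frame with columns `metabolite` (character), `genes`
#'   (list of character vectors), `any_of` (logical).
#' @param name Pathway name.
#' @return An object of class `pathway_definition`.
#' @export
pathway_definition <- function(steps, name = "pathway") {
  steps <- tibble::as_tibble(steps)
  if (nrow(steps) < 1) stop("A pathway needs at least one step.", call. = FALSE)
  if (!all(c("metabolite", "genes", "any_of") %in% names(steps))) {
    stop("`steps` needs columns metabolite, genes, any_of.", call. = FALSE)
  }
  if (!is.list(steps$genes)) steps$genes <- as.list(steps$genes)
  if (any(lengths(steps$genes) == 0)) {
    stop("Every step must require at least one gene.", call. = FALSE)
  }
  steps$any_of <- as.logical(steps$any_of)
  structure(list(steps = steps, name = name), class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat(sprintf("<pathway_definition> '%s', %d steps\n", x$name, nrow(x$steps)))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %d. %s  [%s%s]\n", i, x$steps$metabolite[i],
                paste(x$steps$genes[[i]], collapse = ", "),
                if (x$steps$any_of[i]) "; any of" else ""))
  }
  invisible(x)
}

#' Read a pathway definition from YAML or JSON
#'
#' The file holds `name` and a `steps` list, each step with `metabolite`,
#' `genes`, and optional `any_of` (default false).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pathway_definition()].
#' @export
read_pathway_definition <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  steps <- tibble::tibble(
    metabolite = vapply(spec$steps, function(s) s$metabolite, character(1)),
    genes = lapply(spec$steps, function(s) as.character(unlist(s$genes))),
    any_of = vapply(spec$steps, function(s) isTRUE(s$any_of), logical(1))
  )
  pathway_definition(steps, name = spec$name %||% "pathway")
}

#' The default steroidogenesis pathway shipped with the package
#'
#' Transcribes the canonical chain: cholesterol synthesis/uptake (redundant
#' sources), mitochondrial import through the transduceosome (redundant
#' voltage-dependent anion channels, then Tspo/Star), cholesterol
#' side-chain cleavage by Cyp11a1 yielding pregnenolone, and the
#' downstream branch enzymes Cyp17a1/Hsd3b1.
#'
#' @return A [pathway_definition()].
#' @export
default_steroidogenesis_pathway <- function() {
  read_pathway_definition(
    system.file("extdata", "steroidogenesis_pathway.yaml",
                package = "steroidscreen", mustWork = TRUE))
}

#' Map FPKM to a white-to-red display intensity
#'
#' Linear ramp clipped at both ends: values at or below `low` map to 0
#' (white), values at or above `high` map to 1 (saturated red).
#'
#' @param value Non-negative FPKM value(s).
#' @param low,high Ramp endpoints in FPKM (defaults 3 and 15).
#' @return Intensities in `[0, 1]`, same length as `value`.
#' @export
colorize_expression <- function(value, low = 3, high = 15) {
  if (!is.numeric(value)) stop("`value` must be numeric.", call. = FALSE)
  if (any(value < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative.", call. = FALSE)
  }
  if (!(low >= 0 && low < high)) {
    stop("Need 0 <= low < high.", call. = FALSE)
  }
  pmin(pmax((value - low) / (high - low), 0), 1)
}

#' Score pathway completeness per condition
#'
#' For each condition (column), marks a gene detected iff its value exceeds
#' `low`, then walks the ordered steps: a step is satisfied when all its
#' required genes are detected (or at least one, for `any_of` steps). The
#' condition's `reach` is the metabolite of the last step in an unbroken
#' satisfied prefix ("none" if the first step already fails), and
#' `blocked_at` lists the undetected required genes of the first
#' unsatisfied step.
#'
#' @param expr An [expr_matrix()] with conditions as columns (FPKM).
#' @param pathway A [pathway_definition()].
#' @param low,high Colour-ramp endpoints; `low` doubles as the detection
#'   threshold (strictly greater than).
#' @return Object of class `pathway_reach`: `$summary` tibble (condition,
#'   reach, blocked_at list-column), `$intensity` and `$detected` matrices
#'   over the pathway genes.
#' @export
pathway_reach <- function(expr, pathway, low = 3, high = 15) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!inherits(pathway, "pathway_definition") || nrow(pathway$steps) == 0) {
    stop("`pathway` must be a non-empty pathway_definition.", call. = FALSE)
  }
  all_genes <- unique(unlist(pathway$steps$genes))
  idx <- vapply(all_genes, match_gene, integer(1), pool = gene_ids(expr))
  missing <- all_genes[is.na(idx)]
  if (length(missing) > 0) {
    warning("Pathway gene(s) absent from expression matrix, treated as ",
            "undetected: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- matrix(0, nrow = length(all_genes), ncol = ncol(expr$values),
                 dimnames = list(all_genes, cell_ids(expr)))
  present <- !is.na(idx)
  vals[present, ] <- expr$values[idx[present], , drop = FALSE]
  intensity <- colorize_expression(vals, low = low, high = high)
  detected <- vals > low

  summary <- purrr::map_dfr(cell_ids(expr), function(cond) {
    det <- detected[, cond]
    reach <- "none"
    blocked <- character(0)
    for (i in seq_len(nrow(pathway$steps))) {
      genes <- pathway$steps$genes[[i]]
      ok <- if (pathway$steps$any_of[i]) any(det[genes]) else all(det[genes])
      if (!ok) {
        blocked <- genes[!det[genes]]
        break
      }
      reach <- pathway$steps$metabolite[i]
    }
    tibble::tibble(condition = cond, reach = reach, blocked_at = list(blocked))
  })
  structure(list(summary = summary, intensity = intensity,
                 detected = detected, pathway = pathway,
                 low = low, high = high),
            class = "pathway_reach")
}

#' @export
print.pathway_reach <- function(x, ...) {
  cat(sprintf("<pathway_reach> '%s' over %d condition(s)\n",
              x$pathway$name, nrow(x$summary)))
  for (i in seq_len(nrow(x$summary))) {
    blocked <- x$summary$blocked_at[[i]]
    cat(sprintf("  %s: reach = %s%s\n", x$summary$condition[i],
                x$summary$reach[i],
                if (length(blocked)) paste0(" (blocked at: ",
                                            paste(blocked, collapse = ", "), ")")
                else ""))
  }
  invisible(x)
}

#' @export
report_payload.pathway_reach <- function(result) {
  tab <- dplyr::mutate(result$summary,
                       blocked_at = vapply(result$summary$blocked_at,
                                           paste, character(1), collapse = ";"))
  list(json = list(
    pathway = result$pathway$name,
    low = result$low, high = result$high,
    summary = df_records(result$summary),
    intensity = lapply(asplit(result$intensity, 2), as.list)
  ), table = tab)
}

#' Export the colour-intensity matrix of a pathway_reach result as TSV
#' @param x A `pathway_reach` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  stopifnot(inherits(x, "pathway_reach"))
  df <- data.frame(gene = rownames(x$intensity), fmt_num(x$intensity),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(x$intensity))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
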