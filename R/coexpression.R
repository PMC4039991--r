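#' Spearman rank correlation with a p value
#'
#' Spearman's rho computed as the Pearson correlation of mid-rank
#' (average-tie) ranks. The p value is either the asymptotic
#' t-approximation (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom) or a two-sided permutation test.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param n_permutations Number of permutations when `p_method =
#'   "permutation"` (>= 100).
#' @param seed Optional seed for the permutation null.
#' @return List with elements `rho` and `p`.
#' @export
spearman_rho <- function(x, y, p_method = c("asymptotic", "permutation"),
                         n_permutations = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length.", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("Need at least 3 paired observations.", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("Missing values are not allowed.", call. = FALSE)
  if (is_constant(x) || is_constant(y)) {
    stop(structure(
      class = c("steroidscreen_constant_input", "error", "condition"),
      list(message = "Undefined correlation: constant input vector.",
           call = NULL)))
  }
  rx <- rank(x)  # mid-ranks for ties
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- switch(p_method,
    asymptotic = {
      if (abs(rho) >= 1) {
        0
      } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * stats::pt(-abs(tstat), df = n - 2)
      }
    },
    permutation = {
      if (n_permutations < 100) {
        stop("Need >= 100 permutations.", call. = FALSE)
      }
      run_perm <- function() {
        hits <- 0L
        for (b in seq_len(n_permutations)) {
          rb <- stats::cor(rx, sample(ry))
          if (abs(rb) >= abs(rho) - 1e-12) hits <- hits + 1L
        }
        (1 + hits) / (n_permutations + 1)
      }
      if (!is.null(seed)) with_local_seed(seed, run_perm()) else run_perm()
    })
  list(rho = rho, p = p)
}

is_constant <- function(v) length(unique(v)) <= 1L

# evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration for the anchor-gene correlation screen
#'
#' @param anchor_gene Reference gene symbol against which all other genes
#'   are rank-correlated (default `"Cyp11a1"`).
#' @param screen_threshold Spearman rho above which a gene passes the
#'   screen (strict `>`, default 0.3).
#' @param cell_cluster_threshold Magnitude threshold for the cell-clustering
#'   gene set: genes with `rho > hi` or `rho <= -hi` (default 0.35).
#' @param min_detected_cells Genes (and the anchor) must be detected
#'   (value > 0) in at least this many cells (default 3).
#' @param p_method,n_permutations,seed Passed to [spearman_rho()].
#' @param fdr_alpha Benjamini-Hochberg q-value cutoff used when summarising
#'   discoveries (default 0.05).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(anchor_gene = "Cyp11a1",
                          screen_threshold = 0.3,
                          cell_cluster_threshold = 0.35,
                          min_detected_cells = 3,
                          p_method = c("asymptotic", "permutation"),
                          n_permutations = 1000,
                          seed = NULL,
                          fdr_alpha = 0.05) {
  p_method <- match.arg(p_method)
  stopifnot(screen_threshold > 0, screen_threshold < 1,
            cell_cluster_threshold > 0, cell_cluster_threshold < 1,
            min_detected_cells >= 3)
  if (p_method == "permutation" && n_permutations < 100) {
    stop("Need >= 100 permutations for the permutation null.", call. = FALSE)
  }
  structure(list(anchor_gene = anchor_gene,
                 screen_threshold = screen_threshold,
                 cell_cluster_threshold = cell_cluster_threshold,
                 min_detected_cells = min_detected_cells,
                 p_method = p_method,
                 n_permutations = n_permutations,
                 seed = seed,
                 fdr_alpha = fdr_alpha),
            class = "screen_config")
}

#' Anchor-gene correlation screen across single cells
#'
#' Rank-correlates every gene against the anchor gene across all cells,
#' attaches Benjamini-Hochberg q values and annotation categories, and
#' extracts the two threshold gene sets: `screened_genes` (`rho >`
#' `screen_threshold`) and `cell_cluster_genes` (`|rho|` beyond
#' `cell_cluster_threshold`, signed as `rho > hi` or `rho <= -hi`). Cells
#' in which the anchor is undetected are retained: zeros carry rank
#' information, and dropping them would bias rho upward.
#'
#' @param expr An [expr_matrix()] of single-cell log2-expression.
#' @param annotation Optional [gene_annotation()].
#' @param config A [screen_config()].
#' @return Object of class `anchor_screen` with `$records` (tibble: gene,
#'   rho, p, q, category, n_cells_used, passes_screen, sorted by rho
#'   descending then symbol), `$screened_genes`, `$cell_cluster_genes`,
#'   `$excluded` (gene, reason).
#' @export
anchor_screen <- function(expr, annotation = NULL, config = screen_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!inherits(config, "screen_config")) {
    stop("`config` must be a screen_config().", call. = FALSE)
  }
  a_idx <- match_gene(config$anchor_gene, gene_ids(expr))
  if (is.na(a_idx)) {
    stop("Anchor gene '", config$anchor_gene,
         "' not found in the expression matrix.", call. = FALSE)
  }
  anchor_name <- gene_ids(expr)[a_idx]
  a <- expr$values[a_idx, ]
  if (is_constant(a)) {
    stop("Anchor gene '", anchor_name, "' is constant across cells; ",
         "its correlation is undefined.", call. = FALSE)
  }
  if (sum(a > 0) < config$min_detected_cells) {
    stop("Anchor gene '", anchor_name, "' detected in fewer than ",
         config$min_detected_cells, " cells.", call. = FALSE)
  }

  genes <- setdiff(gene_ids(expr), anchor_name)
  vals <- expr$values[genes, , drop = FALSE]
  detected <- rowSums(vals > 0)
  constant <- apply(vals, 1, is_constant)

  excluded <- dplyr::bind_rows(
    tibble::tibble(gene = genes[constant], reason = "constant"),
    tibble::tibble(gene = genes[!constant & detected < config$min_detected_cells],
                   reason = "too_few_detected_cells")
  )
  keep <- genes[!constant & detected >= config$min_detected_cells]

  stats_list <- lapply(keep, function(g) {
    spearman_rho(vals[g, ], a, p_method = config$p_method,
                 n_permutations = config$n_permutations, seed = config$seed)
  })
  records <- tibble::tibble(
    gene = keep,
    rho = vapply(stats_list, `[[`, numeric(1), "rho"),
    p = vapply(stats_list, `[[`, numeric(1), "p"),
    n_cells_used = ncol(vals)
  )
  records$q <- stats::p.adjust(records$p, method = "BH")
  records$category <- annotation_category(annotation, records$gene)
  records$passes_screen <- records$rho > config$screen_threshold
  records <- dplyr::arrange(records, dplyr::desc(.data$rho), .data$gene)
  records <- records[, c("gene", "rho", "p", "q", "category",
                         "n_cells_used", "passes_screen")]

  hi <- config$cell_cluster_threshold
  structure(list(
    anchor = anchor_name,
    records = records,
    screened_genes = records$gene[records$passes_screen],
    cell_cluster_genes = records$gene[records$rho > hi | records$rho <= -hi],
    excluded = excluded,
    config = config
  ), class = "anchor_screen")
}

#' @export
print.anchor_screen <- function(x, ...) {
  cat(sprintf("<anchor_screen> anchor = %s, %d genes tested, %d pass rho > %g\n",
              x$anchor, nrow(x$records), length(x$screened_genes),
              x$config$screen_threshold))
  print(utils::head(x$records, 10))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.anchor_screen <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.anchor_screen <- function(x, ...) {
  tibble::tibble(
    anchor = x$anchor,
    n_tested = nrow(x$records),
    n_excluded = nrow(x$excluded),
    n_screened = length(x$screened_genes),
    n_cell_cluster_genes = length(x$cell_cluster_genes),
    n_q_significant = sum(x$records$q <= x$config$fdr_alpha),
    screen_threshold = x$config$screen_threshold,
    cell_cluster_threshold = x$config$cell_cluster_threshold
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.anchor_screen <- function(object, top_n = 40, ...) {
  df <- utils::head(object$records, top_n)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$gene,
                                   colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$config$screen_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("Spearman rho vs %s", object$anchor),
                  y = NULL, colour = "category") +
    ggplot2::theme_minimal()
}

#' Rank surface-receptor genes from a completed screen
#'
#' Filters the screen records to `category == "surface_receptor"` and ranks
#' by rho descending (ties by gene symbol), the route by which a sortable
#' surface marker for the anchor-expressing subpopulation is nominated.
#'
#' @param screen An [anchor_screen()] result.
#' @return Tibble (possibly empty): rank, gene, rho, p, q.
#' @export
nominate_surface_markers <- function(screen) {
  stopifnot(inherits(screen, "anchor_screen"))
  out <- dplyr::filter(screen$records, .data$category == "surface_receptor")
  out <- dplyr::arrange(out, dplyr::desc(.data$rho), .data$gene)
  dplyr::mutate(out[, c("gene", "rho", "p", "q")],
                rank = dplyr::row_number(), .before = 1)
}

#' Gene-gene Spearman correlation matrix
#'
#' @param expr An [expr_matrix()].
#' @param genes Optional gene subset (default: all genes). Constant genes
#'   are dropped with a warning; fewer than 2 usable genes is an error.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
gene_correlation_matrix <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(genes)) genes <- gene_ids(expr)
  idx <- vapply(genes, match_gene, integer(1), pool = gene_ids(expr))
  if (anyNA(idx)) {
    stop("Gene(s) not in matrix: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vals <- expr$values[idx, , drop = FALSE]
  constant <- apply(vals, 1, is_constant)
  if (any(constant)) {
    warning("Dropping constant gene(s): ",
            paste(rownames(vals)[constant], collapse = ", "), call. = FALSE)
    vals <- vals[!constant, , drop = FALSE]
  }
  if (nrow(vals) < 2) {
    stop("Need at least 2 non-constant genes for a correlation matrix.",
         call. = FALSE)
  }
  ranks <- t(apply(vals, 1, rank))
  corr <- stats::cor(t(ranks))
  diag(corr) <- 1
  corr
}

#' Cluster genes on a correlation matrix and extract the anchor's module
#'
#' Agglomerative clustering on the distance `1 - rho`. The module partition
#' comes from cutting the dendrogram at height `1 - threshold`; the
#' anchor's own module is refined as the largest dendrogram node containing
#' the anchor whose mean off-diagonal rho still exceeds the threshold, so
#' weakly attached neighbours are not swept in.
#'
#' @param corr Symmetric correlation matrix with unit diagonal (e.g. from
#'   [gene_correlation_matrix()]).
#' @param anchor Anchor gene symbol (must be a row of `corr`).
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @param threshold Mean-correlation threshold for the anchor module and
#'   the partition cut (default 0.3).
#' @return Object of class `gene_modules`: `$hclust`, `$modules` (tibble
#'   gene, module), `$anchor_module` (character), `$correlation_matrix`.
#' @export
cluster_genes <- function(corr, anchor, linkage = c("average", "complete", "single"),
                          threshold = 0.3) {
  linkage <- match.arg(linkage)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr) ||
      max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("`corr` must be a symmetric correlation matrix with unit diagonal.",
         call. = FALSE)
  }
  if (nrow(corr) < 2) {
    stop("Need at least 2 genes to cluster.", call. = FALSE)
  }
  a_idx <- match_gene(anchor, rownames(corr))
  if (is.na(a_idx)) {
    stop("Anchor '", anchor, "' is not in the correlation matrix.",
         call. = FALSE)
  }
  anchor <- rownames(corr)[a_idx]
  hc <- stats::hclust(stats::as.dist(1 - corr), method = linkage)
  part <- stats::cutree(hc, h = 1 - threshold)
  modules <- tibble::tibble(gene = names(part), module = unname(part))

  # walk the merge tree upward from the anchor leaf, staying below the
  # partition cut height; keep the largest node whose internal mean
  # off-diagonal correlation still clears the threshold
  nodes <- anchor_node_members(hc, a_idx)
  anchor_module <- anchor
  for (node in nodes) {
    if (node$height > 1 - threshold) break
    sub <- corr[node$members, node$members, drop = FALSE]
    mean_off <- mean(sub[upper.tri(sub)])
    if (mean_off > threshold) anchor_module <- rownames(corr)[node$members]
  }
  structure(list(hclust = hc, modules = modules,
                 anchor = anchor, anchor_module = anchor_module,
                 correlation_matrix = corr, threshold = threshold,
                 linkage = linkage),
            class = "gene_modules")
}

# member-index sets and merge heights of every dendrogram node containing
# the leaf, ordered smallest to largest
anchor_node_members <- function(hc, leaf_idx) {
  node_members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) -j else node_members[[j]]
    node_members[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  keep <- which(vapply(node_members, function(s) leaf_idx %in% s, logical(1)))
  lapply(keep, function(i) {
    list(members = node_members[[i]], height = hc$height[i])
  })
}

#' @export
print.gene_modules <- function(x, ...) {
  cat(sprintf("<gene_modules> %d genes, %d modules (%s linkage, cut at rho = %g)\n",
              nrow(x$modules), length(unique(x$modules$module)),
              x$linkage, x$threshold))
  cat("anchor module (", x$anchor, "): ",
      paste(x$anchor_module, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_modules <- function(x, ...) {
  dplyr::mutate(x$modules,
                in_anchor_module = .data$gene %in% x$anchor_module)
}

#' Export a gene dendrogram as Newick text
#' @param x A `gene_modules` or `cell_clusters` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(x, path) {
  hc <- x$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Cluster cells on the signed high-correlation gene set
#'
#' Rank-standardises each gene across cells (mid-ranks scaled to zero mean,
#' unit variance), clusters cells hierarchically (Ward linkage on Euclidean
#' distance), and picks `k` by maximising the mean silhouette over
#' `k = 2..6` unless given. The anchor cell cluster is the cluster with the
#' highest mean anchor expression; the fraction of anchor-detected cells
#' captured inside it is reported.
#'
#' @param expr An [expr_matrix()].
#' @param genes Gene set to cluster on (typically `cell_cluster_genes` from
#'   [anchor_screen()]). Must be non-empty.
#' @param anchor Anchor gene symbol.
#' @param k Number of clusters, or `"auto"` (default).
#' @return Object of class `cell_clusters`: `$partition` (tibble cell,
#'   cluster), `$k`, `$anchor_cell_cluster`,
#'   `$fraction_anchor_in_cluster`, `$hclust`, `$silhouette` (tibble).
#' @export
cluster_cells <- function(expr, genes, anchor, k = "auto") {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(genes) == 0) {
    stop("Empty cell-clustering gene set; relax the correlation threshold ",
         "(cell_cluster_threshold) to admit more genes.", call. = FALSE)
  }
  if (ncol(expr$values) < 4) {
    stop("Need at least 4 cells to cluster.", call. = FALSE)
  }
  idx <- vapply(genes, match_gene, integer(1), pool = gene_ids(expr))
  if (anyNA(idx)) {
    stop("Gene(s) not in matrix: ", paste(genes[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  a_idx <- match_gene(anchor, gene_ids(expr))
  if (is.na(a_idx)) {
    stop("Anchor '", anchor, "' not in matrix.", call. = FALSE)
  }
  vals <- expr$values[idx, , drop = FALSE]
  ranks <- t(apply(vals, 1, rank))
  keep <- apply(ranks, 1, stats::sd) > 0
  ranks <- ranks[keep, , drop = FALSE]
  if (nrow(ranks) == 0) {
    stop("All clustering genes are constant across cells.", call. = FALSE)
  }
  z <- t(scale(t(ranks)))
  d <- stats::dist(t(z))
  hc <- stats::hclust(d, method = "ward.D2")

  sil_tbl <- NULL
  if (identical(k, "auto")) {
    ks <- 2:min(6, ncol(expr$values) - 1)
    sil <- vapply(ks, function(kk) {
      cl <- stats::cutree(hc, k = kk)
      if (length(unique(cl)) < 2) return(NA_real_)
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    sil_tbl <- tibble::tibble(k = ks, mean_silhouette = sil)
    k <- ks[which.max(sil)]
  }
  cl <- stats::cutree(hc, k = k)
  anchor_expr <- expr$values[a_idx, ]
  mean_by_cl <- tapply(anchor_expr, cl, mean)
  anchor_cluster <- as.integer(names(mean_by_cl)[which.max(mean_by_cl)])
  anchor_pos <- anchor_expr > 0
  frac <- if (any(anchor_pos)) {
    sum(anchor_pos & cl == anchor_cluster) / sum(anchor_pos)
  } else NA_real_
  structure(list(
    partition = tibble::tibble(cell = cell_ids(expr), cluster = unname(cl)),
    k = as.integer(k),
    anchor = gene_ids(expr)[a_idx],
    anchor_cell_cluster = anchor_cluster,
    fraction_anchor_in_cluster = frac,
    hclust = hc,
    silhouette = sil_tbl,
    genes_used = rownames(ranks)
  ), class = "cell_clusters")
}

#' @export
print.cell_clusters <- function(x, ...) {
  cat(sprintf("<cell_clusters> %d cells in %d clusters on %d genes\n",
              nrow(x$partition), x$k, length(x$genes_used)))
  cat(sprintf("anchor cluster %d holds %.1f%% of %s-detected cells\n",
              x$anchor_cell_cluster, 100 * x$fraction_anchor_in_cluster,
              x$anchor))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cell_clusters <- function(x, ...) x$partition

#' @exportS3Method generics::glance
glance.cell_clusters <- function(x, ...) {
  tibble::tibble(k = x$k,
                 anchor_cell_cluster = x$anchor_cell_cluster,
                 fraction_anchor_in_cluster = x$fraction_anchor_in_cluster,
                 n_genes_used = length(x$genes_used))
}
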