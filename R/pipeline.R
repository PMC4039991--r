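#' Build or read a pipeline run configuration
#'
#' A run configuration is a plain named list with per-stage blocks
#' (`screen`, `proliferation`), a root `seed`, and an `output_dir`. Each
#' stage names either real input paths (`expression`, `annotation`,
#' `sample_sheet`) or a `synthetic` sub-block — never both.
#'
#' @param path Path to a YAML configuration file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A configuration list built in R.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$output_dir)) {
    stop("Config must set `output_dir`.", call. = FALSE)
  }
  for (stage in c("screen", "proliferation")) {
    blk <- config[[stage]]
    if (is.null(blk)) next
    real <- switch(stage,
                   screen = !is.null(blk$expression),
                   proliferation = !is.null(blk$sample_sheet))
    synth <- !is.null(blk$synthetic)
    if (real && synth) {
      stop("Stage '", stage, "' sets both real input paths and a synthetic ",
           "spec; choose exactly one.", call. = FALSE)
    }
    if (!real && !synth) {
      stop("Stage '", stage, "' sets neither input paths nor a synthetic ",
           "spec.", call. = FALSE)
    }
  }
  config
}

# named per-stage substreams derived from the root seed so stages can be
# rerun alone and still reproduce
stage_seed <- function(root_seed, stage) {
  offsets <- c(screen = 1000L, proliferation = 2000L, demo = 3000L)
  (as.integer(root_seed) * 7L + offsets[[stage]]) %% 2147483647L
}

#' Run the anchor-screen pipeline stage
#'
#' Executes load (or generate) -> anchor screen -> surface-marker
#' nomination -> gene-correlation clustering -> cell clustering, writing
#' every artifact plus a manifest recording inputs, seed, thresholds and
#' package version. Identical (config, seed) pairs produce byte-identical
#' outputs.
#'
#' @param config A run configuration (list or path; see
#'   [read_run_config()]).
#' @return List of results (`screen`, `markers`, `gene_modules`,
#'   `cell_clusters`, `paths`), invisibly.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  blk <- config$screen
  if (is.null(blk)) stop("Config has no `screen` block.", call. = FALSE)
  out_dir <- file.path(config$output_dir, "screen")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seed <- stage_seed(config$seed, "screen")

  scfg_args <- blk$screen_config %||% list()
  scfg <- do.call(screen_config, scfg_args)
  say("screen: thresholds rho > %g (screen), |rho| beyond %g (cell clustering), min_detected_cells = %d, p_method = %s",
      scfg$screen_threshold, scfg$cell_cluster_threshold,
      scfg$min_detected_cells, scfg$p_method)

  annotation <- NULL
  if (!is.null(blk$synthetic)) {
    gen_args <- blk$synthetic
    gen_args$seed <- seed
    gen_args$anchor_gene <- scfg$anchor_gene
    cfg <- do.call(synthetic_config, gen_args)
    say("screen: generating synthetic matrix (%d cells, %d+1 module genes, %d background, seed %d)",
        cfg$n_cells, cfg$module_genes, cfg$background_genes, seed)
    sim <- generate_single_cell_matrix(cfg)
    expr <- sim$expr
    annotation <- sim$annotation
  } else {
    say("screen: reading expression from %s", blk$expression)
    expr <- read_expression_table(blk$expression,
                                  layout = blk$layout %||% "genes_in_rows")
    if (!is.null(blk$annotation)) {
      annotation <- read_gene_annotation(blk$annotation)
    }
  }

  screen <- anchor_screen(expr, annotation = annotation, config = scfg)
  write_report(screen, file.path(out_dir, "screen"))
  markers <- nominate_surface_markers(screen)
  write_report(markers, file.path(out_dir, "surface_markers"))

  corr_genes <- unique(c(screen$anchor, screen$cell_cluster_genes))
  modules <- NULL
  cells <- NULL
  if (length(corr_genes) >= 2) {
    corr <- gene_correlation_matrix(expr, corr_genes)
    mat_df <- data.frame(gene = rownames(corr), fmt_num(corr),
                         check.names = FALSE, stringsAsFactors = FALSE)
    colnames(mat_df) <- c("gene", colnames(corr))
    utils::write.table(mat_df, file.path(out_dir, "correlation_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    modules <- cluster_genes(corr, screen$anchor,
                             threshold = scfg$screen_threshold)
    write_report(modules, file.path(out_dir, "gene_modules"))
    write_dendrogram_newick(modules, file.path(out_dir, "gene_dendrogram.nwk"))
    say("screen: anchor module holds %d gene(s)", length(modules$anchor_module))
  } else {
    say("screen: fewer than 2 high-correlation genes; clustering skipped")
  }
  if (length(screen$cell_cluster_genes) >= 1 && ncol(expr$values) >= 4) {
    cells <- cluster_cells(expr, screen$cell_cluster_genes, screen$anchor)
    write_report(cells, file.path(out_dir, "cell_clusters"))
    say("screen: %d cell clusters; anchor cluster captures %.1f%% of anchor+ cells",
        cells$k, 100 * cells$fraction_anchor_in_cluster)
  }

  manifest <- list(
    stage = "screen",
    seed = seed,
    root_seed = config$seed,
    package_version = as.character(utils::packageVersion("steroidscreen")),
    inputs = if (!is.null(blk$synthetic)) list(synthetic = blk$synthetic)
             else list(expression = blk$expression,
                       annotation = blk$annotation),
    thresholds = list(screen_threshold = scfg$screen_threshold,
                      cell_cluster_threshold = scfg$cell_cluster_threshold,
                      min_detected_cells = scfg$min_detected_cells,
                      fdr_alpha = scfg$fdr_alpha)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(screen = screen, markers = markers, gene_modules = modules,
                 cell_clusters = cells, paths = out_dir))
}

#' Run the proliferation / suppression-assay pipeline stage
#'
#' Loads (or generates) dye-dilution samples, deconvolves generations,
#' computes per-replicate division indices, and quantifies suppression
#' against the reference condition, writing artifacts and a manifest.
#'
#' @param config A run configuration (list or path).
#' @return List of results (`assay`, `paths`), invisibly.
#' @export
run_proliferation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  blk <- config$proliferation
  if (is.null(blk)) stop("Config has no `proliferation` block.", call. = FALSE)
  out_dir <- file.path(config$output_dir, "proliferation")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seed <- stage_seed(config$seed, "proliferation")
  max_gen <- blk$max_generations %||% 8

  if (!is.null(blk$synthetic)) {
    sp <- blk$synthetic
    targets <- unlist(sp$di_by_condition)
    say("proliferation: generating synthetic assay (%s; %d replicates, jitter sd %g, seed %d)",
        paste(sprintf("%s=%g", names(targets), targets), collapse = ", "),
        sp$replicates %||% 3, sp$jitter_sd %||% 0.05, seed)
    sim <- generate_suppression_experiment(
      targets,
      replicates = sp$replicates %||% 3,
      jitter_sd = sp$jitter_sd %||% 0.05,
      n_events = sp$n_events %||% 5000,
      sigma = sp$sigma %||% 0.15,
      max_generations = sp$max_generations %||% 6,
      seed = seed)
    samples <- sim$samples
    reference <- blk$reference_condition %||% names(targets)[1]
  } else {
    say("proliferation: reading sample sheet %s", blk$sample_sheet)
    samples <- read_sample_sheet(blk$sample_sheet)
    reference <- blk$reference_condition
    if (is.null(reference)) {
      stop("Proliferation block must set `reference_condition`.",
           call. = FALSE)
    }
  }
  assay <- suppression_assay(samples, reference_condition = reference,
                             max_generations = max_gen)
  say("proliferation: reference '%s'; conditions: %s", reference,
      paste(sprintf("%s DI %.3f (suppression %.1f%%)",
                    assay$summary$condition, assay$summary$mean_di,
                    assay$summary$percent_suppression), collapse = "; "))
  write_report(assay, file.path(out_dir, "suppression_assay"))

  manifest <- list(
    stage = "proliferation",
    seed = seed,
    root_seed = config$seed,
    package_version = as.character(utils::packageVersion("steroidscreen")),
    inputs = if (!is.null(blk$synthetic)) list(synthetic = blk$synthetic)
             else list(sample_sheet = blk$sample_sheet),
    parameters = list(reference_condition = reference,
                      max_generations = max_gen)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(assay = assay, paths = out_dir))
}

#' Run the built-in demonstration pipeline
#'
#' Generates synthetic single-cell and suppression-assay data with the
#' default study-scale parameters and runs both pipeline stages into
#' `output_dir`. Deterministic under (config, seed).
#'
#' @param output_dir Output directory.
#' @param seed Root seed (default 1).
#' @return List with both stages' results, invisibly.
#' @export
run_demo <- function(output_dir, seed = 1) {
  config <- demo_config(output_dir, seed)
  screen_res <- run_screen(config)
  prolif_res <- run_proliferation(config)
  invisible(list(screen = screen_res, proliferation = prolif_res,
                 config = config))
}

#' The demonstration run configuration
#' @param output_dir Output directory.
#' @param seed Root seed.
#' @return A configuration list accepted by [run_screen()] and
#'   [run_proliferation()].
#' @export
demo_config <- function(output_dir, seed = 1) {
  list(
    seed = seed,
    output_dir = output_dir,
    screen = list(
      synthetic = list(n_cells = 91, module_genes = 10,
                       background_genes = 150),
      screen_config = list(anchor_gene = "Cyp11a1")
    ),
    proliferation = list(
      synthetic = list(
        di_by_condition = list(responder_alone = 2.17,
                               coculture_Ly6Cpos = 1.17,
                               coculture_Ly6Cneg = 2.1),
        replicates = 3, jitter_sd = 0.05, n_events = 2000),
      reference_condition = "responder_alone"
    )
  )
}
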