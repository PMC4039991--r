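#' Configuration for the single-cell synthetic-data generator
#'
#' Defaults mirror the scale of the motivating study purely as fixture
#' flavour: 91 cells split 52/39 across the G4P / G2N FACS gates, a
#' 30% anchor-positive subpopulation, a 10-gene module rank-correlated at
#' 0.5 with the anchor over 500 independent background genes, and ~30%
#' dropout at the average expression level.
#'
#' @param n_cells Number of cells (default 91).
#' @param gate_split Named counts per gate label summing to `n_cells`
#'   (default `c(G4P = 52, G2N = 39)`; rescaled proportionally if
#'   `n_cells` differs from their sum).
#' @param subpop_fraction Fraction of cells in the anchor-positive
#'   subpopulation (default 0.3).
#' @param module_genes Number of planted module genes besides the anchor
#'   (default 10).
#' @param module_rho Target pairwise Spearman correlation of the copula
#'   block (default 0.5).
#' @param background_genes Number of independent background genes
#'   (default 500).
#' @param dropout_rate Excess-zero probability at the average gene mean
#'   (default 0.3); per-gene rates follow a logistic curve in the gene
#'   mean with slope `dropout_slope`.
#' @param dropout_slope Logistic slope of dropout vs gene mean
#'   (default 0.5 per log2 unit).
#' @param subpop_shift Log2 mean shift of anchor/module genes inside the
#'   subpopulation (default 7; with the off-state baseline below zero the
#'   anchor is essentially undetected outside the subpopulation, as for an
#'   on/off steroidogenic population).
#' @param module_base_mean,module_sd Off-state latent log2 mean and sd of
#'   anchor/module genes outside the subpopulation (defaults -2 and 1.5;
#'   the negative baseline is mostly truncated to zero).
#' @param background_mean_range,background_sd Uniform range for background
#'   gene means and their sd (defaults `c(2, 8)` and 1.5).
#' @param anchor_gene Anchor gene symbol (default `"Cyp11a1"`).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 91,
                             gate_split = c(G4P = 52, G2N = 39),
                             subpop_fraction = 0.3,
                             module_genes = 10,
                             module_rho = 0.5,
                             background_genes = 500,
                             dropout_rate = 0.3,
                             dropout_slope = 0.5,
                             subpop_shift = 7,
                             module_base_mean = -2,
                             module_sd = 1.5,
                             background_mean_range = c(2, 8),
                             background_sd = 1.5,
                             anchor_gene = "Cyp11a1",
                             seed = 1) {
  stopifnot(n_cells > 0, module_genes > 0, background_genes >= 0,
            subpop_fraction > 0, subpop_fraction < 1,
            module_rho >= 0, module_rho < 1,
            dropout_rate >= 0, dropout_rate < 1)
  if (sum(gate_split) != n_cells) {
    g4 <- round(n_cells * gate_split[1] / sum(gate_split))
    gate_split <- stats::setNames(c(g4, n_cells - g4), names(gate_split))
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic single-cell expression matrix with planted truth
#'
#' Draws a latent Gaussian copula in which the anchor and module genes form
#' an equicorrelated block whose latent Pearson correlation
#' `r = 2 * sin(pi * rho_S / 6)` is chosen to hit the requested Spearman
#' correlation; maps latents to a truncated log-normal marginal on the
#' log2 scale; shifts anchor/module means upward inside the planted
#' subpopulation; and finally applies excess zeros (dropout) with a
#' per-gene probability logistic in the gene mean. Background genes are
#' independent. Bit-reproducible under the config seed.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `$expr` ([expr_matrix()] with gate labels in
#'   `cell_meta`), `$truth` (`$genes`: gene, in_module; `$cells`: cell,
#'   in_subpop, gate_label), and `$annotation` (a [gene_annotation()]
#'   assigning demo categories over module and background genes).
#' @export
generate_single_cell_matrix <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  k <- cfg$module_genes + 1  # anchor + module
  r <- 2 * sin(pi * cfg$module_rho / 6)
  if (r >= 1 || r < 0) {
    stop("Requested module_rho gives a latent correlation outside [0, 1); ",
         "the anchor/module block would not be positive definite.",
         call. = FALSE)
  }
  with_local_seed(cfg$seed, {
    n <- cfg$n_cells
    cells <- sprintf("cell%03d", seq_len(n))
    subpop <- rep(FALSE, n)
    subpop[sample.int(n, round(cfg$subpop_fraction * n))] <- TRUE

    # equicorrelated latent block via a shared factor
    f <- stats::rnorm(n)
    z_block <- sqrt(r) * matrix(f, nrow = k, ncol = n, byrow = TRUE) +
      sqrt(1 - r) * matrix(stats::rnorm(k * n), nrow = k)
    module_names <- c(cfg$anchor_gene,
                      sprintf("Mod%02d", seq_len(cfg$module_genes)))
    x_block <- cfg$module_base_mean +
      cfg$subpop_shift * matrix(subpop, nrow = k, ncol = n, byrow = TRUE) +
      cfg$module_sd * z_block

    bg_names <- if (cfg$background_genes > 0) {
      sprintf("Bg%03d", seq_len(cfg$background_genes))
    } else character(0)
    bg_means <- stats::runif(cfg$background_genes,
                             cfg$background_mean_range[1],
                             cfg$background_mean_range[2])
    x_bg <- bg_means + cfg$background_sd *
      matrix(stats::rnorm(cfg$background_genes * n),
             nrow = cfg$background_genes)

    x <- pmax(rbind(x_block, x_bg), 0)
    rownames(x) <- c(module_names, bg_names)
    colnames(x) <- cells

    # excess zeros, probability logistic in the gene's expressed-state
    # mean (for bimodal module genes the on-state level is what governs
    # detectability, so that, not the population average, is used)
    nominal_mean <- c(rep(cfg$module_base_mean + cfg$subpop_shift, k),
                      bg_means)
    if (cfg$dropout_rate > 0) {
      mu_ref <- mean(nominal_mean)
      p_drop <- stats::plogis(stats::qlogis(cfg$dropout_rate) -
                                cfg$dropout_slope * (nominal_mean - mu_ref))
      drop <- matrix(stats::runif(length(x)), nrow = nrow(x)) < p_drop
      x[drop] <- 0
    }

    gate <- rep(names(cfg$gate_split), times = cfg$gate_split)
    gate <- sample(gate)
    meta <- tibble::tibble(cell_id = cells, gate_label = gate)
    expr <- expr_matrix(x, cell_meta = meta)

    truth <- list(
      genes = tibble::tibble(gene = rownames(x),
                             in_module = rownames(x) %in% module_names &
                               rownames(x) != cfg$anchor_gene),
      cells = tibble::tibble(cell = cells, in_subpop = subpop,
                             gate_label = gate)
    )
    annotation <- synthetic_annotation(rownames(x), cfg$anchor_gene)
    list(expr = expr, truth = truth, annotation = annotation)
  })
}

# demo annotation: cycle categories over module genes so marker nomination
# has surface receptors to rank; background genes are "other"
synthetic_annotation <- function(genes, anchor) {
  module <- genes[startsWith(genes, "Mod")]
  cats <- rep(c("surface_receptor", "cytokine", "transcription_factor"),
              length.out = length(module))
  gene_annotation(tibble::tibble(
    gene = c(anchor, module),
    category = c("other", cats),
    is_suppressor = c(TRUE, cats == "cytokine")
  ))
}

#' Generate an archetypal condition-level FPKM table for pathway scoring
#'
#' Emits naive / Th1 / Th2 archetypes over the default steroidogenesis
#' pathway genes: naive has every pathway gene below the white threshold;
#' Th1 expresses cholesterol synthesis/uptake and transduceosome genes but
#' not Cyp11a1; Th2 expresses everything through Cyp11a1 while the
#' downstream branch enzymes stay off. Gaussian noise is truncated at 0.
#'
#' @param archetypes Named list `condition -> named FPKM vector`; the
#'   default transcribes the three archetypes above.
#' @param noise_sd Standard deviation of added truncated Gaussian noise
#'   (default 0).
#' @param seed Optional seed (only used when `noise_sd > 0`).
#' @param high,low FPKM levels used for "on" and "off" genes in the
#'   default archetypes (defaults 20 and 1).
#' @return An [expr_matrix()] (genes x conditions, FPKM).
#' @export
generate_pathway_table <- function(archetypes = NULL, noise_sd = 0,
                                   seed = NULL, high = 20, low = 1) {
  if (is.null(archetypes)) {
    pw <- default_steroidogenesis_pathway()
    genes <- unique(unlist(pw$steps$genes))
    upstream <- unique(unlist(pw$steps$genes[1:3]))  # synthesis/uptake/import
    archetypes <- list(
      naive = stats::setNames(rep(low, length(genes)), genes),
      Th1 = stats::setNames(ifelse(genes %in% upstream, high, low), genes),
      Th2 = stats::setNames(ifelse(genes %in% c(upstream, "Cyp11a1"),
                                   high, low), genes)
    )
  }
  if (any(unlist(archetypes) < 0)) {
    stop("Archetype expression levels must be non-negative.", call. = FALSE)
  }
  genes <- names(archetypes[[1]])
  m <- vapply(archetypes, function(a) a[genes], numeric(length(genes)))
  rownames(m) <- genes
  if (noise_sd > 0) {
    add_noise <- function() {
      pmax(m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m)), 0)
    }
    m <- if (!is.null(seed)) with_local_seed(seed, add_noise()) else add_noise()
  }
  expr_matrix(m)
}

#' Generate dye-dilution fluorescence events with known generations
#'
#' Each event's generation is drawn from `proportions`; its fluorescence is
#' `2^(g0_center - generation + Normal(0, sigma))`, i.e. log-normal peaks
#' at exact halving intervals.
#'
#' @param proportions Per-generation probabilities (generation 0 first),
#'   summing to 1.
#' @param g0_center Log2-fluorescence of the undivided peak (default 10).
#' @param sigma Peak width in log2 units (> 0, default 0.15).
#' @param n_events Number of events (default 5000).
#' @param seed Integer seed.
#' @param condition,replicate Labels for the emitted sample.
#' @return List with `$events` ([fluorescence_events()]) and `$truth`
#'   (tibble event, generation).
#' @export
generate_dye_dilution <- function(proportions, g0_center = 10, sigma = 0.15,
                                  n_events = 5000, seed = 1,
                                  condition = NA_character_,
                                  replicate = NA_character_) {
  if (sigma <= 0) stop("`sigma` must be positive.", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("`proportions` must be non-negative and sum to 1.", call. = FALSE)
  }
  with_local_seed(seed, {
    gen <- sample(seq_along(proportions) - 1L, n_events, replace = TRUE,
                  prob = proportions)
    values <- 2^(g0_center - gen + stats::rnorm(n_events, 0, sigma))
    list(events = fluorescence_events(values, condition = condition,
                                      replicate = replicate),
         truth = tibble::tibble(event = seq_len(n_events), generation = gen))
  })
}

# one-parameter geometric tilt over generations 0..G: p_i proportional to
# q^i, with q solved numerically so the division index of the family hits
# the target
tilt_proportions <- function(target_di, max_generations) {
  G <- max_generations
  if (target_di < 0 || target_di >= G) {
    stop(sprintf("Target DI %.3f is unreachable with max_generations = %d.",
                 target_di, G), call. = FALSE)
  }
  if (target_di == 0) return(c(1, rep(0, G)))
  di_of <- function(logq) {
    s <- exp(logq) / 2           # precursor weights are (q/2)^i
    w <- s^(0:G)
    sum((0:G) * w) / sum(w)
  }
  root <- stats::uniroot(function(lq) di_of(lq) - target_di,
                         lower = -30, upper = 30, tol = 1e-12)
  q <- exp(root$root)
  p <- q^(0:G)
  p / sum(p)
}

#' Generate a full synthetic suppression experiment
#'
#' For each condition and replicate, jitters the target division index,
#' builds a generation distribution achieving it from a one-parameter
#' geometric-tilt family, and emits dye-dilution events. Optionally writes
#' per-sample event files plus a sample sheet TSV.
#'
#' @param di_by_condition Named vector of target division indices, e.g.
#'   `c(responder_alone = 2.17, coculture_Ly6Cpos = 1.17)`.
#' @param replicates Replicates per condition (>= 2, default 3).
#' @param jitter_sd SD of the per-replicate jitter on the target DI
#'   (default 0.05).
#' @param g0_center,sigma,n_events Event-generation parameters.
#' @param max_generations Support of the generation distribution
#'   (default 6).
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, event files
#'   (`<condition>_<rep>.txt`) and `sample_sheet.tsv` are written there.
#' @return List with `$samples` (list of [fluorescence_events()]),
#'   `$sheet` (tibble condition, replicate, target_di[, file]), and
#'   `$truth` (per-sample true generation tibbles).
#' @export
generate_suppression_experiment <- function(di_by_condition, replicates = 3,
                                            jitter_sd = 0.05,
                                            g0_center = 10, sigma = 0.15,
                                            n_events = 5000,
                                            max_generations = 6, seed = 1,
                                            dir = NULL) {
  stopifnot(length(di_by_condition) >= 1, replicates >= 2,
            all(di_by_condition >= 0))
  conds <- names(di_by_condition)
  if (is.null(conds)) stop("`di_by_condition` must be named.", call. = FALSE)
  samples <- list()
  truth <- list()
  sheet <- list()
  with_local_seed(seed, {
    for (cond in conds) {
      for (rep_i in seq_len(replicates)) {
        target <- max(0, di_by_condition[[cond]] +
                        stats::rnorm(1, 0, jitter_sd))
        props <- tilt_proportions(target, max_generations)
        sub_seed <- sample.int(.Machine$integer.max, 1)
        sim <- generate_dye_dilution(props, g0_center = g0_center,
                                     sigma = sigma, n_events = n_events,
                                     seed = sub_seed, condition = cond,
                                     replicate = as.character(rep_i))
        id <- sprintf("%s_%d", cond, rep_i)
        samples[[id]] <- sim$events
        truth[[id]] <- sim$truth
        sheet[[id]] <- tibble::tibble(condition = cond,
                                      replicate = as.character(rep_i),
                                      target_di = target)
      }
    }
  })
  sheet <- dplyr::bind_rows(sheet)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(nrow(sheet))
    ids <- sprintf("%s_%s", sheet$condition, sheet$replicate)
    for (i in seq_along(ids)) {
      f <- file.path(dir, paste0(ids[i], ".txt"))
      writeLines(fmt_num(samples[[ids[i]]]$values), f)
      files[i] <- f
    }
    sheet$file <- basename(files)
    # analysis-facing files never carry planted truth: the sheet on disk
    # holds only file/condition/replicate, target DIs stay in memory
    utils::write.table(sheet[, c("file", "condition", "replicate")],
                       file.path(dir, "sample_sheet.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(samples = samples, sheet = sheet, truth = truth)
}

#' Read a suppression-assay sample sheet and its event files
#'
#' @param sheet_path Path to a TSV with columns `file`, `condition`,
#'   `replicate` (file paths relative to the sheet's directory).
#' @return List of [fluorescence_events()].
#' @export
read_sample_sheet <- function(sheet_path) {
  if (!file.exists(sheet_path)) {
    stop("File not found: ", sheet_path, call. = FALSE)
  }
  sheet <- utils::read.table(sheet_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  stopifnot(all(c("file", "condition", "replicate") %in% names(sheet)))
  base <- dirname(sheet_path)
  lapply(seq_len(nrow(sheet)), function(i) {
    path <- sheet$file[i]
    if (!file.exists(path)) path <- file.path(base, sheet$file[i])
    if (!file.exists(path)) {
      stop("Event file not found: ", sheet$file[i], call. = FALSE)
    }
    read_fluorescence_events(path, condition = sheet$condition[i],
                             replicate = as.character(sheet$replicate[i]))
  })
}
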