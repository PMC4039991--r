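#' Dye-dilution fluorescence events for one sample
#'
#' @param values Positive fluorescence intensities (arbitrary units), one
#'   per cell.
#' @param condition Condition label (e.g. `"responder_alone"`).
#' @param replicate Replicate identifier.
#' @return Object of class `fluor_events`.
#' @export
fluorescence_events <- function(values, condition = NA_character_,
                                replicate = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values) || any(values <= 0)) {
    stop("Fluorescence values must be positive and non-missing.",
         call. = FALSE)
  }
  structure(list(values = values,
                 condition = as.character(condition),
                 replicate = as.character(replicate)),
            class = "fluor_events")
}

#' @export
print.fluor_events <- function(x, ...) {
  cat(sprintf("<fluor_events> %d events (condition %s, replicate %s)\n",
              length(x$values), x$condition, x$replicate))
  invisible(x)
}

#' Read a single-column fluorescence event file
#' @param path Text/CSV file with one intensity per line (optional header
#'   line is skipped if non-numeric).
#' @param condition,replicate Labels attached to the sample.
#' @return A [fluorescence_events()] object.
#' @export
read_fluorescence_events <- function(path, condition = NA_character_,
                                     replicate = NA_character_) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  suppressWarnings(vals <- as.numeric(lines))
  if (length(vals) > 0 && is.na(vals[1])) {
    vals <- vals[-1]  # header
  }
  if (anyNA(vals)) {
    stop("Non-numeric event value in ", path, call. = FALSE)
  }
  fluorescence_events(vals, condition = condition, replicate = replicate)
}

#' Deconvolve dye-dilution fluorescence into cell generations
#'
#' Fits a one-dimensional Gaussian mixture to log2(fluorescence) with
#' component means fixed at `g0_center - i` for generations
#' `i = 0..max_generations` (the dye halves with every division, so peaks
#' are spaced exactly 1.0 apart in log2 units), a single shared free sigma,
#' and free weights, by EM. With `g0_center = "auto"` the undivided-peak
#' centre is chosen by maximum likelihood over the candidate grid
#' `mode + j` (`j = 0..max_generations`, capped at the brightest events),
#' where `mode` is the dominant kernel-density peak: the undivided peak can
#' be a tiny fraction of events in a fast-proliferating culture, so pure
#' peak-finding is not reliable. Events below `g0_center - max_generations - 0.5` (dye-negative
#' debris, out of model) are assigned to the last generation with a
#' warning.
#'
#' @param events A [fluorescence_events()] sample (>= 50 events).
#' @param g0_center Log2-fluorescence of the undivided peak, or `"auto"`.
#' @param max_generations Highest generation modelled (<= 10, default 8).
#' @param method `"em"` (soft posterior counts, default) or `"hard"`
#'   (nearest-mean assignment, midpoint ties to the lower generation).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return Object of class `generation_fit`: `$counts` (tibble generation,
#'   n), `$g0_center`, `$sigma`, plus fit diagnostics.
#' @export
assign_generations <- function(events, g0_center = "auto",
                               max_generations = 8,
                               method = c("em", "hard"),
                               max_iter = 500, tol = 1e-8) {
  method <- match.arg(method)
  stopifnot(inherits(events, "fluor_events"))
  if (max_generations > 10) {
    stop("`max_generations` must be <= 10.", call. = FALSE)
  }
  x <- log2(events$values)
  n <- length(x)
  if (n < 50) {
    stop("Need at least 50 events for generation deconvolution.",
         call. = FALSE)
  }
  if (identical(g0_center, "auto")) {
    g0_center <- locate_g0(x, max_generations, max_iter, tol)
  }
  stopifnot(is.numeric(g0_center), length(g0_center) == 1)

  floor_lim <- g0_center - max_generations - 0.5
  floored <- x < floor_lim
  if (any(floored)) {
    warning(sprintf(
      "%d event(s) below the autofluorescence floor (log2 < %.2f) assigned to generation %d.",
      sum(floored), floor_lim, max_generations), call. = FALSE)
  }
  xf <- x[!floored]
  mu <- g0_center - (0:max_generations)
  G <- length(mu)

  if (method == "hard") {
    # distance to each fixed mean; ties at midpoints go to the lower
    # (brighter) generation because which.min takes the first minimum
    gen <- apply(abs(outer(xf, mu, "-")), 1, which.min) - 1L
    counts <- tabulate(gen + 1L, nbins = G)
    resid <- xf - mu[gen + 1L]
    sigma <- stats::sd(resid)
    ll <- NA_real_
    iter <- 0L
  } else {
    fit <- em_fixed_means(xf, mu, max_iter = max_iter, tol = tol)
    if (!fit$converged) {
      stop(structure(class = c("steroidscreen_em_failure", "error", "condition"),
                     list(message = sprintf(
                       "EM did not converge after %d iterations (loglik %.4f, sigma %.4f).",
                       fit$iterations, fit$loglik, fit$sigma), call = NULL)))
    }
    sigma <- fit$sigma
    ll <- fit$loglik
    iter <- fit$iterations
    counts <- fit$weights * length(xf)
  }
  counts[G] <- counts[G] + sum(floored)
  structure(list(
    counts = tibble::tibble(generation = 0:max_generations, n = as.numeric(counts)),
    g0_center = g0_center,
    sigma = sigma,
    n_events = n,
    n_floored = sum(floored),
    method = method,
    loglik = if (method == "em") ll else NA_real_,
    iterations = iter,
    condition = events$condition,
    replicate = events$replicate
  ), class = "generation_fit")
}

# undivided-peak centre: anchor the generation grid at the dominant
# kernel-density mode, then slide it brighter one division at a time and
# keep the offset with the best mixture likelihood (near-ties resolve to
# the dimmest candidate, i.e. the brightest events are generation 0)
locate_g0 <- function(log2_values, max_generations, max_iter = 200,
                      tol = 1e-6) {
  d <- stats::density(log2_values, n = 1024)
  mode <- d$x[which.max(d$y)]
  cands <- mode + 0:max_generations
  cands <- cands[cands <= max(log2_values) + 0.5]
  if (length(cands) == 1) return(cands)
  ll <- vapply(cands, function(g0) {
    em_fixed_means(log2_values, g0 - (0:max_generations),
                   max_iter = max_iter, tol = tol)$loglik
  }, numeric(1))
  best <- max(ll)
  min(cands[ll >= best - 1e-6 * (abs(best) + 1)])
}

# EM for a 1-D Gaussian mixture with fixed component means and shared sigma
em_fixed_means <- function(x, mu, max_iter = 500, tol = 1e-8) {
  G <- length(mu)
  w <- rep(1 / G, G)
  sigma <- max(stats::sd(x) / 2, 0.05)
  ll_old <- -Inf
  ll <- -Inf
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    dens <- vapply(seq_len(G), function(i) {
      w[i] * stats::dnorm(x, mu[i], sigma)
    }, numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    resp <- dens / tot
    ll <- sum(log(tot))
    w <- colMeans(resp)
    sigma <- sqrt(sum(resp * (outer(x, mu, "-"))^2) / length(x))
    sigma <- max(sigma, 1e-4)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, sigma = sigma, loglik = ll, iterations = iter,
       converged = converged)
}

#' @export
print.generation_fit <- function(x, ...) {
  cat(sprintf("<generation_fit> %d events, g0 = %.2f, sigma = %.3f (%s)\n",
              x$n_events, x$g0_center, x$sigma, x$method))
  print(x$counts, n = nrow(x$counts))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.generation_fit <- function(x, ...) {
  dplyr::mutate(x$counts, proportion = .data$n / sum(.data$n))
}

#' @exportS3Method ggplot2::autoplot
autoplot.generation_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "generation", y = "proportion of events") +
    ggplot2::theme_minimal()
}

#' Division index from generation counts
#'
#' The division index is the average number of divisions that a cell of
#' the starting population has undergone. Each generation-`i` cohort of
#' `n_i` cells arose from `n_i / 2^i` precursors, so
#' `DI = sum(i * n_i / 2^i) / sum(n_i / 2^i)`.
#'
#' @param counts A [assign_generations()] result, or a bare non-negative
#'   numeric vector of counts per generation starting at generation 0.
#' @return Object of class `division_index` with `$di` and per-generation
#'   `$precursors`.
#' @export
division_index <- function(counts) {
  condition <- NA_character_
  replicate <- NA_character_
  if (inherits(counts, "generation_fit")) {
    condition <- counts$condition
    replicate <- counts$replicate
    n <- counts$counts$n
  } else {
    n <- as.numeric(counts)
  }
  if (length(n) == 0 || anyNA(n) || any(n < 0)) {
    stop("Generation counts must be non-negative numbers.", call. = FALSE)
  }
  if (sum(n) == 0) {
    stop("All generation counts are zero; division index undefined.",
         call. = FALSE)
  }
  gens <- seq_along(n) - 1
  precursors <- n / 2^gens
  di <- sum(gens * precursors) / sum(precursors)
  structure(list(
    di = di,
    precursors = tibble::tibble(generation = gens, n = n,
                                precursors = precursors),
    condition = condition,
    replicate = replicate
  ), class = "division_index")
}

#' @export
print.division_index <- function(x, ...) {
  cat(sprintf("<division_index> DI = %.4f\n", x$di))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.division_index <- function(x, ...) {
  tibble::tibble(condition = x$condition, replicate = x$replicate,
                 di = x$di, n_cells = sum(x$precursors$n))
}

#' @exportS3Method generics::tidy
tidy.division_index <- function(x, ...) x$precursors

#' Quantify a suppression assay across conditions
#'
#' Runs generation deconvolution and division-index computation on every
#' sample, summarises replicate division indices per condition, expresses
#' suppression relative to the reference (responder-alone) condition as
#' `100 * (1 - DI_cond / DI_ref)` percent, and compares each condition to
#' the reference with a classic equal-variance unpaired two-tailed t test
#' (Welch's form available via `var_equal = FALSE`).
#'
#' @param samples List of [fluorescence_events()] with condition and
#'   replicate labels set.
#' @param reference_condition Condition label of the responder-alone
#'   reference (>= 2 replicates required).
#' @param g0_center,max_generations,method Passed to
#'   [assign_generations()].
#' @param var_equal Use the classic equal-variance t statistic (default
#'   `TRUE`).
#' @return Object of class `suppression_assay`: `$summary` (condition,
#'   n_replicates, mean_di, sd_di, percent_suppression, p_value) and
#'   `$replicates` (per-sample division indices). Conditions with a single
#'   replicate get `p_value = NA` with a warning.
#' @export
suppression_assay <- function(samples, reference_condition,
                              g0_center = "auto", max_generations = 8,
                              method = "em", var_equal = TRUE) {
  stopifnot(is.list(samples), length(samples) > 0)
  reps <- purrr::map_dfr(samples, function(s) {
    stopifnot(inherits(s, "fluor_events"))
    fit <- assign_generations(s, g0_center = g0_center,
                              max_generations = max_generations,
                              method = method)
    tibble::tibble(condition = s$condition, replicate = s$replicate,
                   di = division_index(fit)$di)
  })
  if (!reference_condition %in% reps$condition) {
    stop("Reference condition '", reference_condition,
         "' is absent from the samples.", call. = FALSE)
  }
  ref_di <- reps$di[reps$condition == reference_condition]
  if (length(ref_di) < 2) {
    stop("Reference condition needs at least 2 replicates.", call. = FALSE)
  }
  conds <- unique(reps$condition)
  summary <- purrr::map_dfr(conds, function(cond) {
    di <- reps$di[reps$condition == cond]
    p <- NA_real_
    if (cond == reference_condition) {
      p <- NA_real_
    } else if (length(di) < 2) {
      warning("Condition '", cond,
              "' has a single replicate; p value unavailable.", call. = FALSE)
    } else {
      # degenerate case: both groups constant (e.g. literally duplicated
      # samples) has no defined t statistic; report p = NA rather than fail
      p <- tryCatch(
        stats::t.test(di, ref_di, var.equal = var_equal,
                      alternative = "two.sided")$p.value,
        error = function(e) NA_real_)
    }
    tibble::tibble(
      condition = cond,
      n_replicates = length(di),
      mean_di = mean(di),
      sd_di = if (length(di) > 1) stats::sd(di) else NA_real_,
      percent_suppression = 100 * (1 - mean(di) / mean(ref_di)),
      p_value = p
    )
  })
  structure(list(summary = summary, replicates = reps,
                 reference_condition = reference_condition,
                 var_equal = var_equal),
            class = "suppression_assay")
}

#' @export
print.suppression_assay <- function(x, ...) {
  cat(sprintf("<suppression_assay> reference = %s\n", x$reference_condition))
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.suppression_assay <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.suppression_assay <- function(x, ...) {
  tibble::tibble(reference_condition = x$reference_condition,
                 n_conditions = nrow(x$summary),
                 n_samples = nrow(x$replicates))
}

#' @exportS3Method ggplot2::autoplot
autoplot.suppression_assay <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean_di)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_di - .data$sd_di,
                                        ymax = .data$mean_di + .data$sd_di),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(data = object$replicates,
                        ggplot2::aes(y = .data$di), colour = "black") +
    ggplot2::labs(x = NULL, y = "division index") +
    ggplot2::theme_minimal()
}

#' Per-sample log2 histogram table for export
#' @param events A [fluorescence_events()] sample.
#' @param binwidth Bin width in log2 units (default 0.1).
#' @return Tibble with bin edges (log2 units) and event counts.
#' @export
fluorescence_histogram <- function(events, binwidth = 0.1) {
  stopifnot(inherits(events, "fluor_events"))
  x <- log2(events$values)
  breaks <- seq(floor(min(x) / binwidth) * binwidth,
                ceiling(max(x) / binwidth) * binwidth + binwidth,
                by = binwidth)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  tibble::tibble(bin_lo = h$breaks[-length(h$breaks)],
                 bin_hi = h$breaks[-1], count = h$counts)
}
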