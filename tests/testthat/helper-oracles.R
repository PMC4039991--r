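# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ranks are built by explicit sorting with tie
# averaging, Pearson from the raw sum formula, and division indices by
# enumerating precursor cohorts one generation at a time.

# tie-averaged ranks via sorting, no call to rank()
oracle_ranks <- function(v) {
  n <- length(v)
  ord <- order(v)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)  # positions i..j share the averaged rank
    i <- j + 1
  }
  r
}

# Pearson from raw sums
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_ranks(x), oracle_ranks(y))
}

# division index by explicit precursor enumeration: each generation-i
# cohort is halved back i times to its founding precursors, then the
# average generation is taken weighted by precursor count
oracle_division_index <- function(counts) {
  cohorts <- data.frame(generation = seq_along(counts) - 1, n = counts)
  cohorts$precursors <- cohorts$n
  for (row in seq_len(nrow(cohorts))) {
    g <- cohorts$generation[row]
    if (g > 0) {
      for (h in seq_len(g)) {
        cohorts$precursors[row] <- cohorts$precursors[row] / 2
      }
    }
  }
  stats::weighted.mean(cohorts$generation, cohorts$precursors)
}

# random vectors used for spearman equivalence: mixes continuous,
# tie-heavy (small integer) and zero-inflated shapes
random_paired_vectors <- function(n) {
  kind <- sample(c("continuous", "ties", "zero_inflated"), 1)
  switch(kind,
    continuous = list(x = rnorm(n), y = rnorm(n)),
    ties = list(x = sample(0:4, n, replace = TRUE) + 0,
                y = sample(0:3, n, replace = TRUE) + 0),
    zero_inflated = {
      x <- rlnorm(n)
      y <- 0.5 * x + rlnorm(n)
      x[runif(n) < 0.4] <- 0
      y[runif(n) < 0.4] <- 0
      list(x = x, y = y)
    })
}

# regenerate a non-constant pair if needed
random_noncconstant_pair <- function(n) {
  repeat {
    p <- random_paired_vectors(n)
    if (length(unique(p$x)) > 1 && length(unique(p$y)) > 1) return(p)
  }
}

# adjusted Rand index between two labellings (external oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# md5 digest of every file under a directory, named by relative path
dir_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  h
}
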