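test_that("spearman_rho agrees with hand-computed and oracle values", {
  x <- c(2, 5, 1, 9, 4)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  expect_equal(spearman_rho(sort(x), rev(sort(x)))$rho, -1)

  # frozen value computed by the explicit tie-averaging oracle:
  # ranks x = (1, 2.5, 2.5, 4), ranks y = (2, 1, 3.5, 3.5) -> rho = 0.5
  r <- spearman_rho(c(1, 2, 2, 4), c(3, 1, 4, 4))
  expect_equal(r$rho, 0.5)
  expect_equal(r$rho, oracle_spearman(c(1, 2, 2, 4), c(3, 1, 4, 4)))

  set.seed(101)
  for (i in 1:50) {
    p <- random_noncconstant_pair(sample(3:50, 1))
    expect_equal(spearman_rho(p$x, p$y)$rho, oracle_spearman(p$x, p$y),
                 tolerance = 1e-12)
  }
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rlnorm(40)
  y <- 0.3 * x + rlnorm(40)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(log(x), y)$rho, base)
  expect_equal(spearman_rho(x, y^3)$rho, base)
  expect_equal(spearman_rho(exp(x), 5 * y + 2)$rho, base)
})

test_that("spearman_rho rejects degenerate input with a typed condition", {
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "steroidscreen_constant_input")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_error(spearman_rho(1:4, 1:3), "equal length")
})

test_that("asymptotic and permutation p values broadly agree", {
  set.seed(21)
  x <- rnorm(60)
  y <- 0.5 * x + rnorm(60)
  pa <- spearman_rho(x, y, p_method = "asymptotic")$p
  pp <- spearman_rho(x, y, p_method = "permutation",
                     n_permutations = 2000, seed = 5)$p
  expect_lt(abs(log10(max(pa, 5e-4)) - log10(max(pp, 5e-4))), 1)
  # permutation p is reproducible under its seed
  pp2 <- spearman_rho(x, y, p_method = "permutation",
                      n_permutations = 2000, seed = 5)$p
  expect_identical(pp, pp2)
})

test_that("anchor screen ranks a duplicated anchor first and records exclusions", {
  set.seed(3)
  n <- 30
  a <- c(rlnorm(20), rep(0, 10))
  m <- rbind(Cyp11a1 = a,
             Twin = a,                       # identical to the anchor
             Noise = rlnorm(n),
             Flat = rep(2, n),               # constant -> excluded
             Rare = c(1, 2, rep(0, n - 2)))  # detected in 2 < 3 cells
  colnames(m) <- sprintf("c%02d", 1:n)
  scr <- anchor_screen(expr_matrix(m))
  expect_equal(scr$records$gene[1], "Twin")
  expect_equal(scr$records$rho[1], 1)
  expect_setequal(scr$excluded$gene, c("Flat", "Rare"))
  expect_equal(scr$excluded$reason[scr$excluded$gene == "Flat"], "constant")
  expect_equal(scr$excluded$reason[scr$excluded$gene == "Rare"],
               "too_few_detected_cells")
  expect_false(scr$anchor %in% scr$records$gene)
})

test_that("anchor screen recovers a planted module and orders records deterministically", {
  sim <- generate_single_cell_matrix(synthetic_config(n_cells = 200, seed = 42))
  scr <- anchor_screen(sim$expr, sim$annotation)
  planted <- sim$truth$genes$gene[sim$truth$genes$in_module]
  expect_gte(length(intersect(scr$screened_genes, planted)), 9)

  # record order is a pure function of (rho desc, gene symbol)
  expect_equal(scr$records,
               dplyr::arrange(scr$records, dplyr::desc(rho), gene))
  # threshold set algebra
  expect_setequal(intersect(scr$cell_cluster_genes, scr$screened_genes),
                  scr$records$gene[scr$records$rho > 0.35])
  expect_setequal(scr$screened_genes,
                  scr$records$gene[scr$records$rho > 0.3])

  # invariance under cell-column permutation
  set.seed(9)
  perm <- sample(ncol(sim$expr$values))
  expr_p <- expr_matrix(sim$expr$values[, perm])
  scr_p <- anchor_screen(expr_p, sim$annotation)
  expect_equal(scr_p$records, scr$records)
})

test_that("a null matrix yields screen hits consistent with the null tail", {
  set.seed(77)
  n_cells <- 200
  n_genes <- 500
  m <- matrix(rlnorm(n_genes * n_cells), nrow = n_genes,
              dimnames = list(c("Cyp11a1", sprintf("G%03d", 2:n_genes)),
                              sprintf("c%03d", 1:n_cells)))
  scr <- anchor_screen(expr_matrix(m))
  # Monte-Carlo null tail of rho > 0.3 at this n
  null_rho <- replicate(400, cor(sample(n_cells), sample(n_cells),
                                 method = "spearman"))
  p_tail <- mean(null_rho > 0.3)
  expected <- (n_genes - 1) * p_tail
  bound <- expected + 3 * sqrt(max(expected, 1)) + 1
  expect_lte(length(scr$screened_genes), bound)
  # and essentially nothing survives FDR control
  expect_lte(sum(scr$records$q <= 0.05), 1)
})

test_that("anchor screen errors clearly when the anchor is unusable", {
  m <- matrix(rlnorm(40), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"), sprintf("c%02d", 1:10)))
  expect_error(anchor_screen(expr_matrix(m)), "Cyp11a1.*not found")
  m2 <- rbind(m, Cyp11a1 = rep(1, 10))
  expect_error(anchor_screen(expr_matrix(m2)), "Cyp11a1.*constant")
})

test_that("surface-marker nomination reproduces the expected ranking", {
  # Ly6C2 carries the strongest surface-receptor correlation, Ly6C1 sits
  # fourth once three stronger surface genes are inserted above it
  set.seed(5)
  n <- 80
  a <- rlnorm(n)
  make_gene <- function(strength) strength * a + rnorm(n, sd = 0.5)
  m <- rbind(Cyp11a1 = a,
             Ly6C2 = make_gene(2.0),
             SurfA = make_gene(1.4), SurfB = make_gene(1.2),
             Ly6C1 = make_gene(0.8),
             Il10 = make_gene(1.8),
             Bg1 = rnorm(n, 10), Bg2 = rnorm(n, 10))
  m <- pmax(m, 0)
  colnames(m) <- sprintf("c%02d", 1:n)
  ann <- gene_annotation(tibble::tibble(
    gene = c("Ly6C2", "SurfA", "SurfB", "Ly6C1", "Il10"),
    category = c(rep("surface_receptor", 4), "cytokine")))
  scr <- anchor_screen(expr_matrix(m), ann)
  markers <- nominate_surface_markers(scr)
  expect_equal(markers$gene[1], "Ly6C2")
  expect_equal(which(markers$gene == "Ly6C1"), 4L)
  expect_false("Il10" %in% markers$gene)
  expect_equal(markers$rho, sort(markers$rho, decreasing = TRUE))

  # no surface receptors annotated -> empty nomination, no error
  scr2 <- anchor_screen(expr_matrix(m))
  expect_equal(nrow(nominate_surface_markers(scr2)), 0L)
})

test_that("gene correlation matrix matches a brute-force pairwise loop", {
  m <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("up", "down"), sprintf("c%d", 1:4)))
  corr <- gene_correlation_matrix(expr_matrix(m))
  expect_equal(corr["up", "down"], -1)

  dup <- rbind(m, up2 = m[1, ])
  rownames(dup) <- c("up", "down", "up2")
  corr2 <- gene_correlation_matrix(expr_matrix(dup))
  expect_equal(corr2["up", "up2"], 1)

  set.seed(13)
  r <- matrix(rlnorm(100), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%02d", 1:20)))
  r[r < 0.5] <- 0
  corr3 <- gene_correlation_matrix(expr_matrix(r))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(corr3[i, j], oracle_spearman(r[i, ], r[j, ]),
                 tolerance = 1e-12)
  }

  const <- rbind(r, flat = rep(1, 20))
  expect_warning(c4 <- gene_correlation_matrix(expr_matrix(const)), "flat")
  expect_false("flat" %in% rownames(c4))
  expect_error(gene_correlation_matrix(
    expr_matrix(matrix(1:4 + 0, 1, 4, dimnames = list("g", paste0("c", 1:4))))),
    "at least 2")
})

test_that("gene clustering recovers planted blocks and the anchor module", {
  # two 5-gene blocks, within-rho 0.8, across-rho 0
  blocks <- matrix(0, 10, 10)
  blocks[1:5, 1:5] <- 0.8
  blocks[6:10, 6:10] <- 0.8
  diag(blocks) <- 1
  dimnames(blocks) <- list(c("Cyp11a1", paste0("a", 2:5), paste0("b", 1:5)),
                           c("Cyp11a1", paste0("a", 2:5), paste0("b", 1:5)))
  mod <- cluster_genes(blocks, "Cyp11a1")
  expect_equal(length(unique(mod$modules$module)), 2L)
  expect_setequal(mod$modules$gene[mod$modules$module ==
                    mod$modules$module[mod$modules$gene == "Cyp11a1"]],
                  rownames(blocks)[1:5])
  expect_setequal(mod$anchor_module, rownames(blocks)[1:5])
})

test_that("the anchor module keeps the suppressor pair and drops the effector trio", {
  genes <- c("Cyp11a1", "Il10", "Tgfb1", "Il4", "Il5", "Il13")
  corr <- diag(6)
  # anchor + suppressor cytokines correlate at 0.6; effector cytokines
  # form their own block, unlinked to the anchor's
  corr[1:3, 1:3] <- 0.6
  corr[4:6, 4:6] <- 0.6
  diag(corr) <- 1
  dimnames(corr) <- list(genes, genes)
  mod <- cluster_genes(corr, "Cyp11a1")
  expect_setequal(mod$anchor_module, c("Cyp11a1", "Il10", "Tgfb1"))
  expect_false(any(c("Il4", "Il5", "Il13") %in% mod$anchor_module))

  one <- matrix(1, 1, 1, dimnames = list("Cyp11a1", "Cyp11a1"))
  expect_error(cluster_genes(one, "Cyp11a1"), "at least 2")
  expect_error(cluster_genes(corr, "Gata3"), "not in the correlation matrix")
})

test_that("gene clustering is invariant to gene order", {
  set.seed(31)
  sim <- generate_single_cell_matrix(
    synthetic_config(n_cells = 120, background_genes = 30, seed = 8))
  genes <- gene_ids(sim$expr)[1:20]
  corr <- gene_correlation_matrix(sim$expr, genes)
  mod <- cluster_genes(corr, "Cyp11a1")
  perm <- sample(nrow(corr))
  mod_p <- cluster_genes(corr[perm, perm], "Cyp11a1")
  expect_setequal(mod_p$anchor_module, mod$anchor_module)
  # identical partitions up to label renaming
  part <- mod$modules$module[match(mod$modules$gene, mod$modules$gene)]
  part_p <- mod_p$modules$module[match(mod$modules$gene, mod_p$modules$gene)]
  expect_equal(ari(part, part_p), 1)
})

test_that("cell clustering isolates the anchor-positive subpopulation", {
  aris <- vapply(1:3, function(s) {
    sim <- generate_single_cell_matrix(synthetic_config(n_cells = 100, seed = s))
    scr <- anchor_screen(sim$expr, sim$annotation)
    cc <- cluster_cells(sim$expr, scr$cell_cluster_genes, "Cyp11a1")
    ari(cc$partition$cluster, as.integer(sim$truth$cells$in_subpop))
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("cell clustering handles duplicate pairs and an uninformative anchor", {
  # two identical cells and two identical-but-different cells split exactly
  m <- cbind(c1 = c(5, 0, 2), c2 = c(5, 0, 2), c3 = c(0, 4, 1), c4 = c(0, 4, 1))
  rownames(m) <- c("Cyp11a1", "g2", "g3")
  cc <- cluster_cells(expr_matrix(m), c("Cyp11a1", "g2", "g3"), "Cyp11a1", k = 2)
  expect_equal(cc$k, 2L)
  expect_equal(cc$partition$cluster[1], cc$partition$cluster[2])
  expect_equal(cc$partition$cluster[3], cc$partition$cluster[4])
  expect_false(cc$partition$cluster[1] == cc$partition$cluster[3])

  # uniformly expressed anchor: captured fraction tracks cluster share
  set.seed(2)
  n <- 60
  m2 <- rbind(Cyp11a1 = rep(3, n) + rnorm(n, sd = 1e-3),
              g2 = c(rep(5, n / 2), rep(0, n / 2)) + rnorm(n, sd = 0.1),
              g3 = c(rep(0, n / 2), rep(5, n / 2)) + rnorm(n, sd = 0.1))
  m2 <- pmax(m2, 0)
  colnames(m2) <- sprintf("c%02d", 1:n)
  cc2 <- cluster_cells(expr_matrix(m2), c("g2", "g3"), "Cyp11a1", k = 2)
  share <- mean(cc2$partition$cluster == cc2$anchor_cell_cluster)
  expect_equal(cc2$fraction_anchor_in_cluster, share, tolerance = 0.1)

  expect_error(cluster_cells(expr_matrix(m2), character(0), "Cyp11a1"),
               "relax the correlation threshold")
})
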