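test_that("a single undivided peak lands entirely in generation 0", {
  sim <- generate_dye_dilution(c(1), g0_center = 10, sigma = 0.1,
                               n_events = 500, seed = 1)
  fit <- assign_generations(sim$events, max_generations = 5)
  props <- fit$counts$n / sum(fit$counts$n)
  expect_gt(props[1], 0.999)
  expect_equal(sum(fit$counts$n), 500)
  expect_equal(fit$g0_center, 10, tolerance = 0.1)
})

test_that("mixture proportions are recovered from dye-dilution events", {
  props <- c(0.2, 0.3, 0.5)
  sim <- generate_dye_dilution(props, sigma = 0.15, n_events = 5000, seed = 4)
  fit <- assign_generations(sim$events, max_generations = 6)
  rec <- fit$counts$n / sum(fit$counts$n)
  true_p <- tabulate(sim$truth$generation + 1L, nbins = 7) / 5000
  expect_lt(max(abs(rec - true_p)), 0.02)
  expect_equal(fit$sigma, 0.15, tolerance = 0.02)
})

test_that("hard assignment breaks midpoint ties toward the lower generation", {
  # events exactly halfway between generation 0 and 1 peaks
  vals <- rep(2^(10 - 0.5), 60)
  ev <- fluorescence_events(vals)
  fit <- assign_generations(ev, g0_center = 10, max_generations = 3,
                            method = "hard")
  expect_equal(fit$counts$n[fit$counts$generation == 0], 60)
})

test_that("events below the autofluorescence floor go to the last generation", {
  sim <- generate_dye_dilution(c(1), g0_center = 10, sigma = 0.1,
                               n_events = 200, seed = 2)
  vals <- c(sim$events$values, 2^1)  # debris far below the modelled range
  expect_warning(
    fit <- assign_generations(fluorescence_events(vals), g0_center = 10,
                              max_generations = 4),
    "autofluorescence floor")
  expect_gte(fit$counts$n[fit$counts$generation == 4], 1)
  expect_error(fluorescence_events(c(1, -2)), "positive")
})

test_that("refitting events regenerated from a fit reproduces its weights", {
  sim <- generate_dye_dilution(c(0.3, 0.5, 0.2), sigma = 0.15,
                               n_events = 4000, seed = 6)
  fit <- assign_generations(sim$events, max_generations = 4)
  w <- fit$counts$n / sum(fit$counts$n)
  regen <- generate_dye_dilution(w, g0_center = fit$g0_center,
                                 sigma = fit$sigma, n_events = 4000, seed = 7)
  refit <- assign_generations(regen$events, max_generations = 4)
  w2 <- refit$counts$n / sum(refit$counts$n)
  expect_lt(max(abs(w - w2)), 0.03)
})

test_that("division index matches precursor arithmetic exactly", {
  expect_equal(division_index(c(100, 0, 0))$di, 0)
  expect_equal(division_index(c(0, 0, 0, 0, 16))$di, 4)
  # precursors (4, 4, 2): DI = (0 + 4 + 4) / 10
  expect_equal(division_index(c(4, 8, 8))$di, 0.8)
  expect_equal(division_index(c(4, 8, 8))$di,
               oracle_division_index(c(4, 8, 8)))
  expect_error(division_index(c(0, 0)), "zero")
  expect_error(division_index(c(-1, 2)), "non-negative")
})

test_that("division index is scale invariant and strictly monotone", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(0:20, sample(2:6, 1), replace = TRUE)
    if (sum(n) == 0) n[1] <- 1
    di <- division_index(n)$di
    expect_equal(division_index(n * 7)$di, di)
    expect_equal(di, oracle_division_index(n), tolerance = 1e-12)
    # moving one cell up a generation strictly increases the index
    from <- which(n > 0)[1]
    if (from < length(n)) {
      n2 <- n
      n2[from] <- n2[from] - 1
      n2[from + 1] <- n2[from + 1] + 1
      expect_gt(division_index(n2)$di, di)
    }
  }
})

test_that("suppression assay reproduces the expected percent suppression", {
  sim <- generate_suppression_experiment(
    c(responder_alone = 2.17, coculture = 1.17),
    replicates = 3, jitter_sd = 0.05, n_events = 3000, seed = 11)
  res <- suppression_assay(sim$samples, "responder_alone",
                           max_generations = 6)
  s <- res$summary
  ref <- s[s$condition == "responder_alone", ]
  expect_equal(ref$percent_suppression, 0)
  expect_true(is.na(ref$p_value))
  co <- s[s$condition == "coculture", ]
  expect_equal(co$percent_suppression, 100 * (1 - 1.17 / 2.17),
               tolerance = 0.12)
  expect_lt(co$p_value, 0.05)
})

test_that("near-equal division indices give small, non-significant suppression", {
  sim <- generate_suppression_experiment(
    c(alone = 2.17, negative_control = 2.1),
    replicates = 3, jitter_sd = 0.05, n_events = 3000, seed = 12)
  res <- suppression_assay(sim$samples, "alone", max_generations = 6)
  nc <- res$summary[res$summary$condition == "negative_control", ]
  expect_lt(abs(nc$percent_suppression), 12)
})

test_that("identical replicate sets give zero suppression and single replicates no p", {
  sim <- generate_dye_dilution(c(0.4, 0.4, 0.2), n_events = 1000, seed = 3)
  mk <- function(cond, rep) {
    fluorescence_events(sim$events$values, condition = cond, replicate = rep)
  }
  res <- suppression_assay(list(mk("ref", "1"), mk("ref", "2"),
                                mk("same", "1"), mk("same", "2")),
                           "ref", max_generations = 4)
  expect_equal(res$summary$percent_suppression,
               c(0, 0), tolerance = 1e-10)

  expect_warning(
    res2 <- suppression_assay(list(mk("ref", "1"), mk("ref", "2"),
                                   mk("solo", "1")),
                              "ref", max_generations = 4),
    "single replicate")
  expect_true(is.na(res2$summary$p_value[res2$summary$condition == "solo"]))
  expect_error(suppression_assay(list(mk("solo", "1")), "missing"),
               "absent")
})

test_that("the assay's p value matches the closed-form pooled t statistic", {
  sim <- generate_suppression_experiment(c(alone = 2, treated = 1.4),
                                         replicates = 3, jitter_sd = 0.1,
                                         n_events = 1500, seed = 21)
  res <- suppression_assay(sim$samples, "alone", max_generations = 6)
  a <- res$replicates$di[res$replicates$condition == "alone"]
  b <- res$replicates$di[res$replicates$condition == "treated"]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tstat <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_manual <- 2 * pt(-abs(tstat), df = length(a) + length(b) - 2)
  expect_equal(res$summary$p_value[res$summary$condition == "treated"],
               p_manual)
})
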