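test_that("no birth-death events means seed lineages span the window", {
  cfg <- sim_config(lambda = 0, mu = 0, n_seed = 5, rng_seed = 1)
  h <- simulate_bd(cfg)
  expect_equal(nrow(h$lineages), 5L)
  expect_true(all(h$lineages$ts == cfg$t_start))
  expect_true(all(h$lineages$te == cfg$t_end))
  expect_false(any(h$lineages$extinct))
  expect_false(h$all_extinct)
})

test_that("pure birth never produces extinctions", {
  cfg <- sim_config(lambda = 0.15, mu = 0, n_seed = 5, rng_seed = 2)
  h <- simulate_bd(cfg)
  expect_false(any(h$lineages$extinct))
  expect_gt(nrow(h$lineages), 5L)
})

test_that("mean standing diversity matches the analytic expectation", {
  # E[N(T)] = N0 exp((lambda - mu) T); 300 replicates, Monte-Carlo error
  n0 <- 20
  T_ <- 10
  ns <- vapply(1:300, function(s) {
    h <- simulate_bd(sim_config(t_start = 260, t_end = 250, lambda = 0.2,
                                mu = 0.1, n_seed = n0, rng_seed = s))
    sum(!h$lineages$extinct)
  }, numeric(1))
  expected <- n0 * exp(0.1 * T_)
  se <- stats::sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - expected), 4 * se + 0.5)
})

test_that("total extinction is flagged, not raised", {
  cfg <- sim_config(lambda = 0, mu = 5, n_seed = 2, rng_seed = 3)
  h <- simulate_bd(cfg)
  expect_true(h$all_extinct)
  expect_true(all(h$lineages$extinct))
})

test_that("preservation counts follow the Poisson mean", {
  # 2000 identical lineages of duration 10 at q = 0.7 -> counts ~ Pois(7)
  cfg <- sim_config(t_start = 260, t_end = 250, q = 0.7, rng_seed = 4)
  h <- structure(list(
    lineages = data.frame(lineage = 1:2000, ts = 260, te = 250,
                          extinct = FALSE),
    t_start = 260, t_end = 250, all_extinct = FALSE
  ), class = "true_history")
  occ <- simulate_preservation(h, cfg)
  counts <- tabulate(occ$lineage, 2000)
  expect_lt(abs(mean(counts) - 7), 4 * stats::sd(counts) / sqrt(2000))
  expect_true(all(occ$age <= 260 & occ$age >= 250))
})

test_that("doubling q in one bin doubles occurrence density there", {
  q_ep <- data.frame(from = c(260, 255), to = c(255, 250), rate = c(1, 2))
  cfg <- sim_config(t_start = 260, t_end = 250, q = q_ep, rng_seed = 5)
  h <- structure(list(
    lineages = data.frame(lineage = 1:1500, ts = 260, te = 250,
                          extinct = FALSE),
    t_start = 260, t_end = 250, all_extinct = FALSE
  ), class = "true_history")
  occ <- simulate_preservation(h, cfg)
  n_lo <- sum(occ$age > 255)
  n_hi <- sum(occ$age <= 255)
  expect_lt(abs(n_hi / n_lo - 2), 0.15)
})

test_that("zero preservation yields an empty record", {
  cfg <- sim_config(q = 0, rng_seed = 6)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  expect_equal(nrow(occ), 0L)
})

test_that("emitted tables censor true ages into covering substages", {
  cfg <- sim_config(rng_seed = 7)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  emit <- emit_occurrence_table(h, occ, cfg)
  r <- emit$records
  tr <- emit$truth
  expect_equal(nrow(r), nrow(tr))
  expect_true(all(tr$true_age <= r$max_ma + 1e-9 &
                    tr$true_age > r$min_ma - 1e-9))
  # zero-occurrence loss only: emitted genera are a subset of lineages
  expect_true(all(unique(tr$lineage) %in% h$lineages$lineage))
  expect_lte(length(unique(r$accepted_genus)), nrow(h$lineages))
})

test_that("noise-free emission round-trips through curation untouched", {
  cfg <- sim_config(qualifier_noise_p = 0, subgenus_p = 0, terrestrial_p = 0,
                    outlier_p = 0, rng_seed = 8)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  emit <- emit_occurrence_table(h, occ, cfg)
  cl <- clean_occurrences(emit$records)
  expect_equal(nrow(cl$log), 0L)
  expect_equal(nrow(cl$kept), nrow(emit$records))
})

test_that("forced subgenus formatting brackets every name", {
  cfg <- sim_config(subgenus_p = 1, qualifier_noise_p = 0, terrestrial_p = 0,
                    outlier_p = 0, rng_seed = 9)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  emit <- emit_occurrence_table(h, occ, cfg)
  expect_true(all(grepl("^Genus\\d+ \\(Subg\\d+\\)$", emit$records$genus)))
  expect_equal(strip_subgenus(emit$records$genus, "delete_bracket"),
               emit$records$accepted_genus)
})

test_that("injected range outliers are recorded so recall is computable", {
  cfg <- sim_config(outlier_p = 0.5, qualifier_noise_p = 0, terrestrial_p = 0,
                    subgenus_p = 0, rng_seed = 10)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  emit <- emit_occurrence_table(h, occ, cfg)
  expect_gt(sum(emit$truth$injected_outlier), 0)
  # every injected outlier sits older than its genus's true span
  out <- emit$truth[emit$truth$injected_outlier, ]
  ts_of <- h$lineages$ts[match(out$lineage, h$lineages$lineage)]
  expect_true(all(out$true_age > ts_of))
})

test_that("emission is bit-reproducible under a fixed seed", {
  cfg <- sim_config(rng_seed = 11)
  h1 <- simulate_bd(cfg)
  h2 <- simulate_bd(cfg)
  expect_identical(h1, h2)
  o1 <- simulate_preservation(h1, cfg)
  o2 <- simulate_preservation(h2, cfg)
  expect_identical(o1, o2)
  e1 <- emit_occurrence_table(h1, o1, cfg)
  e2 <- emit_occurrence_table(h2, o2, cfg)
  expect_identical(e1, e2)
})

test_that("predictor curves carry their generating rate curves", {
  grid <- seq(276, 244.2, length.out = 100)
  sim <- simulate_predictors(grid, 1, 2, rng_seed = 12, g_lambda = 1.0,
                             lambda0 = 0.1)
  # definition of the exponential link, pointwise
  v <- sim$predictors$signal_1$value
  expect_equal(sim$lambda$value, 0.1 * exp(1.0 * v), tolerance = 1e-12)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(range(v), c(0, 1))
  # no signal -> baseline rates everywhere
  sim0 <- simulate_predictors(grid, 0, 3, rng_seed = 13)
  expect_true(all(sim0$lambda$value == sim0$lambda$value[1]))
  expect_equal(unname(sim0$g_lambda), rep(0, 3))
})
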