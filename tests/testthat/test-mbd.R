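two_point <- function(a0, a1, v0, v1) {
  data.frame(age = c(a0, a1), value = c(v0, v1))
}

test_that("predictor preparation interpolates, rescales and flags", {
  win <- c(260, 250)
  prep <- prepare_predictors(
    list(line = two_point(262, 248, 0, 1),
         flat = two_point(262, 248, 3, 3)),
    win
  )
  expect_equal(prep$grid[1], 260)
  expect_equal(prep$grid[length(prep$grid)], 250)
  # a linear series stays a straight line after min-max rescaling
  v <- prep$values[, 1]
  expect_equal(v, seq(0, 1, length.out = length(v)), tolerance = 1e-9)
  expect_equal(range(v), c(0, 1))
  expect_true(prep$degenerate[["flat"]])
  expect_true(all(prep$values[, 2] == 0))
})

test_that("series not covering the window raise an error naming the gap", {
  expect_error(
    prepare_predictors(list(short = two_point(258, 252, 0, 1)), c(260, 250)),
    "short.*does not cover"
  )
})

test_that("LOWESS smoothing recovers a noisy sine within the noise level", {
  set.seed(51)
  age <- seq(300, 200, by = -0.5)
  truth <- sin(2 * pi * (300 - age) / 50)
  noisy <- truth + rnorm(length(age), 0, 0.4)
  prep <- prepare_predictors(
    list(d13c = data.frame(age = age, value = noisy)),
    c(295, 205), smooth = "d13c"
  )
  truth_grid <- sin(2 * pi * (300 - prep$grid) / 50)
  tg <- (truth_grid - min(truth_grid)) / diff(range(truth_grid))
  rmse <- sqrt(mean((prep$values[, 1] - tg)^2))
  expect_lt(rmse, 0.4 / diff(range(truth + 0.0)) * 2)
})

test_that("carbonate proportion is a per-substage occurrence tally", {
  recs <- rbind(
    make_records(n = 3, max_ma = 250, min_ma = 249, lithology1 = "carbonate"),
    make_records(n = 1, max_ma = 250, min_ma = 249,
                 lithology1 = "siliciclastic")
  )
  cp <- carbonate_proportion(recs)
  sub <- substage_table(load_stage_table())
  i <- paleodiv:::interval_index(249.5, sub$max_ma, sub$min_ma)
  expect_equal(cp$value[i], 0.75)
  expect_true(all(is.na(cp$value[-i])))
  # all-carbonate input gives 1 wherever populated
  cp1 <- carbonate_proportion(make_records(n = 5, max_ma = 250, min_ma = 249))
  expect_equal(cp1$value[i], 1)
  # brute-force tally on a 200-row synthetic table
  cfg <- sim_config(rng_seed = 52)
  h <- simulate_bd(cfg)
  occ <- simulate_preservation(h, cfg)
  emit <- emit_occurrence_table(h, occ, cfg)
  r200 <- emit$records[1:200, ]
  cp2 <- carbonate_proportion(r200)
  mid <- (r200$max_ma + r200$min_ma) / 2
  idx <- paleodiv:::interval_index(mid, sub$max_ma, sub$min_ma)
  for (j in unique(idx)) {
    expect_equal(cp2$value[j],
                 mean(r200$lithology1[idx == j] == "carbonate"))
  }
})

test_that("predator diversity is the pointwise sum of mean curves", {
  g <- seq(260, 250, by = -1)
  c1 <- data.frame(age = g, value = 1:11)
  c0 <- data.frame(age = g, value = rep(0, 11))
  expect_equal(predator_diversity(list(c1))$value, 1:11)
  expect_equal(predator_diversity(list(c1, c0))$value, 1:11)
  expect_error(predator_diversity(list(c1, data.frame(age = g[-1],
                                                      value = 1:10))),
               "share one age grid")
  # the sum of two simulated clades equals the pooled truth count
  h1 <- simulate_bd(sim_config(rng_seed = 53))
  h2 <- simulate_bd(sim_config(rng_seed = 54))
  d1 <- ltt_diversity(h1$lineages, g + 5)
  d2 <- ltt_diversity(h2$lineages, g + 5)
  pooled <- ltt_diversity(rbind(h1$lineages, h2$lineages), g + 5)
  expect_equal(predator_diversity(list(d1, d2))$value, pooled$mean)
})

test_that("zero correlation parameters reduce to the constant-rate model", {
  win <- c(260, 240)
  tm <- make_times(ts = c(258, 255, 250), te = c(252, 244, 241))
  prep <- prepare_predictors(list(a = two_point(262, 238, 0, 1),
                                  b = two_point(262, 238, 1, 0)), win)
  for (link in c("exponential", "linear")) {
    got <- mbd_loglik(tm, 0.3, 0.12, c(0, 0), c(0, 0), prep, link)
    want <- bd_loglik(tm, rate_trajectory(numeric(0), 0.3, win),
                      rate_trajectory(numeric(0), 0.12, win), win)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a unit predictor under the exponential link rescales the baseline", {
  win <- c(260, 240)
  tm <- make_times(ts = c(258, 255, 250), te = c(252, 244, 241))
  grid <- seq(win[1], win[2], by = -0.1)
  ones <- structure(list(grid = grid,
                         values = matrix(1, length(grid), 1),
                         names = "unit", degenerate = c(unit = FALSE)),
                    class = "predictor_set")
  g <- 0.7
  expect_equal(
    mbd_loglik(tm, 0.2, 0.1, g, 0, ones, "exponential"),
    mbd_loglik(tm, 0.2 * exp(g), 0.1, 0, 0, ones, "exponential"),
    tolerance = 1e-10
  )
})

test_that("linear-link rates clamp at zero and zero rates give -Inf", {
  win <- c(260, 240)
  tm <- make_times(ts = 258, te = 250)
  prep <- prepare_predictors(list(a = two_point(262, 238, 1, 0)), win)
  # G = -2 drives the origination rate to zero where the event sits
  expect_identical(
    mbd_loglik(tm, 0.2, 0.1, -2, 0, prep, "linear"), -Inf)
})

test_that("grid integration matches fine exact quadrature on a toy", {
  set.seed(55)
  win <- c(260, 240)
  tm <- make_times(ts = runif(8, 250, 259), te = runif(8, 241, 249))
  prep <- prepare_predictors(list(a = two_point(262, 238, 0, 1),
                                  b = data.frame(age = seq(262, 238, by = -2),
                                                 value = rnorm(13))), win)
  gl <- c(0.8, -0.5)
  lam_g <- 0.2 * exp(drop(prep$values %*% gl))
  mu_g <- rep(0.1, length(prep$grid))
  # oracle: per-lineage integral of the grid-linear rate by fine summing
  o_int <- function(rate_grid) {
    tot <- 0
    for (i in seq_len(nrow(tm))) {
      tt <- seq(tm$te[i], tm$ts[i], length.out = 20001)
      r <- approx(prep$grid, rate_grid, xout = tt)$y
      tot <- tot + mean(r) * (tm$ts[i] - tm$te[i])
    }
    tot
  }
  ev <- sum(log(approx(prep$grid, lam_g, xout = tm$ts)$y)) +
    sum(log(approx(prep$grid, mu_g, xout = tm$te)$y))
  want <- ev - o_int(lam_g) - o_int(mu_g)
  got <- mbd_loglik(tm, 0.2, 0.1, gl, c(0, 0), prep, "exponential")
  expect_lt(abs(got - want), 1e-5 * abs(want) + 1e-5)
})

test_that("stepping-stone evidence matches a conjugate analytic marginal", {
  # y_i ~ N(theta, 1), theta ~ N(0, 1): log marginal available in closed form
  set.seed(56)
  n <- 10
  y <- rnorm(n, 0.4, 1)
  loglik <- function(theta) sum(dnorm(y, theta, 1, log = TRUE))
  K <- 12
  betas <- (0:K / K)^(1 / 0.3)
  ll_list <- lapply(betas[1:K], function(b) {
    post_var <- 1 / (b * n + 1)
    th <- rnorm(4000, b * sum(y) * post_var, sqrt(post_var))
    vapply(th, loglik, numeric(1))
  })
  got <- stepping_stone_evidence(ll_list, betas)
  S <- diag(n) + matrix(1, n, n)
  want <- mvtnorm_free <- -0.5 * (n * log(2 * pi) +
                                    determinant(S)$modulus[1] +
                                    drop(y %*% solve(S, y)))
  expect_lt(abs(got - want), 0.1)
})

test_that("bayes factors compare marginals with a no-support band", {
  expect_equal(bayes_factor(-100, -100)$preferred, "no clear support")
  expect_equal(bayes_factor(-95, -100)$preferred, "exponential")
  expect_equal(bayes_factor(-100, -95)$preferred, "linear")
  expect_equal(bayes_factor(-95, -100)$log_bf, 5)
  expect_error(bayes_factor(list(), list()), "marginal")
})

test_that("a short decoy-only fit leaves every weight below threshold", {
  d <- simulate_mbd_dataset(57, n_signal = 0, n_decoy = 3,
                            n_range = c(200, 1200))
  prep <- prepare_predictors(d$predictors$predictors, c(295, 245))
  fit <- fit_mbd(d$history$lineages, prep, "exponential",
                 mcmc = mcmc_run(n_iter = 3000, n_samples = 300,
                                 rng_seed = 58))
  expect_lt(mean(fit$g_lambda$w), 0.5)
  expect_lt(mean(fit$g_mu$w), 0.5)
  expect_true(all(fit$g_lambda$w < 0.6))
  expect_s3_class(fit, "mbd_result")
})
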