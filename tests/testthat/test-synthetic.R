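test_that("the standard hidden influence is a documented single peak", {
  tt <- grid30()
  h <- default_hidden_influence(tt)
  expect_lt(h$values[1], 0.05)
  expect_lt(h$values[30], 0.05)
  peak_target <- tt[which.min(abs(tt - 0.4 * 10))]
  expect_equal(tt[which.max(h$values)], peak_target)
  expect_equal(max(h$values), 1, tolerance = 0.01)
  expect_identical(h$values, default_hidden_influence(tt)$values)
})

test_that("the dataset generator honours its seeding contract", {
  d1 <- simulate_linear_dataset(3, 1, sigma = 0.1, seed = 80)
  d2 <- simulate_linear_dataset(3, 1, sigma = 0.1, seed = 80)
  d3 <- simulate_linear_dataset(3, 1, sigma = 0.1, seed = 81)
  expect_identical(d1$values, d2$values)
  expect_identical(d1$truth$k_matrix, d2$truth$k_matrix)
  expect_false(identical(d1$truth$k_matrix, d3$truth$k_matrix))
})

test_that("zero noise returns the exact trajectories", {
  d <- simulate_linear_dataset(3, 1, sigma = 0, seed = 82)
  expect_equal(d$values, d$truth$trajectories, ignore_attr = TRUE,
               tolerance = 0)
})

test_that("generated weights are L1-normalized and trajectories positive", {
  for (s in 83:87) {
    d <- simulate_linear_dataset(6, 1, sigma = 0.1, seed = s)
    expect_equal(sum(abs(d$truth$a_true)), 1, tolerance = 1e-12)
    expect_gt(min(d$truth$trajectories), 0)
    expect_gt(min(d$values), 0)  # log-normal observations stay positive
  }
})

test_that("the noise generators have the stated calibration", {
  # log-normal: sd of log(obs / truth) near sigma; median ratio near 1
  pool <- c()
  for (s in 1:38) {
    d <- simulate_linear_dataset(9, 1, sigma = 0.3, seed = 2000 + s)
    pool <- c(pool, log(d$values / d$truth$trajectories))
  }
  expect_gte(length(pool), 1e4)
  expect_gt(sd(pool), 0.29); expect_lt(sd(pool), 0.31)
  expect_gt(median(exp(pool)), 0.98); expect_lt(median(exp(pool)), 1.02)
  # normal: mean bias well below sigma
  pool_n <- c()
  for (s in 1:38) {
    d <- simulate_linear_dataset(9, 1, sigma = 0.1, noise_kind = "normal",
                                 seed = 3000 + s)
    pool_n <- c(pool_n, d$values - d$truth$trajectories)
  }
  expect_lt(abs(mean(pool_n)), 0.01 * 0.1)
})

test_that("observed fractions mark the leading components", {
  d <- simulate_linear_dataset(6, 1 / 3, sigma = 0.1, seed = 88)
  expect_identical(d$observed, c(TRUE, TRUE, rep(FALSE, 4)))
  d2 <- simulate_linear_dataset(9, 2 / 3, sigma = 0.1, seed = 88)
  expect_equal(sum(d2$observed), 6)
  expect_error(simulate_linear_dataset(3, 0, sigma = 0.1, seed = 1),
               "observed_fraction")
})

test_that("the latent-course score is a mean absolute deviation", {
  g <- 0:2
  expect_equal(score_s(hidden_signal(g, c(1, 2, 3)),
                       hidden_signal(g, c(1, 2, 3))), 0)
  expect_equal(score_s(hidden_signal(g, c(1.5, 2.5, 3.5)),
                       hidden_signal(g, c(1, 2, 3))), 0.5)
  expect_equal(score_s(hidden_signal(g, c(1, 2, 3)),
                       hidden_signal(g, c(1, 1, 1))), 1.0)
  expect_error(score_s(hidden_signal(0:3, 1:4), hidden_signal(0:2, 1:3)),
               "grids")
})

test_that("a tiny study run is deterministic with coherent summaries", {
  cfg <- study_config(sizes = 3, noise_levels = 0.1,
                      observed_fractions = 1, replicates = 2,
                      base_seed = 5)
  r1 <- run_simulation_study(cfg)
  r2 <- run_simulation_study(cfg)
  expect_identical(r1$replicates$s, r2$replicates$s)
  expect_equal(nrow(r1$replicates), 2L)
  expect_equal(r1$summary$mean_s, mean(r1$replicates$s))
  expect_lte(r1$summary$q05, r1$summary$mean_s)
  expect_lte(r1$summary$mean_s, r1$summary$q95)
  expect_equal(r1$summary$n_failed, 0L)
})

test_that("the cascade experiment encodes the missing-feedback target", {
  ce <- cascade_experiment(seed = 90)
  expect_equal(ce$data$truth$a_pattern, c(0.5, 0, 0, -0.5))
  expect_identical(ce$data$values,
                   cascade_experiment(seed = 90)$data$values)
  expect_false("k_fb" %in% names(ce$start_model$rates))
  expect_true("k_fb" %in% names(ce$true_model$rates))
  expect_equal(length(ce$start_model$free_rates), 3L)
})

test_that("the misspecified structure shows a systematic lack of fit", {
  ce <- cascade_experiment(seed = 91, sigma = 0)
  sm <- smooth_components(ce$data, "lognormal")
  wrong <- estimate_latent(ce$data, ce$start_model, integer(),
                           noise_kind = "lognormal", smoothers = sm)
  right_model <- build_cascade_model(k = rep(0.1, 3), feedback_rate = 0.1,
                                     initial_values = ce$true_model$x0,
                                     free = TRUE)
  right <- estimate_latent(ce$data, right_model, integer(),
                           noise_kind = "lognormal", smoothers = sm)
  expect_gt(wrong$sigma2, 10 * right$sigma2)
})
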