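test_that("residual extraction recovers an analytic derivative", {
  # no dynamics: the residual is the spline derivative itself
  tt <- seq(0, 1, length.out = 30)
  m <- build_linear_network(matrix(0, 1, 1), 0)
  f <- fit_penalized_spline(tt, tt^2, K = 15, lambda = 0)
  sm <- list(list(value = function(t) predict(f, t),
                  deriv = function(t) predict(f, t, deriv = 1),
                  component = 1L, log_scale = FALSE))
  r <- residual_signal(m, sm, 1, tt)
  interior <- tt > 0.1 & tt < 0.9
  expect_lt(max(abs(r[interior] - 2 * tt[interior])), 1e-2)
})

test_that("residuals reproduce the exact latent course on exact inputs", {
  m <- random_linear_model(21, n = 3)
  tt <- seq(0, 8, length.out = 30)
  h <- default_hidden_influence(tt)
  a <- c(1, 0, 0)
  tr <- t(as.matrix(solve_ode(m, tt, a = a, h = h)[, -1]))
  A <- latentdyn:::linear_A(m)
  # exact value and derivative functions from the true solution
  vfn <- lapply(1:3, function(i) function(t) {
    t(latentdyn:::solve_ode_matrix(m, sort(unique(c(0, t))), a = a,
                                   h = h))[match(t, sort(unique(c(0, t)))), i]
  })
  dfn <- lapply(1:3, function(i) function(t) {
    X <- latentdyn:::solve_ode_matrix(m, sort(unique(c(0, t))), a = a, h = h)
    full <- A %*% X + outer(a, predict(h, sort(unique(c(0, t)))))
    full[i, match(t, sort(unique(c(0, t))))]
  })
  sm <- exact_smoothers(vfn, dfn)
  r1 <- residual_signal(m, sm, 1, tt)
  expect_equal(r1, predict(h, tt), tolerance = 1e-8)
  r2 <- residual_signal(m, sm, 2, tt)       # a_2 = 0: no residual signal
  expect_lt(max(abs(r2)), 1e-8)
})

test_that("aggregation follows the weighted pointwise average", {
  h0 <- rbind(c(2, 4), c(-1, -2))
  h <- aggregate_hidden(h0, c(0.5, -0.5), times = c(0, 1))
  expect_equal(h$values, c(3, 6))
  one <- aggregate_hidden(rbind(1:3, 4:6, 7:9), c(1, 0, 0), times = 1:3)
  expect_equal(one$values, c(1, 2, 3))
  # consistent inputs collapse to the common course for any support
  tt <- 1:5
  hv <- sin(tt)
  a <- c(0.3, -0.5, 0.2)
  h0c <- a %o% hv
  for (sup in list(1, c(1, 3), 1:3)) {
    av <- numeric(3); av[sup] <- a[sup]
    expect_equal(aggregate_hidden(h0c, av, times = tt)$values, hv)
  }
  expect_error(aggregate_hidden(h0, c(0, 0)), "zero")
})

test_that("the Gaussian log-likelihood matches its closed form", {
  m <- random_linear_model(31, n = 3)
  tt <- seq(0, 5, length.out = 10)   # 3 x 10 = 30 observations
  tr <- latentdyn:::solve_ode_matrix(m, tt)
  d <- timeseries_data(tt, tr)
  ll <- log_likelihood(m, d, noise = noise_model("normal", 1))
  expect_equal(ll, -15 * log(2 * pi), tolerance = 1e-4)
  expect_equal(ll, -27.5681, tolerance = 1e-3)
})

test_that("the log-likelihood equals a brute-force density sum", {
  m <- random_linear_model(32, n = 2)
  tt <- seq(0, 4, length.out = 8)
  h <- hidden_signal(tt, cos(tt))
  a <- c(0.7, -0.3)
  set.seed(33)
  obs <- latentdyn:::solve_ode_matrix(m, tt, a = a, h = h) +
    matrix(rnorm(16, 0, 0.2), 2)
  d <- timeseries_data(tt, obs)
  s2 <- 0.21
  ll <- log_likelihood(m, d, a, noise_model("normal", s2), h)
  fit <- latentdyn:::solve_ode_matrix(m, tt, a = a, h = h)
  oracle <- sum(dnorm(obs, fit, sqrt(s2), log = TRUE))
  expect_equal(ll, oracle, tolerance = 1e-10)
  # log-normal variant against dlnorm
  obs_ln <- fit * exp(matrix(rnorm(16, 0, 0.1), 2))
  dln <- timeseries_data(tt, obs_ln)
  ll_ln <- log_likelihood(m, dln, a, noise_model("lognormal", 0.01), h)
  oracle_ln <- sum(dlnorm(obs_ln, log(fit), 0.1, log = TRUE))
  expect_equal(ll_ln, oracle_ln, tolerance = 1e-8)
})

test_that("rescaling weights and latent course leaves the likelihood fixed", {
  m <- random_linear_model(34, n = 3)
  tt <- seq(0, 6, length.out = 12)
  h <- hidden_signal(tt, sin(tt / 2))
  a <- c(0.5, -0.2, 0.3)
  set.seed(35)
  d <- timeseries_data(tt, latentdyn:::solve_ode_matrix(m, tt, a = a, h = h) +
                         matrix(rnorm(36, 0, 0.1), 3))
  nm <- noise_model("normal", 0.01)
  l0 <- log_likelihood(m, d, a, nm, h)
  for (xi in c(-3, -1, 0.25, 2)) {
    l1 <- log_likelihood(m, d, xi * a, nm,
                         hidden_signal(tt, h$values / xi))
    expect_lt(abs(l1 - l0), 1e-8)
  }
})

test_that("the analytic noise variance matches direct and profile oracles", {
  expect_equal(sigma2_mle(matrix(c(1, -1, 2), 1), matrix(0, 1, 3)), 2.0)
  expect_equal(sigma2_mle(matrix(1:4, 2), matrix(1:4, 2)), 0)
  m <- random_linear_model(36, n = 2)
  tt <- seq(0, 4, length.out = 10)
  set.seed(37)
  fit <- latentdyn:::solve_ode_matrix(m, tt)
  obs <- fit + matrix(rnorm(20, 0, 0.3), 2)
  d <- timeseries_data(tt, obs)
  s2_hat <- sigma2_mle(d, fit)
  prof <- optimize(function(s2) -log_likelihood(m, d,
                                                noise = noise_model("normal",
                                                                    s2)),
                   interval = c(1e-4, 2), tol = 1e-12)$minimum
  expect_lt(abs(s2_hat - prof), 1e-6)
})

test_that("noise-free data yields accurate weights and latent course", {
  set.seed(40)
  m <- random_linear_model(40, n = 3)
  tt <- grid30()
  h <- default_hidden_influence(tt)
  a_true <- c(0.6, -0.4, 0)
  d <- make_dataset(m, tt, a = a_true, h = h, sigma = 0.002,
                    noise_kind = "normal", seed = 41)
  est <- estimate_latent(d, m, support = c(1, 2), noise_kind = "normal")
  a_hat <- est$a
  if (sum(a_hat * a_true) < 0) a_hat <- -a_hat
  expect_lt(max(abs(a_hat - a_true)), 0.05)
  h_hat <- hidden_signal(tt, predict(est$hidden, tt))
  if (sum(est$a * a_true) < 0) h_hat$values <- -h_hat$values
  expect_lt(score_s(h_hat, h), 0.05)
  # the null model explains strictly less
  est0 <- estimate_latent(d, m, support = integer(), noise_kind = "normal")
  expect_lt(est0$loglik, est$loglik)
  expect_equal(est0$n_a, 0L)
})

test_that("estimates satisfy the identifiability normalization exactly", {
  set.seed(44)
  for (r in 1:5) {
    d <- simulate_linear_dataset(3, 1, sigma = 0.1, seed = 400 + r)
    m <- latentdyn:::estimation_model(d)
    sup <- sort(sample(1:3, sample(1:3, 1)))
    est <- estimate_latent(d, m, support = sup, noise_kind = "lognormal")
    expect_lt(abs(sum(abs(est$a)) - 1), 1e-10)
    expect_identical(which(est$a != 0), as.integer(sup))
  }
})

test_that("the full-support fit explains at least as much as the null", {
  # the latent course absorbs genuine residual structure, so fitting it on
  # every component cannot lose against the latent-free model
  for (r in 1:5) {
    d <- simulate_linear_dataset(3, 1, sigma = 0.1, seed = 420 + r)
    m <- latentdyn:::estimation_model(d)
    sm <- smooth_components(d, "lognormal")
    full <- estimate_latent(d, m, 1:3, "lognormal", smoothers = sm)
    null <- estimate_latent(d, m, integer(), "lognormal", smoothers = sm)
    expect_gte(full$loglik, null$loglik - 1e-6)
  }
})

test_that("the log-normal noise level is recovered across replicates", {
  sig_hat <- numeric(25)
  for (r in 1:25) {
    d <- simulate_linear_dataset(3, 1, sigma = 0.1,
                                 noise_kind = "lognormal", seed = 700 + r)
    m <- latentdyn:::estimation_model(d)
    est <- estimate_latent(d, m, support = 1:3, noise_kind = "lognormal")
    sig_hat[r] <- sqrt(est$sigma2)
  }
  expect_gt(mean(sig_hat), 0.07)
  expect_lt(mean(sig_hat), 0.13)
})

test_that("single-component supports resolve the direction by likelihood", {
  set.seed(45)
  m <- random_linear_model(45, n = 2)
  tt <- grid30()
  h <- default_hidden_influence(tt)
  d <- make_dataset(m, tt, a = c(-1, 0), h = h, sigma = 0.01,
                    noise_kind = "normal", seed = 46)
  est <- estimate_latent(d, m, support = 1, noise_kind = "normal")
  # direction itself is not identified (a h = (-a)(-h)); the fitted forcing is
  expect_equal(abs(est$a[1]), 1)
  forcing <- est$a[1] * predict(est$hidden, tt)
  expect_lt(mean(abs(forcing - (-1) * h$values)), 0.05)
})
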