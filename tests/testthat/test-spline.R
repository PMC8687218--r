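test_that("constants are reproduced penalty-free with zero derivative", {
  tt <- seq(0, 1, length.out = 12)
  for (lam in c(0, 1, 1e6)) {
    f <- fit_penalized_spline(tt, rep(5, 12), K = 8, lambda = lam)
    expect_equal(predict(f, tt), rep(5, 12), tolerance = 1e-8)
    expect_equal(predict(f, tt, deriv = 1), rep(0, 12), tolerance = 1e-6)
  }
})

test_that("the penalized fit solves the ridge normal equations", {
  set.seed(10)
  tt <- seq(0, 1, length.out = 25)
  y <- sin(2 * pi * tt) + rnorm(25, 0, 0.1)
  K <- 12; lam <- 3.7
  f <- fit_penalized_spline(tt, y, K = K, lambda = lam)
  # independent closed-form solution
  kn <- latentdyn:::bspline_knots(range(tt), K)
  Phi <- splines::splineDesign(kn, tt, ord = 4)
  D <- diff(diag(K), differences = 2)
  beta <- solve(crossprod(Phi) + lam * crossprod(D), crossprod(Phi, y))
  expect_lt(max(abs(f$coefficients - as.numeric(beta))), 1e-8)
})

test_that("a huge penalty collapses the fit onto the least-squares line", {
  set.seed(11)
  tt <- seq(0, 2, length.out = 30)
  y <- 2 * tt + 1 + rnorm(30, 0, 0.1)
  f <- fit_penalized_spline(tt, y, K = 15, lambda = 1e8)
  line <- unname(fitted(lm(y ~ tt)))
  expect_lt(max(abs(predict(f, tt) - line)), 1e-3)
})

test_that("lambda = 0 with a saturated basis interpolates the data", {
  set.seed(12)
  tt <- seq(0, 1, length.out = 10)
  y <- rnorm(10)
  f <- fit_penalized_spline(tt, y, K = 10, lambda = 0)
  expect_lt(sum((predict(f, tt) - y)^2), 1e-8)
})

test_that("the curvature penalty of the fit is non-increasing in lambda", {
  set.seed(13)
  tt <- seq(0, 1, length.out = 30)
  y <- sin(2 * pi * tt) + rnorm(30, 0, 0.2)
  D <- diff(diag(15), differences = 2)
  pen <- vapply(10^seq(-4, 4, length.out = 9), function(lam) {
    b <- fit_penalized_spline(tt, y, K = 15, lambda = lam)$coefficients
    sum((D %*% b)^2)
  }, numeric(1))
  expect_true(all(diff(pen) <= 1e-10))
})

test_that("derivatives agree with finite differences and the quadratic", {
  tt <- seq(0, 1, length.out = 30)
  f <- fit_penalized_spline(tt, tt^2, K = 15, lambda = 0)
  expect_equal(predict(f, 0.5, deriv = 1), 1.0, tolerance = 1e-2)
  set.seed(14)
  pts <- runif(100, 0.01, 0.99)
  fd <- (predict(f, pts + 1e-6) - predict(f, pts - 1e-6)) / 2e-6
  expect_lt(max(abs(fd - predict(f, pts, deriv = 1))), 1e-4)
})

test_that("evaluation outside the fitted window is refused", {
  f <- fit_penalized_spline(seq(0, 1, length.out = 10), rnorm(10), K = 6,
                            lambda = 1)
  expect_error(predict(f, 1.5), "outside")
  expect_error(predict(f, -0.1), "outside")
})

test_that("leave-one-out selection returns grid minimizers", {
  set.seed(15)
  tt <- seq(0, 1, length.out = 20)
  y <- tt + rnorm(20, 0, 0.1)
  sel <- select_lambda_loocv(tt, y, K = 10, lambda_grid = 2.5)
  expect_equal(sel$lambda, 2.5)
  sel2 <- select_lambda_loocv(tt, y, K = 10)
  expect_equal(min(sel2$cv_scores$cv_score),
               sel2$cv_scores$cv_score[sel2$cv_scores$lambda == sel2$lambda])
})

test_that("smoother data earns a larger smoothing parameter", {
  # straight line vs a full sine period under the same noise
  tt <- seq(0, 1, length.out = 30)
  wins <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    noise <- rnorm(30, 0, 0.1)
    lam_line <- select_lambda_loocv(tt, tt + noise, K = 15)$lambda
    lam_sine <- select_lambda_loocv(tt, sin(2 * pi * tt) + noise,
                                    K = 15)$lambda
    wins <- wins + (lam_line >= lam_sine)
  }
  expect_gte(wins, 18)  # >= 90% of replicates
})

test_that("log-scale smoothing keeps positive data positive", {
  set.seed(16)
  tt <- seq(0, 10, length.out = 30)
  truth <- 2 + sin(tt)
  obs <- truth * exp(rnorm(30, 0, 0.1))
  d <- timeseries_data(tt, matrix(obs, 1))
  sm <- smooth_components(d, "lognormal")
  expect_true(all(sm[[1]]$value(tt) > 0))
  # chain rule: derivative of exp(g) is exp(g) g'
  g <- sm[[1]]$fit
  t0 <- 5
  expect_equal(sm[[1]]$deriv(t0),
               exp(predict(g, t0)) * predict(g, t0, deriv = 1))
  expect_error(smooth_components(timeseries_data(tt, matrix(obs - 3, 1)),
                                 "lognormal"), "positive")
})
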