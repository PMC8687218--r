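# small deterministic fixtures shared across tests

grid30 <- function(t_max = 10) seq(0, t_max, length.out = 30)

# two-compartment exchange model with closed-form solution
two_comp_model <- function() {
  k <- matrix(0, 2, 2); k[1, 2] <- 1
  build_linear_network(k, c(0, 1))
}

# seeded random linear network
random_linear_model <- function(seed, n = 3, x0 = NULL) {
  set.seed(seed)
  k <- matrix(runif(n * n), n, n); diag(k) <- 0
  build_linear_network(k, x0 %||% runif(n, 0.5, 1.5))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate a dataset from a given model/weights/h with additive or
# multiplicative noise (bypasses the random draws of the package generator)
make_dataset <- function(model, times, a = NULL, h = NULL, sigma = 0,
                         noise_kind = "normal", seed = 1) {
  truth <- solve_ode(model, times, a = a, h = h)
  tm <- t(as.matrix(truth[, -1]))
  set.seed(seed)
  obs <- if (sigma == 0) tm else if (noise_kind == "normal") {
    tm + matrix(rnorm(length(tm), 0, sigma), nrow(tm))
  } else {
    tm * exp(matrix(rnorm(length(tm), 0, sigma), nrow(tm)))
  }
  timeseries_data(times, obs, noise_kind = noise_kind, sigma = sigma,
                  truth = list(model = model, trajectories = tm,
                               h_true = h, a_true = a))
}

# manual smoothers wrapping known functions (bypasses spline fitting)
exact_smoothers <- function(value_fns, deriv_fns) {
  lapply(seq_along(value_fns), function(i) {
    list(value = value_fns[[i]], deriv = deriv_fns[[i]], component = i,
         log_scale = FALSE)
  })
}
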