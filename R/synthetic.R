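#' The package-standard hidden influence
#'
#' A fixed, deterministic single-peaked course used by every simulation:
#' a Gaussian bump of unit peak height centred at 40% of the time span with
#' width (standard deviation) 15% of the span. Its tails are below 5% of
#' the peak at both ends of the grid.
#'
#' @param times Increasing grid on which to tabulate the signal.
#' @return A [hidden_signal()].
#' @export
default_hidden_influence <- function(times) {
  span <- times[length(times)] - times[1]
  peak <- times[1] + 0.4 * span
  width <- 0.15 * span
  hidden_signal(times, exp(-0.5 * ((times - peak) / width)^2))
}

apply_noise <- function(truth, sigma, noise_kind) {
  if (sigma == 0) return(truth)
  eps <- matrix(stats::rnorm(length(truth), 0, sigma), nrow(truth))
  if (noise_kind == "normal") truth + eps else truth * exp(eps)
}

#' Simulate a random linear network with a shared hidden influence
#'
#' Draws transport rates `k_iu ~ U[0, 1]` and weights `a_i ~ U[-1, 1]`
#' (L1-normalized), simulates the linear mass-flow network driven by
#' [default_hidden_influence()] from initial values `U[0.5, 1.5]`, samples
#' `n_times` equally spaced time points and applies the requested noise.
#' The first `ceiling(observed_fraction * N)` components are marked
#' observed. The full generating truth is stored in the result.
#'
#' @param n_components Network size N.
#' @param observed_fraction Fraction of observed components in `(0, 1]`.
#' @param sigma Noise level (standard deviation; log scale for
#'   `"lognormal"`).
#' @param noise_kind `"lognormal"` (default, matching the positive domain
#'   of concentrations) or `"normal"`.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param n_times Number of equally spaced time points (default 30).
#' @param t_max End of the observation window (start is 0).
#' @return A [timeseries_data()] with a `truth` bundle (`model`, noise-free
#'   `trajectories`, `h_true`, `a_true`, `k_matrix`, `x0`, `seed`).
#' @export
simulate_linear_dataset <- function(n_components, observed_fraction = 1,
                                    sigma = 0.1,
                                    noise_kind = c("lognormal", "normal"),
                                    seed = 1L, n_times = 30L, t_max = 10) {
  noise_kind <- match.arg(noise_kind)
  if (observed_fraction <= 0 || observed_fraction > 1) {
    stop("`observed_fraction` must be in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  N <- n_components
  times <- seq(0, t_max, length.out = n_times)
  h <- default_hidden_influence(times)
  # concentrations must stay positive (the multiplicative noise model is
  # undefined otherwise): redraw parameter sets whose noise-free
  # trajectories dip below a small floor
  for (attempt in 1:200) {
    k <- matrix(stats::runif(N * N), N, N)
    diag(k) <- 0
    a <- stats::runif(N, -1, 1)
    a <- a / sum(abs(a))
    x0 <- stats::runif(N, 0.5, 1.5)
    model <- build_linear_network(k, x0)
    truth <- solve_ode_matrix(model, times, a = a, h = h)
    if (min(truth) > 0.05) break
    if (attempt == 200) {
      stop("could not draw a positive-trajectory network", call. = FALSE)
    }
  }
  obs <- apply_noise(truth, sigma, noise_kind)
  observed <- seq_len(N) <= ceiling(observed_fraction * N)
  rownames(obs) <- model$component_names
  timeseries_data(
    times, obs, observed = observed, noise_kind = noise_kind, sigma = sigma,
    truth = list(model = model, trajectories = truth, h_true = h,
                 a_true = a, k_matrix = k, x0 = x0, seed = seed))
}

#' Mean absolute deviation between latent courses
#'
#' The fit-quality score for an estimated hidden influence:
#' \eqn{s = (1/(n+1)) \sum_j |\hat h(t_j) - h(t_j)|}. Smaller is better.
#'
#' @param h_est,h_true [hidden_signal()] objects on identical grids.
#' @return The score (a scalar).
#' @export
score_s <- function(h_est, h_true) {
  if (length(h_est$times) != length(h_true$times) ||
      max(abs(h_est$times - h_true$times)) > 1e-8) {
    stop("latent courses are tabulated on different grids", call. = FALSE)
  }
  mean(abs(h_est$values - h_true$values))
}

#' Configure a simulation study
#'
#' @param sizes Network sizes to cover.
#' @param noise_levels Noise standard deviations.
#' @param observed_fractions Fractions of observed components.
#' @param replicates Replicates per cell.
#' @param base_seed Base seed; each replicate derives its own seed
#'   deterministically.
#' @param noise_kind Noise model used for generation and estimation.
#' @return A `study_config` list.
#' @export
study_config <- function(sizes = c(3, 6, 9),
                         noise_levels = c(0.01, 0.1, 0.3),
                         observed_fractions = c(1, 2 / 3, 1 / 3),
                         replicates = 100L, base_seed = 1L,
                         noise_kind = "lognormal") {
  structure(list(sizes = sizes, noise_levels = noise_levels,
                 observed_fractions = observed_fractions,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 noise_kind = noise_kind),
            class = "study_config")
}

# estimation model for a simulated dataset: true rates (the network
# structure is assumed known), observed initial values read off the data,
# unobserved initial values flagged unknown
estimation_model <- function(data) {
  model <- data$truth$model
  model$x0 <- ifelse(data$observed, data$values[, 1], 1)
  model$x0_unknown <- !data$observed
  model
}

#' Run the latent-recovery simulation study
#'
#' For every combination of network size, noise level and observed fraction
#' in the configuration, generates replicate datasets with
#' [simulate_linear_dataset()], runs support selection plus latent
#' estimation, and scores the recovered latent course against the truth
#' with [score_s()]. Per-replicate failures are recorded and excluded from
#' the summaries rather than aborting the study.
#'
#' @param config A [study_config()].
#' @param strategy,criterion Passed to [select_support()].
#' @param control A [latent_control()].
#' @return A `study_result` list with `replicates` (one row per run:
#'   cell descriptors, seed, score `s`, selected support size, error flag)
#'   and `summary` (per cell: `mean_s`, `q05`, `q95`, `n_failed`).
#' @export
run_simulation_study <- function(config = study_config(),
                                 strategy = "forward", criterion = "BIC",
                                 control = latent_control()) {
  cells <- expand.grid(size = config$sizes, frac = config$observed_fractions,
                       sigma = config$noise_levels,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells) * config$replicates)
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    N <- cells$size[ci]; frac <- cells$frac[ci]; sig <- cells$sigma[ci]
    for (r in seq_len(config$replicates)) {
      seed <- (config$base_seed + 7919L * ci + r) %% .Machine$integer.max
      idx <- idx + 1L
      res <- tryCatch({
        data <- simulate_linear_dataset(N, frac, sig, config$noise_kind,
                                        seed = seed)
        model <- estimation_model(data)
        sel <- select_support(data, model, strategy = strategy,
                              criterion = criterion,
                              noise_kind = config$noise_kind,
                              control = control)
        h_hat <- hidden_signal(data$times,
                               predict(sel$chosen$hidden, data$times))
        list(s = score_s(h_hat, data$truth$h_true),
             n_support = length(sel$chosen_support), failed = FALSE)
      }, error = function(e) list(s = NA_real_, n_support = NA_integer_,
                                  failed = TRUE))
      rows[[idx]] <- tibble::tibble(
        size = N, frac = frac, sigma = sig, replicate = r, seed = seed,
        s = res$s, n_support = res$n_support, failed = res$failed)
    }
  }
  replicates <- dplyr::bind_rows(rows)
  summary <- replicates |>
    dplyr::group_by(.data$size, .data$frac, .data$sigma) |>
    dplyr::summarise(
      n = dplyr::n(), n_failed = sum(.data$failed),
      mean_s = mean(.data$s, na.rm = TRUE),
      q05 = stats::quantile(.data$s, 0.05, na.rm = TRUE, names = FALSE),
      q95 = stats::quantile(.data$s, 0.95, na.rm = TRUE, names = FALSE),
      .groups = "drop")
  structure(list(replicates = replicates, summary = summary,
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$summary)
  invisible(x)
}

#' Simulate the misspecified-cascade repair experiment
#'
#' Generates data from the four-component forward cascade closed by an
#' end-to-start feedback flow, and returns alongside it the feedback-free
#' cascade (with free rates) as the misspecified starting hypothesis for
#' [repair_network()]. No hidden influence acts on the true system: the
#' latent component is purely a diagnostic device for the missing edge.
#'
#' @param seed Integer seed.
#' @param rates Three forward rates of the true cascade.
#' @param feedback_rate True feedback rate (`x4 -> x1`).
#' @param sigma Noise level.
#' @param noise_kind `"lognormal"` (default) or `"normal"`.
#' @param initial_values Four positive initial states.
#' @param n_times,t_max Sampling grid (30 equally spaced points by
#'   default).
#' @return A list with `data` (a [timeseries_data()] carrying the truth),
#'   `start_model` (the feedback-free hypothesis, rates free, initialized
#'   at 0.1) and `true_model`.
#' @export
cascade_experiment <- function(seed = 1L, rates = c(0.15, 0.29, 0.20),
                               feedback_rate = 0.2, sigma = 0.1,
                               noise_kind = c("lognormal", "normal"),
                               initial_values = c(4, 0.3, 0.3, 0.3),
                               n_times = 30L, t_max = 30) {
  noise_kind <- match.arg(noise_kind)
  set.seed(seed)
  true_model <- build_cascade_model(k = rates, feedback_rate = feedback_rate,
                                    initial_values = initial_values)
  times <- seq(0, t_max, length.out = n_times)
  truth <- solve_ode_matrix(true_model, times)
  obs <- apply_noise(truth, sigma, noise_kind)
  rownames(obs) <- true_model$component_names
  data <- timeseries_data(
    times, obs, noise_kind = noise_kind, sigma = sigma,
    truth = list(model = true_model, trajectories = truth,
                 a_pattern = c(1, 0, 0, -1) / 2, seed = seed))
  start_model <- build_cascade_model(k = rep(0.1, 3), feedback_rate = NULL,
                                     initial_values = initial_values,
                                     free = TRUE)
  list(data = data, start_model = start_model, true_model = true_model)
}
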