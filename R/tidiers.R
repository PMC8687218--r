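#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a latent estimate
#'
#' One row per estimated parameter: the latent weights (all components;
#' inactive ones are exactly zero), any estimated free rates and any
#' estimated initial values.
#'
#' @param x A `latent_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and `type`.
#' @method tidy latent_estimate
#' @export
tidy.latent_estimate <- function(x, ...) {
  out <- tibble::tibble(
    term = paste0("a[", x$component_names, "]"),
    estimate = x$a, type = "weight")
  if (length(x$rates_hat)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = names(x$rates_hat), estimate = unname(x$rates_hat),
      type = "rate"))
  }
  dplyr::bind_rows(out, tibble::tibble(
    term = "sigma2", estimate = x$sigma2, type = "noise"))
}

#' One-line summary of a latent estimate
#'
#' @param x A `latent_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `sigma2`, `AIC`, `BIC`, `n_a`,
#'   `converged` and `iterations`.
#' @method glance latent_estimate
#' @export
glance.latent_estimate <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, sigma2 = x$sigma2, AIC = x$aic,
                 BIC = x$bic, n_a = x$n_a, converged = x$converged,
                 iterations = x$iterations)
}

#' @rdname tidy.latent_estimate
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$path

#' @rdname glance.latent_estimate
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, criterion = x$criterion,
                 chosen = support_label(x$chosen_support),
                 value = x$chosen_criterion, null = x$null_criterion)
}

#' Extract fitted trajectories as a tibble
#'
#' @param est A `latent_estimate`.
#' @return A long tibble with `time`, `component`, `observed` (the data)
#'   and `fitted` (the refitted ODE solution).
#' @export
fitted_trajectories <- function(est) {
  nt <- length(est$times)
  tibble::tibble(
    time = rep(est$times, times = length(est$component_names)),
    component = rep(est$component_names, each = nt),
    observed = as.vector(t(est$data_values)),
    fitted = as.vector(t(est$trajectories)),
    is_observed_component = rep(est$observed, each = nt))
}
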