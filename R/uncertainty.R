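#' Diagonal expected Fisher information and Cramer-Rao bounds
#'
#' For the Gaussian observation model the diagonal information of the
#' latent weights is
#' \eqn{I_k = (1/\sigma^2) \sum_i \sum_j (\partial \hat x_i^{ode,a}(t_j) /
#' \partial a_k)^2}, with trajectory sensitivities computed by central
#' finite differences of the ODE solution (the raw weight is perturbed; no
#' re-normalization). The \eqn{\sigma^2} entry is available in closed form
#' as \eqn{N(n+1) / (2\sigma^4)}. The Cramer-Rao lower bound is the
#' element-wise reciprocal (infinite where the information vanishes). Under
#' log-normal noise the same quantities are computed on the log scale.
#'
#' @param model A `network_model`.
#' @param a Latent weights (length N).
#' @param sigma2 Noise variance.
#' @param h A [hidden_signal()].
#' @param times Observation grid.
#' @param x0 Initial values (required if the model flags unknowns).
#' @param observed Optional indices of observed components (default all).
#' @param noise_kind `"normal"` or `"lognormal"`.
#' @param delta_scale Relative step of the central difference; the step for
#'   weight `k` is `delta_scale * max(|a_k|, 1)`.
#' @return A `fisher_diagnostics` object whose `table` is a tibble with
#'   columns `parameter`, `info` and `crlb`.
#' @export
fisher_diagonal <- function(model, a, sigma2, h, times, x0 = NULL,
                            observed = NULL,
                            noise_kind = c("normal", "lognormal"),
                            delta_scale = 1e-4) {
  noise_kind <- match.arg(noise_kind)
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  obs <- observed %||% seq_len(model$n)
  solve1 <- function(av, k) {
    tryCatch(
      solve_ode_matrix(model, times, a = av, h = h, x0 = x0)[obs, ,
                                                             drop = FALSE],
      error = function(e) {
        stop(sprintf("sensitivity solve failed for weight %d: %s", k,
                     conditionMessage(e)), call. = FALSE)
      })
  }
  info <- numeric(model$n + 1)
  for (k in seq_len(model$n)) {
    if (!model$a_slots[k]) next  # no slot: trajectories are insensitive
    delta <- delta_scale * max(abs(a[k]), 1)
    ap <- a; ap[k] <- a[k] + delta
    am <- a; am[k] <- a[k] - delta
    up <- solve1(ap, k); um <- solve1(am, k)
    if (noise_kind == "lognormal") {
      if (any(up <= 0) || any(um <= 0)) {
        stop("log-scale sensitivities need positive trajectories",
             call. = FALSE)
      }
      up <- log(up); um <- log(um)
    }
    sens <- (up - um) / (2 * delta)
    info[k] <- sum(sens^2) / sigma2
  }
  info[model$n + 1] <- length(obs) * length(times) / (2 * sigma2^2)
  crlb <- ifelse(info > 0, 1 / info, Inf)
  structure(
    list(table = tibble::tibble(
           parameter = c(sprintf("a_%s", model$component_names), "sigma2"),
           info = info, crlb = crlb),
         method = sprintf("central differences, delta = %g * max(|a|, 1)%s",
                          delta_scale,
                          if (noise_kind == "lognormal")
                            " (log scale)" else ""),
         sigma2 = sigma2, noise_kind = noise_kind),
    class = "fisher_diagnostics"
  )
}

#' @export
print.fisher_diagnostics <- function(x, ...) {
  cat("<fisher_diagnostics>", x$method, "\n")
  print(x$table)
  invisible(x)
}

#' @method as_tibble fisher_diagnostics
#' @export
as_tibble.fisher_diagnostics <- function(x, ...) x$table
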