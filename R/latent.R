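#' Noise model specification
#'
#' @param kind `"normal"` (additive Gaussian error with constant variance)
#'   or `"lognormal"` (multiplicative error: the log-observation is Gaussian
#'   around the log of the truth).
#' @param sigma2 Error variance (on the log scale for `"lognormal"`).
#' @return A `noise_model` list.
#' @export
noise_model <- function(kind = c("normal", "lognormal"), sigma2 = 1) {
  kind <- match.arg(kind)
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  structure(list(kind = kind, sigma2 = sigma2), class = "noise_model")
}

#' Control parameters for latent estimation
#'
#' @param n_restarts Number of simplex starts (one data-driven start plus
#'   `n_restarts - 1` seeded random restarts).
#' @param maxit,reltol Nelder-Mead iteration cap and relative tolerance.
#' @param loop_max Iteration cap of the alternating loop for partially
#'   observed networks.
#' @param h_tol,ll_tol Convergence tolerances of that loop: max-abs change
#'   of the latent course and absolute change of the log-likelihood.
#' @param restart_seed Seed of the private stream generating restart
#'   jitters (the caller's RNG state is left untouched).
#' @param rtol,atol ODE solver tolerances used inside the likelihood loop;
#'   slightly looser than the [solve_ode()] defaults since the solver error
#'   is far below the measurement noise there.
#' @return A list of control settings.
#' @export
latent_control <- function(n_restarts = 3L, maxit = 500L, reltol = 1e-8,
                           loop_max = 100L, h_tol = 1e-4, ll_tol = 1e-6,
                           restart_seed = 42L, rtol = 1e-6, atol = 1e-8) {
  list(n_restarts = as.integer(n_restarts), maxit = as.integer(maxit),
       reltol = reltol, loop_max = as.integer(loop_max), h_tol = h_tol,
       ll_tol = ll_tol, restart_seed = as.integer(restart_seed),
       rtol = rtol, atol = atol)
}

# run code under a private RNG stream, restoring the caller's state
with_private_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Residual latent signal of one component
#'
#' Gradient matching: the candidate latent course seen from component `i` is
#' the spline-derivative residual
#' \eqn{\hat h_i^0(t_j) = \dot{\hat x}_i^{spl}(t_j) - \psi_i(k, \hat
#' x^{spl}(t_j))}.
#'
#' @param model A `network_model`.
#' @param smoothers Per-component smoothers from [smooth_components()]; for
#'   components without a smoother, rows of `state_values` are used instead
#'   (ODE-based stand-ins in the partially observed case).
#' @param component Component index `i`.
#' @param times Evaluation grid.
#' @param rates Rate values to evaluate \eqn{\psi_i} with.
#' @param state_values Optional components-by-times matrix of state values
#'   overriding the smoother evaluations.
#' @return Numeric vector of residuals, one per grid point.
#' @export
residual_signal <- function(model, smoothers, component, times,
                            rates = model$rates, state_values = NULL) {
  if (component < 1 || component > model$n) {
    stop("`component` out of range", call. = FALSE)
  }
  X <- state_values %||% smoother_states(model, smoothers, times)
  xdot <- smoother_for(smoothers, component)$deriv(times)
  psi <- psi_eval(model, X, rates, times)
  xdot - psi[component, ]
}

smoother_for <- function(smoothers, component) {
  for (s in smoothers) if (s$component == component) return(s)
  stop(sprintf("no smoother available for component %d", component),
       call. = FALSE)
}

smoother_states <- function(model, smoothers, times) {
  X <- matrix(NA_real_, model$n, length(times))
  for (s in smoothers) X[s$component, ] <- s$value(times)
  if (anyNA(X)) {
    stop("state values missing for unsmoothed components; ",
         "supply `state_values`", call. = FALSE)
  }
  X
}

#' Aggregate per-component residual signals into one latent course
#'
#' Pointwise weighted average over the active components:
#' \eqn{\hat h_a(t_j) = (1/N^a) \sum_{i: a_i \ne 0} \hat h_i^0(t_j) / a_i}.
#'
#' @param h0_table Components-by-times matrix of residual signals.
#' @param a Weight vector (zeros mark inactive components).
#' @param times Grid times (defaults to column indices).
#' @param interpolation Off-grid rule of the returned signal.
#' @return A [hidden_signal()].
#' @export
aggregate_hidden <- function(h0_table, a, times = NULL,
                             interpolation = "linear") {
  h0_table <- as.matrix(h0_table)
  act <- which(a != 0)
  if (length(act) == 0) {
    stop("all weights are zero; no latent course to aggregate",
         call. = FALSE)
  }
  v <- colMeans(h0_table[act, , drop = FALSE] / a[act])
  hidden_signal(times %||% seq_len(ncol(h0_table)), v,
                interpolation = interpolation)
}

# log density sum of the observations given fitted values (matrix in, both
# components x times, restricted to `rows`)
loglik_obs <- function(obs, fit, rows, kind, sigma2, log_obs_sum = NULL) {
  o <- obs[rows, , drop = FALSE]
  f <- fit[rows, , drop = FALSE]
  m <- length(o)
  if (kind == "normal") {
    -m / 2 * log(2 * pi * sigma2) - sum((o - f)^2) / (2 * sigma2)
  } else {
    if (any(f <= 0)) return(-Inf)
    ls <- log_obs_sum %||% sum(log(o))
    -ls - m / 2 * log(2 * pi * sigma2) -
      sum((log(o) - log(f))^2) / (2 * sigma2)
  }
}

#' Log-likelihood of a dataset under a latent-influence model
#'
#' Solves the network with the supplied weights and latent course and sums
#' the observation log densities over the observed components and all time
#' points. Under log-normal noise a non-positive fitted value yields `-Inf`
#' with a warning.
#'
#' @param model A `network_model`.
#' @param data A [timeseries_data()].
#' @param a Latent weights (length N), or `NULL` for the null model.
#' @param noise A [noise_model()].
#' @param h A [hidden_signal()], or `NULL`.
#' @param x0,rates Optional overrides passed to the solver.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(model, data, a = NULL,
                           noise = noise_model("normal", 1), h = NULL,
                           x0 = NULL, rates = model$rates) {
  traj <- solve_ode_matrix(model, data$times, a = a, h = h, rates = rates,
                           x0 = x0)
  ll <- loglik_obs(data$values, traj, which(data$observed), noise$kind,
                   noise$sigma2)
  if (identical(ll, -Inf)) {
    warning("non-positive fitted value under log-normal noise; ",
            "log-likelihood is -Inf", call. = FALSE)
  }
  ll
}

#' Analytic maximum-likelihood noise variance
#'
#' The conditional MLE of the error variance: the mean squared residual
#' between observations and fitted trajectories over all observed entries
#' (squared log-residuals under log-normal noise).
#'
#' @param data A [timeseries_data()] (or a numeric matrix of observations).
#' @param fitted Fitted trajectories, components x times.
#' @param noise_kind `"normal"` or `"lognormal"`.
#' @return The variance estimate.
#' @export
sigma2_mle <- function(data, fitted, noise_kind = c("normal", "lognormal")) {
  noise_kind <- match.arg(noise_kind)
  if (inherits(data, "timeseries_data")) {
    obs <- data$values[data$observed, , drop = FALSE]
    fit <- as.matrix(fitted)[data$observed, , drop = FALSE]
  } else {
    obs <- as.matrix(data); fit <- as.matrix(fitted)
  }
  if (length(obs) == 0) stop("no observed entries", call. = FALSE)
  if (noise_kind == "normal") {
    mean((obs - fit)^2)
  } else {
    if (any(obs <= 0) || any(fit <= 0)) {
      stop("log-normal variance needs positive observations and fits",
           call. = FALSE)
    }
    mean((log(obs) - log(fit))^2)
  }
}

# normalize unconstrained weights onto the L1 sphere
normalize_weights <- function(u) {
  s <- sum(abs(u))
  if (s < 1e-12) return(NULL)
  u / s
}

# deterministic data-driven start: h0 rows are approximately a_i * h, so
# regressing each row on the largest-norm row recovers relative weights
initial_weights <- function(h0) {
  nr <- nrow(h0)
  norms <- sqrt(rowSums(h0^2))
  r <- which.max(norms)
  if (norms[r] < 1e-12) return(rep(1 / nr, nr))
  u <- as.numeric(h0 %*% h0[r, ]) / norms[r]^2
  if (sum(abs(u)) < 1e-8) u <- rep(1 / nr, nr)
  u / sum(abs(u))
}

run_simplex <- function(fn, starts, maxit, reltol) {
  best <- NULL
  for (p0 in starts) {
    res <- if (length(p0) == 1) {
      stats::optim(p0, fn, method = "Brent", lower = p0 - 12, upper = p0 + 12)
    } else {
      stats::optim(p0, fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

new_latent_estimate <- function(model, data, support, a, sigma2, hidden,
                                traj, loglik, rates_hat, x0_hat, noise_kind,
                                converged, iterations = 1L) {
  n_obs <- sum(data$observed)
  n1 <- length(data$times)
  n_a <- length(support)
  structure(
    list(support = support, a = a, sigma2 = sigma2, hidden = hidden,
         trajectories = traj, loglik = loglik, rates_hat = rates_hat,
         x0_hat = x0_hat, n_a = n_a, noise_kind = noise_kind,
         aic = information_criterion(loglik, n_a, n1, n_obs, "AIC"),
         bic = information_criterion(loglik, n_a, n1, n_obs, "BIC"),
         converged = converged, iterations = iterations,
         times = data$times, component_names = model$component_names,
         observed = data$observed, data_values = data$values),
    class = "latent_estimate"
  )
}

#' @export
print.latent_estimate <- function(x, ...) {
  cat(sprintf("<latent_estimate> support {%s}, logLik = %.4f, BIC = %.4f\n",
              paste(x$support, collapse = ","), x$loglik, x$bic))
  if (x$n_a > 0) {
    cat("  weights:", sprintf("%.4f", x$a), "\n")
  }
  cat(sprintf("  sigma2 = %.6g (%s noise)%s\n", x$sigma2, x$noise_kind,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Estimate a latent influence on a fully observed network
#'
#' Maximum-likelihood estimation of the hidden-influence weights restricted
#' to a candidate support, under the identifiability normalization
#' \eqn{\sum_i |a_i| = 1}. At every objective evaluation the latent course
#' is recomputed from the spline residuals via [residual_signal()] and
#' [aggregate_hidden()], the network is re-solved with the candidate
#' weights, and the noise variance is profiled out analytically. Free rates
#' (log-transformed) and unknown initial values are estimated jointly. An
#' empty support fits the null model (no latent influence).
#'
#' @param data A fully observed [timeseries_data()].
#' @param model A `network_model`.
#' @param support Integer vector of components the influence acts on (may
#'   be empty).
#' @param noise_kind `"normal"` or `"lognormal"`.
#' @param smoothers Optional cached result of [smooth_components()]; fitted
#'   here (once) when missing.
#' @param control A [latent_control()].
#' @param u_start Optional warm-start weights over `support` (used by the
#'   stepwise searches).
#' @return A `latent_estimate` with the normalized weights `a`, noise
#'   variance `sigma2`, latent course `hidden`, refitted trajectories,
#'   log-likelihood, AIC/BIC, estimated rates and initial values.
#' @export
estimate_latent <- function(data, model, support = integer(),
                            noise_kind = c("normal", "lognormal"),
                            smoothers = NULL, control = latent_control(),
                            u_start = NULL) {
  noise_kind <- match.arg(noise_kind)
  if (!all(data$observed)) {
    stop("data has unobserved components; use estimate_latent_partial()",
         call. = FALSE)
  }
  support <- sort(unique(as.integer(support)))
  if (length(support) && (min(support) < 1 || max(support) > model$n)) {
    stop("`support` out of range", call. = FALSE)
  }
  if (length(support) && any(!model$a_slots[support])) {
    stop("`support` includes a component without a latent slot",
         call. = FALSE)
  }
  smoothers <- smoothers %||% smooth_components(data, noise_kind)
  fit_latent_core(data, model, support, noise_kind, smoothers,
                  standins = NULL, obs_idx = seq_len(model$n),
                  control = control, u_start = u_start)
}

# shared ML core. `standins` (components x times) provides state values for
# components without smoothers (partially observed case); obs_idx gives the
# components entering the likelihood.
fit_latent_core <- function(data, model, support, noise_kind, smoothers,
                            standins, obs_idx, control, u_start = NULL) {
  times <- data$times
  n <- model$n
  nt <- length(times)
  have_sm <- vapply(smoothers, function(s) s$component, integer(1))
  X <- matrix(NA_real_, n, nt)
  Xdot <- matrix(NA_real_, n, nt)
  for (s in smoothers) {
    X[s$component, ] <- s$value(times)
    Xdot[s$component, ] <- s$deriv(times)
  }
  if (!is.null(standins)) {
    miss <- setdiff(seq_len(n), have_sm)
    X[miss, ] <- standins[miss, , drop = FALSE]
  }
  log_obs_sum <- if (noise_kind == "lognormal") {
    sum(log(data$values[obs_idx, , drop = FALSE]))
  } else NULL

  free_k <- model$free_rates
  nk <- length(free_k)
  x0_free <- which(model$x0_unknown)
  nx <- length(x0_free)
  ns <- length(support)
  n_u <- if (ns >= 2) ns else 0L

  base_rates <- model$rates
  base_x0 <- model$x0
  if (nx) {
    # data-informed default start for unknown initial values
    base_x0[x0_free] <- ifelse(is.finite(base_x0[x0_free]) &
                                 base_x0[x0_free] > 0,
                               base_x0[x0_free], 1)
  }

  unpack <- function(theta, sgn) {
    a <- numeric(n)
    if (ns) {
      if (n_u) {
        w <- normalize_weights(theta[seq_len(n_u)])
        if (is.null(w)) return(NULL)
        a[support] <- w
      } else {
        a[support] <- sgn
      }
    }
    rates <- base_rates
    if (nk) rates[free_k] <- exp(theta[n_u + seq_len(nk)])
    x0 <- base_x0
    if (nx) x0[x0_free] <- theta[n_u + nk + seq_len(nx)]
    list(a = a, rates = rates, x0 = x0)
  }

  # with no free rates psi at the spline states is a constant of the fit
  psi_pre <- if (length(model$free_rates) == 0 && length(support)) {
    psi_eval(model, X, model$rates, times)
  } else NULL
  A_pre <- if (model$kind == "linear" && length(model$free_rates) == 0) {
    linear_A(model, model$rates)
  } else NULL
  slots <- as.numeric(model$a_slots)
  empty <- numeric(0)

  # Superposition fast path. A linear network with fixed rates responds
  # linearly to the forcing and to the initial values, so the trajectory is
  # assembled from unit responses precomputed once per fit:
  #   x(t) = x_fixed(t) + sum_f x0_f U_f(t)
  #          + sum_{i,j in S} a_j / (N^a a_i) R_{ij}(t),
  # R_{ij} being the response of component channel S_j to the residual
  # course h0_i with zero initial state. Objective evaluations then involve
  # no ODE solves at all.
  fast <- !is.null(A_pre)
  if (fast) {
    solve0 <- function(av, hv, x0v) {
      t(.dp45_linear(A_pre, av, if (length(hv)) times else empty, hv,
                     x0v, times, control$rtol, control$atol))
    }
    x0_fixed <- base_x0
    if (nx) x0_fixed[x0_free] <- 0
    traj_fixed_vec <- as.vector(solve0(numeric(n), empty, x0_fixed))
    U <- if (nx) {
      vapply(x0_free, function(f) {
        e <- numeric(n); e[f] <- 1
        as.vector(solve0(numeric(n), empty, e))
      }, numeric(n * nt))
    } else NULL
    if (ns) {
      h0_S <- Xdot[support, , drop = FALSE] -
        psi_pre[support, , drop = FALSE]
      Rmat <- matrix(0, n * nt, ns * ns)
      for (i in seq_len(ns)) {
        for (j in seq_len(ns)) {
          e <- numeric(n); e[support[j]] <- 1
          Rmat[, (i - 1L) * ns + j] <-
            as.vector(solve0(e, h0_S[i, ], numeric(n)))
        }
      }
    }
  }

  eval_fit <- function(a, rates, x0) {
    if (fast) {
      tv <- traj_fixed_vec
      if (nx) tv <- tv + drop(U %*% x0[x0_free])
      if (any(a != 0)) {
        aS <- a[support]
        act <- aS != 0
        # column (i-1)*ns+j carries a_Sj / (N^a a_Si); inactive i drop out
        coef <- outer(aS, ifelse(act, 1 / (sum(act) * aS), 0))
        tv <- tv + drop(Rmat %*% as.vector(coef))
        hv <- colMeans(h0_S[act, , drop = FALSE] / aS[act])
        h <- structure(list(times = times, values = hv,
                            interpolation = "linear"),
                       class = "hidden_signal")
      } else {
        h <- NULL
      }
      traj <- matrix(tv, n, nt)
    } else {
      if (any(a != 0)) {
        act <- which(a != 0)
        psi <- psi_pre %||% psi_eval(model, X, rates, times)
        h0 <- Xdot[act, , drop = FALSE] - psi[act, , drop = FALSE]
        hv <- colMeans(h0 / a[act])
        h <- structure(list(times = times, values = hv,
                            interpolation = "linear"),
                       class = "hidden_signal")
      } else {
        h <- NULL
      }
      traj <- if (model$kind == "linear") {
        # direct compiled path (validation done once up front)
        A <- linear_A(model, rates)
        out <- tryCatch({
          if (is.null(h)) {
            .dp45_linear(A, numeric(model$n), empty, empty, x0, times,
                         control$rtol, control$atol)
          } else {
            .dp45_linear(A, a * slots, times, h$values, x0, times,
                         control$rtol, control$atol)
          }
        }, error = function(e) NULL)
        if (is.null(out) || anyNA(out)) NULL else t(out)
      } else {
        tryCatch(
          solve_ode_matrix(model, times, a = if (is.null(h)) NULL else a,
                           h = h, rates = rates, x0 = x0,
                           rtol = control$rtol, atol = control$atol),
          error = function(e) NULL)
      }
    }
    if (is.null(traj)) return(NULL)
    s2 <- if (noise_kind == "normal") {
      mean((data$values[obs_idx, ] - traj[obs_idx, ])^2)
    } else {
      f <- traj[obs_idx, , drop = FALSE]
      if (any(f <= 0)) return(list(ll = -Inf, traj = traj, h = h,
                                   sigma2 = NA_real_))
      mean((log(data$values[obs_idx, , drop = FALSE]) - log(f))^2)
    }
    s2 <- max(s2, 1e-30)
    ll <- loglik_obs(data$values, traj, obs_idx, noise_kind, s2,
                     log_obs_sum)
    list(ll = ll, traj = traj, h = h, sigma2 = s2)
  }

  objective <- function(theta, sgn = 1) {
    p <- unpack(theta, sgn)
    if (is.null(p)) return(1e10)
    f <- eval_fit(p$a, p$rates, p$x0)
    if (is.null(f) || !is.finite(f$ll)) return(1e10)
    -f$ll
  }

  # starting points --------------------------------------------------------
  theta_k0 <- if (nk) log(pmax(base_rates[free_k], 1e-3)) else numeric(0)
  theta_x0 <- if (nx) base_x0[x0_free] else numeric(0)
  u0 <- if (n_u) {
    rr <- base_rates
    psi0 <- psi_eval(model, X, rr, times)
    h0s <- Xdot[support, , drop = FALSE] - psi0[support, , drop = FALSE]
    initial_weights(h0s)
  } else numeric(0)
  p0 <- c(u0, theta_k0, theta_x0)

  starts <- list(p0)
  if (n_u && !is.null(u_start)) {
    w <- normalize_weights(u_start)
    if (!is.null(w)) starts <- c(list(c(w, theta_k0, theta_x0)), starts)
  }
  if (length(p0) && control$n_restarts > 1) {
    starts <- c(starts, with_private_seed(control$restart_seed, {
      lapply(seq_len(control$n_restarts - 1), function(i) {
        jit <- p0
        if (n_u) jit[seq_len(n_u)] <- stats::runif(n_u, -1, 1)
        if (nk) jit[n_u + seq_len(nk)] <-
            theta_k0 + stats::rnorm(nk, 0, 1)
        if (nx) jit[n_u + nk + seq_len(nx)] <-
            theta_x0 * exp(stats::rnorm(nx, 0, 0.3))
        jit
      })
    }))
  }

  signs <- if (ns && n_u == 0) c(1, -1) else 1
  best <- NULL
  for (sgn in signs) {
    if (length(p0) == 0) {
      val <- objective(numeric(0), sgn)
      cand <- list(par = numeric(0), value = val, convergence = 0L,
                   sgn = sgn)
    } else {
      fn <- function(th) objective(th, sgn)
      cand <- run_simplex(fn, starts, control$maxit, control$reltol)
      cand$sgn <- sgn
    }
    if (is.null(best) || cand$value < best$value) best <- cand
  }

  p <- unpack(best$par, best$sgn)
  f <- eval_fit(p$a, p$rates, p$x0)
  if (is.null(f)) stop("final model solve failed", call. = FALSE)
  # (a, h) and (-a, -h) are likelihood-equivalent; report the
  # representative whose latent course has non-negative mean
  if (!is.null(f$h) && mean(f$h$values) < 0) {
    p$a <- -p$a
    f$h$values <- -f$h$values
  }
  new_latent_estimate(
    model, data, support, p$a, f$sigma2,
    f$h %||% zero_signal(times), f$traj, f$ll,
    rates_hat = p$rates[free_k], x0_hat = p$x0,
    noise_kind = noise_kind,
    converged = is.finite(f$ll) && (best$convergence %||% 0L) == 0L)
}

#' Estimate a latent influence on a partially observed network
#'
#' For networks where only the first `M < N` components (or affine
#' transformations thereof, with the model already expressed in observed
#' coordinates) are measured. A preliminary step solves the full system
#' without a latent influence to obtain stand-in trajectories for the
#' unobserved coordinates; the procedure then alternates (i) residual
#' extraction and aggregation on the observed channels, (ii) a
#' maximum-likelihood update of the weights, noise variance, free rates and
#' unknown initial values, and (iii) a re-solve of the unobserved
#' coordinates under the current latent estimate, until both the latent
#' course and the log-likelihood stabilize.
#'
#' @inheritParams estimate_latent
#' @param data A [timeseries_data()] with at least one unobserved
#'   component; `support` must lie within the observed components.
#' @return A `latent_estimate`; `iterations` records the number of
#'   alternation sweeps and `converged` whether both tolerances were met.
#' @export
estimate_latent_partial <- function(data, model, support = integer(),
                                    noise_kind = c("normal", "lognormal"),
                                    smoothers = NULL,
                                    control = latent_control(),
                                    u_start = NULL) {
  noise_kind <- match.arg(noise_kind)
  if (all(data$observed)) {
    return(estimate_latent(data, model, support, noise_kind, smoothers,
                           control, u_start = u_start))
  }
  obs_idx <- which(data$observed)
  support <- sort(unique(as.integer(support)))
  if (length(support) && !all(support %in% obs_idx)) {
    stop("`support` must lie within the observed components", call. = FALSE)
  }
  smoothers <- smoothers %||% smooth_components(data, noise_kind)

  # preliminary step: solve the full system with h == 0, estimating any
  # unknown initial values there. They are held fixed afterwards: with a
  # free-form latent course active they are no longer identified (the
  # signal can absorb their effect on the observed channels).
  est <- fit_latent_core(data, model, integer(), noise_kind, smoothers,
                         standins = matrix(0, model$n, length(data$times)),
                         obs_idx = obs_idx, control = control)
  standins <- est$trajectories
  if (length(support) == 0) return(est)
  model$x0 <- est$x0_hat
  model$x0_unknown <- rep(FALSE, model$n)

  h_prev <- NULL
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$loop_max)) {
    est <- fit_latent_core(data, model, support, noise_kind, smoothers,
                           standins = standins, obs_idx = obs_idx,
                           control = control, u_start = u_start)
    standins <- est$trajectories
    u_start <- est$a[support]  # warm-start subsequent sweeps
    hv <- est$hidden$values
    dh <- if (is.null(h_prev)) Inf else max(abs(hv - h_prev))
    dll <- abs(est$loglik - ll_prev)
    h_prev <- hv
    ll_prev <- est$loglik
    if (dh < control$h_tol && dll < control$ll_tol) {
      converged <- TRUE
      break
    }
  }
  est$iterations <- iter
  est$converged <- est$converged && converged
  est
}
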