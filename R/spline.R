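#' Default smoothing-parameter grid
#'
#' 25 logarithmically spaced values between 1e-4 and 1e4.
#' @return Numeric vector of candidate lambda values.
#' @export
default_lambda_grid <- function() 10^seq(-4, 4, length.out = 25)

# equally spaced cubic B-spline basis with K functions over [t0, tn]
# (P-spline construction: knots extended three segments past each boundary)
bspline_knots <- function(domain, K) {
  if (K < 4) stop("cubic B-splines need K >= 4", call. = FALSE)
  ndx <- K - 3
  dx <- diff(domain) / ndx
  kn <- domain[1] + dx * seq(-3L, ndx + 3L)
  # pin the boundary knots exactly (guards against floating-point drift)
  kn[4] <- domain[1]
  kn[ndx + 4] <- domain[2]
  kn
}

bspline_basis <- function(knots, x, deriv = 0L) {
  splines::splineDesign(knots, x, ord = 4,
                        derivs = rep(deriv, length(x)),
                        outer.ok = FALSE)
}

#' Fit a penalized B-spline
#'
#' Minimizes \eqn{\|y - \Phi\beta\|^2 + \lambda \beta' D'D \beta} where
#' \eqn{\Phi} is a cubic B-spline basis on an equally spaced grid over the
#' observation window and \eqn{D} is the order-2 difference operator on the
#' coefficients (a finite-difference stand-in for the curvature penalty).
#' The null space of the penalty is the linear functions, so for very large
#' `lambda` the fit approaches the least-squares straight line.
#'
#' @param times Strictly increasing observation times (at least 4).
#' @param values Observations, same length as `times`.
#' @param K Basis dimension; default `min(length(times), 20)`.
#' @param lambda Smoothing parameter, `>= 0`.
#' @return A `spline_fit` with elements `basis_kind`, `K`, `knots`,
#'   `lambda`, `coefficients` and `domain`; evaluate with [predict()] or
#'   [evaluate_spline()].
#' @examples
#' t <- seq(0, 1, length.out = 30)
#' f <- fit_penalized_spline(t, sin(2 * pi * t) + rnorm(30, 0, 0.05), lambda = 1)
#' predict(f, 0.5)
#' @export
fit_penalized_spline <- function(times, values, K = min(length(times), 20L),
                                 lambda = 0) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 4 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with at least 4 points",
         call. = FALSE)
  }
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  domain <- range(times)
  knots <- bspline_knots(domain, K)
  Phi <- bspline_basis(knots, times)
  D <- diff(diag(K), differences = 2)
  M <- crossprod(Phi) + lambda * crossprod(D)
  beta <- tryCatch(solve(M, crossprod(Phi, values)),
                   error = function(e) {
                     stop("penalized normal equations are singular; ",
                          "reduce K or increase lambda", call. = FALSE)
                   })
  structure(
    list(basis_kind = "bspline", K = K, knots = knots, lambda = lambda,
         coefficients = as.numeric(beta), domain = domain),
    class = "spline_fit"
  )
}

#' Evaluate a fitted spline or its first derivative
#'
#' @param fit A `spline_fit`.
#' @param times Evaluation times, all within the fit domain (no
#'   extrapolation).
#' @param derivative_order 0 for values, 1 for first derivatives.
#' @return Numeric vector of evaluations.
#' @export
evaluate_spline <- function(fit, times, derivative_order = 0L) {
  if (!derivative_order %in% c(0L, 1L)) {
    stop("`derivative_order` must be 0 or 1", call. = FALSE)
  }
  eps <- 1e-10 * diff(fit$domain)
  if (any(times < fit$domain[1] - eps | times > fit$domain[2] + eps)) {
    stop("evaluation outside the fitted domain", call. = FALSE)
  }
  times <- pmin(pmax(times, fit$domain[1]), fit$domain[2])
  drop(bspline_basis(fit$knots, times, deriv = derivative_order) %*%
         fit$coefficients)
}

#' @rdname evaluate_spline
#' @param object A `spline_fit`.
#' @param newtimes Evaluation times.
#' @param deriv 0 or 1.
#' @param ... Unused.
#' @export
predict.spline_fit <- function(object, newtimes, deriv = 0L, ...) {
  evaluate_spline(object, newtimes, derivative_order = deriv)
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("<spline_fit> K = %d cubic B-splines on [%g, %g], lambda = %g\n",
              x$K, x$domain[1], x$domain[2], x$lambda))
  invisible(x)
}

#' Select the smoothing parameter by leave-one-out cross-validation
#'
#' For each candidate lambda the spline is refitted `n + 1` times, each time
#' leaving out one observation, and scored by the sum of squared prediction
#' errors at the left-out points. The grid value with the smallest score
#' wins; ties break toward the larger (smoother) lambda. A candidate whose
#' leave-one-out fit fails is scored `Inf` with a warning.
#'
#' @inheritParams fit_penalized_spline
#' @param lambda_grid Positive candidate values; default
#'   [default_lambda_grid()].
#' @return A list with `lambda` (the selected value) and `cv_scores`, a
#'   tibble with columns `lambda` and `cv_score`.
#' @export
select_lambda_loocv <- function(times, values, K = min(length(times), 20L),
                                lambda_grid = default_lambda_grid()) {
  if (length(lambda_grid) < 1) stop("`lambda_grid` is empty", call. = FALSE)
  if (length(times) < 5) {
    stop("need at least 5 observations for leave-one-out selection",
         call. = FALSE)
  }
  domain <- range(times)
  knots <- bspline_knots(domain, K)
  Phi <- bspline_basis(knots, times)
  D2 <- crossprod(diff(diag(K), differences = 2))
  n1 <- length(times)
  scores <- vapply(lambda_grid, function(lam) {
    tryCatch({
      s <- 0
      for (j in seq_len(n1)) {
        Pj <- Phi[-j, , drop = FALSE]
        beta <- solve(crossprod(Pj) + lam * D2,
                      crossprod(Pj, values[-j]))
        s <- s + (values[j] - drop(Phi[j, ] %*% beta))^2
      }
      s
    }, error = function(e) {
      warning(sprintf("leave-one-out fit failed at lambda = %g", lam),
              call. = FALSE)
      Inf
    })
  }, numeric(1))
  best <- max(which(scores == min(scores)))  # ties -> larger lambda
  list(lambda = lambda_grid[best],
       cv_scores = tibble::tibble(lambda = lambda_grid, cv_score = scores))
}

# Per-component smoothers. For log-normal noise the spline is fitted on the
# log scale (keeping the additive-error working assumption coherent) and
# mapped back: value = exp(g), derivative = exp(g) g'.
new_smoother <- function(fit, log_scale) {
  force(fit); force(log_scale)
  if (log_scale) {
    list(value = function(t) exp(evaluate_spline(fit, t)),
         deriv = function(t) {
           g <- evaluate_spline(fit, t)
           exp(g) * evaluate_spline(fit, t, 1L)
         },
         fit = fit, log_scale = TRUE)
  } else {
    list(value = function(t) evaluate_spline(fit, t),
         deriv = function(t) evaluate_spline(fit, t, 1L),
         fit = fit, log_scale = FALSE)
  }
}

#' Smooth all observed components of a dataset
#'
#' Fits one penalized B-spline per observed component, selecting each
#' smoothing parameter by leave-one-out cross-validation. With log-normal
#' noise the splines are fitted on the log scale and transformed back.
#'
#' @param data A [timeseries_data()] object.
#' @param noise_kind `"normal"` or `"lognormal"`.
#' @inheritParams select_lambda_loocv
#' @return A named list of smoothers (one per observed component), each with
#'   `value(t)` and `deriv(t)` evaluators, the underlying `fit` and the
#'   selected lambda.
#' @export
smooth_components <- function(data, noise_kind = c("normal", "lognormal"),
                              K = min(length(data$times), 20L),
                              lambda_grid = default_lambda_grid()) {
  noise_kind <- match.arg(noise_kind)
  obs <- which(data$observed)
  out <- vector("list", length(obs))
  names(out) <- data$component_names[obs]
  for (s in seq_along(obs)) {
    y <- data$values[obs[s], ]
    if (noise_kind == "lognormal") {
      if (any(y <= 0)) {
        stop("log-normal smoothing requires strictly positive observations",
             call. = FALSE)
      }
      y <- log(y)
    }
    sel <- select_lambda_loocv(data$times, y, K = K,
                               lambda_grid = lambda_grid)
    fit <- fit_penalized_spline(data$times, y, K = K, lambda = sel$lambda)
    sm <- new_smoother(fit, log_scale = noise_kind == "lognormal")
    sm$lambda <- sel$lambda
    sm$component <- obs[s]
    out[[s]] <- sm
  }
  out
}
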