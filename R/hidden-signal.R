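#' Create a hidden-signal time course
#'
#' A `hidden_signal` stores a latent (or exogenous) time course \eqn{h(t)} on
#' a grid of time points, together with an interpolation rule used whenever
#' the ODE solver needs \eqn{h} between grid points. Evaluation at a grid
#' point returns exactly the stored value.
#'
#' @param times Strictly increasing numeric vector of grid times.
#' @param values Numeric vector of signal values, same length as `times`.
#' @param interpolation Off-grid evaluation rule: `"linear"` (piecewise
#'   linear, bounded and shape-preserving; the default) or `"cubic"`
#'   (natural cubic spline through the grid values).
#' @return An object of class `hidden_signal`.
#' @examples
#' h <- hidden_signal(0:10, sin(0:10 / 2))
#' predict(h, c(0.5, 3.25))
#' @export
hidden_signal <- function(times, values, interpolation = c("linear", "cubic")) {
  interpolation <- match.arg(interpolation)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with at least two points",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  structure(
    list(times = times, values = values, interpolation = interpolation),
    class = "hidden_signal"
  )
}

#' Evaluate a hidden signal
#'
#' @param object A [hidden_signal()].
#' @param newtimes Times at which to evaluate; values outside the grid range
#'   are held at the boundary values.
#' @param ... Unused.
#' @return Numeric vector of signal values.
#' @export
predict.hidden_signal <- function(object, newtimes, ...) {
  out <- if (object$interpolation == "linear") {
    stats::approx(object$times, object$values, xout = newtimes,
                  rule = 2)$y
  } else {
    f <- stats::splinefun(object$times, object$values, method = "natural")
    tl <- pmin(pmax(newtimes, object$times[1]),
               object$times[length(object$times)])
    f(tl)
  }
  # grid points return the stored values exactly
  hit <- match(newtimes, object$times)
  ok <- !is.na(hit)
  out[ok] <- object$values[hit[ok]]
  out
}

#' @export
print.hidden_signal <- function(x, ...) {
  cat(sprintf("<hidden_signal> %d points on [%g, %g], %s interpolation\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$interpolation))
  invisible(x)
}

#' @method as_tibble hidden_signal
#' @export
as_tibble.hidden_signal <- function(x, ...) {
  tibble::tibble(time = x$times, h = x$values)
}

is_hidden_signal <- function(x) inherits(x, "hidden_signal")

# zero signal on a grid (null model h == 0)
zero_signal <- function(times) {
  hidden_signal(range(times), c(0, 0))
}
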