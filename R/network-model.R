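#' @useDynLib latentdyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom tibble tibble as_tibble
NULL

new_network_model <- function(n, component_names, rates, free_rates, x0,
                              x0_unknown, kind, flows = NULL, psi = NULL,
                              a_slots = rep(TRUE, n), extra = list()) {
  stopifnot(length(component_names) == n, length(x0) == n,
            length(x0_unknown) == n)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  structure(
    list(n = n, component_names = component_names,
         rates = rates, free_rates = free_rates,
         x0 = x0, x0_unknown = x0_unknown,
         kind = kind, flows = flows, psi = psi,
         a_slots = a_slots, extra = extra),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d components (%s), kind = %s\n", x$n,
              paste(x$component_names, collapse = ", "), x$kind))
  cat(sprintf("  rates: %s\n",
              paste(sprintf("%s=%.4g", names(x$rates), x$rates),
                    collapse = ", ")))
  if (length(x$free_rates)) {
    cat(sprintf("  free rates: %s\n", paste(x$free_rates, collapse = ", ")))
  }
  if (any(x$x0_unknown)) {
    cat(sprintf("  unknown initial values: %s\n",
                paste(x$component_names[x$x0_unknown], collapse = ", ")))
  }
  invisible(x)
}

# interaction matrix A of a linear mass-flow model: a flow u -> i with rate r
# contributes +r*x_u to equation i and -r*x_u to equation u.
linear_A <- function(model, rates = model$rates) {
  A <- matrix(0, model$n, model$n)
  fl <- model$flows
  for (r in seq_len(nrow(fl))) {
    k <- rates[[fl$rate[r]]]
    A[fl$to[r], fl$from[r]] <- A[fl$to[r], fl$from[r]] + k
    A[fl$from[r], fl$from[r]] <- A[fl$from[r], fl$from[r]] - k
  }
  A
}

# evaluate the network right-hand side psi_i(k, x) (no hidden term).
# x may be a matrix (components x times); returns the same shape.
psi_eval <- function(model, x, rates = model$rates, t = 0) {
  if (model$kind == "linear") {
    linear_A(model, rates) %*% x
  } else if (is.matrix(x)) {
    vapply(seq_len(ncol(x)),
           function(j) model$psi(t[j], x[, j], rates),
           numeric(model$n))
  } else {
    model$psi(t, x, rates)
  }
}

#' Build a linear mass-flow network
#'
#' Constructs an N-component model with right-hand side
#' \deqn{\dot x_i = \sum_u (k_{iu} x_u - k_{ui} x_i)}
#' where `k_matrix[i, u]` is the transport rate from component `u` into
#' component `i`. Total mass is conserved by construction, so any additive
#' hidden influence with weights summing to zero leaves the total unchanged.
#'
#' @param k_matrix Square non-negative matrix of transport rates
#'   (zero diagonal; diagonal entries are ignored).
#' @param initial_values Numeric vector of initial states, one per component.
#' @param component_names Optional component labels (default `x1`, `x2`, ...).
#' @param free Optional character vector of rate names (`"k_i_u"`) to treat
#'   as unknown and estimate, or `TRUE` for all rates.
#' @return A `network_model`.
#' @examples
#' k <- matrix(0, 2, 2); k[1, 2] <- 1
#' m <- build_linear_network(k, c(0, 1))
#' solve_ode(m, seq(0, 1, 0.25))
#' @export
build_linear_network <- function(k_matrix, initial_values,
                                 component_names = NULL, free = NULL) {
  k_matrix <- as.matrix(k_matrix)
  if (nrow(k_matrix) != ncol(k_matrix)) {
    stop("`k_matrix` must be square", call. = FALSE)
  }
  if (any(k_matrix < 0)) {
    stop("`k_matrix` entries must be non-negative", call. = FALSE)
  }
  n <- nrow(k_matrix)
  if (length(initial_values) != n) {
    stop("`initial_values` must have one entry per component", call. = FALSE)
  }
  if (is.null(component_names)) component_names <- paste0("x", seq_len(n))
  idx <- which(k_matrix != 0 & row(k_matrix) != col(k_matrix), arr.ind = TRUE)
  flows <- tibble::tibble(
    from = as.integer(idx[, 2]), to = as.integer(idx[, 1]),
    rate = sprintf("k_%d_%d", idx[, 1], idx[, 2])
  )
  rates <- stats::setNames(k_matrix[idx], flows$rate)
  if (isTRUE(free)) free <- flows$rate
  free <- as.character(free %||% character())
  if (!all(free %in% flows$rate)) {
    stop("unknown rate name in `free`", call. = FALSE)
  }
  new_network_model(n, component_names, rates, free, initial_values,
                    rep(FALSE, n), kind = "linear", flows = flows)
}

#' Build the four-component forward cascade
#'
#' A transport chain `x1 -> x2 -> x3 -> x4` with rates `k[1:3]`, optionally
#' closed by a feedback flow `x4 -> x1`. Used as the ground truth (with
#' feedback) and the misspecified starting hypothesis (without) in the
#' network-repair workflow.
#'
#' @param k Three non-negative forward rates.
#' @param feedback_rate Feedback rate for the flow `x4 -> x1`, or `NULL` for
#'   the open (feedback-free) cascade.
#' @param initial_values Four initial states.
#' @param free If `TRUE`, all rates are flagged unknown (to be estimated).
#' @return A `network_model` of kind `"linear"`.
#' @export
build_cascade_model <- function(k = c(0.15, 0.29, 0.20), feedback_rate = NULL,
                                initial_values = c(4, 0.3, 0.3, 0.3), free = FALSE) {
  if (length(k) != 3 || any(k < 0)) {
    stop("`k` must be three non-negative rates", call. = FALSE)
  }
  if (!is.null(feedback_rate) && feedback_rate < 0) {
    stop("`feedback_rate` must be non-negative", call. = FALSE)
  }
  flows <- tibble::tibble(from = 1:3, to = 2:4,
                          rate = c("k1", "k2", "k3"))
  rates <- stats::setNames(k, c("k1", "k2", "k3"))
  if (!is.null(feedback_rate)) {
    flows <- dplyr::bind_rows(flows,
                              tibble::tibble(from = 4L, to = 1L,
                                             rate = "k_fb"))
    rates <- c(rates, k_fb = feedback_rate)
  }
  free_rates <- if (isTRUE(free)) names(rates) else character()
  new_network_model(4L, paste0("x", 1:4), rates, free_rates,
                    initial_values, rep(FALSE, 4), kind = "linear",
                    flows = flows)
}

#' Add a transport flow to a linear network
#'
#' Used by the repair workflow to apply a structural edit suggested by the
#' sign pattern of the latent weights.
#'
#' @param model A linear `network_model`.
#' @param from,to Component indices of the new flow.
#' @param value Initial rate value.
#' @param free Whether the new rate is estimated (default `TRUE`).
#' @return The extended model.
#' @export
add_flow <- function(model, from, to, value = 0.1, free = TRUE) {
  if (model$kind != "linear") {
    stop("`add_flow()` requires a linear model", call. = FALSE)
  }
  nm <- sprintf("k_%d_%d", to, from)
  if (nm %in% names(model$rates)) {
    stop(sprintf("flow %d -> %d already present", from, to), call. = FALSE)
  }
  model$flows <- dplyr::bind_rows(
    model$flows,
    tibble::tibble(from = as.integer(from), to = as.integer(to), rate = nm)
  )
  model$rates <- c(model$rates, stats::setNames(value, nm))
  if (free) model$free_rates <- c(model$free_rates, nm)
  model
}

#' Observation map for partially observed networks
#'
#' Describes which model coordinates are read by the observed channels, each
#' through an affine transformation `y = scale * x + offset`.
#'
#' @param index Distinct model-coordinate indices, one per observed channel.
#' @param scale Nonzero multipliers (recycled).
#' @param offset Additive offsets (recycled).
#' @return An `observation_map`.
#' @export
observation_map <- function(index, scale = 1, offset = 0) {
  index <- as.integer(index)
  if (length(index) < 1 || anyDuplicated(index)) {
    stop("`index` must be at least one distinct coordinate", call. = FALSE)
  }
  scale <- rep_len(scale, length(index))
  offset <- rep_len(offset, length(index))
  if (any(scale == 0)) stop("`scale` entries must be nonzero", call. = FALSE)
  structure(list(index = index, scale = scale, offset = offset,
                 n_observed = length(index)),
            class = "observation_map")
}

resolve_x0 <- function(model, x0 = NULL) {
  out <- model$x0
  if (!is.null(x0)) {
    if (length(x0) == model$n) out <- x0
    else out[model$x0_unknown] <- x0
  } else if (any(model$x0_unknown)) {
    stop("model has unknown initial values; supply `x0`", call. = FALSE)
  }
  out
}

# internal fast path: returns a (components x times) matrix
solve_ode_matrix <- function(model, times, a = NULL, h = NULL,
                             rates = model$rates, x0 = NULL,
                             method = "dp45", rtol = 1e-8, atol = 1e-10,
                             n_sub = 16L) {
  x0 <- resolve_x0(model, x0)
  n <- model$n
  if (is.null(a) || is.null(h)) {
    a <- numeric(n)
    ht <- numeric(0); hv <- numeric(0)
  } else {
    if (length(a) != n) stop("`a` must have one weight per component",
                             call. = FALSE)
    a <- a * as.numeric(model$a_slots)  # components without a slot take no h
    ht <- h$times; hv <- h$values
  }
  use_compiled <- model$kind == "linear" &&
    (is.null(h) || h$interpolation == "linear")
  if (use_compiled) {
    A <- linear_A(model, rates)
    out <- if (method == "rk4") {
      .rk4_linear(A, a, ht, hv, x0, times, as.integer(n_sub))
    } else {
      .dp45_linear(A, a, ht, hv, x0, times, rtol, atol)
    }
    if (any(!is.finite(out))) {
      stop("integration produced non-finite states", call. = FALSE)
    }
    return(t(out))
  }
  hfun <- if (length(ht)) function(t) predict(h, t) else function(t) 0
  func <- function(t, y, parms) {
    list(psi_eval(model, y, rates, t) + a * hfun(t))
  }
  de_method <- if (method == "rk4") "rk4" else "ode45"
  if (method == "rk4") {
    # refine the output grid so rk4 takes n_sub steps per interval
    fine <- unique(sort(c(times, unlist(
      lapply(seq_len(length(times) - 1), function(j) {
        seq(times[j], times[j + 1], length.out = n_sub + 1)
      })))))
    sol <- deSolve::ode(y = x0, times = fine, func = func, parms = NULL,
                        method = "rk4")
    sol <- sol[match(times, sol[, 1]), , drop = FALSE]
  } else {
    sol <- deSolve::ode(y = x0, times = times, func = func, parms = NULL,
                        method = de_method, rtol = rtol, atol = atol)
  }
  if (any(!is.finite(sol))) {
    bad <- which(apply(sol, 1, function(r) any(!is.finite(r))))[1]
    stop(sprintf("integration failed near t = %g", sol[bad, 1]),
         call. = FALSE)
  }
  t(sol[, -1, drop = FALSE])
}

#' Solve a network model
#'
#' Integrates \eqn{\dot x_i = \psi_i(k, x) + a_i h(t)} over the requested
#' times with an adaptive Runge-Kutta 4(5) scheme (relative tolerance 1e-8,
#' absolute 1e-10 by default). Omitting `h` (or `a`) solves the plain
#' network without a hidden influence. A fixed-step classical RK4 is
#' available via `method = "rk4"` (with `n_sub` sub-steps per output
#' interval), mainly for convergence checks.
#'
#' @param model A `network_model`.
#' @param times Increasing output times; the first entry is the initial time.
#' @param a Optional hidden-influence weights (length N).
#' @param h Optional [hidden_signal()] for the latent input.
#' @param x0 Initial values; required if the model flags any as unknown.
#' @param rates Optional rate overrides (named as in `model$rates`).
#' @param method `"dp45"` (adaptive, default) or `"rk4"` (fixed step).
#' @param rtol,atol Adaptive-solver tolerances.
#' @param n_sub Sub-steps per output interval for `method = "rk4"`.
#' @return A tibble with a `time` column and one column per component.
#' @export
solve_ode <- function(model, times, a = NULL, h = NULL, x0 = NULL,
                      rates = model$rates, method = c("dp45", "rk4"),
                      rtol = 1e-8, atol = 1e-10, n_sub = 16L) {
  method <- match.arg(method)
  m <- solve_ode_matrix(model, times, a = a, h = h, rates = rates, x0 = x0,
                        method = method, rtol = rtol, atol = atol,
                        n_sub = n_sub)
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(t(m)), model$component_names))
  dplyr::bind_cols(tibble::tibble(time = times), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
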