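#' Construct a time-series dataset
#'
#' The container used by all estimation functions: an increasing time grid,
#' a components-by-times value matrix, and a per-component observed flag.
#' Synthetic datasets additionally carry the generating truth (noise-free
#' trajectories, true hidden course, weights, rates and seed) for scoring.
#'
#' @param times Strictly increasing numeric time grid.
#' @param values Numeric matrix, one row per component, one column per time
#'   point.
#' @param component_names Component labels; default taken from row names or
#'   `x1`, `x2`, ...
#' @param observed Logical per-component flag (default all observed).
#' @param noise_kind,sigma Optional record of the noise model used to
#'   generate the data.
#' @param truth Optional list bundling the generating truth.
#' @return A `timeseries_data` object.
#' @export
timeseries_data <- function(times, values, component_names = NULL,
                            observed = NULL, noise_kind = NULL,
                            sigma = NULL, truth = NULL) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (ncol(values) != length(times)) {
    stop("`values` must have one column per time point", call. = FALSE)
  }
  if (is.null(component_names)) {
    component_names <- rownames(values) %||% paste0("x", seq_len(nrow(values)))
  }
  observed <- observed %||% rep(TRUE, nrow(values))
  if (any(!is.finite(values[observed, ]))) {
    stop("observed components must have no missing entries", call. = FALSE)
  }
  structure(
    list(times = times, values = values,
         component_names = component_names, observed = observed,
         noise_kind = noise_kind, sigma = sigma, truth = truth),
    class = "timeseries_data"
  )
}

#' @export
print.timeseries_data <- function(x, ...) {
  cat(sprintf(
    "<timeseries_data> %d components x %d time points on [%g, %g]; %d observed\n",
    nrow(x$values), length(x$times), x$times[1],
    x$times[length(x$times)], sum(x$observed)))
  invisible(x)
}

#' @method as_tibble timeseries_data
#' @export
as_tibble.timeseries_data <- function(x, ...) {
  out <- tibble::as_tibble(stats::setNames(as.data.frame(t(x$values)),
                                           x$component_names))
  dplyr::bind_cols(tibble::tibble(time = x$times), out)
}

#' Read a time-series dataset from CSV
#'
#' Expects a header row, a first column named `time`, and one numeric column
#' per component.
#'
#' @param path File path.
#' @param observed Optional character vector naming the observed components
#'   (default: all).
#' @return A [timeseries_data()] object.
#' @export
read_timeseries <- function(path, observed = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "time") {
    stop("first column must be named 'time'", call. = FALSE)
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))][1]
    stop(sprintf("non-numeric values in column '%s'", bad), call. = FALSE)
  }
  times <- df$time
  if (any(diff(times) <= 0)) {
    stop(sprintf("times must be strictly increasing (violated at row %d)",
                 which(diff(times) <= 0)[1] + 1L), call. = FALSE)
  }
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  comp <- names(df)[-1]
  obs <- if (is.null(observed)) rep(TRUE, length(comp)) else comp %in% observed
  timeseries_data(times, vals, component_names = comp, observed = obs)
}

#' Write a time-series dataset to CSV
#'
#' @param data A [timeseries_data()] object.
#' @param path File path; columns are `time` followed by the components.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(data, path) {
  readr::write_csv(as_tibble(data), path)
  invisible(path)
}
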