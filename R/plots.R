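#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs geom_ribbon
#' @export
ggplot2::autoplot

#' Plot a latent estimate
#'
#' Data, refitted trajectories (one panel per component) and the estimated
#' latent course in a final panel.
#'
#' @param object A `latent_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot latent_estimate
#' @export
autoplot.latent_estimate <- function(object, ...) {
  tr <- fitted_trajectories(object)
  hc <- tibble::tibble(time = object$times,
                       value = predict(object$hidden, object$times),
                       component = "latent h(t)")
  ggplot(tr, aes(x = .data$time)) +
    geom_point(aes(y = .data$observed), alpha = 0.5, size = 0.8) +
    geom_line(aes(y = .data$fitted), colour = "steelblue") +
    geom_line(data = hc, aes(y = .data$value), colour = "firebrick") +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "time", y = "value",
         title = sprintf("Latent estimate, support %s",
                         support_label(object$support)))
}

#' Plot a hidden signal
#'
#' @param object A `hidden_signal`.
#' @param n Number of interpolated evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hidden_signal
#' @export
autoplot.hidden_signal <- function(object, n = 200, ...) {
  tt <- seq(object$times[1], object$times[length(object$times)],
            length.out = n)
  ggplot(tibble::tibble(time = tt, h = predict(object, tt)),
         aes(.data$time, .data$h)) +
    geom_line() +
    geom_point(data = as_tibble(object), size = 0.8) +
    labs(x = "time", y = "h(t)")
}

#' Plot a selection path
#'
#' Criterion value of every evaluated support, accepted steps highlighted.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot(object$path, aes(x = .data$step, y = .data$criterion,
                          colour = .data$accepted)) +
    geom_point() +
    labs(x = "search step", y = object$criterion,
         title = sprintf("%s selection", object$strategy))
}

#' Plot a simulation-study summary
#'
#' Mean latent-recovery score with 5%/95% quantile ribbons per study cell.
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_result
#' @export
autoplot.study_result <- function(object, ...) {
  s <- object$summary
  s$frac_lab <- sprintf("%.0f%% observed", 100 * s$frac)
  ggplot(s, aes(x = factor(.data$sigma), y = .data$mean_s,
                group = .data$frac_lab)) +
    geom_ribbon(aes(ymin = .data$q05, ymax = .data$q95), alpha = 0.2) +
    geom_line() + geom_point() +
    facet_wrap(~ .data$size + .data$frac_lab) +
    labs(x = "noise level sigma", y = "score s (mean, 5-95%)")
}
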