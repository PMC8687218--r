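#' Information criterion with the latent-weight parameter count
#'
#' Model complexity is counted by the number of active latent weights
#' \eqn{N^a} alone: the remaining quantities (spline coefficients, smoothing
#' parameters, noise variance) are common to all candidate supports. Smaller
#' values are better.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_active Number of nonzero latent weights.
#' @param n_times Number of time points (`n + 1`).
#' @param n_observed Number of observed components.
#' @param kind `"BIC"` (default) or `"AIC"`.
#' @param bic_variant `"total"` (default) uses `log(n_times * n_observed)`,
#'   the log of the total observation count; `"per_component"` uses
#'   `n_observed * log(n_times)`.
#' @return The criterion value.
#' @export
information_criterion <- function(loglik, n_active, n_times, n_observed,
                                  kind = c("BIC", "AIC"),
                                  bic_variant = c("total", "per_component")) {
  kind <- match.arg(kind)
  bic_variant <- match.arg(bic_variant)
  if (n_active < 0 || n_times < 1 || n_observed < 1) {
    stop("counts must be positive (`n_active` >= 0)", call. = FALSE)
  }
  if (kind == "AIC") {
    -2 * loglik + 2 * n_active
  } else if (bic_variant == "total") {
    -2 * loglik + log(n_times * n_observed) * n_active
  } else {
    -2 * loglik + n_observed * log(n_times) * n_active
  }
}

support_label <- function(support) {
  if (length(support) == 0) "{}" else
    paste0("{", paste(support, collapse = ","), "}")
}

#' Select the latent-influence support by information criterion
#'
#' Searches over subsets of components the hidden influence may act on.
#' `"best_subset"` fits every subset of the candidate components (including
#' the empty one) and returns the criterion minimizer; `"forward"` starts
#' from the empty support and greedily adds the single component giving the
#' largest criterion decrease, stopping when no strict decrease remains
#' (once added, a component stays); `"backward"` starts from the full
#' candidate set and greedily removes components. Ties break toward the
#' lower component index; a failing fit is scored `Inf` and the search
#' continues.
#'
#' @inheritParams estimate_latent
#' @param strategy `"forward"`, `"backward"` or `"best_subset"`.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param candidates Candidate components (default: all components with a
#'   latent slot, intersected with the observed ones).
#' @return A `selection_result` with the search `path` (a tibble with one
#'   row per evaluated support), the `chosen` `latent_estimate`, and the
#'   criterion of the null model.
#' @export
select_support <- function(data, model,
                           strategy = c("forward", "backward",
                                        "best_subset"),
                           criterion = c("BIC", "AIC"),
                           noise_kind = c("normal", "lognormal"),
                           candidates = NULL, smoothers = NULL,
                           control = latent_control()) {
  strategy <- match.arg(strategy)
  criterion <- match.arg(criterion)
  noise_kind <- match.arg(noise_kind)
  candidates <- candidates %||%
    intersect(which(model$a_slots), which(data$observed))
  smoothers <- smoothers %||% smooth_components(data, noise_kind)
  partial <- !all(data$observed)
  cache <- new.env(parent = emptyenv())
  fit1 <- function(support, u_start = NULL) {
    key <- support_label(support)
    if (!is.null(cache[[key]])) return(cache[[key]])
    est <- tryCatch({
      if (partial) {
        estimate_latent_partial(data, model, support, noise_kind,
                                smoothers = smoothers, control = control,
                                u_start = u_start)
      } else {
        estimate_latent(data, model, support, noise_kind,
                        smoothers = smoothers, control = control,
                        u_start = u_start)
      }
    }, error = function(e) {
      warning(sprintf("fit failed for support %s: %s", key,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    crit <- if (is.null(est)) Inf else
      if (criterion == "AIC") est$aic else est$bic
    out <- list(est = est, crit = crit)
    cache[[key]] <- out
    out
  }

  path <- list()
  note <- function(step, support, crit, accepted) {
    path[[length(path) + 1]] <<- tibble::tibble(
      step = step, support = support_label(support),
      criterion = crit, accepted = accepted)
  }

  eps <- 1e-6
  null_fit <- fit1(integer())

  if (strategy == "best_subset") {
    subsets <- list(integer())
    for (cand in candidates) {
      subsets <- c(subsets, lapply(subsets, function(s) c(s, cand)))
    }
    crits <- vapply(subsets, function(s) fit1(s)$crit, numeric(1))
    best <- which.min(crits)
    for (i in seq_along(subsets)) {
      note(1L, subsets[[i]], crits[i], i == best)
    }
    chosen <- subsets[[best]]
  } else if (strategy == "forward") {
    current <- integer()
    cur_crit <- null_fit$crit
    note(0L, current, cur_crit, TRUE)
    step <- 0L
    cur_a <- NULL
    repeat {
      step <- step + 1L
      pool <- setdiff(candidates, current)
      if (length(pool) == 0) break
      crits <- vapply(pool, function(j) {
        sup <- sort(c(current, j))
        ws <- if (is.null(cur_a)) NULL else {
          w <- numeric(length(sup))
          w[match(current, sup)] <- cur_a
          w[match(j, sup)] <- 0.02
          w
        }
        fit1(sup, u_start = ws)$crit
      }, numeric(1))
      jbest <- pool[which.min(crits)]  # first minimum -> lowest index
      improved <- min(crits) < cur_crit - eps
      for (idx in seq_along(pool)) {
        note(step, sort(c(current, pool[idx])), crits[idx],
             improved && pool[idx] == jbest)
      }
      if (!improved) break
      current <- sort(c(current, jbest))
      cur_crit <- min(crits)
      est_cur <- fit1(current)$est
      cur_a <- if (is.null(est_cur)) NULL else est_cur$a[current]
    }
    chosen <- current
  } else {  # backward
    current <- candidates
    full_fit <- fit1(current)
    cur_crit <- full_fit$crit
    cur_a <- if (is.null(full_fit$est)) NULL else full_fit$est$a[current]
    note(0L, current, cur_crit, TRUE)
    step <- 0L
    while (length(current) > 0) {
      step <- step + 1L
      crits <- vapply(seq_along(current), function(idx) {
        ws <- if (is.null(cur_a)) NULL else cur_a[-idx]
        fit1(current[-idx], u_start = ws)$crit
      }, numeric(1))
      ibest <- which.min(crits)
      improved <- min(crits) < cur_crit - eps
      for (idx in seq_along(current)) {
        note(step, current[-idx], crits[idx], improved && idx == ibest)
      }
      if (!improved) break
      current <- current[-ibest]
      cur_crit <- min(crits)
      est_cur <- fit1(current)$est
      cur_a <- if (is.null(est_cur)) NULL else est_cur$a[current]
    }
    chosen <- current
  }

  chosen_fit <- fit1(chosen)
  structure(
    list(strategy = strategy, criterion = criterion,
         path = dplyr::bind_rows(path),
         chosen = chosen_fit$est, chosen_support = chosen,
         chosen_criterion = chosen_fit$crit,
         null_criterion = null_fit$crit, null = null_fit$est),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s selection by %s\n", x$strategy,
              x$criterion))
  cat(sprintf("  chosen support %s, %s = %.4f (null %.4f)\n",
              support_label(x$chosen_support), x$criterion,
              x$chosen_criterion, x$null_criterion))
  invisible(x)
}

#' Default structural-edit interpreter
#'
#' Reads the sign pattern of the selected latent weights as a missing
#' transport flow: the influence drains the most negatively weighted
#' component and feeds the most positively weighted one, so the suggested
#' edit is the single edge from the former to the latter.
#'
#' @param estimate A `latent_estimate`.
#' @return `list(from =, to =)` or `NULL` when the pattern has no positive
#'   and negative weight pair.
#' @export
default_edit_interpreter <- function(estimate) {
  a <- estimate$a
  ipos <- which.max(a)
  ineg <- which.min(a)
  if (a[ipos] <= 0 || a[ineg] >= 0) return(NULL)
  list(from = ineg, to = ipos)
}

#' Guided repair of a misspecified network
#'
#' Iterates: fit the current structure (free rates, no latent influence),
#' search for a latent influence with [select_support()], and — if a
#' non-empty support improves the criterion — interpret its weight pattern
#' as a structural edit, apply the edit and refit. The loop stops when the
#' latent component no longer improves the criterion, when the interpreter
#' cannot map the pattern to an edit, or when the edit cap is reached.
#'
#' @inheritParams select_support
#' @param edit_interpreter Function mapping a `latent_estimate` to
#'   `list(from =, to =)` or `NULL`; default [default_edit_interpreter()].
#' @param max_edits Maximum number of structural edits.
#' @return A `repair_report`: a tibble of per-iteration records
#'   (`iterations`), the final `model`, and the `stopped` reason.
#' @export
repair_network <- function(data, model,
                           edit_interpreter = default_edit_interpreter,
                           strategy = "best_subset", criterion = "BIC",
                           noise_kind = c("normal", "lognormal"),
                           max_edits = 3L, smoothers = NULL,
                           control = latent_control()) {
  noise_kind <- match.arg(noise_kind)
  smoothers <- smoothers %||% smooth_components(data, noise_kind)
  rows <- list()
  stopped <- "edit cap reached"
  selections <- list()
  for (it in seq_len(max_edits + 1L)) {
    sel <- select_support(data, model, strategy = strategy,
                          criterion = criterion, noise_kind = noise_kind,
                          smoothers = smoothers, control = control)
    selections[[it]] <- sel
    est <- sel$chosen
    improved <- length(sel$chosen_support) > 0 &&
      sel$chosen_criterion < sel$null_criterion - 1e-6
    edit <- if (improved) edit_interpreter(est) else NULL
    rows[[it]] <- tibble::tibble(
      iteration = it,
      structure = paste(sprintf("%d->%d", model$flows$from,
                                model$flows$to), collapse = " "),
      criterion_null = sel$null_criterion,
      criterion_latent = sel$chosen_criterion,
      support = support_label(sel$chosen_support),
      weights = list(est$a),
      rates = list(sel$null$rates_hat),
      edit = if (is.null(edit)) NA_character_ else
        sprintf("add %d->%d", edit$from, edit$to)
    )
    if (!improved) {
      stopped <- "latent component no longer improves the criterion"
      break
    }
    if (is.null(edit)) {
      stopped <- "uninterpretable weight pattern"
      break
    }
    if (it > max_edits) break
    model <- add_flow(model, edit$from, edit$to, value = 0.1, free = TRUE)
  }
  structure(
    list(iterations = dplyr::bind_rows(rows), model = model,
         stopped = stopped, selections = selections),
    class = "repair_report"
  )
}

#' @export
print.repair_report <- function(x, ...) {
  cat(sprintf("<repair_report> %d iteration(s); stopped: %s\n",
              nrow(x$iterations), x$stopped))
  print(x$iterations[, c("iteration", "structure", "criterion_null",
                         "criterion_latent", "support", "edit")])
  invisible(x)
}

#' Feedback-recovery rate of the cascade repair experiment
#'
#' Repeats the misspecified-cascade experiment over independent seeds: each
#' replicate simulates the feedback cascade with [cascade_experiment()],
#' runs the identification step of [repair_network()] on the feedback-free
#' starting hypothesis (rates re-estimated jointly), and scores a success
#' when the selected latent component activates `x1`, inhibits `x4` and
#' improves the criterion over the latent-free fit -- the signature of the
#' missing feedback loop.
#'
#' @param n_replicates Number of independent replicates.
#' @param base_seed Base seed; replicate `i` uses a seed derived from it.
#' @param criterion,strategy,control Passed to [repair_network()].
#' @param ... Passed to [cascade_experiment()] (rates, feedback rate, noise
#'   level, ...).
#' @return A list with `rate` (fraction of successes) and `results`, a
#'   tibble with one row per replicate.
#' @export
feedback_recovery_rate <- function(n_replicates = 100L, base_seed = 1L,
                                   criterion = "BIC",
                                   strategy = "best_subset",
                                   control = latent_control(), ...) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    seed <- (base_seed * 1000L + i) %% .Machine$integer.max
    ce <- cascade_experiment(seed = seed, ...)
    rep <- tryCatch(
      repair_network(ce$data, ce$start_model, strategy = strategy,
                     criterion = criterion,
                     noise_kind = ce$data$noise_kind, max_edits = 0L,
                     control = control),
      error = function(e) NULL)
    if (is.null(rep) || nrow(rep$iterations) == 0) {
      rows[[i]] <- tibble::tibble(replicate = i, seed = seed,
                                  success = FALSE, support = NA_character_)
      next
    }
    it <- rep$iterations[1, ]
    a <- it$weights[[1]]
    rows[[i]] <- tibble::tibble(
      replicate = i, seed = seed,
      success = it$criterion_latent < it$criterion_null - 1e-6 &&
        a[1] > 0 && a[4] < 0,
      support = it$support)
  }
  results <- dplyr::bind_rows(rows)
  list(rate = mean(results$success), results = results)
}
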