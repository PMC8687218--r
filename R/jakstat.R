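#' Build a JAK2-STAT5 signalling model
#'
#' STAT5 nucleocytoplasmic cycling driven by Epo-induced receptor
#' phosphorylation. States of the core model: cytoplasmic unphosphorylated
#' STAT5 (`x1`), phosphorylated monomeric STAT5 (`x2`), phosphorylated
#' dimeric STAT5 (`x3`) and nuclear STAT5 (`x4`). The receptor activity
#' `EpoR_A(t)` is a measured exogenous time course supplied as a
#' [hidden_signal()].
#'
#' Variants:
#' \describe{
#'   \item{`base`}{the four-state core model.}
#'   \item{`base_lc`}{identical dynamics, with latent-component slots on
#'     `x1`, `x2`, `x3` (the nuclear state carries no slot).}
#'   \item{`delay`}{adds nuclear export back to `x1` with rate `k4`, delayed
#'     through a two-stage linear chain (`z1`, `z2`, time scale `tau`).}
#'   \item{`delay_observed`}{the delay model rewritten on the observed
#'     coordinates `y1 = k5 (x2 + 2 x3)`, `y2 = k6 (x1 + x2 + 2 x3)` plus the
#'     auxiliary states `x3`, `z1`, `z2`; latent slots carry the transformed
#'     weights `(k5 (a2 + 2 a3), k6 (a1 + a2 + 2 a3), a3)`. Also returns the
#'     observation map for `(y1, y2)`.}
#' }
#'
#' @param variant One of `"base"`, `"base_lc"`, `"delay"`,
#'   `"delay_observed"`.
#' @param rates Named non-negative rates `k1`...`k7` (only those the variant
#'   uses are required; `k5`-`k7` are observation scaling factors).
#' @param tau Positive delay time scale (delay variants).
#' @param epor_a [hidden_signal()] carrying the exogenous `EpoR_A(t)` course.
#' @param x1_0 Initial cytoplasmic STAT5; `NA` (default) flags it unknown,
#'   to be estimated. All other species start at zero.
#' @return A `network_model`, or for `"delay_observed"` a list with
#'   elements `model` and `obs_map`.
#' @export
build_jakstat_model <- function(variant = c("base", "base_lc", "delay",
                                            "delay_observed"),
                                rates = c(k1 = 0.021, k2 = 2.46, k3 = 0.1066,
                                          k4 = 0.10, k5 = 1, k6 = 1, k7 = 1),
                                tau = 6.4, epor_a, x1_0 = NA_real_) {
  if (is.character(variant) && length(variant) == 1 &&
      !variant %in% c("base", "base_lc", "delay", "delay_observed")) {
    stop(sprintf("unknown JAK2-STAT5 variant '%s'", variant), call. = FALSE)
  }
  variant <- match.arg(variant)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (!is_hidden_signal(epor_a)) {
    stop("`epor_a` must be a hidden_signal time course", call. = FALSE)
  }
  k <- function(nm) {
    if (!nm %in% names(rates)) stop(sprintf("rate %s missing", nm),
                                    call. = FALSE)
    unname(rates[[nm]])
  }
  E <- function(t) predict(epor_a, t)
  x1v <- if (is.na(x1_0)) 0 else x1_0

  if (variant %in% c("base", "base_lc")) {
    psi <- function(t, x, r) {
      e <- E(t)
      c(-r[["k1"]] * x[1] * e,
        -r[["k2"]] * x[2]^2 + r[["k1"]] * x[1] * e,
        -r[["k3"]] * x[3] + 0.5 * r[["k2"]] * x[2]^2,
        r[["k3"]] * x[3])
    }
    slots <- if (variant == "base_lc") c(TRUE, TRUE, TRUE, FALSE)
             else rep(TRUE, 4)
    return(new_network_model(
      4L, paste0("x", 1:4), rates[c("k1", "k2", "k3")], character(),
      c(x1v, 0, 0, 0), c(is.na(x1_0), FALSE, FALSE, FALSE),
      kind = "general", psi = psi, a_slots = slots,
      extra = list(variant = variant, epor_a = epor_a)))
  }

  if (variant == "delay") {
    psi <- function(t, x, r) {
      e <- E(t)
      c(-r[["k1"]] * x[1] * e + 2 * r[["k4"]] * x[6],
        -r[["k2"]] * x[2]^2 + r[["k1"]] * x[1] * e,
        -r[["k3"]] * x[3] + 0.5 * r[["k2"]] * x[2]^2,
        r[["k3"]] * x[3] - r[["k4"]] * x[6],
        (x[3] - x[5]) / tau,
        2 * (x[5] - x[6]) / tau)
    }
    return(new_network_model(
      6L, c(paste0("x", 1:4), "z1", "z2"),
      rates[c("k1", "k2", "k3", "k4")], character(),
      c(x1v, 0, 0, 0, 0, 0), c(is.na(x1_0), rep(FALSE, 5)),
      kind = "general", psi = psi,
      a_slots = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
      extra = list(variant = variant, epor_a = epor_a, tau = tau)))
  }

  # delay_observed: states (y1, y2, x3, z1, z2); EpoR_A enters as y3 / k7
  k1r <- k("k1"); k2r <- k("k2"); k3r <- k("k3"); k4r <- k("k4")
  k5r <- k("k5"); k6r <- k("k6")
  psi <- function(t, x, r) {
    e <- E(t)
    c(k1r * k5r * x[2] * e / k6r - k1r * x[1] * e - 2 * k3r * k5r * x[3],
      -2 * k3r * k6r * x[3] + 2 * k4r * k6r * x[5],
      -k3r * x[3] + k2r * x[1]^2 / (2 * k5r^2) -
        2 * k2r * x[1] * x[3] / k5r + 2 * k2r * x[3]^2,
      (x[3] - x[4]) / tau,
      2 * (x[4] - x[5]) / tau)
  }
  model <- new_network_model(
    5L, c("y1", "y2", "x3", "z1", "z2"),
    rates[c("k1", "k2", "k3", "k4", "k5", "k6")], character(),
    c(0, k6r * x1v, 0, 0, 0), c(FALSE, is.na(x1_0), FALSE, FALSE, FALSE),
    kind = "general", psi = psi,
    a_slots = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    extra = list(variant = variant, epor_a = epor_a, tau = tau))
  list(model = model, obs_map = observation_map(index = 1:2))
}

#' Transformed latent weights of the observed JAK2-STAT5 system
#'
#' Maps raw latent weights `(a1, a2, a3)` on the STAT5 states to the weights
#' carried by the observed coordinates `(y1, y2, x3)`.
#'
#' @param a Numeric vector `(a1, a2, a3)`.
#' @param k5,k6 Observation scaling factors.
#' @return Numeric vector `(k5 (a2 + 2 a3), k6 (a1 + a2 + 2 a3), a3)`.
#' @export
jakstat_transform_weights <- function(a, k5 = 1, k6 = 1) {
  c(k5 * (a[2] + 2 * a[3]), k6 * (a[1] + a[2] + 2 * a[3]), a[3])
}
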