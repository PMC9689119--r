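#' Parameters of the yellowness and moisture kinetics
#'
#' Both quality attributes follow first-order kinetics toward a
#' temperature-dependent equilibrium, with rate and equilibrium given by
#' power-law correlations in reduced temperature `T/170` (degrees Celsius)
#' and reduced slice thickness `d/10` (mm):
#' \deqn{K_b = 0.12 (T/170)^{2.49} (d/10)^{-0.44}}
#' \deqn{b_e = 36.2 (T/170)^{1.012} (d/10)^{-0.2}}
#' \deqn{X_e = 0.54 (T/170)^{-3.63} (d/10)^{0.89}}
#' \deqn{K_X = 0.78 (T/170)^{1.61} (d/10)^{-2.27}}
#' Yellowness is the CIE-Lab b coordinate; moisture is on the scale on which
#' the crispness recommendation is the interval \[2, 4\]. Defaults correspond
#' to untreated 15 mm slices: `b0 = 22.6`, `X0 = 3.9`.
#'
#' @param d Slice thickness, mm.
#' @param b0 Initial yellowness.
#' @param X0 Initial moisture content.
#' @param coef Named list of power-law coefficients; each entry is
#'   `c(a, pT, pd)` for `a * (T/170)^pT * (d/10)^pd`. Override to explore
#'   other products; defaults are the fitted potato correlations.
#' @return Object of class `quality_params`.
#' @export
quality_params <- function(d = 15, b0 = 22.6, X0 = 3.9,
                           coef = list(
                             Kb = c(a = 0.12, pT = 2.49, pd = -0.44),
                             be = c(a = 36.2, pT = 1.012, pd = -0.2),
                             Xe = c(a = 0.54, pT = -3.63, pd = 0.89),
                             KX = c(a = 0.78, pT = 1.61, pd = -2.27))) {
  if (!is.numeric(d) || d <= 0) {
    rlang::abort("slice thickness `d` must be positive.",
                 class = "frypareto_invalid_parameter")
  }
  stopifnot(setequal(names(coef), c("Kb", "be", "Xe", "KX")))
  structure(list(d = d, b0 = b0, X0 = X0, coef = coef),
            class = "quality_params")
}

power_law <- function(cf, T_C, d) {
  cf[["a"]] * (T_C / 170)^cf[["pT"]] * (d / 10)^cf[["pd"]]
}

#' @rdname quality_correlations
#' @export
yellowness_rate <- function(T_C, p = quality_params()) {
  power_law(p$coef$Kb, T_C, p$d)
}

#' Power-law correlations for quality rates and equilibria
#'
#' `yellowness_rate` (Kb, 1/min), `yellowness_equilibrium` (be, the asymptotic
#' b at temperature `T_C`), `moisture_equilibrium` (Xe) and `moisture_rate`
#' (KX, 1/min). All vectorised over `T_C`.
#'
#' @param T_C Temperature, degrees Celsius.
#' @param p A [quality_params()].
#' @name quality_correlations
#' @export
yellowness_equilibrium <- function(T_C, p = quality_params()) {
  power_law(p$coef$be, T_C, p$d)
}

#' @rdname quality_correlations
#' @export
moisture_equilibrium <- function(T_C, p = quality_params()) {
  power_law(p$coef$Xe, T_C, p$d)
}

#' @rdname quality_correlations
#' @export
moisture_rate <- function(T_C, p = quality_params()) {
  power_law(p$coef$KX, T_C, p$d)
}

#' Yellowness of the fried slice after an isothermal treatment
#'
#' First-order relaxation from `b0` toward the equilibrium `be(T)`:
#' `b(t, T) = be + (b0 - be) exp(-Kb t)`.
#'
#' @param t Frying time, minutes (vectorised; recycled against `T_C`).
#' @param T_C Oil temperature, degrees Celsius.
#' @param p A [quality_params()].
#' @return Yellowness (CIE-Lab b).
#' @export
yellowness <- function(t, T_C, p = quality_params()) {
  if (any(t < 0)) {
    rlang::abort("frying time must be >= 0.", class = "frypareto_domain_error")
  }
  be <- yellowness_equilibrium(T_C, p)
  be + (p$b0 - be) * exp(-yellowness_rate(T_C, p) * t)
}

#' Moisture content of the fried slice after an isothermal treatment
#'
#' First-order drying from `X0` toward the equilibrium moisture `Xe(T)`:
#' `X(t, T) = Xe + (X0 - Xe) exp(-KX t)`.
#'
#' @inheritParams yellowness
#' @return Moisture content (same scale as `X0`).
#' @export
moisture <- function(t, T_C, p = quality_params()) {
  if (any(t < 0)) {
    rlang::abort("frying time must be >= 0.", class = "frypareto_domain_error")
  }
  Xe <- moisture_equilibrium(T_C, p)
  Xe + (p$X0 - Xe) * exp(-moisture_rate(T_C, p) * t)
}

#' Frying time needed to reach a target yellowness
#'
#' Closed-form inversion of the colour law,
#' `t = -log((b - be) / (b0 - be)) / Kb`. Targets at or beyond the asymptote
#' `be(T)` are unreachable and return `NA`.
#'
#' @param b_target Target yellowness, must be `>= b0`.
#' @param T_C Temperature, degrees Celsius (vectorised).
#' @param p A [quality_params()].
#' @return Time in minutes, or `NA_real_` where unreachable.
#' @export
time_to_yellowness <- function(b_target, T_C, p = quality_params()) {
  if (any(b_target < p$b0)) {
    rlang::abort("`b_target` below the initial yellowness b0 is never attained.",
                 class = "frypareto_domain_error")
  }
  be <- yellowness_equilibrium(T_C, p)
  ratio <- (b_target - be) / (p$b0 - be)
  t <- rep(NA_real_, length(ratio))
  ok <- ratio > 0
  t[ok] <- -log(ratio[ok]) / rep_len(yellowness_rate(T_C, p), length(ratio))[ok]
  t
}

#' Frying time needed to dry to a target moisture
#'
#' Inversion of the drying law; targets at or below the equilibrium moisture
#' `Xe(T)` are unreachable and return `NA`.
#'
#' @param X_target Target moisture, must be `<= X0`.
#' @param T_C Temperature, degrees Celsius (vectorised).
#' @param p A [quality_params()].
#' @return Time in minutes, or `NA_real_` where unreachable.
#' @export
time_to_moisture <- function(X_target, T_C, p = quality_params()) {
  if (any(X_target > p$X0)) {
    rlang::abort("`X_target` above the initial moisture X0 is never attained.",
                 class = "frypareto_domain_error")
  }
  Xe <- moisture_equilibrium(T_C, p)
  ratio <- (X_target - Xe) / (p$X0 - Xe)
  t <- rep(NA_real_, length(ratio))
  ok <- ratio > 0
  t[ok] <- -log(ratio[ok]) / rep_len(moisture_rate(T_C, p), length(ratio))[ok]
  t
}
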