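#' Temperature-dependent rate constant for the Maillard network
#'
#' Rate "constants" of the fructose–asparagine reaction network vary smoothly
#' (log-linearly) with frying temperature. Each constant is parameterised as
#' \deqn{\ln K(T) = \ln k_{ref} + a \, g(T)}
#' where `g` is a temperature transform. The default, Arrhenius-type transform
#' is \eqn{g(T) = 1/(T_{ref}+273.15) - 1/(T+273.15)}, so `activation` carries
#' \eqn{E_a/R} semantics (Kelvin). A plain log-linear transform
#' \eqn{g(T) = T - T_{ref}} (slope per degree Celsius) is available via
#' `transform = "loglinear"`.
#'
#' @param k_ref Rate value at the reference temperature. Units are 1/min for
#'   first-order steps and L mmol^-1 min^-1 for the bimolecular steps.
#' @param activation Temperature-dependence coefficient (see Details).
#' @param T_ref Reference temperature in degrees Celsius.
#' @param sd_k_ref,sd_activation Standard deviations used for uncertainty
#'   draws; `0` means the parameter is treated as known.
#' @param order Reaction order of the step this constant multiplies (1 or 2);
#'   carried for unit bookkeeping only.
#' @param transform Temperature transform, `"arrhenius"` (default) or
#'   `"loglinear"`.
#' @return An object of class `rate_constant`.
#' @examples
#' k <- rate_constant(0.01, activation = log(2) / 20, transform = "loglinear")
#' evaluate_rate_constant(k, 160) # k_ref at the reference temperature
#' evaluate_rate_constant(k, 200) # doubled twice: 0.04
#' @export
rate_constant <- function(k_ref, activation = 0, T_ref = 160,
                          sd_k_ref = 0, sd_activation = 0,
                          order = 1,
                          transform = c("arrhenius", "loglinear")) {
  transform <- match.arg(transform)
  vals <- c(k_ref = k_ref, activation = activation, T_ref = T_ref,
            sd_k_ref = sd_k_ref, sd_activation = sd_activation)
  if (any(!is.finite(vals))) {
    rlang::abort("rate_constant parameters must be finite.",
                 class = "frypareto_invalid_parameter")
  }
  if (k_ref <= 0) {
    rlang::abort("`k_ref` must be strictly positive.",
                 class = "frypareto_invalid_parameter")
  }
  if (sd_k_ref < 0 || sd_activation < 0) {
    rlang::abort("standard deviations must be >= 0.",
                 class = "frypareto_invalid_parameter")
  }
  if (!order %in% c(1, 2)) {
    rlang::abort("`order` must be 1 or 2.",
                 class = "frypareto_invalid_parameter")
  }
  structure(
    list(k_ref = k_ref, activation = activation, T_ref = T_ref,
         sd_k_ref = sd_k_ref, sd_activation = sd_activation,
         order = order, transform = transform),
    class = "rate_constant"
  )
}

temperature_transform <- function(T_C, T_ref, transform) {
  switch(transform,
    arrhenius = 1 / (T_ref + 273.15) - 1 / (T_C + 273.15),
    loglinear = T_C - T_ref,
    rlang::abort(paste0("unknown temperature transform: ", transform),
                 class = "frypareto_invalid_parameter")
  )
}

#' Evaluate a rate constant at a frying temperature
#'
#' @param model A [rate_constant()].
#' @param T_C Temperature in degrees Celsius (vectorised). Values outside the
#'   validated 120–200 °C range trigger a warning, not an error.
#' @return Positive rate value(s), same length as `T_C`.
#' @export
evaluate_rate_constant <- function(model, T_C) {
  stopifnot(inherits(model, "rate_constant"))
  if (any(!is.finite(T_C))) {
    rlang::abort("temperature must be finite.",
                 class = "frypareto_invalid_parameter")
  }
  if (any(T_C < 120 | T_C > 200)) {
    rlang::warn("temperature outside the validated 120-200 degC range; extrapolating.")
  }
  g <- temperature_transform(T_C, model$T_ref, model$transform)
  exp(log(model$k_ref) + model$activation * g)
}

#' Bundle of the six Maillard-network rate constants
#'
#' @param constants Named list of six [rate_constant()] objects, names
#'   `K1`..`K6`. `K1` and `K3` are the bimolecular sugar + asparagine steps
#'   (order 2); `K2` (glucose isomerisation), `K4` (Schiff base to
#'   acrylamide), `K5` (Schiff base to melanoidins) and `K6` (acrylamide
#'   elimination) are first order.
#' @param label Provenance string (e.g. `"nominal"`, `"mc-draw-17"`).
#' @return Object of class `kinetic_parameter_set`.
#' @export
kinetic_parameter_set <- function(constants, label = "nominal") {
  wanted <- paste0("K", 1:6)
  if (!is.list(constants) || !setequal(names(constants), wanted)) {
    rlang::abort("`constants` must be a named list with exactly K1..K6.",
                 class = "frypareto_invalid_parameter")
  }
  constants <- constants[wanted]
  ok <- vapply(constants, inherits, logical(1), what = "rate_constant")
  if (!all(ok)) {
    rlang::abort("every entry of `constants` must be a rate_constant.",
                 class = "frypareto_invalid_parameter")
  }
  expected_order <- c(K1 = 2, K2 = 1, K3 = 2, K4 = 1, K5 = 1, K6 = 1)
  for (nm in wanted) {
    if (constants[[nm]]$order != expected_order[[nm]]) {
      rlang::warn(sprintf("%s declared with order %d; the network uses it as order %d.",
                          nm, constants[[nm]]$order, expected_order[[nm]]))
    }
  }
  structure(list(constants = constants, label = label),
            class = "kinetic_parameter_set")
}

#' @export
print.kinetic_parameter_set <- function(x, ...) {
  cat("<kinetic_parameter_set>", x$label, "\n")
  for (nm in names(x$constants)) {
    k <- x$constants[[nm]]
    cat(sprintf("  %s: k_ref=%.5g activation=%.5g (T_ref=%g, %s, sd=%.3g/%.3g)\n",
                nm, k$k_ref, k$activation, k$T_ref, k$transform,
                k$sd_k_ref, k$sd_activation))
  }
  invisible(x)
}

#' Evaluate all six rate constants at a temperature
#'
#' @param params A [kinetic_parameter_set()].
#' @param T_C Scalar temperature in degrees Celsius.
#' @return Named numeric vector `K1`..`K6`.
#' @export
rate_constants_at <- function(params, T_C) {
  stopifnot(inherits(params, "kinetic_parameter_set"), length(T_C) == 1L)
  vapply(params$constants, evaluate_rate_constant, numeric(1), T_C = T_C)
}

#' Initial composition of the raw potato (Agria variety)
#'
#' Defaults are the sugar and free-asparagine pools of the unprocessed slice:
#' 4.12 mmol/L glucose, 2.95 mmol/L fructose, 11.77 mmol/L asparagine. The
#' Schiff-base intermediate and acrylamide are absent before frying.
#'
#' @param glucose,fructose,asparagine,schiff_base,acrylamide Concentrations
#'   in mmol/L.
#' @return Named numeric vector (the ODE state at time zero).
#' @export
initial_composition <- function(glucose = 4.12, fructose = 2.95,
                                asparagine = 11.77, schiff_base = 0,
                                acrylamide = 0) {
  y0 <- c(glucose = glucose, fructose = fructose, asparagine = asparagine,
          schiff_base = schiff_base, acrylamide = acrylamide)
  if (any(!is.finite(y0)) || any(y0 < 0)) {
    rlang::abort("initial concentrations must be finite and nonnegative.",
                 class = "frypareto_invalid_parameter")
  }
  y0
}

maillard_rhs <- function(t, y, K) {
  bi1 <- K[[1L]] * y[[1L]] * y[[3L]]   # K1 [Glu][Asn]
  bi3 <- K[[3L]] * y[[2L]] * y[[3L]]   # K3 [Fru][Asn]
  list(c(
    -bi1 - K[[2L]] * y[[1L]],                       # glucose
    -bi3 + K[[2L]] * y[[1L]],                       # fructose
    -bi1 - bi3,                                     # asparagine
     bi1 + bi3 - (K[[4L]] + K[[5L]]) * y[[4L]],     # Schiff base
     K[[4L]] * y[[4L]] - K[[6L]] * y[[5L]]          # acrylamide
  ))
}

#' Simulate the Maillard reaction network for an isothermal treatment
#'
#' Integrates the five coupled ODEs (glucose, fructose, asparagine, Schiff
#' base, acrylamide) at a constant oil temperature. The network: glucose
#' isomerises to fructose (K2); both sugars condense with asparagine to the
#' Schiff base (K1, K3); the Schiff base decays to acrylamide (K4) or to
#' melanoidins (K5); acrylamide is itself eliminated (K6).
#'
#' @param init Initial state, see [initial_composition()].
#' @param params A [kinetic_parameter_set()].
#' @param t_end Treatment time in minutes (> 0). Ignored when `times` given.
#' @param T_C Oil temperature in degrees Celsius (isothermal).
#' @param times Optional increasing vector of output times (minutes); defaults
#'   to 200 points on `[0, t_end]`.
#' @param rtol,atol Solver tolerances (adaptive, stiff-capable `lsoda`).
#'   The tight absolute tolerance keeps trace-level acrylamide (1e-6 mmol/L
#'   scale) accurate in relative terms.
#' @param conversion Micrograms acrylamide per kilogram of product per mmol/L,
#'   used only for the reporting column (see [acrylamide_mass_fraction()]).
#' @return A tibble of class `fry_trajectory`: `time_min`, the five species
#'   in mmol/L, and `acrylamide_ug_kg`.
#' @export
simulate_network <- function(init, params, t_end = NULL, T_C,
                             times = NULL, rtol = 1e-8, atol = 1e-12,
                             conversion = 71080) {
  stopifnot(inherits(params, "kinetic_parameter_set"))
  if (is.null(times)) {
    if (is.null(t_end) || !is.finite(t_end) || t_end <= 0) {
      rlang::abort("`t_end` must be a positive finite time in minutes.",
                   class = "frypareto_invalid_parameter")
    }
    times <- seq(0, t_end, length.out = 200L)
  }
  if (times[1L] > 0) times <- c(0, times)
  K <- rate_constants_at(params, T_C)
  out <- tryCatch(
    deSolve::ode(y = init, times = times, func = maillard_rhs, parms = K,
                 method = "lsoda", rtol = rtol, atol = atol),
    warning = function(w) {
      rlang::abort(
        sprintf("ODE integration failed at T=%g degC, t_end=%g (params '%s'): %s",
                T_C, max(times), params$label, conditionMessage(w)),
        class = "frypareto_integration_error")
    }
  )
  m <- unclass(out)
  states <- m[, -1L, drop = FALSE]
  if (any(states < -1e-9)) {
    rlang::abort(
      sprintf("negative concentration below tolerance at T=%g degC (params '%s').",
              T_C, params$label),
      class = "frypareto_integration_error")
  }
  states[states < 0] <- 0
  traj <- tibble::tibble(
    time_min = m[, 1L],
    glucose = states[, "glucose"],
    fructose = states[, "fructose"],
    asparagine = states[, "asparagine"],
    schiff_base = states[, "schiff_base"],
    acrylamide_mmol_L = states[, "acrylamide"],
    acrylamide_ug_kg = acrylamide_mass_fraction(states[, "acrylamide"], conversion)
  )
  class(traj) <- c("fry_trajectory", class(traj))
  attr(traj, "T_C") <- T_C
  attr(traj, "label") <- params$label
  traj
}

#' Convert acrylamide concentration to a mass fraction
#'
#' The network state is in mmol/L; regulatory limits are quoted in
#' micrograms per kilogram of product. The default factor assumes acrylamide's
#' molar mass of 71.08 g/mol and 1 L of reacting volume per kg of product, so
#' 1 mmol/L = 71,080 ug/kg. This density/basis assumption is configurable.
#'
#' @param conc Acrylamide concentration(s), mmol/L.
#' @param conversion ug/kg per mmol/L; must be positive.
#' @return Acrylamide in ug/kg.
#' @export
acrylamide_mass_fraction <- function(conc, conversion = 71080) {
  if (!is.numeric(conversion) || length(conversion) != 1L ||
      !is.finite(conversion) || conversion <= 0) {
    rlang::abort("`conversion` must be a single positive number.",
                 class = "frypareto_invalid_parameter")
  }
  conc * conversion
}

#' Final acrylamide (ug/kg) at one temperature for several frying times
#'
#' All requested times at a fixed temperature are read off a single
#' trajectory, so evaluating a whole level curve costs one ODE solve.
#'
#' @param params A [kinetic_parameter_set()].
#' @param t Vector of frying times, minutes.
#' @param T_C Scalar temperature, degrees Celsius.
#' @inheritParams simulate_network
#' @return Numeric vector of acrylamide in ug/kg, aligned with `t`.
#' @export
acrylamide_at <- function(params, t, T_C, init = initial_composition(),
                          rtol = 1e-8, atol = 1e-12, conversion = 71080) {
  if (length(t) == 0L) return(numeric(0))
  if (any(!is.finite(t)) || any(t < 0)) {
    rlang::abort("`t` must be nonnegative and finite.",
                 class = "frypareto_invalid_parameter")
  }
  ord <- order(t)
  ts <- t[ord]
  traj <- simulate_network(init, params, T_C = T_C,
                           times = unique(c(0, ts)),
                           rtol = rtol, atol = atol, conversion = conversion)
  acr <- traj$acrylamide_ug_kg[match(ts, traj$time_min)]
  out <- numeric(length(t))
  out[ord] <- acr
  out
}
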