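#' Specification for synthetic kinetic parameter generation
#'
#' The published rate constants of the fructose–asparagine network live in
#' the primary kinetics literature, not in this package; the generator
#' produces internally consistent stand-ins with the same statistical
#' structure so that every pipeline stage (simulation, optimisation,
#' uncertainty propagation) runs and is testable without an external table.
#' Realism is enforced by calibration: the generated network must yield a
#' final acrylamide level between `target_low` and `target_high` ug/kg for a
#' 2 min treatment at 200 degC — the severe-frying scale reported for this
#' system.
#'
#' @param seed Integer seed controlling the drawn rate-structure.
#' @param target_low,target_high Calibration window for acrylamide at
#'   (2 min, 200 degC), ug/kg (defaults 1200–1300).
#' @param sensitivity Log-slope of each rate constant per degree Celsius;
#'   default `log(2)/20` (every K doubles per +20 degC). Zero gives a
#'   temperature-independent network.
#' @param rel_sd Relative standard deviation attached to each generated
#'   parameter (default 0.15) for uncertainty draws.
#' @param T_ref Reference temperature for the generated constants, degC.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 42L, target_low = 1200, target_high = 1300,
                           sensitivity = log(2) / 20, rel_sd = 0.15,
                           T_ref = 160) {
  stopifnot(target_low > 0, target_high > target_low, rel_sd >= 0)
  structure(list(seed = as.integer(seed), target_low = target_low,
                 target_high = target_high, sensitivity = sensitivity,
                 rel_sd = rel_sd, T_ref = T_ref),
            class = "synthetic_spec")
}

#' Generate a calibrated synthetic kinetic parameter set
#'
#' The relative rate structure of the six constants is drawn once (seeded
#' log-uniform perturbations of a fixed backbone in which Schiff-base
#' formation and decay dominate and acrylamide elimination is slow), then the
#' whole set is scaled jointly by bisection until the simulated acrylamide at
#' (2 min, 200 degC) falls inside the calibration window. The joint scale is
#' monotone in final acrylamide in this regime, so bisection converges; more
#' than 100 iterations raises a generation error.
#'
#' Generated constants use the log-linear temperature transform, so the
#' spec's `sensitivity` doubles every rate per +20 degC exactly at all
#' temperatures.
#'
#' @param spec A [synthetic_spec()].
#' @return A [kinetic_parameter_set()] labelled `"synthetic-seed-<seed>"`.
#' @export
generate_kinetic_set <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  # backbone ratios at T_ref: bimolecular condensation ~1e-3 L/mmol/min,
  # isomerisation ~5e-4, Schiff-base decay ~1e-2, slow acrylamide loss.
  backbone <- c(K1 = 1e-3, K2 = 5e-4, K3 = 1e-3, K4 = 1e-2, K5 = 1e-2,
                K6 = 5e-4)
  ratios <- backbone * exp(stats::runif(6, log(0.5), log(2)))
  orders <- c(K1 = 2, K2 = 1, K3 = 2, K4 = 1, K5 = 1, K6 = 1)

  make_set <- function(scale, label) {
    kinetic_parameter_set(
      purrr::imap(as.list(ratios * scale), function(k, nm) {
        rate_constant(k, activation = spec$sensitivity, T_ref = spec$T_ref,
                      sd_k_ref = spec$rel_sd * k,
                      sd_activation = spec$rel_sd * abs(spec$sensitivity),
                      order = orders[[nm]], transform = "loglinear")
      }),
      label = label)
  }
  acr_at_probe <- function(scale) {
    acrylamide_at(make_set(scale, "calibration"), t = 2, T_C = 200)
  }

  # bracket the calibration window in the joint scale
  lo <- 1e-3; hi <- 1
  it <- 0L
  while (acr_at_probe(hi) < spec$target_low && it < 60L) {
    hi <- hi * 2; it <- it + 1L
  }
  while (acr_at_probe(lo) > spec$target_high && it < 120L) {
    lo <- lo / 2; it <- it + 1L
  }
  target_mid <- (spec$target_low + spec$target_high) / 2
  for (i in seq_len(100L)) {
    mid <- sqrt(lo * hi)
    a <- acr_at_probe(mid)
    if (a >= spec$target_low && a <= spec$target_high) {
      return(make_set(mid, sprintf("synthetic-seed-%d", spec$seed)))
    }
    if (a < target_mid) lo <- mid else hi <- mid
  }
  rlang::abort("calibration search failed to reach the target acrylamide window.",
               class = "frypareto_generation_error")
}

#' Construct a synthetic Pareto-front fixture
#'
#' A strictly non-dominated front over the standard yellowness interval,
#' built without any solver: acrylamide grows as a convex power of the
#' yellowness progress (`shape` controls curvature; larger is more convex),
#' with plausible (t, T) coordinates obtained from the colour-law inversion.
#' Useful for exercising the equivalence and uncertainty machinery directly.
#'
#' @param n_points Number of front points (>= 2).
#' @param shape Curvature exponent (> 0); acrylamide is proportional to
#'   progress^(1 + shape).
#' @param b_range Yellowness interval covered (default `c(22.6, 26.9)`).
#' @param acr_max Acrylamide at the high-yellowness end, ug/kg.
#' @param p Quality parameters used for the (t, T) coordinates.
#' @return A `fry_front` tibble.
#' @export
generate_front_fixture <- function(n_points, shape = 1,
                                   b_range = c(22.6, 26.9), acr_max = 1300,
                                   p = quality_params()) {
  stopifnot(n_points >= 2, shape > 0)
  prog <- seq(0, 1, length.out = n_points)
  b <- b_range[1L] + prog * diff(b_range)
  acr <- acr_max * prog^(1 + shape)
  # temperatures rising along the front; times from the colour inversion
  T_C <- seq(125, 200, length.out = n_points)
  t <- time_to_yellowness(pmax(b, p$b0), T_C, p)
  t[is.na(t)] <- 10
  t <- pmin(pmax(t, 0.1), 10)
  new_fry_front(tibble::tibble(
    t = t, T_C = T_C, acrylamide = acr, yellowness = b,
    moisture = moisture(t, T_C, p), feasible = TRUE),
    provenance = sprintf("fixture-shape-%g", shape))
}
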