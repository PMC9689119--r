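#' Configuration of the Monte-Carlo uncertainty propagation
#'
#' Kinetic-parameter uncertainty is propagated by drawing positive normal
#' parameter sets and re-solving the bi-objective problem per draw. The
#' per-draw solver is the genetic algorithm by default (each draw gets a
#' seed derived from `seed + draw index`); the deterministic complete search
#' can be selected instead, e.g. for exact degenerate checks or coarse
#' sweeps.
#'
#' @param n_draws Number of parameter draws (default 1000).
#' @param seed Integer base seed.
#' @param method Per-draw solver, `"nsga2"` (default) or `"complete"`.
#' @param ga A [ga_config()] used when `method = "nsga2"` (its seed field is
#'   overridden per draw).
#' @param b_star_step,T_step Resolution of the complete search when
#'   `method = "complete"`.
#' @param max_fail_frac Hard-error threshold on the fraction of failed draws.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_draws = 1000, seed = 1L,
                      method = c("nsga2", "complete"),
                      ga = ga_config(), b_star_step = 0.05, T_step = 0.5,
                      max_fail_frac = 0.05) {
  method <- match.arg(method)
  stopifnot(n_draws >= 1)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 method = method, ga = ga, b_star_step = b_star_step,
                 T_step = T_step, max_fail_frac = max_fail_frac),
            class = "mc_config")
}

draw_positive_normal <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  if (stats::pnorm(0, mean, sd) >= 0.45) {
    rlang::abort(
      sprintf("sd %.3g relative to mean %.3g puts nearly half the normal mass below zero; positivity rejection is ill-defined.",
              sd, mean),
      class = "frypareto_configuration_error")
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {           # resample-until-positive rejection
    cand <- stats::rnorm(length(need), mean, sd)
    ok <- cand > 0
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Draw perturbed kinetic parameter sets
#'
#' Each of the six rate constants is perturbed independently: `k_ref` is
#' drawn from a normal centred on its nominal value with its `sd_k_ref`,
#' rejected and redrawn until positive; `activation` likewise when
#' `sd_activation > 0` (the sign of the activation is not constrained).
#' Deterministic given `config$seed`.
#'
#' @param nominal A [kinetic_parameter_set()] whose `sd_*` fields define the
#'   uncertainty widths.
#' @param config An [mc_config()].
#' @return List of `config$n_draws` kinetic parameter sets labelled
#'   `"mc-draw-<i>"`.
#' @export
draw_parameter_sets <- function(nominal, config = mc_config()) {
  stopifnot(inherits(nominal, "kinetic_parameter_set"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  lapply(seq_len(config$n_draws), function(i) {
    ks <- lapply(nominal$constants, function(k) {
      k2 <- k
      k2$k_ref <- draw_positive_normal(1L, k$k_ref, k$sd_k_ref)
      if (k$sd_activation > 0) {
        k2$activation <- stats::rnorm(1L, k$activation, k$sd_activation)
      }
      k2
    })
    kinetic_parameter_set(ks, label = sprintf("mc-draw-%d", i))
  })
}

solve_draw <- function(params, config, bounds, p, draw_index) {
  if (config$method == "complete") {
    pareto_complete_search(params, bounds, p,
                           b_star_step = config$b_star_step,
                           T_step = config$T_step)
  } else {
    ga <- config$ga
    ga$seed <- (config$seed + draw_index) %% .Machine$integer.max
    pareto_nsga2(params, bounds, p, config = ga)
  }
}

#' Propagate kinetic uncertainty to an ensemble of Pareto fronts
#'
#' Draws parameter sets, solves the constrained bi-objective problem for each
#' draw, and collects the fronts. The nominal front is computed by the
#' complete search (it is deterministic and serves as the reference curve).
#' Failed draws are dropped with a warning; more than
#' `config$max_fail_frac` failures is a hard error.
#'
#' @param nominal A [kinetic_parameter_set()] with uncertainty widths.
#' @param config An [mc_config()].
#' @param bounds A [design_bounds()].
#' @param p Quality parameters.
#' @return Object of class `fry_ensemble`: list with `fronts` (per-draw
#'   `fry_front`s), `nominal`, `n_failed`, and the configs.
#' @export
propagate <- function(nominal, config = mc_config(), bounds = design_bounds(),
                      p = quality_params()) {
  draws <- draw_parameter_sets(nominal, config)
  nominal_front <- pareto_complete_search(
    nominal, bounds, p,
    b_star_step = config$b_star_step, T_step = config$T_step)
  fronts <- vector("list", length(draws))
  failed <- integer(0)
  for (i in seq_along(draws)) {
    fronts[[i]] <- tryCatch(
      solve_draw(draws[[i]], config, bounds, p, i),
      error = function(e) NULL)
    if (is.null(fronts[[i]]) || nrow(fronts[[i]]) == 0L) {
      failed <- c(failed, i)
    }
  }
  if (length(failed) > config$max_fail_frac * length(draws)) {
    rlang::abort(sprintf("%d of %d Monte-Carlo draws failed to solve.",
                         length(failed), length(draws)),
                 class = "frypareto_integration_error")
  }
  if (length(failed) > 0L) {
    rlang::warn(sprintf("dropped %d failed draw(s): %s",
                        length(failed), paste(failed, collapse = ", ")))
    fronts[failed] <- NULL
  }
  structure(list(fronts = fronts, nominal = nominal_front,
                 n_failed = length(failed), config = config,
                 bounds = bounds),
            class = "fry_ensemble")
}

#' Quantile envelope of an ensemble of fronts
#'
#' Pools all ensemble front points, bins them by yellowness, and reports
#' acrylamide quantiles per bin. The envelope width (high minus low quantile)
#' summarises how parameter uncertainty inflates along the front.
#'
#' @param ensemble A `fry_ensemble`.
#' @param n_bins Number of yellowness bins.
#' @param probs Quantile levels (low, mid, high).
#' @return Tibble `bin_mid`, `n`, `q_lo`, `q_mid`, `q_hi`, `width`.
#' @export
ensemble_envelope <- function(ensemble, n_bins = 20,
                              probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(ensemble, "fry_ensemble"), length(probs) == 3L)
  pts <- dplyr::bind_rows(lapply(ensemble$fronts, tibble::as_tibble))
  brk <- seq(min(pts$yellowness), max(pts$yellowness), length.out = n_bins + 1L)
  pts$bin <- cut(pts$yellowness, brk, include.lowest = TRUE)
  pts |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      bin_mid = mean(range(.data$yellowness)),
      n = dplyr::n(),
      q_lo = stats::quantile(.data$acrylamide, probs[1L], names = FALSE),
      q_mid = stats::quantile(.data$acrylamide, probs[2L], names = FALSE),
      q_hi = stats::quantile(.data$acrylamide, probs[3L], names = FALSE),
      .groups = "drop") |>
    dplyr::mutate(width = .data$q_hi - .data$q_lo) |>
    dplyr::select(!"bin")
}

#' Fraction of ensemble front points above the acrylamide limit
#'
#' Counts every point of every front in the ensemble (not per-front
#' averages).
#'
#' @param ensemble A `fry_ensemble`.
#' @param limit Acrylamide limit, ug/kg (default 50).
#' @return Fraction in \[0, 1\].
#' @export
exceedance_fraction <- function(ensemble, limit = 50) {
  stopifnot(inherits(ensemble, "fry_ensemble"),
            length(ensemble$fronts) > 0L)
  acr <- unlist(lapply(ensemble$fronts, function(f) f$acrylamide))
  mean(acr > limit)
}
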