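#' Decision bounds and constraints of the frying design problem
#'
#' The decision box is frying time 0.1–10 min by oil temperature 120–200 °C;
#' terminal moisture must lie in \[2, 4\]; the acrylamide benchmark is the
#' 50 ug/kg recommended maximum.
#'
#' @param t_min,t_max Frying-time bounds, minutes.
#' @param T_min,T_max Temperature bounds, degrees Celsius.
#' @param X_low,X_high Moisture constraint interval (checked at final time).
#' @param acrylamide_limit Compliance benchmark, ug/kg.
#' @return Object of class `design_bounds`.
#' @export
design_bounds <- function(t_min = 0.1, t_max = 10,
                          T_min = 120, T_max = 200,
                          X_low = 2, X_high = 4,
                          acrylamide_limit = 50) {
  stopifnot(t_min < t_max, T_min < T_max, X_low < X_high,
            acrylamide_limit > 0)
  structure(list(t_min = t_min, t_max = t_max, T_min = T_min, T_max = T_max,
                 X_low = X_low, X_high = X_high,
                 acrylamide_limit = acrylamide_limit),
            class = "design_bounds")
}

#' Evaluate operating points on the quality (and optionally kinetic) models
#'
#' @param t,T_C Vectors of frying times (min) and temperatures (degC),
#'   recycled to common length.
#' @param p Quality parameters.
#' @param params Optional [kinetic_parameter_set()]; when supplied the
#'   acrylamide objective is computed (one ODE solve per distinct
#'   temperature), otherwise the column is `NA`.
#' @param bounds Design bounds used for the `feasible` flag.
#' @return Tibble with `t`, `T_C`, `acrylamide`, `yellowness`, `moisture`,
#'   `feasible`.
#' @export
evaluate_points <- function(t, T_C, p = quality_params(), params = NULL,
                            bounds = design_bounds()) {
  n <- max(length(t), length(T_C))
  pts <- tibble::tibble(t = rep_len(t, n), T_C = rep_len(T_C, n))
  pts <- dplyr::mutate(
    pts,
    yellowness = yellowness(.data$t, .data$T_C, p),
    moisture = moisture(.data$t, .data$T_C, p)
  )
  if (!is.null(params)) {
    eval_acr <- acrylamide_evaluator(params)
    acr <- rep(NA_real_, n)
    for (Tv in unique(pts$T_C)) {
      idx <- which(pts$T_C == Tv)
      acr[idx] <- eval_acr(pts$t[idx], Tv)
    }
    pts$acrylamide <- acr
  } else {
    pts$acrylamide <- NA_real_
  }
  pts$feasible <- with(pts,
    t >= bounds$t_min & t <= bounds$t_max &
    T_C >= bounds$T_min & T_C <= bounds$T_max &
    moisture >= bounds$X_low & moisture <= bounds$X_high)
  dplyr::select(pts, "t", "T_C", "acrylamide", "yellowness", "moisture", "feasible")
}

#' Grid sample of the feasible operating region
#'
#' Evaluates the quality models on a regular (t, T) grid and keeps the points
#' whose terminal moisture lies within the constraint interval.
#'
#' @param bounds A [design_bounds()].
#' @param grid_resolution Points per axis (>= 2).
#' @param p Quality parameters.
#' @param params Optional kinetic parameters (acrylamide is `NA` without them).
#' @param keep_infeasible Return constraint-violating grid points too
#'   (flagged), e.g. for plotting.
#' @return Tibble as [evaluate_points()]; warns when the feasible set is empty.
#' @export
feasible_region <- function(bounds = design_bounds(), grid_resolution = 200,
                            p = quality_params(), params = NULL,
                            keep_infeasible = FALSE) {
  stopifnot(grid_resolution >= 2)
  grid <- tidyr::expand_grid(
    t = seq(bounds$t_min, bounds$t_max, length.out = grid_resolution),
    T_C = seq(bounds$T_min, bounds$T_max, length.out = grid_resolution)
  )
  pts <- evaluate_points(grid$t, grid$T_C, p, params, bounds)
  if (!any(pts$feasible)) {
    rlang::warn("feasible region is empty under these bounds.")
  }
  if (keep_infeasible) pts else dplyr::filter(pts, .data$feasible)
}

#' Yellowness level curve intersected with the feasible set
#'
#' The level set `S_b*` collects the (t, T) treatments achieving yellowness
#' `b_star`. Each sampled temperature contributes at most one time, obtained
#' by the closed-form inversion of the colour law, and is kept when it lies in
#' the decision box with terminal moisture inside the constraint interval.
#'
#' @param b_star Target yellowness level.
#' @param bounds A [design_bounds()].
#' @param p Quality parameters.
#' @param T_step Temperature sampling step, degrees Celsius.
#' @return Tibble `t`, `T_C`, `yellowness`, `moisture`, ordered by `T_C`;
#'   empty when the level is unreachable inside the feasible set.
#' @export
level_curve <- function(b_star, bounds = design_bounds(),
                        p = quality_params(), T_step = 0.05) {
  T_grid <- seq(bounds$T_min, bounds$T_max, by = T_step)
  t <- time_to_yellowness(b_star, T_grid, p)
  keep <- !is.na(t) & t >= bounds$t_min & t <= bounds$t_max
  T_grid <- T_grid[keep]; t <- t[keep]
  X <- moisture(t, T_grid, p)
  keep <- X >= bounds$X_low & X <= bounds$X_high
  tibble::tibble(t = t[keep], T_C = T_grid[keep],
                 yellowness = b_star, moisture = X[keep])
}

new_fry_front <- function(points, provenance = "nominal", b_star_grid = NULL) {
  points <- dplyr::arrange(points, .data$yellowness, .data$T_C, .data$t)
  class(points) <- c("fry_front", class(tibble::tibble()))
  attr(points, "provenance") <- provenance
  attr(points, "b_star_grid") <- b_star_grid
  points
}

#' Brute-force non-dominated filter
#'
#' O(n^2) dominance filter for the (minimise acrylamide, maximise yellowness)
#' pair. A point is dominated when another is at least as good in both
#' objectives and strictly better in one.
#'
#' @param points Tibble with `acrylamide` and `yellowness` columns.
#' @return The non-dominated subset, original row order preserved.
#' @export
pareto_filter <- function(points) {
  n <- nrow(points)
  if (n <= 1L) return(points)
  a <- points$acrylamide
  b <- points$yellowness
  dominated <- logical(n)
  for (i in seq_len(n)) {
    dominated[i] <- any(
      a <= a[i] & b >= b[i] & (a < a[i] | b > b[i])
    )
  }
  points[!dominated, , drop = FALSE]
}

#' Pareto front by complete search over yellowness level curves
#'
#' Sweeps yellowness levels `b*` across the attainable interval; on each
#' level curve (computed by closed-form time inversion per sampled
#' temperature) the acrylamide objective is minimised. The minimiser per
#' level is one Pareto-front point. Acrylamide for all candidates at a given
#' temperature is read from a single network trajectory, so the search costs
#' one ODE solve per sampled temperature.
#'
#' Ties in acrylamide (within 1e-9 ug/kg) break toward lower temperature,
#' then lower time — the milder treatment.
#'
#' @param params A [kinetic_parameter_set()], or a function `(t, T_C) ->`
#'   acrylamide (ug/kg) to optimise a surrogate objective.
#' @param bounds A [design_bounds()].
#' @param p Quality parameters.
#' @param b_star_step Yellowness level spacing (default 0.01).
#' @param T_step Temperature sampling step along each level curve (degC).
#' @param b_range Optional `c(lo, hi)` overriding the automatic attainable
#'   yellowness interval.
#' @return A `fry_front` tibble: `t`, `T_C`, `acrylamide`, `yellowness`,
#'   `moisture`, `feasible`, sorted by yellowness.
#' @export
pareto_complete_search <- function(params, bounds = design_bounds(),
                                   p = quality_params(), b_star_step = 0.01,
                                   T_step = 0.05, b_range = NULL) {
  stopifnot(b_star_step > 0)
  eval_acr <- acrylamide_evaluator(params)
  label <- if (is.function(params)) "surrogate" else params$label
  T_grid <- seq(bounds$T_min, bounds$T_max, by = T_step)

  # latest feasible time at each T: the moisture lower bound (or the box).
  t_hi <- pmin(bounds$t_max,
               ifelse(is.na(time_to_moisture(bounds$X_low, T_grid, p)),
                      bounds$t_max,
                      time_to_moisture(bounds$X_low, T_grid, p)))
  t_lo <- rep(bounds$t_min, length(T_grid))
  reachable <- t_hi >= t_lo
  if (is.null(b_range)) {
    b_lo <- min(yellowness(t_lo[reachable], T_grid[reachable], p))
    b_hi <- max(yellowness(t_hi[reachable], T_grid[reachable], p))
  } else {
    b_lo <- b_range[1L]; b_hi <- b_range[2L]
  }
  b_grid <- seq(b_lo, b_hi, by = b_star_step)

  candidates <- vector("list", length(T_grid))
  for (j in seq_along(T_grid)) {
    if (!reachable[j]) next
    Tv <- T_grid[j]
    tb <- time_to_yellowness(pmax(b_grid, p$b0), Tv, p)
    ok <- !is.na(tb) & tb >= t_lo[j] & tb <= t_hi[j]
    if (!any(ok)) next
    X <- moisture(tb[ok], Tv, p)
    ok2 <- X >= bounds$X_low & X <= bounds$X_high
    if (!any(ok2)) next
    tt <- tb[ok][ok2]
    candidates[[j]] <- tibble::tibble(
      b_star = b_grid[ok][ok2], t = tt, T_C = Tv,
      moisture = X[ok2],
      acrylamide = eval_acr(tt, Tv)
    )
  }
  cand <- dplyr::bind_rows(candidates)
  if (nrow(cand) == 0L) {
    rlang::warn("no attainable yellowness levels inside the feasible set.")
    return(new_fry_front(tibble::tibble(
      t = numeric(), T_C = numeric(), acrylamide = numeric(),
      yellowness = numeric(), moisture = numeric(), feasible = logical()),
      provenance = paste0("complete-", label), b_star_grid = b_grid))
  }
  front <- cand |>
    dplyr::group_by(.data$b_star) |>
    dplyr::arrange(.data$acrylamide, .data$T_C, .data$t, .by_group = TRUE) |>
    dplyr::filter(.data$acrylamide <= dplyr::first(.data$acrylamide) + 1e-9) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(t = .data$t, T_C = .data$T_C,
                     acrylamide = .data$acrylamide,
                     yellowness = .data$b_star, moisture = .data$moisture,
                     feasible = TRUE)
  front <- pareto_filter(front)
  new_fry_front(front, provenance = paste0("complete-", label),
                b_star_grid = b_grid)
}

#' Flag front points against the acrylamide recommendation
#'
#' @param front A `fry_front` (or any tibble with an `acrylamide` column).
#' @param limit Compliance limit, ug/kg (default 50).
#' @return The input with a logical `compliant` column; the compliant
#'   fraction is attached as attribute `"fraction_compliant"` and reported by
#'   [glance.fry_front()].
#' @export
classify_front <- function(front, limit = 50) {
  stopifnot(is.numeric(limit), limit > 0)
  front$compliant <- front$acrylamide <= limit
  attr(front, "fraction_compliant") <- mean(front$compliant)
  attr(front, "acrylamide_limit") <- limit
  front
}

acrylamide_evaluator <- function(params) {
  if (is.function(params)) {
    function(t, T_C) params(t, T_C)
  } else {
    stopifnot(inherits(params, "kinetic_parameter_set"))
    function(t, T_C) acrylamide_at(params, t, T_C)
  }
}
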