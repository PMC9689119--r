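#' Simulate one frying treatment and summarise it
#'
#' Convenience wrapper tying the kinetic and quality models together for a
#' single (time, temperature) pair; optionally writes the trajectory CSV and
#' a reproducibility manifest.
#'
#' @param t Frying time, minutes.
#' @param T_C Oil temperature, degrees Celsius.
#' @param params A [kinetic_parameter_set()].
#' @param p Quality parameters.
#' @param out_dir Optional output directory (created if needed).
#' @return One-row tibble: `t`, `T_C`, `acrylamide`, `yellowness`,
#'   `moisture`; the full trajectory is attached as attribute
#'   `"trajectory"`.
#' @export
run_simulate <- function(t, T_C, params, p = quality_params(),
                         out_dir = NULL) {
  traj <- simulate_network(initial_composition(), params,
                           times = seq(0, t, length.out = 200L), T_C = T_C)
  summary <- tibble::tibble(
    t = t, T_C = T_C,
    acrylamide = traj$acrylamide_ug_kg[nrow(traj)],
    yellowness = yellowness(t, T_C, p),
    moisture = moisture(t, T_C, p))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
    write_manifest(out_dir, list(command = "simulate", t = t, T_C = T_C,
                                 params_label = params$label))
  }
  attr(summary, "trajectory") <- traj
  summary
}

#' Solve the frying Pareto problem end to end
#'
#' @param method `"complete"` (level-curve search) or `"nsga2"`.
#' @param params A [kinetic_parameter_set()].
#' @param bounds A [design_bounds()].
#' @param p Quality parameters.
#' @param ga A [ga_config()] (used by `"nsga2"`).
#' @param b_star_step,T_step Complete-search resolution.
#' @param out_dir Optional output directory for the front CSV and manifest.
#' @return A classified `fry_front` (see [classify_front()]).
#' @export
run_pareto <- function(method = c("complete", "nsga2"), params,
                       bounds = design_bounds(), p = quality_params(),
                       ga = ga_config(), b_star_step = 0.01, T_step = 0.05,
                       out_dir = NULL) {
  method <- match.arg(method)
  front <- switch(method,
    complete = pareto_complete_search(params, bounds, p,
                                      b_star_step = b_star_step,
                                      T_step = T_step),
    nsga2 = pareto_nsga2(params, bounds, p, config = ga))
  front <- classify_front(front, bounds$acrylamide_limit)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_front_csv(front, file.path(out_dir, paste0("front-", method, ".csv")))
    write_manifest(out_dir, list(command = "pareto", method = method,
                                 seed = ga$seed, params_label = params$label))
  }
  front
}

#' Run the Monte-Carlo uncertainty propagation end to end
#'
#' @param params Nominal [kinetic_parameter_set()] with uncertainty widths.
#' @param config An [mc_config()].
#' @param bounds A [design_bounds()].
#' @param p Quality parameters.
#' @param out_dir Optional output directory; per-draw front CSVs plus a
#'   `summary.json` (seed, draws, failures, exceedance fraction, envelope
#'   table) are written there.
#' @return The `fry_ensemble`.
#' @export
run_mc <- function(params, config = mc_config(), bounds = design_bounds(),
                   p = quality_params(), out_dir = NULL) {
  ens <- propagate(params, config, bounds, p)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(ens$fronts)) {
      write_front_csv(ens$fronts[[i]],
                      file.path(out_dir, sprintf("front-draw-%04d.csv", i)))
    }
    env <- ensemble_envelope(ens)
    jsonlite::write_json(
      list(seed = config$seed, n_draws = config$n_draws,
           n_failed = ens$n_failed,
           exceedance_fraction = exceedance_fraction(ens, bounds$acrylamide_limit),
           envelope = env),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, list(command = "mc", seed = config$seed,
                                 n_draws = config$n_draws,
                                 method = config$method,
                                 params_label = params$label))
  }
  ens
}

#' Detect quasi-equivalent solutions on a front
#'
#' @param front A `fry_front` (or tibble of operating points).
#' @param criteria An [equivalence_criteria()].
#' @param out_dir Optional output directory for the groups CSV.
#' @return A `fry_equivalence` tibble.
#' @export
run_equivalence <- function(front, criteria = equivalence_criteria(),
                            out_dir = NULL) {
  groups <- find_equivalent_sets(front, criteria)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_groups_csv(groups, file.path(out_dir, "equivalent-groups.csv"))
    write_manifest(out_dir, list(command = "equiv",
                                 objective_tol = criteria$objective_tol))
  }
  groups
}

write_manifest <- function(out_dir, info) {
  info$package_version <- as.character(utils::packageVersion("frypareto"))
  info$config_hash <- rlang::hash(info)
  jsonlite::write_json(info, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(info)
}

#' Command-line dispatcher
#'
#' Backs the `frypareto` Rscript front-end (`inst/scripts/frypareto.R`).
#' Subcommands: `simulate --t --T`, `pareto --method complete|nsga2`,
#' `mc --draws`, `equiv`; all take `--config <kinetic yaml/json>` (defaults
#' to a synthetic calibrated set), `--seed` and `--out <dir>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 success, 2 usage error), invisibly.
#' @export
frypareto_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: frypareto <simulate|pareto|mc|equiv> [--t MIN] [--T degC]\n",
            "  [--method complete|nsga2] [--draws N] [--config file.yaml]\n",
            "  [--seed INT] [--pop N] [--gens N] [--out DIR]")
    invisible(2L)
  }
  if (length(args) < 1L) return(usage())
  cmd <- args[[1L]]
  if (!cmd %in% c("simulate", "pareto", "mc", "equiv")) return(usage())
  opt <- parse_cli_flags(args[-1L])
  seed <- as.integer(opt$seed %||% 1L)
  params <- if (!is.null(opt$config)) read_kinetic_config(opt$config)
            else generate_kinetic_set(synthetic_spec(seed = seed))
  out_dir <- opt$out %||% "."
  status <- tryCatch({
    switch(cmd,
      simulate = {
        res <- run_simulate(as.numeric(opt$t %||% 2),
                            as.numeric(opt$T %||% 160),
                            params, out_dir = out_dir)
        message(sprintf("acrylamide %.3f ug/kg, yellowness %.3f, moisture %.3f",
                        res$acrylamide, res$yellowness, res$moisture))
      },
      pareto = {
        method <- opt$method %||% "complete"
        if (!method %in% c("complete", "nsga2")) return(usage())
        ga <- ga_config(pop_size = as.integer(opt$pop %||% 100L),
                        generations = as.integer(opt$gens %||% 200L),
                        seed = seed)
        front <- run_pareto(method, params, ga = ga, out_dir = out_dir)
        g <- glance(front)
        message(sprintf(
          "front: %d points, yellowness [%.2f, %.2f], max acrylamide %.1f ug/kg, %.0f%% compliant",
          g$n_points, g$yellowness_min, g$yellowness_max, g$acrylamide_max,
          100 * g$fraction_compliant))
      },
      mc = {
        cfg <- mc_config(n_draws = as.integer(opt$draws %||% 1000L),
                         seed = seed)
        ens <- run_mc(params, cfg, out_dir = out_dir)
        message(sprintf("ensemble: %d fronts, exceedance fraction %.3f",
                        length(ens$fronts), exceedance_fraction(ens)))
      },
      equiv = {
        front <- run_pareto("complete", params, out_dir = NULL)
        groups <- run_equivalence(front, out_dir = out_dir)
        message(sprintf("%d equivalence group(s) found",
                        if (nrow(groups)) max(groups$group_id) else 0L))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--") && i < length(args)) {
      opt[[substring(a, 3L)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  opt
}
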