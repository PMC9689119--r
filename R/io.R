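#' Read a kinetic parameter configuration file
#'
#' YAML or JSON (by file extension) with top-level keys `K1`..`K6`, each a
#' mapping with `k_ref`, `activation`, `T_ref`, `sd_k_ref`, `sd_activation`,
#' `order` and optionally `transform`. An optional top-level `label` names
#' the set. Missing keys are a validation error, so a file intended to carry
#' published literature rate constants fails loudly when
#' incomplete rather than silently defaulting.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A [kinetic_parameter_set()].
#' @export
read_kinetic_config <- function(path) {
  raw <- parse_config_file(path)
  wanted <- paste0("K", 1:6)
  missing <- setdiff(wanted, names(raw))
  if (length(missing) > 0L) {
    rlang::abort(paste0("kinetic config missing keys: ",
                        paste(missing, collapse = ", ")),
                 class = "frypareto_config_schema_error")
  }
  fields <- c("k_ref", "activation", "T_ref", "sd_k_ref", "sd_activation",
              "order")
  constants <- lapply(wanted, function(nm) {
    entry <- raw[[nm]]
    miss <- setdiff(fields, names(entry))
    if (length(miss) > 0L) {
      rlang::abort(sprintf("kinetic config %s missing fields: %s",
                           nm, paste(miss, collapse = ", ")),
                   class = "frypareto_config_schema_error")
    }
    rate_constant(k_ref = entry$k_ref, activation = entry$activation,
                  T_ref = entry$T_ref, sd_k_ref = entry$sd_k_ref,
                  sd_activation = entry$sd_activation, order = entry$order,
                  transform = entry$transform %||% "arrhenius")
  })
  names(constants) <- wanted
  kinetic_parameter_set(constants, label = raw$label %||% "config")
}

#' Write a kinetic parameter set to a configuration file
#'
#' @param params A [kinetic_parameter_set()].
#' @param path Destination ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_kinetic_config <- function(params, path) {
  stopifnot(inherits(params, "kinetic_parameter_set"))
  payload <- lapply(params$constants, function(k) {
    list(k_ref = k$k_ref, activation = k$activation, T_ref = k$T_ref,
         sd_k_ref = k$sd_k_ref, sd_activation = k$sd_activation,
         order = k$order, transform = k$transform)
  })
  payload$label <- params$label
  write_config_file(payload, path)
  invisible(path)
}

parse_config_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "frypareto_config_schema_error")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    rlang::abort("config must be .yaml, .yml or .json.",
                 class = "frypareto_config_schema_error"))
}

write_config_file <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path, precision = 15L),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    rlang::abort("config must be .yaml, .yml or .json.",
                 class = "frypareto_config_schema_error"))
  invisible(path)
}

front_csv_cols <- c("t_min", "T_C", "acrylamide_ug_kg", "yellowness",
                    "moisture", "feasible", "compliant")

#' Write a Pareto front to the standard CSV schema
#'
#' Columns: `t_min`, `T_C`, `acrylamide_ug_kg`, `yellowness`, `moisture`,
#' `feasible`, `compliant`.
#'
#' @param front A `fry_front` (classified or not; `compliant` is filled with
#'   `NA` when absent).
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_front_csv <- function(front, path) {
  out <- tibble::tibble(
    t_min = front$t, T_C = front$T_C,
    acrylamide_ug_kg = front$acrylamide,
    yellowness = front$yellowness, moisture = front$moisture,
    feasible = front$feasible,
    compliant = if ("compliant" %in% names(front)) front$compliant else NA)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a Pareto front written by [write_front_csv()]
#'
#' @param path CSV path.
#' @param provenance Label attached to the restored front.
#' @return A `fry_front`.
#' @export
read_front_csv <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) {
    rlang::abort(paste0("front CSV not found: ", path),
                 class = "frypareto_config_schema_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(front_csv_cols, names(df))
  if (length(missing) > 0L) {
    rlang::abort(paste0("front CSV missing columns: ",
                        paste(missing, collapse = ", ")),
                 class = "frypareto_config_schema_error")
  }
  front <- tibble::tibble(
    t = df$t_min, T_C = df$T_C, acrylamide = df$acrylamide_ug_kg,
    yellowness = df$yellowness, moisture = df$moisture,
    feasible = df$feasible)
  if (!all(is.na(df$compliant))) front$compliant <- df$compliant
  new_fry_front(front, provenance = provenance)
}

#' Write equivalence groups to CSV
#'
#' @param groups A `fry_equivalence` tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_groups_csv <- function(groups, path) {
  out <- tibble::tibble(
    group_id = groups$group_id, t_min = groups$t, T_C = groups$T_C,
    acrylamide = groups$acrylamide, yellowness = groups$yellowness,
    moisture = groups$moisture)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' @param traj A `fry_trajectory` from [simulate_network()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj), path)
  invisible(path)
}
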