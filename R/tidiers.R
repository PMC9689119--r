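#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Pareto front
#'
#' @param x A `fry_front`.
#' @param ... Unused.
#' @return A plain tibble of front points with a `provenance` column.
#' @export
tidy.fry_front <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$provenance <- attr(x, "provenance") %||% NA_character_
  out
}

#' One-row summary of a Pareto front
#'
#' @param x A `fry_front`.
#' @param ... Unused.
#' @return Tibble with point count, yellowness range, acrylamide range and
#'   (when classified) the compliant fraction.
#' @export
glance.fry_front <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    yellowness_min = min(x$yellowness),
    yellowness_max = max(x$yellowness),
    acrylamide_min = min(x$acrylamide),
    acrylamide_max = max(x$acrylamide),
    fraction_compliant = attr(x, "fraction_compliant") %||% NA_real_,
    provenance = attr(x, "provenance") %||% NA_character_)
}

#' Tidy a Monte-Carlo front ensemble
#'
#' @param x A `fry_ensemble`.
#' @param ... Unused.
#' @return Tibble of all front points with a `draw` index column.
#' @export
tidy.fry_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$fronts, function(f, i) {
    out <- tibble::as_tibble(f)
    out$draw <- i
    out
  })
}

#' One-row summary of a Monte-Carlo front ensemble
#'
#' @param x A `fry_ensemble`.
#' @param limit Acrylamide limit for the exceedance fraction, ug/kg.
#' @param ... Unused.
#' @return Tibble with ensemble size, failures, point count and exceedance
#'   fraction.
#' @export
glance.fry_ensemble <- function(x, limit = 50, ...) {
  tibble::tibble(
    n_fronts = length(x$fronts),
    n_failed = x$n_failed,
    n_points = sum(vapply(x$fronts, nrow, integer(1))),
    exceedance_fraction = exceedance_fraction(x, limit))
}

#' One-row summary of detected equivalence groups
#'
#' @param x A `fry_equivalence`.
#' @param ... Unused.
#' @return Tibble with group count, total members and largest group size.
#' @export
glance.fry_equivalence <- function(x, ...) {
  tibble::tibble(
    n_groups = if (nrow(x)) max(x$group_id) else 0L,
    n_members = nrow(x),
    max_group_size = if (nrow(x)) max(x$group_size) else 0L)
}

#' @export
print.fry_ensemble <- function(x, ...) {
  cat("<fry_ensemble>", length(x$fronts), "fronts (",
      x$n_failed, "failed draws )\n")
  invisible(x)
}
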