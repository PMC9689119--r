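#' Criteria defining practically equivalent operating points
#'
#' Two operating points are quasi-equivalent when their objectives coincide
#' within `objective_tol` (applied to acrylamide in ug/kg and to yellowness)
#' while the treatments themselves differ by at least `min_dT` degrees AND
#' `min_dt` minutes — i.e. genuinely different process settings delivering
#' the same product.
#'
#' @param objective_tol Tolerance on each objective (default 0.01).
#' @param min_dT Minimum temperature separation, degrees Celsius (default 1).
#' @param min_dt Minimum time separation, minutes (default 0.2).
#' @return Object of class `equivalence_criteria`.
#' @export
equivalence_criteria <- function(objective_tol = 0.01, min_dT = 1,
                                 min_dt = 0.2) {
  stopifnot(objective_tol >= 0, min_dT > 0, min_dt > 0)
  structure(list(objective_tol = objective_tol, min_dT = min_dT,
                 min_dt = min_dt),
            class = "equivalence_criteria")
}

equivalent_pair <- function(pts, i, j, crit) {
  db <- abs(pts$yellowness[i] - pts$yellowness[j])
  if (db > crit$objective_tol) return(FALSE)
  ai <- pts$acrylamide[i]; aj <- pts$acrylamide[j]
  if (!is.na(ai) && !is.na(aj) && abs(ai - aj) > crit$objective_tol) {
    return(FALSE)
  }
  abs(pts$T_C[i] - pts$T_C[j]) >= crit$min_dT &&
    abs(pts$t[i] - pts$t[j]) >= crit$min_dt
}

#' Group quasi-equivalent operating points
#'
#' Builds maximal groups under the pairwise equivalence relation: connected
#' components by single linkage, then greedy pruning (dropping the member
#' with the most violated pairs; ties toward higher yellowness, then later
#' input order) until every remaining pair is valid. Groups of fewer than two
#' members are discarded. Output ordering is by representative yellowness, so
#' results do not depend on input order.
#'
#' @param points Tibble with columns `t`, `T_C`, `yellowness` and optionally
#'   `acrylamide` (if present and non-`NA`, acrylamide closeness is required
#'   too).
#' @param criteria An [equivalence_criteria()].
#' @return Tibble of class `fry_equivalence`: `group_id`, member rows, and
#'   per-group representative objectives; zero rows when no groups exist.
#' @export
find_equivalent_sets <- function(points, criteria = equivalence_criteria()) {
  n <- nrow(points)
  empty <- tibble::tibble(group_id = integer(), t = numeric(),
                          T_C = numeric(), acrylamide = numeric(),
                          yellowness = numeric(), moisture = numeric(),
                          group_yellowness = numeric(), group_size = integer())
  if (n < 2L) return(structure(empty, class = c("fry_equivalence", class(empty))))
  if (!"acrylamide" %in% names(points)) points$acrylamide <- NA_real_
  if (!"moisture" %in% names(points)) points$moisture <- NA_real_

  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adj[i, j] <- adj[j, i] <- equivalent_pair(points, i, j, criteria)
    }
  }
  # connected components (single linkage)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cid
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }

  groups <- list()
  for (g in seq_len(cid)) {
    members <- which(comp == g)
    if (length(members) < 2L) next
    # prune to pairwise validity
    repeat {
      sub <- adj[members, members, drop = FALSE]
      bad <- rowSums(!sub) - 1L   # invalid pairs per member
      if (all(bad == 0L)) break
      worst <- which(bad == max(bad))
      drop <- worst[order(points$yellowness[members[worst]],
                          members[worst], decreasing = TRUE)][1L]
      members <- members[-drop]
      if (length(members) < 2L) break
    }
    if (length(members) >= 2L) groups[[length(groups) + 1L]] <- members
  }
  if (length(groups) == 0L) {
    return(structure(empty, class = c("fry_equivalence", class(empty))))
  }
  rep_b <- vapply(groups, function(m) mean(points$yellowness[m]), numeric(1))
  groups <- groups[order(rep_b)]
  out <- purrr::imap_dfr(groups, function(m, gi) {
    rows <- points[m, c("t", "T_C", "acrylamide", "yellowness", "moisture")]
    rows <- dplyr::arrange(rows, .data$T_C)
    dplyr::mutate(rows, group_id = as.integer(gi),
                  group_yellowness = mean(rows$yellowness),
                  group_size = nrow(rows), .before = 1L)
  })
  structure(out, class = c("fry_equivalence", class(out)))
}

#' Locus of operating points delivering a target outcome
#'
#' Traces, in the (t, T) plane, the treatments achieving a target yellowness
#' (and, when kinetic parameters are supplied and a target acrylamide is
#' given, that acrylamide level within tolerance). The locus is the yellowness
#' level curve inside the feasible set; a greedy sweep by increasing
#' temperature marks a maximal subset of members that are pairwise separated
#' by the criteria's minimum temperature and time differences — the distinct,
#' practically interchangeable process settings.
#'
#' @param target List with `yellowness` (required) and optional `acrylamide`.
#' @param criteria An [equivalence_criteria()].
#' @param bounds A [design_bounds()].
#' @param p Quality parameters.
#' @param params Optional kinetic parameters (needed for an acrylamide target).
#' @param T_step Temperature sampling step along the locus.
#' @return Tibble `t`, `T_C`, `yellowness`, `moisture` (+ `acrylamide` when
#'   computed), ordered by `T_C`, with logical column `member` flagging the
#'   separated representatives; attribute `"n_members"` carries their count.
#' @export
equivalence_curve <- function(target, criteria = equivalence_criteria(),
                              bounds = design_bounds(), p = quality_params(),
                              params = NULL, T_step = 0.05) {
  stopifnot(is.list(target), !is.null(target$yellowness))
  locus <- level_curve(target$yellowness, bounds, p, T_step)
  if (nrow(locus) == 0L) {
    locus$member <- logical(0)
    attr(locus, "n_members") <- 0L
    return(locus)
  }
  if (!is.null(params)) {
    eval_acr <- acrylamide_evaluator(params)
    locus$acrylamide <- NA_real_
    for (Tv in unique(locus$T_C)) {
      idx <- which(locus$T_C == Tv)
      locus$acrylamide[idx] <- eval_acr(locus$t[idx], Tv)
    }
    if (!is.null(target$acrylamide)) {
      locus <- dplyr::filter(
        locus, abs(.data$acrylamide - target$acrylamide) <= criteria$objective_tol)
    }
  }
  locus <- dplyr::arrange(locus, .data$T_C)
  member <- logical(nrow(locus))
  chosen <- integer(0)
  for (i in seq_len(nrow(locus))) {
    ok <- all(abs(locus$T_C[i] - locus$T_C[chosen]) >= criteria$min_dT &
              abs(locus$t[i] - locus$t[chosen]) >= criteria$min_dt)
    if (length(chosen) == 0L || ok) {
      chosen <- c(chosen, i)
      member[i] <- TRUE
    }
  }
  locus$member <- member
  attr(locus, "n_members") <- length(chosen)
  locus
}
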