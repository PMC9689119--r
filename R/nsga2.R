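#' Configuration of the genetic multi-objective solver
#'
#' Canonical elitist NSGA-II settings: real-coded genes, simulated binary
#' crossover (SBX), polynomial mutation, binary tournament under constrained
#' domination, environmental selection by rank then crowding distance.
#'
#' @param pop_size Population size (even, >= 4).
#' @param generations Number of generations.
#' @param crossover_prob Per-pair SBX probability.
#' @param crossover_eta SBX distribution index.
#' @param mutation_prob Per-gene polynomial-mutation probability.
#' @param mutation_eta Mutation distribution index.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100, generations = 200,
                      crossover_prob = 0.9, crossover_eta = 15,
                      mutation_prob = 0.5, mutation_eta = 20,
                      seed = NULL) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            crossover_eta > 0, mutation_eta > 0)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 crossover_eta = crossover_eta,
                 mutation_prob = mutation_prob,
                 mutation_eta = mutation_eta,
                 seed = seed),
            class = "ga_config")
}

#' Fast non-dominated sorting (minimisation, constrained)
#'
#' Assigns each point a front rank (1 = non-dominated). Under constrained
#' domination a feasible point dominates every infeasible one; two infeasible
#' points compare by total constraint violation; two feasible points by
#' ordinary Pareto dominance on the objective rows.
#'
#' @param objectives Numeric matrix, one row per point, objectives minimised.
#' @param cv Optional nonnegative constraint-violation vector (0 = feasible).
#' @return Integer vector of ranks starting at 1.
#' @export
fast_non_dominated_sort <- function(objectives, cv = NULL) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (is.null(cv)) cv <- numeric(n)
  dominates <- function(i, j) {
    if (cv[i] < cv[j]) return(TRUE)
    if (cv[i] > cv[j]) return(FALSE)
    if (cv[i] > 0) return(FALSE)           # equally infeasible: neither
    le <- objectives[i, ] <= objectives[j, ]
    all(le) && any(objectives[i, ] < objectives[j, ])
  }
  n_dom <- integer(n)
  dom_set <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) dom_set[[i]] <- c(dom_set[[i]], j)
      else if (dominates(j, i)) n_dom[i] <- n_dom[i] + 1L
    }
  }
  rank <- integer(n)
  current <- which(n_dom == 0L)
  r <- 1L
  while (length(current) > 0L) {
    rank[current] <- r
    nxt <- integer(0)
    for (i in current) {
      for (j in dom_set[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
    r <- r + 1L
  }
  rank
}

#' Crowding distance within one front
#'
#' Per-objective normalised spacing of each point's neighbours; boundary
#' points get infinite distance so the extremes of the front are always
#' retained.
#'
#' @param objectives Numeric matrix (rows = points of a single front).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1L]]
    d[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      mid <- ord[2:(n - 1L)]
      d[mid] <- d[mid] + (o[ord[3:n]] - o[ord[1:(n - 2L)]]) / rng
    }
  }
  # duplicated objective vectors carry no diversity: zero them (interior only)
  key <- apply(objectives, 1L, paste, collapse = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  d[dup & is.finite(d)] <- 0
  d
}

sbx_crossover <- function(p1, p2, lower, upper, eta, prob) {
  if (stats::runif(1) > prob) return(list(p1, p2))
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5,
                 (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutation <- function(x, lower, upper, eta, prob) {
  for (i in seq_along(x)) {
    if (stats::runif(1) < prob) {
      u <- stats::runif(1)
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
               else 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[i] <- x[i] + delta * (upper[i] - lower[i])
    }
  }
  pmin(pmax(x, lower), upper)
}

crowded_better <- function(i, j, rank, crowd) {
  if (rank[i] != rank[j]) return(rank[i] < rank[j])
  crowd[i] > crowd[j]
}

#' Run the elitist non-dominated sorting genetic algorithm
#'
#' Generic real-coded NSGA-II over a box-bounded decision space with an
#' arbitrary number of minimised objectives and an optional constraint
#' violation. Reproducible bit-for-bit given `config$seed`.
#'
#' @param fn Function `x -> numeric vector` of objective values (minimised).
#'   Evaluation failures count as worst fitness.
#' @param lower,upper Decision-variable bounds (equal length).
#' @param config A [ga_config()].
#' @param cv_fn Optional function `x -> nonnegative scalar` total constraint
#'   violation (0 = feasible).
#' @param keep_history Record per-generation objective summaries (used for
#'   convergence diagnostics).
#' @return List with `x` (decision matrix), `objectives`, `cv`, `rank`, and
#'   optionally `history` (tibble with per-generation feasible objective
#'   minima).
#' @export
nsga2_run <- function(fn, lower, upper, config = ga_config(), cv_fn = NULL,
                      keep_history = FALSE) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  nvar <- length(lower)
  np <- config$pop_size
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(config$seed)
  }

  eval_one <- function(x) {
    f <- tryCatch(fn(x), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) f <- NULL
    cv <- if (is.null(cv_fn)) 0 else tryCatch(cv_fn(x), error = function(e) Inf)
    if (is.null(f)) list(f = rep(Inf, n_obj), cv = Inf) else list(f = f, cv = cv)
  }

  # probe objective dimension
  probe <- fn((lower + upper) / 2)
  n_obj <- length(probe)

  X <- matrix(stats::runif(np * nvar, rep(lower, each = np), rep(upper, each = np)),
              nrow = np)
  evals <- lapply(seq_len(np), function(i) eval_one(X[i, ]))
  FV <- do.call(rbind, lapply(evals, `[[`, "f"))
  CV <- vapply(evals, `[[`, numeric(1), "cv")

  history <- if (keep_history) vector("list", config$generations) else NULL

  for (gen in seq_len(config$generations)) {
    rank <- fast_non_dominated_sort(FV, CV)
    crowd <- numeric(np)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding_distance(FV[idx, , drop = FALSE])
    }
    # binary tournament mating selection
    parents <- matrix(0, nrow = np, ncol = nvar)
    for (i in seq_len(np)) {
      a <- sample.int(np, 1L); b <- sample.int(np, 1L)
      parents[i, ] <- if (crowded_better(a, b, rank, crowd)) X[a, ] else X[b, ]
    }
    # variation
    off <- matrix(0, nrow = np, ncol = nvar)
    for (i in seq(1L, np, by = 2L)) {
      ch <- sbx_crossover(parents[i, ], parents[i + 1L, ], lower, upper,
                          config$crossover_eta, config$crossover_prob)
      off[i, ] <- poly_mutation(ch[[1L]], lower, upper,
                                config$mutation_eta, config$mutation_prob)
      off[i + 1L, ] <- poly_mutation(ch[[2L]], lower, upper,
                                     config$mutation_eta, config$mutation_prob)
    }
    oev <- lapply(seq_len(np), function(i) eval_one(off[i, ]))
    OF <- do.call(rbind, lapply(oev, `[[`, "f"))
    OC <- vapply(oev, `[[`, numeric(1), "cv")

    # elitist environmental selection on parents + offspring
    allX <- rbind(X, off); allF <- rbind(FV, OF); allC <- c(CV, OC)
    arank <- fast_non_dominated_sort(allF, allC)
    keep <- integer(0)
    for (r in sort(unique(arank))) {
      idx <- which(arank == r)
      if (length(keep) + length(idx) <= np) {
        keep <- c(keep, idx)
      } else {
        cd <- crowding_distance(allF[idx, , drop = FALSE])
        keep <- c(keep, idx[order(-cd)][seq_len(np - length(keep))])
        break
      }
    }
    X <- allX[keep, , drop = FALSE]
    FV <- allF[keep, , drop = FALSE]
    CV <- allC[keep]
    if (keep_history) {
      feas <- CV == 0
      history[[gen]] <- tibble::tibble(
        generation = gen,
        best_f1 = if (any(feas)) min(FV[feas, 1L]) else NA_real_,
        best_f2 = if (any(feas)) min(FV[feas, 2L]) else NA_real_)
    }
  }
  rank <- fast_non_dominated_sort(FV, CV)
  out <- list(x = X, objectives = FV, cv = CV, rank = rank)
  if (keep_history) out$history <- dplyr::bind_rows(history)
  out
}

#' Pareto front of the frying problem by NSGA-II
#'
#' Solves min (acrylamide, -yellowness) over the (t, T) box with the terminal
#' moisture constraint handled by constrained domination (violation
#' `max(0, X_low - X) + max(0, X - X_high)`). The final rank-1 feasible
#' individuals are dominance-filtered and returned as a `fry_front`.
#'
#' @param params A [kinetic_parameter_set()].
#' @param bounds A [design_bounds()].
#' @param p Quality parameters.
#' @param config A [ga_config()] (the seed makes runs reproducible).
#' @param keep_history Forwarded to [nsga2_run()].
#' @return A `fry_front`; with `keep_history` the per-generation summary is
#'   attached as attribute `"history"`.
#' @export
pareto_nsga2 <- function(params, bounds = design_bounds(),
                         p = quality_params(), config = ga_config(),
                         keep_history = FALSE) {
  fn <- function(x) {
    acr <- acrylamide_at(params, x[1L], x[2L])
    c(acr, -yellowness(x[1L], x[2L], p))
  }
  cv_fn <- function(x) {
    X <- moisture(x[1L], x[2L], p)
    max(0, bounds$X_low - X) + max(0, X - bounds$X_high)
  }
  res <- nsga2_run(fn, lower = c(bounds$t_min, bounds$T_min),
                   upper = c(bounds$t_max, bounds$T_max),
                   config = config, cv_fn = cv_fn,
                   keep_history = keep_history)
  sel <- res$rank == 1L & res$cv == 0
  pts <- tibble::tibble(
    t = res$x[sel, 1L], T_C = res$x[sel, 2L],
    acrylamide = res$objectives[sel, 1L],
    yellowness = -res$objectives[sel, 2L],
    moisture = moisture(res$x[sel, 1L], res$x[sel, 2L], p),
    feasible = TRUE
  )
  pts <- dplyr::distinct(pts, .data$t, .data$T_C, .keep_all = TRUE)
  front <- new_fry_front(pareto_filter(pts),
                         provenance = sprintf("nsga2-%s-seed-%s", params$label,
                                              config$seed %||% "none"))
  if (keep_history) attr(front, "history") <- res$history
  front
}

#' Distance between two fronts in normalised objective space
#'
#' For each point of `front`, the Euclidean distance to the nearest point of
#' `reference` after scaling both objectives to the reference's range. Used
#' to cross-validate the genetic solver against the complete search.
#'
#' @param front,reference `fry_front` tibbles.
#' @return List with `max` and `mean` distance.
#' @export
front_distance <- function(front, reference) {
  ra <- range(reference$acrylamide); rb <- range(reference$yellowness)
  sa <- max(diff(ra), .Machine$double.eps)
  sb <- max(diff(rb), .Machine$double.eps)
  d <- vapply(seq_len(nrow(front)), function(i) {
    min(sqrt(((front$acrylamide[i] - reference$acrylamide) / sa)^2 +
             ((front$yellowness[i] - reference$yellowness) / sb)^2))
  }, numeric(1))
  list(max = max(d), mean = mean(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
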