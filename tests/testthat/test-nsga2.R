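brute_force_ranks <- function(obj, cv = NULL) {
  # O(n^3)-ish dominance-counting oracle, independent of the package sort
  n <- nrow(obj)
  if (is.null(cv)) cv <- numeric(n)
  dom <- function(i, j) {
    if (cv[i] != cv[j]) return(cv[i] < cv[j])
    if (cv[i] > 0) return(FALSE)
    all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ])
  }
  rank <- integer(n)
  alive <- rep(TRUE, n)
  r <- 0L
  while (any(alive)) {
    r <- r + 1L
    idx <- which(alive)
    nd <- idx[vapply(idx, function(i)
      !any(vapply(idx, function(j) i != j && dom(j, i), logical(1))),
      logical(1))]
    rank[nd] <- r
    alive[nd] <- FALSE
  }
  rank
}

test_that("non-dominated sorting matches strict dominance and the brute-force oracle", {
  expect_equal(fast_non_dominated_sort(rbind(c(1, 1), c(2, 2))), c(1L, 2L))
  expect_equal(fast_non_dominated_sort(rbind(c(1, 2), c(2, 1))), c(1L, 1L))

  set.seed(33)
  obj <- matrix(runif(100), ncol = 2)
  expect_equal(fast_non_dominated_sort(obj), brute_force_ranks(obj))

  # with constraints: feasible always outranks infeasible
  cv <- c(rep(0, 30), runif(20, 0.1, 2))
  ranks <- fast_non_dominated_sort(obj, cv)
  expect_equal(ranks, brute_force_ranks(obj, cv))
  expect_lt(max(ranks[cv == 0]), min(ranks[cv > 0]))
})

test_that("crowding distance rewards boundary and spacing", {
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))

  # three equally spaced collinear points: middle gets 1 per objective
  obj <- rbind(c(0, 0), c(1, 1), c(2, 2))
  d <- crowding_distance(obj)
  expect_equal(d[2], 2)
  expect_true(all(is.infinite(d[c(1, 3)])))

  # duplicated interior vectors get zero distance
  obj2 <- rbind(c(0, 2), c(1, 1), c(1, 1), c(2, 0))
  d2 <- crowding_distance(obj2)
  expect_equal(d2[2], 0)
  expect_equal(d2[3], 0)
})

test_that("the GA recovers the analytic front of a convex toy problem", {
  fn <- function(x) c(x[1]^2, (x[1] - 2)^2)
  res <- nsga2_run(fn, lower = -1, upper = 3,
                   config = ga_config(pop_size = 60, generations = 60,
                                      seed = 5))
  sol <- res$x[res$rank == 1L, 1L]
  # analytic Pareto set is u in [0, 2]
  expect_true(all(sol > -1e-2 & sol < 2 + 1e-2))
  expect_gt(diff(range(sol)), 1.5)   # spread along the front, not collapsed
})

test_that("GA runs are bit-identical under a fixed seed", {
  ks <- synth_params()
  cfg <- ga_config(pop_size = 20, generations = 15, seed = 99)
  f1 <- pareto_nsga2(ks, config = cfg)
  f2 <- pareto_nsga2(ks, config = cfg)
  expect_identical(tibble::as_tibble(f1), tibble::as_tibble(f2))
})

test_that("elitism never loses the best feasible objective values", {
  ks <- synth_params()
  front <- pareto_nsga2(ks, config = ga_config(pop_size = 24,
                                               generations = 40, seed = 3),
                        keep_history = TRUE)
  h <- attr(front, "history")
  expect_true(all(diff(h$best_f1) <= 1e-12, na.rm = TRUE))  # min acrylamide
  expect_true(all(diff(h$best_f2) <= 1e-12, na.rm = TRUE))  # max yellowness
})
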