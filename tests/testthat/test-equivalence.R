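test_that("published equivalent pairs satisfy the pairwise definition", {
  tb <- table1_points()
  p45 <- tb[tb$id %in% c("4", "4p"), ]
  groups <- find_equivalent_sets(p45)
  expect_equal(nrow(groups), 2)
  expect_equal(unique(groups$group_id), 1L)
  # printed acrylamide values 0.345 vs 0.348 also pass the 0.01 tolerance
  expect_lte(abs(diff(p45$acrylamide)), 0.01)
})

test_that("separation and tolerance requirements both bind", {
  # identical treatments are not 'equivalent' (no separation)
  same <- tibble::tibble(t = c(2, 2), T_C = c(130, 130),
                         yellowness = c(23, 23))
  expect_equal(nrow(find_equivalent_sets(same)), 0)

  # objective difference of 0.5 violates the tolerance
  far <- tibble::tibble(t = c(2, 4), T_C = c(130, 140),
                        yellowness = c(23, 23.5))
  expect_equal(nrow(find_equivalent_sets(far)), 0)

  # zero tolerance on continuously evaluated points yields no groups
  set.seed(7)
  t <- runif(10, 0.5, 9); Tv <- runif(10, 121, 199)
  pts <- tibble::tibble(t = t, T_C = Tv, yellowness = yellowness(t, Tv))
  crit0 <- equivalence_criteria(objective_tol = 0)
  expect_equal(nrow(find_equivalent_sets(pts, crit0)), 0)
})

test_that("grouping is independent of input order", {
  tb <- table1_points()
  g1 <- find_equivalent_sets(tb)
  set.seed(4)
  g2 <- find_equivalent_sets(tb[sample(nrow(tb)), ])
  cols <- c("group_id", "t", "T_C", "yellowness")
  expect_equal(as.data.frame(g1[cols]), as.data.frame(g2[cols]))
})

test_that("all seven published pairs are recovered as groups", {
  tb <- table1_points()
  # evaluate objectives with the package quality models at the printed (t,T);
  # acrylamide omitted (kinetics of the published table are external)
  pts <- tibble::tibble(t = tb$t, T_C = tb$T_C,
                        yellowness = yellowness(tb$t, tb$T_C),
                        moisture = moisture(tb$t, tb$T_C))
  groups <- find_equivalent_sets(pts)
  expect_equal(max(groups$group_id), 7)
  expect_equal(nrow(groups), 14)
  expect_true(all(groups$group_size == 2))
})

test_that("equivalence loci shrink as the yellowness target rises", {
  # monotone acrylamide surrogate with realistic temperature sensitivity:
  # flat at mild conditions, steep at severe ones
  surr <- function(t, T_C) 1300 * (t / 2)^1.5 * exp(0.134 * (T_C - 200))
  counts <- vapply(c(22.8, 23.4, 24.5), function(b_star) {
    lc <- equivalence_curve(list(yellowness = b_star), params = surr,
                            T_step = 0.2)
    best <- min(lc$acrylamide)
    cur <- equivalence_curve(list(yellowness = b_star, acrylamide = best),
                             params = surr, T_step = 0.2)
    attr(cur, "n_members")
  }, integer(1))
  expect_true(all(diff(counts) < 0))

  # at the front endpoint the active moisture bound pins a unique point
  top <- equivalence_curve(list(yellowness = 26.88), T_step = 0.05)
  expect_lte(attr(top, "n_members"), 1)
})

test_that("a monotone surrogate reduces equivalence to level-curve extent", {
  # strictly monotone surrogate: equivalence on a yellowness level requires
  # the curve itself to span the separation thresholds
  surrogate <- function(t, T_C) 1e-4 * t + 1e-4 * (T_C - 120)
  crit <- equivalence_criteria()
  lc <- level_curve(22.96, T_step = 0.2)
  span_ok <- diff(range(lc$T_C)) >= crit$min_dT &&
    diff(range(lc$t)) >= crit$min_dt
  curve <- equivalence_curve(list(yellowness = 22.96), crit,
                             params = surrogate, T_step = 0.2)
  expect_identical(attr(curve, "n_members") >= 2, span_ok)
})
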