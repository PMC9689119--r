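test_that("feasibility of narrowed design boxes matches the closed-form moisture law", {
  # short, cool treatments barely move moisture: everything feasible
  cool <- design_bounds(t_min = 0.1, t_max = 0.2, T_min = 120, T_max = 121)
  reg <- feasible_region(cool, grid_resolution = 10)
  expect_equal(nrow(reg), 100)
  expect_true(all(abs(reg$moisture - 3.9) < 0.05))

  # long, hot treatments dry below the lower bound: empty feasible set
  hot <- design_bounds(t_min = 9, t_max = 10, T_min = 199, T_max = 200)
  expect_warning(reg2 <- feasible_region(hot, grid_resolution = 10),
                 "empty")
  expect_equal(nrow(reg2), 0)
})

test_that("level curves pass through published points and pinch at the hot boundary", {
  lc <- level_curve(22.96, T_step = 0.05)
  row <- dplyr::filter(lc, abs(T_C - 127) < 1e-9)
  expect_equal(nrow(row), 1)
  expect_equal(row$t, 3.61, tolerance = 0.01)

  # near the maximum attainable yellowness the curve survives only next to
  # the (t ~ 1.96, T = 200) corner where the X = 2 boundary intersects
  hi <- level_curve(26.88, T_step = 0.05)
  expect_gt(nrow(hi), 0)
  expect_true(all(hi$T_C > 199))
  expect_true(all(abs(hi$t - 1.96) < 0.05))

  # the initial-yellowness level set needs t -> 0, excluded by t_min
  expect_equal(nrow(level_curve(22.6, T_step = 1)), 0)
})

test_that("complete search matches a brute-force grid oracle for a monotone surrogate", {
  surrogate <- function(t, T_C) 5 * (t / 10) + 3 * ((T_C - 120) / 80)^2
  bounds <- design_bounds()
  front <- pareto_complete_search(surrogate, bounds, b_star_step = 0.1,
                                  T_step = 0.1)

  # oracle: dense rectangular grid, bin by yellowness, take the feasible min
  grid <- tidyr::expand_grid(t = seq(0.1, 10, length.out = 1500),
                             T_C = seq(120, 200, length.out = 1500))
  b <- yellowness(grid$t, grid$T_C)
  X <- moisture(grid$t, grid$T_C)
  f <- surrogate(grid$t, grid$T_C)
  feas <- X >= 2 & X <= 4
  rows <- round(seq(5, nrow(front) - 2, length.out = 5))
  for (i in rows) {
    b_star <- front$yellowness[i]
    sel <- feas & abs(b - b_star) < 0.005
    oracle_min <- min(f[sel])
    expect_lt(abs(front$acrylamide[i] - oracle_min), 0.02,
              label = sprintf("front minimum at b*=%.2f", b_star))
  }
})

test_that("the nominal front is dominance-free and stable under grid refinement", {
  ks <- synth_params()
  front <- pareto_complete_search(ks, b_star_step = 0.05, T_step = 0.5)
  expect_equal(nrow(pareto_filter(front)), nrow(front))
  expect_true(all(diff(front$acrylamide) >= 0))
  expect_true(all(diff(front$yellowness) > 0))

  finer <- pareto_complete_search(ks, b_star_step = 0.05, T_step = 0.25)
  shared <- intersect(round(front$yellowness, 6), round(finer$yellowness, 6))
  expect_gt(length(shared), 50)
  a1 <- front$acrylamide[match(shared, round(front$yellowness, 6))]
  a2 <- finer$acrylamide[match(shared, round(finer$yellowness, 6))]
  expect_lt(max(abs(a1 - a2) / pmax(a2, 1e-6)), 0.01)

  # the moisture lower bound is active on the high-yellowness end
  top <- dplyr::filter(tibble::as_tibble(front), yellowness > 26.5)
  expect_gt(nrow(top), 0)
  expect_true(all(abs(top$moisture - 2) < 0.02))
})

test_that("compliance classification counts points against the limit", {
  f0 <- tibble::tibble(acrylamide = c(0, 0, 0), yellowness = 23:25)
  expect_equal(attr(classify_front(f0), "fraction_compliant"), 1)

  f1 <- tibble::tibble(acrylamide = c(40, 60), yellowness = c(23, 24))
  cf <- classify_front(f1, limit = 50)
  expect_identical(cf$compliant, c(TRUE, FALSE))
  expect_equal(attr(cf, "fraction_compliant"), 0.5)
})
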