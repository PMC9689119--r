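test_that("rate constant evaluation honours the reference point and transforms", {
  # temperature-independent limit
  k0 <- rate_constant(0.3, activation = 0)
  expect_equal(evaluate_rate_constant(k0, 135), 0.3)
  expect_equal(evaluate_rate_constant(k0, 195), 0.3)

  # reference-point identity regardless of activation
  for (act in c(-0.05, 0.01, 2000)) {
    for (tr in c("arrhenius", "loglinear")) {
      k <- rate_constant(0.07, activation = act, T_ref = 150, transform = tr)
      expect_equal(evaluate_rate_constant(k, 150), 0.07)
    }
  }

  # doubling-per-20-degC closed form under the log-linear transform
  k2 <- rate_constant(0.01, activation = log(2) / 20, T_ref = 160,
                      transform = "loglinear")
  expect_equal(evaluate_rate_constant(k2, 200), 0.04, tolerance = 1e-12)

  # monotone and continuous in T when activation != 0
  ka <- rate_constant(0.01, activation = 8000, T_ref = 160)
  Ts <- seq(120, 200, by = 0.5)
  vals <- evaluate_rate_constant(ka, Ts)
  expect_true(all(diff(vals) > 0))
  expect_true(all(is.finite(vals) & vals > 0))

  expect_warning(evaluate_rate_constant(k0, 250), "validated")
  expect_error(rate_constant(NaN), class = "frypareto_invalid_parameter")
  expect_error(rate_constant(0.1, sd_k_ref = -1),
               class = "frypareto_invalid_parameter")
})

test_that("parameter-set construction enforces the six-constant schema", {
  ks <- synth_params()
  expect_s3_class(ks, "kinetic_parameter_set")
  expect_named(ks$constants, paste0("K", 1:6))
  expect_error(kinetic_parameter_set(ks$constants[1:5]),
               class = "frypareto_invalid_parameter")
  expect_error(kinetic_parameter_set(list(K1 = 1, K2 = 2, K3 = 3,
                                          K4 = 4, K5 = 5, K6 = 6)),
               class = "frypareto_invalid_parameter")
})

test_that("frozen dynamics leave the composition at its initial state", {
  traj <- simulate_network(initial_composition(), near_zero_kinetics(),
                           t_end = 8, T_C = 170)
  final <- traj[nrow(traj), ]
  expect_equal(final$glucose, 4.12, tolerance = 1e-9)
  expect_equal(final$fructose, 2.95, tolerance = 1e-9)
  expect_equal(final$asparagine, 11.77, tolerance = 1e-9)
  expect_equal(final$acrylamide_mmol_L, 0, tolerance = 1e-9)
})

test_that("without asparagine and fructose, glucose decays first order and no acrylamide forms", {
  ks <- synth_params()
  init <- initial_composition(glucose = 4.12, fructose = 0, asparagine = 0)
  traj <- simulate_network(init, ks, t_end = 5, T_C = 160)
  K2 <- evaluate_rate_constant(ks$constants$K2, 160)
  expect_equal(traj$glucose[nrow(traj)], 4.12 * exp(-K2 * 5),
               tolerance = 1e-7)
  expect_equal(max(traj$acrylamide_mmol_L), 0, tolerance = 1e-12)
  expect_equal(max(traj$schiff_base), 0, tolerance = 1e-12)
})

test_that("adaptive solver agrees with the fixed-step RK4 oracle", {
  ks <- synth_params()
  # spec grid: 9 (t, T) pairs spanning the design domain
  grid <- expand.grid(t = c(0.5, 5, 10), T_C = c(120, 160, 200))
  for (i in seq_len(nrow(grid))) {
    adaptive <- acrylamide_at(ks, grid$t[i], grid$T_C[i])
    oracle <- rk4_final_acrylamide(ks, grid$t[i], grid$T_C[i], dt = 1e-4)
    expect_equal(adaptive, oracle, tolerance = 1e-6,
                 label = sprintf("acrylamide at (%g min, %g degC)",
                                 grid$t[i], grid$T_C[i]))
  }
})

test_that("trajectories are nonnegative with non-increasing asparagine", {
  set.seed(101)
  for (rep in 1:5) {
    ks <- generate_kinetic_set(synthetic_spec(seed = 100 + rep))
    Tv <- runif(1, 120, 200)
    traj <- simulate_network(initial_composition(), ks, t_end = 10, T_C = Tv)
    expect_true(all(as.matrix(traj[, -1]) >= -1e-9))
    expect_true(all(diff(traj$asparagine) <= 1e-9))
  }
})

test_that("acrylamide is non-decreasing when its elimination step vanishes", {
  ks <- synth_params()
  ks$constants$K6 <- rate_constant(1e-15, order = 1)
  traj <- simulate_network(initial_composition(), ks, t_end = 10, T_C = 180)
  expect_true(all(diff(traj$acrylamide_mmol_L) >= -1e-12))
})

test_that("final acrylamide is continuous in temperature", {
  ks <- synth_params()
  Ts <- seq(155, 165, by = 0.01)
  acr <- vapply(Ts, function(Tv) acrylamide_at(ks, 5, Tv), numeric(1))
  rel_jump <- abs(diff(acr)) / pmax(abs(acr[-length(acr)]), 1e-12)
  expect_lt(max(rel_jump), 1e-3)
})

test_that("mass-fraction conversion is linear with the stated default factor", {
  expect_equal(acrylamide_mass_fraction(0), 0)
  expect_equal(acrylamide_mass_fraction(0.01), 710.8)
  x <- 0.0137
  expect_equal(acrylamide_mass_fraction(2 * x),
               2 * acrylamide_mass_fraction(x))
  expect_error(acrylamide_mass_fraction(0.01, conversion = -1),
               class = "frypareto_invalid_parameter")
})

test_that("integration failures carry context and bad inputs are rejected", {
  ks <- synth_params()
  expect_error(simulate_network(initial_composition(), ks, t_end = -1,
                                T_C = 160),
               class = "frypareto_invalid_parameter")
  expect_error(initial_composition(glucose = -1),
               class = "frypareto_invalid_parameter")
})
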