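test_that("parameter draws are positive, unbiased, seeded and degenerate at sd 0", {
  ks <- synth_params()

  # sd = 0: every draw equals the nominal values
  ks0 <- ks
  for (nm in names(ks0$constants)) {
    ks0$constants[[nm]]$sd_k_ref <- 0
    ks0$constants[[nm]]$sd_activation <- 0
  }
  d0 <- draw_parameter_sets(ks0, mc_config(n_draws = 5, seed = 1))
  for (d in d0) {
    expect_equal(vapply(d$constants, `[[`, numeric(1), "k_ref"),
                 vapply(ks0$constants, `[[`, numeric(1), "k_ref"))
  }

  # law of large numbers: empirical sd within 5% of 0.1 * mean at n = 10000
  k1 <- ks$constants$K1$k_ref
  ks1 <- ks
  ks1$constants$K1$sd_k_ref <- 0.1 * k1
  dd <- draw_parameter_sets(ks1, mc_config(n_draws = 10000, seed = 2))
  vals <- vapply(dd, function(d) d$constants$K1$k_ref, numeric(1))
  expect_true(all(vals > 0))
  expect_equal(sd(vals), 0.1 * k1, tolerance = 0.05)
  expect_equal(mean(vals), k1, tolerance = 3 * 0.1 / sqrt(10000))

  # fixed seed reproduces the draw sequence exactly
  da <- draw_parameter_sets(ks, mc_config(n_draws = 10, seed = 9))
  db <- draw_parameter_sets(ks, mc_config(n_draws = 10, seed = 9))
  expect_identical(da, db)

  # absurd sd is a configuration error
  ks_bad <- ks
  ks_bad$constants$K2$sd_k_ref <- 1e6 * ks$constants$K2$k_ref
  expect_error(draw_parameter_sets(ks_bad, mc_config(n_draws = 1, seed = 1)),
               class = "frypareto_configuration_error")
})

test_that("zero-variance propagation collapses exactly onto the nominal front", {
  ks <- synth_params()
  for (nm in names(ks$constants)) {
    ks$constants[[nm]]$sd_k_ref <- 0
    ks$constants[[nm]]$sd_activation <- 0
  }
  cfg <- mc_config(n_draws = 3, seed = 1, method = "complete",
                   b_star_step = 0.2, T_step = 2)
  ens <- propagate(ks, cfg)
  for (f in ens$fronts) {
    expect_equal(as.data.frame(f)[c("t", "T_C", "acrylamide")],
                 as.data.frame(ens$nominal)[c("t", "T_C", "acrylamide")])
  }
})

test_that("exceedance counts every point of every front", {
  mk <- function(acr) {
    new_front <- tibble::tibble(t = seq_along(acr), T_C = 150,
                                acrylamide = acr,
                                yellowness = 23 + seq_along(acr) * 0.1,
                                moisture = 3, feasible = TRUE)
    structure(new_front, class = c("fry_front", class(tibble::tibble())))
  }
  ens <- structure(list(fronts = list(mk(c(10, 60)), mk(c(70, 80))),
                        nominal = mk(0), n_failed = 0L),
                   class = "fry_ensemble")
  expect_equal(exceedance_fraction(ens, 50), 0.75)
  ens0 <- structure(list(fronts = list(mk(c(0, 0)), mk(c(0, 0))),
                         nominal = mk(0), n_failed = 0L),
                    class = "fry_ensemble")
  expect_equal(exceedance_fraction(ens0, 50), 0)
})

test_that("the ensemble brackets the nominal front and widens with severity", {
  ks <- synth_params()
  cfg <- mc_config(n_draws = 50, seed = 21, method = "complete",
                   b_star_step = 0.1, T_step = 2)
  ens <- propagate(ks, cfg)
  expect_equal(length(ens$fronts), 50)

  # seeded determinism of the whole ensemble
  ens2 <- propagate(ks, cfg)
  expect_identical(lapply(ens$fronts, tibble::as_tibble),
                   lapply(ens2$fronts, tibble::as_tibble))

  env <- ensemble_envelope(ens, n_bins = 12)
  nominal <- ens$nominal
  # nominal lies within the pointwise [2.5, 97.5]% envelope for >= 90% of bins
  hits <- vapply(seq_len(nrow(env)), function(i) {
    j <- which.min(abs(nominal$yellowness - env$bin_mid[i]))
    nominal$acrylamide[j] >= env$q_lo[i] &&
      nominal$acrylamide[j] <= env$q_hi[i]
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # uncertainty grows along the front (monotone trend of a smoothed width)
  expect_gt(cor(env$bin_mid, env$width, method = "spearman"), 0.9)
  expect_gt(env$width[nrow(env)], env$width[1])
})

test_that("doubling parameter sds does not shrink the envelope", {
  ks <- synth_params()
  ks2 <- ks
  for (nm in names(ks2$constants)) {
    ks2$constants[[nm]]$sd_k_ref <- 2 * ks2$constants[[nm]]$sd_k_ref
    ks2$constants[[nm]]$sd_activation <- 2 * ks2$constants[[nm]]$sd_activation
  }
  cfg <- mc_config(n_draws = 50, seed = 8, method = "complete",
                   b_star_step = 0.2, T_step = 2)
  e1 <- ensemble_envelope(propagate(ks, cfg), n_bins = 3)
  e2 <- ensemble_envelope(propagate(ks2, cfg), n_bins = 3)
  expect_gte(median(e2$width), median(e1$width))
})
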