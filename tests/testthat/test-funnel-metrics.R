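test_that("P_Near is exactly 1 when every model sits on the native", {
  ens <- ensemble(energy = c(-3, -1, 0, 2, 7), similarity = rep(0, 5))
  expect_identical(compute_pnear(ens, funnel_params(lambda = 4, kbt = 1)), 1)
})

test_that("single-model P_Near is the closed-form proximity factor", {
  for (e in c(-1e5, 0, 42)) {
    ens <- ensemble(energy = e, similarity = 4.0)
    expect_equal(compute_pnear(ens, funnel_params(lambda = 4.0)), exp(-1),
                 tolerance = 1e-12)
  }
})

test_that("P_Near matches the direct-summation oracle on mock ensembles", {
  ens <- generate_ensemble(mock_protocol_params(n_models = 200, seed = 11))
  got <- compute_pnear(ens, funnel_params())
  want <- pnear_oracle(ens$models$energy, ens$models$similarity)
  expect_equal(got, want, tolerance = 1e-12)

  # and on adversarial random ensembles
  for (seed in 1:20) {
    r <- make_random_ensemble(n = 100, seed = seed)
    expect_equal(compute_pnear(r, funnel_params(lambda = 2, kbt = 1.5)),
                 pnear_oracle(r$models$energy, r$models$similarity,
                              lambda = 2, kbt = 1.5),
                 tolerance = 1e-12)
  }
})

test_that("mock default landscape gives the pilot-established P_Near band", {
  # a 1e5-model pilot of the default landscape puts the expected value at
  # ~0.9985; at n = 500 the sampling spread stays above 0.97
  ens <- generate_ensemble(mock_protocol_params(n_models = 500, seed = 1))
  p <- compute_pnear(ens)
  expect_gt(p, 0.97)
  expect_lte(p, 1)
})

test_that("P_Near is bounded, shift-invariant and overflow-proof", {
  for (seed in 1:50) {
    ens <- make_random_ensemble(n = 30, seed = seed)
    p <- compute_pnear(ens)
    expect_gte(p, 0)
    expect_lte(p, 1)
    for (shift in c(-1e6, -17.3, 1e3, 1e6)) {
      shifted <- ens
      shifted$models$energy <- ens$models$energy + shift
      expect_lt(abs(compute_pnear(shifted) - p), 1e-10)
    }
  }
  # energies at huge magnitude must not overflow to NaN
  huge <- ensemble(energy = c(-1e9, -1e9 + 1), similarity = c(0.1, 8))
  expect_true(is.finite(compute_pnear(huge)))
})

test_that("decreasing one model's similarity strictly increases P_Near", {
  # kbt wide enough that no model's Boltzmann weight underflows: strict
  # monotonicity only holds while every model carries nonzero weight
  pars <- funnel_params(lambda = 4, kbt = 20)
  set.seed(3)
  ens <- make_random_ensemble(n = 25)
  p0 <- compute_pnear(ens, pars)
  for (i in c(1, 10, 25)) {
    better <- ens
    better$models$similarity[i] <- better$models$similarity[i] * 0.5
    expect_gt(compute_pnear(better, pars), p0)
  }
})

test_that("P_Near limits: all-native gives 1, far Boltzmann-dominant model gives ~0", {
  set.seed(4)
  near <- ensemble(energy = rnorm(40), similarity = rep(0, 40))
  expect_identical(compute_pnear(near), 1)
  # one model holds essentially all Boltzmann weight but is very far away
  dominant <- ensemble(energy = c(-500, rep(0, 9)),
                       similarity = c(1e4, runif(9, 0, 5)))
  expect_lt(compute_pnear(dominant), 1e-12)
})

test_that("ensemble validation names the offending model", {
  ens <- ensemble(energy = c(-1, 2), similarity = c(0.1, 3),
                  tag = c("good_model", "bad_model"))
  ens$models$energy[2] <- NaN
  expect_error(compute_pnear(ens), "bad_model")
  expect_error(ensemble(energy = numeric(0), similarity = numeric(0)),
               "at least one model")
})

test_that("correlation handles exact linear relations and matches the textbook oracle", {
  x <- 1:10
  expect_equal(metric_correlation(x, 2 * x + 1)$coefficient, 1,
               tolerance = 1e-12)
  expect_equal(metric_correlation(x, -x)$coefficient, -1, tolerance = 1e-12)

  fx <- read.csv(system.file("extdata", "corr_fixture.csv",
                             package = "funnelbench"))
  got <- metric_correlation(fx$x, fx$y)
  expect_equal(got$coefficient, pearson_oracle(fx$x, fx$y),
               tolerance = 1e-12)
  expect_equal(got$r_squared, got$coefficient^2, tolerance = 1e-15)
  got_s <- metric_correlation(fx$x, fx$y, method = "spearman")
  expect_equal(got_s$coefficient, spearman_oracle(fx$x, fx$y),
               tolerance = 1e-12)
})

test_that("correlation is symmetric and scale-invariant up to sign", {
  set.seed(7)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  r <- metric_correlation(x, y)$coefficient
  expect_equal(metric_correlation(y, x)$coefficient, r, tolerance = 1e-12)
  expect_equal(metric_correlation(3 * x + 2, y)$coefficient, r,
               tolerance = 1e-12)
  expect_equal(metric_correlation(-3 * x + 2, y)$coefficient, -r,
               tolerance = 1e-12)
})

test_that("correlation rejects degenerate input", {
  expect_error(metric_correlation(1:5, 1:4), "length")
  expect_error(metric_correlation(1:2, 1:2), "at least 3")
  expect_error(metric_correlation(rep(1, 5), 1:5), "constant")
})

test_that("select_lowest_scoring returns the n best-energy models deterministically", {
  ens <- ensemble(energy = c(5, 1, 3), similarity = c(1, 2, 3),
                  tag = c("a", "b", "c"))
  top2 <- select_lowest_scoring(ens, 2)
  expect_equal(sort(top2$models$energy), c(1, 3))

  # n = size is the identity up to energy ordering
  all3 <- select_lowest_scoring(ens, 3)
  expect_setequal(all3$models$tag, ens$models$tag)

  # ties broken by tag lexicographically
  tied <- ensemble(energy = c(1, 1, 1), similarity = 1:3,
                   tag = c("zz", "aa", "mm"))
  expect_equal(select_lowest_scoring(tied, 2)$models$tag, c("aa", "mm"))

  # full-sort oracle prefix on a random 100-model ensemble
  set.seed(12)
  big <- make_random_ensemble(n = 100)
  want <- big$models[order(big$models$energy, big$models$tag), ][1:10, ]
  got <- select_lowest_scoring(big, 10)$models
  expect_equal(got$tag, want$tag)

  expect_error(select_lowest_scoring(ens, 0), "between 1")
  expect_error(select_lowest_scoring(ens, 4), "between 1")
})

test_that("sequence recovery counts identical positions", {
  expect_identical(sequence_recovery("ACDEFG", "ACDEFG"), 1)
  expect_identical(sequence_recovery("AAAA", "CCCC"), 0)
  expect_equal(sequence_recovery("ACDEFG", "ACDEYG"), 5 / 6)
  expect_error(sequence_recovery("ACD", "AC"), "same length")
})

test_that("metric orientation registry distinguishes rmsd-like metrics", {
  expect_identical(metric_orientation("pnear"), "higher")
  expect_identical(metric_orientation("sequence_recovery"), "higher")
  expect_identical(metric_orientation("I_rmsd"), "lower")
  expect_identical(metric_orientation("loop_RMSD"), "lower")
})
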