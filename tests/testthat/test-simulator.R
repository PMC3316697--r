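cen <- aquifer_census(18, 16, 11)
rep2 <- function(p, n) colonization_scenario("repeated", c(p, 1), pool_size = n)
single1 <- function(p, q) colonization_scenario("single", p, diversification_prob = q)

test_that("single-aquifer simulation honours the trivial regimes", {
  set.seed(1)
  out <- simulate_aquifer(2, rep2(1, 10))
  expect_identical(out$classification, "none")
  expect_identical(sort(out$occupants$niche), 1:2)
  expect_true(all(out$occupants$event == 1L))

  out <- simulate_aquifer(3, single1(1, 1))
  expect_identical(out$classification, "none")
  expect_identical(nrow(out$occupants), 3L)
  expect_true(all(out$occupants$origin == "colonization"))

  # q = 0 never fills in situ
  out <- simulate_aquifer(3, single1(0.5, 0))
  expect_true(all(out$occupants$origin == "colonization"))
})

test_that("simulated frequencies match the closed forms", {
  reps <- 20000
  for (case in list(list(niches = 2, scen = rep2(0.5, 10)),
                    list(niches = 3, scen = rep2(0.3, 5)),
                    list(niches = 3, scen = single1(0.78, 1)),
                    list(niches = 3, scen = single1(0.5, 0.6)))) {
    s <- case$scen
    if (s$model == "repeated") {
      exp_pair <- pair_probability_repeated(case$niches, s$event_probs, s$pool_size)
      exp_trip <- if (case$niches == 3)
        triplet_probability_repeated(s$event_probs, s$pool_size) else 0
    } else {
      exp_pair <- pair_probability_single(case$niches, s$event_probs[1],
                                          s$diversification_prob)
      exp_trip <- if (case$niches == 3)
        triplet_probability_single(s$event_probs[1], s$diversification_prob) else 0
    }
    freq <- mc_aquifer_freq(case$niches, s, reps, seed = 99)
    se_pair <- sqrt(exp_pair * (1 - exp_pair) / reps)
    se_trip <- sqrt(exp_trip * (1 - exp_trip) / reps)
    expect_lt(abs(freq["pair"] - exp_pair), 3 * se_pair + 1e-12)
    expect_lt(abs(freq["triplet"] - exp_trip), 3 * se_trip + 1e-12)
  }
})

test_that("region simulation is deterministic and order-independent", {
  t1 <- simulate_region(cen, rep2(0.5, 5), replicates = 200, seed = 7)
  t2 <- simulate_region(cen, rep2(0.5, 5), replicates = 200, seed = 7)
  expect_identical(t1, t2)
  # the first 100 replicates do not depend on how many more were run
  t3 <- simulate_region(cen, rep2(0.5, 5), replicates = 100, seed = 7)
  expect_equal(t3$pair_aquifers, t1$pair_aquifers[1:100])
  expect_equal(t3$triplet_aquifers, t1$triplet_aquifers[1:100])
  # a different seed decorrelates
  t4 <- simulate_region(cen, rep2(0.5, 5), replicates = 200, seed = 8)
  expect_false(identical(t1$pair_aquifers, t4$pair_aquifers))
})

test_that("region means agree with the closed-form expectation", {
  pred <- expected_sister_fractions(cen, single1(0.784, 1))
  tall <- simulate_region(cen, single1(0.784, 1), replicates = 5000, seed = 3)
  se <- sd(tall$sister_fraction) / sqrt(nrow(tall))
  expect_lt(abs(mean(tall$sister_fraction) - pred$expected_sister_fraction), 3 * se)

  # huge pool: cross-event species matches vanish
  tall <- simulate_region(cen, rep2(0.5, 1e6), replicates = 500, seed = 3)
  expect_lt(mean(tall$sister_fraction), 1e-3)
})

test_that("percentile bands follow the stated estimator", {
  tall <- simulate_region(cen, rep2(0.5, 5), replicates = 500, seed = 11)
  band <- percentile_band(tall)
  expect_equal(band$lower,
               unname(quantile(tall$sister_fraction, 0.05, type = 7)))
  expect_equal(band$upper,
               unname(quantile(tall$sister_fraction, 0.95, type = 7)))
  expect_lte(band$lower, band$mean)
  expect_lte(band$mean, band$upper)
  expect_identical(band$seed, 11)

  # two-event repeated model never yields triplets
  band_t <- percentile_band(tall, statistic = "triplet_fraction")
  expect_identical(c(band_t$lower, band_t$upper), c(0, 0))

  # constant statistic collapses the band
  const <- tall
  const$sister_fraction <- rep(0.2, nrow(const))
  bc <- percentile_band(const)
  expect_equal(c(bc$lower, bc$upper), c(0.2, 0.2))
})

test_that("pool-size scan finds where the observation escapes the band", {
  obs0 <- sister_tally(0, 0, 45)
  res <- min_pool_size_outside_band(cen, obs0, n_range = 3:5,
                                    replicates = 300, seed = 2)
  expect_true(is.na(res))
  expect_identical(nrow(attr(res, "scan")), 3L)
  expect_error(min_pool_size_outside_band(cen, obs0, n_range = 2:5,
                                          replicates = 10, seed = 1),
               "infeasible")
  # a large pool makes the observed 11/45 clearly exceed the band
  obs <- sister_tally(9, 2, 45)
  res <- min_pool_size_outside_band(cen, obs, n_range = 30, replicates = 500,
                                    seed = 2)
  expect_identical(as.integer(res), 30L)
})
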