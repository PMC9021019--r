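test_that("steady-state contact probability follows the rate ratio", {
  mk <- function(kc, kf) mechanistic_params(kc, kf, 1, 1, 1, 0.1, 1, 1, 10)
  expect_equal(steady_contact_probability(mk(2, 2)), 0.5)
  expect_equal(steady_contact_probability(mk(1, 0)), 1)
  expect_equal(steady_contact_probability(mk(1, 3)), 0.25)
  expect_error(steady_contact_probability(mk(0, 0)), "positive")
})

test_that("Gillespie trajectories are reproducible and respect the rules", {
  mp <- mechanistic_params(4, 4, 3, 1, 3, 0.2, 2, 1.5, 20)
  s1 <- gillespie_simulate(mp, t_end = 50, seed = 9)
  s2 <- gillespie_simulate(mp, t_end = 50, seed = 9)
  expect_identical(s1$trajectory, s2$trajectory)
  tr <- s1$trajectory
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(tr$step >= 0 & tr$step <= mp$n))
  # forward steps only occur while in contact
  fwd <- which(diff(tr$step) == 1)
  expect_true(all(tr$contact[fwd] == 1))
  # no transcription without initiation
  mp0 <- mechanistic_params(4, 4, 3, 1, 3, 0.2, 2, 1.5, mu = 0)
  expect_true(all(sample_mechanistic(mp0, 200, seed = 2) == 0))
  # trajectories round-trip through TSV with their seed
  f <- tempfile(fileext = ".tsv")
  write_trajectory(s1, f)
  tr2 <- read_trajectory(f)
  expect_equal(attr(tr2, "seed"), 9L)
  expect_equal(nrow(tr2), nrow(tr))
  expect_equal(tr2$m, tr$m)
})

test_that("mechanistic chain with equal on rates collapses to the telegraph model", {
  mp <- mechanistic_params(3, 5, 2, 1, 4, kon_basal = 0.8, kon_enh = 0.8,
                           k_off = 1.2, mu = 15)
  tp <- telegraph_params(0.8, 1.2, 15)
  expect_lt(tv_distance(as.numeric(mechanistic_pmf(mp)),
                        as.numeric(telegraph_pmf(tp))), 1e-8)
  s <- sample_mechanistic(mp, 2e5, seed = 21)
  p <- telegraph_pmf(tp)
  emp <- tabulate(s + 1, nbins = length(p)) / length(s)
  expect_lt(tv_distance(emp, as.numeric(p)), 0.01)
})

test_that("unreachable or absorbing step layers reduce to basal/enhanced telegraph", {
  # k_forward = 0: enhanced regime unreachable
  mp0 <- mechanistic_params(3, 3, 0, 1, 3, 0.3, 3, 1, 12)
  expect_lt(tv_distance(as.numeric(mechanistic_pmf(mp0)),
                        as.numeric(telegraph_pmf(telegraph_params(0.3, 1, 12)))),
            1e-10)
  s <- sample_mechanistic(mp0, 5e4, seed = 5)
  p <- telegraph_pmf(telegraph_params(0.3, 1, 12))
  emp <- tabulate(s + 1, nbins = length(p)) / length(s)
  expect_lt(tv_distance(emp, as.numeric(p)), 0.02)
  # k_back = 0: completed steps never revert, enhanced regime absorbs
  mp1 <- mechanistic_params(3, 3, 5, 0, 1, 0.3, 3, 1, 12)
  expect_lt(tv_distance(as.numeric(mechanistic_pmf(mp1)),
                        as.numeric(telegraph_pmf(telegraph_params(3, 1, 12)))),
            1e-10)
})

test_that("full mechanistic pmf agrees with Gillespie sampling", {
  mp <- mechanistic_params(4, 4, 3, 1, 3, 0.2, 2, 1.5, 20)
  p <- mechanistic_pmf(mp)
  expect_lt(abs(sum(p) - 1), 1e-10)
  s <- sample_mechanistic(mp, 2e5, seed = 11)
  emp <- tabulate(s + 1, nbins = length(p)) / length(s)
  expect_lt(tv_distance(emp, as.numeric(p)), 0.01)
})

test_that("apparent on rate has the right limits and midpoint", {
  expect_equal(apparent_kon(0, beta = 5, n = 3, 0.1, 2), 0.1)
  expect_equal(apparent_kon(1, beta = 1e8, n = 3, 0.1, 2), 2,
               tolerance = 1e-6)
  # n = 1 at r = 1: two equal-rate states, occupancy 1/2
  expect_equal(apparent_kon(0.5, beta = 2, n = 1, 0.1, 2),
               0.1 + (2 - 0.1) / 2)
  # beta = Inf (k_back = 0) still well-defined
  expect_equal(apparent_kon(c(0, 0.5), beta = Inf, n = 2, 0.1, 2), c(0.1, 2))
})

test_that("apparent on rate is sigmoidal for n >= 2 and beta > 1", {
  p <- seq(0, 1, 1e-3)
  for (n in c(2, 5)) {
    k <- apparent_kon(p, beta = 7, n = n, kon_basal = 0.15, kon_enh = 2)
    d2 <- diff(diff(k))
    expect_gt(d2[2], 0)                      # convex at small p
    sign_change <- which(diff(sign(d2)) != 0)
    expect_gt(length(sign_change), 0)        # inflection inside (0, 1)
    expect_true(p[sign_change[1]] > 0 && p[sign_change[1]] < 1)
  }
})

test_that("reduction to the apparent two-state model improves as timescales separate", {
  # degenerate case: identical on rates, reduction is exact
  mp_eq <- mechanistic_params(3, 3, 2, 1, 2, 0.5, 0.5, 1, 10)
  expect_lt(reduction_error(mp_eq, 1), 1e-8)
  set.seed(1)
  mp <- random_mech()
  tv <- sapply(c(1, 1/2, 1/4, 1/8), function(e) reduction_error(mp, e))
  expect_true(all(diff(tv) < 0.002))
  expect_lt(tv[4], 0.02)
})

test_that("contacts decouple from transcription in the separated regime", {
  set.seed(3)
  for (i in 1:3) {
    mp <- scale_separation(random_mech(), 1/8)
    expect_lt(abs(contact_activity_correlation(mp)), 0.1)
  }
})
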