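test_that("Hill response hits its limits, midpoint and step-function limit", {
  hp <- hill_params(kon0 = 0.2, kon1 = 3, c = 0.3, h = 2.8)
  expect_equal(hill_response(0, hp), 0.2)
  expect_equal(hill_response(hp$c, hp), 0.2 + (3 - 0.2) / 2)
  hp_steep <- hill_params(0.2, 3, c = 0.3, h = 200)
  expect_lt(hill_response(0.25, hp_steep), 0.2 + 1e-6)
  expect_gt(hill_response(0.35, hp_steep), 3 - 1e-4)
  # monotone in p and in kon1
  p <- seq(0, 1, 0.01)
  expect_true(all(diff(hill_response(p, hp)) >= 0))
  hp_hi <- hill_params(0.2, 4, 0.3, 2.8)
  expect_true(all(hill_response(p, hp_hi) >= hill_response(p, hp)))
  expect_error(hill_response(-0.1, hp), "\\[0, 1\\]")
  expect_error(hill_params(1, 2, c = 0, h = 2), "positive")
})

test_that("analytic mean matches the closed form and its limits", {
  expect_equal(telegraph_mean(telegraph_params(1, 1, 10)), 5)
  expect_equal(telegraph_mean(telegraph_params(2, 0, 12)), 12)
  expect_equal(telegraph_mean(telegraph_params(1, 1, 0)), 0)
  expect_error(telegraph_mean(telegraph_params(0, 0, 1)), "degenerate")
})

test_that("stationary pmf is normalized and moment-consistent over a sweep", {
  set.seed(11)
  for (i in 1:100) {
    tp <- random_tp()
    p <- telegraph_pmf(tp, tail_mass = 1e-8)
    expect_lt(abs(sum(p) - 1), 1e-10)
    m <- pmf_moments(p)[["mean"]]
    expect_lt(abs(m - telegraph_mean(tp)) / telegraph_mean(tp), 1e-6)
  }
})

test_that("pmf agrees with the analytic variance and the beta-Poisson form", {
  set.seed(5)
  for (i in 1:5) {
    tp <- random_tp()
    p <- telegraph_pmf(tp, tail_mass = 1e-6)
    expect_lt(abs(pmf_moments(p)[["var"]] - telegraph_variance(tp)) /
                telegraph_variance(tp), 1e-5)
    bp <- beta_poisson_pmf(tp, length(p) - 1)
    expect_lt(max(abs(as.numeric(p) - bp)), 1e-5)
  }
})

test_that("always-ON limit is Poisson and approach to it is monotone", {
  tp <- telegraph_params(3, 0, 10)
  p <- telegraph_pmf(tp)
  pois <- dpois(seq_along(p) - 1, 10)
  expect_lt(max(abs(as.numeric(p) - pois / sum(pois))), 1e-8)
  # k_on/k_off -> infinity with mu/delta fixed: TV to Poisson(mu) shrinks
  tv <- sapply(c(1, 2, 4, 8, 16), function(f) {
    pp <- telegraph_pmf(telegraph_params(2 * f, 1 * f, 10))
    pois <- dpois(seq_along(pp) - 1, 10 * 2 / 3)
    tv_distance(as.numeric(pp), pois / sum(pois))
  })
  expect_true(all(diff(tv) < 0))
})

test_that("pmf matches a long Gillespie run of the same model", {
  tp <- tp_generic()
  p <- telegraph_pmf(tp)
  s <- sample_telegraph(tp, n_samples = 2e5, seed = 101)
  emp <- tabulate(s + 1, nbins = length(p)) / length(s)
  expect_lt(tv_distance(emp, as.numeric(p)), 0.01)
})

test_that("CV matches the Poisson limit, the analytic form and simulation", {
  tp_on <- telegraph_params(1, 0, 25)
  expect_equal(telegraph_cv(tp_on), 1 / sqrt(25), tolerance = 1e-6)
  tp <- tp_generic()
  expect_equal(telegraph_cv(tp), telegraph_cv(tp, "analytic"),
               tolerance = 1e-6)
  s <- sample_telegraph(tp, 1e5, seed = 33)
  expect_equal(telegraph_cv(tp), sd(s) / mean(s), tolerance = 0.02)
  expect_error(telegraph_cv(telegraph_params(1, 1, 0)), "undefined")
})

test_that("CV is non-increasing in the on rate at fixed k_off, mu", {
  cvs <- sapply(c(0.2, 0.5, 1, 2, 5, 10), function(kon)
    telegraph_cv(telegraph_params(kon, 2, 20)))
  expect_true(all(diff(cvs) <= 1e-8))
})

test_that("modulation variants target the right rate", {
  hp <- hill_params(0.1, 2, 0.3, 3)
  base <- telegraph_params(0.7, 5, 50)
  v_on <- apply_variant(0, hp, base, "on_rate")
  expect_equal(v_on$k_on, 0.1)
  expect_equal(v_on$k_off, 5)
  expect_equal(v_on$mu, 50)
  # saturated Hill drives the initiation rate to kon1
  hp_sat <- hill_params(0.1, 2, c = 0.001, h = 2)
  v_mu <- apply_variant(1, hp_sat, base, "initiation_rate")
  expect_equal(v_mu$mu, hill_response(1, hp_sat))
  expect_lt(abs(v_mu$mu - 2), 0.01)
  # off-rate variant decreases with p
  v_off0 <- apply_variant(0, hp, base, "off_rate")
  v_off1 <- apply_variant(1, hp, base, "off_rate")
  expect_gt(v_off0$k_off, v_off1$k_off)
  expect_equal(v_off0$k_off, hp$kon1)
})

test_that("only on-rate modulation reproduces the falling CV profile", {
  # responses chosen so all variants traverse comparable mean ranges
  p <- seq(0.05, 1, length.out = 6)
  base <- telegraph_params(0.5, 8, 250)
  prof_on <- variant_profile(p, hill_params(0.15, 2, 0.25, 2.8), base,
                             "on_rate")
  prof_mu <- variant_profile(p, hill_params(10, 330, 0.25, 2.8),
                             telegraph_params(0.5, 8, 10),
                             "initiation_rate")
  expect_true(all(diff(prof_on$cv) < 0))
  expect_gt(prof_on$cv[1] / prof_on$cv[6], 1.5)
  # initiation-rate modulation at matched means: CV falls far less, and the
  # Fano factor rises steeply with p (burst size grows), unlike on-rate
  # modulation where the Fano factor falls
  expect_gt(prof_mu$fano[6], prof_mu$fano[1])
  expect_lt(prof_on$fano[6], prof_on$fano[1])
})

test_that("pmfs and parameters round-trip through plain-text files", {
  tp <- tp_generic()
  f <- tempfile(fileext = ".tsv")
  write_pmf(telegraph_pmf(tp), f)
  expect_equal(as.numeric(read_pmf(f)), as.numeric(telegraph_pmf(tp)),
               tolerance = 1e-12)
  fp <- tempfile(fileext = ".cfg")
  write_params(tp, fp)
  tp2 <- read_params(fp)
  expect_s3_class(tp2, "telegraph_params")
  expect_equal(tp2$mu, tp$mu)
  hp <- hill_params(0.1, 2, 0.3, 2.8)
  write_params(hp, fp)
  expect_equal(read_params(fp)$h, 2.8)
})
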