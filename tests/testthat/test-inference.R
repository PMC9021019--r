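test_that("composite log-likelihood matches a by-hand toy computation", {
  par <- list(kon0 = 0.5, kon1 = 2, k_off = 1, mu = 10, c = 0.3, h = 2)
  screen <- screen_dataset(data.frame(
    id = c("a", "b"), p_c = c(0, 1), mean = c(3, 6.2),
    sd = c(0.6, 0.8), n_rep = c(4L, 4L)))
  fish <- fish_dataset("f1", 0.5, cells = list(c(0L, 1L, 1L, 2L, 3L)))
  got <- composite_loglik(par, screen, fish, "phenomenological",
                          mean_error = "per_line")
  # independent arithmetic: Hill rates, telegraph means, Gaussian densities
  kon <- function(p) 0.5 + 1.5 * p^2 / (0.3^2 + p^2)
  mu_model <- function(p) 10 * kon(p) / (kon(p) + 1)
  ll_mean <- dnorm(3, mu_model(0), 0.6 / 2, log = TRUE) +
    dnorm(6.2, mu_model(1), 0.8 / 2, log = TRUE)
  pmf <- telegraph_pmf(telegraph_params(kon(0.5), 1, 10))
  ll_fish <- 1 * log(pmf[1]) + 2 * log(pmf[2]) + 1 * log(pmf[3]) +
    1 * log(pmf[4])
  expect_equal(as.numeric(got), ll_mean + ll_fish, tolerance = 1e-10)
  expect_equal(unname(attr(got, "components")),
               c(ll_mean, ll_fish), tolerance = 1e-10)
  # no FISH data: the Gaussian term alone remains
  got2 <- composite_loglik(par, screen, NULL, "phenomenological",
                           mean_error = "per_line")
  expect_equal(as.numeric(got2), ll_mean, tolerance = 1e-10)
})

test_that("the likelihood is maximal at a perfect fit", {
  par <- list(kon0 = 0.3, kon1 = 1.5, k_off = 2, mu = 30, c = 0.3, h = 2)
  p_lines <- c(0.1, 0.6)
  mu_model <- epcomm:::.model_mean(par, p_lines, "phenomenological")
  screen <- screen_dataset(data.frame(
    id = c("a", "b"), p_c = p_lines, mean = mu_model, sd = 0.2,
    n_rep = 3L))
  pmf <- telegraph_pmf(telegraph_params(
    epcomm:::.model_kon(par, 0.4, "phenomenological"), par$k_off, par$mu))
  fish <- fish_dataset("f", 0.4, hist = list(as.numeric(pmf) * 1000))
  ll_star <- composite_loglik(par, screen, fish, mean_error = "per_line")
  # analytic maximum of the distribution term: n_m * log(n_m / N)
  h <- as.numeric(pmf) * 1000
  nz <- h > 0
  ll_fish_max <- sum(h[nz] * log(h[nz] / sum(h)))
  expect_equal(unname(attr(ll_star, "components")["fish"]), ll_fish_max,
               tolerance = 1e-10)
  # perturbations can only lower the likelihood
  for (dp in list(c("mu", 1.1), c("h", 1.2), c("k_off", 0.9))) {
    par2 <- par
    par2[[dp[1]]] <- par[[dp[1]]] * as.numeric(dp[2])
    expect_lt(as.numeric(composite_loglik(par2, screen, fish,
                                          mean_error = "per_line")),
              as.numeric(ll_star))
  }
})

test_that("noiseless synthetic data are recovered within one percent", {
  ns <- noiseless_study(cells = 3000)
  fit <- fit_phenomenological(ns$screen, ns$fish, n_starts = 12, seed = 1,
                              se_floor = 0.02)
  expect_true(fit$convergence)
  for (nm in c("kon0", "kon1", "k_off", "mu", "c", "h")) {
    expect_lt(abs(fit$par[[nm]] - ns$truth[[nm]]) / ns$truth[[nm]], 0.01,
              label = paste("relative error of", nm))
  }
})

test_that("a flat response raises the h-unidentifiable flag", {
  truth <- list(kon0 = 0.8, kon1 = 0.8, k_off = 10, mu = 360, c = 0.25,
                h = 2.8)
  ns <- noiseless_study(truth = truth, n_lines = 30,
                        fish_p = c(0.1, 0.9), cells = 200)
  fit <- fit_phenomenological(ns$screen, ns$fish, n_starts = 8, seed = 2)
  expect_true(fit$h_unidentifiable)
})

test_that("freeing parameters never lowers the maximized likelihood", {
  cfg <- study_config(seed = 31, model = "apparent", n_lines = 40L,
                      cells_per_line = 120L, n_fish = 4L)
  b <- gen_full_study(cfg)
  ref <- fit_apparent(b$screen, b$fish, n_grid = 5, n_starts = 8,
                      seed = 31)
  v_beta <- fit_apparent_variant(b$screen, b$fish, ref, "beta_only",
                                 seed = 31)
  v_both <- fit_apparent_variant(b$screen, b$fish, ref, "both", seed = 31)
  expect_gte(v_both$loglik, v_beta$loglik - 1e-6)
  expect_gte(ref$loglik, v_both$loglik - 1e-6)
  # likelihood-ratio mechanics: unchanged data keep small variants viable
  cmp <- lrt_compare(ref, list(beta_only = v_beta, both = v_both))
  expect_true(all(cmp$statistic >= 0))
  expect_equal(cmp$df, c(4, 3))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})

test_that("a profile interval matches the quadratic (Wald) approximation", {
  cfg <- study_config(seed = 41, model = "apparent", n_lines = 60L,
                      cells_per_line = 150L, n_fish = 4L)
  b <- gen_full_study(cfg)
  ref <- fit_apparent(b$screen, b$fish, n_grid = 5, n_starts = 8, seed = 41)
  vfit <- fit_apparent_variant(b$screen, b$fish, ref, "kon_enh_only",
                               seed = 41)
  ci <- profile_ci(vfit, "kon_enh")
  # one-dimensional likelihood: numeric curvature gives the Wald width
  gain_hat <- vfit$par$kon_enh - vfit$par$kon_basal
  eps <- 1e-3 * gain_hat
  ll_at <- function(g) {
    par <- vfit$par; par$kon_enh <- par$kon_basal + g
    as.numeric(composite_loglik(par, b$screen, b$fish, "apparent"))
  }
  d2 <- (ll_at(gain_hat + eps) - 2 * ll_at(gain_hat) +
           ll_at(gain_hat - eps)) / eps^2
  se <- 1 / sqrt(-d2)
  expect_equal(ci$upper - ci$lower, 2 * 1.96 * se, tolerance = 0.15)
  expect_gt(vfit$par$kon_enh, ci$lower)
  expect_lt(vfit$par$kon_enh, ci$upper)
})

test_that("weak-enhancer predictions scale the response as expected", {
  cfg <- study_config(seed = 51, model = "apparent", n_lines = 40L,
                      cells_per_line = 100L, n_fish = 3L)
  b <- gen_full_study(cfg)
  fit <- fit_apparent(b$screen, b$fish, n_grid = 5, n_starts = 8, seed = 51)
  same <- predict_weak_enhancer(fit, "scale_kon_enh", factor = 1)
  expect_equal(same$mean,
               epcomm:::.model_mean(fit$par, same$p, "apparent"))
  expect_error(predict_weak_enhancer(fit, "scale_beta", factor = 0),
               "positive")
  # halving kon_enh with a negligible basal rate scales the whole
  # basal-subtracted response by a common factor
  par0 <- fit$par; par0$kon_basal <- 1e-4
  fit0 <- fit; fit0$par <- par0
  full <- predict_weak_enhancer(fit0, "scale_kon_enh", 1)
  half <- predict_weak_enhancer(fit0, "scale_kon_enh", 0.5)
  floor0 <- epcomm:::.model_mean(
    within(par0, kon_enh <- kon_basal), 0, "apparent")
  sel <- full$p > 0.2
  ratio <- (half$mean[sel] - floor0) / (full$mean[sel] - floor0)
  # the ratio varies only through promoter-occupancy saturation
  expect_lt(diff(range(ratio)), 0.06)
  # halving beta shifts the half-maximum to larger contact probabilities
  full_b <- predict_weak_enhancer(fit, "scale_beta", 1,
                                  p_grid = seq(0, 1, 1e-3))
  half_b <- predict_weak_enhancer(fit, "scale_beta", 0.5,
                                  p_grid = seq(0, 1, 1e-3))
  half_point <- function(d) {
    lvl <- d$mean[1] + (max(d$mean) - d$mean[1]) / 2
    d$p[which(d$mean >= lvl)[1]]
  }
  expect_gt(half_point(half_b), half_point(full_b))
})
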