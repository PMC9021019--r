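#' Per-line screen dataset
#'
#' Validates and classes the per-cell-line table of a mobilization screen:
#' one row per cell line with its enhancer insertion, the contact
#' probability between promoter and insertion site, and the replicate
#' summary of mean expression (in mRNA-per-cell units after calibration).
#'
#' @param x data.frame with columns `id`, `p_c` (contact probability in
#'   \[0, 1\]), `mean` (mean mRNA per cell), and optionally `coord`
#'   (insertion coordinate, bp), `orientation` (`"+"`/`"-"`), `sd`
#'   (replicate standard deviation) and `n_rep` (replicate count,
#'   default 1).
#' @return The validated data.frame with class `screen_dataset`.
#' @export
screen_dataset <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("id", "p_c", "mean")
  if (!all(req %in% names(x)))
    stop("screen dataset needs columns: ", paste(req, collapse = ", "))
  if (any(x$p_c < 0 | x$p_c > 1)) stop("p_c must lie in [0, 1]")
  if (is.null(x$sd)) x$sd <- 0
  if (is.null(x$n_rep)) x$n_rep <- 1L
  if (any(x$n_rep < 1)) stop("replicate count must be >= 1")
  class(x) <- unique(c("screen_dataset", class(x)))
  x
}

#' Per-line smFISH count dataset
#'
#' Per-cell mRNA counts measured by single-molecule RNA FISH in a subset of
#' cell lines, stored as per-line histograms (number of cells observed at
#' each mRNA count, starting at count 0).
#'
#' @param id character vector of line ids.
#' @param p_c contact probability of each line.
#' @param cells list of integer vectors of per-cell mRNA counts (one vector
#'   per line); alternatively supply `hist` directly.
#' @param hist list of histogram vectors (`hist[[i]][m + 1]` = number of
#'   cells of line `i` with `m` transcripts).
#' @return An object of class `fish_dataset` with fields `id`, `p_c`,
#'   `hist`, `n_cells`.
#' @export
fish_dataset <- function(id, p_c, cells = NULL, hist = NULL) {
  stopifnot(length(id) == length(p_c))
  if (is.null(hist)) {
    if (is.null(cells)) stop("supply either cells or hist")
    stopifnot(length(cells) == length(id))
    hist <- lapply(cells, function(x) {
      if (length(x) < 1) stop("every FISH line needs at least one cell")
      if (any(x < 0 | x != floor(x))) stop("counts must be non-negative integers")
      tabulate(x + 1L, nbins = max(x) + 1L)
    })
  }
  stopifnot(length(hist) == length(id))
  if (any(p_c < 0 | p_c > 1)) stop("p_c must lie in [0, 1]")
  structure(list(id = as.character(id), p_c = as.numeric(p_c), hist = hist,
                 n_cells = vapply(hist, sum, numeric(1))),
            class = "fish_dataset")
}

#' Read smFISH counts from a long-format table
#'
#' @param df data.frame with columns `line`, `cell`, `count`.
#' @param p_c named vector of contact probabilities (names = line ids).
#' @return A [fish_dataset()].
#' @export
fish_from_table <- function(df, p_c) {
  stopifnot(all(c("line", "count") %in% names(df)))
  ids <- unique(as.character(df$line))
  cells <- lapply(ids, function(l) as.integer(df$count[df$line == l]))
  fish_dataset(ids, unname(p_c[ids]), cells = cells)
}

# model-specific on rate at contact probability p
.model_kon <- function(par, p, model) {
  if (model == "phenomenological")
    par$kon0 + (par$kon1 - par$kon0) * p^par$h / (par$c^par$h + p^par$h)
  else
    apparent_kon(p, par$beta, par$n, par$kon_basal, par$kon_enh)
}

.model_mean <- function(par, p, model) {
  kon <- .model_kon(par, p, model)
  delta <- if (is.null(par$delta)) 1 else par$delta
  par$mu * kon / (delta * (kon + par$k_off))
}

#' Composite log-likelihood of means and smFISH distributions
#'
#' Joint log-likelihood used for simultaneous fitting: (a) a term for each
#' screen line's observed mean expression given the model mean, under the
#' replicate error model selected by `mean_error`, plus (b) a multinomial
#' term for each smFISH histogram under the model's stationary mRNA pmf
#' (up to the data-dependent multinomial coefficient, which is constant in
#' the parameters). The two components can be reweighted via `weights`.
#'
#' @param par named list of model parameters. Phenomenological model:
#'   `kon0`, `kon1`, `k_off`, `mu`, `c`, `h`. Apparent model: `kon_basal`,
#'   `kon_enh`, `k_off`, `mu`, `beta`, `n`. `delta` defaults to 1.
#' @param screen a [screen_dataset()] (may have zero rows).
#' @param fish a [fish_dataset()] or `NULL`.
#' @param model `"phenomenological"` or `"apparent"`.
#' @param weights length-2 weights for the mean and distribution terms.
#' @param tail_mass pmf truncation tolerance.
#' @param se_floor lower bound on the per-line standard error.
#' @param mean_error error model for the observed means. `"lognormal"`
#'   (default) treats each observed mean as log-normally distributed
#'   around the model mean with a single relative replicate error
#'   estimated across all lines -- the natural model for multiplicative
#'   (scale-like) measurement noise. `"pooled"` is its Gaussian
#'   approximation, `se_i = rel * mu_i(theta) / sqrt(n_rep)`.
#'   `"per_line"` uses each line's own `sd / sqrt(n_rep)`, which is noisy
#'   (and overconfident) when `n_rep` is small. Models needing a pooled
#'   error fall back to `"per_line"` when no line has positive mean and
#'   sd.
#' @return Log-likelihood (scalar) with attribute `components` holding the
#'   separate mean and distribution terms.
#' @export
composite_loglik <- function(par, screen, fish = NULL,
                             model = c("phenomenological", "apparent"),
                             weights = c(1, 1), tail_mass = 1e-6,
                             se_floor = 1e-3,
                             mean_error = c("lognormal", "pooled",
                                            "per_line")) {
  model <- match.arg(model)
  mean_error <- match.arg(mean_error)
  delta <- if (is.null(par$delta)) 1 else par$delta
  ll_mean <- 0
  if (!is.null(screen) && nrow(screen) > 0) {
    mu_hat <- .model_mean(par, screen$p_c, model)
    rel <- .pooled_rel(screen)
    if (mean_error == "lognormal" && !is.null(rel) &&
        all(screen$mean > 0)) {
      if (any(mu_hat <= 0)) {
        ll_mean <- -Inf
      } else {
        # mean of n_rep log-normal replicates, approximated log-normally:
        # E = mu, cv = rel / sqrt(n_rep)
        s2 <- log(1 + rel^2 / screen$n_rep)
        ll_mean <- sum(stats::dnorm(log(screen$mean),
                                    log(mu_hat) - s2 / 2, sqrt(s2),
                                    log = TRUE))
      }
    } else {
      se <- .screen_se(screen, se_floor, mean_error, mu_hat)
      ll_mean <- sum(stats::dnorm(screen$mean, mu_hat, se, log = TRUE))
    }
  }
  ll_fish <- 0
  if (!is.null(fish) && length(fish$id) > 0) {
    for (i in seq_along(fish$id)) {
      h <- fish$hist[[i]]
      kon <- .model_kon(par, fish$p_c[i], model)
      pmf <- .telegraph_pmf_core(kon, par$k_off, par$mu, delta, tail_mass,
                                 min_length = length(h))
      nz <- which(h > 0)
      ll_fish <- ll_fish + sum(h[nz] * log(pmax(pmf[nz], 1e-300)))
    }
  }
  ll <- weights[1] * ll_mean + weights[2] * ll_fish
  attr(ll, "components") <- c(mean = ll_mean, fish = ll_fish)
  ll
}

# pooled relative replicate error across lines (NULL when not estimable)
.pooled_rel <- function(screen) {
  ok <- screen$mean > 0 & screen$sd > 0
  if (!any(ok)) return(NULL)
  sqrt(mean((screen$sd[ok] / screen$mean[ok])^2))
}

# per-line standard errors of the observed means. The pooled model is a
# relative-error likelihood: one replicate CV estimated across all lines,
# applied to the MODEL mean (so weights are not correlated with the
# realized noise, which would bias the fit).
.screen_se <- function(screen, se_floor, mean_error, model_mean = NULL) {
  if (mean_error != "per_line") {
    rel <- .pooled_rel(screen)
    if (!is.null(rel)) {
      scale <- if (is.null(model_mean)) abs(screen$mean) else abs(model_mean)
      return(pmax(rel * scale / sqrt(screen$n_rep), se_floor))
    }
  }
  pmax(screen$sd / sqrt(screen$n_rep), se_floor)
}

# ---- internal optimization machinery ------------------------------------

# box-logistic transform on the log scale keeps all parameters positive
# and inside their bounds while the optimizer works unconstrained
.box_fwd <- function(x, lo, hi) {
  x <- pmin(pmax(x, lo * 1.000001), hi * 0.999999)
  u <- (log(x) - log(lo)) / (log(hi) - log(lo))
  log(u / (1 - u))
}
.box_inv <- function(t, lo, hi) {
  u <- 1 / (1 + exp(-t))
  exp(log(lo) + u * (log(hi) - log(lo)))
}

# free-parameter tables; the maximum on rate is parameterized as
# kon0 + gain (gain = kon1 - kon0 >= 0) so the order constraint holds
.par_table <- function(model) {
  if (model == "phenomenological")
    data.frame(name = c("kon0", "gain", "k_off", "mu", "c", "h"),
               lo = c(1e-3, 1e-3, 1e-3, 1e-2, 0.01, 0.5),
               hi = c(1e3, 1e3, 1e3, 1e3, 1, 10))
  else
    data.frame(name = c("kon_basal", "gain", "k_off", "mu", "beta"),
               lo = c(1e-3, 1e-3, 1e-3, 1e-2, 1e-2),
               hi = c(1e3, 1e3, 1e3, 1e3, 1e3))
}

# internal params (with gain) -> user-facing params
.expand_par <- function(th, model, n = NULL) {
  if (model == "phenomenological")
    list(kon0 = th[["kon0"]], kon1 = th[["kon0"]] + th[["gain"]],
         k_off = th[["k_off"]], mu = th[["mu"]], c = th[["c"]],
         h = th[["h"]])
  else
    list(kon_basal = th[["kon_basal"]],
         kon_enh = th[["kon_basal"]] + th[["gain"]],
         k_off = th[["k_off"]], mu = th[["mu"]], beta = th[["beta"]],
         n = n)
}

# user-facing params -> internal vector
.collapse_par <- function(par, model) {
  if (model == "phenomenological")
    c(kon0 = par$kon0, gain = par$kon1 - par$kon0, k_off = par$k_off,
      mu = par$mu, c = par$c, h = par$h)
  else
    c(kon_basal = par$kon_basal, gain = par$kon_enh - par$kon_basal,
      k_off = par$k_off, mu = par$mu, beta = par$beta)
}

# data-informed start: match the largest and smallest observed means
.informed_start <- function(screen, model, tab) {
  mmax <- max(screen$mean, 1)
  mmin <- max(min(screen$mean), 0.05)
  k_off <- 5; kon1 <- 1
  mu <- mmax * (kon1 + k_off) / kon1
  kon0 <- mmin * k_off / max(mu - mmin, 0.1)
  th <- if (model == "phenomenological")
    c(kon0 = kon0, gain = max(kon1 - kon0, 1e-3), k_off = k_off, mu = mu,
      c = 0.3, h = 2)
  else
    c(kon_basal = kon0, gain = max(kon1 - kon0, 1e-3), k_off = k_off,
      mu = mu, beta = 3)
  pmin(pmax(th, tab$lo * 1.01), tab$hi * 0.99)
}

# core multi-start maximizer over a subset of free parameters
.fit_core <- function(screen, fish, model, n = NULL, fixed = list(),
                      n_starts = 32L, seed = 1L, weights = c(1, 1),
                      tail_mass = 1e-6, se_floor = 1e-3,
                      mean_error = "pooled", n_polish = 5L,
                      maxit_short = 300L, maxit_polish = 2000L,
                      refine = TRUE, extra_starts = NULL) {
  tab <- .par_table(model)
  free <- setdiff(tab$name, names(fixed))
  if (length(free) == 0) {
    # nothing to optimize: evaluate the likelihood at the fixed values
    th <- numeric(nrow(tab)); names(th) <- tab$name
    for (nm in names(fixed)) th[nm] <- fixed[[nm]]
    par <- .expand_par(th, model, n)
    ll <- composite_loglik(par, screen, fish, model, weights, tail_mass,
                           se_floor, mean_error)
    return(list(par = par, loglik = as.numeric(ll),
                components = attr(ll, "components"), convergence = TRUE,
                start_values = as.numeric(ll), n_free = 0L,
                free = character(0), fixed = fixed))
  }
  ftab <- tab[match(free, tab$name), ]
  objective <- function(t) {
    th <- numeric(nrow(tab)); names(th) <- tab$name
    th[free] <- .box_inv(t, ftab$lo, ftab$hi)
    for (nm in names(fixed)) th[nm] <- fixed[[nm]]
    par <- .expand_par(th, model, n)
    ll <- tryCatch(
      composite_loglik(par, screen, fish, model, weights, tail_mass,
                       se_floor, mean_error),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e12)
    -as.numeric(ll)
  }
  set.seed(seed)
  starts <- matrix(NA_real_, n_starts, length(free),
                   dimnames = list(NULL, free))
  s1 <- .informed_start(screen, model, tab)
  starts[1, ] <- s1[free]
  if (n_starts > 1) {
    # log-uniform draws within the box
    for (j in seq_along(free))
      starts[-1, j] <- exp(stats::runif(n_starts - 1,
                                        log(ftab$lo[j] * 1.05),
                                        log(ftab$hi[j] * 0.95)))
  }
  if (!is.null(extra_starts)) {
    for (es in extra_starts) {
      starts <- rbind(starts, pmin(pmax(es[free], ftab$lo * 1.01),
                                   ftab$hi * 0.99))
    }
  }
  run <- function(t0, maxit) {
    if (length(t0) == 1L) {
      # one free parameter: golden-section/parabolic search on the
      # transformed axis (|t| = 30 saturates the box transform)
      o <- stats::optim(t0, objective, method = "Brent", lower = -30,
                        upper = 30, control = list(maxit = maxit))
      o$convergence <- 0L
      return(o)
    }
    stats::optim(t0, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
  }
  short <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    t0 <- .box_fwd(starts[i, ], ftab$lo, ftab$hi)
    short[[i]] <- run(t0, maxit_short)
  }
  vals <- vapply(short, function(o) o$value, numeric(1))
  keep <- order(vals)[seq_len(min(n_polish, length(short)))]
  polished <- lapply(keep, function(i) run(short[[i]]$par, maxit_polish))
  pvals <- vapply(polished, function(o) o$value, numeric(1))
  best <- polished[[which.min(pvals)]]
  # Nelder-Mead can report convergence on a collapsed simplex well short of
  # the optimum: restart the winner until its value stabilizes, then (for
  # full-precision fits) refine with a gradient method, which handles the
  # curved ridges (e.g. k_off vs mu) on which a simplex stalls.
  for (r in seq_len(if (refine) 3L else 1L)) {
    o2 <- run(best$par, maxit_polish)
    improved <- best$value - o2$value
    if (o2$value <= best$value) best <- o2
    if (improved < 1e-6) break
  }
  if (refine) {
    o3 <- tryCatch(
      stats::optim(best$par, objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14,
                                  ndeps = rep(1e-6, length(best$par)))),
      error = function(e) NULL)
    if (!is.null(o3) && o3$value < best$value) best <- o3
  }
  th <- numeric(nrow(tab)); names(th) <- tab$name
  th[free] <- .box_inv(best$par, ftab$lo, ftab$hi)
  for (nm in names(fixed)) th[nm] <- fixed[[nm]]
  par <- .expand_par(th, model, n)
  ll <- composite_loglik(par, screen, fish, model, weights, tail_mass,
                         se_floor, mean_error)
  list(par = par, loglik = as.numeric(ll),
       components = attr(ll, "components"),
       convergence = best$convergence == 0,
       start_values = -vals, n_free = length(free), free = free,
       fixed = fixed)
}

.new_fit <- function(core, model, screen, fish, seed, n_starts,
                     weights, tail_mass, se_floor, mean_error = "pooled",
                     extra = list()) {
  structure(c(list(model = model, par = core$par, loglik = core$loglik,
                   components = core$components,
                   convergence = core$convergence,
                   start_values = core$start_values, n_free = core$n_free,
                   free = core$free, fixed = core$fixed, seed = seed,
                   n_starts = n_starts, weights = weights,
                   tail_mass = tail_mass, se_floor = se_floor,
                   mean_error = mean_error,
                   screen = screen, fish = fish), extra),
            class = "ep_fit")
}

#' @export
print.ep_fit <- function(x, ...) {
  cat(sprintf("Simultaneous fit of the %s two-state model\n", x$model))
  cat("  log-likelihood:", format(x$loglik), "\n")
  p <- x$par
  cat("  parameters (rates per mRNA lifetime):\n")
  for (nm in names(p)) cat(sprintf("    %-10s %g\n", nm, p[[nm]]))
  if (isTRUE(x$h_unidentifiable))
    cat("  note: response is flat; Hill exponent not identifiable\n")
  invisible(x)
}

#' Fit the phenomenological two-state model
#'
#' Simultaneous maximum-likelihood fit of the telegraph model with
#' Hill-modulated on rate to per-line means and smFISH distributions. Free
#' parameters: `kon0`, `kon1`, `k_off`, `mu`, `c`, `h` (with `delta` fixed
#' at 1, i.e. rates in mRNA-lifetime units). Multi-start Nelder-Mead on
#' box-logistic transformed parameters: every start runs a short
#' optimization and the best few are polished to convergence; the draw of
#' starts is fixed by `seed`.
#'
#' @param screen a [screen_dataset()].
#' @param fish a [fish_dataset()] (optional).
#' @param n_starts number of random starts (a data-informed start is always
#'   included).
#' @param seed integer seed controlling start draws.
#' @param weights,tail_mass,se_floor see [composite_loglik()].
#' @param n_polish number of best starts polished to full convergence.
#' @return An `ep_fit` object: parameter estimates, log-likelihood,
#'   component log-likelihoods, per-start values and the data (retained for
#'   profiling). If the fitted response is essentially flat
#'   (`kon1 - kon0` below 5% of `kon0`), `h_unidentifiable` is set.
#' @export
fit_phenomenological <- function(screen, fish = NULL, n_starts = 32L,
                                 seed = 1L, weights = c(1, 1),
                                 tail_mass = 1e-6, se_floor = 1e-3,
                                 mean_error = c("lognormal", "pooled", "per_line"),
                                 n_polish = 5L) {
  mean_error <- match.arg(mean_error)
  if (nrow(screen) < 6) stop("need at least 6 screen lines")
  core <- .fit_core(screen, fish, "phenomenological", n_starts = n_starts,
                    seed = seed, weights = weights, tail_mass = tail_mass,
                    se_floor = se_floor, mean_error = mean_error,
                    n_polish = n_polish)
  flat <- (core$par$kon1 - core$par$kon0) < 0.05 * core$par$kon0
  .new_fit(core, "phenomenological", screen, fish, seed, n_starts, weights,
           tail_mass, se_floor, mean_error,
           extra = list(h_unidentifiable = flat))
}

#' Fit the apparent two-state model
#'
#' For each candidate number of regulatory steps `n` in `n_grid`, maximizes
#' the composite likelihood over the continuous parameters (`kon_basal`,
#' `kon_enh`, `k_off`, `mu`, `beta`); the best continuous solution of the
#' previous `n` seeds one start of the next, and the per-`n` profile of
#' maximized log-likelihoods is retained so that [profile_ci()] can return
#' an integer confidence set for `n`.
#'
#' @inheritParams fit_phenomenological
#' @param n_grid integer candidates for the number of regulatory steps.
#' @param n_starts_rest random starts used after the first grid point,
#'   where the previous best solution seeds a continuation start.
#' @return An `ep_fit` with the overall best parameters (including `n`) and
#'   a `profile_n` data.frame (`n`, `loglik`).
#' @export
fit_apparent <- function(screen, fish = NULL, n_grid = 1:10, n_starts = 16L,
                         seed = 1L, weights = c(1, 1), tail_mass = 1e-6,
                         se_floor = 1e-3,
                         mean_error = c("lognormal", "pooled", "per_line"),
                         n_polish = 3L,
                         n_starts_rest = max(4L, n_starts %/% 4L)) {
  mean_error <- match.arg(mean_error)
  stopifnot(all(n_grid >= 1), all(n_grid == floor(n_grid)))
  cores <- vector("list", length(n_grid))
  warm <- NULL
  for (i in seq_along(n_grid)) {
    first <- is.null(warm)
    cores[[i]] <- .fit_core(screen, fish, "apparent", n = n_grid[i],
                            n_starts = if (first) n_starts else n_starts_rest,
                            seed = seed, weights = weights,
                            tail_mass = tail_mass, se_floor = se_floor,
                            mean_error = mean_error,
                            n_polish = if (first) n_polish else
                              min(n_polish, 2L),
                            maxit_short = if (first) 300L else 200L,
                            maxit_polish = if (first) 1200L else 800L,
                            refine = FALSE,
                            extra_starts = warm)
    warm <- list(.collapse_par(cores[[i]]$par, "apparent"))
  }
  lls <- vapply(cores, function(cc) cc$loglik, numeric(1))
  best <- which.max(lls)
  # final polish of the winning n from its own solution
  refined <- .fit_core(screen, fish, "apparent", n = n_grid[best],
                       n_starts = 1L, seed = seed, weights = weights,
                       tail_mass = tail_mass, se_floor = se_floor,
                       mean_error = mean_error,
                       n_polish = 1L, maxit_polish = 3000L,
                       extra_starts = list(.collapse_par(cores[[best]]$par,
                                                         "apparent")))
  if (refined$loglik >= cores[[best]]$loglik) cores[[best]] <- refined
  lls[best] <- cores[[best]]$loglik
  profile_n <- data.frame(n = as.integer(n_grid), loglik = lls)
  .new_fit(cores[[best]], "apparent", screen, fish, seed, n_starts, weights,
           tail_mass, se_floor, mean_error,
           extra = list(profile_n = profile_n))
}

#' Refit the apparent model with a restricted free-parameter set
#'
#' Nested model variants used for the truncated-enhancer comparison: all
#' parameters except the chosen free set are fixed at the reference fit's
#' estimates (the full-length-enhancer best fit), and `n` is kept at the
#' reference value.
#'
#' @param screen,fish data for the variant (e.g. truncated-enhancer lines).
#' @param reference an `ep_fit` of the apparent model supplying fixed
#'   values.
#' @param free which parameters to leave free: `"beta_only"`,
#'   `"kon_enh_only"`, `"both"` or `"all_free"`.
#' @inheritParams fit_phenomenological
#' @return An `ep_fit` with attribute `variant` naming the free set.
#' @export
fit_apparent_variant <- function(screen, fish = NULL, reference,
                                 free = c("beta_only", "kon_enh_only",
                                          "both", "all_free"),
                                 n_starts = 16L, seed = 1L,
                                 weights = c(1, 1), tail_mass = 1e-6,
                                 se_floor = 1e-3,
                                 mean_error = c("lognormal", "pooled", "per_line")) {
  free <- match.arg(free)
  mean_error <- match.arg(mean_error)
  stopifnot(inherits(reference, "ep_fit"), reference$model == "apparent")
  base <- .collapse_par(reference$par, "apparent")
  free_names <- switch(free,
    beta_only = "beta",
    kon_enh_only = "gain",
    both = c("beta", "gain"),
    all_free = c("kon_basal", "gain", "k_off", "mu", "beta"))
  fixed <- as.list(base[setdiff(names(base), free_names)])
  core <- .fit_core(screen, fish, "apparent", n = reference$par$n,
                    fixed = fixed, n_starts = n_starts, seed = seed,
                    weights = weights, tail_mass = tail_mass,
                    se_floor = se_floor, mean_error = mean_error,
                    extra_starts = list(base))
  .new_fit(core, "apparent", screen, fish, seed, n_starts, weights,
           tail_mass, se_floor, mean_error,
           extra = list(variant = free))
}

#' Profile-likelihood confidence interval
#'
#' Profiles the composite log-likelihood over one parameter, re-optimizing
#' all remaining free parameters at each fixed value (warm-started from the
#' neighbouring profile point), and returns the interval where
#' `2 * (ll_max - ll_profile) <= qchisq(level, 1)`. For the integer step
#' count `n` of the apparent model the per-`n` profile stored in the fit is
#' used and the confidence set of integers is returned.
#'
#' @param fit an `ep_fit` from [fit_phenomenological()] or
#'   [fit_apparent()].
#' @param param parameter name (e.g. `"h"`, `"beta"`, `"n"`).
#' @param level confidence level (default 0.95).
#' @param step multiplicative step between profile grid points.
#' @param max_steps maximum profile points per side.
#' @return List with `lower`, `upper`, `level` and the profile `points`
#'   (data.frame of parameter value and profile log-likelihood). Open ends
#'   are reported at the parameter bounds with a warning; a flat profile
#'   yields the full box with a warning.
#' @export
profile_ci <- function(fit, param, level = 0.95, step = 1.08,
                       max_steps = 60L) {
  stopifnot(inherits(fit, "ep_fit"))
  drop <- stats::qchisq(level, 1) / 2
  if (param == "n") {
    if (is.null(fit$profile_n)) stop("fit has no per-n profile")
    ok <- fit$profile_n$loglik >= max(fit$profile_n$loglik) - drop
    ns <- fit$profile_n$n[ok]
    return(list(lower = min(ns), upper = max(ns), level = level,
                points = fit$profile_n, set = ns))
  }
  model <- fit$model
  tab <- .par_table(model)
  # map user-facing parameter to the internal parameterization
  internal <- switch(param, kon1 = "gain", kon_enh = "gain", param)
  if (!internal %in% tab$name) stop("unknown parameter: ", param)
  th_hat <- .collapse_par(fit$par, model)
  lo <- tab$lo[tab$name == internal]; hi <- tab$hi[tab$name == internal]
  ll_max <- fit$loglik
  prof_one <- function(value, warm) {
    fixed <- c(list(), fit$fixed)
    fixed[[internal]] <- value
    core <- .fit_core(fit$screen, fit$fish, model, n = fit$par$n,
                      fixed = fixed, n_starts = 1L, seed = fit$seed,
                      weights = fit$weights, tail_mass = fit$tail_mass,
                      se_floor = fit$se_floor, mean_error = fit$mean_error,
                      n_polish = 1L, refine = FALSE,
                      maxit_short = 50L, maxit_polish = 800L,
                      extra_starts = list(warm))
    list(ll = core$loglik, th = .collapse_par(core$par, model))
  }
  scan <- function(direction) {
    out <- data.frame(value = numeric(0), loglik = numeric(0))
    warm <- th_hat
    v <- th_hat[[internal]]
    for (k in seq_len(max_steps)) {
      v <- if (direction > 0) v * step else v / step
      if (v <= lo || v >= hi) {
        v <- if (direction > 0) hi * 0.999 else lo * 1.001
        r <- prof_one(v, warm)
        out <- rbind(out, data.frame(value = v, loglik = r$ll))
        break
      }
      r <- prof_one(v, warm)
      warm <- r$th
      out <- rbind(out, data.frame(value = v, loglik = r$ll))
      if (r$ll < ll_max - drop - 1) break
    }
    out
  }
  up <- scan(+1); dn <- scan(-1)
  cross <- function(pts, bound) {
    if (nrow(pts) == 0) return(bound)
    dev <- 2 * (ll_max - pts$loglik)
    if (all(dev < stats::qchisq(level, 1))) {
      warning("profile for '", param,
              "' is flat to the parameter bound; interval is open-ended")
      return(bound)
    }
    i <- which(dev >= stats::qchisq(level, 1))[1]
    if (i == 1) {
      x0 <- th_hat[[internal]]; d0 <- 0
    } else {
      x0 <- pts$value[i - 1]; d0 <- dev[i - 1]
    }
    x1 <- pts$value[i]; d1 <- dev[i]
    # interpolate on the root deviance, which is ~linear in log(parameter)
    # for a locally quadratic log-likelihood
    r0 <- sqrt(max(d0, 0)); r1 <- sqrt(d1)
    rstar <- sqrt(stats::qchisq(level, 1))
    exp(log(x0) + (rstar - r0) / (r1 - r0) * (log(x1) - log(x0)))
  }
  points <- rbind(dn[rev(seq_len(nrow(dn))), ],
                  data.frame(value = th_hat[[internal]], loglik = ll_max),
                  up)
  # report on the user-facing scale: gain intervals shift by kon0/kon_basal
  offset <- if (param %in% c("kon1", "kon_enh")) {
    if (model == "phenomenological") fit$par$kon0 else fit$par$kon_basal
  } else 0
  list(lower = cross(dn, lo) + offset, upper = cross(up, hi) + offset,
       level = level, points = points)
}

#' Likelihood-ratio comparison of nested model variants
#'
#' Compares restricted variants (see [fit_apparent_variant()]) to a
#' reference fit in which all parameters are free, using
#' `2 * (ll_ref - ll_variant)` against a chi-squared null with degrees of
#' freedom equal to the difference in free-parameter counts. The selected
#' variant is the smallest model not rejected at `alpha`.
#'
#' @param reference `ep_fit` with all parameters free (same data as the
#'   variants).
#' @param variants named list of restricted `ep_fit` objects.
#' @param alpha rejection level (default 0.05).
#' @return data.frame with one row per variant (`statistic`, `df`,
#'   `p_value`, `rejected`) and attribute `selected` (name of the chosen
#'   variant, or `"all_free"` if every restriction is rejected).
#' @export
lrt_compare <- function(reference, variants, alpha = 0.05) {
  stopifnot(inherits(reference, "ep_fit"))
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    stat <- 2 * (reference$loglik - v$loglik)
    if (stat < -1e-6)
      stop("variant '", nm, "' exceeds the reference likelihood: ",
           "optimizer failure in the reference fit")
    stat <- max(stat, 0)
    df <- reference$n_free - v$n_free
    if (df < 1) stop("variant '", nm, "' is not nested in the reference")
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    data.frame(variant = nm, statistic = stat, df = df, p_value = p,
               n_free = v$n_free, rejected = p < alpha)
  })
  out <- do.call(rbind, rows)
  keep <- out[!out$rejected, ]
  selected <- if (nrow(keep) == 0) "all_free" else {
    keep <- keep[order(keep$n_free, -keep$p_value), ]
    keep$variant[1]
  }
  attr(out, "selected") <- selected
  out
}

#' Predicted transcriptional response of a weakened enhancer
#'
#' Scales one parameter of a fitted apparent model - the step bias `beta`
#' (slower flow of regulatory information) or the enhanced on rate
#' `kon_enh` (weaker activation once engaged) - and returns the predicted
#' mean-expression curve over a contact-probability grid. Scaling `kon_enh`
#' preserves the shape of the response in `p_c` while lowering its
#' amplitude; scaling `beta` shifts the sensitive region.
#'
#' @param fit an `ep_fit` of the apparent model.
#' @param mode `"scale_kon_enh"` or `"scale_beta"`.
#' @param factor positive scale factor applied to the chosen parameter.
#' @param p_grid contact-probability grid.
#' @return data.frame with columns `p` and `mean`.
#' @export
predict_weak_enhancer <- function(fit, mode = c("scale_kon_enh",
                                                "scale_beta"),
                                  factor = 1, p_grid = seq(0, 1, 0.01)) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "ep_fit"), fit$model == "apparent")
  if (factor <= 0) stop("factor must be positive")
  par <- fit$par
  if (mode == "scale_kon_enh") {
    par$kon_enh <- max(par$kon_enh * factor, par$kon_basal)
  } else {
    par$beta <- par$beta * factor
  }
  data.frame(p = p_grid, mean = .model_mean(par, p_grid, "apparent"))
}
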