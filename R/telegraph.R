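#' Two-state (telegraph) promoter model parameters
#'
#' Rates of the two-state model of transcriptional bursting: the promoter
#' switches between OFF and ON with rates `k_on` and `k_off`; while ON,
#' transcripts initiate at rate `mu`; mRNA degrades at rate `delta`. The
#' natural time unit is the mRNA lifetime, so `delta = 1` by default and all
#' other rates are expressed per mRNA lifetime.
#'
#' @param k_on promoter OFF -> ON switching rate (burst frequency), >= 0.
#' @param k_off promoter ON -> OFF switching rate, >= 0.
#' @param mu transcription initiation rate while ON, >= 0.
#' @param delta mRNA degradation rate, > 0 (default 1: time in mRNA lifetimes).
#' @return An object of class `telegraph_params`.
#' @seealso [telegraph_mean()], [telegraph_pmf()], [telegraph_cv()]
#' @export
#' @examples
#' tp <- telegraph_params(k_on = 1, k_off = 1, mu = 10)
#' telegraph_mean(tp)
telegraph_params <- function(k_on, k_off, mu, delta = 1) {
  stopifnot(is.numeric(k_on), is.numeric(k_off), is.numeric(mu),
            is.numeric(delta), length(k_on) == 1L, length(k_off) == 1L,
            length(mu) == 1L, length(delta) == 1L)
  if (k_on < 0 || k_off < 0 || mu < 0)
    stop("telegraph rates must be non-negative")
  if (delta <= 0) stop("delta must be positive")
  structure(list(k_on = k_on, k_off = k_off, mu = mu, delta = delta),
            class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat(sprintf(
    "Telegraph model: k_on = %g, k_off = %g, mu = %g, delta = %g\n",
    x$k_on, x$k_off, x$mu, x$delta))
  invisible(x)
}

#' Hill-function response of the promoter on rate to contact probability
#'
#' Parameters of the saturating response
#' `k_on(p) = kon0 + (kon1 - kon0) * p^h / (c^h + p^h)` that maps the
#' enhancer-promoter contact probability `p` onto the promoter's on rate.
#' `kon0` and `kon1` are the minimum and maximum on rates, `c` is the
#' critical threshold (in contact-probability units) and `h` the Hill
#' (sensitivity) exponent; `h > 1` gives a sigmoidal, switch-like response.
#'
#' @param kon0 minimum on rate (response at `p = 0`), >= 0.
#' @param kon1 maximum on rate (saturating response), >= `kon0`.
#' @param c critical threshold of the Hill function, > 0.
#' @param h Hill exponent, > 0.
#' @return An object of class `hill_params`.
#' @export
#' @examples
#' hp <- hill_params(kon0 = 0.1, kon1 = 2, c = 0.25, h = 2.8)
#' hill_response(c(0, 0.25, 1), hp)
hill_params <- function(kon0, kon1, c, h) {
  stopifnot(is.numeric(kon0), is.numeric(kon1), is.numeric(c), is.numeric(h))
  if (kon0 < 0 || kon1 < kon0)
    stop("need 0 <= kon0 <= kon1")
  if (c <= 0) stop("Hill threshold c must be positive")
  if (h <= 0) stop("Hill exponent h must be positive")
  structure(list(kon0 = kon0, kon1 = kon1, c = c, h = h),
            class = "hill_params")
}

#' Evaluate the Hill response
#'
#' @param p contact probability (vectorized), each value in \[0, 1\].
#' @param hp a [hill_params()] object.
#' @return Numeric vector of on rates, non-decreasing in `p`.
#' @export
hill_response <- function(p, hp) {
  stopifnot(inherits(hp, "hill_params"), is.numeric(p))
  if (any(p < 0 | p > 1)) stop("contact probabilities must lie in [0, 1]")
  hp$kon0 + (hp$kon1 - hp$kon0) * p^hp$h / (hp$c^hp$h + p^hp$h)
}

#' Analytic mean mRNA number of the telegraph model
#'
#' The stationary mean is `mu * k_on / (delta * (k_on + k_off))`: the
#' initiation rate scaled by the fraction of time the promoter spends ON,
#' in units of transcripts per cell.
#'
#' @param tp a [telegraph_params()] object.
#' @return Mean mRNA count.
#' @export
telegraph_mean <- function(tp) {
  stopifnot(inherits(tp, "telegraph_params"))
  if (tp$k_on + tp$k_off == 0) {
    if (tp$mu > 0) stop("degenerate parameters: k_on + k_off = 0 with mu > 0")
    return(0)
  }
  tp$mu * tp$k_on / (tp$delta * (tp$k_on + tp$k_off))
}

#' Analytic variance of the telegraph model
#'
#' Stationary variance `mean * (1 + lambda * b / ((a + b) * (1 + a + b)))`
#' with `a = k_on/delta`, `b = k_off/delta`, `lambda = mu/delta`; the second
#' factor is the Fano factor (1 in the always-ON Poisson limit `b = 0`).
#'
#' @inheritParams telegraph_mean
#' @return Stationary variance of the mRNA count.
#' @export
telegraph_variance <- function(tp) {
  stopifnot(inherits(tp, "telegraph_params"))
  a <- tp$k_on / tp$delta
  b <- tp$k_off / tp$delta
  lam <- tp$mu / tp$delta
  m <- telegraph_mean(tp)
  if (a + b == 0) return(0)
  m * (1 + lam * b / ((a + b) * (1 + a + b)))
}

# fast internal path: stationary mRNA pmf without S3 overhead.
# Returns a probability vector over counts 0..M (M chosen adaptively).
.telegraph_pmf_core <- function(k_on, k_off, mu, delta, tail_mass,
                                min_length = 0L) {
  if (mu == 0 || k_on == 0) {
    out <- c(1, rep(0, max(0L, min_length - 1L)))
    return(out)
  }
  if (k_off == 0) {  # always-ON limit: truncated Poisson(mu/delta)
    lam <- mu / delta
    M <- max(min_length - 1L, stats::qpois(1 - tail_mass / 10, lam) + 5L)
    p <- stats::dpois(0:M, lam)
    return(p / sum(p))
  }
  m1 <- mu * k_on / (delta * (k_on + k_off))
  a <- k_on / delta; b <- k_off / delta; lam <- mu / delta
  v <- m1 * (1 + lam * b / ((a + b) * (1 + a + b)))
  M <- max(15L, min_length - 1L, ceiling(m1 + 8 * sqrt(v)))
  for (i in 1:12) {
    # anchor the solve at the bulk of the distribution to avoid underflow
    ref_m <- min(as.integer(M), max(0L, as.integer(round(m1))))
    sol <- .telegraph_stationary_cpp(k_on, k_off, mu, delta, as.integer(M),
                                     ref_m)
    pmf <- sol$pmf
    # geometric estimate of the truncated tail from the last two entries
    r <- if (pmf[M] > 0) pmf[M + 1] / pmf[M] else 0
    tail_est <- if (r > 0 && r < 1) pmf[M + 1] * r / (1 - r) else pmf[M + 1]
    if (is.finite(tail_est) && tail_est < tail_mass) return(pmf)
    M <- 2L * M
    if (M > 2e6) break
  }
  stop("telegraph_pmf truncation did not converge: tail mass estimate ",
       format(tail_est), " above requested ", format(tail_mass),
       " at M = ", M)
}

#' Stationary mRNA-count distribution of the telegraph model
#'
#' Solves the truncated chemical master equation's stationary linear system
#' over promoter state x mRNA count, with the truncation bound grown
#' geometrically until the estimated truncated tail mass falls below
#' `tail_mass`. The returned vector is normalized to sum to 1.
#'
#' @inheritParams telegraph_mean
#' @param tail_mass upper bound on the probability mass lost to truncation;
#'   must lie in `(0, 1e-4]`.
#' @param min_length minimum support length (counts `0..min_length-1`),
#'   useful to guarantee coverage of observed counts.
#' @return Numeric vector `p` with `p[m + 1] = P(mRNA = m)`, class
#'   `count_pmf`.
#' @export
#' @examples
#' p <- telegraph_pmf(telegraph_params(1, 1, 10))
#' sum(p)
#' pmf_moments(p)
telegraph_pmf <- function(tp, tail_mass = 1e-6, min_length = 0L) {
  stopifnot(inherits(tp, "telegraph_params"))
  if (!(tail_mass > 0 && tail_mass <= 1e-4))
    stop("tail_mass must lie in (0, 1e-4]")
  p <- .telegraph_pmf_core(tp$k_on, tp$k_off, tp$mu, tp$delta, tail_mass,
                           as.integer(min_length))
  structure(p, class = "count_pmf")
}

#' Mean, variance and CV of a count pmf
#'
#' @param p probability vector over counts `0..length(p)-1`.
#' @return Named numeric vector with `mean`, `var`, `cv`.
#' @export
pmf_moments <- function(p) {
  m <- seq_along(p) - 1
  mu1 <- sum(m * p)
  v <- sum((m - mu1)^2 * p)
  c(mean = mu1, var = v, cv = if (mu1 > 0) sqrt(v) / mu1 else NA_real_)
}

#' Coefficient of variation of the telegraph model
#'
#' sd/mean of the stationary mRNA distribution, computed from the numeric
#' pmf (default) or from the closed-form second moment.
#'
#' @inheritParams telegraph_pmf
#' @param method `"pmf"` (numeric stationary solve) or `"analytic"`
#'   (closed-form moments).
#' @return The coefficient of variation.
#' @export
telegraph_cv <- function(tp, method = c("pmf", "analytic"),
                         tail_mass = 1e-6) {
  method <- match.arg(method)
  m <- telegraph_mean(tp)
  if (m <= 0) stop("CV undefined: stationary mean is zero")
  if (method == "analytic") return(sqrt(telegraph_variance(tp)) / m)
  unname(pmf_moments(telegraph_pmf(tp, tail_mass))["cv"])
}

#' Modulate one telegraph rate by the Hill response
#'
#' Builds the telegraph parameters at contact probability `p` under one of
#' three modulation variants: the on rate (`"on_rate"`, the burst-frequency
#' model), the off rate (`"off_rate"`) or the initiation rate
#' (`"initiation_rate"`). For `off_rate` the response must fall with contact
#' probability, so the Hill limits swap roles: the rate decreases from
#' `kon1` at `p = 0` towards `kon0` at saturation.
#'
#' @param p contact probability in \[0, 1\] (scalar).
#' @param hp a [hill_params()] object describing the response limits.
#' @param base a [telegraph_params()] object supplying the unmodulated rates.
#' @param variant which rate responds to contact probability.
#' @return A [telegraph_params()] object.
#' @export
apply_variant <- function(p, hp, base,
                          variant = c("on_rate", "off_rate",
                                      "initiation_rate")) {
  variant <- match.arg(variant)
  stopifnot(length(p) == 1L)
  r <- hill_response(p, hp)
  switch(variant,
    on_rate = telegraph_params(r, base$k_off, base$mu, base$delta),
    off_rate = {
      # decreasing response: kon1 at p = 0 down to kon0 at saturation
      rr <- hp$kon1 + (hp$kon0 - hp$kon1) * p^hp$h / (hp$c^hp$h + p^hp$h)
      telegraph_params(base$k_on, rr, base$mu, base$delta)
    },
    initiation_rate = telegraph_params(base$k_on, base$k_off, r, base$delta)
  )
}

#' CV/Fano profile of a modulation variant along contact probability
#'
#' Evaluates mean, CV and Fano factor of the modulated telegraph model over
#' a grid of contact probabilities, using the stationary pmf. Used to
#' contrast the burst-frequency (on-rate) model, whose CV falls with
#' contact probability, against off-rate and initiation-rate modulation.
#'
#' @param p_grid contact probabilities to evaluate.
#' @inheritParams apply_variant
#' @param tail_mass pmf truncation tolerance.
#' @return A data.frame with columns `p`, `mean`, `cv`, `fano`.
#' @export
variant_profile <- function(p_grid, hp, base,
                            variant = c("on_rate", "off_rate",
                                        "initiation_rate"),
                            tail_mass = 1e-6) {
  variant <- match.arg(variant)
  out <- lapply(p_grid, function(p) {
    tp <- apply_variant(p, hp, base, variant)
    mo <- pmf_moments(telegraph_pmf(tp, tail_mass))
    data.frame(p = p, mean = mo[["mean"]], cv = mo[["cv"]],
               fano = mo[["var"]] / max(mo[["mean"]], .Machine$double.eps))
  })
  do.call(rbind, out)
}

#' Closed-form telegraph pmf (beta-Poisson mixture cross-check)
#'
#' The stationary telegraph distribution is a Poisson(`mu/delta * x`)
#' mixture over `x ~ Beta(k_on/delta, k_off/delta)`. This evaluates the
#' mixture by quantile-space quadrature, which stays finite where the naive
#' confluent-hypergeometric form overflows. Intended as an independent
#' cross-check of [telegraph_pmf()], not as the primary solver.
#'
#' @inheritParams telegraph_mean
#' @param M largest count to evaluate.
#' @param n_nodes number of quadrature nodes in Beta-quantile space.
#' @return Probability vector over counts `0..M` (not renormalized).
#' @export
beta_poisson_pmf <- function(tp, M, n_nodes = 4000L) {
  stopifnot(inherits(tp, "telegraph_params"), tp$k_on > 0, tp$k_off > 0)
  a <- tp$k_on / tp$delta
  b <- tp$k_off / tp$delta
  lam <- tp$mu / tp$delta
  x <- stats::qbeta((seq_len(n_nodes) - 0.5) / n_nodes, a, b)
  vapply(0:M, function(m) mean(stats::dpois(m, lam * x)), numeric(1))
}
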