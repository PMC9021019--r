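#' Mechanistic enhancer-promoter communication model parameters
#'
#' Continuous-time Markov chain in which the enhancer stochastically comes
#' into contact with the promoter (rates `k_close`/`k_far`), contact drives
#' `n` reversible regulatory steps (forward rate `k_forward`, available only
#' while in contact; reverse rate `k_back`, active in either contact state),
#' and the promoter runs a two-state bursting cycle whose on rate is
#' `kon_enh` when all `n` steps are complete and `kon_basal` otherwise.
#' Transcription initiates at `mu` while ON; mRNA degrades at `delta`.
#'
#' @param k_close,k_far contact formation/disassembly rates, >= 0.
#' @param k_forward,k_back regulatory step forward/reverse rates, >= 0.
#' @param n number of regulatory steps, integer >= 1.
#' @param kon_basal,kon_enh basal and enhanced promoter on rates,
#'   `kon_enh >= kon_basal >= 0`.
#' @param k_off promoter ON -> OFF rate, >= 0.
#' @param mu initiation rate while ON, >= 0.
#' @param delta mRNA degradation rate, > 0 (default 1: mRNA-lifetime units).
#' @return An object of class `mechanistic_params`. The derived step-bias
#'   ratio `beta = k_forward / k_back` is available via `$beta`.
#' @export
#' @examples
#' mp <- mechanistic_params(k_close = 64, k_far = 64, k_forward = 56,
#'                          k_back = 8, n = 5, kon_basal = 0.15,
#'                          kon_enh = 2, k_off = 10, mu = 360)
#' steady_contact_probability(mp)
mechanistic_params <- function(k_close, k_far, k_forward, k_back, n,
                               kon_basal, kon_enh, k_off, mu, delta = 1) {
  rates <- c(k_close, k_far, k_forward, k_back, kon_basal, kon_enh, k_off, mu)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (delta <= 0) stop("delta must be positive")
  if (kon_enh < kon_basal) stop("kon_enh must be >= kon_basal")
  n <- as.integer(n)
  if (n < 1) stop("n must be an integer >= 1")
  structure(list(k_close = k_close, k_far = k_far, k_forward = k_forward,
                 k_back = k_back, n = n, kon_basal = kon_basal,
                 kon_enh = kon_enh, k_off = k_off, mu = mu, delta = delta,
                 beta = if (k_back > 0) k_forward / k_back else Inf),
            class = "mechanistic_params")
}

#' @export
print.mechanistic_params <- function(x, ...) {
  cat(sprintf(
    paste0("Mechanistic model: k_close = %g, k_far = %g, k_forward = %g, ",
           "k_back = %g,\n  n = %d, kon_basal = %g, kon_enh = %g, ",
           "k_off = %g, mu = %g, delta = %g (beta = %g)\n"),
    x$k_close, x$k_far, x$k_forward, x$k_back, x$n, x$kon_basal, x$kon_enh,
    x$k_off, x$mu, x$delta, x$beta))
  invisible(x)
}

#' Steady-state enhancer-promoter contact probability
#'
#' The fraction of time the chain spends in the close contact state,
#' `k_close / (k_close + k_far)`.
#'
#' @param mp a [mechanistic_params()] object.
#' @return Contact probability in \[0, 1\].
#' @export
steady_contact_probability <- function(mp) {
  stopifnot(inherits(mp, "mechanistic_params"))
  if (mp$k_close + mp$k_far == 0)
    stop("k_close + k_far must be positive")
  mp$k_close / (mp$k_close + mp$k_far)
}

#' Gillespie simulation of the mechanistic model
#'
#' Exact stochastic simulation of the full CTMC. With `n_samples > 0`, mRNA
#' counts are recorded on the grid `burn_in + (0:(n_samples-1)) *
#' sample_spacing`; with `record = TRUE` the complete event trajectory is
#' returned as a data.frame. The same `seed` always yields the identical
#' trajectory.
#'
#' @param mp a [mechanistic_params()] object.
#' @param t_end simulation end time (> `burn_in`).
#' @param burn_in time discarded before sampling begins (default 0).
#' @param seed integer RNG seed (required for reproducibility).
#' @param n_samples number of thinned state samples to collect (0 = none).
#' @param sample_spacing time between samples (default `3 / delta`, several
#'   mRNA lifetimes, so successive samples are nearly decorrelated).
#' @param record return the full trajectory (default `TRUE` when
#'   `n_samples == 0`).
#' @param max_events cap on stored trajectory events.
#' @param init optional initial state `list(contact =, step =, promoter =,
#'   m =)`; defaults to (far, 0, OFF, 0).
#' @return A list of class `mech_trajectory` with elements `samples`
#'   (integer mRNA counts), `trajectory` (data.frame, if recorded), `seed`,
#'   `burn_in`, `absorbed`, `truncated`.
#' @export
gillespie_simulate <- function(mp, t_end, burn_in = 0, seed,
                               n_samples = 0L, sample_spacing = 3 / mp$delta,
                               record = n_samples == 0L,
                               max_events = 5e6, init = NULL) {
  stopifnot(inherits(mp, "mechanistic_params"))
  if (!(t_end > burn_in && burn_in >= 0))
    stop("need t_end > burn_in >= 0")
  if (missing(seed)) stop("a seed is required")
  if (is.null(init)) init <- list(contact = 0L, step = 0L, promoter = 0L,
                                  m = 0L)
  if (init$step > mp$n) stop("initial step exceeds n")
  set.seed(seed)
  res <- .gillespie_cpp(mp$k_close, mp$k_far, mp$k_forward, mp$k_back, mp$n,
                        mp$kon_basal, mp$kon_enh, mp$k_off, mp$mu, mp$delta,
                        t_end, burn_in, sample_spacing,
                        as.integer(n_samples), record,
                        as.integer(max_events), as.integer(init$contact),
                        as.integer(init$step), as.integer(init$promoter),
                        as.integer(init$m))
  if (res$absorbed)
    warning("all propensities vanished before t_end; state held constant")
  traj <- NULL
  if (record)
    traj <- data.frame(time = res$time, contact = res$contact,
                       step = res$step, promoter = res$promoter, m = res$m)
  structure(list(samples = res$samples, trajectory = traj, seed = seed,
                 burn_in = burn_in, sample_spacing = sample_spacing,
                 absorbed = res$absorbed, truncated = res$truncated,
                 t_final = res$t_final, events = res$events),
            class = "mech_trajectory")
}

#' Thinned stationary samples of the mechanistic mRNA count
#'
#' Convenience wrapper around [gillespie_simulate()] drawing `n_samples`
#' mRNA counts from one long trajectory after a burn-in of `20 / delta`,
#' spaced `3 / delta` apart.
#'
#' @inheritParams gillespie_simulate
#' @param n_samples number of samples.
#' @return Integer vector of mRNA counts.
#' @export
sample_mechanistic <- function(mp, n_samples, seed,
                               burn_in = 20 / mp$delta,
                               sample_spacing = 3 / mp$delta) {
  t_end <- burn_in + n_samples * sample_spacing + sample_spacing
  sim <- gillespie_simulate(mp, t_end = t_end, burn_in = burn_in, seed = seed,
                            n_samples = n_samples,
                            sample_spacing = sample_spacing, record = FALSE)
  sim$samples
}

#' Thinned stationary samples of the telegraph mRNA count
#'
#' Gillespie sampling of the plain two-state model, implemented as the
#' mechanistic chain with `kon_basal = kon_enh` so the contact and step
#' layers are irrelevant. Serves as the stochastic-simulation oracle for
#' [telegraph_pmf()].
#'
#' @param tp a [telegraph_params()] object.
#' @inheritParams sample_mechanistic
#' @return Integer vector of mRNA counts.
#' @export
sample_telegraph <- function(tp, n_samples, seed, burn_in = 20 / tp$delta,
                             sample_spacing = 3 / tp$delta) {
  mp <- mechanistic_params(k_close = 1, k_far = 1, k_forward = 1, k_back = 1,
                           n = 1L, kon_basal = tp$k_on, kon_enh = tp$k_on,
                           k_off = tp$k_off, mu = tp$mu, delta = tp$delta)
  sample_mechanistic(mp, n_samples, seed, burn_in, sample_spacing)
}

# internal: state-space-capped stationary solve with adaptive m-truncation
.mechanistic_pmf_core <- function(mp, tail_mass, min_length = 0L,
                                  max_states = 5e5) {
  # special cases that reduce exactly to a telegraph model
  tel <- function(kon) .telegraph_pmf_core(kon, mp$k_off, mp$mu, mp$delta,
                                           tail_mass, min_length)
  if (mp$kon_basal == mp$kon_enh) return(tel(mp$kon_basal))
  if (mp$k_forward == 0 || mp$k_close == 0) return(tel(mp$kon_basal))
  if (mp$k_back == 0) return(tel(mp$kon_enh))  # top step absorbing
  # envelope truncation from the enhanced regime (largest possible mean)
  tp_hi <- telegraph_params(mp$kon_enh, mp$k_off, mp$mu, mp$delta)
  m1 <- telegraph_mean(tp_hi)
  v <- telegraph_variance(tp_hi)
  M <- max(15L, min_length - 1L, ceiling(m1 + 8 * sqrt(v)))
  K <- 4L * (mp$n + 1L)
  for (i in 1:10) {
    if (K * (M + 1) > max_states)
      stop("mechanistic state space exceeds cap (", K * (M + 1), " > ",
           max_states, " states); raise max_states or lower mu")
    # anchor between the basal and enhanced means to avoid underflow
    m_lo <- telegraph_mean(telegraph_params(max(mp$kon_basal, 1e-12),
                                            mp$k_off, mp$mu, mp$delta))
    ref_m <- min(as.integer(M), max(0L, as.integer(round((m_lo + m1) / 2))))
    sol <- .mechanistic_stationary_cpp(mp$k_close, mp$k_far, mp$k_forward,
                                       mp$k_back, mp$n, mp$kon_basal,
                                       mp$kon_enh, mp$k_off, mp$mu, mp$delta,
                                       as.integer(M), ref_m)
    pmf <- sol$pmf
    r <- if (pmf[M] > 0) pmf[M + 1] / pmf[M] else 0
    tail_est <- if (r > 0 && r < 1) pmf[M + 1] * r / (1 - r) else pmf[M + 1]
    if (is.finite(tail_est) && tail_est < tail_mass) {
      attr(pmf, "step_occ") <- sol$step_occ
      attr(pmf, "joint_cp") <- sol$joint_cp
      return(pmf)
    }
    M <- 2L * M
  }
  stop("mechanistic_pmf truncation did not converge")
}

#' Stationary mRNA distribution of the mechanistic model
#'
#' Solves the stationary linear system of the full CTMC over
#' (contact) x (step) x (promoter) x (mRNA count), with the mRNA truncation
#' grown until the estimated lost tail mass is below `tail_mass`. The
#' marginal over mRNA counts is returned; the stationary contact x promoter
#' joint table and the step occupancy are attached as attributes
#' `joint_cp` and `step_occ`.
#'
#' @inheritParams gillespie_simulate
#' @param tail_mass truncation tolerance in `(0, 1e-4]`.
#' @param min_length minimum support length of the returned pmf.
#' @param max_states cap on the total state-space size (error above it).
#' @return Probability vector over counts `0..M`, class `count_pmf`.
#' @export
mechanistic_pmf <- function(mp, tail_mass = 1e-6, min_length = 0L,
                            max_states = 5e5) {
  stopifnot(inherits(mp, "mechanistic_params"))
  if (!(tail_mass > 0 && tail_mass <= 1e-4))
    stop("tail_mass must lie in (0, 1e-4]")
  p <- .mechanistic_pmf_core(mp, tail_mass, as.integer(min_length),
                             max_states)
  class(p) <- "count_pmf"
  p
}

#' Stationary correlation between contact and promoter activity
#'
#' Lag-zero Pearson correlation between the contact indicator and the
#' promoter-ON indicator under the stationary law of the mechanistic chain.
#' In the separated-timescale regime contacts are averaged out long before
#' the promoter switches, so this correlation is near zero: contacts do not
#' coincide with transcription bursts.
#'
#' @inheritParams mechanistic_pmf
#' @return Correlation in \[-1, 1\].
#' @export
contact_activity_correlation <- function(mp, tail_mass = 1e-6) {
  p <- mechanistic_pmf(mp, tail_mass)
  j <- attr(p, "joint_cp")
  if (is.null(j)) return(0)  # degenerate reduction: layers decoupled exactly
  pc <- sum(j[2, ])  # P(contact = close)
  pon <- sum(j[, 2]) # P(promoter = ON)
  cov <- j[2, 2] - pc * pon
  den <- sqrt(pc * (1 - pc) * pon * (1 - pon))
  if (den == 0) return(0)
  cov / den
}

# stationary occupancy of the top state of an (n+1)-state birth-death chain
# with uniform bias ratio r between forward and backward rates
.top_occupancy <- function(r, n) {
  ifelse(abs(r - 1) < 1e-9, 1 / (n + 1),
         ifelse(r < 1,
                r^n * (1 - r) / (1 - r^(n + 1)),
                (1 - 1 / r) / (1 - r^-(n + 1))))  # overflow-safe for r > 1
}

#' Apparent on rate of the reduced two-state model
#'
#' Under timescale separation (contacts much faster than regulatory steps,
#' both much faster than promoter bursting), the mechanistic model reduces
#' to a two-state model whose on rate depends on contact probability `p`
#' through the stationary occupancy of the completed-step state:
#' `kon_app(p) = kon_basal + (kon_enh - kon_basal) * pi_n(beta * p)` where
#' `pi_n(r) = r^n (1 - r) / (1 - r^(n+1))` (and `1/(n+1)` at `r = 1`) is the
#' top-state occupancy of an (n+1)-state birth-death chain with bias `r`.
#' For `n >= 2` and `beta > 1` the response is sigmoidal in `p`.
#'
#' @param p contact probability (vectorized), each in \[0, 1\].
#' @param beta step bias ratio `k_forward / k_back`, >= 0.
#' @param n number of regulatory steps, integer >= 1.
#' @param kon_basal,kon_enh basal and enhanced on rates.
#' @return Numeric vector of apparent on rates.
#' @export
#' @examples
#' apparent_kon(c(0, 0.5, 1), beta = 7, n = 5, kon_basal = 0.15, kon_enh = 2)
apparent_kon <- function(p, beta, n, kon_basal, kon_enh) {
  stopifnot(beta >= 0, n >= 1)
  if (any(p < 0 | p > 1)) stop("contact probabilities must lie in [0, 1]")
  r <- beta * p
  r[p == 0] <- 0  # covers beta = Inf (k_back = 0) at p = 0
  kon_basal + (kon_enh - kon_basal) * .top_occupancy(r, as.integer(n))
}

#' Scale mechanistic rates into the separated-timescale regime
#'
#' Applies the two-level separation with a single knob `eps`: contact rates
#' are multiplied by `1/eps^2`, regulatory-step rates by `1/eps`, and
#' promoter/mRNA rates are left unscaled, so `eps -> 0` realizes
#' contacts >> steps >> bursting.
#'
#' @param mp a [mechanistic_params()] object.
#' @param eps separation factor in `(0, 1]`.
#' @return A scaled [mechanistic_params()] object.
#' @export
scale_separation <- function(mp, eps) {
  stopifnot(inherits(mp, "mechanistic_params"), eps > 0, eps <= 1)
  mechanistic_params(mp$k_close / eps^2, mp$k_far / eps^2,
                     mp$k_forward / eps, mp$k_back / eps, mp$n,
                     mp$kon_basal, mp$kon_enh, mp$k_off, mp$mu, mp$delta)
}

#' Total-variation distance between two count pmfs
#'
#' @param p,q probability vectors (padded with zeros to a common length).
#' @return TV distance in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  L <- max(length(p), length(q))
  p <- c(p, rep(0, L - length(p)))
  q <- c(q, rep(0, L - length(q)))
  0.5 * sum(abs(p - q))
}

#' Error of the apparent two-state reduction
#'
#' Total-variation distance between the stationary mRNA distribution of the
#' mechanistic model scaled into the separated regime (see
#' [scale_separation()]) and the telegraph model with on rate
#' [apparent_kon()] at the chain's steady-state contact probability. The
#' distance shrinks as `eps` decreases.
#'
#' @inheritParams scale_separation
#' @param tail_mass pmf truncation tolerance.
#' @return TV distance between the two stationary distributions.
#' @export
reduction_error <- function(mp, eps = 1, tail_mass = 1e-6) {
  stopifnot(inherits(mp, "mechanistic_params"))
  sc <- scale_separation(mp, eps)
  p_mech <- mechanistic_pmf(sc, tail_mass)
  pc <- steady_contact_probability(mp)
  kon <- apparent_kon(pc, mp$beta, mp$n, mp$kon_basal, mp$kon_enh)
  p_tel <- telegraph_pmf(telegraph_params(kon, mp$k_off, mp$mu, mp$delta),
                         tail_mass)
  tv_distance(p_mech, p_tel)
}
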