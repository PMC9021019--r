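# shared fixtures built in code

# a generic bursty telegraph parameter set (super-Poissonian)
tp_generic <- function() telegraph_params(k_on = 1, k_off = 1, mu = 10)

# random telegraph parameters in a moderate range
random_tp <- function() {
  telegraph_params(k_on = exp(stats::runif(1, log(0.1), log(5))),
                   k_off = exp(stats::runif(1, log(0.1), log(5))),
                   mu = stats::runif(1, 2, 40))
}

# random mechanistic parameters with tiered base rates: contacts above
# steps above promoter/bursting rates, the ordering under which the
# apparent two-state reduction is derived
random_mech <- function() {
  mechanistic_params(
    k_close = exp(stats::runif(1, log(8), log(24))),
    k_far = exp(stats::runif(1, log(8), log(24))),
    k_forward = exp(stats::runif(1, log(2), log(6))),
    k_back = exp(stats::runif(1, log(2), log(6))),
    n = sample(1:5, 1),
    kon_basal = stats::runif(1, 0.05, 0.3),
    kon_enh = stats::runif(1, 0.5, 2),
    k_off = stats::runif(1, 0.3, 1.5),
    mu = stats::runif(1, 5, 50))
}

# a small noiseless screen + exact-expectation FISH dataset generated
# directly from the Hill-modulated telegraph model (no sampling noise)
noiseless_study <- function(truth = list(kon0 = 0.15, kon1 = 2, k_off = 10,
                                         mu = 360, c = 0.25, h = 2.8),
                            n_lines = 50, fish_p = c(0, 0.1, 0.2, 0.5, 1),
                            cells = 300) {
  p <- seq(0.02, 1, length.out = n_lines)
  hp <- hill_params(truth$kon0, truth$kon1, truth$c, truth$h)
  mean_fun <- function(pp) {
    kon <- hill_response(pp, hp)
    truth$mu * kon / (kon + truth$k_off)
  }
  screen <- screen_dataset(data.frame(
    id = sprintf("N%02d", seq_along(p)), p_c = p, mean = mean_fun(p),
    sd = 0, n_rep = 1L))
  hists <- lapply(fish_p, function(pp) {
    kon <- hill_response(pp, hp)
    pmf <- telegraph_pmf(telegraph_params(kon, truth$k_off, truth$mu),
                         tail_mass = 1e-8)
    as.numeric(pmf) * cells  # exact expected histogram
  })
  fish <- fish_dataset(sprintf("F%d", seq_along(fish_p)), fish_p,
                       hist = hists)
  list(screen = screen, fish = fish, truth = truth)
}
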