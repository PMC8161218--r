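# Independent oracles, kept deliberately separate from the package's code
# paths: literal one-line formula evaluations and a brute-force uniroot
# psychrometer solver.

# literal fitted-index formula, term by term in one expression
oracle_etis <- function(t, rh, u) {
  t + 0.0006 * (rh - 50) * t - 0.3132 * u^0.6827 * (38 - t) -
    4.79 * (1.0086 * 38 - t) +
    4.8957e-8 * ((38 + 273.15)^4 - (t + 273.15)^4)
}

oracle_svp <- function(t) 6.1078 * 10^(7.5 * t / (237.3 + t))

oracle_dew_point <- function(t, rh) {
  x <- log10(rh / 100 * oracle_svp(t) / 6.1078)
  237.3 * x / (7.5 - x)
}

# brute-force psychrometer equation solve (Assmann coefficient), scalar
oracle_wet_bulb <- function(t, rh, p_hpa = 1013.25) {
  mapply(function(t, rh) {
    e <- rh / 100 * oracle_svp(t)
    f <- function(tw) {
      oracle_svp(tw) - 6.62e-4 * (1 + 0.00115 * tw) * p_hpa * (t - tw) - e
    }
    if (rh >= 100) return(t)
    stats::uniroot(f, c(oracle_dew_point(t, rh) - 1e-9, t),
                   tol = 1e-11)$root
  }, t, rh)
}

# random valid moist-air states
random_states <- function(n, seed, t_range = c(-10, 50),
                          rh_range = c(1, 100)) {
  set.seed(seed)
  data.frame(t = runif(n, t_range[1], t_range[2]),
             rh = runif(n, rh_range[1], rh_range[2]))
}
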