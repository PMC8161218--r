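# Synthetic barn-like environment/physiology data.
#
# Marginals are moment-matched truncated normals: the underlying normal
# location/scale are solved numerically so the *truncated* distribution
# hits the target mean/sd (naive clipping would bias both).  Temperature
# and humidity are tied by a Gaussian copula (modest negative dependence by
# default); air velocity is independent.  Physiology is generated from the
# fitted index / THI with noise scales solved from target squared
# correlations given the realized index variance.

# Truncated-normal moments for underlying N(mu, sigma) on [lo, hi].
.tn_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Solve for underlying (mu, sigma) whose truncation to [lo, hi] best
# matches the target moments.  Exact for mild truncation; for severe
# truncation the least-squares optimum (closest achievable moments) is
# returned with the achieved values attached.
.tn_solve <- function(mean, sd, lo, hi) {
  if (!(lo < mean && mean < hi)) {
    stop("infeasible moment target: mean ", mean, " outside bounds [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  if (sd <= 0) stop("sd target must be positive", call. = FALSE)
  obj <- function(p) {
    mm <- .tn_moments(p[1], exp(p[2]), lo, hi)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(maxit = 5000, reltol = 1e-15))
  o2 <- stats::optim(o$par, obj, control = list(maxit = 5000,
                                                reltol = 1e-15))
  mu <- o2$par[1]; sigma <- exp(o2$par[2])
  list(mu = mu, sigma = sigma, lo = lo, hi = hi,
       achieved = .tn_moments(mu, sigma, lo, hi),
       target = c(mean = mean, sd = sd))
}

# Inverse-CDF truncated-normal draw from uniforms, computed on the upper
# tail so that extreme truncation (survival probabilities ~1e-12) keeps
# full precision.
.tn_quantile <- function(p, sol) {
  s_lo <- stats::pnorm((sol$lo - sol$mu) / sol$sigma, lower.tail = FALSE)
  s_hi <- stats::pnorm((sol$hi - sol$mu) / sol$sigma, lower.tail = FALSE)
  s <- s_lo + p * (s_hi - s_lo)
  q <- sol$mu + sol$sigma * stats::qnorm(s, lower.tail = FALSE)
  pmin(pmax(q, sol$lo), sol$hi)
}

#' Barn data generator configuration
#'
#' Defines the study conditions emulated by the generator: per-variable
#' moment targets and observed ranges for air temperature, relative
#' humidity and air velocity; the temperature-humidity copula correlation;
#' and the physiological response models (skin temperature driven by the
#' fitted index, respiration rate and core temperature driven linearly by
#' THI) with noise scales solved from target squared correlations.
#'
#' Defaults reproduce the summer sow-barn dataset summary: T mean 28.7 sd
#' 2.6 on [21.9, 34.0] degC; RH mean 65.8 sd 10.0 on [40.4, 89.8] percent;
#' u mean 0.07 sd 0.07 on [0, 0.29] m/s (for u the targets are infeasible
#' under truncation and the closest achievable moments, about mean 0.075 sd
#' 0.067, are used and recorded); skin temperature mean 34.9 sd 1.4 with
#' squared correlation 0.6341 on the index; respiration rate
#' `2.2137 THI - 135.98` floored at 12 breaths/min with target R^2 0.1386;
#' core temperature `0.0454 THI + 34.873` with target R^2 0.0972.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param t,rh,u Length-4 numeric vectors `c(mean, sd, min, max)` of moment
#'   targets and truncation bounds.
#' @param t_rh_cor Gaussian-copula correlation between temperature and
#'   humidity, in (-1, 1).
#' @param skin List: either moment targets `mean`, `sd`, `r2` (the default
#'   mode, which centers and scales the index-driven signal to hit them) or
#'   an explicit linear model `intercept`, `slope`, `sigma` on the index.
#' @param respiration List with `slope`, `intercept` (on THI), `r2` or
#'   explicit `sigma`, and `floor` (physiological minimum, breaths/min).
#' @param core List with `slope`, `intercept` (on THI) and `r2` or explicit
#'   `sigma`.
#' @param thi_variant THI variant driving respiration/core (and available
#'   for threshold work); the `0.8 T` form by default, the variant whose
#'   pregnancy-rate breakpoints anchor the classifier.
#' @param params [etis_params()] set defining the skin-temperature signal.
#' @return Object of class `"barn_config"`.
#' @export
barn_config <- function(n = 1029, seed = 1L,
                        t = c(mean = 28.7, sd = 2.6, min = 21.9, max = 34.0),
                        rh = c(mean = 65.8, sd = 10.0, min = 40.4, max = 89.8),
                        u = c(mean = 0.07, sd = 0.07, min = 0, max = 0.29),
                        t_rh_cor = -0.3,
                        skin = list(mean = 34.9, sd = 1.4, r2 = 0.6341),
                        respiration = list(slope = 2.2137,
                                           intercept = -135.98,
                                           r2 = 0.1386, floor = 12),
                        core = list(slope = 0.0454, intercept = 34.873,
                                    r2 = 0.0972),
                        thi_variant = "thi_b",
                        params = etis_params()) {
  stopifnot(n >= 1, length(t) == 4, length(rh) == 4, length(u) == 4)
  if (abs(t_rh_cor) >= 1) {
    stop("t_rh_cor must lie in (-1, 1)", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 t = unname(t), rh = unname(rh), u = unname(u),
                 t_rh_cor = t_rh_cor, skin = skin,
                 respiration = respiration, core = core,
                 thi_variant = thi_variant, params = params),
            class = "barn_config")
}

#' Generate synthetic barn environment records
#'
#' Draws `config$n` records with moment-matched truncated-normal marginals
#' and a Gaussian-copula temperature-humidity dependence.  Reproducible per
#' seed; a provenance block (config echo plus the solved marginal
#' parameters and their achieved moments) is attached as attribute
#' `"generator"`.
#'
#' @param config A [barn_config()].
#' @return Data frame with `record_id`, `air_temperature_C`,
#'   `relative_humidity_pct`, `air_velocity_ms`.
#' @examples
#' env <- generate_environment(barn_config(n = 500, seed = 1))
#' colMeans(env[-1])
#' @export
generate_environment <- function(config = barn_config()) {
  stopifnot(inherits(config, "barn_config"))
  sol <- list(t = .tn_solve(config$t[1], config$t[2], config$t[3],
                            config$t[4]),
              rh = .tn_solve(config$rh[1], config$rh[2], config$rh[3],
                             config$rh[4]),
              u = .tn_solve(config$u[1], config$u[2], config$u[3],
                            config$u[4]))
  n <- config$n
  set.seed(config$seed)
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  rho <- config$t_rh_cor
  z2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  env <- data.frame(
    record_id = seq_len(n),
    air_temperature_C = .tn_quantile(stats::pnorm(z[, 1]), sol$t),
    relative_humidity_pct = .tn_quantile(stats::pnorm(z2), sol$rh),
    air_velocity_ms = .tn_quantile(stats::runif(n), sol$u))
  attr(env, "generator") <- list(config = config, marginals = sol)
  env
}

# Noise sd giving target squared correlation r2 for a signal of variance
# var_sig:  r2 = var_sig / (var_sig + sigma^2).
.sigma_for_r2 <- function(var_sig, r2) sqrt(var_sig * (1 - r2) / r2)

#' Generate synthetic sow physiology for environment records
#'
#' Skin temperature is an index-driven signal plus Gaussian noise: by
#' default the fitted-index values are centered and scaled so the skin
#' series hits its target mean/sd with the target squared correlation on
#' the index; an explicit `intercept`/`slope`/`sigma` model can be supplied
#' instead.  Respiration rate and core temperature are linear in THI with
#' noise solved from their target squared correlations given the realized
#' THI variance; respiration is floored at the configured physiological
#' minimum.
#'
#' @param env Environment records from [generate_environment()].
#' @param config The same [barn_config()].
#' @return Data frame with `skin_temperature_C`, `respiration_rate_bpm`,
#'   `core_temperature_C`; generation metadata (signal coefficients and
#'   solved noise scales) attached as attribute `"generator"`.
#' @export
generate_physiology <- function(env, config = barn_config()) {
  stopifnot(inherits(config, "barn_config"))
  if (nrow(env) == 0) stop("empty environment records", call. = FALSE)
  n <- nrow(env)
  idx <- etis(env$air_temperature_C, env$relative_humidity_pct,
              env$air_velocity_ms, config$params)
  thi_v <- thi(env$air_temperature_C, env$relative_humidity_pct,
               config$thi_variant)

  sk <- config$skin
  explicit <- !is.null(sk$sigma) && !is.null(sk$slope)
  if (explicit) {
    skin_signal <- (if (is.null(sk$intercept)) 0 else sk$intercept) +
      sk$slope * idx
    sigma_skin <- sk$sigma
    skin_meta <- c(intercept = if (is.null(sk$intercept)) 0 else
      sk$intercept, slope = sk$slope, sigma = sigma_skin)
  } else {
    # center/scale the index signal to the target skin moments: slope
    # sd * sqrt(r2) / sd(index) and noise sd * sqrt(1 - r2)
    slope <- sk$sd * sqrt(sk$r2) / stats::sd(idx)
    skin_signal <- sk$mean + slope * (idx - mean(idx))
    sigma_skin <- sk$sd * sqrt(1 - sk$r2)
    skin_meta <- c(intercept = sk$mean - slope * mean(idx), slope = slope,
                   sigma = sigma_skin)
  }

  rr <- config$respiration
  rr_signal <- rr$slope * thi_v + rr$intercept
  sigma_rr <- if (!is.null(rr$sigma)) rr$sigma else
    .sigma_for_r2(rr$slope^2 * stats::var(thi_v), rr$r2)
  co <- config$core
  core_signal <- co$slope * thi_v + co$intercept
  sigma_core <- if (!is.null(co$sigma)) co$sigma else
    .sigma_for_r2(co$slope^2 * stats::var(thi_v), co$r2)

  set.seed(config$seed + 1L)
  out <- data.frame(
    skin_temperature_C = skin_signal + stats::rnorm(n, 0, sigma_skin),
    respiration_rate_bpm = pmax(rr_signal + stats::rnorm(n, 0, sigma_rr),
                                rr$floor),
    core_temperature_C = core_signal + stats::rnorm(n, 0, sigma_core))
  attr(out, "generator") <- list(skin = skin_meta,
                                 sigma_rr = sigma_rr,
                                 sigma_core = sigma_core)
  out
}

#' Simulate a complete synthetic barn dataset
#'
#' Convenience wrapper: environment plus physiology, column-bound into one
#' barn record table.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param config Optional full [barn_config()]; `n` and `seed` are taken
#'   from it when supplied.
#' @return Data frame with environment and physiology columns; provenance
#'   attached as attribute `"generator"`.
#' @examples
#' d <- simulate_barn(n = 100, seed = 42)
#' head(d)
#' @export
simulate_barn <- function(n = 1029, seed = 1L, config = NULL) {
  if (is.null(config)) config <- barn_config(n = n, seed = seed)
  env <- generate_environment(config)
  phys <- generate_physiology(env, config)
  out <- cbind(env, phys)
  attr(out, "generator") <- c(attr(env, "generator"),
                              physiology = list(attr(phys, "generator")))
  out
}
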