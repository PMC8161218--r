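# Moist-air conversions used by the comparison indices.
#
# Saturation vapor pressure uses the Magnus-Tetens base-10 form
#   es(t) = 6.1078 * 10^(7.5 t / (237.3 + t))   [hPa, t in degC]
# which is also the exponent structure of the moist-air enthalpy index.

.MAGNUS <- c(es0 = 6.1078, a = 7.5, b = 237.3)

# declared validity window for dry-bulb inputs, degC
.T_WINDOW <- c(-20, 60)

.check_temperature <- function(t, what = "temperature") {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop(what, " must be finite numeric", call. = FALSE)
  }
  if (any(t < .T_WINDOW[1] | t > .T_WINDOW[2])) {
    stop(what, " outside validity window [", .T_WINDOW[1], ", ",
         .T_WINDOW[2], "] degC", call. = FALSE)
  }
  invisible(t)
}

.check_rh <- function(rh, allow_zero = FALSE) {
  if (!is.numeric(rh) || any(!is.finite(rh))) {
    stop("relative humidity must be finite numeric", call. = FALSE)
  }
  lo_ok <- if (allow_zero) rh >= 0 else rh > 0
  if (any(!lo_ok | rh > 100)) {
    stop("relative humidity must lie in ",
         if (allow_zero) "[0, 100]" else "(0, 100]", call. = FALSE)
  }
  invisible(rh)
}

#' Saturation vapor pressure of moist air
#'
#' Magnus-Tetens approximation over liquid water, valid for dry-bulb
#' temperatures between -20 and 60 degC.
#'
#' @param t Dry-bulb temperature, degC.
#' @return Saturation vapor pressure, hPa.
#' @examples
#' saturation_vapor_pressure(0)    # ~6.11 hPa
#' saturation_vapor_pressure(28.7)
#' @export
saturation_vapor_pressure <- function(t) {
  .check_temperature(t)
  .MAGNUS[["es0"]] * 10^(.MAGNUS[["a"]] * t / (.MAGNUS[["b"]] + t))
}

#' Dew-point temperature
#'
#' Analytic inversion of the Magnus-Tetens saturation curve: the dew point
#' is the temperature at which the actual vapor pressure
#' `rh/100 * es(t)` saturates.
#'
#' @param t Dry-bulb temperature, degC.
#' @param rh Relative humidity, percent, in (0, 100].
#' @return Dew-point temperature, degC; equals `t` iff `rh == 100`.
#' @examples
#' dew_point(25, 100)      # 25
#' dew_point(28.7, 65.8)   # ~21.66
#' @export
dew_point <- function(t, rh) {
  .check_temperature(t)
  .check_rh(rh)
  e <- rh / 100 * saturation_vapor_pressure(t)
  x <- log10(e / .MAGNUS[["es0"]])
  .MAGNUS[["b"]] * x / (.MAGNUS[["a"]] - x)
}

# Stull's closed-form wet-bulb approximation (sea-level fit).
.wet_bulb_stull <- function(t, rh) {
  t * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(t + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
}

# Assmann psychrometer coefficient, 1/degC (WMO ventilated psychrometer).
.psy_A <- function(tw) 6.62e-4 * (1 + 0.00115 * tw)

#' Wet-bulb temperature
#'
#' Solves the Assmann psychrometer relation
#' `e = es(tw) - A(tw) * P * (t - tw)` for `tw` by Newton iteration,
#' started from Stull's closed-form approximation.  `method = "stull"`
#' returns the closed form itself (fastest, accurate to a few tenths of a
#' degree near sea level at moderate humidities); `method = "psychrometer"`
#' skips the closed-form start.
#'
#' @param t Dry-bulb temperature, degC.
#' @param rh Relative humidity, percent, in (0, 100].
#' @param pressure Barometric pressure, kPa (default one standard
#'   atmosphere).
#' @param method One of `"auto"` (default; psychrometer solution seeded by
#'   the closed form), `"stull"`, `"psychrometer"`.
#' @return Wet-bulb temperature, degC, satisfying
#'   `dew_point(t, rh) <= tw <= t` with equality at saturation.
#' @examples
#' wet_bulb(25, 100)      # 25
#' wet_bulb(28.7, 65.8)   # ~23.7
#' @export
wet_bulb <- function(t, rh, pressure = 101.325,
                     method = c("auto", "stull", "psychrometer")) {
  method <- match.arg(method)
  .check_temperature(t)
  .check_rh(rh)
  if (!is.numeric(pressure) || any(pressure <= 0)) {
    stop("pressure must be positive (kPa)", call. = FALSE)
  }
  n <- max(length(t), length(rh))
  t <- rep_len(t, n); rh <- rep_len(rh, n)
  p_hpa <- rep_len(pressure * 10, n)

  if (method == "stull") {
    out_of_fit <- rh < 5 | rh > 99 | t < -20 | t > 50
    if (any(out_of_fit)) {
      warning("relative humidity/temperature outside the closed-form fit ",
              "range; falling back to the iterative psychrometer solution")
    }
    tw <- .wet_bulb_stull(t, rh)
    if (any(out_of_fit)) {
      tw[out_of_fit] <- wet_bulb(t[out_of_fit], rh[out_of_fit],
                                 pressure, method = "psychrometer")
    }
    return(tw)
  }

  tdp <- dew_point(t, rh)
  e <- rh / 100 * saturation_vapor_pressure(t)
  tw <- if (method == "auto") pmin(.wet_bulb_stull(t, rh), t) else (t + tdp) / 2
  tw <- pmax(tw, tdp)
  # f(tw) = es(tw) - A(tw) P (t - tw) - e is strictly increasing on [tdp, t]
  ln10 <- log(10)
  for (i in seq_len(25L)) {
    es_tw <- .MAGNUS[["es0"]] * 10^(.MAGNUS[["a"]] * tw / (.MAGNUS[["b"]] + tw))
    f <- es_tw - .psy_A(tw) * p_hpa * (t - tw) - e
    des <- es_tw * ln10 * .MAGNUS[["a"]] * .MAGNUS[["b"]] / (.MAGNUS[["b"]] + tw)^2
    df <- des + .psy_A(tw) * p_hpa - 6.62e-4 * 0.00115 * p_hpa * (t - tw)
    step <- f / df
    tw <- pmin(pmax(tw - step, tdp), t)
    if (max(abs(step)) < 1e-12) break
  }
  tw
}
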