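# The equivalent temperature index for sows (ETIS).
#
# ETIS = T + T_rh + T_u + T_f + T_r: dry-bulb air temperature plus
# equivalent-temperature increments for relative humidity, air velocity
# (convection), floor conduction and long-wave radiation.  Each increment
# is the air-temperature change with the same thermal-load effect as the
# corresponding non-temperature factor.

#' ETIS coefficient set
#'
#' Constructs the parameter set defining an ETIS instance.  The defaults
#' are the published fitted constants for lactating-type sows on solid
#' concrete floors:
#' \deqn{ETIS = T + 0.0006 (RH - 50) T - 0.3132 u^{0.6827} (38 - T)
#'       - 4.79 (1.0086 \cdot 38 - T)
#'       + 4.8957 \times 10^{-8} ((38 + 273.15)^4 - (T + 273.15)^4)}
#'
#' @param a Humidity coefficient (dimensionless), multiplies `(RH - 50) T`.
#' @param e Velocity coefficient (dimensionless); negative values cool when
#'   air temperature is below skin temperature.
#' @param c Velocity exponent (> 0); the convective power-law exponent for
#'   a recumbent sow.
#' @param d Conduction coefficient (dimensionless).
#' @param r_rad Radiation coefficient, degC K^-4, applied to the difference
#'   of fourth-power absolute temperatures.
#' @param ts Reference skin temperature, degC, in (30, 42).
#' @param conduction_ref Dimensionless multiplier applied to `ts` inside the
#'   fitted conduction term (`1.0086` in the fitted index; `1` gives the
#'   plain gradient form `d (ts - t)`).
#' @param r_rad_skin,r_rad_air Optional distinct radiation coefficients for
#'   the skin-side and air-side fourth-power terms (the two-coefficient
#'   variant of the calibration output).  When both are supplied they
#'   override `r_rad`.
#' @return An object of class `"etis_params"`.
#' @examples
#' etis_params()                   # fitted defaults
#' etis_params(a = 0, e = 0, d = 0, r_rad = 0)  # degenerate: ETIS == T
#' @export
etis_params <- function(a = 0.0006, e = -0.3132, c = 0.6827,
                        d = -4.79, r_rad = 4.8957e-8, ts = 38,
                        conduction_ref = 1.0086,
                        r_rad_skin = NULL, r_rad_air = NULL) {
  stopifnot(is.numeric(a), is.numeric(e), is.numeric(c), is.numeric(d),
            is.numeric(r_rad), is.numeric(ts), is.numeric(conduction_ref))
  if (c <= 0) stop("velocity exponent 'c' must be positive", call. = FALSE)
  if (ts <= 30 || ts >= 42) {
    stop("reference skin temperature must lie in (30, 42) degC", call. = FALSE)
  }
  two_coef <- !is.null(r_rad_skin) && !is.null(r_rad_air)
  if (xor(is.null(r_rad_skin), is.null(r_rad_air))) {
    stop("supply both r_rad_skin and r_rad_air, or neither", call. = FALSE)
  }
  structure(
    list(a = a, e = e, c = c, d = d, r_rad = r_rad, ts = ts,
         conduction_ref = conduction_ref,
         r_rad_skin = if (two_coef) r_rad_skin,
         r_rad_air = if (two_coef) r_rad_air),
    class = "etis_params")
}

#' @export
print.etis_params <- function(x, ...) {
  cat("ETIS coefficient set\n")
  cat(sprintf("  humidity      a      = %.6g\n", x$a))
  cat(sprintf("  velocity      e      = %.6g  (exponent c = %.6g)\n", x$e, x$c))
  cat(sprintf("  conduction    d      = %.6g  (reference factor %.6g)\n",
              x$d, x$conduction_ref))
  if (is.null(x$r_rad_skin)) {
    cat(sprintf("  radiation     r_rad  = %.6g degC/K^4\n", x$r_rad))
  } else {
    cat(sprintf("  radiation     skin %.6g / air %.6g degC/K^4\n",
                x$r_rad_skin, x$r_rad_air))
  }
  cat(sprintf("  reference skin temperature ts = %.4g degC\n", x$ts))
  invisible(x)
}

#' Equivalent temperature for relative humidity
#'
#' `a * (rh - 50) * t`: zero at 50 percent relative humidity, warming above
#' it (for `a > 0`), cooling below.
#'
#' @param t Dry-bulb air temperature, degC.
#' @param rh Relative humidity, percent, in `[0, 100]`.
#' @param a Humidity coefficient.
#' @return Equivalent temperature increment, degC.
#' @export
teq_humidity <- function(t, rh, a = 0.0006) {
  .check_rh(rh, allow_zero = TRUE)
  a * (rh - 50) * t
}

#' Equivalent temperature for air velocity
#'
#' `e * u^c * (ts - t)`: the convective term, zero in still air or when the
#' air is at skin temperature.  With `e < 0` and `t < ts`, faster air cools.
#'
#' @param t Dry-bulb air temperature, degC.
#' @param u Air velocity, m/s (>= 0).
#' @param ts Skin (reference) temperature, degC.
#' @param e Velocity coefficient.
#' @param c Velocity exponent.
#' @return Equivalent temperature increment, degC.
#' @export
teq_velocity <- function(t, u, ts = 38, e = -0.3132, c = 0.6827) {
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("air velocity must be finite and >= 0", call. = FALSE)
  }
  e * u^c * (ts - t)
}

#' Equivalent temperature for floor conduction
#'
#' `d * (conduction_ref * ts - t)`.  With `conduction_ref = 1` this is the
#' plain gradient form `d (ts - t)`, zero when the floor (taken at air
#' temperature) matches skin temperature; the fitted index uses
#' `conduction_ref = 1.0086`.
#'
#' @param t Floor surface temperature, degC (air temperature under the
#'   indoor assumption).
#' @param ts Skin (reference) temperature, degC.
#' @param d Conduction coefficient.
#' @param conduction_ref Reference multiplier on `ts`.
#' @return Equivalent temperature increment, degC.
#' @export
teq_conduction <- function(t, ts = 38, d = -4.79, conduction_ref = 1) {
  d * (conduction_ref * ts - t)
}

#' Equivalent temperature for long-wave radiation
#'
#' `r_rad * ((ts + 273.15)^4 - (t + 273.15)^4)`: the Kelvin fourth-power
#' radiant exchange between skin and surroundings, zero when the two
#' temperatures agree and antisymmetric in their exchange.
#'
#' @param t Mean radiant temperature, degC (air temperature under the
#'   indoor assumption); must exceed absolute zero.
#' @param ts Skin (reference) temperature, degC.
#' @param r_rad Radiation coefficient, degC K^-4.
#' @return Equivalent temperature increment, degC.
#' @export
teq_radiation <- function(t, ts = 38, r_rad = 4.8957e-8) {
  if (any(t <= -273.15) || any(ts <= -273.15)) {
    stop("temperatures must exceed absolute zero", call. = FALSE)
  }
  r_rad * ((ts + 273.15)^4 - (t + 273.15)^4)
}

#' Equivalent temperature index for sows
#'
#' Evaluates the general parameterized index
#' `ETIS = T + T_rh + T_u + T_f + T_r` for vectors of environmental
#' readings.  Floor and mean radiant temperatures default to air
#' temperature (the usual indoor assumption); supplying them replaces air
#' temperature inside the conduction and radiation terms only.
#'
#' @param t Dry-bulb air temperature, degC.
#' @param rh Relative humidity, percent.
#' @param u Air velocity, m/s.
#' @param params An [etis_params()] coefficient set.
#' @param floor_temp Optional floor surface temperature, degC.
#' @param radiant_temp Optional mean radiant temperature, degC.
#' @param components If `TRUE`, return a data frame with the four
#'   equivalent-temperature terms, the base air temperature and the index;
#'   otherwise the index vector.
#' @return Numeric vector of index values (degC), or a data frame when
#'   `components = TRUE`.
#' @examples
#' etis(28.7, 65.8, 0.07)                     # ~34.84
#' etis(28.7, 65.8, 0.07, components = TRUE)
#' @export
etis <- function(t, rh, u, params = etis_params(),
                 floor_temp = NULL, radiant_temp = NULL,
                 components = FALSE) {
  stopifnot(inherits(params, "etis_params"))
  n <- max(length(t), length(rh), length(u))
  t <- rep_len(t, n); rh <- rep_len(rh, n); u <- rep_len(u, n)
  t_floor <- if (is.null(floor_temp)) t else rep_len(floor_temp, n)
  t_rad <- if (is.null(radiant_temp)) t else rep_len(radiant_temp, n)

  t_rh <- teq_humidity(t, rh, params$a)
  t_u <- teq_velocity(t, u, params$ts, params$e, params$c)
  t_f <- teq_conduction(t_floor, params$ts, params$d, params$conduction_ref)
  t_r <- if (is.null(params$r_rad_skin)) {
    teq_radiation(t_rad, params$ts, params$r_rad)
  } else {
    params$r_rad_skin * (params$ts + 273.15)^4 -
      params$r_rad_air * (t_rad + 273.15)^4
  }
  out <- t + t_rh + t_u + t_f + t_r
  if (components) {
    data.frame(base_t = t, t_rh = t_rh, t_u = t_u, t_f = t_f, t_r = t_r,
               etis = out)
  } else {
    out
  }
}

#' Fitted ETIS
#'
#' Direct evaluation of the published fitted index (humidity coefficient
#' 0.0006, velocity term -0.3132 u^0.6827, conduction -4.79 with reference
#' factor 1.0086, radiation 4.8957e-8).  Identical to
#' `etis(t, rh, u, etis_params())` to within floating-point roundoff.
#'
#' @inheritParams etis
#' @return Numeric vector of index values, degC.
#' @examples
#' etis_fitted(28.7, 65.8, 0.07)  # ~34.84
#' @export
etis_fitted <- function(t, rh, u) {
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("air velocity must be finite and >= 0", call. = FALSE)
  }
  t + 0.0006 * (rh - 50) * t - 0.3132 * u^0.6827 * (38 - t) -
    4.79 * (1.0086 * 38 - t) +
    4.8957e-8 * ((38 + 273.15)^4 - (t + 273.15)^4)
}
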