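# Classical thermal-comfort indices used to benchmark ETIS: eight
# temperature-humidity index (THI) variants, the black-globe humidity
# index, effective temperature for pigs and moist-air enthalpy.
#
# Fahrenheit-native variants (thi_d, thi_f) convert the dry bulb to degF
# internally and report on their native scale: their published stress
# breakpoints are scale-specific, so values are never silently converted.

.f_of_c <- function(t) 1.8 * t + 32

#' Temperature-humidity index variants
#'
#' Evaluates one of the eight classical THI formulations:
#' \describe{
#'   \item{thi_a}{`T + 0.36 Twb + 41.5`}
#'   \item{thi_b}{`0.8 T + RH (T - 14.4)/100 + 46.4`}
#'   \item{thi_c}{`0.65 T + 0.35 Twb`}
#'   \item{thi_d}{`Tf - (0.55 - 0.0055 RH) (Tf - 58)` with `Tf` in degF
#'     (reported in degF)}
#'   \item{thi_e}{`0.72 T + 0.72 Twb + 40.6`}
#'   \item{thi_f}{`Tf - 0.55 (RH/100) (Tf - 58)` with `Tf` in degF
#'     (reported in degF)}
#'   \item{thi_g}{`T - (0.55 - 0.0055 RH) (T - 14.5)`}
#'   \item{thi_h}{`0.27 T + 1.35 Twb + 34.07`}
#' }
#' Wet-bulb temperatures are derived with [wet_bulb()].
#'
#' @param t Dry-bulb temperature, degC.
#' @param rh Relative humidity, percent.
#' @param variant One of `"thi_a"` ... `"thi_h"`.
#' @param pressure Barometric pressure, kPa (for the wet-bulb conversion).
#' @return Index values on the variant's native scale.
#' @examples
#' thi(28.7, 65.8, "thi_b")  # ~78.77
#' @export
thi <- function(t, rh, variant = "thi_b", pressure = 101.325) {
  switch(variant,
    thi_a = t + 0.36 * wet_bulb(t, rh, pressure) + 41.5,
    thi_b = 0.8 * t + rh * (t - 14.4) / 100 + 46.4,
    thi_c = 0.65 * t + 0.35 * wet_bulb(t, rh, pressure),
    thi_d = {
      tf <- .f_of_c(t)
      tf - (0.55 - 0.0055 * rh) * (tf - 58)
    },
    thi_e = 0.72 * t + 0.72 * wet_bulb(t, rh, pressure) + 40.6,
    thi_f = {
      tf <- .f_of_c(t)
      tf - 0.55 * (rh / 100) * (tf - 58)
    },
    thi_g = t - (0.55 - 0.0055 * rh) * (t - 14.5),
    thi_h = 0.27 * t + 1.35 * wet_bulb(t, rh, pressure) + 34.07,
    stop("unknown THI variant: ", variant, call. = FALSE)
  )
}

#' Black-globe humidity index
#'
#' `BGHI = Tg + 0.36 Tdp + 41.5`.  When no black-globe temperature is
#' available, the dry bulb stands in for it (the indoor mean-radiant
#' assumption), so the index degenerates to the `thi_a`-style form with the
#' dew point in place of the wet bulb.
#'
#' @param t Dry-bulb temperature, degC.
#' @param rh Relative humidity, percent (used to derive the dew point).
#' @param globe_temp Optional black-globe temperature, degC.
#' @return Index values.
#' @examples
#' bghi(28.7, 65.8)
#' bghi(28.7, 65.8, globe_temp = 30)
#' @export
bghi <- function(t, rh, globe_temp = NULL) {
  tg <- if (is.null(globe_temp)) t else globe_temp
  tg + 0.36 * dew_point(t, rh) + 41.5
}

#' Effective temperature for pigs
#'
#' `ET = T + 0.0015 (RH - 50) T - (42 - T) (u^0.66 - 0.2^0.66)`: dry bulb
#' corrected for humidity (null at 50 percent) and for air movement
#' relative to a 0.2 m/s still-air reference.  `strict_paper = TRUE`
#' evaluates the literal typeset grouping
#' `T + 0.0015 (RH - 50) T + (-42 - T (u^0.66 - 0.2^0.66))`, preserved for
#' comparison with the printed source.
#'
#' @param t Dry-bulb temperature, degC.
#' @param rh Relative humidity, percent.
#' @param u Air velocity, m/s.
#' @param strict_paper Evaluate the literal printed grouping instead of the
#'   reconstructed one.
#' @return Effective temperature, degC.
#' @examples
#' effective_temperature(30, 50, 0.2)  # 30: both corrections null
#' @export
effective_temperature <- function(t, rh, u, strict_paper = FALSE) {
  if (any(!is.finite(u)) || any(u < 0)) {
    stop("air velocity must be finite and >= 0", call. = FALSE)
  }
  vterm <- u^0.66 - 0.2^0.66
  if (strict_paper) {
    t + 0.0015 * (rh - 50) * t + (-1.0 * 42 - t * vterm)
  } else {
    t + 0.0015 * (rh - 50) * t - 1.0 * (42 - t) * vterm
  }
}

#' Moist-air enthalpy index
#'
#' `H = 1.006 T + (RH / Pm) 10^(7.5 T / (237.3 + T)) (71.28 + 0.052 T)` in
#' kJ per kg dry air, with `Pm` the barometric pressure in mmHg.
#' `strict_paper = TRUE` uses 273.3 in the exponent denominator as printed
#' in the source table (the Magnus denominator is 237.3; the printed value
#' is treated as a typo but remains reproducible).
#'
#' @param t Dry-bulb temperature, degC.
#' @param rh Relative humidity, percent.
#' @param pressure Barometric pressure, kPa; converted to mmHg internally.
#' @param strict_paper Use the printed 273.3 exponent denominator.
#' @return Enthalpy, kJ/kg dry air.
#' @examples
#' enthalpy_index(28.7, 65.8)
#' @export
enthalpy_index <- function(t, rh, pressure = 101.325, strict_paper = FALSE) {
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  pm <- pressure * 7.50062  # kPa -> mmHg
  denom <- if (strict_paper) 273.3 else 237.3
  1.006 * t + rh / pm * 10^(7.5 * t / (denom + t)) * (71.28 + 0.052 * t)
}

#' Registry of benchmark thermal indices
#'
#' Twelve entries: ETIS plus the eleven literature indices.  Each entry
#' declares its required inputs and native scale and evaluates on a barn
#' record table (columns `air_temperature_C`, `relative_humidity_pct`,
#' `air_velocity_ms`, optional `globe_temperature_C`).
#'
#' @return A named list of entries; each entry has `name`, `label`,
#'   `inputs`, `scale` and `fun(data, strict_paper, pressure)`.
#' @seealso [compute_index()], [list_indices()]
#' @export
index_registry <- function() {
  env_in <- c("air_temperature_C", "relative_humidity_pct")
  entry <- function(name, label, inputs, scale, fun) {
    list(name = name, label = label, inputs = inputs, scale = scale,
         fun = fun)
  }
  thi_entry <- function(name, label, scale = "dimensionless") {
    entry(name, label, env_in, scale, function(d, strict_paper, pressure) {
      thi(d$air_temperature_C, d$relative_humidity_pct, name, pressure)
    })
  }
  reg <- list(
    entry("etis", "equivalent temperature index for sows",
          c(env_in, "air_velocity_ms"), "degC",
          function(d, strict_paper, pressure) {
            etis_fitted(d$air_temperature_C, d$relative_humidity_pct,
                        d$air_velocity_ms)
          }),
    thi_entry("thi_a", "THI, dry bulb + 0.36 wet bulb + 41.5"),
    thi_entry("thi_b", "THI, 0.8 T + RH (T - 14.4)/100 + 46.4"),
    thi_entry("thi_c", "THI, 0.65 T + 0.35 wet bulb"),
    thi_entry("thi_d", "THI, Fahrenheit form with 0.55 - 0.0055 RH",
              scale = "degF"),
    thi_entry("thi_e", "THI, 0.72 (T + wet bulb) + 40.6"),
    thi_entry("thi_f", "THI, Fahrenheit form with 0.55 RH/100",
              scale = "degF"),
    thi_entry("thi_g", "THI, T - (0.55 - 0.0055 RH)(T - 14.5)"),
    thi_entry("thi_h", "THI, 0.27 T + 1.35 wet bulb + 34.07"),
    entry("bghi", "black-globe humidity index",
          c(env_in, "globe_temperature_C (optional)"), "dimensionless",
          function(d, strict_paper, pressure) {
            bghi(d$air_temperature_C, d$relative_humidity_pct,
                 d$globe_temperature_C)
          }),
    entry("et", "effective temperature for pigs",
          c(env_in, "air_velocity_ms"), "degC",
          function(d, strict_paper, pressure) {
            effective_temperature(d$air_temperature_C,
                                  d$relative_humidity_pct,
                                  d$air_velocity_ms, strict_paper)
          }),
    entry("h", "moist-air enthalpy", c(env_in, "pressure"), "kJ/kg",
          function(d, strict_paper, pressure) {
            enthalpy_index(d$air_temperature_C, d$relative_humidity_pct,
                           pressure, strict_paper)
          })
  )
  names(reg) <- vapply(reg, `[[`, "", "name")
  reg
}

#' Tabulate the index registry
#'
#' @param registry A registry from [index_registry()].
#' @return A data frame with one row per index: name, native scale and
#'   required inputs.
#' @export
list_indices <- function(registry = index_registry()) {
  data.frame(
    name = vapply(registry, `[[`, "", "name"),
    scale = vapply(registry, `[[`, "", "scale"),
    inputs = vapply(registry, function(e) paste(e$inputs, collapse = ", "),
                    ""),
    row.names = NULL)
}

#' Compute a registered thermal index on a barn record table
#'
#' @param name Registry identifier (see [list_indices()]).
#' @param data Data frame with at least `air_temperature_C` and
#'   `relative_humidity_pct`; velocity-dependent indices also need
#'   `air_velocity_ms`.
#' @param strict_paper Evaluate printed-formula variants where the typeset
#'   source differs from the reconstruction (effective temperature,
#'   enthalpy).
#' @param pressure Barometric pressure, kPa.
#' @param registry Index registry.
#' @return Numeric vector of index values on the index's native scale.
#' @examples
#' d <- data.frame(air_temperature_C = 28.7, relative_humidity_pct = 65.8,
#'                 air_velocity_ms = 0.07)
#' compute_index("etis", d)
#' compute_index("thi_b", d)
#' @export
compute_index <- function(name, data, strict_paper = FALSE,
                          pressure = 101.325, registry = index_registry()) {
  if (!name %in% names(registry)) {
    stop("unknown index: ", name, "; see list_indices()", call. = FALSE)
  }
  e <- registry[[name]]
  need <- sub(" \\(optional\\)$", "",
              e$inputs[!grepl("optional|pressure", e$inputs)])
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("index ", name, " requires missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  e$fun(data, strict_paper, pressure)
}
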