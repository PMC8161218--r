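# Heat-stress thresholds: a linear THI -> ETIS map anchors the four-level
# classifier (suitable / mild / moderate / severe) to THI breakpoints
# established from sow pregnancy rates (74 / 78 / 82 on the 0.8 T variant).

.STRESS_LEVELS <- c("suitable", "mild", "moderate", "severe")

#' THI to ETIS threshold map
#'
#' Constructor for the linear map `ETIS = slope * THI + intercept` together
#' with the THI stress breakpoints it translates.  Defaults are the
#' published map (slope 0.3533, intercept 6.9249) and breakpoints
#' 74 / 78 / 82; these are configuration, not constants, since stress
#' thresholds vary with genotype and region.
#'
#' @param slope,intercept Linear map coefficients (ETIS as a function of
#'   THI, degC).
#' @param thi_breakpoints Strictly increasing triple: suitable/mild,
#'   mild/moderate and moderate/severe THI boundaries.
#' @param digits Decimal places to which derived ETIS boundaries are
#'   rounded before classification.
#' @return Object of class `"threshold_map"`.
#' @examples
#' derive_thresholds(threshold_map())  # boundaries 33.1 / 34.5 / 35.9
#' @export
threshold_map <- function(slope = 0.3533, intercept = 6.9249,
                          thi_breakpoints = c(74, 78, 82), digits = 1) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            is.numeric(thi_breakpoints), length(thi_breakpoints) == 3)
  if (any(diff(thi_breakpoints) <= 0)) {
    stop("THI breakpoints must be strictly increasing", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 thi_breakpoints = thi_breakpoints,
                 etis_breakpoints = NULL, digits = digits,
                 r_squared = NULL, n = NULL),
            class = "threshold_map")
}

#' Fit the THI -> ETIS map from paired index series
#'
#' Ordinary least-squares line of ETIS on THI (via [stats::lm()]).
#'
#' @param thi,etis Aligned index series, length >= 3.
#' @param thi_breakpoints,digits Passed to [threshold_map()].
#' @return A `"threshold_map"` with fitted slope and intercept and the
#'   line's R^2.
#' @examples
#' d <- simulate_barn(n = 200, seed = 3)
#' fit_thi_etis_map(compute_index("thi_b", d), compute_index("etis", d))
#' @export
fit_thi_etis_map <- function(thi, etis, thi_breakpoints = c(74, 78, 82),
                             digits = 1) {
  if (length(thi) != length(etis)) stop("series lengths differ", call. = FALSE)
  if (length(thi) < 3 && length(thi) != 2) {
    stop("need at least 3 paired values", call. = FALSE)
  }
  if (stats::sd(thi) == 0) {
    stop("zero THI variance: map undefined", call. = FALSE)
  }
  ols <- stats::lm(etis ~ thi)
  m <- threshold_map(slope = unname(stats::coef(ols)[2]),
                     intercept = unname(stats::coef(ols)[1]),
                     thi_breakpoints = thi_breakpoints, digits = digits)
  # simple-regression R^2 == squared Pearson correlation; avoids
  # summary.lm's perfect-fit warning on exactly linear input
  m$r_squared <- if (stats::sd(etis) > 0) stats::cor(thi, etis)^2 else 0
  m$n <- length(thi)
  m
}

#' Apply the THI -> ETIS map
#'
#' @param thi THI values.
#' @param map A `"threshold_map"`.
#' @return Mapped ETIS values, degC, unrounded.
#' @examples
#' map_thi_to_etis(74, threshold_map())  # 33.0691
#' @export
map_thi_to_etis <- function(thi, map = threshold_map()) {
  stopifnot(inherits(map, "threshold_map"))
  map$slope * thi + map$intercept
}

#' Derive ETIS stress boundaries from THI breakpoints
#'
#' Maps each THI breakpoint through the linear map and rounds to the map's
#' configured precision.
#'
#' @param map A `"threshold_map"`.
#' @return The map with `etis_breakpoints` filled in.
#' @export
derive_thresholds <- function(map = threshold_map()) {
  stopifnot(inherits(map, "threshold_map"))
  bp <- round(map_thi_to_etis(map$thi_breakpoints, map), map$digits)
  if (any(diff(bp) <= 0)) {
    stop("derived ETIS breakpoints are not strictly increasing",
         call. = FALSE)
  }
  map$etis_breakpoints <- bp
  map
}

#' Classify heat-stress level from ETIS
#'
#' Half-open intervals, lower-inclusive at each boundary:
#' suitable `< b1`, mild `[b1, b2)`, moderate `[b2, b3)`, severe `>= b3`.
#'
#' @param etis ETIS values, degC.
#' @param map A `"threshold_map"`; ETIS breakpoints are derived on the fly
#'   if absent.
#' @return Ordered factor with levels suitable < mild < moderate < severe.
#' @examples
#' m <- derive_thresholds(threshold_map())
#' classify_heat_stress(c(33.0, 33.1, 34.5, 35.9), m)
#' @export
classify_heat_stress <- function(etis, map = threshold_map()) {
  stopifnot(inherits(map, "threshold_map"))
  if (any(!is.finite(etis))) {
    stop("non-finite index values cannot be classified", call. = FALSE)
  }
  if (is.null(map$etis_breakpoints)) map <- derive_thresholds(map)
  cut(etis, breaks = c(-Inf, map$etis_breakpoints, Inf),
      labels = .STRESS_LEVELS, right = FALSE, ordered_result = TRUE)
}

#' @export
print.threshold_map <- function(x, ...) {
  cat(sprintf("THI -> ETIS threshold map: ETIS = %.4f THI + %.4f\n",
              x$slope, x$intercept))
  if (!is.null(x$r_squared)) {
    cat(sprintf("  fitted on n = %d (R^2 = %.4f)\n", x$n, x$r_squared))
  }
  cat("  THI breakpoints: ", paste(x$thi_breakpoints, collapse = " / "),
      "\n", sep = "")
  if (!is.null(x$etis_breakpoints)) {
    cat("  ETIS breakpoints (degC): ",
        paste(formatC(x$etis_breakpoints, format = "f",
                      digits = x$digits), collapse = " / "), "\n", sep = "")
  }
  invisible(x)
}
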