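# Calibration of the ETIS coefficients against skin temperature.
#
# The regression design mirrors the index structure term by term with the
# reference skin temperature frozen at 38 degC:
#   y = b0 + b1 T + b2 (50 T) + b3 (RH T) + b4 u^0.6827 (38 - T)
#       + b5 38 + b6 T + b7 (38 + 273.15)^4 + b8 (T + 273.15)^4
# The design is rank-deficient by construction (duplicate T columns, 50 T
# proportional to T, two constant columns besides the intercept), so the
# solver returns the minimum-norm least-squares solution; fitted values are
# unique even though individual coefficients are not.

.DESIGN_COLS <- c("(Intercept)", "T", "50T", "RH.T", "uc.TsT", "Ts", "T.2",
                  "Ts4", "T4")

#' Build the ETIS calibration design matrix
#'
#' @param data Data frame with columns `air_temperature_C`,
#'   `relative_humidity_pct`, `air_velocity_ms`.
#' @param ts_ref Reference skin temperature frozen into the design, degC.
#' @param c_exp Convective velocity exponent.
#' @return Numeric matrix with 9 named columns in the fixed order
#'   intercept, `T`, `50T`, `RH.T`, `uc.TsT` (velocity term), `Ts`
#'   (constant), duplicate `T`, `Ts4` (constant fourth power), `T4`.
#' @examples
#' d <- data.frame(air_temperature_C = 28.7, relative_humidity_pct = 65.8,
#'                 air_velocity_ms = 0.07)
#' build_design_matrix(d)
#' @export
build_design_matrix <- function(data, ts_ref = 38, c_exp = 0.6827) {
  req <- c("air_temperature_C", "relative_humidity_pct", "air_velocity_ms")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("no observations", call. = FALSE)
  t <- data$air_temperature_C
  rh <- data$relative_humidity_pct
  u <- data$air_velocity_ms
  if (any(u < 0)) stop("air velocity must be >= 0", call. = FALSE)
  x <- cbind(1, t, 50 * t, rh * t, u^c_exp * (ts_ref - t),
             ts_ref, t, (ts_ref + 273.15)^4, (t + 273.15)^4)
  colnames(x) <- .DESIGN_COLS
  x
}

#' Seeded train/test split
#'
#' Random, disjoint, exhaustive partition with `floor(n * fraction)`
#' training rows, reproducible per seed.
#'
#' @param n Number of records (or a data frame, in which case its row
#'   count is used).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' s <- split_train_test(1029, 0.7, seed = 1)
#' length(s$train)  # 720
#' length(s$test)   # 309
#' @export
split_train_test <- function(n, fraction = 0.7, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(is.numeric(n), length(n) == 1)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  if (n < 10) stop("need at least 10 records to split", call. = FALSE)
  n_train <- floor(n * fraction)
  perm <- local({
    set.seed(seed)
    sample.int(n)
  })
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1):n]),
       seed = seed, fraction = fraction)
}

# Minimum-norm least squares via SVD; returns coefficients, rank and a
# condition indicator.  Fitted values are the unique projection onto the
# column space regardless of which solution is reported.
.min_norm_lm <- function(x, y) {
  # columns scaled to unit norm before the SVD: the fourth-power column is
  # ~1e10 larger than the others and would otherwise swamp the rank test
  sc <- sqrt(colSums(x^2))
  s <- svd(sweep(x, 2, sc, "/"))
  tol <- max(dim(x)) * .Machine$double.eps * s$d[1]
  keep <- s$d > tol
  coefs <- s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep])
  list(coefficients = drop(coefs) / sc, rank = sum(keep),
       condition = s$d[1] / min(s$d[keep]))
}

# Squared Pearson correlation between observed and predicted values
# (the scatter-plot definition of R^2 used throughout).
.r_squared <- function(obs, pred) {
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) return(NA_real_)
  stats::cor(obs, pred)^2
}

#' Calibrate ETIS coefficients against skin temperature
#'
#' Fits the rank-deficient calibration design by minimum-norm least squares
#' on a seeded 70/30 train/test split and assembles an ETIS coefficient set
#' from the fit.
#'
#' Under `convention = "paper"` the returned coefficient set is the
#' published fitted constant set ([etis_params()] defaults), with the
#' regression retained as diagnostics.  Under `convention = "direct"` the
#' identifiable coefficient combinations are mapped back onto index
#' parameters: the humidity coefficient from the `RH.T` column, the
#' velocity coefficient from the velocity column, the radiation coefficient
#' from the (sign-flipped) `T4` column, the conduction coefficient from the
#' total linear-in-T mass minus the unit base-temperature contribution, and
#' the conduction reference factor from the residual constant mass.  The
#' mapping is recorded in the fit's `mapping` field; it reproduces the
#' generating parameters only up to the scale of the response on the index.
#'
#' @param data Data frame with environment columns plus the response.
#' @param response Name of the response column (default skin temperature).
#' @param fraction Training fraction.
#' @param seed Split seed.
#' @param convention `"paper"` or `"direct"` (see Details).
#' @param ts_ref,c_exp Frozen reference skin temperature and velocity
#'   exponent of the design.
#' @return An object of class `"etis_fit"`: coefficients `b0` ... `b8`,
#'   solver rank and condition, train/test R^2, split metadata, the
#'   assembled [etis_params()] and the convention used.
#' @examples
#' set.seed(1)
#' d <- simulate_barn(n = 300, seed = 1)
#' fit <- etis_calibrate(d, seed = 1)
#' summary(fit)
#' @export
etis_calibrate <- function(data, response = "skin_temperature_C",
                           fraction = 0.7, seed = 1L,
                           convention = c("paper", "direct"),
                           ts_ref = 38, c_exp = 0.6827) {
  convention <- match.arg(convention)
  if (!response %in% names(data)) {
    stop("response column not found: ", response, call. = FALSE)
  }
  y <- data[[response]]
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  x <- build_design_matrix(data, ts_ref, c_exp)
  sp <- split_train_test(nrow(x), fraction, seed)
  fit <- .min_norm_lm(x[sp$train, , drop = FALSE], y[sp$train])
  b <- fit$coefficients
  names(b) <- paste0("b", 0:8)
  pred_train <- drop(x[sp$train, , drop = FALSE] %*% b)
  pred_test <- drop(x[sp$test, , drop = FALSE] %*% b)
  if (stats::sd(y[sp$train]) == 0) {
    warning("constant response on the training set; R^2 undefined")
  }
  params <- assemble_etis_params(b, convention, ts_ref = ts_ref,
                                 c_exp = c_exp)
  structure(
    list(coefficients = b, rank = fit$rank, condition = fit$condition,
         r_squared = c(train = .r_squared(y[sp$train], pred_train),
                       test = .r_squared(y[sp$test], pred_test)),
         n_train = length(sp$train), n_test = length(sp$test),
         split = sp, fitted.values = pred_train,
         residuals = y[sp$train] - pred_train,
         residual_var = stats::var(y[sp$train] - pred_train),
         params = params, convention = convention,
         mapping = attr(params, "mapping"),
         ts_ref = ts_ref, c_exp = c_exp, response = response,
         call = match.call()),
    class = "etis_fit")
}

#' Assemble an ETIS coefficient set from regression coefficients
#'
#' @param coefs Named numeric vector `b0` ... `b8` (e.g.
#'   `coef(etis_calibrate(...))`).
#' @param convention `"paper"` returns the published constant set verbatim;
#'   `"direct"` maps identifiable coefficient combinations onto index
#'   parameters (see [etis_calibrate()]).
#' @param ts_ref,c_exp Design constants.
#' @return An [etis_params()] object; for `"direct"`, the mapping rule is
#'   attached as attribute `"mapping"`.
#' @export
assemble_etis_params <- function(coefs, convention = c("paper", "direct"),
                                 ts_ref = 38, c_exp = 0.6827) {
  convention <- match.arg(convention)
  if (convention == "paper") {
    return(etis_params())
  }
  stopifnot(length(coefs) == 9)
  b <- unname(coefs)
  a <- b[4]
  e <- b[5]
  r_rad <- -b[9]
  # total coefficient on T spread across the three proportional columns;
  # the index contributes 1 (base T) - 50 a (from a (RH - 50) T) - d, so
  # d = 1 - 50 a - total
  t_mass <- b[2] + 50 * b[3] + b[7]
  d <- 1 - 50 * a - t_mass
  # constant mass (intercept + both constant columns) = d * f * ts + r_rad
  # * (ts + 273.15)^4, solved for the conduction reference factor f
  c_mass <- b[1] + ts_ref * b[6] + (ts_ref + 273.15)^4 * b[8]
  f <- if (abs(d) > 1e-12) {
    (c_mass - r_rad * (ts_ref + 273.15)^4) / (d * ts_ref)
  } else {
    1
  }
  p <- etis_params(a = a, e = e, c = c_exp, d = d, r_rad = r_rad,
                   ts = ts_ref, conduction_ref = f)
  attr(p, "mapping") <- c(
    a = "b3 (RH.T column)", e = "b4 (velocity column)",
    r_rad = "-b8 (T4 column)",
    d = "1 - 50 a - (b1 + 50 b2 + b6) (linear-in-T mass)",
    conduction_ref = "(b0 + 38 b5 + 311.15^4 b7 - r_rad 311.15^4)/(d 38)")
  p
}

#' @export
print.etis_fit <- function(x, ...) {
  cat("ETIS calibration fit (minimum-norm least squares)\n")
  cat(sprintf("  n = %d train / %d test (fraction %.2f, seed %s)\n",
              x$n_train, x$n_test, x$split$fraction, x$split$seed))
  cat(sprintf("  design rank %d of 9 (condition %.3g)\n", x$rank,
              x$condition))
  cat(sprintf("  R^2 train %.4f / test %.4f\n", x$r_squared["train"],
              x$r_squared["test"]))
  cat(sprintf("  convention: %s\n", x$convention))
  invisible(x)
}

#' @export
summary.etis_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients (one minimum-norm representative):\n")
  print(signif(object$coefficients, 5))
  cat("\nAssembled index parameters:\n")
  print(object$params)
  invisible(object)
}

#' @export
coef.etis_fit <- function(object, ...) object$coefficients

#' @export
predict.etis_fit <- function(object, newdata, ...) {
  x <- build_design_matrix(newdata, object$ts_ref, object$c_exp)
  drop(x %*% object$coefficients)
}

#' @export
fitted.etis_fit <- function(object, ...) object$fitted.values

#' @export
residuals.etis_fit <- function(object, ...) object$residuals

#' Pearson correlation with validation
#'
#' Thin wrapper over [stats::cor()] that enforces the preconditions used by
#' the index comparison: equal lengths of at least 3 and non-degenerate
#' variance on both sides.
#'
#' @param a,b Numeric series.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Rank thermal indices by correlation with a physiological series
#'
#' Computes every registered index on the environment records and reports
#' its Pearson correlation with the physiological series, sorted from
#' strongest to weakest.
#'
#' @param data Environment records (barn record table columns).
#' @param physio Numeric physiological series aligned with `data` rows
#'   (e.g. skin temperature).
#' @param registry Index registry.
#' @param strict_paper,pressure Passed to [compute_index()].
#' @return Data frame of class `"index_comparison"`: index name, Pearson
#'   `r`, sample size and native scale, sorted by decreasing `r`.
#' @examples
#' d <- simulate_barn(n = 200, seed = 7)
#' compare_indices(d, d$skin_temperature_C)
#' @export
compare_indices <- function(data, physio, registry = index_registry(),
                            strict_paper = FALSE, pressure = 101.325) {
  if (nrow(data) != length(physio)) {
    stop("environment records and physiological series are not aligned",
         call. = FALSE)
  }
  r <- vapply(names(registry), function(nm) {
    pearson_r(compute_index(nm, data, strict_paper, pressure, registry),
              physio)
  }, numeric(1))
  out <- data.frame(index = names(registry), r = unname(r),
                    n = length(physio),
                    scale = vapply(registry, `[[`, "", "scale"),
                    row.names = NULL)
  out <- out[order(-out$r), ]
  rownames(out) <- NULL
  class(out) <- c("index_comparison", "data.frame")
  out
}

#' @export
print.index_comparison <- function(x, ...) {
  cat("Thermal index comparison (Pearson r vs physiology), n =",
      x$n[1], "\n")
  print.data.frame(x[, c("index", "r", "scale")], digits = 4, ...)
  invisible(x)
}
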