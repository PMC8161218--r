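test_that("design matrix has the fixed column structure with exact collinearities", {
  d <- data.frame(air_temperature_C = 28.7, relative_humidity_pct = 65.8,
                  air_velocity_ms = 0.07)
  x <- build_design_matrix(d)
  expect_equal(dim(x), c(1L, 9L))
  expect_equal(unname(x[1, "uc.TsT"]), 1.5136706, tolerance = 1e-6)
  expect_equal(unname(x[1, "RH.T"]), 65.8 * 28.7)
  expect_equal(unname(x[1, "50T"]), 50 * 28.7)

  set.seed(41)
  d2 <- data.frame(air_temperature_C = runif(50, 20, 38),
                   relative_humidity_pct = runif(50, 30, 90),
                   air_velocity_ms = runif(50, 0, 0.3))
  d2$air_temperature_C[1] <- 38  # velocity column vanishes at t = ts
  x2 <- build_design_matrix(d2)
  expect_equal(x2[1, "uc.TsT"], c(uc.TsT = 0))
  expect_equal(unname(x2[, "T"]), unname(x2[, "T.2"]))
  expect_equal(unname(x2[, "50T"]), 50 * unname(x2[, "T"]))
  expect_true(all(x2[, "Ts"] == 38))
  expect_error(build_design_matrix(d2[0, ]), "no observations")
  expect_error(build_design_matrix(d2[, -1]), "air_temperature_C")
})

test_that("train/test split is exhaustive, disjoint, sized and reproducible", {
  s <- split_train_test(1029, 0.7, seed = 1)
  expect_length(s$train, 720)
  expect_length(s$test, 309)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:1029)
  expect_identical(split_train_test(1029, 0.7, seed = 1), s)
  expect_false(identical(split_train_test(1029, 0.7, seed = 2)$train,
                         s$train))
  expect_equal(lengths(split_train_test(10, 0.5, seed = 3)[1:2]),
               c(train = 5L, test = 5L))
  expect_error(split_train_test(9, 0.7, 1), "at least 10")
  expect_error(split_train_test(100, 1.2, 1), "fraction")
})

test_that("minimum-norm fit recovers noiseless responses with unique predictions", {
  d <- simulate_barn(n = 400, seed = 6)
  x <- build_design_matrix(d)
  beta <- c(2, 1, 0.01, 5e-4, -0.3, 0.05, 0.5, 1e-9, -4e-8)
  d$resp <- drop(x %*% beta)
  fit <- etis_calibrate(d, response = "resp", seed = 2)
  expect_lt(fit$rank, 9)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  expect_equal(unname(fit$r_squared), c(1, 1), tolerance = 1e-9)

  # null-space invariance: shifting weight between the duplicate T columns
  # leaves predictions unchanged
  delta <- c(0, 1, 0, 0, 0, 0, -1, 0, 0)
  expect_lt(max(abs(x %*% delta)), 1e-12)
  expect_equal(drop(x %*% (coef(fit) + delta)), drop(x %*% coef(fit)))
})

test_that("residual scale tracks the generating noise", {
  # Monte-Carlo: index-structured truth plus sigma = 0.5 noise
  rmse <- vapply(1:10, function(s) {
    d <- simulate_barn(config = barn_config(
      n = 1000, seed = s, skin = list(intercept = 0, slope = 1, sigma = 0.5)))
    fit <- etis_calibrate(d, seed = s)
    sqrt(mean(residuals(fit)^2))
  }, numeric(1))
  expect_equal(mean(rmse), 0.5, tolerance = 0.05)
})

test_that("direct convention recovers identifiable generating parameters", {
  cfg <- barn_config(n = 1000, seed = 2,
                     skin = list(intercept = 0, slope = 1, sigma = 0))
  d <- simulate_barn(config = cfg)
  fit <- etis_calibrate(d, seed = 1, convention = "direct")
  p <- fit$params
  expect_equal(p$a, 6e-4, tolerance = 1e-6)
  expect_equal(p$e, -0.3132, tolerance = 1e-6)
  expect_equal(p$r_rad, 4.8957e-8, tolerance = 1e-6)
  expect_equal(p$d, -4.79, tolerance = 1e-6)
  expect_equal(p$conduction_ref, 1.0086, tolerance = 1e-6)
  expect_true(!is.null(fit$mapping))

  # assembled index reproduces the generating surface, so it correlates
  # perfectly with fitted values on the training rows
  idx <- etis(d$air_temperature_C, d$relative_humidity_pct,
              d$air_velocity_ms, p)
  expect_equal(cor(idx[fit$split$train], fitted(fit)), 1, tolerance = 1e-12)

  # paper convention returns the published constant set verbatim
  fit_p <- etis_calibrate(d, seed = 1, convention = "paper")
  expect_equal(unclass(fit_p$params), unclass(etis_params()))
})

test_that("pearson_r enforces preconditions and matches known correlations", {
  a <- rnorm(50)
  expect_equal(pearson_r(a, 2 * a + 1), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_error(pearson_r(a, a[-1]), "lengths")
  expect_error(pearson_r(a[1:2], a[1:2]), "at least 3")
  expect_error(pearson_r(rep(1, 10), a[1:10]), "zero variance")
  set.seed(43)
  expect_lt(abs(pearson_r(rnorm(1e4), rnorm(1e4))), 0.05)
})

test_that("index comparison ranks, aligns and degrades to noise sensibly", {
  d <- simulate_barn(n = 300, seed = 9)
  cmp <- compare_indices(d, d$skin_temperature_C)
  expect_s3_class(cmp, "index_comparison")
  expect_equal(nrow(cmp), 12)
  expect_true(all(diff(cmp$r) <= 0))
  expect_true(all(abs(cmp$r) <= 1))
  expect_error(compare_indices(d, d$skin_temperature_C[-1]), "aligned")

  # single-entry registry gives a single-row report
  cmp1 <- compare_indices(d, d$skin_temperature_C,
                          registry = index_registry()["etis"])
  expect_equal(nrow(cmp1), 1)

  # pure-noise physiology: no strong correlation with any index
  set.seed(44)
  cmp_noise <- compare_indices(d, rnorm(nrow(d)))
  expect_lt(max(abs(cmp_noise$r)), 0.25)
})
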