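test_that("environment generator is deterministic, bounded and moment-matched", {
  cfg <- barn_config(n = 20000, seed = 1)
  env <- generate_environment(cfg)
  expect_identical(generate_environment(cfg), env)
  expect_equal(nrow(env), 20000)

  # range compliance: zero out-of-bounds samples
  expect_true(all(env$air_temperature_C >= 21.9 &
                    env$air_temperature_C <= 34.0))
  expect_true(all(env$relative_humidity_pct >= 40.4 &
                    env$relative_humidity_pct <= 89.8))
  expect_true(all(env$air_velocity_ms >= 0 & env$air_velocity_ms <= 0.29))

  # T and RH moments within 3 standard errors of their targets
  expect_equal(mean(env$air_temperature_C), 28.7,
               tolerance = 3 * 2.6 / sqrt(20000) / 28.7)
  expect_equal(sd(env$air_temperature_C), 2.6, tolerance = 0.02)
  expect_equal(mean(env$relative_humidity_pct), 65.8,
               tolerance = 3 * 10 / sqrt(20000) / 65.8)
  expect_equal(sd(env$relative_humidity_pct), 10, tolerance = 0.02)

  # velocity: targets are infeasible under the [0, 0.29] truncation; the
  # sample must match the solver's achieved (closest) moments instead
  ach <- attr(env, "generator")$marginals$u$achieved
  expect_equal(mean(env$air_velocity_ms), unname(ach["mean"]),
               tolerance = 0.03)
  expect_equal(unname(ach["mean"]), 0.07, tolerance = 0.12)
  expect_equal(unname(ach["sd"]), 0.07, tolerance = 0.12)

  # configured negative T-RH dependence is realized
  expect_lt(cor(env$air_temperature_C, env$relative_humidity_pct), -0.2)
})

test_that("infeasible moment targets raise a configuration error", {
  expect_error(generate_environment(
    barn_config(n = 10, u = c(mean = 5, sd = 1, min = 0, max = 1))),
    "infeasible")
  expect_error(barn_config(t_rh_cor = 1.2), "t_rh_cor")
})

test_that("physiology generator hits its target moments and correlation structure", {
  cfg <- barn_config(n = 10000, seed = 5)
  d <- simulate_barn(config = cfg)
  expect_equal(mean(d$skin_temperature_C), 34.9, tolerance = 0.005)
  expect_equal(sd(d$skin_temperature_C), 1.4, tolerance = 0.05)

  thi_v <- compute_index(cfg$thi_variant, d)
  expect_equal(cor(d$respiration_rate_bpm, thi_v)^2, 0.1386,
               tolerance = 0.05 / 0.1386)
  expect_equal(cor(d$core_temperature_C, thi_v)^2, 0.0972,
               tolerance = 0.05 / 0.0972)
  expect_equal(cor(d$skin_temperature_C, compute_index("etis", d))^2,
               0.6341, tolerance = 0.05 / 0.6341)

  # respiration floor honored
  expect_true(all(d$respiration_rate_bpm >= 12))
  expect_error(generate_physiology(d[0, ], cfg), "empty")
})

test_that("noiseless explicit skin model is an exact function of the index", {
  cfg <- barn_config(n = 500, seed = 8,
                     skin = list(intercept = 1, slope = 0.9, sigma = 0))
  d <- simulate_barn(config = cfg)
  idx <- compute_index("etis", d)
  expect_equal(d$skin_temperature_C, 1 + 0.9 * idx)
  fit <- etis_calibrate(d, seed = 1)
  expect_equal(unname(fit$r_squared["train"]), 1, tolerance = 1e-9)
})

test_that("full simulation carries provenance and composes end to end", {
  d <- simulate_barn(n = 800, seed = 13)
  gen <- attr(d, "generator")
  expect_equal(gen$config$seed, 13L)
  expect_true(all(c("skin", "sigma_rr", "sigma_core") %in%
                    names(gen$physiology)))

  # end-to-end: direct-convention calibration on generated data recovers
  # the configured skin-response coefficients up to the response scale
  cfg <- barn_config(n = 1500, seed = 14,
                     skin = list(intercept = 2, slope = 0.8, sigma = 0.05))
  d2 <- simulate_barn(config = cfg)
  fit <- etis_calibrate(d2, seed = 1, convention = "direct")
  expect_equal(fit$params$a / 0.8, 6e-4, tolerance = 0.02)
  expect_equal(fit$params$e / 0.8, -0.3132, tolerance = 0.02)
  expect_equal(fit$params$r_rad / 0.8, 4.8957e-8, tolerance = 0.02)
})
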