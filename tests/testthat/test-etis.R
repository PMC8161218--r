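test_that("equivalent-temperature terms match hand-computed values and null points", {
  # humidity: null at RH = 50, sign follows a (rh - 50) t
  expect_equal(teq_humidity(30, 50), 0)
  expect_equal(teq_humidity(28.7, 65.8), 0.272076, tolerance = 1e-10)
  expect_equal(teq_humidity(28.7, 40), -0.172200, tolerance = 1e-10)

  # velocity: null in still air or at skin temperature
  expect_equal(teq_velocity(25, 0), 0)
  expect_equal(teq_velocity(38, 0.2), 0)
  expect_equal(teq_velocity(28.7, 0.07), -0.4740816, tolerance = 1e-6)
  expect_error(teq_velocity(25, -0.1), "velocity")

  # conduction: plain gradient form null at t = ts; fitted reference factor
  expect_equal(teq_conduction(38, ts = 38, d = 2), 0)
  expect_equal(teq_conduction(30, ts = 38, d = 1), 8)
  expect_equal(teq_conduction(28.7, ts = 38, d = -4.79,
                              conduction_ref = 1.0086),
               -46.112372, tolerance = 1e-9)

  # radiation: null at equal temperatures, antisymmetric in the exchange
  expect_equal(teq_radiation(38, ts = 38), 0)
  expect_equal(teq_radiation(28.7, ts = 38, r_rad = 4.8957e-8),
               52.4504384, tolerance = 1e-6)
  expect_equal(teq_radiation(28.7, ts = 38), -teq_radiation(38, ts = 28.7))
  expect_error(teq_radiation(-300), "absolute zero")
})

test_that("general index satisfies the additive decomposition and degenerates to T", {
  set.seed(21)
  t <- runif(500, 15, 40); rh <- runif(500, 20, 100); u <- runif(500, 0, 1)
  comp <- etis(t, rh, u, components = TRUE)
  expect_equal(comp$etis,
               comp$base_t + comp$t_rh + comp$t_u + comp$t_f + comp$t_r)
  expect_equal(comp$base_t, t)

  zero <- etis_params(a = 0, e = 0, d = 0, r_rad = 0)
  expect_equal(etis(t, rh, u, zero), t)
})

test_that("fitted index matches the independent oracle and published spot values", {
  expect_equal(etis_fitted(28.7, 65.8, 0.07), 34.84, tolerance = 0.002)
  expect_equal(etis_fitted(38, 50, 0), 36.434628, tolerance = 1e-9)
  expect_equal(etis_fitted(21.9, 40.4, 0.29), 28.7782826, tolerance = 1e-6)

  set.seed(22)
  t <- runif(2000, 15, 40); rh <- runif(2000, 0, 100)
  u <- runif(2000, 0, 0.5)
  expect_lt(max(abs(etis(t, rh, u) - etis_fitted(t, rh, u))), 1e-9)
  expect_lt(max(abs(etis_fitted(t, rh, u) - oracle_etis(t, rh, u))), 1e-9)
})

test_that("fitted index is increasing in T and velocity cools below skin temperature", {
  grid <- expand.grid(rh = seq(40, 90, by = 10), u = seq(0, 0.29, by = 0.05))
  t <- seq(21.9, 34.0, by = 0.1)
  for (i in seq_len(nrow(grid))) {
    v <- etis_fitted(t, grid$rh[i], grid$u[i])
    expect_true(all(diff(v) > 0))
  }
  u <- seq(0, 0.29, by = 0.01)
  for (tt in c(21.9, 28.7, 34.0, 37.9)) {
    expect_true(all(diff(etis_fitted(tt, 65.8, u)) <= 0))
  }
})

test_that("optional floor and radiant temperatures replace air temperature in their terms", {
  base <- etis(28.7, 65.8, 0.07, components = TRUE)
  with_floor <- etis(28.7, 65.8, 0.07, floor_temp = 25, components = TRUE)
  expect_equal(with_floor$t_f, teq_conduction(25, 38, -4.79, 1.0086))
  expect_equal(with_floor$t_rh, base$t_rh)
  expect_equal(with_floor$t_r, base$t_r)
  with_rad <- etis(28.7, 65.8, 0.07, radiant_temp = 32, components = TRUE)
  expect_equal(with_rad$t_r, teq_radiation(32, 38, 4.8957e-8))
  expect_equal(with_rad$t_f, base$t_f)
})

test_that("parameter constructor validates and supports the two-coefficient radiation mode", {
  expect_error(etis_params(c = -1), "exponent")
  expect_error(etis_params(ts = 45), "skin temperature")
  expect_error(etis_params(r_rad_skin = 1e-8), "both")
  p2 <- etis_params(r_rad_skin = 2.9370e-8, r_rad_air = 4.8957e-8)
  v <- etis(28.7, 65.8, 0.07, p2, components = TRUE)
  expect_equal(v$t_r,
               2.9370e-8 * (38 + 273.15)^4 - 4.8957e-8 * (28.7 + 273.15)^4)
})
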