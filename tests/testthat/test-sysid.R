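test_that("cascade simulation equals the expanded-rational oracle", {
  # packaged fullerene model, unit step, against a hand-written
  # difference-equation loop on the expanded polynomials
  m <- table2_fullerene()
  u <- rep(1, 50)
  expect_equal(tf_simulate(m, u), simulate_expanded(m, u),
               tolerance = 1e-12)

  # and on longer, richer inputs across random stable models
  withr::with_seed(42, {
    for (trial in 1:5) {
      m <- random_stable_tf()
      u <- stats::rnorm(1000)
      y <- tf_simulate(m, u)
      yo <- simulate_expanded(m, u)
      expect_lt(max(abs(y - yo)) / max(abs(yo)), 1e-9)
    }
  })
})

test_that("simulation degenerates correctly and is linear", {
  zero_gain <- discrete_tf(a = 0, b = 0.5, e = 0.2, f = 0.1)
  expect_equal(tf_simulate(zero_gain, stats::rnorm(20)), rep(0, 20))

  pure <- discrete_tf(a = 3.5)
  u <- stats::rnorm(30)
  expect_equal(tf_simulate(pure, u), 3.5 * u)

  m <- withr::with_seed(1, random_stable_tf())
  u1 <- stats::rnorm(200); u2 <- stats::rnorm(200)
  lhs <- tf_simulate(m, 2 * u1 - 3 * u2)
  rhs <- 2 * tf_simulate(m, u1) - 3 * tf_simulate(m, u2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("DC gain matches the closed form and the step steady state", {
  expect_equal(tf_dc_gain(discrete_tf(a = 2.5)), 2.5)
  expect_equal(tf_dc_gain(discrete_tf(a = 1, b = 1)), 0)
  expect_error(tf_dc_gain(discrete_tf(a = 1, e = 2, f = 1)), "singular")

  # CNT model: long-run unit-step response converges to the DC gain
  m <- table2_cnt()
  y <- tf_simulate(m, rep(1, 20000))
  expect_equal(mean(tail(y, 500)), tf_dc_gain(m), tolerance = 0.02)

  # property over random stable models
  withr::with_seed(99, {
    for (trial in 1:10) {
      m <- random_stable_tf(max_pole = 0.9)
      y <- tf_simulate(m, rep(1, 5000))
      expect_equal(tail(y, 1), tf_dc_gain(m),
                   tolerance = max(1e-6, 1e-3 * abs(tf_dc_gain(m))))
    }
  })
})

test_that("poles and zeros come from the factor quadratics", {
  m <- discrete_tf(a = 1, e = 0, f = 0.25)
  pz <- tf_poles_zeros(m)
  expect_equal(sort(Im(pz$poles)), c(-0.5, 0.5))
  expect_equal(Re(pz$poles), c(0, 0))
  expect_true(pz$stable)

  expect_true(tf_poles_zeros(discrete_tf(a = 1))$stable)
  expect_length(tf_poles_zeros(discrete_tf(a = 1))$poles, 0)

  # stability flag vs companion-matrix eigenvalue oracle, fullerene model
  m <- table2_fullerene()
  tp <- expand_tf(m)
  den <- tp$den  # 1 + a1 z^-1 + ... : companion of z^6 + a1 z^5 + ...
  comp <- rbind(-den[-1], cbind(diag(5), 0))
  eig <- eigen(comp, only.values = TRUE)$values
  expect_identical(tf_poles_zeros(m)$stable, all(Mod(eig) < 1))
  expect_false(tf_poles_zeros(m)$stable)  # one pair sits at ~1.03
  expect_equal(sort(Mod(tf_poles_zeros(m)$poles)), sort(Mod(eig)),
               tolerance = 1e-9)
})

test_that("frequency response is consistent with gain and DC limits", {
  pure <- discrete_tf(a = 0.05)
  fr <- tf_frequency_response(pure, c(1e6, 1e9, 1e12))
  expect_equal(fr$magnitude_db, rep(20 * log10(0.05), 3))

  m <- table2_cnt()
  fr_low <- tf_frequency_response(m, 1e3)
  expect_equal(fr_low$magnitude_db, 20 * log10(abs(tf_dc_gain(m))),
               tolerance = 1e-6)

  expect_error(tf_frequency_response(m, 1e15), "Nyquist")
  expect_error(tf_frequency_response(m, -1), "positive")
})

test_that("fullerene magnitude is flat over the constant-gain band", {
  m <- table2_fullerene()
  freqs <- 10^seq(9, 13, length.out = 400)
  fr <- tf_frequency_response(m, freqs)
  expect_lt(diff(range(fr$magnitude_db)), 3)
})

test_that("fit percentage and mse follow their definitions", {
  y <- c(0, 1, 2, 3)
  expect_equal(fit_percent(y, y), 100)
  expect_equal(fit_percent(y, rep(mean(y), 4)), 0)
  expect_equal(fit_percent(y, c(0, 1, 2, 2)), 100 * (1 - 1 / sqrt(5)))
  expect_error(fit_percent(rep(1, 4), y), "constant")
  expect_error(fit_percent(1:3, 1:4), "length")

  expect_equal(mse(y, y), 0)
  expect_equal(mse(c(1, 2, 3), c(0, 3, 1)), 2)
  expect_equal(mse(rep(0, 3), rep(2, 3)), 4)
})

test_that("model JSON round-trips and the packaged models match Table values", {
  m <- table2_cnt()
  f <- withr::local_tempfile(fileext = ".json")
  write_tf_json(m, f, label = "roundtrip")
  back <- read_tf_json(f)
  expect_identical(back$coef, m$coef)
  expect_identical(back$Ts, m$Ts)

  expect_equal(m$coef[["a"]], -2.83e-10)
  expect_equal(table2_fullerene()$coef[["a"]], -4.60e-10)
  expect_true(tf_poles_zeros(m)$stable)

  writeLines('{"a": 1}', f)
  expect_error(read_tf_json(f), "missing")
})

test_that("tidy and glance expose coefficients and summary", {
  m <- table2_fullerene()
  td <- tidy(m)
  expect_equal(td$term, letters[1:12])
  gl <- glance(m)
  expect_equal(gl$dc_gain, tf_dc_gain(m))
  expect_false(gl$stable)
})
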