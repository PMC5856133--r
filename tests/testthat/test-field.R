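test_that("magnetic constants default to the bead parameters", {
  mc <- magnetic_constants()
  expect_equal(mc$mu0, 4e-7 * pi)
  expect_equal(mc$r_a, 2e-9)
  expect_equal(mc$V, (4 / 3) * pi * (2e-9)^3)
  expect_equal(mc$chi_bead, 0.17)
  expect_error(magnetic_constants(r_a = 2e-9, V = 1e-27), "inconsistent")
  expect_error(magnetic_constants(chi_bead = -1), "positive")

  f <- withr::local_tempfile(fileext = ".json")
  write_magnetic_constants(mc, f)
  expect_equal(read_magnetic_constants(f), mc)
})

test_that("velocity scaling follows the fixed crossing distance", {
  # 55 A in 60 s
  sc <- crossing_scenario(t_s = 60, x_membrane = 5.5e-9)
  expect_equal(scaled_velocity(sc), 5.5e-9 / 60)

  # t_s = t_sim reproduces the simulated velocity
  sim <- crossing_scenario(t_s = 5.5e-9 / 100, x_membrane = 5.5e-9,
                           v_sim = 100)
  expect_equal(scaled_velocity(sim), 100)

  # doubling the time halves the velocity
  expect_equal(scaled_velocity(crossing_scenario(120)),
               scaled_velocity(crossing_scenario(60)) / 2)

  expect_error(crossing_scenario(-1), "positive")
  expect_error(crossing_scenario(60, v_sim = 100, t_sim = 1), "inconsistent")
})

test_that("quasi-static crossing force uses the DC gain magnitude", {
  expect_equal(crossing_force(table2_fullerene(), 0), 0)
  pure <- discrete_tf(a = -2e-10)
  expect_equal(crossing_force(pure, 1e-10), 2e-10 * 1e-10)

  # fullerene model: DC gain equals the long-run steady state of the
  # expanded-rational step response (oracle loop)
  m <- table2_cnt()  # stable model converges; oracle run at length 2e4
  y <- simulate_expanded(m, rep(1, 20000))
  v_s <- scaled_velocity(crossing_scenario(60))
  expect_equal(crossing_force(m, v_s), abs(mean(tail(y, 200))) * v_s,
               tolerance = 0.02)
})

test_that("magnetophoretic product inverts the force law", {
  mc <- magnetic_constants()
  expect_equal(magnetophoretic_product(0, mc), 0)

  # hand evaluation: U = F mu0 / (V chi)
  F <- 6.9477e-11
  U_hand <- F * (4e-7 * pi) / ((4 / 3) * pi * (2e-9)^3 * 0.17)
  expect_equal(magnetophoretic_product(F, mc), U_hand)

  mc2 <- magnetic_constants(chi_bead = 0.34)
  expect_equal(magnetophoretic_product(F, mc2),
               magnetophoretic_product(F, mc) / 2)
  # scale covariance: U is exactly linear in the force
  expect_equal(magnetophoretic_product(3 * F, mc),
               3 * magnetophoretic_product(F, mc))
})

test_that("product bounds are ordered by crossing time and gain", {
  m <- table2_fullerene()
  mc <- magnetic_constants()
  slow <- crossing_scenario(60)
  fast <- crossing_scenario(6)
  b <- product_bounds(m, mc, slow, fast)
  expect_lt(b[["L_min"]], b[["L_max"]])
  expect_equal(b[["L_max"]] / b[["L_min"]], 10)  # linear in v_s

  same <- product_bounds(m, mc, slow, slow)
  expect_equal(same[["L_min"]], same[["L_max"]])

  expect_error(product_bounds(m, mc, fast, slow), "inverted")

  # CNT vs fullerene bounds ordered by |DC gain|
  b_cnt <- product_bounds(table2_cnt(), mc, slow, fast)
  expect_equal(b[["L_max"]] > b_cnt[["L_max"]],
               abs(tf_dc_gain(m)) > abs(tf_dc_gain(table2_cnt())))
})

test_that("L bounds shrink monotonically as crossing time grows", {
  m <- table2_fullerene()
  mc <- magnetic_constants()
  ts <- c(1, 10, 60, 600, 3600)
  U <- vapply(ts, function(t) {
    magnetophoretic_product(
      crossing_force(m, scaled_velocity(crossing_scenario(t))), mc)
  }, numeric(1))
  expect_true(all(diff(U) < 0))
})

test_that("feasible region obeys the band and the MRI box", {
  reg <- feasible_region(0.05, 0.2)
  expect_false(reg$empty)
  bd <- reg$boundary
  expect_true(all(bd$b >= 0 & bd$b <= 2.4))
  expect_true(all(bd$g >= 0 & bd$g <= 0.18))
  expect_true(all(region_contains(reg, bd$b, bd$g)))

  # L_min above the corner product 2.4 * 0.18 = 0.432: empty
  expect_true(feasible_region(0.45, 1)$empty)
  expect_false(feasible_region(0.432, 1)$empty)

  # L_min = 0: the full box below the L_max hyperbola
  reg0 <- feasible_region(0, 0.1)
  expect_true(region_contains(reg0, 0, 0))
  expect_true(region_contains(reg0, 0, 0.18))
  expect_false(region_contains(reg0, 2.4, 0.18))  # product 0.432 > 0.1

  expect_error(feasible_region(0.2, 0.1), "L_min")
  expect_error(feasible_region(0, 1, resolution = 1), "resolution")
})

test_that("region membership agrees with a dense rejection-sampling oracle", {
  reg <- feasible_region(0.03, 0.3)
  pts <- withr::with_seed(21, {
    tibble::tibble(b = stats::runif(20000, 0, 2.4),
                   g = stats::runif(20000, 0, 0.18))
  })
  oracle <- pts$b * pts$g >= 0.03 & pts$b * pts$g <= 0.3
  expect_identical(region_contains(reg, pts$b, pts$g, tol = 0), oracle)
})

test_that("narrower bands give nested regions", {
  outer <- feasible_region(0.02, 0.4)
  inner <- feasible_region(0.05, 0.2)
  pts <- withr::with_seed(22, {
    tibble::tibble(b = stats::runif(5000, 0, 2.4),
                   g = stats::runif(5000, 0, 0.18))
  })
  inside_inner <- region_contains(inner, pts$b, pts$g)
  expect_true(all(region_contains(outer, pts$b, pts$g)[inside_inner]))
})

test_that("region export round-trips and respects hardware ceilings", {
  reg <- feasible_region(0.01, 0.1, resolution = 50)
  fj <- withr::local_tempfile(fileext = ".json")
  export_region(reg, fj, "json")
  back <- read_region(fj)
  expect_equal(back$boundary, reg$boundary)
  expect_equal(back$L_min, reg$L_min)
  expect_equal(back$empty, reg$empty)

  fc <- withr::local_tempfile(fileext = ".csv")
  export_region(reg, fc, "csv")
  lines <- readLines(fc)
  rows <- lines[!startsWith(lines, "#")][-1]
  expect_length(rows, nrow(reg$boundary))  # resolution-determined count
  b_vals <- as.numeric(vapply(strsplit(rows, ","), `[`, "", 1))
  expect_true(all(b_vals <= 2.4))

  # empty region: metadata-only file, flag set
  ereg <- feasible_region(0.5, 1)
  export_region(ereg, fc, "csv")
  lines <- readLines(fc)
  expect_true(any(grepl("# empty\ttrue", lines)))
  expect_length(lines[!startsWith(lines, "#")][-1], 0)
})
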