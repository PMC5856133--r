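test_that("penetration work matches closed forms", {
  # constant force F over depth D: W = F * D (trapezoid is exact)
  tr <- force_trace(time = 0:10, depth = 0:10, force = rep(2.5, 11),
                    velocity = 1)
  wc <- penetration_work(tr)
  expect_equal(wc$work[1], 0)
  expect_equal(wc$work[11], 2.5 * 10)

  # linear force alpha * z over [0, D]: W = alpha D^2 / 2; oracle is a
  # fine-grid Riemann sum
  alpha <- 0.7; D <- 12
  z <- seq(0, D, length.out = 241)
  tr2 <- force_trace(time = z, depth = z, force = alpha * z, velocity = 1)
  w <- penetration_work(tr2)$work[241]
  zf <- seq(0, D, length.out = 2e5)
  riemann <- sum(alpha * (zf[-1] + zf[-length(zf)]) / 2 * diff(zf))
  expect_equal(w, riemann, tolerance = 1e-6)
  expect_equal(w, alpha * D^2 / 2, tolerance = 1e-3)

  # single sample: no interval, zero work
  expect_equal(penetration_work(force_trace(0, 0, 5, 1))$work, 0)

  tr3 <- force_trace(time = 0:2, depth = c(0, 2, 1), force = rep(1, 3),
                     velocity = 1)
  expect_error(penetration_work(tr3), "non-decreasing")
})

test_that("work is additive over subintervals on a shared grid", {
  cfg <- trace_config(noise_sd = 0)
  tr <- generate_trace(cfg, 1.0, 55)
  wc <- penetration_work(tr)
  cut <- 250
  w1 <- penetration_work(tr[1:cut, ])$work[cut]
  lower <- force_trace(tr$time[cut:nrow(tr)], tr$depth[cut:nrow(tr)],
                       tr$force[cut:nrow(tr)], velocity = 1.0)
  w2 <- penetration_work(lower)$work[nrow(tr) - cut + 1]
  expect_equal(w1 + w2, wc$work[nrow(tr)], tolerance = 1e-12)
})

test_that("crossing work increases with velocity for a velocity-gained bump", {
  cfg <- trace_config(velocity_gain = 10, noise_sd = 0)
  total <- vapply(velocity_grid(1, 2, 0.2), function(v) {
    wc <- penetration_work(generate_trace(cfg, v, 55 / v))
    wc$work[nrow(wc)]
  }, numeric(1))
  expect_true(all(diff(total) > 0))
})

test_that("mean force profile recovers the generator bump and flags gaps", {
  cfg <- trace_config(noise_sd = 0, peak_amplitude = 20, velocity_gain = 0,
                      peak_center = 25, peak_width = 8, timestep = 0.05)
  tr <- generate_trace(cfg, 1.0, 50)
  prof <- mean_force_profile(list(tr), bin_width = 0.5)
  filled <- prof[!prof$empty, ]
  predicted <- 20 * exp(-(filled$bin_center - 25)^2 / (2 * 8^2))
  expect_lt(max(abs(filled$mean_force - predicted)), 0.05)

  # two identical traces: same profile as one
  prof2 <- mean_force_profile(list(tr, tr), bin_width = 0.5)
  expect_equal(prof2$mean_force, prof$mean_force)
  expect_equal(prof2$n, 2L * prof$n)

  # a depth gap leaves an empty, flagged bin
  tr_gap <- force_trace(time = c(0, 1, 10, 11), depth = c(0, 1, 10, 11),
                        force = rep(1, 4), velocity = 1)
  pg <- mean_force_profile(list(tr_gap), bin_width = 1)
  expect_true(any(pg$empty))
  expect_true(all(is.na(pg$mean_force[pg$empty])))

  expect_error(mean_force_profile(list()), "at least one")
  expect_error(mean_force_profile(list(tr), breaks = 1), "bin")
})

test_that("per-bin noise shrinks as one over sqrt n", {
  cfg <- function(seed) trace_config(noise_sd = 2, seed = seed,
                                     velocity_gain = 0)
  clean <- mean_force_profile(
    list(generate_trace(trace_config(noise_sd = 0, velocity_gain = 0), 1.0, 55)),
    bin_width = 2)
  prof_sd <- function(n) {
    traces <- lapply(seq_len(n), function(s) {
      generate_trace(cfg(s), 1.0, 55)
    })
    prof <- mean_force_profile(traces, bin_width = 2)
    # binned noiseless profile is the exact expectation of each bin mean
    stats::sd(prof$mean_force - clean$mean_force, na.rm = TRUE)
  }
  s4 <- prof_sd(4); s64 <- prof_sd(64)
  expect_equal(s4 / s64, 4, tolerance = 0.5)
})

test_that("rmsd series matches the displacement formula without alignment", {
  ref <- matrix(stats::rnorm(30), ncol = 3)
  expect_equal(rmsd_series(ref, list(ref, ref)), c(0, 0))

  shifted <- sweep(ref, 2, c(1, 0, 0), "+")
  expect_equal(rmsd_series(ref, list(shifted)), 1)

  # one of N atoms displaced by delta: RMSD = delta / sqrt(N)
  one <- ref; one[3, ] <- one[3, ] + c(0, 0, 0.6)
  expect_equal(rmsd_series(ref, list(one)), 0.6 / sqrt(10))

  # global reflection about the reference leaves RMSD unchanged
  refl <- 2 * ref - shifted
  expect_equal(rmsd_series(ref, list(refl)), rmsd_series(ref, list(shifted)))

  expect_error(rmsd_series(ref, list(ref[1:5, ])), "dimensions")
})

test_that("rmsd slope fit is exact on a line and order-invariant", {
  depth <- seq(1, 20, by = 0.5)
  fit <- rmsd_slope(depth, 0.3 * depth)
  expect_equal(fit$slope, 0.3)
  expect_equal(fit$stderr, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)

  set.seed(7)
  rmsd <- 0.3 * depth + rnorm(length(depth), 0, 0.05)
  perm <- sample(seq_along(depth))
  f1 <- rmsd_slope(depth, rmsd)
  f2 <- rmsd_slope(depth[perm], rmsd[perm])
  expect_equal(f2$slope, f1$slope)
  expect_equal(f2$stderr, f1$stderr)

  expect_error(rmsd_slope(rep(1, 5), 1:5), "constant")
  expect_error(rmsd_slope(1:2, 1:2), "3 points")
})

test_that("noisy slope estimate lands within three standard errors", {
  set.seed(11)
  depth <- seq(0, 30, length.out = 100)
  rmsd <- 0.2 * depth + rnorm(100, 0, 0.01)
  fit <- rmsd_slope(depth, rmsd)
  expect_lt(abs(fit$slope - 0.2), 3 * fit$stderr)
  g <- glance(fit)
  expect_equal(g$slope, fit$slope)
  expect_gt(g$r.squared, 0.99)
})
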