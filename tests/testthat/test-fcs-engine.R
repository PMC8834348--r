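test_that("the Gaussian detector weights particles by exp(-2 r^2 / w^2)", {
  prof <- detection_profile(waist = 0.25, center = c(1, 1), brightness = 100,
                            background = 0)
  # immobile particle at the spot centre
  ens <- immobile_ensemble(1, 1)
  tr <- intensity_trace(ens, prof, noise = FALSE)
  expect_equal(tr$counts, rep(100, 10))
  # immobile particle one waist away
  ens2 <- immobile_ensemble(1 + 0.25, 1)
  tr2 <- intensity_trace(ens2, prof, noise = FALSE)
  expect_equal(tr2$counts, rep(100 * exp(-2), 10), tolerance = 1e-12)
  # minimum-image: a particle across the periodic boundary is close
  ens3 <- immobile_ensemble(2 - 0.05, 1, box = 2)
  prof3 <- detection_profile(0.25, c(0.05, 1), 100, 0)
  tr3 <- intensity_trace(ens3, prof3, noise = FALSE)
  expect_equal(tr3$counts[1], 100 * exp(-2 * 0.01 / 0.0625), tolerance = 1e-12)
})

test_that("Poisson photon noise has the right mean", {
  ens <- immobile_ensemble(1, 1, n_frames = 4000)
  prof <- detection_profile(0.25, c(1, 1), brightness = 100, background = 0)
  tr <- intensity_trace(ens, prof, noise = TRUE, seed = 21)
  expect_lt(abs(mean(tr$counts) - 100), 3 * sqrt(100 / 4000))
  expect_true(all(tr$counts >= 0))
})

test_that("bin_time must be an integer multiple of dt", {
  ens <- immobile_ensemble(1, 1)
  prof <- detection_profile(0.25, c(1, 1))
  expect_error(intensity_trace(ens, prof, bin_time = 2.5e-4), "multiple")
  tr <- intensity_trace(ens, prof, bin_time = 2e-4, noise = FALSE)
  expect_length(tr$counts, 5)
})

test_that("direct estimator reproduces hand-computed correlations", {
  tr <- make_trace(c(1, 2, 1, 2))
  acf <- direct_acf(tr, max_lag = 2)
  # zero lag: population variance over squared mean
  expect_equal(acf$g[1], 0.25 / 2.25, tolerance = 1e-12)
  # lag 1 of the alternating trace is negative
  expect_lt(acf$g[2], 0)
  expect_equal(acf$g[2], naive_sym_corr(c(1, 2, 1, 2), 1), tolerance = 1e-12)
  expect_equal(acf$g[3], naive_sym_corr(c(1, 2, 1, 2), 2), tolerance = 1e-12)
  # constant trace is degenerate for both estimators
  expect_error(direct_acf(make_trace(rep(5, 100)), 10), "constant")
  expect_error(multitau_acf(make_trace(rep(5, 100))), "constant")
})

test_that("multi-tau agrees with the direct estimator on shared lags", {
  # deterministic noiseless trace from a short free-diffusion run
  cfg <- sim_config(n_particles = 16, duration = 0.6, dt = 1e-4, d_out = 1,
                    seed = 41)
  ens <- simulate_membrane(cfg)
  prof <- detection_profile(0.25, c(1, 1), brightness = 5, background = 0.1)
  tr <- intensity_trace(ens, prof, noise = FALSE)
  mt <- multitau_acf(tr)
  dc <- direct_acf(tr, max_lag = 64)
  shared <- intersect(round(mt$lag_s / tr$bin_time), 1:64)
  for (k in shared) {
    gm <- mt$g[abs(mt$lag_s - k * tr$bin_time) < 1e-12]
    gd <- dc$g[abs(dc$lag_s - k * tr$bin_time) < 1e-12]
    expect_equal(gm, gd, tolerance = 1e-2)
  }
  # stage-0 lags (no rebinning yet) must agree exactly
  for (k in 1:16) {
    gm <- mt$g[abs(mt$lag_s - k * tr$bin_time) < 1e-12]
    gd <- dc$g[abs(dc$lag_s - k * tr$bin_time) < 1e-12]
    expect_equal(gm, gd, tolerance = 1e-12)
  }
})

test_that("white noise shows no correlation at positive lags", {
  set.seed(5)
  y <- rpois(20000, 100)
  acf <- multitau_acf(make_trace(y))
  se <- (var(y) / mean(y)^2) / sqrt(20000 - round(acf$lag_s / 1e-4))
  pos <- acf$lag_s > 0
  expect_true(all(abs(acf$g[pos]) <= 3.5 * se[pos]))
})

test_that("normalized correlation is invariant to intensity rescaling", {
  set.seed(8)
  y <- rpois(5000, 20) + 1
  a <- multitau_acf(make_trace(y))
  b <- multitau_acf(make_trace(7.3 * y))
  expect_equal(a$g, b$g, tolerance = 1e-12)
})

test_that("run averaging computes per-lag means and standard errors", {
  tr <- make_trace(rpois(2000, 50))
  base <- multitau_acf(tr)
  # twenty identical curves: mean is the input, SE is zero
  avg <- average_acf(rep(list(base), 20))
  expect_equal(avg$g, base$g)
  expect_equal(avg$g_err, rep(0, nrow(base)))
  expect_identical(attr(avg, "n_runs"), 20L)
  # two-point special case: SE equals half the range
  c1 <- raftdyn:::new_acf_curve(c(1e-4, 2e-4), c(0.2, 0.2))
  c2 <- raftdyn:::new_acf_curve(c(1e-4, 2e-4), c(0.4, 0.4))
  avg2 <- average_acf(list(c1, c2))
  expect_equal(avg2$g, c(0.3, 0.3))
  expect_equal(avg2$g_err, c(0.1, 0.1))
  # mismatched grids are refused
  c3 <- raftdyn:::new_acf_curve(c(1e-4, 3e-4), c(0.4, 0.4))
  expect_error(average_acf(list(c1, c3)), "lag grid")
})

test_that("ACF amplitude scales inversely with spot occupancy", {
  amp_for <- function(n, seed) {
    cfg <- sim_config(box_size = 2, n_particles = n, duration = 5, dt = 1e-4,
                      d_out = 1, seed = seed)
    ens <- simulate_membrane(cfg, max_entries = 1e7)
    prof <- detection_profile(0.3, c(1, 1), brightness = 4, background = 0.1)
    tr <- intensity_trace(ens, prof, noise = TRUE, seed = seed + 1)
    coef(fit_acf(multitau_acf(tr)))["amplitude"]
  }
  a32 <- mean(vapply(1:3, function(i) amp_for(32, 600 + i), numeric(1)))
  a64 <- mean(vapply(1:3, function(i) amp_for(64, 700 + i), numeric(1)))
  expect_equal(a32 / a64, 2, tolerance = 0.15)
})

test_that("fitted diffusion time matches omega^2 / (4 D) for free diffusion", {
  cfg <- sim_config(box_size = 2, n_particles = 48, duration = 3, dt = 1e-4,
                    d_out = 1, seed = 55)
  prof <- detection_profile(0.25, c(1, 1), brightness = 3, background = 0.1)
  runs <- lapply(1:10, function(r) {
    cfg$seed <- 550 + r
    ens <- simulate_membrane(cfg, max_entries = 1e7)
    multitau_acf(intensity_trace(ens, prof, noise = TRUE, seed = 800 + r))
  })
  fit <- fit_acf(average_acf(runs))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["tau_d"]), 0.25^2 / 4, tolerance = 0.1)
})
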