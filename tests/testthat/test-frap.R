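test_that("the uniform-disk recovery curve has the right limits", {
  expect_equal(soumpasis_recovery(0, 1), 0)
  expect_equal(soumpasis_recovery(1e6, 1), 1, tolerance = 1e-3)
  t <- seq(0.1, 50, by = 0.1)
  f <- soumpasis_recovery(t, 5)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
})

test_that("the closed-form recovery matches a lattice-diffusion oracle", {
  d <- 0.025
  r <- 1.25
  tau <- r^2 / (4 * d)
  for (t in c(0.5 * tau, tau, 2 * tau)) {
    oracle <- lattice_frap_recovery(t, d, r)
    expect_equal(soumpasis_recovery(t, tau), oracle, tolerance = 0.02)
  }
})

test_that("simulated curves honour depth, mobility and noiselessness", {
  cfg <- frap_config(noise_cv = 0, bleach_depth = 0.8)
  # immobile pool only: flat post-bleach at 1 - depth
  flat <- simulate_frap(0.025, 0, cfg)
  post <- flat$intensity[flat$time_s >= 0]
  expect_equal(post, rep(0.2, length(post)), tolerance = 1e-12)
  # full recovery at 100% mobile: approaches the pre-bleach level
  full <- simulate_frap(0.1, 100, frap_config(noise_cv = 0, bleach_depth = 1,
                                              n_postbleach = 400))
  expect_equal(tail(full$intensity, 1), 1, tolerance = 0.01)
  expect_error(simulate_frap(0.025, 150, cfg), "mobile_fraction")
})

test_that("normalization anchors first post-bleach frame at 0, pre-bleach at 1", {
  raw <- structure(data.frame(time_s = c(-2, -1, 0, 1, 2),
                              intensity = c(100, 100, 40, 70, 85)),
                   class = c("frap_curve", "data.frame"))
  nrm <- normalize_frap(raw)
  expect_equal(nrm$normalized, c(1, 1, 0, 0.5, 0.75))
  # idempotence: an already normalized curve is unchanged
  again <- normalize_frap(data.frame(time_s = raw$time_s,
                                     intensity = nrm$normalized))
  expect_equal(again$normalized, nrm$normalized)
  # constant curve has no bleach to normalize against
  expect_error(normalize_frap(data.frame(time_s = c(-1, 0, 1),
                                         intensity = c(5, 5, 5))),
               "degenerate")
})

test_that("noiseless round trips recover t_half and mobile fraction", {
  cfg <- frap_config(noise_cv = 0)
  tau <- 13.7 / raftdyn:::soumpasis_half_factor()
  d <- (cfg$roi_diameter / 2)^2 / (4 * tau)
  fit <- fit_frap(normalize_frap(simulate_frap(d, 42.13, cfg)))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["mobile_fraction"]), 42.13, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["t_half"]), 13.7, tolerance = 1e-3)
  # the fitted curve reaches half its plateau exactly at t_half
  co <- coef(fit)
  expect_equal(unname(predict(fit, co["t_half"])),
               unname(co["mobile_fraction"]) / 200, tolerance = 1e-6)
})

test_that("the single-exponential model has t_half = tau log(2)", {
  cfg <- frap_config(noise_cv = 0)
  t_post <- seq(0, 148.5, by = 1.5)
  y <- 1 - exp(-t_post / 10)
  curve <- data.frame(time_s = c(-1.5, t_post), intensity = c(1, 1 - y))
  # intensity constructed so the normalized curve equals y exactly
  curve$intensity[-1] <- 1 - (1 - 0) * (1 - y)
  fit <- fit_frap(normalize_frap(curve), model = "exponential")
  expect_equal(unname(coef(fit)["tau_model"]), 10, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["t_half"]), 10 * log(2), tolerance = 1e-4)
})

test_that("noisy round trips are unbiased within 3%", {
  cfg <- frap_config(noise_cv = 0.02)
  tau <- 13.7 / raftdyn:::soumpasis_half_factor()
  d <- (cfg$roi_diameter / 2)^2 / (4 * tau)
  fits <- lapply(1:50, function(i)
    fit_frap(normalize_frap(simulate_frap(d, 42.13, cfg, seed = 3000 + i))))
  th <- vapply(fits, function(f) unname(coef(f)["t_half"]), numeric(1))
  mf <- vapply(fits, function(f) unname(coef(f)["mobile_fraction"]), numeric(1))
  expect_equal(mean(th), 13.7, tolerance = 0.03)
  expect_equal(mean(mf), 42.13, tolerance = 0.03)
  expect_true(all(mf <= 100))
})

test_that("fits are invariant under affine rescaling of raw intensities", {
  cfg <- frap_config(noise_cv = 0.02)
  curve <- simulate_frap(0.03, 60, cfg, seed = 99)
  scaled <- curve
  scaled$intensity <- 850 * curve$intensity + 120
  f1 <- coef(fit_frap(normalize_frap(curve)))
  f2 <- coef(fit_frap(normalize_frap(scaled)))
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("a flat post-bleach curve is reported as fully immobile", {
  cfg <- frap_config(noise_cv = 0)
  fit <- fit_frap(normalize_frap(simulate_frap(0.025, 0, cfg)))
  expect_equal(unname(coef(fit)["mobile_fraction"]), 0)
  expect_true(is.na(coef(fit)["t_half"]))
})
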