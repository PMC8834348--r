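test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config(d_in = 2, d_out = 1), "d_in")
  expect_error(sim_config(p_enter = 1.2), "p_enter")
  expect_error(sim_config(dt = 1, d_out = 1, box_size = 2), "time step")
  expect_error(sim_config(box_size = -1), "box_size")
})

test_that("domain placement matches the area-fraction count and never overlaps", {
  cfg <- sim_config(box_size = 2)
  # no-domain case
  dm0 <- init_domains(cfg, 0, 0.05)
  expect_equal(nrow(dm0$centers), 0)
  expect_equal(dm0$area_fraction, 0)
  # nearest-integer disk count, checked by direct area summation
  dm <- init_domains(cfg, 0.10, 0.05, seed = 11)
  expect_equal(nrow(dm$centers), 51)
  area <- nrow(dm$centers) * pi * 0.05^2 / 2^2
  expect_equal(dm$area_fraction, area)
  expect_lt(abs(area - 0.10) / 0.10, 0.01)
  # pairwise minimum-image separation at least one diameter
  n <- nrow(dm$centers)
  d2min <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- abs(dm$centers[i, 1] - dm$centers[j, 1]); dx <- min(dx, 2 - dx)
    dy <- abs(dm$centers[i, 2] - dm$centers[j, 2]); dy <- min(dy, 2 - dy)
    d2min <- min(d2min, dx^2 + dy^2)
  }
  expect_gte(sqrt(d2min), 2 * 0.05 - 1e-12)
  # precondition: a domain as large as the box
  expect_error(init_domains(cfg, 0.1, 1), "radius")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_particles = 10, duration = 0.01, dt = 1e-4, seed = 99)
  dm <- init_domains(cfg, 0.1, 0.04, seed = 5)
  e1 <- simulate_membrane(cfg, dm)
  e2 <- simulate_membrane(cfg, dm)
  expect_identical(e1$x, e2$x)
  expect_identical(e1$y, e2$y)
  expect_identical(e1$in_domain, e2$in_domain)
})

test_that("free diffusion obeys the Einstein relation MSD = 4 D t", {
  cfg <- sim_config(n_particles = 1000, duration = 0.03, dt = 1e-4,
                    d_out = 1, seed = 2)
  ens <- simulate_membrane(cfg)
  m <- msd(ens, lags = c(1, 2, 5, 10, 20, 50, 100))
  expect_true(all(abs(m$msd_um2 / (4 * 1 * m$lag_s) - 1) < 0.05))
})

test_that("transparent domains reproduce domain-free Brownian motion", {
  # p_enter = p_escape = 1 and d_in = d_out: the stepper must reduce
  # exactly to free diffusion (no acceptance draws are consumed)
  cfg <- sim_config(n_particles = 200, duration = 0.2, dt = 2e-5,
                    d_out = 0.5, d_in = 0.5, p_enter = 1, p_escape = 1,
                    seed = 31)
  dm <- init_domains(cfg, 0.1, 0.04, seed = 6)
  with_domains <- simulate_membrane(cfg, dm)
  free <- simulate_membrane(cfg, NULL)
  expect_identical(with_domains$x, free$x)
  expect_identical(with_domains$y, free$y)
  m <- msd(with_domains, lags = c(10, 50, 100))
  expect_true(all(abs(m$msd_um2 / (4 * 0.5 * m$lag_s) - 1) < 0.02))
})

test_that("a trap with p_escape = 0 is absorbing", {
  cfg <- sim_config(box_size = 2, n_particles = 5, duration = 0.05, dt = 2e-5,
                    d_out = 1, d_in = 0.1, p_enter = 1, p_escape = 0, seed = 3)
  dm <- structure(list(centers = matrix(c(1, 1), 1, 2), radius = 0.1,
                       area_fraction = pi * 0.01 / 4, box_size = 2),
                  class = "domain_map")
  ens <- simulate_membrane(cfg, dm,
                           init = list(x = rep(1, 5), y = rep(1, 5)))
  expect_true(all(ens$in_domain))
})

test_that("trapping enriches domain occupancy above the area fraction", {
  cfg <- sim_config(box_size = 2, n_particles = 32, duration = 4, dt = 2e-5,
                    d_out = 1.8, d_in = 0.1, p_enter = 0.02, p_escape = 0.018,
                    seed = 17)
  dm <- init_domains(cfg, 0.1, 0.04, seed = 18)
  ens <- simulate_membrane(cfg, dm, max_entries = 1e7)
  # discard the equilibration from the uniform start
  occ <- mean(ens$in_domain[-(1:50000), ])
  expect_gt(occ, dm$area_fraction * 1.5)
})

test_that("mean residence time does not decrease when p_escape is lowered", {
  mean_res <- function(p_escape) {
    taus <- vapply(1:5, function(r) {
      cfg <- sim_config(box_size = 2, n_particles = 16, duration = 2,
                        dt = 2e-5, d_out = 1.5, d_in = 0.1, p_enter = 0.05,
                        p_escape = p_escape, seed = 400 + r)
      dm <- init_domains(cfg, 0.1, 0.04, seed = 500 + r)
      mean(residence_times(simulate_membrane(cfg, dm, max_entries = 1e7)))
    }, numeric(1))
    mean(taus)
  }
  res <- vapply(c(0.09, 0.03, 0.01), mean_res, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("the memory guard refuses oversized ensembles", {
  cfg <- sim_config(n_particles = 1000, duration = 10, dt = 1e-4)
  expect_error(simulate_membrane(cfg), "too large")
})

test_that("presets cover the study conditions and order trapping strength", {
  expect_error(condition_preset("nope"), "unknown condition")
  expect_setequal(preset_conditions(),
                  c("SM_control", "SM_KnD", "SM_ZA_Myr", "SM_rescue",
                    "PC_control", "PC_KnD", "Thy1_control", "Thy1_KnD",
                    "Flot2_control", "Flot2_KnD", "Flot2_MbCD"))
  # the non-raft lipid diffuses freely: no effective trapping
  pc <- condition_preset("PC_control")
  expect_equal(pc$config$p_enter, 0)
  expect_equal(pc$domains$area_fraction, 0)
  # MPP1 knockdown weakens confinement: shorter domain residence than control
  res_for <- function(cond) {
    p <- condition_preset(cond, n_particles = 16, duration = 3)
    p$config$seed <- 77
    dm <- init_domains(p$config, p$domains$area_fraction, p$domains$radius,
                       seed = 78)
    mean(residence_times(simulate_membrane(p$config, dm, max_entries = 1e7)))
  }
  expect_gt(res_for("SM_control"), res_for("SM_KnD"))
  # published intercepts order Thy-1 above SM in the control cells
  expect_gt(condition_preset("Thy1_control")$law$t0_ms,
            condition_preset("SM_control")$law$t0_ms)
})

test_that("step_ensemble advances a state by one frame", {
  cfg <- sim_config(n_particles = 4, duration = 0.01, dt = 1e-4, d_out = 1)
  st <- list(x = c(0.5, 1, 1.5, 0.2), y = c(0.5, 1, 1.5, 0.2))
  nxt <- step_ensemble(st, cfg, seed = 9)
  expect_length(nxt$x, 4)
  expect_true(all(nxt$x >= 0 & nxt$x < 2))
  step <- sqrt((nxt$x - st$x)^2 + (nxt$y - st$y)^2)
  expect_true(all(step < 10 * sqrt(2 * 1 * 1e-4) * sqrt(2)))
})
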