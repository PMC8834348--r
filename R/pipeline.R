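# One virtual cell measured by svFCS: simulate trajectories for the whole
# acquisition (runs_per_cell consecutive runs), record photon traces through
# one Gaussian spot per waist (all spots share the box centre, so the same
# membrane is observed at every spot size), correlate each run, average the
# runs and fit the 2D diffusion model per waist. Returns tau_d (s) per waist.
particle_cell_tau <- function(preset, waists, runs_per_cell, run_duration,
                              seed, cell_id = NA, warmup_s = 2) {
  cfg <- preset$config
  det <- preset$detection
  bin <- det$bin_time_s
  steps_per_bin <- as.integer(round(bin / cfg$dt))
  stopifnot(abs(steps_per_bin * cfg$dt - bin) < 1e-12, steps_per_bin >= 1)
  bins_per_run <- as.integer(round(run_duration / bin))
  n_bins <- bins_per_run * runs_per_cell

  set.seed(seed)
  if (preset$domains$area_fraction > 0 && cfg$p_enter > 0) {
    domains <- init_domains(cfg, preset$domains$area_fraction,
                            preset$domains$radius,
                            seed = sample.int(.Machine$integer.max, 1L))
  } else {
    domains <- empty_domains(cfg)
  }
  x0 <- runif(cfg$n_particles, 0, cfg$box_size)
  y0 <- runif(cfg$n_particles, 0, cfg$box_size)
  dom0 <- locate_domains(x0, y0, domains)
  ctr <- cfg$box_size / 2
  lam <- .sim_intensity_cpp(x0, y0, dom0, n_bins, steps_per_bin,
                            as.integer(round(warmup_s / cfg$dt)),
                            cfg$dt, cfg$box_size, cfg$d_out, cfg$d_in,
                            cfg$p_enter, cfg$p_escape,
                            domains$centers, domains$radius,
                            rep(ctr, length(waists)), rep(ctr, length(waists)),
                            waists, det$brightness, det$background,
                            sample.int(.Machine$integer.max, 1L))
  counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam))

  vapply(seq_along(waists), function(s) {
    runs <- lapply(seq_len(runs_per_cell), function(r) {
      i0 <- (r - 1L) * bins_per_run
      trace <- new_intensity_trace(counts[i0 + seq_len(bins_per_run), s],
                                   bin, run_id = r, cell_id = cell_id)
      multitau_acf(trace)
    })
    fit <- fit_acf(average_acf(runs))
    unname(coef(fit)["tau_d"])
  }, numeric(1))
}

#' Run a virtual svFCS experiment for one condition
#'
#' End-to-end orchestration of the diffusion-law measurement, at one of two
#' fidelity tiers. In `"particle"` mode each cell is a fresh Monte Carlo
#' membrane (own domain map and probes); photon traces are recorded through
#' Gaussian spots of every requested waist, correlated run by run with the
#' multi-tau estimator, averaged per cell, and fitted with the 2D lateral
#' diffusion model; the per-cell diffusion times are aggregated per waist
#' and the diffusion law is fitted. In `"law_level"` mode per-cell
#' diffusion times are drawn directly from the condition's published law
#' parameters ([simulate_law_points()]), which makes parameter-recovery
#' round trips run in milliseconds. Both modes share the inference code
#' path from [aggregate_cells()] onwards.
#'
#' @param condition a preset name, see [preset_conditions()].
#' @param waists spot waists (um).
#' @param n_cells number of cells.
#' @param runs_per_cell,run_duration acquisition per cell (particle mode).
#' @param seed root RNG seed; child seeds for every stage are derived from
#'   it, so reports are exactly reproducible.
#' @param mode fidelity tier.
#' @param threshold regime significance threshold.
#' @return object of class `svfcs_report`: the fitted `diffusion_law`, the
#'   per-waist table, and provenance (condition, mode, seed, sizes).
#' @examples
#' rep <- run_svfcs_experiment("PC_control", mode = "law_level", seed = 1)
#' rep$law$regime
#' @export
run_svfcs_experiment <- function(condition,
                                 waists = NULL,
                                 n_cells = 15,
                                 runs_per_cell = 20,
                                 run_duration = 5,
                                 seed = NULL,
                                 mode = c("law_level", "particle"),
                                 threshold = 2) {
  mode <- match.arg(mode)
  stopifnot(n_cells >= 2, runs_per_cell >= 1, run_duration > 0)
  preset <- condition_preset(condition, duration = run_duration)
  if (is.null(waists)) waists <- preset$waists
  seed <- resolve_seed(seed)
  set.seed(seed)

  if (mode == "law_level") {
    if (is.null(preset$law))
      stop("stage law_level: condition '", condition,
           "' has no published diffusion-law parameters")
    points <- simulate_law_points(preset$law$t0_ms, preset$law$d_eff,
                                  waists = waists, n_cells = n_cells,
                                  cell_noise_cv = preset$law$cell_cv %||% 0.15,
                                  seed = sample.int(.Machine$integer.max, 1L))
  } else {
    cell_seeds <- sample.int(.Machine$integer.max, n_cells)
    tau <- vapply(seq_len(n_cells), function(i)
      particle_cell_tau(preset, waists, runs_per_cell, run_duration,
                        seed = cell_seeds[i], cell_id = i),
      numeric(length(waists)))
    tau <- matrix(tau, nrow = length(waists))  # [waist, cell], seconds
    points <- do.call(rbind, lapply(seq_along(waists), function(s)
      aggregate_cells(1000 * tau[s, ], waists[s])))
  }
  law <- tryCatch(fit_diffusion_law(points, threshold = threshold),
                  error = function(e)
                    stop("stage diffusion_law: ", conditionMessage(e)))
  structure(list(condition = condition, mode = mode, law = law,
                 points = points,
                 provenance = list(seed = seed, n_cells = n_cells,
                                   waists = waists,
                                   runs_per_cell = runs_per_cell,
                                   run_duration = run_duration,
                                   preset_version = preset_db()$version,
                                   package_version =
                                     as.character(utils::packageVersion("raftdyn")))),
            class = "svfcs_report")
}

#' @export
print.svfcs_report <- function(x, ...) {
  cat(sprintf("svFCS condition report: %s (%s mode, seed %d)\n",
              x$condition, x$mode, x$provenance$seed))
  print(x$law)
  invisible(x)
}

#' Run a virtual FRAP experiment for one condition
#'
#' Simulates `n_cells` recovery curves from the condition's ground-truth
#' half-time and mobile fraction, fits each with [fit_frap()], and reports
#' mean and SD of the recovered parameters.
#'
#' @param condition a preset with FRAP ground truth (see [frap_preset()]).
#' @param n_cells number of cells (curves).
#' @param config a [frap_config()].
#' @param seed root RNG seed.
#' @return object of class `frap_experiment` with `summary` (one-row
#'   data.frame) and the per-cell `fits`.
#' @examples
#' ex <- run_frap_experiment("Flot2_control", n_cells = 5, seed = 1)
#' ex$summary
#' @export
run_frap_experiment <- function(condition, n_cells = 37,
                                config = frap_config(), seed = NULL) {
  gt <- frap_preset(condition)
  stopifnot(n_cells >= 1)
  seed <- resolve_seed(seed)
  set.seed(seed)
  r <- config$roi_diameter / 2
  tau <- gt$t_half_s / soumpasis_half_factor()
  d <- r^2 / (4 * tau)
  fits <- lapply(seq_len(n_cells), function(i) {
    curve <- simulate_frap(d, gt$mobile_pct, config,
                           seed = sample.int(.Machine$integer.max, 1L))
    fit_frap(normalize_frap(curve))
  })
  th <- vapply(fits, function(f) coef(f)["t_half"], numeric(1))
  mf <- vapply(fits, function(f) coef(f)["mobile_fraction"], numeric(1))
  summary <- data.frame(condition = condition, n_cells = n_cells,
                        t_half_mean_s = mean(th),
                        t_half_sd_s = if (n_cells > 1) sd(th) else 0,
                        mobile_mean_pct = mean(mf),
                        mobile_sd_pct = if (n_cells > 1) sd(mf) else 0)
  structure(list(condition = condition, summary = summary, fits = fits,
                 provenance = list(seed = seed, n_cells = n_cells,
                                   config = unclass(config))),
            class = "frap_experiment")
}

#' @export
print.frap_experiment <- function(x, ...) {
  cat(sprintf("FRAP experiment: %s, %d cells\n", x$condition,
              x$provenance$n_cells))
  cat(sprintf("  t_half          %.3g +/- %.2g s (mean +/- SD)\n",
              x$summary$t_half_mean_s, x$summary$t_half_sd_s))
  cat(sprintf("  mobile fraction %.4g +/- %.2g %%\n",
              x$summary$mobile_mean_pct, x$summary$mobile_sd_pct))
  invisible(x)
}

#' Tabulate and contrast condition reports
#'
#' Side-by-side comparison of two or more reports of the same kind:
#' svFCS reports are contrasted on `t0` and `D_eff`, FRAP experiments on
#' `t_half` and mobile fraction. Differences and ratios are taken against
#' the first (reference) report; for svFCS the reference/other `t0` ratio
#' (e.g. control over knockdown) is included.
#'
#' @param reports list of `svfcs_report`s or of `frap_experiment`s.
#' @return data.frame with one row per report plus contrast columns.
#' @examples
#' a <- run_svfcs_experiment("SM_control", mode = "law_level", seed = 1)
#' b <- run_svfcs_experiment("SM_KnD", mode = "law_level", seed = 2)
#' compare_conditions(list(a, b))
#' @export
compare_conditions <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 2)
  is_sv <- vapply(reports, inherits, TRUE, "svfcs_report")
  is_fr <- vapply(reports, inherits, TRUE, "frap_experiment")
  if (all(is_sv)) {
    tab <- do.call(rbind, lapply(reports, function(r)
      data.frame(condition = r$condition, t0_ms = r$law$t0,
                 t0_sem_ms = r$law$t0_sem, d_eff = r$law$d_eff,
                 d_eff_sem = r$law$d_eff_sem, regime = r$law$regime)))
    tab$t0_diff_ms <- tab$t0_ms - tab$t0_ms[1]
    tab$t0_ratio_ref <- tab$t0_ms[1] / tab$t0_ms
    tab$d_eff_ratio <- tab$d_eff / tab$d_eff[1]
  } else if (all(is_fr)) {
    tab <- do.call(rbind, lapply(reports, function(r) r$summary))
    tab$t_half_diff_s <- tab$t_half_mean_s - tab$t_half_mean_s[1]
    tab$mobile_diff_pct <- tab$mobile_mean_pct - tab$mobile_mean_pct[1]
  } else {
    stop("cannot compare mixed or unknown report types")
  }
  tab
}
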