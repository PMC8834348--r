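#' Read and write autocorrelation curves as CSV
#'
#' The on-disk format has columns `lag_s`, `g` and optionally `g_err`,
#' matching the per-lag structure of [multitau_acf()] output, so measured
#' curves from other correlators can enter [fit_acf()] directly.
#'
#' @param curve an `acf_curve`.
#' @param path file path.
#' @param bin_time,duration metadata attached on read (s); used for the
#'   default fitted lag range.
#' @return `read_acf_csv` returns an `acf_curve`; `write_acf_csv` its
#'   `path`, invisibly.
#' @export
write_acf_csv <- function(curve, path) {
  stopifnot(inherits(curve, "acf_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_acf_csv
#' @export
read_acf_csv <- function(path, bin_time = NA_real_, duration = NA_real_) {
  d <- read.csv(path)
  stopifnot(all(c("lag_s", "g") %in% names(d)))
  if (is.null(d$g_err)) d$g_err <- NA_real_
  d <- d[order(d$lag_s), ]
  new_acf_curve(d$lag_s, d$g, d$g_err, bin_time = bin_time,
                duration = duration)
}

#' Read per-waist diffusion-time tables
#'
#' Expects columns `waist_um` (or `waist_sq_um2`), `tau_d_ms`, and
#' optionally `tau_d_sem_ms`, `n_cells`; rows are per-waist summaries
#' ready for [fit_diffusion_law()].
#'
#' @param path CSV file path.
#' @return data.frame of per-waist rows.
#' @export
read_law_csv <- function(path) {
  d <- read.csv(path)
  if (!"waist_sq_um2" %in% names(d)) {
    stopifnot("waist_um" %in% names(d))
    d$waist_sq_um2 <- d$waist_um^2
  }
  if (!"waist_um" %in% names(d)) d$waist_um <- sqrt(d$waist_sq_um2)
  stopifnot("tau_d_ms" %in% names(d))
  if (is.null(d$tau_d_sem_ms)) d$tau_d_sem_ms <- NA_real_
  if (is.null(d$n_cells)) d$n_cells <- NA_integer_
  d
}

#' Write a condition report as tidy CSV plus JSON summary
#'
#' The CSV carries one row per waist (condition, waist, squared waist, mean
#' diffusion time, SEM, cells); the JSON carries the fitted law summary
#' (t0, D_eff, SEMs, regime) and provenance.
#'
#' @param report an `svfcs_report`.
#' @param csv_path,json_path output paths (`NULL` skips that file).
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "svfcs_report"))
  if (!is.null(csv_path)) {
    tab <- cbind(condition = report$condition, report$points)
    write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    law <- report$law
    jsonlite::write_json(
      list(condition = report$condition, mode = report$mode,
           t0_ms = law$t0, t0_sem_ms = law$t0_sem,
           d_eff = law$d_eff, d_eff_sem = law$d_eff_sem,
           regime = law$regime, provenance = report$provenance),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}

#' Read and write FRAP curves as CSV
#'
#' Columns `time_s`, `intensity` (bleach at time 0, pre-bleach frames at
#' negative times) and optionally `normalized`.
#'
#' @param curve a `frap_curve`.
#' @param path file path.
#' @return `read_frap_csv` returns a `frap_curve`; `write_frap_csv` its
#'   `path`, invisibly.
#' @export
write_frap_csv <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("time_s", "intensity") %in% names(d)))
  structure(d[order(d$time_s), , drop = FALSE],
            class = c("frap_curve", "data.frame"))
}

#' Export trajectories
#'
#' `write_trajectories_csv` writes the long format (`particle_id`, `frame`,
#' `x_um`, `y_um`, `in_domain`); `write_trajectories_bin` writes a compact
#' little-endian double array (header: n_frames, n_particles, dt, box_size;
#' then x, y column-major; then in_domain as doubles).
#'
#' @param ensemble a [simulate_membrane()] result.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_trajectories_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  nf <- nrow(ensemble$x); np <- ncol(ensemble$x)
  d <- data.frame(particle_id = rep(seq_len(np), each = nf),
                  frame = rep(seq_len(nf), np),
                  x_um = as.vector(ensemble$x),
                  y_um = as.vector(ensemble$y),
                  in_domain = as.vector(ensemble$in_domain))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
write_trajectories_bin <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(c(nrow(ensemble$x), ncol(ensemble$x),
                       ensemble$dt, ensemble$box_size)), con, endian = "little")
  writeBin(as.double(ensemble$x), con, endian = "little")
  writeBin(as.double(ensemble$y), con, endian = "little")
  writeBin(as.double(ensemble$in_domain), con, endian = "little")
  invisible(path)
}

#' Read and write simulation configurations as JSON
#'
#' Field names match [sim_config()] arguments (`box_size`, `n_particles`,
#' `dt`, `duration`, `d_out`, `d_in`, `p_enter`, `p_escape`, `seed`).
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config()]; `write_sim_config`
#'   its `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, jsonlite::fromJSON(path))
}
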