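#' Configuration of a membrane diffusion simulation
#'
#' Collects the physical and numerical parameters of the particle-level
#' Monte Carlo model: free Brownian motion at `d_out` outside circular
#' trapping nanodomains, slowed motion at `d_in` inside them, and
#' probabilistic boundary crossing (`p_enter` outwards-in, `p_escape`
#' inwards-out). The membrane is a periodic square of side `box_size`.
#'
#' The time step must resolve the box (`sqrt(2 * d_out * dt) <= box_size/10`);
#' when domains are present the caller should additionally keep the step
#' below about a quarter of the domain radius so that boundary interactions
#' are resolved rather than tunnelled through (the presets do).
#'
#' @param box_size side of the periodic box (um).
#' @param n_particles number of probes.
#' @param dt integration time step (s).
#' @param duration simulated time span (s).
#' @param d_out diffusion coefficient outside domains (um^2/s).
#' @param d_in diffusion coefficient inside domains (um^2/s); must satisfy
#'   `0 < d_in <= d_out`.
#' @param p_enter probability that a step crossing a domain boundary from
#'   outside is accepted, in `[0, 1]`.
#' @param p_escape probability that a step crossing a domain boundary from
#'   inside is accepted, in `[0, 1]`.
#' @param seed integer RNG seed; `NULL` draws one from the session RNG.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_particles = 10, duration = 0.01)
#' cfg
#' @export
sim_config <- function(box_size = 2, n_particles = 64, dt = 5e-5,
                       duration = 5, d_out = 1, d_in = d_out,
                       p_enter = 1, p_escape = 1, seed = NULL) {
  stopifnot(box_size > 0, n_particles >= 1, dt > 0, duration >= dt,
            d_out > 0, d_in > 0, d_in <= d_out,
            p_enter >= 0, p_enter <= 1, p_escape >= 0, p_escape <= 1)
  if (sqrt(2 * d_out * dt) > box_size / 10)
    stop("time step too coarse: sqrt(2 * d_out * dt) must be <= box_size / 10")
  structure(list(box_size = box_size, n_particles = as.integer(n_particles),
                 dt = dt, duration = duration, d_out = d_out, d_in = d_in,
                 p_enter = p_enter, p_escape = p_escape,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Membrane simulation configuration\n")
  cat(sprintf("  box %.2f um, %d particles, dt %.2g s, duration %.3g s\n",
              x$box_size, x$n_particles, x$dt, x$duration))
  cat(sprintf("  D_out %.3g um^2/s, D_in %.3g um^2/s, p_enter %.3g, p_escape %.3g\n",
              x$d_out, x$d_in, x$p_enter, x$p_escape))
  invisible(x)
}

#' Place non-overlapping trapping nanodomains
#'
#' Draws `round(f * L^2 / (pi * r^2))` disk centres by rejection sampling so
#' that no two disks overlap (minimum-image distance at least `2 * radius`),
#' giving an achieved area fraction within 1% of the target. Raft
#' nanodomains in cells are sub-100-nm objects, hence the default radius.
#'
#' @param config a [sim_config()].
#' @param target_area_fraction fraction of the box covered by domains,
#'   in `[0, 0.5)`.
#' @param radius common domain radius (um); must be below `box_size / 4`.
#' @param seed integer RNG seed; `NULL` draws one from the session RNG.
#' @param max_reject maximum number of rejected placements before the
#'   packing is declared infeasible.
#' @return an object of class `domain_map`: list with `centers` (n x 2
#'   matrix, um), `radius`, `area_fraction` and `box_size`.
#' @examples
#' cfg <- sim_config()
#' dm <- init_domains(cfg, 0.10, 0.04, seed = 1)
#' dm$area_fraction
#' @export
init_domains <- function(config, target_area_fraction = 0.1, radius = 0.04,
                         seed = NULL, max_reject = 1e5) {
  stopifnot(inherits(config, "sim_config"),
            target_area_fraction >= 0, target_area_fraction < 0.5)
  if (radius >= config$box_size / 4)
    stop("domain radius must be below box_size / 4")
  L <- config$box_size
  n <- round(target_area_fraction * L^2 / (pi * radius^2))
  if (n == 0)
    return(structure(list(centers = matrix(numeric(0), 0, 2), radius = radius,
                          area_fraction = 0, box_size = L),
                     class = "domain_map"))
  set.seed(resolve_seed(seed))
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  rejected <- 0L
  min2 <- (2 * radius)^2
  while (placed < n) {
    p <- runif(2, 0, L)
    ok <- TRUE
    if (placed > 0) {
      dx <- abs(centers[seq_len(placed), 1] - p[1])
      dy <- abs(centers[seq_len(placed), 2] - p[2])
      dx <- pmin(dx, L - dx)
      dy <- pmin(dy, L - dy)
      ok <- all(dx * dx + dy * dy >= min2)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- p
    } else {
      rejected <- rejected + 1L
      if (rejected > max_reject)
        stop("domain packing infeasible: too many rejected placements for ",
             "area fraction ", target_area_fraction)
    }
  }
  structure(list(centers = centers, radius = radius,
                 area_fraction = n * pi * radius^2 / L^2, box_size = L),
            class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("Domain map: %d disks of radius %.3g um, area fraction %.3f in a %.2f um box\n",
              nrow(x$centers), x$radius, x$area_fraction, x$box_size))
  invisible(x)
}

empty_domains <- function(config) {
  structure(list(centers = matrix(numeric(0), 0, 2), radius = 0.01,
                 area_fraction = 0, box_size = config$box_size),
            class = "domain_map")
}

#' Which domain contains each point
#'
#' @param x,y coordinates (um).
#' @param domains a [init_domains()] map.
#' @return integer vector, 0 for "outside", otherwise the 1-based disk index.
#' @export
locate_domains <- function(x, y, domains) {
  .locate_domains_cpp(as.numeric(x), as.numeric(y), domains$centers,
                      domains$radius, domains$box_size)
}

#' Simulate probe trajectories
#'
#' Runs the Monte Carlo stepper for `duration / dt` frames and returns all
#' positions, wrapped periodically into `[0, box_size)`. Reproducible given
#' `config$seed`. A memory guard refuses ensembles above `max_entries`
#' stored positions; record intensities on the fly with
#' [intensity_trace()]'s `ensemble = NULL` pathway (see
#' [run_svfcs_experiment()]) for long runs.
#'
#' @param config a [sim_config()].
#' @param domains a [init_domains()] map; `NULL` for a domain-free membrane.
#' @param init optional list with `x`, `y` initial positions (um); default
#'   uniform in the box.
#' @param max_entries memory guard on `frames * particles`.
#' @return an object of class `trajectory_ensemble`: list with matrices
#'   `x`, `y`, `in_domain` indexed `[frame, particle]`, plus `dt` and
#'   `box_size`.
#' @examples
#' cfg <- sim_config(n_particles = 20, duration = 0.01, seed = 1)
#' ens <- simulate_membrane(cfg)
#' dim(ens$x)
#' @export
simulate_membrane <- function(config, domains = NULL, init = NULL,
                              max_entries = 6e7) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(domains)) domains <- empty_domains(config)
  n_frames <- as.integer(round(config$duration / config$dt))
  if (as.double(n_frames) * config$n_particles > max_entries)
    stop("ensemble too large (", n_frames, " frames x ", config$n_particles,
         " particles); raise max_entries or record intensities on the fly")
  set.seed(resolve_seed(config$seed))
  if (is.null(init)) {
    x0 <- runif(config$n_particles, 0, config$box_size)
    y0 <- runif(config$n_particles, 0, config$box_size)
  } else {
    x0 <- init$x; y0 <- init$y
    stopifnot(length(x0) == config$n_particles, length(y0) == config$n_particles)
  }
  dom0 <- locate_domains(x0, y0, domains)
  cseed <- sample.int(.Machine$integer.max, 1L)
  res <- .sim_trajectories_cpp(x0, y0, dom0, n_frames, config$dt,
                               config$box_size, config$d_out, config$d_in,
                               config$p_enter, config$p_escape,
                               domains$centers, domains$radius, cseed)
  structure(list(x = res$x, y = res$y, in_domain = res$in_domain,
                 dt = config$dt, box_size = config$box_size),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d particles x %d frames (dt %.2g s, box %.2f um)\n",
              ncol(x$x), nrow(x$x), x$dt, x$box_size))
  invisible(x)
}

#' Advance an ensemble state by one frame
#'
#' Single-step version of the Monte Carlo update, mainly useful for
#' inspecting the stepper. `state` is a list with `x`, `y` (um) and
#' optionally `dom` (0 = outside); the updated state is returned.
#'
#' @param state list with numeric `x`, `y` and optional integer `dom`.
#' @param config a [sim_config()].
#' @param domains a [init_domains()] map; `NULL` for none.
#' @param seed RNG seed for this step.
#' @return list with updated `x`, `y`, `dom`.
#' @export
step_ensemble <- function(state, config, domains = NULL, seed = NULL) {
  if (is.null(domains)) domains <- empty_domains(config)
  dom <- state$dom %||% locate_domains(state$x, state$y, domains)
  res <- .sim_trajectories_cpp(state$x, state$y, dom, 2L, config$dt,
                               config$box_size, config$d_out, config$d_in,
                               config$p_enter, config$p_escape,
                               domains$centers, domains$radius,
                               resolve_seed(seed))
  list(x = res$x[2, ], y = res$y[2, ],
       dom = locate_domains(res$x[2, ], res$y[2, ], domains))
}

#' Mean squared displacement of an ensemble
#'
#' Computes the ensemble- and time-averaged MSD over the requested frame
#' lags, unwrapping the periodic box via minimum-image displacement
#' increments.
#'
#' @param ensemble a [simulate_membrane()] result.
#' @param lags integer frame lags.
#' @return data.frame with `lag_s` and `msd_um2`.
#' @export
msd <- function(ensemble, lags = 1:50) {
  L <- ensemble$box_size
  # unwrap: cumulative minimum-image increments
  unwrap <- function(m) {
    d <- diff(m)
    d <- d - L * round(d / L)
    apply(rbind(m[1, , drop = FALSE], d), 2, cumsum)
  }
  X <- unwrap(ensemble$x)
  Y <- unwrap(ensemble$y)
  n <- nrow(X)
  out <- vapply(lags, function(k) {
    dx <- X[seq_len(n - k) + k, , drop = FALSE] - X[seq_len(n - k), , drop = FALSE]
    dy <- Y[seq_len(n - k) + k, , drop = FALSE] - Y[seq_len(n - k), , drop = FALSE]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  data.frame(lag_s = lags * ensemble$dt, msd_um2 = out)
}

#' Domain residence times of an ensemble
#'
#' Extracts the durations of completed inside-domain episodes from the
#' `in_domain` indicator (episodes truncated by the start or end of the
#' recording are dropped).
#'
#' @param ensemble a [simulate_membrane()] result.
#' @return numeric vector of residence times (s); length 0 when no
#'   completed episode was observed.
#' @export
residence_times <- function(ensemble) {
  out <- lapply(seq_len(ncol(ensemble$in_domain)), function(i) {
    r <- rle(ensemble$in_domain[, i])
    if (length(r$lengths) <= 2) return(numeric(0))
    keep <- which(r$values)
    keep <- keep[keep > 1 & keep < length(r$lengths)]
    r$lengths[keep] * ensemble$dt
  })
  unlist(out)
}
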