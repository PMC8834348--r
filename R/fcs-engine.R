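#' Gaussian confocal detection profile
#'
#' The detector weights each particle by `exp(-2 * r^2 / waist^2)`, where
#' `r` is the minimum-image distance to the spot centre and `waist` the
#' 1/e^2 beam radius.
#'
#' @param waist 1/e^2 spot radius (um).
#' @param center numeric length-2 spot centre (um).
#' @param brightness expected counts per sampling bin from one particle at
#'   the spot centre.
#' @param background expected background counts per bin.
#' @return object of class `detection_profile`.
#' @export
detection_profile <- function(waist, center = c(0, 0), brightness = 3,
                              background = 0.1) {
  stopifnot(waist > 0, length(center) == 2, brightness > 0, background >= 0)
  structure(list(waist = waist, center = as.numeric(center),
                 brightness = brightness, background = background),
            class = "detection_profile")
}

new_intensity_trace <- function(counts, bin_time, run_id = NA, cell_id = NA) {
  structure(list(counts = counts, bin_time = bin_time,
                 duration = length(counts) * bin_time,
                 run_id = run_id, cell_id = cell_id),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace: %d bins of %.2g s (%.3g s), mean %.3g counts/bin\n",
              length(x$counts), x$bin_time, x$duration, mean(x$counts)))
  invisible(x)
}

#' Fluorescence intensity trace through a Gaussian spot
#'
#' Bins a trajectory ensemble into sampling intervals of `bin_time` and
#' computes the expected signal per bin, `lambda = background + brightness *
#' sum_i exp(-2 * |r_i - center|^2 / waist^2)` (minimum-image convention),
#' evaluated at the frame entering each bin. With `noise = TRUE` (default)
#' the emitted counts are Poisson draws around `lambda`, emulating photon
#' counting; `noise = FALSE` returns `lambda` itself.
#'
#' @param ensemble a [simulate_membrane()] result.
#' @param profile a [detection_profile()].
#' @param bin_time sampling interval (s); must be an integer multiple of
#'   the ensemble `dt`.
#' @param noise logical; draw Poisson counts?
#' @param seed RNG seed for the Poisson draws.
#' @param run_id,cell_id identifiers carried into the trace.
#' @return an `intensity_trace`.
#' @export
intensity_trace <- function(ensemble, profile, bin_time = ensemble$dt,
                            noise = TRUE, seed = NULL,
                            run_id = NA, cell_id = NA) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(profile, "detection_profile"))
  step <- bin_time / ensemble$dt
  if (abs(step - round(step)) > 1e-8 || step < 1)
    stop("bin_time must be a positive integer multiple of the ensemble dt")
  step <- as.integer(round(step))
  idx <- seq(1L, nrow(ensemble$x), by = step)
  L <- ensemble$box_size
  dx <- ensemble$x[idx, , drop = FALSE] - profile$center[1]
  dx <- dx - L * round(dx / L)
  dy <- ensemble$y[idx, , drop = FALSE] - profile$center[2]
  dy <- dy - L * round(dy / L)
  lam <- profile$background +
    profile$brightness * rowSums(exp(-2 * (dx * dx + dy * dy) / profile$waist^2))
  if (noise) {
    set.seed(resolve_seed(seed))
    lam <- rpois(length(lam), lam)
  }
  new_intensity_trace(lam, bin_time, run_id = run_id, cell_id = cell_id)
}

new_acf_curve <- function(lags, g, g_err = rep(NA_real_, length(g)),
                          n_runs = 1L, bin_time = NA_real_,
                          duration = NA_real_) {
  stopifnot(length(lags) == length(g), all(diff(lags) > 0))
  structure(data.frame(lag_s = lags, g = g, g_err = g_err),
            class = c("acf_curve", "data.frame"),
            n_runs = n_runs, bin_time = bin_time, duration = duration)
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("ACF curve: %d lags from %.2g to %.3g s (%d run%s)\n",
              nrow(x), min(x$lag_s[x$lag_s > 0]), max(x$lag_s),
              attr(x, "n_runs"), if (attr(x, "n_runs") == 1) "" else "s"))
  invisible(x)
}

check_not_constant <- function(counts) {
  if (var(as.numeric(counts)) == 0)
    stop("constant intensity trace: autocorrelation is undefined")
}

# symmetric-normalization correlation at integer lag k of series y:
# G(k) = <y_i * y_{i+k}> / (<y_left> <y_right>) - 1
sym_corr <- function(y, k) {
  n <- length(y)
  a <- y[seq_len(n - k)]
  b <- y[seq_len(n - k) + k]
  mean(a * b) / (mean(a) * mean(b)) - 1
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Estimates the normalized fluctuation autocorrelation `G(tau) =
#' <dF(t) dF(t+tau)> / <F>^2` on a quasi-logarithmic lag grid, emulating a
#' hardware correlator: `m` linear lags at full time resolution, then `m/2`
#' lags per stage with the trace binned by a factor 2 between stages.
#' Symmetric normalization (per-lag left/right means) is used, which keeps
#' the estimator stable against slow drift.
#'
#' @param trace an [intensity_trace()].
#' @param m channels per stage (even, default 16).
#' @param include_zero include the zero-lag point (variance/mean^2)?
#' @return an `acf_curve` data.frame with columns `lag_s`, `g`, `g_err`.
#' @export
multitau_acf <- function(trace, m = 16, include_zero = TRUE) {
  stopifnot(inherits(trace, "intensity_trace"), m %% 2 == 0, m >= 4)
  y <- as.numeric(trace$counts)
  if (length(y) < 2 * m) stop("trace too short for ", m, " channels per stage")
  check_not_constant(y)
  lags <- integer(0)
  g <- numeric(0)
  level <- 1L
  stage <- 0L
  repeat {
    n <- length(y)
    ks <- if (stage == 0L) seq_len(m) else (m %/% 2 + 1L):m
    ks <- ks[ks <= n - m]
    for (k in ks) {
      lags <- c(lags, k * level)
      g <- c(g, sym_corr(y, k))
    }
    n2 <- n %/% 2L
    if (n2 < 2 * m) break
    y <- (y[seq(1L, 2L * n2, by = 2L)] + y[seq(2L, 2L * n2, by = 2L)]) / 2
    level <- level * 2L
    stage <- stage + 1L
  }
  if (include_zero) {
    y0 <- as.numeric(trace$counts)
    lags <- c(0L, lags)
    g <- c(mean(y0^2) / mean(y0)^2 - 1, g)
  }
  new_acf_curve(lags * trace$bin_time, g, bin_time = trace$bin_time,
                duration = trace$duration)
}

#' Direct (brute-force) autocorrelation estimator
#'
#' Lag-by-lag evaluation of the same normalized, symmetrically-normalized
#' fluctuation autocorrelation as [multitau_acf()], at every integer lag up
#' to `max_lag` bins. Quadratic in the trace length; intended as an
#' independent cross-check of the multi-tau estimator.
#'
#' @param trace an [intensity_trace()].
#' @param max_lag largest lag in bins (must be below the trace length).
#' @param include_zero include the zero-lag point?
#' @return an `acf_curve`.
#' @export
direct_acf <- function(trace, max_lag, include_zero = TRUE) {
  stopifnot(inherits(trace, "intensity_trace"))
  y <- as.numeric(trace$counts)
  if (max_lag >= length(y)) stop("max_lag must be below the trace length")
  check_not_constant(y)
  ks <- if (include_zero) 0:max_lag else seq_len(max_lag)
  g <- vapply(ks, function(k) {
    if (k == 0) mean(y^2) / mean(y)^2 - 1 else sym_corr(y, k)
  }, numeric(1))
  new_acf_curve(ks * trace$bin_time, g, bin_time = trace$bin_time,
                duration = trace$duration)
}

#' Average autocorrelation curves across runs
#'
#' Per-lag mean and standard error over repeated acquisitions, e.g. the 20
#' consecutive 5-s runs recorded on one cell.
#'
#' @param curves list of `acf_curve` objects sharing one lag grid.
#' @return an `acf_curve` with `g_err` = per-lag standard error of the mean.
#' @export
average_acf <- function(curves) {
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE, "acf_curve")))
  lags <- curves[[1]]$lag_s
  for (cv in curves[-1])
    if (length(cv$lag_s) != length(lags) || any(abs(cv$lag_s - lags) > 1e-12))
      stop("curves do not share a common lag grid")
  G <- vapply(curves, function(cv) cv$g, numeric(length(lags)))
  G <- matrix(G, nrow = length(lags))
  n <- length(curves)
  m <- rowMeans(G)
  se <- if (n > 1) apply(G, 1, sd) / sqrt(n) else rep(NA_real_, length(lags))
  new_acf_curve(lags, m, g_err = se, n_runs = n,
                bin_time = attr(curves[[1]], "bin_time"),
                duration = attr(curves[[1]], "duration"))
}

#' @export
plot.acf_curve <- function(x, log = "x", xlab = "lag (s)",
                           ylab = expression(G(tau)), ...) {
  keep <- x$lag_s > 0
  plot(x$lag_s[keep], x$g[keep], log = log, xlab = xlab, ylab = ylab, ...)
  if (any(is.finite(x$g_err[keep])))
    arrows(x$lag_s[keep], x$g[keep] - x$g_err[keep],
           x$lag_s[keep], x$g[keep] + x$g_err[keep],
           angle = 90, code = 3, length = 0.02, col = "grey50")
  invisible(x)
}
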