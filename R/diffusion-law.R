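#' Aggregate per-cell diffusion times at one waist
#'
#' Mean and standard error of the mean (sample SD / sqrt(n)) of the
#' per-cell diffusion times measured at one spot size, the unit entering
#' the diffusion law. A single cell yields SEM 0 (flagged by `n_cells = 1`).
#'
#' @param tau_d_ms per-cell diffusion times (ms).
#' @param waist calibrated spot waist (um).
#' @return one-row data.frame with `waist_um`, `waist_sq_um2`, `tau_d_ms`,
#'   `tau_d_sem_ms`, `n_cells`.
#' @examples
#' aggregate_cells(c(8, 12), waist = 0.25)
#' @export
aggregate_cells <- function(tau_d_ms, waist) {
  tau_d_ms <- tau_d_ms[is.finite(tau_d_ms)]
  if (length(tau_d_ms) == 0) stop("no diffusion times to aggregate")
  stopifnot(waist > 0)
  n <- length(tau_d_ms)
  data.frame(waist_um = waist, waist_sq_um2 = waist^2,
             tau_d_ms = mean(tau_d_ms),
             tau_d_sem_ms = if (n > 1) sd(tau_d_ms) / sqrt(n) else 0,
             n_cells = n)
}

#' Classify the diffusion regime from the law intercept
#'
#' The sign of the diffusion-law intercept diagnoses the mode of motion:
#' positive means temporal entrapment in nanodomains ("trapped"), negative
#' means meshwork/cytoskeleton hindrance ("meshwork"), zero means free
#' Brownian diffusion. Significance is judged against `threshold` standard
#' errors (default 2).
#'
#' @param t0 intercept (ms).
#' @param t0_sem its standard error (ms), non-negative.
#' @param threshold significance multiple of `t0_sem`.
#' @return one of `"trapped"`, `"meshwork"`, `"free"`.
#' @examples
#' classify_regime(10.25, 1.43)  # trapped
#' classify_regime(1.04, 2.49)   # free
#' @export
classify_regime <- function(t0, t0_sem, threshold = 2) {
  stopifnot(t0_sem >= 0, threshold >= 0)
  if (t0 > threshold * t0_sem) "trapped"
  else if (t0 < -threshold * t0_sem) "meshwork"
  else "free"
}

#' Fit the svFCS diffusion law
#'
#' Linear regression of the mean diffusion time on the squared waist,
#' `tau_d(omega^2) = t0 + omega^2 / (4 * D_eff)`. When every point carries
#' a positive SEM, the fit is weighted by `1/SEM^2` and parameter standard
#' errors come from the known-variance (generalized least squares)
#' covariance `(X' W X)^-1`; otherwise the fit is ordinary least squares
#' with residual-based errors. The slope (ms/um^2) converts to the
#' effective diffusion coefficient as `D_eff = 1000 / (4 * slope)` um^2/s,
#' with its SEM propagated via `d_eff_sem = d_eff * slope_sem / slope`.
#'
#' A non-positive fitted slope signals an unphysical law and raises an
#' error.
#'
#' @param points data.frame of per-waist rows as produced by
#'   [aggregate_cells()] (at least two distinct `waist_sq_um2` values).
#' @param threshold regime significance threshold passed to
#'   [classify_regime()].
#' @return object of class `diffusion_law` with elements `t0`, `t0_sem`
#'   (ms), `d_eff`, `d_eff_sem` (um^2/s), `slope`, `slope_sem` (ms/um^2),
#'   `regime`, `points`, `weighted`.
#' @examples
#' pts <- simulate_law_points(10.25, 1.18, seed = 1)
#' fit_diffusion_law(pts)
#' @export
fit_diffusion_law <- function(points, threshold = 2) {
  stopifnot(is.data.frame(points),
            all(c("waist_sq_um2", "tau_d_ms") %in% names(points)))
  if (length(unique(points$waist_sq_um2)) < 2)
    stop("need at least two distinct waists to fit a diffusion law")
  x <- points$waist_sq_um2
  y <- points$tau_d_ms
  sem <- points$tau_d_sem_ms
  weighted <- !is.null(sem) && all(is.finite(sem)) && all(sem > 0)
  w <- if (weighted) 1 / sem^2 else rep(1, length(x))

  X <- cbind(1, x)
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  beta <- drop(V %*% (XtW %*% y))
  if (!weighted) {
    rss <- sum((y - X %*% beta)^2)
    dof <- max(1L, length(y) - 2L)
    V <- V * rss / dof
  }
  t0 <- unname(beta[1])
  slope <- unname(beta[2])
  if (slope <= 0)
    stop("unphysical diffusion law: fitted slope is not positive, ",
         "D_eff is undefined")
  t0_sem <- sqrt(V[1, 1])
  slope_sem <- sqrt(V[2, 2])
  d_eff <- 1000 / (4 * slope)
  structure(list(t0 = t0, t0_sem = t0_sem,
                 d_eff = d_eff, d_eff_sem = d_eff * slope_sem / slope,
                 slope = slope, slope_sem = slope_sem,
                 regime = classify_regime(t0, t0_sem, threshold),
                 threshold = threshold, points = points,
                 weighted = weighted, vcov = V),
            class = "diffusion_law")
}

#' @export
print.diffusion_law <- function(x, ...) {
  cat("svFCS diffusion law: tau_d = t0 + omega^2 / (4 D_eff)\n")
  cat(sprintf("  t0    %8.2f +/- %.2f ms\n", x$t0, x$t0_sem))
  cat(sprintf("  D_eff %8.2f +/- %.2f um^2/s\n", x$d_eff, x$d_eff_sem))
  cat(sprintf("  regime: %s (|t0| vs %g x SEM)\n", x$regime, x$threshold))
  cat(sprintf("  %d waists, %s fit\n", nrow(x$points),
              if (x$weighted) "1/SEM^2-weighted" else "unweighted"))
  invisible(x)
}

#' @export
coef.diffusion_law <- function(object, ...) {
  c(t0_ms = object$t0, slope_ms_per_um2 = object$slope)
}

#' @export
vcov.diffusion_law <- function(object, ...) object$vcov

#' @export
summary.diffusion_law <- function(object, ...) {
  out <- data.frame(t0_ms = object$t0, t0_sem_ms = object$t0_sem,
                    d_eff = object$d_eff, d_eff_sem = object$d_eff_sem,
                    regime = object$regime, n_waists = nrow(object$points))
  class(out) <- c("summary.diffusion_law", "data.frame")
  out
}

#' @export
print.summary.diffusion_law <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
predict.diffusion_law <- function(object, waist_sq = NULL, ...) {
  if (is.null(waist_sq)) waist_sq <- object$points$waist_sq_um2
  object$t0 + object$slope * waist_sq
}

#' @export
residuals.diffusion_law <- function(object, ...) {
  object$points$tau_d_ms - predict(object)
}

#' @export
plot.diffusion_law <- function(x, xlab = expression(omega^2 ~ (mu * m^2)),
                               ylab = expression(tau[d] ~ (ms)), ...) {
  p <- x$points
  xr <- c(0, max(p$waist_sq_um2) * 1.05)
  yr <- range(0, p$tau_d_ms + p$tau_d_sem_ms, p$tau_d_ms - p$tau_d_sem_ms,
              x$t0)
  plot(p$waist_sq_um2, p$tau_d_ms, xlim = xr, ylim = yr,
       xlab = xlab, ylab = ylab, pch = 19, ...)
  if (all(p$tau_d_sem_ms > 0))
    arrows(p$waist_sq_um2, p$tau_d_ms - p$tau_d_sem_ms,
           p$waist_sq_um2, p$tau_d_ms + p$tau_d_sem_ms,
           angle = 90, code = 3, length = 0.03)
  abline(a = x$t0, b = x$slope, col = 2, lwd = 2)
  abline(h = 0, lty = 3, col = "grey50")
  invisible(x)
}

#' Generate synthetic diffusion-law points
#'
#' Law-level generator for fast round trips: per-cell diffusion times at
#' each waist are drawn as `Normal(t0 + 1000 * omega^2 / (4 * d_eff),
#' (cv * mean)^2)` (non-positive draws are re-drawn, i.e. the distribution
#' is truncated at zero) and aggregated with [aggregate_cells()].
#'
#' @param t0 generating intercept (ms).
#' @param d_eff generating effective diffusion coefficient (um^2/s).
#' @param waists spot waists (um), at least two.
#' @param n_cells cells per waist, at least two.
#' @param cell_noise_cv cell-to-cell coefficient of variation of tau_d.
#' @param seed RNG seed.
#' @return data.frame of per-waist rows (see [aggregate_cells()]).
#' @examples
#' simulate_law_points(10.25, 1.18, seed = 1)
#' @export
simulate_law_points <- function(t0, d_eff, waists = c(0.20, 0.25, 0.30, 0.35),
                                n_cells = 15, cell_noise_cv = 0.15,
                                seed = NULL) {
  stopifnot(length(waists) >= 2, n_cells >= 2, cell_noise_cv >= 0, d_eff > 0)
  set.seed(resolve_seed(seed))
  rows <- lapply(waists, function(w) {
    mu <- t0 + 1000 * w^2 / (4 * d_eff)
    if (mu <= 0) stop("generating parameters give non-positive mean tau_d")
    tau <- rnorm(n_cells, mu, cell_noise_cv * mu)
    bad <- which(tau <= 0)
    while (length(bad)) {  # truncate at zero by redrawing
      tau[bad] <- rnorm(length(bad), mu, cell_noise_cv * mu)
      bad <- bad[tau[bad] <= 0]
    }
    aggregate_cells(tau, w)
  })
  do.call(rbind, rows)
}

#' Simulate law points from a fitted diffusion law
#'
#' Draws replicate per-waist data sets using the fitted `t0` and `D_eff` as
#' generating truth, at the same waists as the fit.
#'
#' @param object a `diffusion_law`.
#' @param nsim number of replicate data sets.
#' @param seed RNG seed.
#' @param n_cells,cell_noise_cv passed to [simulate_law_points()].
#' @param ... unused.
#' @return a list of `nsim` data.frames (a single data.frame if
#'   `nsim = 1`).
#' @export
simulate.diffusion_law <- function(object, nsim = 1, seed = NULL,
                                   n_cells = 15, cell_noise_cv = 0.15, ...) {
  set.seed(resolve_seed(seed))
  out <- lapply(seq_len(nsim), function(i)
    simulate_law_points(object$t0, object$d_eff,
                        waists = object$points$waist_um,
                        n_cells = n_cells, cell_noise_cv = cell_noise_cv,
                        seed = sample.int(.Machine$integer.max, 1L)))
  if (nsim == 1) out[[1]] else out
}
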