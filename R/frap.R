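#' FRAP acquisition configuration
#'
#' Mirrors the acquisition protocol: a circular bleach region of interest
#' (ROI), a handful of pre-bleach frames, and a post-bleach time series of
#' ROI mean intensities.
#'
#' @param roi_diameter bleach ROI diameter (um).
#' @param n_prebleach number of pre-bleach frames.
#' @param frame_interval time between frames (s).
#' @param n_postbleach number of post-bleach frames.
#' @param bleach_depth fraction of ROI intensity removed by the bleach,
#'   in `(0, 1]`.
#' @param noise_cv relative (multiplicative Gaussian) noise per frame.
#' @return object of class `frap_config`.
#' @export
frap_config <- function(roi_diameter = 2.5, n_prebleach = 5,
                        frame_interval = 1.5, n_postbleach = 100,
                        bleach_depth = 0.8, noise_cv = 0.02) {
  stopifnot(roi_diameter > 0, n_prebleach >= 1, frame_interval > 0,
            n_postbleach >= 2, bleach_depth > 0, bleach_depth <= 1,
            noise_cv >= 0)
  structure(list(roi_diameter = roi_diameter,
                 n_prebleach = as.integer(n_prebleach),
                 frame_interval = frame_interval,
                 n_postbleach = as.integer(n_postbleach),
                 bleach_depth = bleach_depth, noise_cv = noise_cv),
            class = "frap_config")
}

#' Uniform-disk 2D diffusion recovery curve
#'
#' Closed-form fractional fluorescence recovery of a uniformly bleached
#' circular disk by pure lateral diffusion,
#' `f(t) = exp(-2 tau_d / t) * (I0(2 tau_d / t) + I1(2 tau_d / t))`
#' with `tau_d = r^2 / (4 D)` the characteristic diffusion time of the ROI
#' radius `r`. `f(0) = 0` and `f(t) -> 1` as `t -> Inf`.
#'
#' @param t time since bleach (s), non-negative.
#' @param tau_d characteristic recovery time (s).
#' @return recovery fraction in `[0, 1)`.
#' @export
soumpasis_recovery <- function(t, tau_d) {
  stopifnot(tau_d > 0, all(t >= 0))
  out <- numeric(length(t))
  pos <- t > 0
  x <- 2 * tau_d / t[pos]
  # scaled Bessel functions: besselI(x, nu, TRUE) = exp(-x) I_nu(x)
  out[pos] <- besselI(x, 0, expon.scaled = TRUE) +
    besselI(x, 1, expon.scaled = TRUE)
  out
}

# ratio t_half / tau_d for the uniform-disk recovery, solved once
.frap_env <- new.env(parent = emptyenv())
soumpasis_half_factor <- function() {
  if (is.null(.frap_env$half)) {
    f <- function(r) soumpasis_recovery(r, 1) - 0.5
    .frap_env$half <- uniroot(f, c(0.1, 20), tol = 1e-12)$root
  }
  .frap_env$half
}

#' Simulate a FRAP recovery curve
#'
#' Pre-bleach frames sit at intensity 1 (times < 0); the bleach occurs at
#' t = 0 and the first post-bleach frame is recorded immediately, so the
#' noiseless post-bleach signal is
#' `F(t) = (1 - bleach_depth) + bleach_depth * (mobile_fraction/100) * f(t)`
#' with `f` the uniform-disk recovery ([soumpasis_recovery()]) at
#' `tau_d = r^2 / (4 d)`. Multiplicative Gaussian noise of CV
#' `config$noise_cv` is applied to every frame.
#'
#' @param d diffusion coefficient of the mobile pool (um^2/s).
#' @param mobile_fraction recovering share of the bleached signal, percent.
#' @param config a [frap_config()].
#' @param seed RNG seed.
#' @param scale arbitrary intensity scale of the raw trace.
#' @return object of class `frap_curve`: data.frame with `time_s` and
#'   `intensity` (plus `normalized` once [normalize_frap()] has run).
#' @examples
#' cfg <- frap_config(noise_cv = 0)
#' curve <- simulate_frap(0.025, 42.13, cfg)
#' @export
simulate_frap <- function(d, mobile_fraction, config = frap_config(),
                          seed = NULL, scale = 1) {
  stopifnot(inherits(config, "frap_config"), d > 0,
            mobile_fraction >= 0, mobile_fraction <= 100)
  r <- config$roi_diameter / 2
  tau_d <- r^2 / (4 * d)
  t_pre <- -rev(seq_len(config$n_prebleach)) * config$frame_interval
  t_post <- (seq_len(config$n_postbleach) - 1) * config$frame_interval
  f <- soumpasis_recovery(t_post, tau_d)
  intensity <- c(rep(1, config$n_prebleach),
                 (1 - config$bleach_depth) +
                   config$bleach_depth * (mobile_fraction / 100) * f)
  if (config$noise_cv > 0) {
    set.seed(resolve_seed(seed))
    intensity <- intensity * (1 + config$noise_cv * rnorm(length(intensity)))
  }
  structure(data.frame(time_s = c(t_pre, t_post), intensity = scale * intensity),
            class = c("frap_curve", "data.frame"),
            n_prebleach = config$n_prebleach,
            roi_diameter = config$roi_diameter)
}

#' Normalize a FRAP curve
#'
#' Anchors the curve between the first post-bleach frame and the pre-bleach
#' level: `F_n(t) = (F(t) - F0) / (F_pre - F0)` with `F_pre` the mean of
#' the pre-bleach frames (times < 0) and `F0` the first post-bleach frame.
#' So `F_n(0) = 0` and a full recovery reaches 1; the result is invariant
#' under affine rescaling of the raw intensities.
#'
#' @param raw a `frap_curve` (or data.frame with `time_s`, `intensity`).
#' @return the curve with a `normalized` column added.
#' @export
normalize_frap <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("time_s", "intensity") %in% names(raw)))
  pre <- raw$time_s < 0
  if (!any(pre) || sum(!pre) < 2)
    stop("need at least 1 pre-bleach (time < 0) and 2 post-bleach frames")
  f_pre <- mean(raw$intensity[pre])
  f0 <- raw$intensity[which(!pre)[1]]
  if (abs(f_pre - f0) < 1e-12 * max(abs(f_pre), 1))
    stop("degenerate normalization: no bleach detected (F_pre == F0)")
  raw$normalized <- (raw$intensity - f0) / (f_pre - f0)
  if (!inherits(raw, "frap_curve")) class(raw) <- c("frap_curve", class(raw))
  raw
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("FRAP curve: %d pre- and %d post-bleach frames, %s\n",
              sum(x$time_s < 0), sum(x$time_s >= 0),
              if ("normalized" %in% names(x)) "normalized" else "raw"))
  invisible(x)
}

#' Fit a FRAP recovery curve
#'
#' Fits `F_n(t) = M * f(t; tau)` to the normalized post-bleach frames by
#' least squares, with `M` in `[0, 1]` the mobile fraction and `f` either
#' the uniform-disk diffusion recovery ([soumpasis_recovery()], default) or
#' a single-exponential `1 - exp(-t / tau)`. The half-time of recovery is
#' the time at which the fitted curve reaches `M / 2`, obtained from the
#' fitted timescale (`t_half = c * tau` with `c` the model's half-recovery
#' factor, `log(2)` for the exponential).
#'
#' A post-bleach curve that never rises above 2% recovery is reported as
#' fully immobile (`mobile_fraction = 0`, `t_half = NA`).
#'
#' @param curve a `frap_curve`; normalized with [normalize_frap()] first if
#'   needed.
#' @param model recovery model.
#' @return object of class `frap_fit` with coefficients `mobile_fraction`
#'   (percent), `t_half` (s), `tau_model` (s), plus `converged`, `model`.
#' @examples
#' cfg <- frap_config(noise_cv = 0)
#' fit <- fit_frap(simulate_frap(0.025, 42.13, cfg))
#' coef(fit)
#' @export
fit_frap <- function(curve, model = c("soumpasis", "exponential")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(curve))
  if (!"normalized" %in% names(curve)) curve <- normalize_frap(curve)
  post <- curve[curve$time_s >= 0, , drop = FALSE]
  if (nrow(post) < 10) stop("need at least 10 post-bleach frames")
  t <- post$time_s
  y <- post$normalized

  half_factor <- switch(model, soumpasis = soumpasis_half_factor(),
                        exponential = log(2))
  fmodel <- switch(model,
                   soumpasis = function(t, tau) soumpasis_recovery(t, tau),
                   exponential = function(t, tau) 1 - exp(-t / tau))

  plateau <- mean(tail(y, max(5L, length(y) %/% 10L)))
  if (plateau < 0.02) {
    out <- list(coefficients = c(mobile_fraction = 0, t_half = NA_real_,
                                 tau_model = NA_real_),
                converged = TRUE, model = model, curve = curve,
                data = post, fit = NULL)
    class(out) <- "frap_fit"
    return(out)
  }
  m0 <- min(max(plateau, 0.05), 1)
  cross <- which(y >= m0 / 2)
  t_cross <- if (length(cross)) max(t[cross[1]], t[2]) else median(t)
  tau0 <- t_cross / half_factor

  d <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ M * fmodel(t, tau), data = d,
                      start = list(M = m0, tau = tau0),
                      lower = c(M = 0, tau = 1e-6), upper = c(M = 1, tau = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(coefficients = c(mobile_fraction = NA_real_,
                                 t_half = NA_real_, tau_model = NA_real_),
                converged = FALSE, model = model, curve = curve,
                data = post, fit = NULL)
    class(out) <- "frap_fit"
    return(out)
  }
  co <- coef(fit)
  out <- list(coefficients = c(mobile_fraction = 100 * unname(co["M"]),
                               t_half = half_factor * unname(co["tau"]),
                               tau_model = unname(co["tau"])),
              converged = isTRUE(fit$convInfo$isConv %||% TRUE),
              model = model, curve = curve, data = post, fit = fit)
  class(out) <- "frap_fit"
  out
}

#' @export
coef.frap_fit <- function(object, ...) object$coefficients

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit (%s recovery model)\n", x$model))
  if (!x$converged) cat("  (did not converge)\n")
  cat(sprintf("  t_half          %.3g s\n", x$coefficients["t_half"]))
  cat(sprintf("  mobile fraction %.4g %%\n", x$coefficients["mobile_fraction"]))
  invisible(x)
}

#' @export
predict.frap_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) time <- object$data$time_s
  co <- object$coefficients
  if (co["mobile_fraction"] == 0 || !is.finite(co["tau_model"]))
    return(rep(0, length(time)))
  f <- switch(object$model,
              soumpasis = soumpasis_recovery(time, co["tau_model"]),
              exponential = 1 - exp(-time / co["tau_model"]))
  co["mobile_fraction"] / 100 * f
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$data$normalized - predict(object)
}

#' @export
plot.frap_fit <- function(x, xlab = "time since bleach (s)",
                          ylab = "normalized recovery", ...) {
  plot(x$data$time_s, x$data$normalized, xlab = xlab, ylab = ylab,
       col = "grey40", ...)
  tt <- seq(0, max(x$data$time_s), length.out = 300)
  lines(tt, predict(x, tt), col = 2, lwd = 2)
  if (is.finite(x$coefficients["t_half"]))
    abline(v = x$coefficients["t_half"], lty = 2, col = "grey60")
  invisible(x)
}

#' Simulate replicate curves from a fitted FRAP model
#'
#' @param object a `frap_fit`.
#' @param nsim number of curves.
#' @param seed RNG seed.
#' @param config a [frap_config()] describing the acquisition to emulate.
#' @param ... unused.
#' @return list of `frap_curve`s (a single curve if `nsim = 1`).
#' @export
simulate.frap_fit <- function(object, nsim = 1, seed = NULL,
                              config = frap_config(), ...) {
  co <- object$coefficients
  if (!is.finite(co["tau_model"]))
    stop("cannot simulate from an immobile/non-converged fit")
  r <- config$roi_diameter / 2
  d <- r^2 / (4 * co["tau_model"])
  set.seed(resolve_seed(seed))
  out <- lapply(seq_len(nsim), function(i)
    simulate_frap(d, co["mobile_fraction"], config,
                  seed = sample.int(.Machine$integer.max, 1L)))
  if (nsim == 1) out[[1]] else out
}
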