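#' Two-dimensional lateral diffusion ACF model
#'
#' Closed form of the autocorrelation of free 2D diffusion through a
#' Gaussian spot, `G(tau) = baseline + amplitude / (1 + tau / tau_d)`,
#' where `tau_d` is the mean diffusion (dwell) time in the spot and the
#' amplitude is the inverse of the mean spot occupancy.
#'
#' @param lag lag times (s).
#' @param amplitude zero-lag excess correlation (1/N).
#' @param tau_d diffusion time (s), positive.
#' @param baseline long-lag offset.
#' @return correlation values.
#' @examples
#' acf_model_g(0.005, amplitude = 0.1, tau_d = 0.005)  # half amplitude
#' @export
acf_model_g <- function(lag, amplitude, tau_d, baseline = 0) {
  stopifnot(tau_d > 0)
  baseline + amplitude / (1 + lag / tau_d)
}

#' Fit the 2D lateral diffusion model to an ACF curve
#'
#' Weighted least squares of [acf_model_g()] against an [multitau_acf()]
#' curve; weights are `1/g_err^2` when per-lag errors are available (and
#' positive), otherwise the fit is unweighted. Initialization is
#' derivative-free: baseline from the median of the last decade of lags,
#' amplitude from the maximum above it, `tau_d` from the half-amplitude
#' crossing. Lags shorter than `lag_min` (default three sampling bins, to
#' stay clear of shot-noise artifacts) and, when known, longer than a tenth
#' of the run duration are excluded.
#'
#' Optimizer failure is reported through `converged = FALSE`, never as an
#' error.
#'
#' @param curve an `acf_curve`.
#' @param init optional named list/vector with starting `amplitude`,
#'   `tau_d`, `baseline`.
#' @param lag_min,lag_max fitted lag range (s); `NULL` for the defaults
#'   above.
#' @return object of class `acf_fit` with coefficients `amplitude`,
#'   `tau_d`, `baseline`, plus `tau_d_err`, `chi2_reduced`, `converged`.
#' @export
fit_acf <- function(curve, init = NULL, lag_min = NULL, lag_max = NULL) {
  stopifnot(inherits(curve, "acf_curve"))
  bin <- attr(curve, "bin_time")
  if (is.null(lag_min)) lag_min <- if (is.finite(bin)) 3 * bin else 0
  dur <- attr(curve, "duration")
  if (is.null(lag_max)) lag_max <- if (is.finite(dur %||% NA)) dur / 10 else Inf
  d <- curve[curve$lag_s >= lag_min & curve$lag_s <= lag_max &
               is.finite(curve$g), , drop = FALSE]
  if (nrow(d) < 4)
    stop("underdetermined fit: need at least 4 usable lags, got ", nrow(d))
  span <- range(d$lag_s)
  if (span[2] / span[1] < 10)
    warning("fitted lags span less than one decade; tau_d may be poorly constrained")

  w <- if (all(is.finite(d$g_err)) && all(d$g_err > 0)) 1 / d$g_err^2
       else rep(1, nrow(d))

  if (is.null(init)) {
    last_dec <- d[d$lag_s >= span[2] / 10, , drop = FALSE]
    base0 <- median(last_dec$g)
    amp0 <- max(d$g) - base0
    if (amp0 <= 0) amp0 <- max(abs(d$g - base0), .Machine$double.eps)
    half <- base0 + amp0 / 2
    below <- which(d$g <= half)
    tau0 <- if (length(below)) d$lag_s[below[1]] else median(d$lag_s)
    if (tau0 <= span[1]) tau0 <- exp(mean(log(span)))
    init <- c(amplitude = amp0, tau_d = tau0, baseline = base0)
  }
  init <- unlist(init)[c("amplitude", "tau_d", "baseline")]

  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ baseline + amplitude / (1 + lag_s / tau_d),
      data = as.data.frame(d), weights = w,
      start = as.list(init),
      lower = c(amplitude = 0, tau_d = span[1] / 100, baseline = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    out <- list(coefficients = c(amplitude = NA_real_, tau_d = NA_real_,
                                 baseline = NA_real_),
                tau_d_err = NA_real_, vcov = NULL, chi2_reduced = NA_real_,
                converged = FALSE, curve = curve, data = d, weights = w)
    class(out) <- "acf_fit"
    return(out)
  }
  co <- coef(fit)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  res <- d$g - acf_model_g(d$lag_s, co["amplitude"], co["tau_d"], co["baseline"])
  chi2 <- sum(w * res^2) / max(1, nrow(d) - 3)
  out <- list(coefficients = co[c("amplitude", "tau_d", "baseline")],
              tau_d_err = if (!is.null(V)) sqrt(V["tau_d", "tau_d"]) else NA_real_,
              vcov = V, chi2_reduced = chi2,
              converged = isTRUE(fit$convInfo$isConv %||% TRUE),
              curve = curve, data = d, weights = w)
  class(out) <- "acf_fit"
  out
}

#' @export
coef.acf_fit <- function(object, ...) object$coefficients

#' @export
vcov.acf_fit <- function(object, ...) object$vcov

#' @export
print.acf_fit <- function(x, ...) {
  cat("2D lateral diffusion ACF fit\n")
  if (!x$converged) cat("  (did not converge)\n")
  cat(sprintf("  tau_d     %.4g s (SE %.2g)\n", x$coefficients["tau_d"], x$tau_d_err))
  cat(sprintf("  amplitude %.4g   baseline %.3g\n",
              x$coefficients["amplitude"], x$coefficients["baseline"]))
  cat(sprintf("  reduced chi^2 %.3g on %d lags\n", x$chi2_reduced, nrow(x$data)))
  invisible(x)
}

#' @export
predict.acf_fit <- function(object, lag = NULL, ...) {
  if (is.null(lag)) lag <- object$data$lag_s
  co <- object$coefficients
  acf_model_g(lag, co["amplitude"], co["tau_d"], co["baseline"])
}

#' @export
residuals.acf_fit <- function(object, ...) {
  object$data$g - predict(object)
}

#' @export
plot.acf_fit <- function(x, ...) {
  plot(x$curve, ...)
  lag <- exp(seq(log(min(x$data$lag_s)), log(max(x$data$lag_s)), length.out = 200))
  lines(lag, predict(x, lag), col = 2, lwd = 2)
  invisible(x)
}

#' Calibrate the spot waist from a reference dye
#'
#' In free 3D->2D projected diffusion the dwell time obeys
#' `tau_d = waist^2 / (4 * D)`, so a measured reference dwell time and a
#' known reference diffusion coefficient give `waist =
#' sqrt(4 * d_ref * tau_d_ref)`. The default reference coefficient is the
#' literature value for Rhodamine 6G in water at room temperature.
#'
#' @param tau_d_ref fitted reference diffusion time (s), positive.
#' @param d_ref reference diffusion coefficient (um^2/s), positive.
#' @return object of class `waist_calibration` with `waist` (um).
#' @examples
#' calibrate_waist(3.77e-5)$waist  # ~0.25 um
#' @export
calibrate_waist <- function(tau_d_ref, d_ref = 414) {
  if (!is.numeric(tau_d_ref) || tau_d_ref <= 0)
    stop("tau_d_ref must be positive")
  if (!is.numeric(d_ref) || d_ref <= 0)
    stop("d_ref must be positive")
  structure(list(waist = sqrt(4 * d_ref * tau_d_ref),
                 d_ref = d_ref, tau_d_ref = tau_d_ref),
            class = "waist_calibration")
}

#' @export
print.waist_calibration <- function(x, ...) {
  cat(sprintf("Waist calibration: omega = %.4f um (D_ref %.4g um^2/s, tau_d_ref %.4g s)\n",
              x$waist, x$d_ref, x$tau_d_ref))
  invisible(x)
}
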