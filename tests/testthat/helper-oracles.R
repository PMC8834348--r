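# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# brute-force grid search for the 2D diffusion ACF model: tau_d scanned over
# a log grid, amplitude/baseline solved analytically per tau_d by linear
# least squares.
grid_fit_acf <- function(lags, g, n_grid = 200,
                         tau_range = range(lags[lags > 0]) * c(0.1, 10)) {
  scan <- function(lo, hi, n) {
    taus <- exp(seq(log(lo), log(hi), length.out = n))
    best <- NULL
    for (tau in taus) {
      X <- cbind(1 / (1 + lags / tau), 1)
      beta <- qr.solve(X, g)
      rss <- sum((g - X %*% beta)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(tau_d = tau, amplitude = beta[1], baseline = beta[2],
                     rss = rss)
    }
    best
  }
  coarse <- scan(tau_range[1], tau_range[2], n_grid)
  # refine around the coarse minimum so grid spacing is ~0.05%
  scan(coarse$tau_d / 1.1, coarse$tau_d * 1.1, 400)
}

# spectral (FFT) solution of the 2D diffusion equation for a bleached-disk
# initial condition on a periodic grid; returns the ROI mean recovery
# fraction at the requested times. Independent of the closed-form curve.
lattice_frap_recovery <- function(times, d, roi_radius, box = 20, n = 256) {
  h <- box / n
  xs <- (seq_len(n) - 0.5) * h - box / 2
  X <- matrix(xs, n, n)
  Y <- t(X)
  roi <- (X^2 + Y^2) <= roi_radius^2
  u0 <- ifelse(roi, 0, 1)  # fully bleached disk in a uniform field
  k <- 2 * pi * c(0:(n / 2), (-n / 2 + 1):(-1)) / box
  K2 <- outer(k^2, k^2, "+")
  U0 <- fft(u0)
  vapply(times, function(t) {
    u <- Re(fft(U0 * exp(-d * K2 * t), inverse = TRUE)) / n^2
    mean(u[roi])
  }, numeric(1))
}

# direct unnormalized-to-normalized correlation of an explicit sequence,
# written independently of the package estimator
naive_sym_corr <- function(y, k) {
  n <- length(y)
  num <- 0
  for (i in seq_len(n - k)) num <- num + y[i] * y[i + k]
  num <- num / (n - k)
  num / (mean(y[1:(n - k)]) * mean(y[(1 + k):n])) - 1
}

# analytic diffusion-law line, Table-style parameters
law_line <- function(t0_ms, d_eff, waists) {
  t0_ms + 1000 * waists^2 / (4 * d_eff)
}

make_trace <- function(counts, bin_time = 1e-4) {
  raftdyn:::new_intensity_trace(counts, bin_time)
}

# immobile-particle ensemble at fixed positions (one frame repeated)
immobile_ensemble <- function(x, y, n_frames = 10, dt = 1e-4, box = 2) {
  structure(list(x = matrix(rep(x, each = n_frames), n_frames),
                 y = matrix(rep(y, each = n_frames), n_frames),
                 in_domain = matrix(FALSE, n_frames, length(x)),
                 dt = dt, box_size = box),
            class = "trajectory_ensemble")
}
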