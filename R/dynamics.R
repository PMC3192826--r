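## Forward problem: numerical simulation of the linear stochastic network,
## spectral estimation from traces, and regression-based recovery of W.

#' Simulate the linear stochastic network dynamics
#'
#' Integrates `dx = W x dt + noise` with the Euler-Maruyama scheme
#' `x <- x + dt * W %*% x + sqrt(dt) * sigma * eta` (standard normal `eta`
#' per channel and step), or, for `method = "exact"`, with the exact
#' one-step update of the stationary process (`x <- Phi x + L z` with
#' `Phi = expm(W dt)` and `L L^T` the one-step noise covariance; requires
#' diagonalizable `W`, white noise only). The initial state is zero and a
#' burn-in period is discarded.
#'
#' With `noise = "lowpass"` the white drive is replaced by an exponential
#' low-pass filtered (colored) process with time constant `tau`,
#' normalized to unit stationary variance. This steepens the spectral
#' fall-off at high frequency from `1/f^2` to `1/f^4`.
#'
#' @param W Stable real square connectivity matrix (rad/s).
#' @param sigma Noise standard deviation (signal units per sqrt(s)).
#' @param dt Time step in seconds; must satisfy `dt <= 0.1 / rho(W)` with
#'   `rho` the spectral radius.
#' @param duration Record length in seconds (after burn-in).
#' @param seed Integer seed (all randomness through R's RNG).
#' @param burn_in Discarded transient, seconds.
#' @param noise `"white"` or `"lowpass"`.
#' @param tau Low-pass filter time constant in seconds (default 0.01).
#' @param method `"euler"` (default) or `"exact"`.
#' @return Object of class `ou_panel`: list with `data` (channels x
#'   samples matrix), `dt`, `sigma`, `noise`, `tau`, `seed`.
#' @export
#' @examples
#' p <- simulate_network(matrix(-2), sigma = 1, dt = 0.01, duration = 2,
#'                       seed = 1)
simulate_network <- function(W, sigma = 1, dt = 2e-4, duration = 60,
                             seed = 1L, burn_in = 2,
                             noise = c("white", "lowpass"), tau = 0.01,
                             method = c("euler", "exact")) {
  W <- as.matrix(unclass(W))
  noise <- match.arg(noise)
  method <- match.arg(method)
  n <- nrow(W)
  stopifnot(ncol(W) == n, sigma > 0, dt > 0, duration > 0, burn_in >= 0)
  ev <- check_stable(W)
  rho <- max(Mod(ev))
  if (method == "euler" && dt > 0.1 / rho)
    stop(sprintf("dt too coarse for stability: need dt <= %.3g", 0.1 / rho))
  if (method == "exact" && noise != "white")
    stop("exact one-step updates support white noise only")
  n_keep <- round(duration / dt)
  n_burn <- round(burn_in / dt)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * (n_keep + n_burn)), n, n_keep + n_burn)
  if (method == "euler") {
    A <- diag(n) + dt * W
    if (noise == "white") {
      B <- diag(sqrt(dt) * sigma, n)
      x <- sim_linear_recursion(A, B, Z, n_burn, 0L, dt, 1, sigma)
    } else {
      x <- sim_linear_recursion(A, diag(0, n), Z, n_burn, 1L, dt, tau, sigma)
    }
  } else {
    ed <- eigen(W)
    if (cond2(ed$vectors) > 1e10)
      stop("W is too close to non-diagonalizable for the exact method")
    Phi <- Re(ed$vectors %*% diag(exp(ed$values * dt), n) %*% solve(ed$vectors))
    Cinf <- stationary_covariance(W, sigma)
    Sd <- Cinf - Phi %*% Cinf %*% t(Phi)
    Sd <- (Sd + t(Sd)) / 2
    es <- eigen(Sd, symmetric = TRUE)
    B <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), n) %*% t(es$vectors)
    x <- sim_linear_recursion(Phi, B, Z, n_burn, 0L, dt, 1, sigma)
  }
  structure(list(data = x, dt = dt, sigma = sigma, noise = noise,
                 tau = if (noise == "lowpass") tau else NA_real_,
                 seed = as.integer(seed)),
            class = "ou_panel")
}

#' @export
print.ou_panel <- function(x, ...) {
  cat(sprintf("Time-series panel: %d channels x %d samples, dt = %g s (%s noise)\n",
              nrow(x$data), ncol(x$data), x$dt, x$noise))
  invisible(x)
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

#' Welch power spectral density of a time-series panel
#'
#' Standard averaged periodogram: the record is split into Hann-windowed
#' segments with the given overlap, each segment is demeaned, and the
#' squared-magnitude FFTs are averaged. The result is reported in the
#' two-sided spectral-density convention on positive frequencies, matching
#' [analytic_spectrum()] so that the two can be compared directly.
#'
#' @param panel An `ou_panel` (or a channels x samples matrix plus `dt`).
#' @param segment_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param dt Sampling step, required when `panel` is a bare matrix.
#' @return An `ou_spectrum` data frame (`frequency_hz`, channel-averaged
#'   `power`) with attribute `per_channel` (freq x channel matrix) and
#'   `n_segments`.
#' @export
welch_spectrum <- function(panel, segment_s = 2, overlap = 0.5, dt = NULL) {
  if (inherits(panel, "ou_panel")) {
    x <- panel$data; dt <- panel$dt
  } else {
    x <- as.matrix(panel)
    if (is.null(dt)) stop("'dt' required for a bare matrix")
  }
  stopifnot(segment_s > 0, overlap >= 0, overlap < 1)
  nseg <- round(segment_s / dt)
  T <- ncol(x)
  if (nseg > T) stop("record shorter than one segment")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, T - nseg + 1L, by = step)
  if (length(starts) < 8)
    warning("fewer than 8 Welch segments; spectral estimate will be noisy")
  w <- hann_window(nseg)
  scale <- dt / sum(w^2)                       # two-sided density
  nfreq <- floor(nseg / 2) + 1L
  freq <- (seq_len(nfreq) - 1L) / (nseg * dt)
  nch <- nrow(x)
  P <- matrix(0, nfreq, nch)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- stats::mvfft(t(seg * rep(w, each = nch)))
    P <- P + Mod(X[seq_len(nfreq), , drop = FALSE])^2 * scale
  }
  P <- P / length(starts)
  keep <- freq > 0
  out <- structure(
    data.frame(frequency_hz = freq[keep], power = rowMeans(P)[keep]),
    class = c("ou_spectrum", "data.frame"))
  attr(out, "per_channel") <- P[keep, , drop = FALSE]
  attr(out, "n_segments") <- length(starts)
  out
}

#' Spectrogram (time-resolved power spectrum) of one channel
#'
#' Short-time power spectra on sliding Hann windows, via
#' [signal::specgram()].
#'
#' @param panel An `ou_panel`.
#' @param channel Channel index.
#' @param window_s Window length, seconds (default 0.5).
#' @param step_s Step between window starts, seconds (default 0.05,
#'   i.e. 90% overlap).
#' @return List with `time_s`, `frequency_hz` and `power` (freq x time
#'   matrix, two-sided density convention).
#' @export
spectrogram_panel <- function(panel, channel = 1L, window_s = 0.5,
                              step_s = 0.05) {
  stopifnot(inherits(panel, "ou_panel"))
  x <- panel$data[channel, ]
  nwin <- round(window_s / panel$dt)
  step <- max(1L, round(step_s / panel$dt))
  if (nwin > length(x)) stop("record shorter than one window")
  sg <- signal::specgram(x - mean(x), n = nwin, Fs = 1 / panel$dt,
                         window = hann_window(nwin),
                         overlap = nwin - step)
  pw <- Mod(sg$S)^2 * panel$dt / sum(hann_window(nwin)^2)
  list(time_s = as.numeric(sg$t), frequency_hz = as.numeric(sg$f),
       power = pw)
}

#' Estimate the connectivity matrix from recorded traces by regression
#'
#' Least-squares fit of the finite-difference derivatives
#' `(x(t + dt) - x(t)) / dt` onto `x(t)`: the row-wise regression
#' `Y = W X` solved via the normal equations. Returns the estimated drift
#' matrix and the implied noise standard deviation.
#'
#' @param panel An `ou_panel` (or channels x samples matrix with `dt`).
#' @param dt Sampling step for a bare matrix.
#' @return List with `W` (estimated connectivity, rad/s) and `sigma`
#'   (estimated noise SD).
#' @export
#' @examples
#' pan <- simulate_network(diag(-c(1, 2)), dt = 1e-3, duration = 20,
#'                         seed = 3)
#' estimate_connectivity(pan)$W
estimate_connectivity <- function(panel, dt = NULL) {
  if (inherits(panel, "ou_panel")) {
    x <- panel$data; dt <- panel$dt
  } else {
    x <- as.matrix(panel)
    if (is.null(dt)) stop("'dt' required for a bare matrix")
  }
  T <- ncol(x)
  if (T < nrow(x)^2)
    warning("few samples relative to channels^2; estimate will be poor")
  X <- x[, -T, drop = FALSE]
  Y <- (x[, -1, drop = FALSE] - X) / dt
  XtX <- X %*% t(X)
  if (rcond(XtX) < 1e-14) stop("rank-deficient regressor matrix")
  W_hat <- Y %*% t(X) %*% solve(XtX)
  resid <- Y - W_hat %*% X
  sigma_hat <- sqrt(mean(resid^2) * dt)
  list(W = W_hat, sigma = sigma_hat)
}
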