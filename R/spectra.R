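## Spectral prescriptions and analytic spectral quantities for the linear
## stochastic network model dx/dt = W x + sigma * xi.
##
## Unit convention, fixed package-wide: eigenvalues of W are stored in rad/s.
## All user-facing frequencies are in Hz, with
##   f_peak = Im(lambda) / (2*pi),   hwhm = |Re(lambda)| / (2*pi).

#' Frequency grid for spectral evaluation
#'
#' @param f_min,f_max Band limits in Hz (`0 < f_min < f_max`).
#' @param n Number of grid points.
#' @param log Logical; log-spaced (default) or linear spacing.
#'
#' @return Numeric vector of strictly increasing frequencies in Hz.
#' @export
#' @examples
#' g <- frequency_grid(0.1, 500, 64)
frequency_grid <- function(f_min = 0.1, f_max = 500, n = 512, log = TRUE) {
  stopifnot(f_min > 0, f_max > f_min, n >= 2)
  if (log) 10^seq(log10(f_min), log10(f_max), length.out = n)
  else seq(f_min, f_max, length.out = n)
}

#' Build a spectral prescription for one of the five scenario groups
#'
#' A prescription is the list of spectral peaks (peak frequency and half
#' width at half maximum, both in Hz) plus the node count, noise level and
#' seed that together define the target power spectrum of a virtual brain.
#'
#' The groups emulate characteristic classes of EEG/MEG power spectra:
#' \describe{
#'   \item{Normal}{`n_peaks` frequency bands evenly spaced on a logarithmic
#'     axis: a geometric sequence `base_f * ratio^(0:(n_peaks-1))`.}
#'   \item{Entrained}{bands at exact small-integer frequency ratios
#'     (default 2.7 and 8.1 Hz, ratio 1:3), which phase-lock.}
#'   \item{Incomplete}{the Normal sequence with the `n_drop` highest bands
#'     removed (loss of high-frequency rhythms).}
#'   \item{Background}{no peaks at all; purely non-oscillatory 1/f-type
#'     background from real eigenvalues.}
#'   \item{Random}{the Normal peak count with frequencies drawn uniformly
#'     on the log-frequency axis, a fresh draw per realization (controlled
#'     by `seed`).}
#' }
#'
#' The bounds for the real (non-oscillatory) eigenvalues are in all groups
#' taken from the Normal group's complex pairs: `[-2*pi*max(hwhm),
#' -2*pi*min(hwhm)]` of the Normal sequence implied by `base_f`, `ratio`,
#' `n_peaks` and `hwhm_frac`, unless overridden via `real_eig_bounds`.
#'
#' @param group One of `"Normal"`, `"Entrained"`, `"Incomplete"`,
#'   `"Background"`, `"Random"`.
#' @param n_nodes Number of network nodes (channels).
#' @param base_f Base frequency of the Normal sequence, Hz.
#' @param ratio Geometric ratio between consecutive Normal bands.
#' @param n_peaks Number of bands in the Normal sequence.
#' @param hwhm_frac Half width at half maximum as a fraction of the peak
#'   frequency (default 0.2).
#' @param bands Peak frequencies in Hz for the Entrained group (default
#'   `c(2.7, 8.1)`, a 1:3 ratio).
#' @param n_drop Number of top bands removed for the Incomplete group.
#' @param sigma Noise standard deviation (signal units per sqrt(s)).
#' @param seed Integer seed controlling the random draws (real eigenvalues,
#'   Random-group peak positions).
#' @param f_limit Bandwidth limit in Hz; peak frequencies above it are
#'   rejected.
#' @param real_eig_bounds Optional length-2 numeric, interval of negative
#'   reals (rad/s) for the real eigenvalues; overrides the Normal-derived
#'   default.
#'
#' @return An object of class `ou_prescription`: a list with elements
#'   `group`, `peaks` (data frame `f_peak`, `hwhm`, in Hz), `n_nodes`,
#'   `real_eig_bounds` (rad/s), `sigma`, `seed`.
#' @export
#' @examples
#' p <- spectrum_prescription("Normal", n_nodes = 20, n_peaks = 2, seed = 1)
#' p$peaks
spectrum_prescription <- function(group = c("Normal", "Entrained",
                                            "Incomplete", "Background",
                                            "Random"),
                                  n_nodes = 80,
                                  base_f = 2, ratio = 2.6, n_peaks = 6,
                                  hwhm_frac = 0.2,
                                  bands = c(2.7, 8.1),
                                  n_drop = 2,
                                  sigma = 1, seed = 1L,
                                  f_limit = 500,
                                  real_eig_bounds = NULL) {
  group <- match.arg(group)
  stopifnot(n_nodes >= 1, base_f > 0, ratio > 0, n_peaks >= 1,
            hwhm_frac > 0, sigma > 0)
  if (ratio <= 0) stop("'ratio' must be positive")
  normal_f <- base_f * ratio^(seq_len(n_peaks) - 1)
  f <- switch(group,
    Normal     = normal_f,
    Entrained  = sort(bands),
    Incomplete = {
      if (n_drop >= n_peaks) stop("'n_drop' must leave at least one band")
      normal_f[seq_len(n_peaks - n_drop)]
    },
    Background = numeric(0),
    Random     = {
      lim <- log(range(normal_f))
      withr_seed <- seed + 77003L  # fresh draw per realization seed
      set.seed(withr_seed)
      sort(exp(stats::runif(n_peaks, lim[1], lim[2])))
    })
  if (any(f > f_limit))
    stop("peak frequencies exceed the bandwidth limit 'f_limit'")
  if (2 * length(f) > n_nodes)
    stop("need n_nodes >= 2 * number of peaks")
  hw <- hwhm_frac * f
  if (is.null(real_eig_bounds)) {
    normal_hw <- hwhm_frac * normal_f
    real_eig_bounds <- c(-2 * pi * max(normal_hw), -2 * pi * min(normal_hw))
  }
  stopifnot(length(real_eig_bounds) == 2, all(real_eig_bounds < 0),
            real_eig_bounds[1] <= real_eig_bounds[2])
  structure(list(group = group,
                 peaks = data.frame(f_peak = f, hwhm = hw),
                 n_nodes = as.integer(n_nodes),
                 real_eig_bounds = real_eig_bounds,
                 sigma = sigma, seed = as.integer(seed)),
            class = "ou_prescription")
}

#' @export
print.ou_prescription <- function(x, ...) {
  cat(sprintf("Spectral prescription: group %s, %d nodes, %d peak(s)\n",
              x$group, x$n_nodes, nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks)
  cat(sprintf("real eigenvalue bounds [%.4g, %.4g] rad/s, sigma = %g, seed = %d\n",
              x$real_eig_bounds[1], x$real_eig_bounds[2], x$sigma, x$seed))
  invisible(x)
}

#' Eigenvalue set implied by a spectral prescription
#'
#' Each spectral peak maps to one complex-conjugate eigenvalue pair
#' `-2*pi*hwhm +/- i * 2*pi*f_peak` (rad/s): the imaginary part sets the
#' peak frequency, the magnitude of the real part the half width at half
#' maximum. The remaining `n_nodes - 2*n_peaks` eigenvalues are real,
#' drawn uniformly from `real_eig_bounds` with the prescription's seed.
#'
#' @param presc An `ou_prescription`.
#'
#' @return An object of class `ou_eigenset`: list with `complex_pairs`
#'   (complex vector, positive imaginary parts; conjugates implied) and
#'   `reals` (negative reals), all in rad/s, plus `n_nodes`.
#' @export
#' @examples
#' e <- prescription_eigenvalues(
#'   spectrum_prescription("Background", n_nodes = 6, seed = 2))
#' stopifnot(length(e$reals) == 6)
prescription_eigenvalues <- function(presc) {
  stopifnot(inherits(presc, "ou_prescription"))
  n <- presc$n_nodes
  n_pairs <- nrow(presc$peaks)
  if (2 * n_pairs > n) stop("more eigenvalues prescribed than nodes")
  cp <- complex(real = -2 * pi * presc$peaks$hwhm,
                imaginary = 2 * pi * presc$peaks$f_peak)
  set.seed(presc$seed)
  reals <- stats::runif(n - 2 * n_pairs,
                        presc$real_eig_bounds[1], presc$real_eig_bounds[2])
  out <- structure(list(complex_pairs = cp, reals = reals,
                        n_nodes = as.integer(n)),
                   class = "ou_eigenset")
  validate_eigenset(out)
  out
}

#' Construct an eigenvalue set directly
#'
#' @param complex_pairs Complex vector with negative real and positive
#'   imaginary parts (rad/s); each entry implies its conjugate.
#' @param reals Numeric vector of negative reals (rad/s).
#' @return An `ou_eigenset`.
#' @export
#' @examples
#' eigenset(complex(real = -1, imaginary = 2 * pi * 10))
eigenset <- function(complex_pairs = complex(0), reals = numeric(0)) {
  out <- structure(list(complex_pairs = as.complex(complex_pairs),
                        reals = as.numeric(reals),
                        n_nodes = as.integer(2 * length(complex_pairs) +
                                             length(reals))),
                   class = "ou_eigenset")
  validate_eigenset(out)
  out
}

validate_eigenset <- function(e) {
  stopifnot(inherits(e, "ou_eigenset"))
  if (length(e$complex_pairs) &&
      (any(Re(e$complex_pairs) >= 0) || any(Im(e$complex_pairs) <= 0)))
    stop("complex pairs must have negative real and positive imaginary part")
  if (any(e$reals >= 0)) stop("real eigenvalues must be negative")
  if (2 * length(e$complex_pairs) + length(e$reals) != e$n_nodes)
    stop("eigenvalue count does not match n_nodes")
  invisible(e)
}

#' Full eigenvalue vector (conjugates expanded) of an `ou_eigenset`
#' @param e An `ou_eigenset`.
#' @return Complex vector of length `n_nodes`.
#' @export
eigenset_values <- function(e) {
  validate_eigenset(e)
  c(e$complex_pairs, Conj(e$complex_pairs), complex(real = e$reals))
}

#' @export
print.ou_eigenset <- function(x, ...) {
  cat(sprintf("Eigenvalue set: %d nodes, %d complex pair(s), %d real(s) [rad/s]\n",
              x$n_nodes, length(x$complex_pairs), length(x$reals)))
  invisible(x)
}

## resolvent (i*2*pi*f*I - W)^{-1} at one frequency
resolvent <- function(W, f) {
  n <- nrow(W)
  solve(complex(imaginary = 2 * pi * f) * diag(n) - W)
}

check_stable <- function(W, tol = 0) {
  ev <- eigen(W, only.values = TRUE)$values
  if (max(Re(ev)) >= tol)
    stop("matrix is not stable: an eigenvalue has non-negative real part")
  invisible(ev)
}

#' Analytic channel-averaged power spectrum of the network
#'
#' For the stationary linear stochastic system driven by white noise of
#' standard deviation `sigma`, the channel-averaged power spectral density
#' at frequency `f` (Hz) is
#' `P(f) = (sigma^2 / N) * ||(i*2*pi*f*I - W)^{-1}||_F^2`,
#' the trace of the cross-spectrum matrix divided by `N`.
#'
#' @param W Stable real square connectivity matrix (rad/s units).
#' @param sigma Noise standard deviation.
#' @param grid Frequency grid in Hz (see [frequency_grid()]).
#'
#' @return An object of class `ou_spectrum`: data frame with columns
#'   `frequency_hz` and `power` (two-sided spectral density convention,
#'   reported on positive frequencies).
#' @export
#' @examples
#' P <- analytic_spectrum(matrix(-1), 1, frequency_grid(0.01, 10, 32))
analytic_spectrum <- function(W, sigma = 1, grid = frequency_grid()) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W), sigma > 0, all(diff(grid) > 0), all(grid > 0))
  check_stable(W)
  n <- nrow(W)
  p <- vapply(grid, function(f) {
    R <- resolvent(W, f)
    sigma^2 / n * sum(Mod(R)^2)
  }, numeric(1))
  structure(data.frame(frequency_hz = grid, power = p),
            class = c("ou_spectrum", "data.frame"))
}

#' Lorentzian-superposition spectrum from an eigenvalue set
#'
#' For a normal (orthogonally diagonalizable) connectivity matrix the
#' analytic spectrum reduces to a superposition of Lorentzians centred on
#' the eigenvalue imaginary parts with widths given by the real parts:
#' `P(f) = (sigma^2/N) * sum_k 1 / ((2*pi*f - Im(l_k))^2 + Re(l_k)^2)`.
#' For non-normal matrices this is the idealized target spectrum implied
#' by the eigenvalues alone.
#'
#' @param eigs An `ou_eigenset`.
#' @inheritParams analytic_spectrum
#' @return An `ou_spectrum` data frame.
#' @export
lorentzian_spectrum <- function(eigs, sigma = 1, grid = frequency_grid()) {
  lam <- eigenset_values(eigs)
  n <- length(lam)
  p <- vapply(grid, function(f) {
    w <- 2 * pi * f
    sigma^2 / n * sum(1 / ((w - Im(lam))^2 + Re(lam)^2))
  }, numeric(1))
  structure(data.frame(frequency_hz = grid, power = p),
            class = c("ou_spectrum", "data.frame"))
}

#' Analytic cross-spectrum matrix
#'
#' `S(f) = sigma^2 * (i*2*pi*f*I - W)^{-1} (i*2*pi*f*I - W)^{-dagger}`,
#' Hermitian positive semidefinite at each frequency. Its diagonal holds
#' the per-channel power spectra; the channel average of the diagonal is
#' the analytic power spectrum.
#'
#' @inheritParams analytic_spectrum
#' @return Object of class `ou_cross_spectrum`: list with `frequency_hz`
#'   and `S`, a complex array of dimension `c(N, N, length(grid))`.
#' @export
cross_spectrum <- function(W, sigma = 1, grid = frequency_grid()) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == ncol(W), sigma > 0)
  check_stable(W)
  n <- nrow(W)
  S <- array(complex(1), dim = c(n, n, length(grid)))
  for (k in seq_along(grid)) {
    R <- resolvent(W, grid[k])
    S[, , k] <- sigma^2 * (R %*% Conj(t(R)))
  }
  structure(list(frequency_hz = grid, S = S), class = "ou_cross_spectrum")
}

#' Per-node power spectra (diagonal of the cross-spectrum)
#' @param cs An `ou_cross_spectrum`.
#' @return Data frame: `frequency_hz` plus one column per node.
#' @export
node_spectra <- function(cs) {
  stopifnot(inherits(cs, "ou_cross_spectrum"))
  n <- dim(cs$S)[1]
  out <- sapply(seq_len(n), function(i) Re(cs$S[i, i, ]))
  colnames(out) <- paste0("node", seq_len(n))
  data.frame(frequency_hz = cs$frequency_hz, out)
}

#' Coherence and phase spectra from a cross-spectrum
#'
#' The coherency between channels i and j is the normalized cross-spectrum
#' `S_ij / sqrt(S_ii * S_jj)`; the coherence is its squared magnitude (in
#' `[0, 1]`) and the phase spectrum is its angle (in `(-pi, pi]`).
#'
#' @param cs An `ou_cross_spectrum`.
#' @return List with `frequency_hz`, `coherence` and `phase`, both real
#'   arrays of dimension `c(N, N, n_freq)`. Pairs with zero diagonal power
#'   yield `NA` (undefined coherency).
#' @export
coherence_phase <- function(cs) {
  stopifnot(inherits(cs, "ou_cross_spectrum"))
  d <- dim(cs$S)
  coh <- array(NA_real_, d)
  ph  <- array(NA_real_, d)
  for (k in seq_len(d[3])) {
    Sk <- cs$S[, , k]
    pk <- Re(diag(Sk))
    denom <- sqrt(outer(pk, pk))
    cy <- Sk / denom
    cy[denom == 0] <- NA
    coh[, , k] <- pmin(Mod(cy)^2, 1)
    ph[, , k]  <- Arg(cy)
  }
  list(frequency_hz = cs$frequency_hz, coherence = coh, phase = ph)
}

#' Spectral slope (power-law decay exponent) over a band
#'
#' Least-squares slope of `log10(power)` against `log10(frequency)` over
#' `[f_lo, f_hi]`, returned as the positive decay exponent `alpha` for a
#' spectrum falling off as `1/f^alpha`.
#'
#' @param curve An `ou_spectrum` (or data frame with `frequency_hz`,
#'   `power`).
#' @param f_lo,f_hi Band limits in Hz; must contain at least 3 grid points.
#' @return Scalar `alpha` (positive for decaying spectra).
#' @export
#' @examples
#' g <- frequency_grid(1, 100, 64)
#' curve <- data.frame(frequency_hz = g, power = g^-2)
#' spectral_slope(curve, 2, 50)  # 2
spectral_slope <- function(curve, f_lo, f_hi) {
  stopifnot(f_lo > 0, f_hi > f_lo)
  sel <- curve$frequency_hz >= f_lo & curve$frequency_hz <= f_hi
  if (sum(sel) < 3) stop("fewer than 3 grid points in the band")
  if (any(curve$power[sel] <= 0)) stop("power must be positive on the band")
  fit <- stats::lm(log10(power) ~ log10(frequency_hz), data = curve[sel, ])
  -unname(stats::coef(fit)[2])
}

#' Locate local maxima of a spectrum
#'
#' Finds interior local maxima of `log10(power)` on the grid, refined by
#' parabolic interpolation of the three points around each maximum, and
#' ranked by prominence (height above the higher of the two flanking
#' minima).
#'
#' @param curve An `ou_spectrum`-like data frame.
#' @param f_range Optional length-2 band in Hz restricting the search.
#' @param smooth Odd window length for a running-mean smoother applied to
#'   `log10(power)` before peak finding (1 = no smoothing); useful for
#'   noisy Welch estimates.
#' @return Data frame with `frequency_hz`, `power`, `prominence_log10`,
#'   ordered by decreasing prominence.
#' @export
spectral_peaks <- function(curve, f_range = NULL, smooth = 1L) {
  f <- curve$frequency_hz; p <- log10(curve$power)
  if (smooth > 1) {
    p <- as.numeric(stats::filter(p, rep(1 / smooth, smooth), sides = 2))
    keep <- !is.na(p)
    f <- f[keep]; p <- p[keep]
  }
  if (!is.null(f_range)) {
    sel <- f >= f_range[1] & f <= f_range[2]
    f <- f[sel]; p <- p[sel]
  }
  n <- length(f)
  if (n < 3) return(data.frame(frequency_hz = numeric(0), power = numeric(0),
                               prominence_log10 = numeric(0)))
  idx <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
  mins <- c(1L, which(p[2:(n - 1)] < p[1:(n - 2)] &
                      p[2:(n - 1)] <= p[3:n]) + 1L, n)
  out <- lapply(idx, function(i) {
    ## parabolic refinement on log-frequency axis
    lf <- log10(f[(i - 1):(i + 1)]); y <- p[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    dx <- if (denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
    dx <- max(-0.5, min(0.5, dx))
    f_hat <- 10^(lf[2] + dx * (lf[3] - lf[2]))
    left  <- max(mins[mins < i])
    right <- min(mins[mins > i])
    prom <- p[i] - max(min(p[left:i]), min(p[i:right]))
    data.frame(frequency_hz = f_hat, power = 10^p[i], prominence_log10 = prom)
  })
  out <- do.call(rbind, out)
  out[order(-out$prominence_log10), , drop = FALSE]
}
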