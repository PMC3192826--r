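test_that("prescriptions encode the five scenario groups", {
  p <- spectrum_prescription("Normal", n_nodes = 20, base_f = 2,
                             ratio = 2.6, n_peaks = 6, seed = 1)
  expect_equal(p$peaks$f_peak, 2 * 2.6^(0:5))
  expect_equal(diff(log(p$peaks$f_peak)),
               rep(log(2.6), 5))  # evenly spaced on log axis

  e <- spectrum_prescription("Entrained", n_nodes = 20,
                             bands = c(2.7, 8.1), seed = 1)
  expect_equal(e$peaks$f_peak[2] / e$peaks$f_peak[1], 3)

  i <- spectrum_prescription("Incomplete", n_nodes = 20, n_peaks = 6,
                             n_drop = 2, seed = 1)
  expect_equal(i$peaks$f_peak, 2 * 2.6^(0:3))  # top bands removed

  b <- spectrum_prescription("Background", n_nodes = 20, seed = 1)
  expect_equal(nrow(b$peaks), 0)

  r1 <- spectrum_prescription("Random", n_nodes = 20, n_peaks = 6, seed = 1)
  r2 <- spectrum_prescription("Random", n_nodes = 20, n_peaks = 6, seed = 2)
  expect_equal(nrow(r1$peaks), 6)
  expect_false(isTRUE(all.equal(r1$peaks$f_peak, r2$peaks$f_peak)))
  expect_true(all(r1$peaks$f_peak >= 2 & r1$peaks$f_peak <= 2 * 2.6^5))

  expect_error(spectrum_prescription("Normal", n_nodes = 4, n_peaks = 6),
               "n_nodes")
  expect_error(spectrum_prescription("Entrained", bands = c(100, 600)),
               "bandwidth")
})

test_that("eigenvalue mapping follows the peak/HWHM convention in rad/s", {
  p <- spectrum_prescription("Entrained", n_nodes = 2, bands = c(10),
                             hwhm_frac = 0.1, seed = 1)  # 10 Hz, 1 Hz HWHM
  e <- prescription_eigenvalues(p)
  expect_equal(e$complex_pairs, complex(real = -2 * pi,
                                        imaginary = 20 * pi))
  expect_length(e$reals, 0)

  b <- spectrum_prescription("Background", n_nodes = 20,
                             real_eig_bounds = c(-50, -1), seed = 4)
  eb <- prescription_eigenvalues(b)
  expect_length(eb$reals, 20)
  expect_true(all(eb$reals >= -50 & eb$reals <= -1))
  expect_length(eb$complex_pairs, 0)

  n80 <- prescription_eigenvalues(
    spectrum_prescription("Normal", n_nodes = 80, n_peaks = 6, seed = 1))
  expect_length(n80$complex_pairs, 6)   # 12 complex eigenvalues as pairs
  expect_length(n80$reals, 68)

  expect_equal(sort(Re(eigenset_values(n80))),
               sort(Re(c(n80$complex_pairs, Conj(n80$complex_pairs),
                         n80$reals))))
})

test_that("analytic spectrum reduces to the scalar Lorentzian", {
  g <- frequency_grid(0.01, 5, 128)
  P <- analytic_spectrum(matrix(-1), 1, g)
  expect_equal(P$power, 1 / (1 + (2 * pi * g)^2), tolerance = 1e-12)
})

test_that("a 2x2 rotation block produces a peak at (f0, hwhm)", {
  gamma <- 2 * pi * 1.5; omega0 <- 2 * pi * 12
  W <- rbind(c(-gamma, omega0), c(-omega0, -gamma))
  g <- frequency_grid(6, 24, 4001, log = FALSE)
  P <- analytic_spectrum(W, 1, g)
  f_hat <- g[which.max(P$power)]
  expect_equal(f_hat, 12, tolerance = 2e-2)
  ## dense-grid brute-force HWHM: half-maximum crossings around the peak
  pmax_ <- max(P$power)
  above <- g[P$power >= pmax_ / 2]
  hwhm_hat <- (max(above) - min(above)) / 2
  expect_equal(hwhm_hat, 1.5, tolerance = 0.1)
})

test_that("channel-averaged spectrum equals mean diagonal of the cross-spectrum", {
  W <- random_stable_matrix(6, seed = 3)
  g <- frequency_grid(0.5, 80, 17)
  P <- analytic_spectrum(W, 1.3, g)
  cs <- cross_spectrum(W, 1.3, g)
  for (k in seq_along(g))
    expect_equal(P$power[k], mean(Re(diag(cs$S[, , k]))), tolerance = 1e-12)
})

test_that("cross-spectrum is Hermitian PSD with real nonnegative diagonal", {
  W <- random_stable_matrix(5, seed = 9)
  cs <- cross_spectrum(W, 1, frequency_grid(0.2, 50, 9))
  for (k in seq_len(9)) {
    Sk <- cs$S[, , k]
    expect_lt(max(Mod(Sk - Conj(t(Sk)))), 1e-10)
    ev <- eigen((Sk + Conj(t(Sk))) / 2, only.values = TRUE)$values
    expect_gt(min(Re(ev)), -1e-10)
    expect_true(all(Re(diag(Sk)) >= 0))
  }
})

test_that("coherence is bounded, phase antisymmetric, diagonal trivial", {
  W <- random_stable_matrix(5, seed = 2)
  cp <- coherence_phase(cross_spectrum(W, 1, frequency_grid(0.5, 60, 11)))
  expect_true(all(cp$coherence >= 0 & cp$coherence <= 1))
  for (k in seq_len(11)) {
    ph <- cp$phase[, , k]
    off <- row(ph) != col(ph)
    expect_equal(ph[off], -t(ph)[off], tolerance = 1e-10)
    expect_equal(diag(cp$coherence[, , k]), rep(1, 5), tolerance = 1e-12)
    expect_equal(diag(ph), rep(0, 5), tolerance = 1e-12)
  }
  ## independent channels: zero coherence off the diagonal
  cpd <- coherence_phase(cross_spectrum(diag(-c(1, 2, 3)), 1,
                                        frequency_grid(0.5, 20, 5)))
  for (k in seq_len(5)) {
    co <- cpd$coherence[, , k]
    expect_lt(max(co[row(co) != col(co)]), 1e-20)
  }
})

test_that("high-frequency pairwise phase approaches a quarter cycle", {
  ## resolvent expansion: off-diagonal cross-spectrum is purely imaginary
  ## to leading order in 1/f, so |phase| -> pi/2
  W <- random_stable_matrix(6, seed = 5)
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  dev_at <- function(mult) {
    cp <- coherence_phase(cross_spectrum(W, 1, mult * rho / (2 * pi)))
    ph <- abs(cp$phase[, , 1])
    median(abs(ph[row(ph) != col(ph)] - pi / 2))
  }
  expect_lt(dev_at(200), 0.02)
  expect_lt(dev_at(200), dev_at(20))  # concentration improves with f
})

test_that("spectrum of a normal matrix equals the Lorentzian superposition", {
  ## orthogonal similarity of the real block form keeps the matrix normal
  e <- eigenset(complex_pairs = complex(real = c(-2, -5),
                                        imaginary = c(30, 80)),
                reals = c(-1, -4))
  L <- real_block_form(e)
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  W <- Q %*% L %*% t(Q)
  g <- frequency_grid(0.5, 40, 33)
  expect_equal(analytic_spectrum(W, 1.1, g)$power,
               lorentzian_spectrum(e, 1.1, g)$power, tolerance = 1e-10)
})

test_that("spectral slope recovers exact and asymptotic power laws", {
  g <- frequency_grid(1, 200, 128)
  expect_equal(spectral_slope(data.frame(frequency_hz = g, power = g^-2),
                              2, 100), 2, tolerance = 1e-10)
  ## scalar OU tail is 1/f^2
  P <- analytic_spectrum(matrix(-2 * pi * 0.5), 1, frequency_grid(20, 400, 64))
  expect_equal(spectral_slope(P, 30, 300), 2, tolerance = 0.05)
  expect_error(spectral_slope(data.frame(frequency_hz = 1:2, power = c(1, 1)),
                              1, 2), "3 grid points")
})

test_that("spectral peak finder locates and ranks local maxima", {
  g <- frequency_grid(0.5, 50, 600)
  two_peaks <- 1 / ((g - 5)^2 + 0.5) + 0.3 / ((g - 20)^2 + 2) + 1e-3
  pk <- spectral_peaks(data.frame(frequency_hz = g, power = two_peaks))
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$frequency_hz), c(5, 20), tolerance = 0.05)
  expect_gt(pk$prominence_log10[1], pk$prominence_log10[2])
})
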