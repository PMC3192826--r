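test_that("closed-form covariance matches the Lyapunov oracle", {
  ## isotropic decay: C = I / (2 gamma)
  expect_equal(stationary_covariance(diag(-2, 3), 1), diag(1 / 4, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## random stable instances vs the independent Kronecker solve
  worst <- 0
  for (trial in 1:100) {
    n <- 3 + trial %% 4
    W <- random_stable_matrix(n, seed = trial, sd = 0.8)
    s <- 0.5 + (trial %% 3)
    C <- stationary_covariance(W, s)
    worst <- max(worst, max(abs(C - lyapunov_oracle(W, s))))
  }
  expect_lt(worst, 1e-7)
})

test_that("covariance is symmetric PSD and solves the Lyapunov equation", {
  W <- random_stable_matrix(6, seed = 21)
  C <- stationary_covariance(W, 1.2)
  expect_equal(C, t(C), tolerance = 1e-10, ignore_attr = TRUE)
  expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  expect_equal(W %*% C + C %*% t(W), diag(-1.2^2, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## direct method agrees
  Cd <- stationary_covariance(W, 1.2, method = "lyapunov")
  expect_equal(C, Cd, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("simulated channel SDs match the analytic covariance diagonal", {
  W <- random_stable_matrix(4, seed = 31)
  C <- stationary_covariance(W)
  pan <- simulate_network(W, dt = 5e-4, duration = 120, seed = 31)
  sd_emp <- apply(pan$data, 1, sd)
  expect_equal(sd_emp, sqrt(diag(C)), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("TSE complexity is zero for independent channels", {
  for (n in c(3, 6, 10))
    expect_equal(as.numeric(tse_complexity(diag(n))), 0, tolerance = 1e-10)
  ## and also for any scaled identity
  expect_equal(as.numeric(tse_complexity(diag(2.7, 5))), 0, tolerance = 1e-10)
})

test_that("Monte-Carlo TSE complexity agrees with exact enumeration", {
  C <- random_psd(8, seed = 5)
  exact <- as.numeric(tse_complexity(C, mode = "exact"))
  mc <- replicate(12, as.numeric(
    tse_complexity(C, mode = "montecarlo", n_subset_samples = 60,
                   seed = sample.int(1e6, 1))))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - exact), 3 * se + 1e-8)
  expect_gt(exact, 0)
})

test_that("TSE complexity is invariant to permutation and rescaling", {
  C <- random_psd(7, seed = 9)
  base <- as.numeric(tse_complexity(C, mode = "exact"))
  p <- sample(7)
  expect_equal(as.numeric(tse_complexity(C[p, p], mode = "exact")), base,
               tolerance = 1e-9)
  expect_equal(as.numeric(tse_complexity(3.7 * C, mode = "exact")), base,
               tolerance = 1e-9)
})

test_that("node strength table reports TNS, inputs and ranks coherently", {
  W <- rbind(c(-1,  2, 0),
             c(-3, -1, 0.5),
             c( 0,  1, -1))
  ns <- node_strengths(W, stationary_covariance(W))
  expect_equal(ns$tns, c(2 + 3, 3 + 0.5 + 2 + 1, 1 + 0.5))  # |in| + |out|
  expect_equal(sort(ns$rank), 1:3)
  expect_equal(ns$rank[which.max(ns$tns)], 1L)  # low rank = greatest TNS
  expect_equal(ns$exc_in, c(2, 0.5, 1))
  expect_equal(ns$inh_in, c(0, 3, 0))
  expect_equal(ns$net_in, rowSums(W))
  expect_equal(ns$net_out, colSums(W))
  expect_true(all(ns$sd > 0))
  ## TNS invariant under sign flips
  ns2 <- node_strengths(-W)
  expect_equal(ns2$tns, ns$tns)
})

test_that("hierarchy curve is normalized, non-increasing, with sensible p50", {
  ## flat network: every node equal, half the nodes reach half the total
  Wf <- matrix(0.5, 10, 10); diag(Wf) <- -3
  h <- hierarchy_curve(node_strengths(Wf))
  expect_equal(h$tns_norm, rep(1, 10))
  expect_equal(h$p50_index, 5)
  ## star network: the hub dominates
  Ws <- fixture_network("star", n = 8)
  hs <- hierarchy_curve(node_strengths(Ws))
  expect_equal(hs$p50_index, 1)
  expect_true(all(diff(hs$tns_norm) <= 1e-12))
  expect_equal(which.max(node_strengths(Ws)$tns), 1)  # node 1 is the hub
})

test_that("node removal leaves independent channels untouched", {
  W <- diag(-c(1, 2, 3, 4))
  g <- frequency_grid(0.1, 10, 24)
  ## per-channel spectra of the reduced network equal the originals
  full <- node_spectra(cross_spectrum(W, 1, g))
  red <- node_spectra(cross_spectrum(W[-2, -2], 1, g))
  expect_equal(red$node1, full$node1, tolerance = 1e-12)
  expect_equal(red$node2, full$node3, tolerance = 1e-12)
  rs <- node_removal_scan(W, grid = g)
  expect_true(all(rs$stable))
  expect_true(all(rs$error >= 0))
})

test_that("twin nodes produce identical removal errors", {
  ## two symmetric halves: nodes 1/2 are exchangeable, as are 3/4
  W <- rbind(c(-2, 1, 0.5, 0.5),
             c(1, -2, 0.5, 0.5),
             c(0.5, 0.5, -3, 1),
             c(0.5, 0.5, 1, -3))
  rs <- node_removal_scan(W, grid = frequency_grid(0.1, 20, 32))
  expect_equal(rs$error[1], rs$error[2], tolerance = 1e-10)
  expect_equal(rs$error[3], rs$error[4], tolerance = 1e-10)
})

test_that("hub removal dominates the spectral error in peaked networks", {
  p <- spectrum_prescription("Normal", n_nodes = 12, n_peaks = 2, seed = 8)
  W <- solve_iep(p, seed = 8)
  rs <- node_removal_scan(W, grid = frequency_grid(0.5, 300, 64))
  ## nodes of increasing TNS rank contribute decreasingly to the spectrum
  expect_lt(attr(rs, "cor_rank_error"), -0.4)
  expect_gt(attr(rs, "cor_tns_error"), 0.4)
})

test_that("bootstrap test behaves at the null and under separation", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  bt <- bootstrap_mean_diff(a, b, n_iter = 2000, seed = 1)
  expect_equal(bt$observed, 0)
  expect_true(bt$p_value >= 0 && bt$p_value <= 1)

  ## strong separation: a below b gives a tiny left-tail p
  set.seed(4)
  x <- rnorm(20); y <- rnorm(20) + 5
  bt2 <- bootstrap_mean_diff(x, y, n_iter = 1e4, seed = 2)
  expect_lt(bt2$p_value, 0.01)

  ## type-I error: p roughly uniform when groups share a distribution
  set.seed(5)
  ps <- replicate(60, {
    u <- rnorm(12); v <- rnorm(12)
    suppressWarnings(  # deliberately coarse n_iter for speed
      bootstrap_mean_diff(u, v, n_iter = 400, seed = sample.int(1e6, 1),
                          alternative = "two.sided")$p_value)
  })
  expect_gt(mean(ps < 0.05), 0.0)   # sanity: p-values vary
  expect_lt(mean(ps < 0.05), 0.2)   # close to the nominal 5% level
  expect_gt(mean(ps), 0.3)          # not collapsed toward 0
  expect_warning(bootstrap_mean_diff(1:3, 4:6, n_iter = 10, seed = 1),
                 "coarse")
})

test_that("determinism: same seed gives the same bootstrap p-value", {
  x <- rnorm(10); y <- rnorm(10)
  b1 <- bootstrap_mean_diff(x, y, n_iter = 2000, seed = 9)
  b2 <- bootstrap_mean_diff(x, y, n_iter = 2000, seed = 9)
  expect_identical(b1$p_value, b2$p_value)
})
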