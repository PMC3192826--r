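## Closed-form covariance, TSE neural complexity, nodal-strength
## hierarchy, node-removal spectral perturbation and bootstrap tests.

#' Stationary covariance of the network dynamics in closed form
#'
#' For the stable linear stochastic system driven by white noise with
#' covariance `Q = sigma^2 I`, the stationary covariance `C` solves the
#' Lyapunov equation `W C + C W^T = -Q`. With the eigendecomposition
#' `W = L D L^{-1}`, transform `Qt = L^{-1} Q L^{-dagger}`, set
#' `Ct_ij = -Qt_ij / (lambda_i + conj(lambda_j))` and map back
#' `C = L Ct L^dagger`. If the eigenvector matrix is too ill-conditioned
#' the Lyapunov equation is solved directly (vectorized Kronecker solve)
#' and the result is flagged via attribute `method`.
#'
#' @param W Stable real square matrix (rad/s).
#' @param sigma Noise standard deviation.
#' @param method `"eigen"` (closed form, default), `"lyapunov"` (direct
#'   solve), or `"auto"` behaviour of `"eigen"` with fallback.
#' @param cond_threshold Eigenvector condition number above which the
#'   direct solve is used.
#' @return Symmetric positive semidefinite covariance matrix (signal
#'   units squared) with attribute `method`.
#' @export
#' @examples
#' stationary_covariance(diag(-2, 3), sigma = 1)  # I / 4
stationary_covariance <- function(W, sigma = 1,
                                  method = c("eigen", "lyapunov"),
                                  cond_threshold = 1e10) {
  W <- as.matrix(unclass(W))
  method <- match.arg(method)
  n <- nrow(W)
  stopifnot(ncol(W) == n, sigma > 0)
  check_stable(W)
  used <- method
  if (method == "eigen") {
    ed <- eigen(W)
    if (cond2(ed$vectors) > cond_threshold) {
      used <- "lyapunov"
    } else {
      L <- ed$vectors
      Li <- solve(L)
      Qt <- sigma^2 * (Li %*% Conj(t(Li)))
      denom <- outer(ed$values, Conj(ed$values), `+`)
      Ct <- -Qt / denom
      C <- L %*% Ct %*% Conj(t(L))
      if (max(abs(Im(C))) > 1e-6 * max(abs(Re(C))))
        warning("large imaginary residue in covariance; check conditioning")
      C <- Re(C)
    }
  }
  if (used == "lyapunov") {
    A <- diag(n) %x% W + W %x% diag(n)     # vec(WC + CW^T) = A vec(C)
    C <- matrix(solve(A, -as.vector(diag(sigma^2, n))), n, n)
  }
  C <- (C + t(C)) / 2
  structure(C, method = used)
}

## 2-norm condition number, valid for complex matrices
cond2 <- function(M) {
  d <- svd(M, nu = 0, nv = 0)$d
  d[1] / d[length(d)]
}

gaussian_entropy <- function(C, jitter = 1e-12) {
  ## 0.5 * log det(2 pi e C), with regularization for singular submatrices
  k <- nrow(C)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(C + diag(jitter, k))
  0.5 * k * log(2 * pi * exp(1)) + sum(log(diag(ch)))
}

#' Tononi-Sporns-Edelman neural complexity of a covariance matrix
#'
#' Gaussian-entropy TSE complexity:
#' `C_N = sum_{k=1}^{N} [ <H(subset of size k)> - (k/N) H(all) ]`,
#' where `H` is the Gaussian differential entropy from log-determinants
#' and `<.>` averages over subsets of size `k`. Subsets are enumerated
#' exactly for `N <= exact_limit` and sampled (seeded Monte Carlo)
#' otherwise. The measure is zero for independent channels (`C`
#' proportional to the identity), invariant under channel permutations
#' and under uniform rescaling of `C`, and balances functional
#' segregation against integration.
#'
#' @param C Covariance matrix (PSD, strictly positive diagonal).
#' @param mode `"auto"` (default), `"exact"` or `"montecarlo"`.
#' @param n_subset_samples Monte Carlo subsets per size level.
#' @param seed Seed for the subset sampler.
#' @param exact_limit Largest `N` enumerated exhaustively in auto mode.
#' @return Scalar complexity (nonnegative up to sampling error), with
#'   attribute `mode`.
#' @export
#' @examples
#' tse_complexity(diag(4))  # 0
tse_complexity <- function(C, mode = c("auto", "exact", "montecarlo"),
                           n_subset_samples = 200, seed = 1L,
                           exact_limit = 12L) {
  mode <- match.arg(mode)
  C <- as.matrix(unclass(C))
  n <- nrow(C)
  stopifnot(ncol(C) == n, all(diag(C) > 0))
  if (mode == "auto") mode <- if (n <= exact_limit) "exact" else "montecarlo"
  H_all <- gaussian_entropy(C)
  total <- 0
  if (mode == "exact") {
    for (k in seq_len(n - 1)) {
      subsets <- utils::combn(n, k)
      Hk <- mean(apply(subsets, 2, function(s)
        gaussian_entropy(C[s, s, drop = FALSE])))
      total <- total + Hk - k / n * H_all
    }
  } else {
    set.seed(as.integer(seed))
    for (k in seq_len(n - 1)) {
      n_avail <- choose(n, k)
      m <- min(n_subset_samples, n_avail)
      Hk <- mean(vapply(seq_len(m), function(i) {
        s <- sample(n, k)
        gaussian_entropy(C[s, s, drop = FALSE])
      }, numeric(1)))
      total <- total + Hk - k / n * H_all
    }
  }
  structure(total, mode = mode)
}

#' Nodal strength table and hierarchy summaries
#'
#' Total nodal strength (TNS) of node i is the sum of the absolute values
#' of all its input and output connection strengths,
#' `sum_{j != i} |W_ij| + sum_{j != i} |W_ji|` (self-connections
#' excluded). Ranking TNS in descending order defines the network
#' hierarchy: low rank nodes have the greatest TNS, high rank nodes the
#' least. The table also reports the total excitatory and inhibitory
#' input (sums of absolute values of positive resp. negative off-diagonal
#' row entries), the net input (full row sum) and net output (full column
#' sum), and, when a covariance is supplied, the fluctuation standard
#' deviation of each channel (square root of the covariance diagonal).
#'
#' @param W Connectivity matrix.
#' @param C Optional stationary covariance from the same `W`.
#' @return Object of class `ou_node_strengths`: data frame with columns
#'   `node`, `tns`, `rank`, `exc_in`, `inh_in`, `net_in`, `net_out` and
#'   (optionally) `sd`.
#' @export
node_strengths <- function(W, C = NULL) {
  W <- as.matrix(unclass(W))
  n <- nrow(W)
  stopifnot(ncol(W) == n)
  A <- abs(W); diag(A) <- 0
  tns <- rowSums(A) + colSums(A)
  Wo <- W; diag(Wo) <- 0
  out <- data.frame(
    node = seq_len(n),
    tns = tns,
    rank = rank(-tns, ties.method = "first"),
    exc_in = rowSums(Wo * (Wo > 0)),
    inh_in = rowSums(abs(Wo) * (Wo < 0)),
    net_in = rowSums(W),
    net_out = colSums(W))
  if (!is.null(C)) out$sd <- sqrt(pmax(diag(as.matrix(C)), 0))
  structure(out, class = c("ou_node_strengths", "data.frame"))
}

#' Hierarchy curve and 50th-percentile rank index
#'
#' Normalized TNS against rank (rank-1 TNS scaled to one) and the
#' smallest rank k whose cumulative TNS reaches half the network total
#' ("the nodes up to that rank account for 50% of the total nodal
#' strength"). Steep curves with a small percentile index indicate a
#' pronounced hierarchy.
#'
#' @param ns An `ou_node_strengths` table (or a connectivity matrix).
#' @return List with `rank`, `tns_norm` (non-increasing), `p50_index`.
#' @export
hierarchy_curve <- function(ns) {
  if (!inherits(ns, "ou_node_strengths")) ns <- node_strengths(ns)
  s <- sort(ns$tns, decreasing = TRUE)
  cum <- cumsum(s)
  list(rank = seq_along(s),
       tns_norm = s / s[1],
       p50_index = which(cum >= 0.5 * cum[length(cum)])[1])
}

#' Node-removal spectral perturbation scan
#'
#' For each node i, deletes row and column i from `W`, recomputes the
#' analytic channel-averaged power spectrum of the reduced network on the
#' same grid, and scores the perturbation as the normalized sum of
#' absolute differences between the log10 spectra:
#' `error_i = sum_f |log10 P^(i) - log10 P| / sum_f |log10 P|`.
#' Also reports the Pearson (and Spearman) correlation between the TNS
#' rank of the removed node and its error: strongly negative correlations
#' in rank mean that hub nodes (low rank, high TNS) dominate the spectrum.
#'
#' @param W Stable connectivity matrix with at least 3 nodes.
#' @param sigma Noise standard deviation.
#' @param grid Frequency grid in Hz.
#' @return Object of class `ou_removal_scan`: data frame with `node`,
#'   `rank`, `tns`, `error`, `stable`; attributes `cor_rank_error`
#'   (Pearson), `cor_rank_error_spearman`, `cor_tns_error`.
#' @export
node_removal_scan <- function(W, sigma = 1, grid = frequency_grid()) {
  W <- as.matrix(unclass(W))
  n <- nrow(W)
  stopifnot(n >= 3)
  base <- log10(analytic_spectrum(W, sigma, grid)$power)
  norm <- sum(abs(base))
  ns <- node_strengths(W)
  err <- numeric(n); stab <- logical(n)
  for (i in seq_len(n)) {
    Wi <- W[-i, -i, drop = FALSE]
    ev <- eigen(Wi, only.values = TRUE)$values
    stab[i] <- max(Re(ev)) < 0
    err[i] <- if (stab[i]) {
      pert <- log10(analytic_spectrum(Wi, sigma, grid)$power)
      sum(abs(pert - base)) / norm
    } else NA_real_
  }
  out <- data.frame(node = seq_len(n), rank = ns$rank, tns = ns$tns,
                    error = err, stable = stab)
  ok <- stats::complete.cases(out[, c("rank", "error")])
  safe_cor <- function(x, y, ...) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, ...)
  }
  structure(out, class = c("ou_removal_scan", "data.frame"),
            cor_rank_error = safe_cor(out$rank[ok], out$error[ok]),
            cor_rank_error_spearman =
              safe_cor(out$rank[ok], out$error[ok], method = "spearman"),
            cor_tns_error = safe_cor(out$tns[ok], out$error[ok]))
}

#' Bootstrap test for a difference of group means
#'
#' Pools the two groups, repeatedly splits the pool at random into
#' surrogate groups of the original sizes, and builds the null
#' distribution of surrogate mean differences. The p-value is the
#' left-tail integral of that distribution up to the observed difference
#' (`alternative = "less"`, the default); a two-sided variant is also
#' provided.
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param n_iter Number of bootstrap iterations (warning below 1000).
#' @param seed Integer seed.
#' @param alternative `"less"` (left tail) or `"two.sided"`.
#' @return Object of class `ou_bootstrap`: list with `observed` (mean(a) -
#'   mean(b)), `p_value`, `n_iter`, `alternative`.
#' @export
#' @examples
#' bootstrap_mean_diff(rnorm(10), rnorm(10) + 5, n_iter = 2000, seed = 1)
bootstrap_mean_diff <- function(values_a, values_b, n_iter = 1e4,
                                seed = 1L,
                                alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  if (n_iter < 1000) warning("n_iter < 1000: p-value will be coarse")
  pool <- c(values_a, values_b)
  na <- length(values_a); np <- length(pool)
  obs <- mean(values_a) - mean(values_b)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_iter), function(i) {
    idx <- sample.int(np, na)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1))
  p <- switch(alternative,
              less = mean(null <= obs),
              two.sided = mean(abs(null) >= abs(obs)))
  structure(list(observed = obs, p_value = p, n_iter = as.integer(n_iter),
                 alternative = alternative),
            class = "ou_bootstrap")
}

#' @export
print.ou_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap mean-difference test (%s): observed %.4g, p = %.4g (%d iterations)\n",
              x$alternative, x$observed, x$p_value, x$n_iter))
  invisible(x)
}
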