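## shared fixtures, all generated in code

## random stable matrix: random entries with a shifted diagonal
random_stable_matrix <- function(n, seed = 1, sd = 0.5, shift = NULL) {
  set.seed(seed)
  W <- matrix(rnorm(n * n, sd = sd), n, n)
  if (is.null(shift)) shift <- 2 * sd * sqrt(n)
  diag(W) <- diag(W) - shift
  stopifnot(max(Re(eigen(W, only.values = TRUE)$values)) < 0)
  W
}

## random symmetric PSD covariance with unit-scale diagonal
random_psd <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  C <- crossprod(A) / n + diag(0.5, n)
  (C + t(C)) / 2
}

## direct Lyapunov solve W C + C W^T = -sigma^2 I via Kronecker
## vectorization; independent oracle for the closed-form covariance
lyapunov_oracle <- function(W, sigma = 1) {
  n <- nrow(W)
  A <- diag(n) %x% W + W %x% diag(n)
  matrix(solve(A, -as.vector(diag(sigma^2, n))), n, n)
}

## signed adjacency object built directly from a sign matrix
signs_fixture <- function(S) {
  structure(list(signs = S, subset = seq_len(nrow(S)), rel_threshold = 0),
            class = "ou_signed_adjacency")
}

expect_all_finite <- function(x) expect_true(all(is.finite(unlist(x))))
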