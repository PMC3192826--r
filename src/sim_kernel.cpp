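// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Linear stochastic recursion driving the forward simulation.
//
// mode 0 (white drive, Euler-Maruyama or exact one-step):
//   x_{k+1} = A x_k + B z_k
// mode 1 (low-pass filtered drive, Euler-Maruyama):
//   s_{k+1} = (1 - dt/tau) s_k + sqrt(2 dt / tau) z_k
//   x_{k+1} = A x_k + (sigma * dt) s_k
// Z is n_channels x n_steps of standard normals generated in R so that
// reproducibility is governed by R's RNG. The first `burn` columns of the
// trajectory are discarded.
// [[Rcpp::export]]
arma::mat sim_linear_recursion(const arma::mat& A, const arma::mat& B,
                               const arma::mat& Z, int burn, int mode,
                               double dt, double tau, double sigma) {
    const arma::uword n = A.n_rows, T = Z.n_cols;
    arma::mat out(n, T - burn);
    arma::vec x(n, arma::fill::zeros), s(n, arma::fill::zeros);
    const double a_s = 1.0 - dt / tau, b_s = std::sqrt(2.0 * dt / tau);
    for (arma::uword k = 0; k < T; ++k) {
        if (mode == 0) {
            x = A * x + B * Z.col(k);
        } else {
            x = A * x + (sigma * dt) * s;
            s = a_s * s + b_s * Z.col(k);
        }
        if ((int)k >= burn) out.col(k - burn) = x;
    }
    return out;
}
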