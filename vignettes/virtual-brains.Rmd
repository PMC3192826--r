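---
title: "Reconstructing stochastic brain networks from prescribed power spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing stochastic brain networks from prescribed power spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ounet)
```

## The model

`ounet` treats multichannel recordings of ongoing neural activity (EEG,
MEG, field potentials) as realizations of a multivariate
Ornstein–Uhlenbeck process

$$\dot{x} = W x + \sigma\,\xi(t),$$

where $x_i(t)$ is the activity of node (channel) $i$ about its baseline,
$\xi$ is uncorrelated white noise, and $W$ is a real $N \times N$
*functional* connectivity matrix in units of 1/s. A positive $W_{ij}$
acts as functional excitation of node $i$ by node $j$, a negative entry
as functional inhibition; neither needs to correspond to an anatomical
pathway. Stability requires every eigenvalue of $W$ to have a negative
real part, and because $W$ is real the complex eigenvalues come in
conjugate pairs.

The power spectrum of this process is a superposition of Lorentzians
governed by the eigenvalues of $W$: each conjugate pair
$-2\pi h \pm i\,2\pi f$ contributes a spectral band peaked at $f$ Hz with
half width at half maximum $h$ Hz, while real eigenvalues contribute
zero-frequency Lorentzians that build the non-oscillatory $1/f^2$-type
background. The channel-averaged spectrum has the closed form

$$P(f) = \frac{\sigma^2}{N}\,
  \bigl\lVert (i\,2\pi f\,I - W)^{-1} \bigr\rVert_F^2 ,$$

implemented by `analytic_spectrum()`; the full cross-spectrum matrix,
coherence and phase spectra come from the same resolvent
(`cross_spectrum()`, `coherence_phase()`).

**Unit convention.** Eigenvalues are stored in rad/s throughout;
everything user-facing is in Hz with $f = \mathrm{Im}\,\lambda / 2\pi$
and $h = |\mathrm{Re}\,\lambda| / 2\pi$. One consequence worth knowing:
entries of $W$ are rad/s, so their magnitudes scale with $2\pi$ times
the effective bandwidth of the prescribed spectrum.

## Spectral prescriptions: what the generator emulates

`spectrum_prescription()` builds target spectra for five scenario
groups. They emulate characteristic classes of EEG/MEG spectra, not any
particular data set:

* **Normal** — bands evenly spaced on a logarithmic frequency axis, the
  signature of long recordings from healthy individuals. Default: 6
  bands, geometric from 2 Hz with ratio 2.6 (so the top band is
  ≈ 238 Hz and the spectrum carries power over roughly 0–300 Hz), and
  HWHM equal to 0.2 of the peak frequency. The published figure from
  which these bands descend prints no numeric table, so the defaults are
  configurable stand-ins with the right qualitative structure.
* **Entrained** — bands at exact small-integer frequency ratios
  (default 2.7 and 8.1 Hz, ratio 1:3), which phase-lock; this models
  cross-talk between rhythms as seen in epileptic recordings.
* **Incomplete** — the Normal sequence with the top bands removed
  (default drops 2 of 6), modeling the loss of high-frequency rhythms
  reported in cognitive disorders.
* **Background** — no bands at all: a pure $1/f^\alpha$ floor, the
  control shared by all groups.
* **Random** — the Normal band count with frequencies drawn uniformly
  on the log-frequency axis, fresh per realization; a second control.

The remaining $N - 2 \times (\text{bands})$ eigenvalues are real, drawn
uniformly between the smallest and largest real part of the *Normal*
group's complex pairs; all groups reuse those bounds so that the
background floor is comparable across groups. The noise level defaults
to $\sigma = 1$ for every channel.

What the generator does **not** emulate: measurement noise, volume
conduction/channel mixing, non-Gaussian or bistable dynamics, and any
spatial arrangement of channels. Tests that pass on these synthetic
conditions show that the algorithms are correct and that the group
contrasts are reproducible under the model's assumptions — not that a
particular clinical data set would show them.

## The inverse eigenvalue problem

Reconstruction asks: which real matrices $W$ have exactly the
prescribed eigenvalues and a prescribed set of zero entries? Following
the least-squares formulation of inverse eigenvalue problems, the
package parameterizes candidates isospectrally,

$$X(V) = V \Lambda V^{-1},$$

where $\Lambda$ (`real_block_form()`) is the real block-diagonal form of
the eigenvalue set — a $2 \times 2$ rotation–scaling block
$[[a, b], [-b, a]]$ per conjugate pair $a \pm ib$, reals on the
diagonal — so that $X$ is real and has the prescribed spectrum for
*every* invertible real $V$. With $\Pi$ the projection that overwrites
the prescribed positions with their prescribed values, the residual
$R = X - \Pi(X)$ measures the distance to the constraint subspace, and
the flow minimizes $J(V) = \tfrac12 \lVert R \rVert_F^2$. The gradient
has the closed form

$$\nabla_V J = \bigl(X R^{\mathsf T} - R^{\mathsf T} X\bigr)^{\mathsf T} V^{-\mathsf T},$$

derived from the first variation $dX = [\,dV\,V^{-1}, X\,]$; the
commutator structure is inherent to similarity flows. The implementation
validates this gradient against central finite differences (relative
error below $10^{-5}$) in the test suite.

Numerical choices, all configurable:

* **Initialization.** `init_flow_matrix()` draws entries i.i.d. uniform
  with width one and a random center in $[-0.5, 0.5]$, and rejects
  candidates until the condition number is below 200. The random center
  makes the initial distribution almost surely asymmetric about zero,
  which avoids starting on the symmetric-matrix manifold.
* **Integration.** `deSolve::lsodar` (adaptive, stiff-capable) with
  `rtol = 1e-6`, `atol = 1e-8`, and a root function that halts exactly
  when the residual crosses the threshold.
* **Stopping.** The reference residual threshold is 10 for the 80-node,
  35%-zeros configuration (2212 prescribed entries); because the
  residual is a Frobenius norm over the prescribed positions, the
  threshold scales proportionally with the prescribed-entry count
  (`residual_threshold()`). At reference scale the initial residual of a
  random start is of order $10^4$, so convergence spans three orders of
  magnitude. Below the threshold the flow's progress slows drastically;
  a stall rule (relative residual decrease below $10^{-4}$ over a
  geometrically growing flow-time window) returns the current matrix
  with a warning rather than iterating indefinitely.
* **Constraints.** 35% of the off-diagonal entries are prescribed zero
  by default, drawn with a dedicated seed. The diagonal is left free:
  reconstructed self-connections come out strictly negative
  (inhibitory), and constraining them would fight stability. Converged
  matrices are in practice much sparser than the 35% bound — typically
  40–50% of entries fall below 1% of the maximum magnitude
  (`sparsity_fraction()`).

Isospectrality is exact by construction (the returned matrix is
$V \Lambda V^{-1}$ at the final $V$), so eigenvalue error is set by
floating-point conditioning, not by convergence; the suite checks it at
$10^{-8}$ relative to the spectral radius. Runs are bitwise reproducible
for a fixed seed and tolerances.

## Forward simulation and estimation

`simulate_network()` integrates the model by Euler–Maruyama
($x \leftarrow x + \Delta t\,W x + \sqrt{\Delta t}\,\sigma\,\eta$) with
defaults $\Delta t = 2\times10^{-4}$ s, 60 s duration and 2 s burn-in —
chosen so that the slowest default band (2 Hz, HWHM 0.4 Hz) is resolved
and the step is far inside the stability region (the step is rejected if
$\Delta t > 0.1/\rho(W)$). An exact one-step update (matrix exponential
plus exact one-step noise covariance) is available for diagonalizable
$W$ as a cross-check. With `noise = "lowpass"` the drive is replaced by
an exponentially filtered process with time constant $\tau = 10$ ms and
unit stationary variance, which steepens the high-frequency fall-off
from $1/f^2$ to $1/f^4$; the white/colored slope pair is asserted in the
tests via `spectral_slope()`.

`welch_spectrum()` implements Hann-windowed averaged periodograms (2 s
segments, 50% overlap by default) and reports densities in the same
two-sided convention as the analytic formula so the two can be compared
without conversion factors; `spectrogram_panel()` wraps
`signal::specgram` for time-resolved spectra. `estimate_connectivity()`
recovers $W$ from traces by regressing forward-difference derivatives on
the states — the practical recipe for applying these analyses to real
recordings. Forward differencing incurs an $O(\Delta t\,\lambda)$ bias,
negligible at the default step but visible if the data are coarsely
sampled.

## Analytics

**Stationary covariance.** With $W = L D L^{-1}$, the covariance solves
$W C + C W^{\mathsf T} = -\sigma^2 I$ and has the closed form
$C = L \tilde C L^\dagger$ with
$\tilde C_{ij} = -\tilde Q_{ij} / (\lambda_i + \bar\lambda_j)$. If the
eigenvector matrix is ill-conditioned (condition number above $10^{10}$)
the package solves the Lyapunov equation directly by Kronecker
vectorization and flags the result. The two routes agree to $10^{-7}$ on
batches of random stable matrices in the tests.

**TSE complexity.** The Tononi–Sporns–Edelman measure is computed from
Gaussian subset entropies of $C$:
$C_N = \sum_k [\langle H_k\rangle - (k/N) H_N]$. Subsets are enumerated
exactly up to $N = 12$ and sampled (200 seeded subsets per size by
default) beyond; the Monte Carlo estimate agrees with enumeration within
sampling error in the tests. Singular submatrices fall back to a
jittered ($10^{-12}$) log-determinant. The measure is zero for
independent channels and invariant to permutation and uniform rescaling.

**Hierarchy.** The total nodal strength
$\mathrm{TNS}_i = \sum_{j\neq i}|W_{ij}| + \sum_{j\neq i}|W_{ji}|$
excludes the diagonal: self-connections are uniformly inhibitory and
would mask hub structure. Ranked in descending order it yields the
hierarchy curve and the 50th-percentile rank index (`hierarchy_curve()`);
peaked-group reconstructions are strongly hierarchical while Background
networks are flat. Net input/output use the *full* row and column sums
(diagonal included), matching their definition as sums of all elements
of a row or column.

**Node removal.** `node_removal_scan()` deletes one node at a time and
scores the perturbed analytic spectrum by the normalized sum of absolute
log10 differences, $\sum_f |\Delta \log_{10} P| / \sum_f |\log_{10} P|$
(the normalization is one of several reasonable conventions; it is fixed
here and documented). Pearson correlation between removal error and the
removed node's TNS rank is the headline statistic; Spearman is also
reported since the choice is not canonical.

**Bootstrap.** `bootstrap_mean_diff()` pools two groups, re-splits at
random preserving group sizes, and integrates the surrogate
mean-difference distribution from the left up to the observed value
(one-sided; a two-sided option exists). Production analyses at full
scale would use $10^6$ iterations; the package default is $10^4$ and the
tests use $10^3$–$10^4$, which is ample for the effect sizes involved.

## Motif census

Among hub nodes (those at or below the 50th-percentile rank index),
`signed_adjacency()` keeps only connection signs, with an edge deemed
present when its magnitude exceeds 5% (configurable, always reported) of
the largest in-subset off-diagonal magnitude — the underlying matrices
have no exact zeros, so some threshold is unavoidable and it is exposed
rather than hidden. `motif_census()` enumerates two families up to five
nodes: cyclic subgraphs (single-direction or fully reciprocal edges
around a cycle) and radial subgraphs (a center reciprocally linked to
leaves, leaf–leaf connections ignored). Two equivalences define the
classes: within a reciprocal pair the direction of excitation versus
inhibition is not distinguished (classes EE, II, EI), and the
arrangement of pair classes around the cycle or star is immaterial (the
class is the multiset). Occurrences are counted non-induced — a motif's
specified edges must be present, unspecified edges are ignored — which
makes class totals add up exactly to the number of placements with all
edges present, an invariant the tests assert by brute force.
Probabilities are percentages of possible placements, aggregable across
the matrices of a group with `merge_census()`.

The catalogue is generated programmatically from these family
definitions; enumeration is exhaustive and refuses (with an explicit
error) subsets too large to enumerate, rather than sampling silently.

## Problem sizes and reproducibility

The reference study conditions are 80-node networks, 20 per group. The
package's own tests and the acceptance script run the identical pipeline
at reduced scale — 20-node reconstructions (10–14 nodes for the group
ordering checks), 3 matrices per group, 60–120 s simulations — which
keeps a full run at desk scale while preserving every qualitative
contrast checked: Background has the lowest TSE complexity, Normal
hierarchies are steeper than Background, removal-error correlations are
stronger for peaked groups, and the counterbalanced
excitation/inhibition pair is the most common reciprocal 2-node motif.
For the round-trip band-recovery experiment (`roundtrip_peaks()`) the
Welch segments are lengthened to 5 s (0.2 Hz resolution) and the
log-spectrum is smoothed with a 5-bin running mean before peak picking,
because the slower band (2.7 Hz, HWHM 0.54 Hz) would be unresolvable
with the 2 s default.

Every random draw in the package (initial conditions, constraint masks,
real-eigenvalue draws, simulations, subset sampling, bootstrap) is
governed by an explicit integer seed, and identical seeds give bitwise
identical results; `run_group_study()` derives all per-matrix seeds
deterministically from a single master seed.

## Known limitations

* The least-squares flow guarantees convergence to a stationary point,
  not to a zero-residual solution; infeasible constraint sets stall and
  are returned with a warning flag and the achieved residual.
* The closed-form covariance assumes diagonalizable $W$; the Lyapunov
  fallback covers the rest but is $O(N^6)$ memory-naive and intended
  for moderate $N$.
* The linear Gaussian model cannot produce bistable or otherwise
  non-Gaussian dynamics; transient spindle-like events it generates are
  chance excursions of a stationary Gaussian field.
* Motif probabilities depend on the edge-presence threshold; compare
  censuses only at equal thresholds.

## A minimal session

```{r example, eval = FALSE}
presc <- spectrum_prescription("Normal", n_nodes = 20, n_peaks = 2,
                               seed = 1)
W <- solve_iep(presc, seed = 1)
attr(W, "residual"); sparsity_fraction(W)

pan <- simulate_network(W, dt = 2e-4, duration = 60, seed = 1)
plot(welch_spectrum(pan)$frequency_hz, welch_spectrum(pan)$power,
     log = "xy", type = "l")

C <- stationary_covariance(W)
tse_complexity(C)
hierarchy_curve(node_strengths(W, C))$p50_index
motif_census(signed_adjacency(W))
```
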