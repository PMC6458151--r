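---
title: "Inferring entropy production from bead-spring trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring entropy production from bead-spring trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprinfer)
```

## The model and its assumptions

`eprinfer` studies multi-bath bead-spring chains: $n$ beads on a line,
coupled to their neighbours and to walls at both ends by identical springs
of stiffness $k$, each bead overdamped in its own bath with friction
$\gamma$ and temperature $T_i$ (stored as thermal energies, $k_B = 1$).
The dynamics is the linear Langevin equation
$\dot{\mathbf x} = A\mathbf x + F\boldsymbol\xi$ with
$A = (k/\gamma)\,\mathrm{tridiag}(1,-2,1)$ and
$F_{ii} = \sqrt{2T_i/\gamma}$; the associated Fokker–Planck current is
$\mathbf j = A\mathbf x\rho - D\nabla\rho$ with $D = FF^\top/2$.
Everything downstream assumes this structure: linear (harmonic) forces,
overdamped dynamics, additive white noise, a unique Gaussian steady state.
Nonlinear springs, inertia, and external driving forces are out of scope.

Because the model is linear, every steady-state quantity has an exact
expression that the estimators can be tested against: the covariance
$\mathcal C$ solves the Lyapunov equation
$A\mathcal C + \mathcal C A^\top + 2D = 0$ (solved densely by the
Kronecker/vec method; chains here are short, so no iterative solver is
needed), the current is
$\mathbf j_{ss}(\mathbf x) = (A + D\mathcal C^{-1})\mathbf x\,
\rho_{ss}(\mathbf x)$, the thermodynamic force is the linear covector
field $\mathbf F(\mathbf x) = \mathbf j_{ss}^\top D^{-1}/\rho_{ss}$, and
the total entropy production rate is
$\dot S_{ss} = \mathrm{Tr}\{AD^{-1}A\mathcal C - \mathcal C^{-1}D\}$.
For two beads this reduces to $k(T_h-T_c)^2/(4\gamma T_hT_c)$ and the
implementation returns that closed form after verifying the trace value
against it; at equal temperatures it returns exactly zero. The two-bead
heat flow is $k(T_h-T_c)/(4\gamma)$, and
$\dot Q_{ss}(T_c^{-1}-T_h^{-1}) = \dot S_{ss}$ is asserted in the tests.

The reference parameter set used throughout the tests and the acceptance
script is $k=\gamma=1$, $k_BT_h = 250$, $k_BT_c = 25$
($\dot S_{ss} = 2.025$), and a five-bead variant whose bath temperatures
ramp linearly from 25 to 250 inclusive of both endpoints
($\dot S_{ss} \approx 0.630$). "Linear ramp" is interpreted as linear
spacing including both end temperatures; any other ramp can be passed as
an explicit `temps` vector.

## What the simulators emulate

`euler_maruyama()` generates the discrete-time data an experiment would
record: the stochastic Euler scheme
$\mathbf x_{i+1} = \mathbf x_i + A\mathbf x_i\Delta t + F\boldsymbol\eta$,
$\mathrm{Var}\,\eta = \Delta t$, at the default $\Delta t = 10^{-3}$
(the fastest relaxation rate of the reference chain is 3, so
$\Delta t\,|\lambda|_{max} = 3\times10^{-3}$; a warning fires above 0.1).
Initial conditions are drawn from the exact Gaussian steady state — for
this linear model that is identical to an infinitely long burn-in, and a
finite `burn_in` option exists for generality. What the generator does
*not* emulate: measurement noise, finite localization precision, hidden
degrees of freedom, or non-harmonic interactions. Passing tests therefore
demonstrate correctness of the estimators under ideal sampling of the
model, not robustness to the artifacts of real tracking data.

`jump_rates()` + `gillespie()` provide the complementary continuous-time
picture: a nearest-neighbour jump process on a rectangular lattice with
rates $D_{ii}/h_i^2 \pm (A\mathbf x)_i/(2h_i)$, which recovers the
Fokker–Planck equation as $h\to 0$ (the tests check the stationary law
against the Gaussian and the sampled cumulants against exact ones). Three
numerical consequences matter:

* **Positivity.** The drift term can overwhelm the diffusive term on a
  coarse grid far from the origin; `jump_rates()` refuses such lattices
  and names the offending site. In practice the box half-width $L_i$ and
  counts must satisfy $h_i < 2D_{ii}/\max|(A\mathbf x)_i|$.
* **Boundaries.** Jumps off the grid edge are dropped (reflecting
  boundary). This preserves probability and is invisible when the box
  extends past $\approx 4$ standard deviations of the steady state.
* **Discrete detailed balance.** At equal temperatures the discretization
  satisfies detailed balance only to $O(h^2)$, so a tiny spurious mean
  current survives on any finite grid; the tests bound it and check that
  it shrinks under refinement.

## Field estimation

`estimate_density()` and `estimate_current()` implement the empirical
density $\hat\rho(\mathbf x) = (\Delta t/\tau)\sum_i K(\mathbf x_i,
\mathbf x)$ and the kernel-regression current
$\hat{\jmath}(\mathbf x) = \hat\rho(\mathbf x)\,
\overline{[\mathbf x_{i+1}-\mathbf x_{i-1}]}_L/(2\Delta t)$, with central
differences averaged under a second kernel $L$. Kernels: bin indicators
(histogram), a product Gaussian with exponent
$-(\mathbf x-\mathbf x_i)^\top\Sigma^{-1}(\mathbf x-\mathbf x_i)$,
$\Sigma_{jj}=b_j^2$ (the exponent is taken negative; kernels are
normalized to integrate to one), and the product Epanechnikov kernel
$\prod_j(1-(x_j-x_{i;j})^2/b_j^2)$ on $|x_j - x_{i;j}| < b_j$. The default
grid is $100\times100$ on $[-50,50]\times[-20,20]$; grids generalize to
any dimension, and above $10^6$ bins the histogram estimators switch to
sparse occupied-bin storage keyed by the linear bin index, which is what
makes five-dimensional estimation feasible.

The rule-of-thumb bandwidth is
$b = (4/(N(d+2)))^{1/(d+4)}\tilde\sigma/0.6745$ per dimension. Two robust
scales $\tilde\sigma$ are provided: the geometric mean of the speed MAD
and the per-coordinate position MAD (`"velocity_position"`, the default),
and the position MAD alone (`"positions"`). The mixed scale inherits the
units of $\sqrt{\text{velocity}\times\text{position}}$ and at
$\Delta t = 10^{-3}$ produces bandwidths several times wider than the
position scale; both are exposed because neither reading is compelled by
the formula's ambiguous units, and all downstream functions accept an
explicit bandwidth.

Smooth-kernel sums are evaluated *exactly* at the bin centers in compiled
code (separable product kernels, per-dimension weight caching, Gaussian
support truncated at $6b$). For long trajectories with wide kernels the
exact sums cost $O(N\times\text{window})$, so a binned evaluation — bin
first, then convolve the bin totals with the kernel sampled at
center-to-center offsets, two 1-D passes — is selected automatically when
the exact cost would be prohibitive and $b \ge 2h$; its error is
$O((h/b)^2)$ and is measured against the exact path in the tests.

`estimate_force()` forms $\hat{\mathbf F} = \hat{\jmath}^\top
D^{-1}/\hat\rho$ and flags bins holding fewer than `min_samples`
(default 5) samples; flagged bins contribute zero to all downstream sums.
The floor avoids division blow-ups in never-visited bins. Setting
`min_samples = 0` integrates every visited bin instead — that variant
reproduces the textbook weakness of the spatial average (rarely visited
bins contribute pure rectified noise), and it is the default inside
`convergence_study()` precisely so that the spatial/temporal comparison
reflects that mechanism rather than the floor's editing. Both behaviours
are deliberate options because the histogramming protocol alone does not
dictate one.

## The three estimators

The spatial estimator is the Riemann sum
$\sum_{\text{bins}}\hat{\mathbf F}\cdot\hat{\jmath}\,\Delta V$ over
estimated bins; the temporal estimator is the Stratonovich sum
$\tau^{-1}\sum_i\hat{\mathbf F}((\mathbf x_i+\mathbf x_{i-1})/2)\cdot
(\mathbf x_i-\mathbf x_{i-1})$ with nearest-bin force lookup (bilinear
interpolation was considered and rejected: the histogram force is
piecewise constant, so interpolating it adds no information; an analytic
or linear force can be passed directly and is evaluated exactly at the
midpoints). A step whose midpoint leaves the estimated region contributes
zero; if more than half do, the estimate carries a warning.

Both plug-in estimators are biased at any finite $\tau$ because
$\hat{\mathbf F}$ is only asymptotically unbiased. Two mechanisms
dominate: *self-noise* (the same displacements enter $\hat{\mathbf F}$ and
the temporal sum, giving a positive $O(1/\tau)$ bias at fixed bins) and
*rectified tail noise* in the spatial integral. The convergence study in
the acceptance tests shows both estimators approaching
$\dot S_{ss}$ from above with the temporal one closer at every
$\tau \in \{500, 2000, 8000\}$; the clean 3-SEM consistency check against
2.025 is run with the exact force, where the only error is statistical.

The TUR route needs no force estimate: `accumulate_current()` splits the
trajectory into non-overlapping windows of length $\Delta\tau$
(non-overlapping, because overlapping windows bias the variance), forms
$j_d^{(k)} = \Delta\tau^{-1}\sum_i d(\text{midpoint})\cdot\Delta\mathbf x$
per window, and `tur_bound()` returns
$2\langle j_d\rangle^2/(\Delta\tau\,\mathrm{Var}\,j_d)$. The window length
plays the role of the observation time in the bound; the default
$\Delta\tau = 100\,\gamma/k$ sits far above the chain's slowest relaxation
time, and a stability test compares bounds at $\Delta\tau$ and
$2\Delta\tau$. The bound is invariant under $d \to c\,d$, which the tests
verify both on windows and on exact cumulants.

## Exact cumulants on the lattice

For lattice dynamics the mean and scaled variance of any generalized
current are computed without sampling: the weight field is discretized
onto directed edges by the midpoint rule
$d_{x+h,x} = d(x+h/2)\cdot h$ (antisymmetric by construction; for the
entropy-production current the alternative log-flux-ratio weight
$\ln(W_{xy}p_y/W_{yx}p_x)$ is also available via
`discretize_weight_field("epr", rates)`), the generator's off-diagonals
are tilted by $e^{\lambda d_e}$, and $\phi(\lambda)$ is the Perron
eigenvalue of the tilted operator. Numerics:

* The eigenvalue is found by shift-inverted inverse iteration on a sparse
  LU factorization of $W(\lambda)-\sigma I$. The shift (default
  $\sigma = 0.4$) must lie between the Perron eigenvalue
  ($|\phi|\ll 1$ in the $\lambda$ regime used) and the rest of the
  spectrum, whose real parts sit below the chain's slowest relaxation rate
  ($\approx 1$ for the reference chain); convergence is then geometric
  with ratio $\sigma/(\sigma + \text{gap})$.
* The eigenvalue is read off through a two-sided quotient whose left
  vector is the all-ones covector (the exact left null vector of the
  untilted generator). Its numerator is assembled with `expm1`, so
  $\phi(0) = 0$ holds exactly and $\phi(\pm10^{-5})\sim10^{-5}$ suffers no
  cancellation — this is what makes the tiny-step central differences
  $\langle j_d\rangle = (\phi(\delta\lambda)-\phi(-\delta\lambda))/
  2\delta\lambda$ and $\mathrm{Var} = (\phi(\delta\lambda)+
  \phi(-\delta\lambda))/\delta\lambda^2$ stable at the default
  $\delta\lambda = 10^{-5}$ (cumulants move only in the sixth digit when
  $\delta\lambda$ is varied a hundredfold).
* State spaces of at most 400 sites use a dense full-spectrum solve; the
  two paths agree to $10^{-10}$ and the dense path serves as the oracle in
  the tests.

The TUR tightness $\eta = \dot S_{TUR}^{(F)}/\dot S_{ss}$ is exposed by
`eta()` for two beads only — the lattice state count is $\prod_i n_i$ and
explodes in higher dimension, so five-bead current statistics come from
Gillespie sampling instead. One pitfall found while validating: on a box
of *fixed* physical size the error of lattice cumulants is dominated by
the reflecting-boundary truncation, not by $h$ — the stationary spread
grows as the cold bath warms, and a box that is $4\sigma$ at
$T_c/T_h = 0.1$ is only $1.6\sigma$ at 0.95, which visibly depresses
$\eta$. `temperature_sweep()` therefore builds a per-ratio lattice on a
$\pm4\sigma$ box (200×200 sites by default); with that choice
$\eta(0.95) = 0.999$ and is unchanged at 300×300, and the continuum limit
of the entropy current is approached only when box and spacing are refined
together, which is how the refinement test is written.

## Optimizing the weight field

`mc_optimize()` searches for a weight field with a maximal TUR ratio. The
field is a basis of $M = 100$ Gaussians: 50 free centers uniform over the
lattice box with breadth $B_{ii} = (0.1\times\text{box length})^2$, each
mirrored at $-\mathbf x^{(i)}$ with opposite weight so that
$d(-\mathbf x) = -d(\mathbf x)$ exactly. The printed scalar expansion is
read componentwise (each free Gaussian carries one weight per vector
component), since the weighting field must be a covector field. Proposals
perturb all free weights by uniform increments of half-width 0.5 (random
start) or 0.05 (start about the thermodynamic force, where the field is
$\mathbf F$ plus the basis) and are accepted with the Metropolis factor
$\min[1, e^{-\beta(S_{TUR}^{(d)}-S_{TUR}^{(d')})}]$ at $\beta = 5000$;
$\beta = \infty$ degenerates to hill climbing, for which the accepted
sequence is provably monotone (and tested). Every proposal is scored from
*exact* lattice cumulants, never from a sampled trajectory — scoring on a
single trajectory invites over-optimization of its sampling noise; a
cross-validated sampled mode (optimize on one trajectory, score on an
independent one) is the natural extension but is intentionally not the
default. For speed the Gaussian envelopes are precomputed once per lattice
(edge weights are linear in the free weights), so each step costs one
sparse factorization pair. The acceptance run uses a 60×60 lattice on a
$\pm3\sigma$ box and 500 steps per chain; both starts plateau within 10%
of each other and between $\dot S_{TUR}^{(F)}$ and $\dot S_{ss}$.

## Five-bead study and bandwidth sensitivity

In five dimensions the dense-grid machinery is unusable
($100^5$ bins), so the histogram estimators run on sparse occupied bins
with bin widths proportional to the rule-of-thumb bandwidth, and the MSE
sweep `mse_vs_bandwidth()` varies that width (factors 2, 4, 8 of the
position-scale rule in the acceptance run; at width factor 2 the plug-in
force is wildly noisy, which is the point of the comparison). MSEs are
measured against the analytic $\dot S_{ss}$ for the temporal estimator
and, for the TUR bound, against a long-trajectory sampled
$\dot S_{TUR}^{(F)}$ with the exact force — exact lattice cumulants being
unavailable at $n = 5$, a $\tau = 6000$ reference run is the package's
substitute for the infinite-sampling limit. The tested claim is the
max/min ratio of MSE across bandwidths: the TUR bound's ratio is far
smaller than the temporal estimator's, i.e. the bound is the
bandwidth-robust quantity. Study sizes: $\tau = 1200$ at
$\Delta t = 10^{-3}$, five replicates per bandwidth, window
$\Delta\tau = 100$ for the MSE sweep and 60 for the replicate-mean bound.

## Known limitations

* Estimator bias at finite $\tau$ is intrinsic; only the exact-force
  temporal average and the lattice cumulants are unbiased, and the
  convergence claims about plug-in estimators are qualitative
  (ordering and monotone approach), not sharp rates.
* The lattice machinery (exact cumulants, `eta`, `mc_optimize`) is
  restricted to two dimensions by state-count growth.
* Reflecting boundaries make lattice cumulants converge to a
  truncated-box limit; boxes must be sized to the model (the package
  auto-sizes them where it builds lattices itself, and errors out on
  rate-positivity violations otherwise).
* The sampled TUR bound near equilibrium needs
  $\tau \gtrsim 1/(\dot S_{ss}\times\text{rel. tol}^2)$ to resolve its
  mean current, which diverges as $T_c \to T_h$; near-equilibrium
  tightness is therefore demonstrated with exact lattice cumulants, not
  sampling.
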