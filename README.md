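# eprinfer

Inferring the entropy production rate of a nonequilibrium steady state from
trajectory data.

## The problem

A system coupled to several thermal reservoirs breaks detailed balance:
probability flows in closed loops through configuration space, heat flows
from hot baths to cold ones, and the total reservoir entropy grows at the
steady rate S&#775;<sub>ss</sub>. In biophysical settings the heat flux
itself is rarely measurable, but trajectories of the system's coordinates
are. `eprinfer` implements and compares three strategies for extracting
S&#775;<sub>ss</sub> (units of k<sub>B</sub>/time, with k<sub>B</sub> = 1)
from such trajectories:

1. **Spatial average** — estimate the steady density ρ̂(x) and current
   ĵ(x) on a grid by histogram or kernel methods, form the thermodynamic
   force F̂ = ĵᵀD⁻¹/ρ̂, and integrate F̂ · ĵ over configuration space.
2. **Temporal average** — integrate F̂ along the trajectory itself with
   the Stratonovich (midpoint) convention:
   (1/τ) Σᵢ F̂((xᵢ+xᵢ₋₁)/2) · (xᵢ−xᵢ₋₁).
3. **Current fluctuations (TUR)** — pick any weight field d(x), record the
   generalized current j_d over trajectory windows of length Δτ, and apply
   the thermodynamic uncertainty relation
   S&#775;<sub>ss</sub> ≥ 2⟨j_d⟩² / (Δτ Var j_d),
   which needs only a scalar time series and no force estimation.

The test bed is the exactly solvable bead-spring chain: n beads in a line,
coupled to each other and to two walls by springs of stiffness k, each bead
immersed in its own bath of friction γ and temperature Tᵢ. The dynamics is
the overdamped Langevin equation dx = A x dt + F dW with tridiagonal drift
A = (k/γ)·tridiag(1, −2, 1) and diagonal noise Fᵢᵢ = √(2Tᵢ/γ). Everything
is known analytically: the stationary covariance 𝒞 solves
A𝒞 + 𝒞Aᵀ + 2D = 0 (D = FFᵀ/2), the current is
j_ss(x) = (A + D𝒞⁻¹)x ρ_ss(x), and the entropy production rate is
S&#775;<sub>ss</sub> = Tr{AD⁻¹A𝒞 − 𝒞⁻¹D}, which for two beads reduces to
k(T_h−T_c)²/(4γT_hT_c) with heat flow Q&#775; = k(T_h−T_c)/(4γ).

Beyond sampling, the package computes current statistics **exactly** on a
lattice discretization of the dynamics: nearest-neighbour jump rates
Dᵢᵢ/hᵢ² ± (Ax)ᵢ/(2hᵢ) recover the Fokker–Planck equation as h → 0, and the
scaled cumulant generating function φ(λ) of any generalized current is the
top eigenvalue of the tilted generator 𝕎(λ)_{x+h,x} = 𝕎_{x+h,x}
e^{λ d_{x+h,x}}. Central differences of φ at λ = 0 give ⟨j_d⟩ and the
scaled variance without any sampling noise, which in turn powers a
Metropolis Monte Carlo search for the weight field d\*(x) whose TUR bound
is as tight as possible.

## Worked example

```r
library(eprinfer)

model <- build_chain(2, k = 1, gamma = 1, temps = c(250, 25))
ss <- steady_state(model)
ss
#> steady state of 2-bead chain: epr = 2.025 (k_B/time)
heat_flow(ss)
#> [1] 56.25

traj <- euler_maruyama(model, dt = 1e-3, n_steps = 2e6, seed = 1)
temporal_estimator(force_matrix(ss), traj)
#> EPR estimate (temporal): 2.04277

st <- accumulate_current(traj, force_matrix(ss), window = 50)
tur_bound(st)
#> TUR bound (sampled): S_dot >= 1.12493 (k_B/time)

lat <- lattice_spec(c(-36, -15), c(36, 15), c(60, 60))
e <- eta(model, lat)
round(c(epr = e$epr, tur_exact = e$tur$value, eta = e$eta), 4)
#>       epr tur_exact       eta
#>    2.0250    1.3854    0.6841
```

The temporal average along a τ = 2000 trajectory lands within a couple of
percent of the exact 2.025. The sampled TUR bound (40 windows of length
50) certifies about half the dissipation at this strong driving; the exact
lattice computation shows the infinite-sampling bound for d = F is 1.385
here, i.e. a tightness η ≈ 0.68, and η → 1 as the bath temperatures
approach each other. `mc_optimize()` searches for weight fields that beat
d = F; `convergence_study()` and `temperature_sweep()` run the full
estimator comparisons; `mse_vs_bandwidth()` probes sensitivity to the
kernel smoothing scale. A thin command-line driver over these functions is
installed at `inst/cli/eprinfer.R` (subcommands `simulate`, `epr`, `tur`,
`ldt`, `sweep`, `optimize`).

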