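# Shared fixtures: the two-bead chain at the reference parameters
# (k = gamma = 1, k_B T = 250 / 25), its equilibrium twin, and lattices
# small enough for fast exact computations. The reference entropy
# production rate is k (T_h - T_c)^2 / (4 gamma T_h T_c) = 2.025.

two_bead <- function() build_chain(2, 1, 1, temps = c(250, 25))

equilibrium_model <- function(temp = 100) {
  build_chain(2, 1, 1, temps = c(temp, temp))
}

EPR_REF <- 2.025

# 60 x 60 lattice on a ~3 sigma box where all jump rates stay positive
# (this box needs at least ~40 sites per axis for positive rates)
small_lattice <- function(counts = c(60, 60)) {
  lattice_spec(c(-36, -15), c(36, 15), counts)
}

# coarsest feasible lattice: 30 x 30 on a ~2.2 sigma box
tiny_lattice <- function() {
  lattice_spec(c(-30, -12), c(30, 12), c(30, 30))
}

# random stable two-bead parameter set (positive k, gamma, temps)
random_two_bead <- function() {
  build_chain(2, k = runif(1, 0.2, 5), gamma = runif(1, 0.2, 5),
              temps = runif(2, 5, 500))
}

# noiseless copy of a model (for deterministic Euler checks)
silence_noise <- function(model) {
  model$Fnoise <- matrix(0, model$n_beads, model$n_beads)
  model
}
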