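three_cycle <- function(f = 2, b = 0.5) {
  # uniform cycle 1 -> 2 -> 3 -> 1 with forward rate f, backward rate b
  W <- matrix(0, 3, 3)
  W[2, 1] <- W[3, 2] <- W[1, 3] <- f
  W[1, 2] <- W[2, 3] <- W[3, 1] <- b
  diag(W) <- -colSums(W)
  W
}

cycle_weights <- function() {
  d <- matrix(0, 3, 3)
  d[2, 1] <- d[3, 2] <- d[1, 3] <- 1
  d[1, 2] <- d[2, 3] <- d[3, 1] <- -1
  d
}

test_that("tilting at lambda = 0 or with zero weights is the identity", {
  W <- three_cycle()
  d <- cycle_weights()
  expect_lt(max(abs(tilted_matrix(W, d, 0) - W)), 1e-14)
  for (lam in c(-0.7, 0.3, 2)) {
    expect_lt(max(abs(tilted_matrix(W, matrix(0, 3, 3), lam) - W)), 1e-14)
  }
  tl <- as.matrix(tilted_matrix(W, d, 0.2))
  expect_equal(tl[2, 1], W[2, 1] * exp(0.2))
  expect_equal(tl[1, 2], W[1, 2] * exp(-0.2))
  expect_equal(diag(tl), diag(W))   # escape rates left untilted
})

test_that("two-site scgf matches the quadratic-formula closed form", {
  a <- 2; b <- 0.7
  W <- matrix(c(-a, a, b, -b), 2)
  d <- matrix(c(0, 0.8, -0.3, 0), 2)  # d[to, from]
  for (lam in c(-0.5, 0.1, 0.4)) {
    tr_sum <- -(a + b)
    det_t <- a * b - a * exp(lam * 0.8) * b * exp(lam * -0.3)
    mu <- (tr_sum + sqrt(tr_sum^2 - 4 * det_t)) / 2
    expect_equal(scgf(W, d, lam), mu, tolerance = 1e-10)
  }
  # antisymmetric weights on a two-site chain: no cycle, phi identically 0
  danti <- matrix(c(0, 1, -1, 0), 2)
  expect_equal(scgf(W, danti, 0.3), 0, tolerance = 1e-12)
})

test_that("three-state cycle scgf matches a dense full-spectrum solve", {
  W <- three_cycle(3, 0.4)
  d <- cycle_weights()
  for (lam in c(-0.3, 0.05, 0.25)) {
    tl <- as.matrix(tilted_matrix(W, d, lam))
    mu <- max(Re(eigen(tl, only.values = TRUE)$values))
    expect_equal(scgf(W, d, lam), mu, tolerance = 1e-10)
  }
  expect_equal(scgf(W, d, 0), 0, tolerance = 1e-12)
})

test_that("cycle cumulants match the known affinity structure", {
  f <- 3; b <- 0.4
  W <- three_cycle(f, b)
  d <- cycle_weights()
  cum <- exact_cumulants(W, d, dlambda = 1e-5)
  # stationary distribution uniform; net current per edge f/3 - b/3,
  # three edges counted once each per cycle step
  expect_equal(cum$mean, (f - b), tolerance = 1e-4)
  expect_gt(cum$var, 0)
  cz <- exact_cumulants(W, matrix(0, 3, 3))
  expect_equal(cz$mean, 0, tolerance = 1e-12)
  expect_equal(cz$var, 0, tolerance = 1e-12)
})

test_that("sparse iterative and dense scgf agree on a physical lattice", {
  m <- two_bead()
  ss <- steady_state(m)
  lat <- tiny_lattice()
  rates <- jump_rates(m, lat)
  w <- discretize_weight_field(force_matrix(ss), rates)
  for (lam in c(-1e-3, 1e-3)) {
    expect_equal(scgf(rates, w, lam, dense_threshold = 0L),
                 scgf(rates, w, lam, dense_threshold = 1000L),
                 tolerance = 1e-10)
  }
})

test_that("detailed-balance dynamics gives a symmetric scgf", {
  # reversible birth-death chain (exact detailed balance) with
  # antisymmetric edge weights: phi(lambda) must equal phi(-lambda)
  n <- 12
  W <- matrix(0, n, n)
  set.seed(3)
  up <- runif(n - 1, 0.5, 2)
  pi0 <- exp(runif(n, -1, 1))
  for (i in 1:(n - 1)) {
    W[i + 1, i] <- up[i]
    W[i, i + 1] <- up[i] * pi0[i] / pi0[i + 1]   # DB: W_ab pi_b = W_ba pi_a
  }
  diag(W) <- -colSums(W)
  d <- matrix(0, n, n)
  dw <- runif(n - 1, -1, 1)
  for (i in 1:(n - 1)) { d[i + 1, i] <- dw[i]; d[i, i + 1] <- -dw[i] }
  for (lam in c(0.05, 0.2)) {
    expect_equal(scgf(W, d, lam), scgf(W, d, -lam), tolerance = 1e-10)
  }
})

test_that("scgf is convex on a five-point stencil", {
  m <- two_bead()
  ss <- steady_state(m)
  rates <- jump_rates(m, small_lattice(c(40, 40)))
  set.seed(9)
  for (d in list(discretize_weight_field(force_matrix(ss), rates),
                 discretize_weight_field(
                   init_field("random", lattice = small_lattice(c(40, 40)),
                              M = 10, seed = 5), rates))) {
    lams <- c(-2e-3, -1e-3, 0, 1e-3, 2e-3)
    phis <- vapply(lams, function(l) scgf(rates, d, l), numeric(1))
    expect_true(all(diff(phis, differences = 2) > -1e-12))
  }
})

test_that("exact current mean equals the stationary flux average", {
  # independent oracle: <j_d> = sum_edges pi_from * W_e * d_e
  m <- two_bead()
  ss <- steady_state(m)
  rates <- jump_rates(m, small_lattice(c(40, 40)))
  w <- discretize_weight_field(force_matrix(ss), rates)
  p <- stationary_distribution(rates)
  flux_mean <- sum(p[rates$edges$from] * rates$Woff@x * w$w)
  cum <- exact_cumulants(rates, w)
  expect_equal(cum$mean, flux_mean, tolerance = 1e-6)
})

test_that("lattice entropy current converges to 2.025 under refinement", {
  # refine spacing and box together: on a fixed box the error plateaus at
  # the reflecting-boundary truncation level, so the continuum limit needs
  # h -> 0 with the box growing past the Gaussian support
  m <- two_bead()
  ss <- steady_state(m)
  specs <- list(list(b = c(36, 15), n = 60L),
                list(b = c(50, 20), n = 200L),
                list(b = c(55, 25), n = 280L))
  errs <- vapply(specs, function(sp) {
    lat <- lattice_spec(-sp$b, sp$b, c(sp$n, sp$n))
    rates <- jump_rates(m, lat)
    w <- discretize_weight_field(force_matrix(ss), rates)
    abs(exact_cumulants(rates, w)$mean - ss$epr)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[2] / EPR_REF, 0.02)   # the reference 200 x 200 lattice
  expect_lt(errs[3] / EPR_REF, 0.001)
})

test_that("TUR inequality holds for random weight fields on the lattice", {
  m <- two_bead()
  ss <- steady_state(m)
  lat <- small_lattice(c(40, 40))
  rates <- jump_rates(m, lat)
  for (s in 1:5) {
    fld <- init_field("random", lattice = lat, M = 20, seed = 100 + s)
    w <- discretize_weight_field(fld, rates)
    expect_lte(exact_tur_ratio(rates, w)$value, ss$epr * (1 + 1e-6))
  }
})

test_that("equilibrium lattice currents certify (near) zero dissipation", {
  # the drift-diffusion discretization only satisfies detailed balance up
  # to O(h^2), so the spurious mean current must be tiny and must shrink
  # under grid refinement
  m <- equilibrium_model(40)
  means <- vapply(c(24, 48), function(nc) {
    lat <- lattice_spec(c(-16, -16), c(16, 16), c(nc, nc))
    rates <- jump_rates(m, lat)
    fld <- init_field("random", lattice = lat, M = 10, seed = 2)
    abs(exact_cumulants(rates, discretize_weight_field(fld, rates))$mean)
  }, numeric(1))
  expect_lt(means[1], 5e-3)
  expect_lt(means[2], means[1])
  lat <- lattice_spec(c(-16, -16), c(16, 16), c(24, 24))
  rates <- jump_rates(m, lat)
  fld <- init_field("random", lattice = lat, M = 10, seed = 2)
  cum <- exact_cumulants(rates, discretize_weight_field(fld, rates))
  expect_lt(2 * cum$mean^2 / max(cum$var, 1e-300), 1e-5)
})

test_that("eta is restricted to two-bead chains", {
  m5 <- build_chain(5, 1, 1, endpoints = c(25, 250))
  expect_error(eta(m5, small_lattice()), "two beads")
})
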