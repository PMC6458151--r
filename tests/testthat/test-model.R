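test_that("chain construction follows the tridiagonal wall-anchored pattern", {
  m <- two_bead()
  expect_equal(m$A, matrix(c(-2, 1, 1, -2), 2))
  expect_equal(m$D, diag(c(250, 25)))
  expect_equal(m$Fnoise, diag(sqrt(2 * c(250, 25))))
  m3 <- build_chain(3, k = 2, gamma = 4, temps = c(10, 20, 30))
  expect_equal(diag(m3$A), rep(-2 * 2 / 4, 3))
  expect_equal(m3$A[1, 2], 2 / 4)
  expect_equal(m3$A[1, 3], 0)
  expect_true(all(eigen(m3$A, only.values = TRUE)$values < 0))
})

test_that("temperature endpoints are linearly interpolated inclusive", {
  m5 <- build_chain(5, 1, 1, endpoints = c(25, 250))
  expect_equal(m5$temps, c(25, 81.25, 137.5, 193.75, 250))
})

test_that("invalid chain parameters are rejected", {
  expect_error(build_chain(1, 1, 1, temps = 10), "n_beads")
  expect_error(build_chain(2, k = 0, gamma = 1, temps = c(1, 1)), "k")
  expect_error(build_chain(2, k = 1, gamma = -1, temps = c(1, 1)), "gamma")
  expect_error(build_chain(2, 1, 1, temps = c(10, -5)), "positive")
  expect_error(build_chain(2, 1, 1, temps = c(1, 2, 3)), "length")
  expect_error(build_chain(2, 1, 1), "exactly one")
  expect_error(build_chain(2, 1, 1, temps = c(1, 2), endpoints = c(1, 2)),
               "exactly one")
})

test_that("stationary covariance matches the two-bead closed form", {
  C <- stationary_covariance(two_bead())
  expect_equal(C, matrix(c(1775, 550, 550, 425), 2) / 12, tolerance = 1e-12)
  # equal temperatures: Boltzmann covariance T K^{-1} of the spring network
  Ceq <- stationary_covariance(equilibrium_model(100))
  expect_equal(Ceq, (100 / 12) * matrix(c(8, 4, 4, 8), 2), tolerance = 1e-12)
})

test_that("Lyapunov residual vanishes for random chains of several sizes", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    m <- build_chain(n, runif(1, 0.2, 4), runif(1, 0.2, 4),
                     temps = runif(n, 5, 400))
    C <- stationary_covariance(m)
    res <- m$A %*% C + C %*% t(m$A) + 2 * m$D
    expect_lt(max(abs(res)), 1e-10 * max(abs(m$D)))
    expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("trace formula matches the two-bead closed form over random sets", {
  set.seed(21)
  for (rep in 1:100) {
    m <- random_two_bead()
    ss <- steady_state(m)
    closed <- m$k * diff(m$temps)^2 / (4 * m$gamma * prod(m$temps))
    expect_lt(abs(ss$epr - closed), 1e-10 * max(1, closed))
  }
})

test_that("entropy production symmetry and scaling follow the closed form", {
  base <- steady_state(build_chain(2, 1.3, 0.7, temps = c(300, 60)))$epr
  swapped <- steady_state(build_chain(2, 1.3, 0.7, temps = c(60, 300)))$epr
  expect_equal(base, swapped, tolerance = 1e-12)
  k2 <- steady_state(build_chain(2, 2 * 1.3, 0.7, temps = c(300, 60)))$epr
  expect_equal(k2, 2 * base, tolerance = 1e-10)
  g2 <- steady_state(build_chain(2, 1.3, 2 * 0.7, temps = c(300, 60)))$epr
  expect_equal(g2, base / 2, tolerance = 1e-10)
})

test_that("heat flow times the thermodynamic affinity gives the entropy rate", {
  set.seed(31)
  for (rep in 1:20) {
    m <- random_two_bead()
    ss <- steady_state(m)
    affinity <- 1 / m$temps[2] - 1 / m$temps[1]
    expect_lt(abs(ss$heat_flow * affinity - ss$epr), 1e-10 * max(1, ss$epr))
  }
  expect_error(heat_flow(steady_state(build_chain(3, 1, 1,
                                                  temps = c(1, 2, 3)))),
               "two-bead")
})

test_that("reference parameters give epr 2.025 and heat flow 56.25", {
  ss <- steady_state(two_bead())
  expect_equal(ss$epr, EPR_REF, tolerance = 1e-12)
  expect_equal(ss$heat_flow, 56.25, tolerance = 1e-12)
  expect_equal(steady_state(equilibrium_model())$epr, 0, tolerance = 1e-14)
})

test_that("steady density is normalized and current is divergence-free", {
  ss <- steady_state(two_bead())
  g <- grid_spec(counts = c(200, 200))
  sites <- lattice_sites(g)
  rho <- steady_density(ss, sites)
  expect_equal(sum(rho) * prod(g$h), 1, tolerance = 1e-3)
  # stationarity: div j = 0 by central differences on the grid interior
  jx <- matrix(steady_current(ss, sites)[, 1], g$counts[1], g$counts[2])
  jy <- matrix(steady_current(ss, sites)[, 2], g$counts[1], g$counts[2])
  div <- (jx[3:200, 2:199] - jx[1:198, 2:199]) / (2 * g$h[1]) +
    (jy[2:199, 3:200] - jy[2:199, 1:198]) / (2 * g$h[2])
  expect_lt(max(abs(div)), 1e-4 * max(abs(jx)))
})

test_that("equilibrium currents, forces and local rates vanish identically", {
  ss <- steady_state(equilibrium_model())
  x <- matrix(rnorm(40, sd = 10), 20, 2)
  expect_lt(max(abs(steady_current(ss, x))), 1e-12)
  expect_lt(max(abs(thermodynamic_force(ss, x))), 1e-14)
  expect_lt(max(abs(local_epr(ss, x))), 1e-14)
})

test_that("local entropy production is nonnegative and integrates to the total", {
  ss <- steady_state(two_bead())
  expect_equal(local_epr(ss, c(0, 0)), 0)
  expect_lt(max(abs(thermodynamic_force(ss, c(0, 0)))), 1e-14)
  set.seed(5)
  x <- matrix(rnorm(200, sd = 8), 100, 2)
  expect_true(all(local_epr(ss, x) >= 0))
  g <- grid_spec(counts = c(200, 200))
  sites <- lattice_sites(g)
  quad <- sum(rowSums(thermodynamic_force(ss, sites) *
                        steady_current(ss, sites))) * prod(g$h)
  expect_equal(quad, ss$epr, tolerance = 0.01)
  expect_equal(sum(local_epr(ss, sites)) * prod(g$h), ss$epr,
               tolerance = 0.01)
})

test_that("model parameters round-trip through a key-value config file", {
  path <- tempfile(fileext = ".yaml")
  m <- build_chain(4, 1.5, 0.8, endpoints = c(30, 120))
  model_to_config(m, path)
  m2 <- model_from_config(path)
  expect_equal(m2$temps, m$temps)
  expect_equal(m2$A, m$A)
  unlink(path)
})
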