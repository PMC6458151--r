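make_traj <- function(positions, dt = 1e-3) {
  eprinfer:::new_trajectory(as.matrix(positions), dt)
}

test_that("bandwidth rule reproduces the rule-of-thumb arithmetic", {
  # positions with per-dimension MAD exactly 1: b = (4/(N(d+2)))^{1/(d+4)}/0.6745
  N <- 1000
  X <- cbind(rep(c(-1, 1), N / 2), rep(c(1, -1), N / 2) * 1)
  b <- bandwidth_rule(make_traj(X), scale = "positions")
  expect_equal(b, rep((0.001)^(1 / 6) / 0.6745, 2), tolerance = 1e-10)
  expect_equal(b[1], 0.4688, tolerance = 1e-3)
})

test_that("bandwidths are scale-equivariant and shrink as N^{-1/(d+4)}", {
  set.seed(2)
  X <- matrix(rnorm(2000), 1000, 2)
  t1 <- make_traj(X)
  t2 <- make_traj(2 * X)
  expect_equal(bandwidth_rule(t2, "positions"),
               2 * bandwidth_rule(t1, "positions"), tolerance = 1e-12)
  expect_equal(bandwidth_rule(t2), 2 * bandwidth_rule(t1),
               tolerance = 1e-12)
  Xbig <- X[rep(1:1000, 8), ]   # same robust scale, 8x the data
  expect_equal(bandwidth_rule(make_traj(Xbig), "positions") /
                 bandwidth_rule(t1, "positions"),
               rep(8^(-1 / 6), 2), tolerance = 1e-10)
  expect_error(bandwidth_rule(make_traj(cbind(rep(1, 100), rnorm(100)))),
               "degenerate")
})

test_that("histogram density puts all mass where the samples are", {
  g <- grid_spec(counts = c(10, 10))
  X <- matrix(rep(c(3, 3), 50), ncol = 2, byrow = TRUE)
  dens <- estimate_density(make_traj(X), g)
  expect_equal(sum(dens$values > 0), 1L)
  expect_equal(sum(dens$values) * prod(g$h), 1, tolerance = 1e-12)
  m <- two_bead()
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 5e4, seed = 6)
  dens2 <- estimate_density(tr, grid_spec())
  expect_equal(sum(dens2$values) * prod(grid_spec()$h), 1, tolerance = 1e-12)
})

test_that("smooth kernel density integrates to one and matches histograms", {
  m <- two_bead()
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 2e5, seed = 8)
  g <- grid_spec()
  cfg <- kernel_config("gaussian", "epanechnikov", bandwidth = c(1.5, 0.8))
  dsm <- estimate_density(tr, g, cfg)
  expect_equal(sum(dsm$values) * prod(g$h), 1, tolerance = 1e-2)
  dhist <- estimate_density(tr, g)
  l2 <- sqrt(sum((dsm$values - dhist$values)^2) * prod(g$h))
  ref <- sqrt(sum(dhist$values^2) * prod(g$h))
  expect_lt(l2 / ref, 0.25)
})

test_that("binned and exact smooth-kernel evaluations agree when b >> h", {
  m <- two_bead()
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 5e4, seed = 19)
  g <- grid_spec()
  cfg <- kernel_config("gaussian", "epanechnikov", bandwidth = c(4, 2))
  de <- estimate_density(tr, g, cfg, method = "exact")
  db <- estimate_density(tr, g, cfg, method = "binned")
  expect_equal(db$values, de$values, tolerance = 0.02)
  ce <- estimate_current(tr, g, cfg, density = de, method = "exact")
  cb <- estimate_current(tr, g, cfg, density = de, method = "binned")
  rel_l2 <- sqrt(mean((cb$values - ce$values)^2)) /
    sqrt(mean(ce$values^2))
  expect_lt(rel_l2, 0.2)
  expect_lt(max(abs(cb$values - ce$values)), 0.3 * max(abs(ce$values)))
})

test_that("empirical density approaches the Gaussian steady state", {
  m <- equilibrium_model()
  ss <- steady_state(m)
  g <- grid_spec(lower = c(-40, -40), upper = c(40, 40), counts = c(40, 40))
  rho <- steady_density(ss, lattice_sites(g))
  err <- vapply(c(2e4, 2e5), function(n) {
    tr <- euler_maruyama(m, dt = 1e-3, n_steps = n, seed = 4)
    dens <- estimate_density(tr, g)
    max(abs(dens$values - rho))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("current estimates flip sign under time reversal", {
  m <- two_bead()
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 2e4, seed = 5)
  rev <- make_traj(tr$positions[nrow(tr$positions):1, ], tr$dt)
  g <- grid_spec(counts = c(40, 40))
  cf <- estimate_current(tr, g)
  cr <- estimate_current(rev, g)
  expect_equal(cr$values, -cf$values, tolerance = 1e-12)
})

test_that("estimated currents align with the analytic current field", {
  m <- two_bead()
  ss <- steady_state(m)
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 1e6, seed = 16)
  g <- grid_spec(counts = c(50, 50))
  dens <- estimate_density(tr, g)
  curr <- estimate_current(tr, g, density = dens)
  jan <- steady_current(ss, lattice_sites(g))
  dense_bins <- which(dens$counts >= 200)
  cosang <- sum(curr$values[dense_bins, ] * jan[dense_bins, ]) /
    sqrt(sum(curr$values[dense_bins, ]^2) * sum(jan[dense_bins, ]^2))
  expect_gt(cosang, 0.5)
})

test_that("plug-in force recovers the analytic force from analytic fields", {
  m <- two_bead()
  ss <- steady_state(m)
  g <- grid_spec(counts = c(60, 60))
  dens <- field_from_function(g, function(x) steady_density(ss, x),
                              "density")
  curr <- field_from_function(g, function(x) steady_current(ss, x),
                              "current")
  fh <- estimate_force(dens, curr, m)
  fan <- thermodynamic_force(ss, lattice_sites(g))
  expect_equal(fh$values, fan, tolerance = 1e-10, ignore_attr = TRUE)
  # linearity: scaling the current scales the force
  curr2 <- curr; curr2$values <- 3 * curr2$values
  fh3 <- estimate_force(dens, curr2, m)
  expect_equal(fh3$values, 3 * fh$values, tolerance = 1e-12)
})

test_that("occupation floor flags rarely visited bins", {
  m <- two_bead()
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 5e3, seed = 23)
  g <- grid_spec(counts = c(50, 50))
  dens <- estimate_density(tr, g)
  curr <- estimate_current(tr, g, density = dens)
  fh <- estimate_force(dens, curr, m, min_samples = 5)
  expect_true(all(dens$counts[fh$estimated] >= 5))
  expect_true(all(fh$values[!fh$estimated, ] == 0))
  lk <- eprinfer:::field_values_at(fh, matrix(c(200, 200), 1))
  expect_false(lk$ok[1])
  expect_equal(as.numeric(lk$values), c(0, 0))
})

test_that("sparse high-dimensional histogram fields match dense results", {
  m <- two_bead()
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 2e4, seed = 31)
  g <- grid_spec(counts = c(30, 30))
  dd <- estimate_density(tr, g)
  dsp <- estimate_density(tr, g, sparse_threshold = 1)
  expect_equal(dsp$values, dd$values[dsp$bins], tolerance = 1e-12)
  cd <- estimate_current(tr, g, density = dd)
  csp <- estimate_current(tr, g, density = dsp, sparse_threshold = 1)
  expect_equal(csp$values, cd$values[csp$bins, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  fd <- estimate_force(dd, cd, m)
  fsp <- estimate_force(dsp, csp, m)
  tv <- temporal_estimator(fd, tr)$value
  tv_sp <- temporal_estimator(fsp, tr)$value
  expect_equal(tv_sp, tv, tolerance = 1e-12)
})

test_that("fields round-trip through delimited text", {
  m <- two_bead()
  tr <- euler_maruyama(m, dt = 1e-3, n_steps = 5e3, seed = 2)
  g <- grid_spec(counts = c(20, 20))
  dens <- estimate_density(tr, g)
  path <- tempfile(fileext = ".tsv")
  write_field(dens, path)
  back <- read_field(path, g, "density")
  expect_equal(back$values, dens$values, tolerance = 1e-10)
  unlink(path)
})
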