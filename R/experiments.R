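#' Convergence study of the dissipation estimators
#'
#' For each observation time, runs `n_replicates` independent Langevin
#' trajectories, estimates the density/current/force fields, and evaluates
#' the requested estimators. Each estimate is also reported normalized by
#' its infinite-sampling limit: the analytic entropy production rate for
#' the direct estimators, and the exact lattice TUR ratio for `d = F` for
#' the TUR estimator (supplied via `tur_limit`, or computed on `lattice`
#' for two-bead models).
#'
#' @param model a `bead_spring_model`.
#' @param tau_list observation times to sweep.
#' @param estimators subset of `c("spatial", "temporal", "tur")`.
#' @param n_replicates independent trajectories per point (default 10).
#' @param dt Euler timestep.
#' @param grid estimation grid.
#' @param config kernel configuration.
#' @param window TUR window length (defaults to `min(tau/10, 100 gamma/k)`).
#' @param min_samples occupation floor passed to [estimate_force()]; the
#'   default 0 integrates every visited bin, mirroring the histogrammed
#'   protocol whose spatial average degrades in rarely visited regions.
#' @param lattice optional `lattice_spec` for the exact TUR limit (2 beads).
#' @param tur_limit optional precomputed infinite-sampling TUR value.
#' @param seed integer seed.
#' @return a data frame (one row per estimator x tau) with mean, SE,
#'   normalized mean and SE, replicate count, and the reference values.
#' @export
convergence_study <- function(model, tau_list,
                              estimators = c("spatial", "temporal", "tur"),
                              n_replicates = 10L, dt = 1e-3,
                              grid = grid_spec(), config = kernel_config(),
                              window = NULL, lattice = NULL,
                              tur_limit = NULL, min_samples = 0, seed = 1L) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  ss <- steady_state(model)
  sdot <- ss$epr
  if ("tur" %in% estimators && is.null(tur_limit)) {
    if (is.null(lattice) || model$n_beads != 2L)
      stop("supply tur_limit (or a lattice for a two-bead model) to ",
           "normalize the TUR estimator")
    rates <- jump_rates(model, lattice)
    wF <- discretize_weight_field(force_matrix(ss), rates)
    tur_limit <- exact_tur_ratio(rates, wF)$value
  }
  rows <- list()
  for (tau in tau_list) {
    win <- if (is.null(window))
      max(10 * dt, min(tau / 10, 100 * model$gamma / model$k)) else window
    vals <- matrix(NA_real_, n_replicates, 3,
                   dimnames = list(NULL, c("spatial", "temporal", "tur")))
    for (r in seq_len(n_replicates)) {
      traj <- euler_maruyama(model, dt = dt, n_steps = round(tau / dt),
                             seed = seed + 1000L * match(tau, tau_list) + r)
      dens <- estimate_density(traj, grid, config)
      curr <- estimate_current(traj, grid, config, density = dens)
      fhat <- estimate_force(dens, curr, model, min_samples = min_samples)
      if ("spatial" %in% estimators)
        vals[r, "spatial"] <- spatial_estimator(fhat, curr, tau)$value
      if ("temporal" %in% estimators)
        vals[r, "temporal"] <- temporal_estimator(fhat, traj)$value
      if ("tur" %in% estimators)
        vals[r, "tur"] <-
          tur_bound(accumulate_current(traj, fhat, window = win))$value
    }
    for (est in estimators) {
      limit <- if (est == "tur") tur_limit else sdot
      v <- vals[, est]
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, tau_obs = tau, n_replicates = n_replicates,
        mean = mean(v), se = stats::sd(v) / sqrt(n_replicates),
        limit = limit, normalized = mean(v) / limit,
        normalized_se = stats::sd(v / limit) / sqrt(n_replicates),
        seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' Temperature-ratio sweep of the TUR tightness
#'
#' For each ratio `T_c / T_h` (at fixed `T_h`), reports the analytic
#' entropy production rate, the exact lattice TUR ratio for `d = F`, and
#' the tightness `eta` (two-bead models); optionally adds a sampled TUR
#' bound from Langevin current statistics.
#'
#' @param ratios vector of temperature ratios in (0, 1].
#' @param t_hot hot-bath temperature (energy units).
#' @param n_beads chain length; the exact lattice column requires 2.
#' @param k,gamma chain parameters.
#' @param lattice `lattice_spec` for the exact computation; `NULL` builds a
#'   per-ratio lattice of `counts` sites on a `sigma_box`-standard-deviation
#'   box (the stationary spread grows as the cold bath warms, so a fixed box
#'   truncates the near-equilibrium ensembles).
#' @param counts,sigma_box per-axis site counts and box half-width in
#'   stationary standard deviations for the automatic lattice.
#' @param sampled if `TRUE`, also compute a sampled TUR bound per ratio.
#' @param tau,dt,window sampling parameters for the sampled column.
#' @param seed integer seed.
#' @return data frame with one row per ratio.
#' @export
temperature_sweep <- function(ratios, t_hot = 250, n_beads = 2L, k = 1,
                              gamma = 1, lattice = NULL, sampled = FALSE,
                              tau = 1000, dt = 1e-3, window = 50,
                              counts = c(200, 200), sigma_box = 4,
                              seed = 1L) {
  auto_lattice <- is.null(lattice)
  rows <- lapply(ratios, function(r) {
    model <- build_chain(n_beads, k, gamma,
                         endpoints = c(t_hot, r * t_hot))
    ss <- steady_state(model)
    out <- data.frame(ratio = r, epr = ss$epr, tur_exact = NA_real_,
                      eta = NA_real_, tur_sampled = NA_real_)
    if (n_beads == 2L) {
      lat <- if (auto_lattice) {
        box <- sigma_box * sqrt(diag(ss$cov))
        lattice_spec(-box, box, counts)
      } else lattice
      e <- eta(model, lat)
      out$tur_exact <- e$tur$value
      out$eta <- e$eta
    }
    if (sampled) {
      traj <- euler_maruyama(model, dt = dt, n_steps = round(tau / dt),
                             seed = seed + round(1000 * r))
      st <- accumulate_current(traj, force_matrix(ss), window = window)
      out$tur_sampled <- tur_bound(st)$value
    }
    out
  })
  do.call(rbind, rows)
}

#' Generate small deterministic fixtures for tests and examples
#'
#' Writes a short two-bead Langevin trajectory and its histogram density
#' field as plain text under `dir`, with the seed recorded in the file
#' names. Regeneration with the same seed is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_steps trajectory length (kept small by design).
#' @return invisible character vector of file paths.
#' @export
fixture_generator <- function(dir, seed = 42L, n_steps = 2000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- build_chain(2, 1, 1, temps = c(250, 25))
  traj <- euler_maruyama(model, dt = 1e-3, n_steps = n_steps, seed = seed)
  tpath <- file.path(dir, sprintf("traj_2bead_seed%d.tsv", seed))
  write_trajectory(traj, tpath)
  grid <- grid_spec(counts = c(20, 20))
  dens <- estimate_density(traj, grid)
  dpath <- file.path(dir, sprintf("density_2bead_seed%d.tsv", seed))
  write_field(dens, dpath)
  invisible(c(tpath, dpath))
}
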