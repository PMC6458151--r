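#' Simulate a discrete-time Langevin trajectory
#'
#' Integrates the overdamped dynamics `dx = A x dt + Fnoise dW` with the
#' stochastic Euler scheme `x_{i+1} = x_i + A x_i dt + Fnoise eta`, where
#' `eta` has independent Gaussian components of variance `dt`.
#'
#' @param model a `bead_spring_model`.
#' @param x0 initial configuration (n-vector); default is a steady-state
#'   draw (see [draw_steady_initial()]).
#' @param dt timestep; a warning is issued when `dt * max|eig(A)| > 0.1`.
#' @param n_steps number of Euler steps.
#' @param seed integer RNG seed (recorded in the result).
#' @param thin store every `thin`-th state (the integration always proceeds
#'   at `dt`).
#' @param burn_in number of unrecorded equilibration steps before the clock
#'   starts (an alternative to the exact steady-state draw).
#' @return a `trajectory`: list with `dt` (sampling interval `dt * thin`),
#'   `positions` (matrix, one configuration per row), `t0`, `seed`.
#' @export
euler_maruyama <- function(model, x0 = NULL, dt = 1e-3, n_steps,
                           seed = NULL, thin = 1L, burn_in = 0L) {
  stopifnot(inherits(model, "bead_spring_model"))
  if (dt <= 0) stop("dt must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (dt * max(abs(eigen(model$A, only.values = TRUE)$values)) > 0.1)
    warning("dt is large relative to the fastest relaxation rate; ",
            "the Euler scheme may be inaccurate")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- draw_steady_initial(model)
  if (burn_in > 0L) {
    warm <- cpp_euler(model$A, model$Fnoise, as.numeric(x0), dt,
                      as.integer(burn_in), as.integer(burn_in))
    x0 <- warm[nrow(warm), ]
  }
  pos <- cpp_euler(model$A, model$Fnoise, as.numeric(x0), dt, n_steps,
                   as.integer(thin))
  new_trajectory(pos, dt * thin, seed = seed)
}

new_trajectory <- function(positions, dt, t0 = 0, seed = NULL) {
  structure(list(dt = dt, positions = positions, t0 = t0, seed = seed),
            class = "trajectory")
}

#' Observation time spanned by a trajectory
#' @param traj a `trajectory`.
#' @return `dt * (number of samples - 1)`.
#' @export
tau_obs <- function(traj) traj$dt * (nrow(traj$positions) - 1L)

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples of dim %d, dt = %g, tau_obs = %g\n",
              nrow(x$positions), ncol(x$positions), x$dt, tau_obs(x)))
  invisible(x)
}

#' Draw configurations from the exact steady state
#'
#' Samples the zero-mean Gaussian with the stationary covariance (exact for
#' this linear model, equivalent to an infinitely long burn-in).
#'
#' @param model a `bead_spring_model`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return an n-vector for `n = 1`, otherwise a matrix with one draw per row.
#' @export
draw_steady_initial <- function(model, n = 1L, seed = NULL) {
  stopifnot(inherits(model, "bead_spring_model"))
  if (!is.null(seed)) set.seed(seed)
  C <- stationary_covariance(model)
  z <- matrix(stats::rnorm(n * model$n_beads), n, model$n_beads)
  x <- z %*% chol(C)
  if (n == 1L) as.numeric(x) else x
}

#' Rectangular lattice specification
#'
#' A regular grid of `counts[j]` sites per dimension on the box
#' `[lower, upper]`, with sites at cell centers and spacing
#' `h = (upper - lower) / counts`.
#'
#' @param lower,upper per-dimension box bounds.
#' @param counts per-dimension site counts (>= 2).
#' @return a `lattice_spec` with `lower`, `upper`, `counts`, `h`, `centers`
#'   (list of per-dimension center coordinates).
#' @export
lattice_spec <- function(lower, upper, counts) {
  d <- length(lower)
  stopifnot(length(upper) == d, length(counts) == d)
  counts <- as.integer(counts)
  if (any(counts < 2L)) stop("counts must be >= 2 in every dimension")
  if (any(upper <= lower)) stop("bounds must satisfy lower < upper")
  h <- (upper - lower) / counts
  centers <- lapply(seq_len(d), function(j)
    lower[j] + (seq_len(counts[j]) - 0.5) * h[j])
  structure(list(lower = lower, upper = upper, counts = counts, h = h,
                 centers = centers),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat("lattice:", paste(x$counts, collapse = " x "), "sites on [",
      paste(sprintf("%g..%g", x$lower, x$upper), collapse = "] x ["), "]\n")
  invisible(x)
}

#' Coordinates of all lattice sites
#'
#' Sites are ordered with the first dimension varying fastest (column-major
#' multi-index order).
#'
#' @param lattice a `lattice_spec`.
#' @return matrix with one site coordinate per row.
#' @export
lattice_sites <- function(lattice) {
  as.matrix(expand.grid(lattice$centers, KEEP.OUT.ATTRS = FALSE))
}

#' Linear site index of configurations on a lattice
#'
#' Maps configurations to the 1-based linear index of the lattice cell they
#' fall in (`NA` outside the box), first dimension fastest.
#'
#' @param lattice a `lattice_spec`.
#' @param x configuration matrix (one per row) or single n-vector.
#' @return integer-valued numeric vector of site indices.
#' @export
site_index <- function(lattice, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  d <- length(lattice$counts)
  idx <- rep(0, nrow(x))
  stride <- 1
  for (j in seq_len(d)) {
    ij <- floor((x[, j] - lattice$lower[j]) / lattice$h[j])
    ij[ij < 0 | ij >= lattice$counts[j]] <- NA
    idx <- idx + ij * stride
    stride <- stride * lattice$counts[j]
  }
  idx + 1
}

#' Transition rates of the lattice jump process
#'
#' Builds the generator of the continuous-time Markov jump process whose
#' small-`h` limit is the model's Fokker-Planck equation: for a step of
#' `+/- h_j` along axis `j` from a site at `x`, the rate is
#' `D_jj / h_j^2 +/- (A x)_j / (2 h_j)`. Jumps leaving the box are dropped
#' (reflecting boundary); diagonal entries close each column to zero.
#'
#' @param model a `bead_spring_model` with `n_beads == length(lattice$counts)`.
#' @param lattice a `lattice_spec` covering a region where all rates are
#'   positive (an error names the first offending site otherwise).
#' @return a `rate_matrix`: list with `W` (sparse generator, entry
#'   `[to, from]` is the from->to rate, columns sum to zero), `Woff`
#'   (off-diagonal part), `exit` (escape rates), `edges` (data frame
#'   `from`, `to` aligned with `Woff@x`), `lattice`, `sites`.
#' @export
jump_rates <- function(model, lattice) {
  stopifnot(inherits(model, "bead_spring_model"),
            inherits(lattice, "lattice_spec"))
  d <- length(lattice$counts)
  if (model$n_beads != d)
    stop("lattice dimension must equal the number of beads")
  sites <- lattice_sites(lattice)
  S <- nrow(sites)
  drift <- sites %*% t(model$A)
  Dd <- diag(model$D)
  multi <- lapply(seq_len(d), function(j) {
    stride <- if (j == 1L) 1L else prod(lattice$counts[seq_len(j - 1L)])
    ij <- ((seq_len(S) - 1L) %/% stride) %% lattice$counts[j]
    ij  # 0-based index along dimension j
  })
  from <- integer(0); to <- integer(0); val <- numeric(0)
  for (j in seq_len(d)) {
    stride <- if (j == 1L) 1L else prod(lattice$counts[seq_len(j - 1L)])
    base <- Dd[j] / lattice$h[j]^2
    for (s in c(1, -1)) {
      ok <- if (s > 0) multi[[j]] < lattice$counts[j] - 1L else multi[[j]] > 0L
      r <- base + s * drift[, j] / (2 * lattice$h[j])
      if (any(r[ok] <= 0)) {
        bad <- which(ok & r <= 0)[1]
        stop(sprintf(paste0("nonpositive jump rate at site (%s) along axis %d;",
                            " refine or shrink the lattice"),
                     paste(signif(sites[bad, ], 4), collapse = ", "), j))
      }
      from <- c(from, which(ok))
      to <- c(to, which(ok) + as.integer(s * stride))
      val <- c(val, r[ok])
    }
  }
  Woff <- Matrix::sparseMatrix(i = to, j = from, x = val, dims = c(S, S))
  # recover the (from, to) pairs in Woff@x slot order
  Woff_t <- methods::as(Woff, "TsparseMatrix")
  ord <- order(Woff_t@j, Woff_t@i)
  edges <- data.frame(from = Woff_t@j[ord] + 1L, to = Woff_t@i[ord] + 1L)
  exit <- Matrix::colSums(Woff)
  W <- Woff - Matrix::Diagonal(S, exit)
  structure(list(W = W, Woff = Woff, exit = as.numeric(exit), edges = edges,
                 lattice = lattice, sites = sites),
            class = "rate_matrix")
}

#' Wrap an arbitrary generator matrix as a rate matrix
#'
#' Builds the `rate_matrix` structure (off-diagonal rates, escape rates,
#' edge list) from a plain generator whose entry `[to, from]` is the
#' from->to rate and whose columns sum to zero. Useful for toy chains and
#' cycles that do not come from a lattice discretization.
#'
#' @param W square generator matrix (dense or sparse).
#' @param sites optional matrix of site coordinates (one row per site);
#'   defaults to the 1-D site index.
#' @return a `rate_matrix`.
#' @export
rate_matrix_from_generator <- function(W, sites = NULL) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  S <- nrow(W)
  if (is.null(sites)) sites <- matrix(seq_len(S), S, 1)
  Woff <- W
  Matrix::diag(Woff) <- 0
  Woff <- Matrix::drop0(Woff)
  if (any(Woff@x < 0)) stop("off-diagonal rates must be nonnegative")
  exit <- as.numeric(Matrix::colSums(Woff))
  Wt <- methods::as(Woff, "TsparseMatrix")
  ord <- order(Wt@j, Wt@i)
  edges <- data.frame(from = Wt@j[ord] + 1L, to = Wt@i[ord] + 1L)
  structure(list(W = Woff - Matrix::Diagonal(S, exit), Woff = Woff,
                 exit = exit, edges = edges, lattice = NULL,
                 sites = as.matrix(sites)),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("lattice generator: %d sites, %d directed edges\n",
              nrow(x$sites), nrow(x$edges)))
  invisible(x)
}

#' Stationary distribution of a lattice generator
#'
#' Right null vector of the generator (probability over sites), computed by
#' shift-inverted inverse iteration.
#'
#' @param rates a `rate_matrix`.
#' @param sigma positive spectral shift; must lie strictly inside the
#'   spectral gap (default 0.4 suits chains with relaxation rates >= 1).
#' @return probability vector over sites.
#' @export
stationary_distribution <- function(rates, sigma = 0.4) {
  stopifnot(inherits(rates, "rate_matrix"))
  S <- nrow(rates$sites)
  f <- Matrix::lu(rates$W - sigma * Matrix::Diagonal(S))
  v <- rep(1 / S, S)
  for (it in seq_len(100)) {
    v_new <- as.numeric(Matrix::solve(f, v))
    v_new <- v_new / sqrt(sum(v_new^2))
    if (sum(abs(abs(v_new) - abs(v))) < 1e-14) { v <- v_new; break }
    v <- v_new
  }
  v <- abs(v)
  v / sum(v)
}

#' Simulate the lattice jump process with the Gillespie algorithm
#'
#' Exact stochastic simulation: exponentially distributed waiting times with
#' each site's total escape rate, next site drawn proportionally to the
#' outgoing rates, truncated at `tau_obs`.
#'
#' @param rates a `rate_matrix`.
#' @param start_site 1-based starting site index; default samples from the
#'   stationary distribution restricted to the lattice.
#' @param tau_obs total simulated time (> 0).
#' @param seed integer RNG seed.
#' @param max_jumps safety cap on the number of jumps.
#' @return a `jump_trajectory`: `sites` (1-based indices, first entry is the
#'   start), `times` (entry times, starting at 0), `tau_obs`, `seed`.
#' @export
gillespie <- function(rates, start_site = NULL, tau_obs, seed = NULL,
                      max_jumps = 5e7) {
  stopifnot(inherits(rates, "rate_matrix"))
  if (tau_obs <= 0) stop("tau_obs must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_site)) {
    p <- stationary_distribution(rates)
    start_site <- sample.int(length(p), 1L, prob = p)
  }
  res <- cpp_gillespie(rates$Woff@p, rates$Woff@i, rates$Woff@x,
                       rates$exit, as.integer(start_site) - 1L,
                       tau_obs, max_jumps)
  structure(list(sites = res$sites + 1L, times = res$times,
                 tau_obs = tau_obs, seed = seed),
            class = "jump_trajectory")
}

#' @export
print.jump_trajectory <- function(x, ...) {
  cat(sprintf("jump trajectory: %d jumps over tau_obs = %g\n",
              length(x$sites) - 1L, x$tau_obs))
  invisible(x)
}

#' Occupation time per lattice site
#'
#' @param jumptraj a `jump_trajectory`.
#' @param n_sites total number of lattice sites.
#' @return vector of occupation times summing to `tau_obs`.
#' @export
occupation_times <- function(jumptraj, n_sites) {
  stopifnot(inherits(jumptraj, "jump_trajectory"))
  dwell <- diff(c(jumptraj$times, jumptraj$tau_obs))
  occ <- numeric(n_sites)
  agg <- rowsum(dwell, jumptraj$sites)
  occ[as.integer(rownames(agg))] <- agg[, 1]
  occ
}

#' Write or read a trajectory as delimited text
#'
#' Format: a header line then rows `t, x1, ..., xn` (tab-separated).
#'
#' @param traj a `trajectory`.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n <- ncol(traj$positions)
  tab <- data.frame(
    t = traj$t0 + traj$dt * (seq_len(nrow(traj$positions)) - 1L),
    traj$positions)
  names(tab) <- c("t", paste0("x", seq_len(n)))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory` returns a `trajectory`.
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (nrow(tab) < 2L) stop("trajectory file must contain at least 2 samples")
  dts <- diff(tab$t)
  if (max(abs(dts - dts[1])) > 1e-9 * max(abs(dts)))
    stop("trajectory samples are not uniformly spaced in time")
  new_trajectory(as.matrix(tab[, -1, drop = FALSE]), dts[1], t0 = tab$t[1])
}
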