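#' Generalized-current statistics from a Langevin trajectory
#'
#' Splits the trajectory into non-overlapping windows of length `window`
#' and, within each window `k`, accumulates the Stratonovich sum
#' `J_d^(k) = sum_i d((x_i + x_{i-1})/2) . (x_i - x_{i-1})`; the window's
#' current sample is `j_d^(k) = J_d^(k) / window`. The sample mean and
#' variance over windows feed the TUR bound.
#'
#' @param traj a `trajectory`.
#' @param d weight field: a function mapping a configuration matrix to
#'   covector rows, an `n x n` matrix `B` for the linear field `d(x) = B x`,
#'   a force-like `field_on_grid` (nearest-bin lookup), or a
#'   `gaussian_basis_field`.
#' @param window window length `Delta tau` (time units); must be at least
#'   two steps and at most half the observation time.
#' @return a `current_stats`: window samples, their `mean` and `var`,
#'   `window`, `n_windows`.
#' @export
accumulate_current <- function(traj, d, window) {
  stopifnot(inherits(traj, "trajectory"))
  win_steps <- round(window / traj$dt)
  if (win_steps < 1L) stop("window shorter than one timestep")
  n_steps <- nrow(traj$positions) - 1L
  if (n_steps %/% win_steps < 2L)
    stop("fewer than 2 complete windows: shorten the window or extend tau_obs")
  X <- traj$positions
  if (is.matrix(d) && !inherits(d, "field_on_grid")) {
    J <- cpp_accumulate_linear(X, d, as.integer(win_steps))
  } else {
    N <- nrow(X)
    mid <- (X[-1L, , drop = FALSE] + X[-N, , drop = FALSE]) / 2
    dx <- X[-1L, , drop = FALSE] - X[-N, , drop = FALSE]
    w <- if (inherits(d, "field_on_grid")) field_values_at(d, mid)$values
         else if (inherits(d, "gaussian_basis_field")) eval_weight_field(d, mid)
         else if (is.function(d)) d(mid)
         else stop("unsupported weight field representation")
    step_contrib <- rowSums(w * dx)
    k <- (seq_len(N - 1L) - 1L) %/% win_steps + 1L
    keep <- k <= n_steps %/% win_steps
    J <- as.numeric(rowsum(step_contrib[keep], k[keep]))
  }
  new_current_stats(J / (win_steps * traj$dt), win_steps * traj$dt)
}

new_current_stats <- function(samples, window) {
  structure(list(samples = samples, window = window,
                 n_windows = length(samples), mean = mean(samples),
                 var = stats::var(samples)),
            class = "current_stats")
}

#' @export
print.current_stats <- function(x, ...) {
  cat(sprintf(
    "current statistics: %d windows of length %g; mean %.5g, var %.5g\n",
    x$n_windows, x$window, x$mean, x$var))
  invisible(x)
}

#' Generalized-current statistics from a lattice jump trajectory
#'
#' Each jump contributes the edge weight `d_{to,from}` of the transition it
#' takes; windows of length `window` partition `[0, tau_obs]` by jump time.
#'
#' @param jumptraj a `jump_trajectory`.
#' @param weights an `edge_weights` object (see [discretize_weight_field()]).
#' @param window window length `Delta tau`.
#' @return a `current_stats`.
#' @export
accumulate_current_jump <- function(jumptraj, weights, window) {
  stopifnot(inherits(jumptraj, "jump_trajectory"),
            inherits(weights, "edge_weights"))
  n_win <- floor(jumptraj$tau_obs / window)
  if (n_win < 2L) stop("fewer than 2 complete windows")
  ns <- length(jumptraj$sites)
  if (ns < 2L) {
    return(new_current_stats(rep(0, n_win), window))
  }
  from <- jumptraj$sites[-ns]
  to <- jumptraj$sites[-1L]
  S <- weights$n_sites
  key <- (from - 1) + S * (to - 1)
  w <- weights$w[match(key, weights$key)]
  if (anyNA(w)) stop("jump along an edge with no weight entry")
  tj <- jumptraj$times[-1L]  # time of each jump
  k <- floor(tj / window) + 1L
  keep <- k <= n_win
  J <- numeric(n_win)
  agg <- rowsum(w[keep], k[keep])
  J[as.integer(rownames(agg))] <- agg[, 1]
  new_current_stats(J / window, window)
}

#' Discretize a weight field onto lattice edges
#'
#' Midpoint rule: the weight of the directed edge from site `x` to
#' neighbour `x + h` is `d((x + (x+h))/2) . h`. Antisymmetry
#' `d_{x,y} = -d_{y,x}` holds by construction for any single-valued field.
#'
#' @param d weight field in any representation accepted by
#'   [accumulate_current()] (function, linear matrix, grid field, or
#'   Gaussian basis field), or the string `"epr"` for the entropy-production
#'   log-ratio weight `ln(W_{yx} p_x / W_{xy} p_y)` built from the lattice
#'   stationary distribution.
#' @param rates a `rate_matrix` giving the edge set.
#' @return an `edge_weights` object: weights `w` aligned with
#'   `rates$Woff@x`, edge keys for jump lookup, and the edge list.
#' @export
discretize_weight_field <- function(d, rates) {
  stopifnot(inherits(rates, "rate_matrix"))
  from_xy <- rates$sites[rates$edges$from, , drop = FALSE]
  to_xy <- rates$sites[rates$edges$to, , drop = FALSE]
  if (identical(d, "epr")) {
    p <- stationary_distribution(rates)
    Wx <- rates$Woff@x
    # weight of edge (from -> to): log of forward/backward flux ratio
    rev_key <- (rates$edges$to - 1) + nrow(rates$sites) * (rates$edges$from - 1)
    fwd_key <- (rates$edges$from - 1) + nrow(rates$sites) * (rates$edges$to - 1)
    wrev <- Wx[match(rev_key, fwd_key)]
    w <- log((Wx * p[rates$edges$from]) / (wrev * p[rates$edges$to]))
  } else {
    mid <- (from_xy + to_xy) / 2
    h <- to_xy - from_xy
    dv <- if (is.matrix(d) && !inherits(d, "field_on_grid")) mid %*% t(d)
          else if (inherits(d, "field_on_grid")) field_values_at(d, mid)$values
          else if (inherits(d, "gaussian_basis_field")) eval_weight_field(d, mid)
          else if (is.function(d)) d(mid)
          else stop("unsupported weight field representation")
    w <- rowSums(dv * h)
  }
  S <- nrow(rates$sites)
  structure(list(w = as.numeric(w),
                 key = (rates$edges$from - 1) + S * (rates$edges$to - 1),
                 edges = rates$edges, n_sites = S),
            class = "edge_weights")
}

#' TUR lower bound on the entropy production rate
#'
#' `S_TUR = 2 k_B mean(j_d)^2 / (window * var(j_d))` from windowed current
#' samples (with `k_B = 1`). Valid for any weight field; invariant under
#' rescaling the weights.
#'
#' @param stats a `current_stats`.
#' @return a `tur_bound` object with elements `value`, `mean`, `var`,
#'   `window`, `provenance = "sampled"`.
#' @export
tur_bound <- function(stats) {
  stopifnot(inherits(stats, "current_stats"))
  if (!is.finite(stats$var) || stats$var <= 0)
    stop("degenerate current: zero variance across windows")
  structure(list(value = 2 * stats$mean^2 / (stats$window * stats$var),
                 mean = stats$mean, var = stats$var, window = stats$window,
                 provenance = "sampled"),
            class = "tur_bound")
}

#' @export
print.tur_bound <- function(x, ...) {
  cat(sprintf("TUR bound (%s): S_dot >= %.6g (k_B/time)\n",
              x$provenance, x$value))
  invisible(x)
}
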