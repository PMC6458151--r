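#' Estimation grid
#'
#' Rectangular grid of bins used by the field estimators (default: the
#' 100 x 100 grid on `[-50, 50] x [-20, 20]` used throughout the two-bead
#' examples). Structurally identical to a [lattice_spec()]: bins are cells,
#' values live at cell centers.
#'
#' @inheritParams lattice_spec
#' @return a `lattice_spec`.
#' @export
grid_spec <- function(lower = c(-50, -20), upper = c(50, 20),
                      counts = c(100, 100)) {
  lattice_spec(lower, upper, counts)
}

bin_volume <- function(grid) prod(grid$h)
n_bins <- function(grid) prod(grid$counts)

#' Kernel configuration for field estimation
#'
#' @param density_kernel kernel `K` for the density: `"histogram"` (bin
#'   indicator) or `"gaussian"` (product Gaussian with exponent
#'   `-(x - x_i)' Sigma^{-1} (x - x_i)`, `Sigma_jj = b_j^2`).
#' @param current_kernel kernel `L` for the local mean velocity:
#'   `"histogram"` or `"epanechnikov"` (product kernel
#'   `prod_j (1 - (x_j - x_{i;j})^2 / b_j^2)` on `|x_j - x_{i;j}| < b_j`).
#' @param bandwidth per-dimension bandwidth vector `b` (required for smooth
#'   kernels; defaults to [bandwidth_rule()] at estimation time).
#' @return a `kernel_config`.
#' @export
kernel_config <- function(density_kernel = c("histogram", "gaussian"),
                          current_kernel = c("histogram", "epanechnikov"),
                          bandwidth = NULL) {
  density_kernel <- match.arg(density_kernel)
  current_kernel <- match.arg(current_kernel)
  if (!is.null(bandwidth) && any(bandwidth <= 0))
    stop("bandwidths must be positive")
  structure(list(density_kernel = density_kernel,
                 current_kernel = current_kernel, bandwidth = bandwidth),
            class = "kernel_config")
}

#' Rule-of-thumb kernel bandwidth
#'
#' Bowman-Azzalini style rule `b = (4 / (N (d + 2)))^{1/(d+4)} *
#' sigma_tilde / 0.6745`, returned per dimension. Two robust scales are
#' offered: `"velocity_position"` takes `sigma_tilde_j` as the geometric
#' mean of the median absolute deviation (MAD) of the speeds
#' `|x_{i+1} - x_i| / dt` and the MAD of the `j`-th position coordinate;
#' `"positions"` uses the per-coordinate position MAD alone. Both scales
#' shrink as `N^{-1/(d+4)}`.
#'
#' @param traj a `trajectory` with at least 10 samples.
#' @param scale which robust scale to use.
#' @return numeric bandwidth vector, one entry per dimension.
#' @export
bandwidth_rule <- function(traj, scale = c("velocity_position", "positions")) {
  stopifnot(inherits(traj, "trajectory"))
  scale <- match.arg(scale)
  X <- traj$positions
  N <- nrow(X)
  if (N < 10L) stop("trajectory too short for a bandwidth rule (N < 10)")
  d <- ncol(X)
  mad0 <- function(z) stats::median(abs(z - stats::median(z)))
  sig_x <- apply(X, 2, mad0)
  if (any(sig_x == 0))
    stop("degenerate (constant) coordinate: zero robust scale")
  sig <- if (scale == "positions") {
    sig_x
  } else {
    v <- sqrt(rowSums(diff(X)^2)) / traj$dt
    sqrt(mad0(v) * sig_x)
  }
  (4 / (N * (d + 2)))^(1 / (d + 4)) * sig / 0.6745
}

# Internal constructor for fields sampled on a grid. `values`: vector
# (scalar field) or matrix with one row per stored bin (vector field).
# `bins = NULL` means dense storage over all prod(counts) bins in linear
# order; otherwise `bins` holds the linear indices of the stored bins.
new_field <- function(grid, kind, values, bins = NULL, counts = NULL,
                      estimated = NULL, n_samples = NULL) {
  structure(list(grid = grid, kind = kind, values = values, bins = bins,
                 counts = counts, estimated = estimated,
                 n_samples = n_samples),
            class = "field_on_grid")
}

#' @export
print.field_on_grid <- function(x, ...) {
  stored <- if (is.null(x$bins)) n_bins(x$grid) else length(x$bins)
  cat(sprintf("%s field on %s grid (%d stored bins%s)\n", x$kind,
              paste(x$grid$counts, collapse = " x "), stored,
              if (is.null(x$bins)) ", dense" else ", sparse"))
  invisible(x)
}

# Row lookup of field values at configurations: nearest-bin (the bin the
# point falls in). Returns list(values = matrix, ok = logical).
field_values_at <- function(field, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  idx <- site_index(field$grid, x)
  rows <- if (is.null(field$bins)) idx else match(idx, field$bins)
  vals <- as.matrix(field$values)
  ok <- !is.na(rows)
  if (!is.null(field$estimated)) ok[ok] <- field$estimated[rows[ok]]
  out <- matrix(0, nrow(x), ncol(vals))
  out[ok, ] <- vals[rows[ok], , drop = FALSE]
  list(values = out, ok = ok)
}

#' Evaluate an analytic field on a grid
#'
#' Convenience for plugging exact densities/currents/forces into the
#' estimator pipeline (e.g. to isolate quadrature error).
#'
#' @param grid a grid from [grid_spec()].
#' @param fun function mapping a configuration matrix to values.
#' @param kind one of `"density"`, `"current"`, `"force"`.
#' @return a dense `field_on_grid`.
#' @export
field_from_function <- function(grid, fun, kind) {
  vals <- fun(lattice_sites(grid))
  new_field(grid, kind, vals,
            estimated = rep(TRUE, n_bins(grid)))
}

# --- binned evaluation of separable smooth kernels -------------------------
# For long trajectories with wide kernels, the exact per-point sums are
# O(N * window); the standard alternative bins the data onto the grid first
# and convolves the bin totals with the kernel sampled at center-to-center
# offsets (error O((h/b)^2), negligible when b >> h). Kernels are separable,
# so the convolution is a pair of 1-D passes.

kernel_taps <- function(b, h, type) {
  reach <- if (type == "gaussian") 6 * b else b
  m <- floor(reach / h)
  u <- (seq(-m, m) * h) / b
  k <- if (type == "gaussian") exp(-u^2) / (b * sqrt(pi)) else
    pmax(0, 1 - u^2) * 0.75 / b
  k
}

# zero-padded 1-D convolution of each column of `mat` with centered taps
conv_cols <- function(mat, taps) {
  m <- (length(taps) - 1L) %/% 2L
  nr <- nrow(mat)
  out <- matrix(0, nr, ncol(mat))
  for (t in seq_along(taps)) {
    off <- t - 1L - m
    src <- seq_len(nr) + off
    ok <- src >= 1L & src <= nr
    out[ok, ] <- out[ok, ] + taps[t] * mat[src[ok], , drop = FALSE]
  }
  out
}

sep_conv2 <- function(mat, taps1, taps2) {
  t(conv_cols(t(conv_cols(mat, taps1)), taps2))
}

# per-bin totals of `weights` (default: counts) over a 2-D grid
bin_totals <- function(grid, idx, weights = NULL) {
  G <- n_bins(grid)
  if (is.null(weights)) {
    v <- tabulate(as.integer(idx[!is.na(idx)]), nbins = G)
  } else {
    v <- numeric(G)
    agg <- rowsum(weights[!is.na(idx)], idx[!is.na(idx)])
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  matrix(v, grid$counts[1], grid$counts[2])
}

binned_kernel_cost <- function(grid, b, type, N) {
  reach <- if (type == "gaussian") 6 * b else b
  N * prod(pmin(2 * reach / grid$h + 1, grid$counts))
}

# keep only in-grid central-difference triples (point i with both neighbours)
central_differences <- function(traj) {
  X <- traj$positions
  N <- nrow(X)
  if (N < 3L) stop("trajectory too short for current estimation (N < 3)")
  list(points = X[2:(N - 1L), , drop = FALSE],
       disp = X[3:N, , drop = FALSE] - X[1:(N - 2L), , drop = FALSE])
}

#' Estimate the steady-state density from a trajectory
#'
#' Empirical density `rho_hat(x) = (dt / tau_obs) sum_i K(x_i, x)` evaluated
#' at bin centers. The histogram kernel gives bin occupation fractions
#' normalized by bin volume (masses sum to one exactly); the Gaussian kernel
#' gives the smooth kernel density estimate evaluated exactly at the
#' centers. Grids with more than `sparse_threshold` bins are stored
#' sparsely (occupied bins only; histogram kernel required).
#'
#' For smooth kernels, `method = "exact"` evaluates the kernel sums at the
#' bin centers exactly (O(N x kernel window)); `method = "binned"` bins the
#' samples first and convolves the bin totals with the kernel (standard
#' binned kernel estimate, error O((h/b)^2)); `"auto"` picks `"binned"`
#' when the exact cost is prohibitive and the bandwidth is wide enough.
#'
#' @param traj a `trajectory`.
#' @param grid estimation grid.
#' @param config a [kernel_config()].
#' @param sparse_threshold bin count above which sparse storage is used.
#' @param method smooth-kernel evaluation: `"auto"`, `"exact"`, `"binned"`.
#' @return a `field_on_grid` of kind `"density"` with per-bin sample counts.
#' @export
estimate_density <- function(traj, grid, config = kernel_config(),
                             sparse_threshold = 1e6,
                             method = c("auto", "exact", "binned")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "trajectory"))
  X <- traj$positions
  N <- nrow(X)
  G <- n_bins(grid)
  idx <- site_index(grid, X)
  inside <- sum(!is.na(idx))
  if (inside == 0L) stop("no trajectory samples fall inside the grid")
  if (config$density_kernel == "histogram") {
    if (G <= sparse_threshold) {
      cnt <- tabulate(as.integer(idx[!is.na(idx)]), nbins = G)
      vals <- cnt / (N * bin_volume(grid))
      return(new_field(grid, "density", vals, counts = cnt,
                       n_samples = N))
    }
    agg <- rowsum(rep(1, inside), idx[!is.na(idx)])
    bins <- as.numeric(rownames(agg))
    cnt <- unname(agg[, 1])
    return(new_field(grid, "density", cnt / (N * bin_volume(grid)),
                     bins = bins, counts = cnt, n_samples = N))
  }
  if (G > sparse_threshold)
    stop("smooth kernels require a dense grid (too many bins)")
  b <- config$bandwidth
  if (is.null(b)) b <- bandwidth_rule(traj)
  cnt <- tabulate(as.integer(idx[!is.na(idx)]), nbins = G)
  if (method == "auto")
    method <- if (length(grid$counts) == 2L && all(b >= 2 * grid$h) &&
                    binned_kernel_cost(grid, b, "gaussian", N) > 2e8)
      "binned" else "exact"
  if (method == "binned") {
    if (length(grid$counts) != 2L)
      stop("binned kernel evaluation is implemented for 2-D grids")
    ksum <- sep_conv2(matrix(cnt, grid$counts[1], grid$counts[2]),
                      kernel_taps(b[1], grid$h[1], "gaussian"),
                      kernel_taps(b[2], grid$h[2], "gaussian"))
    ksum <- as.numeric(ksum)
  } else {
    ksum <- cpp_kernel_density_grid(X, grid$lower, grid$h, grid$counts, b, 0L)
  }
  new_field(grid, "density", ksum / N, counts = cnt, n_samples = N)
}

#' Estimate the steady-state current from a trajectory
#'
#' Kernel regression of central-difference displacements: at bin center `x`,
#' `j_hat(x) = rho_hat(x) / (2 dt) * sum_i L(x_i, x) [x_{i+1} - x_{i-1}] /
#' sum_i L(x_i, x)`. Bins never visited by the kernel get zero current.
#'
#' @inheritParams estimate_density
#' @param density optional precomputed density field on the same grid; by
#'   default it is estimated with the density kernel of `config`.
#' @inheritParams estimate_density
#' @return a `field_on_grid` of kind `"current"`.
#' @export
estimate_current <- function(traj, grid, config = kernel_config(),
                             density = NULL, sparse_threshold = 1e6,
                             method = c("auto", "exact", "binned")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(density))
    density <- estimate_density(traj, grid, config, sparse_threshold, method)
  cd <- central_differences(traj)
  G <- n_bins(grid)
  d <- ncol(cd$points)
  if (config$current_kernel == "histogram") {
    idx <- site_index(grid, cd$points)
    keep <- !is.na(idx)
    if (!any(keep)) stop("no trajectory samples fall inside the grid")
    agg_d <- unname(rowsum(cd$disp[keep, , drop = FALSE], idx[keep]))
    agg_n <- rowsum(rep(1, sum(keep)), idx[keep])
    bins <- as.numeric(rownames(agg_n))
    meanv <- agg_d / agg_n[, 1]
    if (is.null(density$bins)) {
      vals <- matrix(0, G, d)
      rho <- density$values
      vals[bins, ] <- meanv * rho[bins] / (2 * traj$dt)
      return(new_field(grid, "current", vals, counts = density$counts,
                       n_samples = density$n_samples))
    }
    rho <- density$values[match(bins, density$bins)]
    rho[is.na(rho)] <- 0
    return(new_field(grid, "current", meanv * rho / (2 * traj$dt),
                     bins = bins,
                     counts = density$counts[match(bins, density$bins)],
                     n_samples = density$n_samples))
  }
  if (G > sparse_threshold)
    stop("smooth kernels require a dense grid (too many bins)")
  b <- config$bandwidth
  if (is.null(b)) b <- bandwidth_rule(traj)
  if (method == "auto")
    method <- if (length(grid$counts) == 2L && all(b >= 2 * grid$h) &&
                    binned_kernel_cost(grid, b, "epanechnikov",
                                       nrow(cd$points)) > 2e8)
      "binned" else "exact"
  if (method == "binned") {
    if (length(grid$counts) != 2L)
      stop("binned kernel evaluation is implemented for 2-D grids")
    idx_cd <- site_index(grid, cd$points)
    t1 <- kernel_taps(b[1], grid$h[1], "epanechnikov")
    t2 <- kernel_taps(b[2], grid$h[2], "epanechnikov")
    w <- as.numeric(sep_conv2(bin_totals(grid, idx_cd), t1, t2))
    meanv <- vapply(seq_len(d), function(j)
      as.numeric(sep_conv2(bin_totals(grid, idx_cd, cd$disp[, j]), t1, t2)),
      numeric(G))
  } else {
    reg <- cpp_kernel_current_grid(cd$points, cd$disp, grid$lower, grid$h,
                                   grid$counts, b, 1L)
    meanv <- reg$vsum
    w <- reg$wsum
  }
  nz <- w > 0
  meanv[nz, ] <- meanv[nz, , drop = FALSE] / w[nz]
  meanv[!nz, ] <- 0
  rho <- if (is.null(density$bins)) density$values else {
    rr <- numeric(G); rr[density$bins] <- density$values; rr
  }
  new_field(grid, "current", meanv * rho / (2 * traj$dt),
            counts = density$counts, n_samples = density$n_samples)
}

#' Estimate the thermodynamic force field
#'
#' Plug-in estimator `F_hat(x) = j_hat(x)' D^{-1} / rho_hat(x)` (with
#' `k_B = 1`). Bins with fewer than `min_samples` samples (or zero density)
#' are flagged unestimated and contribute zero to downstream sums.
#'
#' @param density,current matching `field_on_grid` estimates.
#' @param model the `bead_spring_model` supplying the diffusion tensor `D`.
#' @param min_samples occupation floor below which a bin is flagged.
#' @return a `field_on_grid` of kind `"force"` with an `estimated` flag.
#' @export
estimate_force <- function(density, current, model, min_samples = 5) {
  stopifnot(inherits(density, "field_on_grid"),
            inherits(current, "field_on_grid"),
            identical(density$grid$counts, current$grid$counts))
  Dinv <- solve(model$D)
  if (!is.null(current$bins) || !is.null(density$bins)) {
    if (is.null(current$bins) || is.null(density$bins))
      stop("density and current must share a storage layout")
    rows <- match(current$bins, density$bins)
    rho <- density$values[rows]
    cnt <- density$counts[rows]
  } else {
    rho <- density$values
    cnt <- if (!is.null(density$counts)) density$counts
           else if (!is.null(density$n_samples))
             rho * bin_volume(density$grid) * density$n_samples
           else Inf  # analytic plug-in fields: no occupation floor
  }
  est <- !is.na(rho) & rho > 0 & !is.na(cnt) & cnt >= min_samples
  jmat <- as.matrix(current$values)
  fvals <- matrix(0, nrow(jmat), ncol(jmat))
  fvals[est, ] <- (jmat[est, , drop = FALSE] %*% Dinv) / rho[est]
  new_field(current$grid, "force", fvals, bins = current$bins,
            counts = cnt, estimated = est, n_samples = density$n_samples)
}

#' Write or read a field as delimited text
#'
#' Format: header then one row per stored bin: the bin center coordinates
#' followed by the field value component(s).
#'
#' @param field a `field_on_grid`.
#' @param path file path.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_on_grid"))
  sites <- lattice_sites(field$grid)
  bins <- if (is.null(field$bins)) seq_len(nrow(sites)) else field$bins
  vals <- as.matrix(field$values)
  tab <- data.frame(bin = bins, sites[bins, , drop = FALSE], vals)
  names(tab) <- c("bin", paste0("x", seq_len(ncol(sites))),
                  paste0("v", seq_len(ncol(vals))))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @param grid the grid the field was written from.
#' @param kind field kind for the reconstructed object.
#' @export
read_field <- function(path, grid, kind = "density") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  d <- length(grid$counts)
  vals <- as.matrix(tab[, -(seq_len(d + 1L)), drop = FALSE])
  if (ncol(vals) == 1L) vals <- as.numeric(vals)
  if (nrow(tab) == n_bins(grid) && all(tab$bin == seq_len(n_bins(grid))))
    new_field(grid, kind, vals)
  else
    new_field(grid, kind, vals, bins = tab$bin)
}
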