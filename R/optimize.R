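#' Gaussian-basis current weighting field
#'
#' A weight field `d(x)` expanded over `M` Gaussian envelopes,
#' `d(x) = base(x) + sum_i w^(i) exp[-(x - x^(i))' B^{-1} (x - x^(i))]`,
#' where each free Gaussian carries one weight per vector component (so the
#' expansion reduces to the scalar formula componentwise). Only the first
#' `M/2` Gaussians are free: each is paired with a mirror Gaussian at
#' `-x^(i)` carrying weight `-w^(i)`, which enforces the antisymmetry
#' `d(-x) = -d(x)` exactly (the optional base field, a linear map, is
#' antisymmetric by construction).
#'
#' @param centers free Gaussian centers, `(M/2) x n` matrix.
#' @param weights free weights, `(M/2) x n` matrix (component per column).
#' @param breadth per-axis squared breadths `B_jj` (length n).
#' @param base optional `n x n` matrix `B0` adding the linear base field
#'   `B0 x` (used for sampling about the thermodynamic force).
#' @return a `gaussian_basis_field`.
#' @export
gaussian_basis_field <- function(centers, weights, breadth, base = NULL) {
  centers <- as.matrix(centers)
  weights <- as.matrix(weights)
  stopifnot(nrow(centers) == nrow(weights),
            ncol(centers) == ncol(weights),
            length(breadth) == ncol(centers), all(breadth > 0))
  structure(list(centers = centers, weights = weights,
                 breadth = as.numeric(breadth), base = base,
                 M = 2L * nrow(centers), n = ncol(centers)),
            class = "gaussian_basis_field")
}

#' @export
print.gaussian_basis_field <- function(x, ...) {
  cat(sprintf("gaussian-basis weight field: M = %d (%d free pairs), dim %d%s\n",
              x$M, nrow(x$centers), x$n,
              if (is.null(x$base)) "" else ", linear base field"))
  invisible(x)
}

# Gaussian envelopes of the free centers evaluated at configurations:
# G[p, i] = exp(-sum_j (x[p,j] - centers[i,j])^2 / breadth[j])
gauss_envelopes <- function(centers, breadth, x) {
  G <- matrix(0, nrow(x), nrow(centers))
  for (i in seq_len(nrow(centers))) {
    q <- rowSums(sweep(x, 2, centers[i, ], "-")^2 /
                   rep(breadth, each = nrow(x)))
    G[, i] <- exp(-q)
  }
  G
}

#' Evaluate a Gaussian-basis weight field
#'
#' @param field a `gaussian_basis_field`.
#' @param x configuration matrix (one row per point) or single vector.
#' @return matrix of covector rows `d(x)`.
#' @export
eval_weight_field <- function(field, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  Gp <- gauss_envelopes(field$centers, field$breadth, x)
  Gm <- gauss_envelopes(-field$centers, field$breadth, x)
  out <- (Gp - Gm) %*% field$weights
  if (!is.null(field$base)) out <- out + x %*% t(field$base)
  out
}

#' Initialize a weight field for Monte Carlo optimization
#'
#' `M/2` free centers are drawn uniformly over the lattice box, mirrored to
#' enforce antisymmetry; per-axis breadths are `(0.1 * box length)^2`. In
#' `"random"` mode the free weights start uniform on `[-1, 1]`; in
#' `"around_force"` mode they start at zero and the thermodynamic force is
#' the base field, so the initial field is exactly `d = F`.
#'
#' @param mode `"random"` or `"around_force"`.
#' @param model a `bead_spring_model` (needed for `"around_force"`).
#' @param lattice the `lattice_spec` whose box bounds the centers.
#' @param M total number of Gaussians (even; default 100).
#' @param seed integer seed.
#' @return a `gaussian_basis_field`.
#' @export
init_field <- function(mode = c("random", "around_force"), model = NULL,
                       lattice, M = 100L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(lattice, "lattice_spec"))
  if (M %% 2L != 0L || M < 2L) stop("M must be a positive even integer")
  if (!is.null(seed)) set.seed(seed)
  n <- length(lattice$counts)
  half <- M %/% 2L
  centers <- sapply(seq_len(n), function(j)
    stats::runif(half, lattice$lower[j], lattice$upper[j]))
  centers <- matrix(centers, half, n)
  breadth <- (0.1 * (lattice$upper - lattice$lower))^2
  if (mode == "random") {
    w <- matrix(stats::runif(half * n, -1, 1), half, n)
    gaussian_basis_field(centers, w, breadth)
  } else {
    if (is.null(model)) stop("around_force mode requires the model")
    B0 <- force_matrix(steady_state(model))
    gaussian_basis_field(centers, matrix(0, half, n), breadth, base = B0)
  }
}

# Precomputed edge discretization of a gaussian basis field on a lattice:
# edge weight_e = base_e + s_e * h_{axis(e)} * (Gdiff[e, ] %*% w[, axis(e)])
edge_basis <- function(field, rates) {
  from_xy <- rates$sites[rates$edges$from, , drop = FALSE]
  to_xy <- rates$sites[rates$edges$to, , drop = FALSE]
  mid <- (from_xy + to_xy) / 2
  hmat <- to_xy - from_xy
  axis <- max.col(abs(hmat))
  hval <- hmat[cbind(seq_len(nrow(hmat)), axis)]
  Gdiff <- gauss_envelopes(field$centers, field$breadth, mid) -
    gauss_envelopes(-field$centers, field$breadth, mid)
  base_w <- if (is.null(field$base)) numeric(nrow(mid)) else
    rowSums((mid %*% t(field$base)) * hmat)
  list(Gdiff = Gdiff, axis = axis, hval = hval, base_w = base_w)
}

edge_weights_from_basis <- function(eb, w, rates) {
  wedge <- eb$base_w
  for (j in sort(unique(eb$axis))) {
    sel <- eb$axis == j
    wedge[sel] <- wedge[sel] +
      eb$hval[sel] * as.numeric(eb$Gdiff[sel, , drop = FALSE] %*% w[, j])
  }
  S <- nrow(rates$sites)
  structure(list(w = wedge,
                 key = (rates$edges$from - 1) + S * (rates$edges$to - 1),
                 edges = rates$edges, n_sites = S),
            class = "edge_weights")
}

#' Metropolis Monte Carlo optimization of the TUR ratio
#'
#' Random walk over the free weights of a Gaussian-basis field: at each
#' step every free weight is perturbed by a uniform increment of half-width
#' `proposal_width` (mirrored partners follow automatically), the field is
#' discretized onto the lattice edges, the exact TUR ratio
#' `2 phi'(0)^2 / phi''(0)` is computed from the tilted-operator cumulants,
#' and the move is accepted with probability
#' `min[1, exp(-beta (S_old - S_new))]` - i.e. moves that increase the
#' bound are always accepted. Ratios are always evaluated from exact
#' lattice cumulants, never from a single sampled trajectory, so the search
#' cannot over-optimize to sampling noise. `beta = Inf` gives greedy
#' hill-climbing.
#'
#' @param rates a `rate_matrix`.
#' @param field initial `gaussian_basis_field` (see [init_field()]).
#' @param beta inverse temperature of the acceptance rule.
#' @param n_steps number of proposals.
#' @param proposal_width uniform half-width of the weight perturbations;
#'   defaults to 0.05 when a base field is present (sampling about `F`) and
#'   0.5 otherwise.
#' @param seed integer seed.
#' @param dlambda,sigma passed to the cumulant computation.
#' @return an `mc_trace`: per-step data frame (`step`, `ratio`, `accepted`,
#'   `best`), the best field and ratio, and the run settings.
#' @export
mc_optimize <- function(rates, field, beta = 5000, n_steps = 500L,
                        proposal_width = NULL, seed = NULL,
                        dlambda = 1e-5, sigma = 0.4) {
  stopifnot(inherits(rates, "rate_matrix"),
            inherits(field, "gaussian_basis_field"))
  if (is.null(proposal_width))
    proposal_width <- if (is.null(field$base)) 0.5 else 0.05
  if (!is.null(seed)) set.seed(seed)
  eb <- edge_basis(field, rates)
  ratio_of <- function(w) {
    ew <- edge_weights_from_basis(eb, w, rates)
    tryCatch(exact_tur_ratio(rates, ew, dlambda = dlambda,
                             sigma = sigma)$value,
             error = function(e) NA_real_)
  }
  w <- field$weights
  cur <- ratio_of(w)
  if (!is.finite(cur)) stop("initial field yields a non-finite TUR ratio")
  best <- cur
  best_w <- w
  step_id <- integer(n_steps); ratios <- numeric(n_steps)
  accepted <- logical(n_steps); best_tr <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    prop <- w + matrix(stats::runif(length(w), -proposal_width,
                                    proposal_width), nrow(w), ncol(w))
    val <- ratio_of(prop)
    acc <- FALSE
    if (is.finite(val)) {
      acc <- if (is.infinite(beta)) val >= cur else
        stats::runif(1) < exp(pmin(0, -beta * (cur - val)))
      # (runif is always consumed at finite beta to keep the walk seeded
      #  deterministically)
      if (acc) { w <- prop; cur <- val }
      if (cur > best) { best <- cur; best_w <- w }
    }
    step_id[s] <- s; ratios[s] <- cur; accepted[s] <- acc; best_tr[s] <- best
  }
  best_field <- gaussian_basis_field(field$centers, best_w, field$breadth,
                                     base = field$base)
  structure(list(trace = data.frame(step = step_id, ratio = ratios,
                                    accepted = accepted, best = best_tr),
                 best_field = best_field, best_ratio = best,
                 acceptance_rate = mean(accepted), beta = beta,
                 proposal_width = proposal_width, seed = seed),
            class = "mc_trace")
}

#' @export
print.mc_trace <- function(x, ...) {
  cat(sprintf(
    "MC optimization: %d steps, best TUR ratio %.6g, acceptance %.1f%%\n",
    nrow(x$trace), x$best_ratio, 100 * x$acceptance_rate))
  invisible(x)
}
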