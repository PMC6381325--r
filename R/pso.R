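#' Particle swarm optimization (minimization)
#'
#' Canonical inertia-weight PSO: each particle keeps a position and velocity
#' in the bounded search box; velocities are updated with inertia, cognitive
#' (personal-best) and social (global-best) terms, clamped per dimension to a
#' fraction of the box width, and positions are clamped to the bounds.
#' Deterministic given the seed. The global-best objective trace is recorded
#' per iteration and is non-increasing by construction.
#'
#' @param fn objective to minimize; called with a numeric parameter vector.
#' @param lower,upper box bounds (finite, equal length).
#' @param n_particles number of particles (>= 1).
#' @param n_iter number of velocity/position update iterations (>= 1).
#' @param seed RNG seed.
#' @param init optional matrix of initial positions (particles x dims);
#'   remaining particles are drawn uniformly in the box.
#' @param inertia,cognitive,social velocity-update coefficients (defaults
#'   0.72 / 1.49 / 1.49, the canonical constriction values).
#' @param v_clamp velocity clamp as a fraction of the box width.
#' @return list with \code{par}, \code{value}, \code{trace} (global best
#'   after initialization and after each iteration) and \code{n_evals}.
#' @export
psoOptimize <- function(fn, lower, upper, n_particles = 20, n_iter = 20,
                        seed = 1, init = NULL, inertia = 0.72,
                        cognitive = 1.49, social = 1.49, v_clamp = 0.2) {
  stopifnot(length(lower) == length(upper), all(is.finite(c(lower, upper))),
            all(upper >= lower), n_particles >= 1, n_iter >= 1)
  d <- length(lower)
  set.seed(seed)
  X <- matrix(stats::runif(n_particles * d, rep(lower, each = n_particles),
                           rep(upper, each = n_particles)), n_particles, d)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    nseed <- min(nrow(init), n_particles)
    X[seq_len(nseed), ] <- init[seq_len(nseed), , drop = FALSE]
  }
  width <- upper - lower
  vmax <- v_clamp * width
  V <- matrix(stats::runif(n_particles * d, -1, 1), n_particles, d) *
    rep(vmax, each = n_particles)
  evalf <- function(x) {
    val <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }
  pbest <- X
  pval <- apply(X, 1L, evalf)
  gi <- which.min(pval)
  gbest <- X[gi, ]; gval <- pval[gi]
  trace <- gval
  n_evals <- n_particles
  for (it in seq_len(n_iter)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    V <- inertia * V + cognitive * r1 * (pbest - X) +
      social * r2 * (matrix(gbest, n_particles, d, byrow = TRUE) - X)
    V <- pmin(pmax(V, rep(-vmax, each = n_particles)),
              rep(vmax, each = n_particles))
    X <- X + V
    X <- pmin(pmax(X, rep(lower, each = n_particles)),
              rep(upper, each = n_particles))
    vals <- apply(X, 1L, evalf)
    n_evals <- n_evals + n_particles
    better <- vals < pval
    pbest[better, ] <- X[better, , drop = FALSE]
    pval[better] <- vals[better]
    gi <- which.min(pval)
    if (pval[gi] < gval) { gbest <- pbest[gi, ]; gval <- pval[gi] }
    trace <- c(trace, gval)
  }
  list(par = gbest, value = gval, trace = trace, n_evals = n_evals)
}
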