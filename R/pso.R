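#' Particle swarm control parameters
#'
#' Settings for the bound-constrained adaptive particle swarm used to
#' minimise the grid cost. The defaults follow the standard adaptive-PSO
#' contract: inertia adapted within \code{inertia_range} (doubled after
#' consecutive improvements, halved after persistent stagnation), cognitive
#' and social coefficients 1.49, random dynamic neighborhoods of at least
#' \code{min_neighborhood_fraction * K} particles that grow while the best
#' cost stalls, and termination when the best cost improves by no more than
#' \code{tolerance} for \code{stall_iterations} consecutive iterations.
#'
#' @param swarm_density number of particles per optimised coordinate
#'   (\code{K = round(swarm_density * N)}); densities of 6-12 work well.
#' @param tolerance stopping tolerance on the change in best cost.
#' @param stall_iterations consecutive low-improvement iterations required
#'   to stop.
#' @param max_iterations iteration cap; default \code{200 * N}.
#' @param inertia_range adaptive inertia bounds.
#' @param cognitive_coeff,social_coeff attraction to the personal and the
#'   neighborhood best.
#' @param min_neighborhood_fraction minimum fraction of the swarm in each
#'   particle's (random, per-iteration) neighborhood.
#' @param seed optional RNG seed set at the start of the optimisation for a
#'   fully reproducible run.
#' @return A list of class \code{pso_control}.
#' @export
pso_control <- function(swarm_density = 8,
                        tolerance = 1e-4,
                        stall_iterations = 20L,
                        max_iterations = NULL,
                        inertia_range = c(0.1, 1.1),
                        cognitive_coeff = 1.49,
                        social_coeff = 1.49,
                        min_neighborhood_fraction = 0.25,
                        seed = NULL) {
  stopifnot(swarm_density > 0, tolerance > 0, stall_iterations >= 1,
            cognitive_coeff > 0 || cognitive_coeff == 0,
            social_coeff > 0 || social_coeff == 0,
            min_neighborhood_fraction > 0, min_neighborhood_fraction <= 1,
            length(inertia_range) == 2L, inertia_range[1] <= inertia_range[2])
  structure(list(swarm_density = swarm_density,
                 tolerance = tolerance,
                 stall_iterations = as.integer(stall_iterations),
                 max_iterations = max_iterations,
                 inertia_range = inertia_range,
                 cognitive_coeff = cognitive_coeff,
                 social_coeff = social_coeff,
                 min_neighborhood_fraction = min_neighborhood_fraction,
                 seed = seed),
            class = "pso_control")
}

#' Initialise a swarm
#'
#' Creates \code{K = round(swarm_density * n)} particles. All but one are
#' positioned i.i.d. uniformly inside the per-coordinate bounds; one "null"
#' particle sits at the zero vector, i.e. the unmodified uniform grid, so
#' the search can never end worse than its starting layout. Initial
#' velocities are uniform within the bound span per coordinate.
#'
#' @param n number of coordinates (for a P x Q grid, \code{n = 2*P*Q}).
#' @param bounds non-negative vector (recycled to length \code{n}) of
#'   symmetric per-coordinate bounds: coordinate i lives in
#'   \code{[-bounds[i], bounds[i]]}.
#' @param control a \code{\link{pso_control}}.
#' @return A list of class \code{pso_swarm}; costs are unset until the
#'   first \code{\link{pso_step}}.
#' @export
pso_init_swarm <- function(n, bounds, control = pso_control()) {
  if (n < 1) stop("need at least one coordinate")
  b <- rep_len(as.numeric(bounds), n)
  if (any(b < 0)) stop("bounds must be non-negative")
  K <- as.integer(round(control$swarm_density * n))
  if (K < 2) stop("swarm would have fewer than 2 particles; raise swarm_density")
  X <- matrix(stats::runif(n * K, -b, b), n, K)
  X[, 1L] <- 0  # null particle: the uniform grid itself
  span <- 2 * b
  Vl <- matrix(stats::runif(n * K, -span, span), n, K)
  structure(list(position = X, velocity = Vl, bounds = b, n = n, K = K,
                 pbest_position = X, pbest_cost = NULL,
                 best_cost = Inf, best_index = NA_integer_,
                 inertia = control$inertia_range[2],
                 adapt_counter = 0L,
                 nbh_size = max(2L, floor(control$min_neighborhood_fraction * K))),
            class = "pso_swarm")
}

#' Advance a swarm by one iteration
#'
#' Evaluates the cost of every particle, updates personal and neighborhood
#' bests, and moves the particles:
#' \code{v <- w*v + c1*r1*(pbest - x) + c2*r2*(nbest - x)} with fresh
#' uniform \code{r1}, \code{r2}, velocities clamped to the bound span and
#' positions clamped to the bounds (the velocity component is zeroed on
#' contact). Each particle's neighborhood is a fresh random subset of the
#' swarm (plus itself) whose size grows while the global best stalls and
#' shrinks back after improvement; the inertia weight adapts within its
#' range. The recorded best cost never increases.
#'
#' @param swarm a \code{pso_swarm}.
#' @param cost_fn batch cost: takes an n x K matrix of candidate positions,
#'   returns K finite costs.
#' @param control a \code{\link{pso_control}}.
#' @return The updated swarm, with \code{improvement} (previous best minus
#'   new best) attached.
#' @export
pso_step <- function(swarm, cost_fn, control = pso_control()) {
  s <- swarm
  n <- s$n; K <- s$K
  if (is.null(s$pbest_cost)) {
    cost <- as.numeric(cost_fn(s$position))
    if (any(!is.finite(cost)))
      stop("cost function returned a non-finite value during initialisation")
    s$pbest_cost <- cost
    s$best_index <- which.min(cost)
    s$best_cost <- cost[s$best_index]
  }
  prev_best <- s$best_cost

  # dynamic random neighborhoods: self plus nbh_size - 1 random particles
  m <- s$nbh_size
  idx <- matrix(sample.int(K, (m - 1L) * K, replace = TRUE), m - 1L, K)
  pbc <- matrix(s$pbest_cost[idx], m - 1L, K)
  pbc <- rbind(pbc, s$pbest_cost)          # self is always a member
  idx <- rbind(idx, seq_len(K))
  win <- max.col(-t(pbc), ties.method = "first")
  nb_idx <- idx[cbind(win, seq_len(K))]
  nbest <- s$pbest_position[, nb_idx, drop = FALSE]

  r1 <- matrix(stats::runif(n * K), n, K)
  r2 <- matrix(stats::runif(n * K), n, K)
  Vl <- s$inertia * s$velocity +
    control$cognitive_coeff * r1 * (s$pbest_position - s$position) +
    control$social_coeff * r2 * (nbest - s$position)
  vmax <- 2 * s$bounds
  Vl <- pmin(pmax(Vl, -vmax), vmax)
  X <- s$position + Vl
  over <- X > s$bounds
  under <- X < -s$bounds
  if (any(over)) { X[over] <- rep(s$bounds, K)[over]; Vl[over] <- 0 }
  if (any(under)) { X[under] <- rep(-s$bounds, K)[under]; Vl[under] <- 0 }
  s$position <- X
  s$velocity <- Vl

  cost <- as.numeric(cost_fn(X))
  if (any(!is.finite(cost)))
    stop("cost function returned a non-finite value")
  better <- cost < s$pbest_cost
  if (any(better)) {
    s$pbest_cost[better] <- cost[better]
    s$pbest_position[, better] <- X[, better]
  }
  s$best_index <- which.min(s$pbest_cost)
  new_best <- s$pbest_cost[s$best_index]

  min_nbh <- max(2L, floor(control$min_neighborhood_fraction * K))
  if (new_best < prev_best) {
    s$adapt_counter <- max(0L, s$adapt_counter - 1L)
    s$nbh_size <- min_nbh
  } else {
    s$adapt_counter <- s$adapt_counter + 1L
    s$nbh_size <- min(s$nbh_size + min_nbh, K)
  }
  # inertia grows while the swarm keeps improving, shrinks under
  # persistent stagnation to refine locally
  if (s$adapt_counter < 2L) {
    s$inertia <- 2 * s$inertia
  } else if (s$adapt_counter > 5L) {
    s$inertia <- s$inertia / 2
  }
  s$inertia <- min(max(s$inertia, control$inertia_range[1]),
                   control$inertia_range[2])
  s$best_cost <- new_best
  s$improvement <- prev_best - new_best
  s
}

#' Minimise a cost over bound-constrained displacements by PSO
#'
#' Runs the swarm until the best cost changes by no more than
#' \code{tolerance} for \code{stall_iterations} consecutive iterations or
#' the iteration cap is reached, and returns the best particle. With a seed
#' in \code{control} the run is fully deterministic.
#'
#' @inheritParams pso_init_swarm
#' @param cost_fn batch cost function (n x K matrix in, K costs out),
#'   finite everywhere in the bound box.
#' @return A list of class \code{pso_result}: \code{par} (best position),
#'   \code{value} (best cost), \code{cost_trace} (per-iteration best cost,
#'   non-increasing), \code{iterations}, \code{terminated_by}
#'   (\code{"tolerance"} or \code{"max_iterations"}), \code{n_particles}.
#' @export
pso_optimize <- function(cost_fn, n, bounds, control = pso_control()) {
  if (!is.null(control$seed)) set.seed(control$seed)
  b <- rep_len(as.numeric(bounds), n)
  if (all(b == 0)) {
    val <- as.numeric(cost_fn(matrix(0, n, 1L)))
    if (!is.finite(val)) stop("cost function returned a non-finite value")
    return(structure(list(par = numeric(n), value = val, cost_trace = val,
                          iterations = 0L, terminated_by = "tolerance",
                          n_particles = 1L),
                     class = "pso_result"))
  }
  max_iter <- control$max_iterations %||% (200L * n)
  swarm <- pso_init_swarm(n, b, control)
  trace <- numeric(0)
  it <- 0L
  terminated <- "max_iterations"
  win <- control$stall_iterations
  while (it < max_iter) {
    it <- it + 1L
    swarm <- pso_step(swarm, cost_fn, control)
    trace[it] <- swarm$best_cost
    # stop when the best cost has changed by no more than the tolerance
    # over the last `stall_iterations` consecutive iterations
    if (it > win && trace[it - win] - trace[it] <= control$tolerance) {
      terminated <- "tolerance"
      break
    }
  }
  structure(list(par = swarm$pbest_position[, swarm$best_index],
                 value = swarm$best_cost,
                 cost_trace = trace,
                 iterations = it,
                 terminated_by = terminated,
                 n_particles = swarm$K),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result> best cost %.6g after %d iterations (%s), %d particles\n",
              x$value, x$iterations, x$terminated_by, x$n_particles))
  invisible(x)
}
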