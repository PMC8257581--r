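#' Walk model parameters
#'
#' Bundle the two governing parameters of the (persistent) self-attracting
#' walk: the persistence parameter \code{k} (dimensionless, >= 0) and the
#' footprint-coupling parameter \code{beta} (dimensionless; negative values
#' mean self-attraction). The derived persistence length and time are
#' \code{l_p = t_p = exp(2 k)} in lattice units (unit speed).
#'
#' @param k persistence parameter, finite and >= 0.
#' @param beta footprint coupling, finite real; negative = self-attraction.
#' @param dim spatial dimension, 1 or 2. The 2D model has no persistence
#'   term, so \code{k} is ignored (and must be 0) when \code{dim = 2}.
#' @return An object of class \code{walk_params}: a list with elements
#'   \code{k}, \code{beta}, \code{dim}, \code{l_p}, \code{t_p}.
#' @examples
#' p <- walk_params(k = 1, beta = -1)
#' p$l_p  # exp(2)
#' @export
walk_params <- function(k = 0, beta = 0, dim = 1L) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    stop("'k' must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("'beta' must be a single finite number", call. = FALSE)
  if (!dim %in% c(1L, 2L))
    stop("'dim' must be 1 or 2", call. = FALSE)
  if (dim == 2L && k != 0)
    stop("the 2D SATW has no persistence term; use k = 0 when dim = 2",
         call. = FALSE)
  structure(list(k = k, beta = beta, dim = as.integer(dim),
                 l_p = exp(2 * k), t_p = exp(2 * k)),
            class = "walk_params")
}

#' @export
print.walk_params <- function(x, ...) {
  cat(sprintf("%dD walk parameters: k = %g, beta = %g (l_p = t_p = %.3g)\n",
              x$dim, x$k, x$beta, x$l_p))
  invisible(x)
}

#' Interior reversal probability of the persistent walk
#'
#' Probability that a walker inside its visited domain reverses direction:
#' \code{p_ri = exp(-k) / (exp(-k) + exp(k))}. It continues with
#' \code{1 - p_ri}. \code{k = 0} gives 1/2 (no persistence); large \code{k}
#' suppresses reversals.
#'
#' @param k persistence parameter, finite.
#' @return The reversal probability, in (0, 1).
#' @export
reversal_prob_interior <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)))
    stop("'k' must be finite", call. = FALSE)
  1 / (1 + exp(2 * k))
}

#' Edge reversal probability of the persistent self-attracting walk
#'
#' Probability that a walker whose next site (in its current direction) is
#' unvisited reverses, i.e. turns back into the visited domain:
#' \code{p_re = exp(-k - beta) / (exp(-k - beta) + exp(k))}. With
#' \code{beta < 0} this exceeds the interior reversal probability, the inward
#' bias at the frontier of the visited territory; \code{beta = 0} reduces it
#' to \code{\link{reversal_prob_interior}}.
#'
#' @param k persistence parameter, finite.
#' @param beta footprint coupling, finite.
#' @return The reversal probability, in (0, 1).
#' @export
reversal_prob_edge <- function(k, beta) {
  if (!is.numeric(k) || any(!is.finite(k)))
    stop("'k' must be finite", call. = FALSE)
  if (!is.numeric(beta) || any(!is.finite(beta)))
    stop("'beta' must be finite", call. = FALSE)
  1 / (1 + exp(2 * k + beta))
}

#' SATW jump weights over neighbouring sites
#'
#' Normalised jump probabilities of the self-attracting walk: the weight of
#' neighbour \code{j} is proportional to \code{exp(-beta * f(n_j))} with the
#' saturating memory function \code{f(0) = 0}, \code{f(n > 0) = 1}, where
#' \code{n_j} is the visit count of that site.
#'
#' @param neighbor_visits non-negative integer visit counts, one per
#'   neighbouring site (at least 2 neighbours).
#' @param beta footprint coupling, finite.
#' @return Numeric probability vector of the same length, summing to 1.
#' @export
satw_jump_weights <- function(neighbor_visits, beta) {
  if (length(neighbor_visits) < 2L)
    stop("need at least 2 neighbours", call. = FALSE)
  if (any(!is.finite(neighbor_visits)) || any(neighbor_visits < 0))
    stop("visit counts must be finite and >= 0", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("'beta' must be a single finite number", call. = FALSE)
  w <- exp(-beta * as.numeric(neighbor_visits > 0))
  w / sum(w)
}

## Per-trajectory RNG streams: a master seed is expanded into one 31-bit
## sub-seed per walker via R's own generator, so ensembles are reproducible
## and individual trajectories can be regenerated in isolation.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

new_lattice_trajectory <- function(sites, params, seed) {
  structure(list(sites = sites, params = params, seed = seed),
            class = "lattice_trajectory")
}

#' Simulate a 1D persistent self-attracting walk (PSATW)
#'
#' Discrete-time walk on the 1D integer lattice. At each step the walker
#' looks at the site ahead in its current direction: if that site is
#' unvisited it reverses with the edge probability
#' \code{\link{reversal_prob_edge}(k, beta)}, otherwise with the interior
#' probability \code{\link{reversal_prob_interior}(k)}; it then moves one
#' site and the arrival site's visit count is incremented. The walker starts
#' at the origin (counted as visited once) with a uniformly random initial
#' direction, so the first step is always an edge step.
#'
#' @param k persistence parameter (>= 0).
#' @param beta footprint coupling; negative values attract the walker to its
#'   own visited domain.
#' @param n_steps number of steps (>= 1).
#' @param seed integer RNG seed; identical inputs give bit-identical paths.
#' @return A \code{lattice_trajectory}: list with \code{sites} (integer
#'   vector of length \code{n_steps + 1}, starting at 0), \code{params}
#'   (\code{\link{walk_params}}) and \code{seed}.
#' @seealso \code{\link{simulate_satw_2d}}, \code{\link{psatw_ensemble}}
#' @export
simulate_psatw_1d <- function(k, beta, n_steps, seed) {
  params <- walk_params(k = k, beta = beta, dim = 1L)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  sites <- cpp_psatw_path(params$k, params$beta, n_steps)
  new_lattice_trajectory(sites, params, as.integer(seed))
}

#' Simulate a 2D self-attracting walk (SATW)
#'
#' Walk on the 4-neighbour square lattice without persistence: each step is
#' drawn from \code{\link{satw_jump_weights}} over the four neighbours.
#'
#' @param beta footprint coupling.
#' @param n_steps number of steps (>= 1).
#' @param seed integer RNG seed.
#' @return A \code{lattice_trajectory} whose \code{sites} is an integer
#'   matrix with columns x, y and \code{n_steps + 1} rows.
#' @export
simulate_satw_2d <- function(beta, n_steps, seed) {
  params <- walk_params(k = 0, beta = beta, dim = 2L)
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  sites <- cpp_satw2d_path(params$beta, n_steps)
  colnames(sites) <- c("x", "y")
  new_lattice_trajectory(sites, params, as.integer(seed))
}

#' Simulate an ensemble of independent walks
#'
#' Each walker gets its own RNG stream derived from \code{seed} (see the
#' package vignette), so the ensemble is reproducible and any single
#' trajectory can be regenerated alone.
#'
#' @param k,beta model parameters (see \code{\link{walk_params}}).
#' @param n_steps steps per walker.
#' @param n_walkers number of independent walkers.
#' @param seed master integer seed.
#' @return For \code{psatw_ensemble}, a \code{lattice_ensemble} with a
#'   numeric matrix \code{x} of dim \code{(n_steps + 1, n_walkers)}. For
#'   \code{satw2d_ensemble}, matrices \code{x} and \code{y}.
#' @export
psatw_ensemble <- function(k, beta, n_steps, n_walkers, seed) {
  params <- walk_params(k = k, beta = beta, dim = 1L)
  seeds <- derive_seeds(seed, n_walkers)
  x <- matrix(0, nrow = n_steps + 1L, ncol = n_walkers)
  for (i in seq_len(n_walkers)) {
    set.seed(seeds[i])
    x[, i] <- cpp_psatw_path(params$k, params$beta, as.integer(n_steps))
  }
  structure(list(x = x, params = params, seed = as.integer(seed),
                 walker_seeds = seeds),
            class = "lattice_ensemble")
}

#' @rdname psatw_ensemble
#' @export
satw2d_ensemble <- function(beta, n_steps, n_walkers, seed) {
  params <- walk_params(k = 0, beta = beta, dim = 2L)
  seeds <- derive_seeds(seed, n_walkers)
  x <- matrix(0, nrow = n_steps + 1L, ncol = n_walkers)
  y <- matrix(0, nrow = n_steps + 1L, ncol = n_walkers)
  for (i in seq_len(n_walkers)) {
    set.seed(seeds[i])
    p <- cpp_satw2d_path(params$beta, as.integer(n_steps))
    x[, i] <- p[, 1]
    y[, i] <- p[, 2]
  }
  structure(list(x = x, y = y, params = params, seed = as.integer(seed),
                 walker_seeds = seeds),
            class = "lattice_ensemble")
}

#' Span of the visited domain along a trajectory
#'
#' Number of distinct lattice sites visited up to each time (1D), a
#' non-decreasing sequence.
#'
#' @param traj a \code{lattice_trajectory} (1D) or an integer site vector.
#' @return Integer vector: span (max - min + 1) after each step.
#' @export
trajectory_span <- function(traj) {
  sites <- if (inherits(traj, "lattice_trajectory")) traj$sites else traj
  if (is.matrix(sites)) stop("span is defined for 1D trajectories", call. = FALSE)
  cummax(sites) - cummin(sites) + 1L
}

#' Export lattice trajectories to the package track format
#'
#' @param trajs a \code{lattice_trajectory} or list of them.
#' @return A data.frame with columns walker_id, step, x (and y for 2D).
#' @export
lattice_to_table <- function(trajs) {
  if (inherits(trajs, "lattice_trajectory")) trajs <- list(trajs)
  any2d <- any(vapply(trajs, function(tr) is.matrix(tr$sites), logical(1)))
  out <- lapply(seq_along(trajs), function(i) {
    s <- trajs[[i]]$sites
    df <- if (is.matrix(s))
      data.frame(walker_id = i, step = seq_len(nrow(s)) - 1L,
                 x = s[, 1], y = s[, 2])
    else
      data.frame(walker_id = i, step = seq_along(s) - 1L, x = s)
    if (any2d && is.null(df$y)) df$y <- NA_integer_
    df
  })
  do.call(rbind, out)
}
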