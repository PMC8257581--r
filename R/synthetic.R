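## Synthetic cell-track generator: dresses PSATW lattice paths into
## continuous-space, continuous-time 1D tracks with the statistical
## structure the analysis pipeline assumes (sawtooth oscillations with
## slowly growing amplitude, bi-exponential hop durations with mean 0.6 h,
## ~20 um cells that transiently spread during reversals, positional noise,
## cell-to-cell parameter variability).

#' Population model hyperparameters for synthetic cells
#'
#' Defaults describe oscillatory cells on 1D micropatterned lines:
#' per-cell (k, beta) drawn from truncated normals, a 20 um reference
#' length, bi-exponential hop durations with overall mean 0.6 h (mixture
#' 0.7/0.3 of means 0.3 h and 1.3 h), transient spreading up to ~100 um
#' during reversals, 6-min frames, 1 um positional noise.
#'
#' @param k_mean,k_sd population mean and sd of the persistence parameter
#'   (k is truncated at 0).
#' @param beta_mean,beta_sd population mean and sd of the footprint
#'   coupling.
#' @param L_ref_um lattice/cell length scale, micrometres.
#' @param jump_mix_weight,jump_mean_fast_h,jump_mean_slow_h bi-exponential
#'   hop-duration mixture: weight of the fast component and the two
#'   component means (hours). Defaults give mean 0.6 h.
#' @param cell_length_um baseline cell length, micrometres.
#' @param spread_length_um maximum extra elongation during a reversal.
#' @param noise_sd_um positional noise sd added to the centroid.
#' @param frame_dt_h frame interval, hours (default 0.1 = 6 min).
#' @return A \code{population_model} list.
#' @export
population_model <- function(k_mean = 0.7, k_sd = 0.2,
                             beta_mean = -2, beta_sd = 0.5,
                             L_ref_um = 20,
                             jump_mix_weight = 0.7,
                             jump_mean_fast_h = 0.3,
                             jump_mean_slow_h = 1.3,
                             cell_length_um = 20,
                             spread_length_um = 80,
                             noise_sd_um = 1,
                             frame_dt_h = 0.1) {
  m <- list(k_mean = k_mean, k_sd = k_sd, beta_mean = beta_mean,
            beta_sd = beta_sd, L_ref_um = L_ref_um,
            jump_mix_weight = jump_mix_weight,
            jump_mean_fast_h = jump_mean_fast_h,
            jump_mean_slow_h = jump_mean_slow_h,
            cell_length_um = cell_length_um,
            spread_length_um = spread_length_um,
            noise_sd_um = noise_sd_um, frame_dt_h = frame_dt_h)
  scales <- c("L_ref_um", "jump_mean_fast_h", "jump_mean_slow_h",
              "cell_length_um", "frame_dt_h")
  if (any(!vapply(m, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                  logical(1))))
    stop("all hyperparameters must be single finite numbers", call. = FALSE)
  if (any(unlist(m[scales]) <= 0))
    stop("scale hyperparameters must be positive", call. = FALSE)
  if (m$jump_mix_weight < 0 || m$jump_mix_weight > 1)
    stop("'jump_mix_weight' must lie in [0, 1]", call. = FALSE)
  if (m$k_sd < 0 || m$beta_sd < 0 || m$noise_sd_um < 0 || m$spread_length_um < 0)
    stop("spreads and noise must be >= 0", call. = FALSE)
  if (m$jump_mean_fast_h <= m$frame_dt_h || m$jump_mean_slow_h <= m$frame_dt_h)
    stop("jump-duration means must exceed the frame interval", call. = FALSE)
  structure(m, class = "population_model")
}

#' Mean hop duration implied by a population model
#' @param model a \code{\link{population_model}}.
#' @return Mean jump duration, hours.
#' @export
mean_jump_duration <- function(model) {
  model$jump_mix_weight * model$jump_mean_fast_h +
    (1 - model$jump_mix_weight) * model$jump_mean_slow_h
}

#' Draw per-cell walk parameters from a population model
#'
#' k from a normal truncated at 0 (resampling), beta from a normal.
#'
#' @param model a \code{\link{population_model}}.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return data.frame with \code{cell_id}, \code{k}, \code{beta},
#'   \code{L_ref}.
#' @export
sample_population <- function(model, n_cells, seed) {
  stopifnot(inherits(model, "population_model"))
  set.seed(as.integer(seed))
  k <- stats::rnorm(n_cells, model$k_mean, model$k_sd)
  while (any(k < 0))
    k[k < 0] <- stats::rnorm(sum(k < 0), model$k_mean, model$k_sd)
  beta <- stats::rnorm(n_cells, model$beta_mean, model$beta_sd)
  data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
             k = k, beta = beta, L_ref = model$L_ref_um,
             stringsAsFactors = FALSE)
}

## Bi-exponential hop durations with a floor of one frame interval: each
## draw is frame_dt plus an exponential whose mean is the component mean
## minus frame_dt, so the overall mean is exactly the configured mixture
## mean and no hop is shorter than a frame (a sub-frame round trip would be
## invisible to the sampled track).
rbiexp_jump <- function(n, model) {
  fast <- stats::runif(n) < model$jump_mix_weight
  dt <- model$frame_dt_h
  t <- numeric(n)
  t[fast] <- dt + stats::rexp(sum(fast), 1 / (model$jump_mean_fast_h - dt))
  t[!fast] <- dt + stats::rexp(sum(!fast), 1 / (model$jump_mean_slow_h - dt))
  t
}

#' Render a lattice path as a continuous cell track
#'
#' Maps a lattice site sequence to centroid positions \code{x = X * L_ref},
#' draws a bi-exponential duration for every hop, interpolates the centroid
#' linearly between hops, resamples on the regular frame grid, attaches
#' cell edges (centroid +/- length/2, with a transient triangular
#' elongation during reversal hops), and adds positional noise. At zero
#' noise the rendering inverts exactly: \code{\link{discretise}} with the
#' same \code{L_ref} recovers the generating site sequence.
#'
#' @param lattice a \code{lattice_trajectory} (1D) or integer site vector.
#' @param L_ref lattice spacing, micrometres.
#' @param model a \code{\link{population_model}} (dressing parameters).
#' @param seed seed for the dressing randomness (independent of the
#'   lattice-path randomness, so one path can be re-dressed).
#' @param cell_id identifier for the output rows.
#' @param duration_h optional duration: tracks are truncated to this length
#'   (or, for a hop-free path, rendered stationary for this long,
#'   default 10 h).
#' @return data.frame with \code{cell_id}, \code{t_h}, \code{x_um},
#'   \code{x_left_um}, \code{x_right_um}.
#' @export
render_continuous_track <- function(lattice, L_ref, model, seed,
                                    cell_id = "cell001", duration_h = NULL) {
  stopifnot(inherits(model, "population_model"))
  sites <- if (inherits(lattice, "lattice_trajectory")) lattice$sites else lattice
  if (is.matrix(sites)) stop("only 1D lattice paths can be rendered", call. = FALSE)
  set.seed(as.integer(seed))
  n_hops <- length(sites) - 1L
  dt <- model$frame_dt_h
  if (n_hops == 0L) {
    dur <- if (is.null(duration_h)) 10 else duration_h
    frames <- seq(0, dur, by = dt)
    x <- rep(sites[1L] * L_ref, length(frames))
  } else {
    t_jump <- rbiexp_jump(n_hops, model)
    T_hop <- cumsum(t_jump)
    total <- T_hop[n_hops]
    if (!is.null(duration_h)) total <- min(total, duration_h)
    ## run the regular grid to the next frame multiple past the last hop so
    ## the terminal arrival is always sampled (position held constant past it)
    frames <- seq(0, ceiling(total / dt) * dt, by = dt)
    x <- stats::approx(c(0, T_hop), sites * L_ref, xout = frames,
                       rule = 2)$y
  }
  len <- rep(model$cell_length_um, length(frames))
  if (n_hops >= 2L && model$spread_length_um > 0) {
    d <- diff(sites)
    rev_hops <- which(d[-1L] != d[-length(d)]) + 1L  # hop indices that reverse
    amp <- model$spread_length_um * stats::runif(length(rev_hops), 0.3, 1)
    for (j in seq_along(rev_hops)) {
      h <- rev_hops[j]
      ## transient spreading episode centred on the reversal, at most 0.3 h:
      ## the compact ~cell_length state remains the typical (median) state
      mid <- (T_hop[h - 1L] + T_hop[h]) / 2
      w <- min(0.3, T_hop[h] - T_hop[h - 1L])
      a <- mid - w / 2; b <- mid + w / 2
      inside <- frames >= a & frames <= b
      if (any(inside)) {
        u <- (frames[inside] - a) / (b - a)
        len[inside] <- len[inside] + amp[j] * (1 - abs(2 * u - 1))
      }
    }
  }
  noise <- if (model$noise_sd_um > 0)
    stats::rnorm(length(frames), 0, model$noise_sd_um) else 0
  xc <- x + noise
  data.frame(cell_id = cell_id, t_h = frames, x_um = xc,
             x_left_um = xc - len / 2, x_right_um = xc + len / 2,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic single-cell track dataset
#'
#' The \code{"control"} preset emulates oscillatory cells confined by their
#' own footprints (strongly negative mean beta); the \code{"conditioned"}
#' preset emulates cells on a substrate pre-covered with footprints, which
#' see no frontier (mean beta ~ 0) and keep the same intrinsic persistence
#' k — persistent motion and larger net displacement.
#'
#' @param preset \code{"control"} or \code{"conditioned"}.
#' @param n_cells number of cells.
#' @param duration_h track duration per cell, hours; ignored when
#'   \code{n_hops} is given.
#' @param seed master seed; everything (population draw, lattice paths,
#'   dressing) derives from it.
#' @param n_hops optional fixed number of lattice hops per cell (overrides
#'   \code{duration_h}).
#' @param model optional \code{\link{population_model}} overriding the
#'   preset hyperparameters.
#' @return A \code{synthetic_dataset}: list with \code{tracks} (long
#'   data.frame in the track-table format), \code{truth} (per-cell
#'   generating parameters), \code{manifest} (everything needed for
#'   bit-identical regeneration, see \code{\link{regenerate_dataset}}).
#' @export
generate_dataset <- function(preset = c("control", "conditioned"),
                             n_cells = 100, duration_h = 90, seed = 1,
                             n_hops = NULL, model = NULL) {
  preset <- match.arg(preset)
  if (is.null(model)) {
    model <- switch(preset,
      control = population_model(),
      conditioned = population_model(beta_mean = 0, beta_sd = 0.1))
  }
  stopifnot(inherits(model, "population_model"))
  pop_seed <- derive_seeds(seed, 1L)
  truth <- sample_population(model, n_cells, pop_seed)
  cell_seeds <- matrix(derive_seeds(seed + 1L, 2L * n_cells), ncol = 2L)
  steps <- if (is.null(n_hops))
    ceiling(1.5 * duration_h / mean_jump_duration(model)) + 20L
  else as.integer(n_hops)
  tracks <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    lat <- simulate_psatw_1d(truth$k[i], truth$beta[i], steps,
                             seed = cell_seeds[i, 1L])
    tracks[[i]] <- render_continuous_track(
      lat, L_ref = truth$L_ref[i], model = model,
      seed = cell_seeds[i, 2L], cell_id = truth$cell_id[i],
      duration_h = if (is.null(n_hops)) duration_h else NULL)
  }
  manifest <- list(preset = preset, n_cells = n_cells,
                   duration_h = duration_h, seed = seed, n_hops = n_hops,
                   model = unclass(model))
  structure(list(tracks = do.call(rbind, tracks), truth = truth,
                 manifest = manifest),
            class = "synthetic_dataset")
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest the \code{manifest} element of a
#'   \code{\link{generate_dataset}} result.
#' @return A \code{synthetic_dataset}, bit-identical to the original.
#' @export
regenerate_dataset <- function(manifest) {
  generate_dataset(preset = manifest$preset, n_cells = manifest$n_cells,
                   duration_h = manifest$duration_h, seed = manifest$seed,
                   n_hops = manifest$n_hops,
                   model = do.call(population_model, manifest$model))
}
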