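## Ensemble statistics: ageing increments, MSD, first-passage survival with
## persistence-exponent fits, oscillation detection, effective diffusion.

ensemble_positions <- function(trajs) {
  if (inherits(trajs, "lattice_ensemble")) {
    list(x = trajs$x, y = trajs$y)   # y NULL in 1D
  } else if (is.matrix(trajs)) {
    list(x = trajs, y = NULL)
  } else {
    stop("'trajs' must be a lattice_ensemble or a positions matrix ",
         "(time along rows, walkers along columns)", call. = FALSE)
  }
}

#' Ageing increments I(T, t) of an ensemble
#'
#' Mean squared increments \code{I(T, t) = <|x(t + t0) - x(t0)|^2>} with the
#' start time t0 sliding over \code{[T, T + window]} and averaged over
#' walkers, for each measurement age \code{T}. Dependence of the curves on
#' \code{T} (ageing) is the signature of long-lived spatial memory; a
#' memoryless walk gives T-independent increments. Lags are reported up to
#' \code{window / 3} by default so every lag is averaged over a full window.
#'
#' @param trajs a \code{lattice_ensemble} (1D or 2D) or a numeric matrix of
#'   positions, time (rows) by walkers (columns), first row = time 0.
#' @param ages vector of ages T, in steps.
#' @param window sliding-average window length, steps.
#' @param lags lag grid, steps; default log-spaced up to \code{max_lag}.
#' @param max_lag largest lag, default \code{floor(window / 3)}.
#' @return data.frame with columns \code{age}, \code{lag}, \code{value},
#'   \code{sem} (over walkers), \code{n}.
#' @export
increments <- function(trajs, ages, window, lags = NULL,
                       max_lag = floor(window / 3)) {
  P <- ensemble_positions(trajs)
  n_steps <- nrow(P$x) - 1L
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(log(1), log(max_lag), length.out = 25L))))
  }
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L)) stop("lags must be >= 1", call. = FALSE)
  ages <- as.integer(ages)
  if (max(ages) + window + max(lags) > n_steps)
    stop("trajectories too short for the requested ages/window/lags",
         call. = FALSE)
  n_walk <- ncol(P$x)
  out <- vector("list", length(ages) * length(lags))
  idx <- 0L
  for (T_age in ages) {
    i0 <- (T_age:(T_age + window)) + 1L
    for (lg in lags) {
      dx <- P$x[i0 + lg, , drop = FALSE] - P$x[i0, , drop = FALSE]
      per_walker <- colMeans(dx * dx)
      if (!is.null(P$y)) {
        dy <- P$y[i0 + lg, , drop = FALSE] - P$y[i0, , drop = FALSE]
        per_walker <- per_walker + colMeans(dy * dy)
      }
      idx <- idx + 1L
      out[[idx]] <- data.frame(
        age = T_age, lag = lg, value = mean(per_walker),
        sem = stats::sd(per_walker) / sqrt(n_walk), n = n_walk)
    }
  }
  do.call(rbind, out)
}

#' Ensemble mean squared displacement from the origin
#'
#' Per walker \code{|x(t) - x(0)|^2} (or the unsquared norm with
#' \code{squared = FALSE}), averaged over walkers at each time.
#'
#' @param trajs as in \code{\link{increments}}.
#' @param squared if FALSE, average the displacement norm instead of its
#'   square.
#' @return data.frame with \code{step}, \code{msd}, \code{sem}, \code{n}.
#' @export
msd <- function(trajs, squared = TRUE) {
  P <- ensemble_positions(trajs)
  dx <- sweep(P$x, 2L, P$x[1L, ])
  s2 <- dx * dx
  if (!is.null(P$y)) {
    dy <- sweep(P$y, 2L, P$y[1L, ])
    s2 <- s2 + dy * dy
  }
  if (!squared) s2 <- sqrt(s2)
  n <- ncol(s2)
  m <- rowMeans(s2)
  v <- rowMeans(s2 * s2) - m * m
  sem <- sqrt(pmax(v, 0) * n / (n - 1)) / sqrt(n)
  data.frame(step = seq_len(nrow(s2)) - 1L, msd = m, sem = sem, n = n)
}

#' Survival probability of a distant target under the 1D PSATW
#'
#' Monte-Carlo estimate of S(t), the probability that a single target site
#' at +r on the infinite line has not yet been visited by time t, for
#' independent walkers started at the origin. The long-time tail
#' \code{S(t) ~ t^-theta} defines the persistence exponent; memoryless
#' walks give theta = 1/2, the attractive walk theta = exp(-beta)/2 (see
#' \code{\link{theta_theory}}).
#'
#' @param k,beta PSATW parameters.
#' @param r target distance, lattice sites (>= 1).
#' @param n_walkers number of independent walkers.
#' @param t_max horizon, steps; walkers not arrived by then are censored.
#' @param seed master seed (one derived stream per walker).
#' @param n_grid number of log-spaced evaluation times.
#' @return A \code{survival_curve}: list with \code{curve} (data.frame
#'   \code{time}, \code{S}, \code{sem}), the raw \code{hit_times}
#'   (Inf = censored), \code{r}, \code{t_max}, \code{params}.
#' @export
survival_probability <- function(k, beta, r, n_walkers, t_max, seed,
                                 n_grid = 200L) {
  params <- walk_params(k = k, beta = beta, dim = 1L)
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("'r' must be >= 1", call. = FALSE)
  seeds <- derive_seeds(seed, n_walkers)
  hit <- numeric(n_walkers)
  for (i in seq_len(n_walkers)) {
    set.seed(seeds[i])
    ht <- cpp_psatw_first_passage(params$k, params$beta, r, as.integer(t_max))
    hit[i] <- if (ht < 0) Inf else ht
  }
  times <- unique(round(exp(seq(log(1), log(t_max), length.out = n_grid))))
  S <- vapply(times, function(tt) mean(hit > tt), numeric(1))
  sem <- sqrt(S * (1 - S) / n_walkers)
  structure(list(curve = data.frame(time = times, S = S, sem = sem),
                 hit_times = hit, r = r, t_max = as.integer(t_max),
                 n_walkers = n_walkers, params = params,
                 seed = as.integer(seed)),
            class = "survival_curve")
}

#' Theoretical persistence exponent of the PSATW
#'
#' \code{theta = exp(-beta) / 2}: 1/2 for the memoryless walk (beta = 0),
#' larger for self-attraction (beta < 0), strictly decreasing in beta.
#'
#' @param beta footprint coupling.
#' @return The persistence exponent.
#' @export
theta_theory <- function(beta) exp(-beta) / 2

#' Power-law exponent by log-log least squares
#'
#' Fits \code{log(y) ~ log(x)} over a window of x and reports the slope
#' with its standard error and R^2 as a goodness diagnostic (an exponential
#' shows up as a visibly poor R^2). Windows containing zero or negative
#' values are refused, as are fits with fewer than 5 points.
#'
#' @param x,y positive numeric vectors (e.g. lag and increment, or time and
#'   survival).
#' @param window length-2 numeric, x range (inclusive) to fit over.
#' @return An \code{exponent_fit}: list with \code{exponent}, \code{se},
#'   \code{r_squared}, \code{window}, \code{n_points}.
#' @export
fit_power_exponent <- function(x, y, window = range(x)) {
  keep <- is.finite(x) & is.finite(y) & x >= window[1] & x <= window[2]
  if (any(y[keep] <= 0) || any(x[keep] <= 0))
    stop("fit window contains non-positive values", call. = FALSE)
  if (sum(keep) < 5L)
    stop("need at least 5 points in the fit window", call. = FALSE)
  fit <- stats::lm(log(y[keep]) ~ log(x[keep]))
  sm <- suppressWarnings(summary(fit))  # exact fits trip a benign lm warning
  structure(list(exponent = unname(stats::coef(fit)[2L]),
                 se = sm$coefficients[2L, 2L],
                 r_squared = sm$r.squared,
                 window = window, n_points = sum(keep)),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("power-law exponent %.4f (se %.4f, R^2 %.4f, %d points in [%g, %g])\n",
              x$exponent, x$se, x$r_squared, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Persistence exponent from a survival curve's tail
#'
#' Fits the power-law tail of S(t) over the times where S lies in
#' \code{s_range} (default [1e-3, 1e-1], i.e. the late tail) and reports
#' theta = -slope. The Monte-Carlo standard error is estimated by
#' bootstrap over walkers: first-passage times are resampled with
#' replacement and the tail refitted.
#'
#' @param sc a \code{\link{survival_probability}} result.
#' @param s_range survival range selecting the fit window.
#' @param n_boot bootstrap replicates (0 disables; then se is the
#'   least-squares se).
#' @param seed seed for the bootstrap resampling.
#' @return An \code{exponent_fit} with \code{exponent} = theta (> 0 for a
#'   decaying tail) and \code{se} the bootstrap standard error.
#' @export
fit_survival_tail <- function(sc, s_range = c(1e-3, 1e-1), n_boot = 100L,
                              seed = 1L) {
  stopifnot(inherits(sc, "survival_curve"))
  cv <- sc$curve
  tail_fit <- function(S) {
    keep <- S >= s_range[1] & S <= s_range[2] & S > 0
    if (sum(keep) < 5L) return(NA_real_)
    f <- stats::lm(log(S[keep]) ~ log(cv$time[keep]))
    -unname(stats::coef(f)[2L])
  }
  keep <- cv$S >= s_range[1] & cv$S <= s_range[2] & cv$S > 0
  if (sum(keep) < 5L)
    stop("fewer than 5 survival points in the requested S range", call. = FALSE)
  fit <- fit_power_exponent(cv$time[keep], cv$S[keep],
                            window = range(cv$time[keep]))
  theta <- -fit$exponent
  se <- fit$se
  if (n_boot > 0L) {
    set.seed(as.integer(seed))
    n <- length(sc$hit_times)
    th_b <- vapply(seq_len(n_boot), function(b) {
      ht <- sample(sc$hit_times, n, replace = TRUE)
      S <- vapply(cv$time, function(tt) mean(ht > tt), numeric(1))
      tail_fit(S)
    }, numeric(1))
    se <- stats::sd(th_b, na.rm = TRUE)
  }
  structure(list(exponent = theta, se = se, r_squared = fit$r_squared,
                 window = fit$window, n_points = fit$n_points),
            class = "exponent_fit")
}

#' Detect reversals and oscillation geometry in a 1D track
#'
#' Turning points are sign changes of the smoothed centroid velocity whose
#' excursion exceeds \code{min_excursion} (a hysteresis rule, so positional
#' noise does not spawn spurious reversals). The amplitude of an
#' oscillation is the excursion between consecutive turning points; its
#' period is the time between successive same-sign reversals. For a runner
#' bouncing at constant speed v, amplitude / period = v / 2.
#'
#' @param track data.frame with \code{t_h}, \code{x_um}.
#' @param min_excursion minimum excursion, micrometres (default 10, half a
#'   typical 20 um run).
#' @param smooth_window moving-average width for the centroid (default 3).
#' @return An \code{oscillation_summary}: list with \code{times} (turning
#'   points, h), \code{amplitudes} (um), \code{periods} (h),
#'   \code{ratios} (amplitude over enclosing period, um/h). All empty when
#'   no turning point is found.
#' @export
detect_oscillations <- function(track, min_excursion = 10, smooth_window = 3) {
  validate_track_1d(track)
  x <- smooth_series(track$x_um, smooth_window)
  t <- track$t_h
  ok <- is.finite(x)
  x <- x[ok]; t <- t[ok]
  empty <- structure(list(times = numeric(0), amplitudes = numeric(0),
                          periods = numeric(0), ratios = numeric(0)),
                     class = "oscillation_summary")
  if (length(x) < 3L) return(empty)
  tp <- integer(0)
  dir <- 0L
  ext_i <- 1L       # running extremum index in the current sweep
  for (i in seq_along(x)[-1L]) {
    if (dir == 0L) {
      if (x[i] - min(x[1:i]) >= min_excursion) {
        dir <- 1L; ext_i <- which.min(x[1:i]); tp <- c(tp, ext_i); ext_i <- i
      } else if (max(x[1:i]) - x[i] >= min_excursion) {
        dir <- -1L; ext_i <- which.max(x[1:i]); tp <- c(tp, ext_i); ext_i <- i
      }
    } else if (dir == 1L) {
      if (x[i] > x[ext_i]) ext_i <- i
      if (x[ext_i] - x[i] >= min_excursion) {
        tp <- c(tp, ext_i); dir <- -1L; ext_i <- i
      }
    } else {
      if (x[i] < x[ext_i]) ext_i <- i
      if (x[i] - x[ext_i] >= min_excursion) {
        tp <- c(tp, ext_i); dir <- 1L; ext_i <- i
      }
    }
  }
  if (length(tp) < 2L) return(empty)
  times <- t[tp]
  amp <- abs(diff(x[tp]))
  periods <- if (length(tp) >= 3L) diff(times, lag = 2L) else numeric(0)
  ratios <- if (length(periods) > 0L)
    amp[seq_along(periods)] / periods else numeric(0)
  structure(list(times = times, amplitudes = amp, periods = periods,
                 ratios = ratios),
            class = "oscillation_summary")
}

#' Effective diffusion constant from an MSD curve
#'
#' Least-squares slope of MSD versus time over a window, divided by
#' \code{2 * dim}.
#'
#' @param msd_curve data.frame from \code{\link{msd}} (columns \code{step},
#'   \code{msd}), or any data.frame with those columns.
#' @param window length-2 time range to fit over.
#' @param dim spatial dimension (1 or 2).
#' @return Diffusion constant in (length^2 / step) units of the input.
#' @export
effective_diffusion <- function(msd_curve, window = range(msd_curve$step),
                                dim = 1L) {
  keep <- msd_curve$step >= window[1] & msd_curve$step <= window[2]
  if (sum(keep) < 2L) stop("need at least 2 points in the window", call. = FALSE)
  fit <- stats::lm(msd ~ step, data = msd_curve[keep, ])
  unname(stats::coef(fit)[2L]) / (2 * dim)
}
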