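## Footprint-field kinematics for 1D cell tracks.
##
## A 1D track records, per frame, the cell's left and right edge positions
## and its centroid (micrometres, hours). The footprint field phi(x, t) is
## the cumulative time the cell body has covered position x up to time t;
## cells reading the field at their two ends (phi_l, phi_r) and accelerating
## down the gradient is the kinematic signature of self-attraction.

validate_track_1d <- function(track, need_edges = FALSE) {
  if (!is.data.frame(track) || nrow(track) == 0L)
    stop("track must be a non-empty data.frame", call. = FALSE)
  if (!all(c("t_h", "x_um") %in% names(track)))
    stop("track needs columns 't_h' and 'x_um'", call. = FALSE)
  if (any(diff(track$t_h) <= 0))
    stop("track times must be strictly increasing", call. = FALSE)
  if (need_edges && !all(c("x_left_um", "x_right_um") %in% names(track)))
    stop("track needs edge columns 'x_left_um' and 'x_right_um'", call. = FALSE)
  if (need_edges && any(track$x_left_um > track$x_right_um))
    stop("x_left_um must not exceed x_right_um", call. = FALSE)
  invisible(track)
}

#' Footprint field of a 1D cell track
#'
#' Accumulates the cumulative occupancy time phi(x, t): at each frame
#' interval the elapsed time is deposited into every spatial bin overlapped
#' by the cell body \code{[x_left, x_right]}, in proportion to the overlap
#' fraction. A bin fully inside the cell for the whole track therefore
#' carries phi equal to the track duration. The field satisfies the exact
#' conservation identity \code{sum(phi[, n]) * dx == sum(dt_m * L_m, m <= n)}
#' with \code{L_m} the cell length at frame m (rectangle-rule quadrature of
#' cell length over time).
#'
#' @param track data.frame with columns \code{t_h}, \code{x_um},
#'   \code{x_left_um}, \code{x_right_um} (one cell).
#' @param dx spatial bin width, micrometres (default 2, well below the
#'   ~20 um cell length).
#' @return A \code{footprint_field}: list with \code{grid} (bin centres),
#'   \code{edges} (bin edges), \code{times}, and matrix \code{phi}
#'   (bins x frames), cumulative in time.
#' @export
compute_footprint_field <- function(track, dx = 2) {
  validate_track_1d(track, need_edges = TRUE)
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop("'dx' must be a positive number", call. = FALSE)
  l <- track$x_left_um; r <- track$x_right_um; t <- track$t_h
  ## grid anchored at the track's own midpoint: translating a track
  ## translates the grid with it (shift-invariant phi) and mirroring a track
  ## maps bins onto bins (mirror-symmetric phi)
  mid <- (min(l) + max(r)) / 2
  nb_half <- max(1L, ceiling((max(r) - mid) / dx))
  edges <- mid + dx * (-nb_half:nb_half)
  nb <- length(edges) - 1L
  nf <- length(t)
  phi <- matrix(0, nrow = nb, ncol = nf)
  bin_lo <- edges[-length(edges)]
  bin_hi <- edges[-1]
  acc <- numeric(nb)
  for (m in seq_len(nf)) {
    if (m > 1L) {
      dt <- t[m] - t[m - 1L]
      ov <- pmax(0, pmin(bin_hi, r[m]) - pmax(bin_lo, l[m]))
      acc <- acc + dt * ov / dx
    }
    phi[, m] <- acc
  }
  structure(list(grid = (bin_lo + bin_hi) / 2, edges = edges,
                 times = t, phi = phi, dx = dx),
            class = "footprint_field")
}

## nearest-bin lookup; positions off the grid read as zero (never deposited)
field_value_at <- function(field, x, col) {
  nb <- nrow(field$phi)
  i <- findInterval(x, field$edges, rightmost.closed = TRUE)
  j <- pmin(pmax(i, 1L), nb)
  ifelse(i >= 1L & i <= nb, field$phi[cbind(j, col)], 0)
}

#' Centroid acceleration of a track
#'
#' Second derivative of the (optionally moving-average smoothed) centroid by
#' the three-point central difference, exact for quadratics and valid on
#' irregular time grids. The two endpoints are undefined and returned as NA.
#'
#' @param track data.frame with \code{t_h} and \code{x_um} (>= 3 frames).
#' @param smooth_window odd moving-average width in frames (default 3);
#'   1 disables smoothing.
#' @return Numeric vector of accelerations, um h^-2, same length as the
#'   track, NA at the ends (and wherever smoothing is undefined).
#' @export
centroid_acceleration <- function(track, smooth_window = 3) {
  validate_track_1d(track)
  if (nrow(track) < 3L) stop("need at least 3 frames", call. = FALSE)
  x <- smooth_series(track$x_um, smooth_window)
  t <- track$t_h
  n <- length(x)
  a <- rep(NA_real_, n)
  i <- 2:(n - 1L)
  dtm <- t[i] - t[i - 1L]
  dtp <- t[i + 1L] - t[i]
  a[i] <- 2 * (x[i - 1L] * dtp - x[i] * (dtm + dtp) + x[i + 1L] * dtm) /
    (dtm * dtp * (dtm + dtp))
  a
}

## centred moving average; NA at the ends where the window is incomplete
smooth_series <- function(x, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("'smooth_window' must be a positive odd integer", call. = FALSE)
  if (window == 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
}

#' Footprint values at the two cell ends, with centroid acceleration
#'
#' For every frame, evaluates the footprint field (nearest bin) at the
#' cell's left and right edge positions, using the field accumulated
#' strictly before that frame — the occupancy deposited during the current
#' frame interval cannot causally influence its own acceleration reading.
#' The first frame therefore reads phi_l = phi_r = 0.
#'
#' @param field a \code{\link{compute_footprint_field}} result.
#' @param track the same track the field was computed from.
#' @param smooth_window passed to \code{\link{centroid_acceleration}}.
#' @return data.frame with columns \code{t_h}, \code{phi_l}, \code{phi_r},
#'   \code{dphi} (= phi_r - phi_l) and \code{a} (um h^-2, NA at endpoints).
#' @export
sample_edge_footprints <- function(field, track, smooth_window = 3) {
  validate_track_1d(track, need_edges = TRUE)
  if (!inherits(field, "footprint_field"))
    stop("'field' must be a footprint_field", call. = FALSE)
  if (length(field$times) != nrow(track) ||
      max(abs(field$times - track$t_h)) > 1e-9)
    stop("field and track must share the time axis", call. = FALSE)
  nf <- nrow(track)
  prev <- pmax(seq_len(nf) - 1L, 1L)
  phi_l <- field_value_at(field, track$x_left_um, prev)
  phi_r <- field_value_at(field, track$x_right_um, prev)
  phi_l[1L] <- 0; phi_r[1L] <- 0
  a <- if (nf >= 3L) centroid_acceleration(track, smooth_window) else rep(NA_real_, nf)
  data.frame(t_h = track$t_h, phi_l = phi_l, phi_r = phi_r,
             dphi = phi_r - phi_l, a = a)
}

#' Mean acceleration binned over (phi_l, phi_r)
#'
#' Pools edge-footprint samples from one or many cells and bins the
#' acceleration over the (phi_l, phi_r) plane. Bins that receive no sample
#' are reported as NA (missing), not zero.
#'
#' @param samples data.frame with columns \code{phi_l}, \code{phi_r},
#'   \code{a} (rows with NA acceleration are dropped), e.g. row-bound
#'   outputs of \code{\link{sample_edge_footprints}}.
#' @param bin_width bin width in hours (default 2).
#' @param breaks optional explicit bin edges (overrides \code{bin_width}).
#' @return An \code{accel_heatmap}: list with \code{breaks}, matrix
#'   \code{mean_a} (phi_l bins x phi_r bins) and matrix \code{count}.
#' @export
acceleration_heatmap <- function(samples, bin_width = 2, breaks = NULL) {
  keep <- stats::complete.cases(samples[, c("phi_l", "phi_r", "a")])
  s <- samples[keep, , drop = FALSE]
  if (is.null(breaks)) {
    top <- max(s$phi_l, s$phi_r, 0) + bin_width
    breaks <- seq(0, top, by = bin_width)
  }
  il <- cut(s$phi_l, breaks, include.lowest = TRUE, labels = FALSE)
  ir <- cut(s$phi_r, breaks, include.lowest = TRUE, labels = FALSE)
  nb <- length(breaks) - 1L
  cnt <- matrix(0L, nb, nb)
  sum_a <- matrix(0, nb, nb)
  ok <- !is.na(il) & !is.na(ir)
  for (j in which(ok)) {
    cnt[il[j], ir[j]] <- cnt[il[j], ir[j]] + 1L
    sum_a[il[j], ir[j]] <- sum_a[il[j], ir[j]] + s$a[j]
  }
  mean_a <- ifelse(cnt > 0L, sum_a / pmax(cnt, 1L), NA_real_)
  structure(list(breaks = breaks, mean_a = mean_a, count = cnt,
                 n_samples = sum(ok)),
            class = "accel_heatmap")
}
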