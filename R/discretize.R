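## Discretisation of continuous 1D tracks onto lattice hop sequences and
## per-cell inference of (k, beta) from conditional reversal frequencies.

#' Discretise a continuous 1D track onto lattice sites
#'
#' Maps the centroid onto the integer grid \code{X = floor(x / L_ref + 0.5)}
#' and extracts the sequence of unit hopping events. Within each frame
#' interval the centroid is taken as linear, so hop times are found by
#' interpolating the crossings of the site boundaries
#' \code{(s + 1/2) * L_ref}; a frame-to-frame change of several sites is
#' split into unit hops with interpolated times.
#'
#' @param track data.frame with \code{t_h} and \code{x_um} (one cell).
#' @param L_ref discretisation length, micrometres (> 0); typically the
#'   cell length, see \code{\link{choose_Lref}}.
#' @param hysteresis_um debouncing margin, micrometres: a hop is registered
#'   only once the centroid passes the site boundary by this much, so
#'   positional noise hovering at a boundary does not spawn spurious
#'   back-and-forth hops. 0 (the default) reduces exactly to the plain
#'   grid rule; the inference pipeline (\code{\link{fit_cells}}) uses a
#'   margin of a few times the positional noise. Must be below
#'   \code{L_ref / 2}.
#' @return A \code{discrete_trajectory}: list with \code{X} (site sequence,
#'   consecutive entries differing by exactly 1), \code{T_hop} (hop times,
#'   hours, one per hop), \code{t_jump} (jump durations between successive
#'   hops, \code{diff(T_hop)}), \code{L_ref}.
#' @export
discretise <- function(track, L_ref, hysteresis_um = 0) {
  validate_track_1d(track)
  if (!is.numeric(L_ref) || length(L_ref) != 1L || !is.finite(L_ref) || L_ref <= 0)
    stop("'L_ref' must be a positive length", call. = FALSE)
  if (!is.numeric(hysteresis_um) || length(hysteresis_um) != 1L ||
      !is.finite(hysteresis_um) || hysteresis_um < 0 ||
      hysteresis_um >= L_ref / 2)
    stop("'hysteresis_um' must lie in [0, L_ref / 2)", call. = FALSE)
  x <- track$x_um
  t <- track$t_h
  delta <- hysteresis_um
  nf <- length(x)
  X <- integer(nf * 4L)          # grown if ever needed
  T_hop <- numeric(nf * 4L)
  s <- floor(x[1L] / L_ref + 0.5)
  X[1L] <- s
  h <- 0L
  up <- (s + 0.5) * L_ref + delta
  dn <- (s - 0.5) * L_ref - delta
  for (j in seq_len(nf)[-1L]) {
    xj <- x[j]
    while (xj >= up || xj < dn) {
      step <- if (xj >= up) 1L else -1L
      ## hop time: crossing of the plain boundary (s +/- 1/2) L_ref; with a
      ## margin the trigger segment may postdate the crossing, so walk back
      ## to the segment that straddles the boundary
      xb <- (s + 0.5 * step) * L_ref
      jj <- j
      if (step > 0L) {
        while (jj > 2L && x[jj - 1L] >= xb) jj <- jj - 1L
      } else {
        while (jj > 2L && x[jj - 1L] <= xb) jj <- jj - 1L
      }
      tb <- t[jj - 1L] + (t[jj] - t[jj - 1L]) *
        (xb - x[jj - 1L]) / (x[jj] - x[jj - 1L])
      h <- h + 1L
      if (h + 1L > length(X)) {
        X <- c(X, integer(length(X)))
        T_hop <- c(T_hop, numeric(length(T_hop)))
      }
      s <- s + step
      X[h + 1L] <- s
      T_hop[h] <- if (h > 1L) max(tb, T_hop[h - 1L] + 1e-9) else tb
      up <- (s + 0.5) * L_ref + delta
      dn <- (s - 0.5) * L_ref - delta
    }
  }
  n_hops <- h
  X <- X[seq_len(n_hops + 1L)]
  T_hop <- T_hop[seq_len(n_hops)]
  structure(list(X = X, T_hop = T_hop, t_jump = diff(T_hop),
                 L_ref = L_ref),
            class = "discrete_trajectory")
}

#' Reference length for discretisation
#'
#' The cell-specific typical length: the median instantaneous cell length
#' \code{x_right - x_left} over the track.
#'
#' @param track data.frame with edge columns \code{x_left_um},
#'   \code{x_right_um}.
#' @return Length in micrometres.
#' @export
choose_Lref <- function(track) {
  if (!all(c("x_left_um", "x_right_um") %in% names(track)))
    stop("track has no edge columns; supply L_ref explicitly", call. = FALSE)
  stats::median(track$x_right_um - track$x_left_um)
}

#' Conditional reversal counts of a discrete trajectory
#'
#' Classifies every hop after the first by the state of the site ahead in
#' the incoming direction: if that site had already been visited earlier in
#' the discrete path the hop is an interior step, otherwise an edge step.
#' A reversal is a hop opposite to the previous hop. Visit history starts
#' at the path's first site (no prior history is assumed).
#'
#' @param dtraj a \code{\link{discretise}} result with >= 2 hops.
#' @return List with counts \code{n_interior}, \code{n_edge},
#'   \code{n_rev_interior}, \code{n_rev_edge} and raw frequencies
#'   \code{p_ri_hat}, \code{p_re_hat} (NaN when a class is empty).
#' @export
classify_and_count <- function(dtraj) {
  if (!inherits(dtraj, "discrete_trajectory"))
    stop("'dtraj' must be a discrete_trajectory", call. = FALSE)
  X <- dtraj$X
  n_hops <- length(X) - 1L
  if (n_hops < 2L)
    stop("need at least 2 hops to classify reversals", call. = FALSE)
  d <- diff(X)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  assign(as.character(X[1L]), TRUE, envir = visited)
  n_int <- n_edg <- r_int <- r_edg <- 0L
  for (j in seq_len(n_hops)) {
    if (j >= 2L) {
      ahead <- X[j] + d[j - 1L]
      edge <- !exists(as.character(ahead), envir = visited, inherits = FALSE)
      rev <- d[j] != d[j - 1L]
      if (edge) {
        n_edg <- n_edg + 1L
        if (rev) r_edg <- r_edg + 1L
      } else {
        n_int <- n_int + 1L
        if (rev) r_int <- r_int + 1L
      }
    }
    assign(as.character(X[j + 1L]), TRUE, envir = visited)
  }
  list(n_interior = n_int, n_edge = n_edg,
       n_rev_interior = r_int, n_rev_edge = r_edg,
       p_ri_hat = if (n_int > 0L) r_int / n_int else NaN,
       p_re_hat = if (n_edg > 0L) r_edg / n_edg else NaN)
}

#' Invert reversal frequencies into (k, beta)
#'
#' Algebraic inverse of the forward reversal probabilities
#' \code{\link{reversal_prob_interior}} and \code{\link{reversal_prob_edge}}:
#' \code{k = log((1 - p_ri) / p_ri) / 2} and
#' \code{beta = log((1 - p_re) / p_re) - 2 k}.
#'
#' @param p_ri interior reversal frequency, in (0, 1).
#' @param p_re edge reversal frequency, in (0, 1).
#' @return List with \code{k} and \code{beta}.
#' @export
invert_params <- function(p_ri, p_re) {
  if (any(!is.finite(c(p_ri, p_re))) || p_ri <= 0 || p_ri >= 1 ||
      p_re <= 0 || p_re >= 1)
    stop("frequencies must lie strictly inside (0, 1); ",
         "apply a pseudocount for degenerate counts", call. = FALSE)
  k <- 0.5 * log((1 - p_ri) / p_ri)
  beta <- log((1 - p_re) / p_re) - 2 * k
  list(k = k, beta = beta)
}

## Agresti-style +1/2 pseudocount keeps the inversion finite when a class
## has 0 or 100% reversals on a short track.
shrunk_freq <- function(rev, n) (rev + 0.5) / (n + 1)

#' Fit (k, beta) per cell from continuous tracks
#'
#' Full inference pipeline: per cell, choose the discretisation length
#' (median cell length unless \code{L_ref} is given), discretise the
#' centroid, count conditional reversal frequencies, and invert them into
#' the per-cell estimates. Degenerate frequencies (0 or 1, or an empty
#' class) are replaced by the +1/2 pseudocount frequency and flagged.
#'
#' @param tracks long data.frame in the track-table format (see
#'   \code{\link{read_tracks}}) with one or more \code{cell_id} values.
#' @param L_ref optional fixed discretisation length for all cells;
#'   default picks \code{\link{choose_Lref}} per cell.
#' @param hysteresis_um debouncing margin for \code{\link{discretise}}
#'   (default 2 um, a few times the typical positional noise).
#' @return data.frame with one row per cell: \code{cell_id}, \code{L_ref},
#'   \code{n_interior}, \code{n_edge}, \code{p_ri_hat}, \code{p_re_hat},
#'   \code{k_hat}, \code{beta_hat}, \code{flag} ("" or "pseudocount";
#'   "too_short" rows carry NA estimates).
#' @export
fit_cells <- function(tracks, L_ref = NULL, hysteresis_um = 2) {
  if (!all(c("cell_id", "t_h", "x_um") %in% names(tracks)))
    stop("'tracks' must have columns cell_id, t_h, x_um", call. = FALSE)
  rows <- lapply(split(tracks, tracks$cell_id), function(tr) {
    tr <- tr[order(tr$t_h), , drop = FALSE]
    L <- if (is.null(L_ref)) choose_Lref(tr) else L_ref
    id <- as.character(tr$cell_id[1L])
    base <- data.frame(cell_id = id, L_ref = L, n_interior = NA_integer_,
                       n_edge = NA_integer_, p_ri_hat = NA_real_,
                       p_re_hat = NA_real_, k_hat = NA_real_,
                       beta_hat = NA_real_, flag = "too_short",
                       stringsAsFactors = FALSE)
    dt <- discretise(tr, L, hysteresis_um = min(hysteresis_um, L * 0.49))
    if (length(dt$X) < 3L) return(base)
    cc <- classify_and_count(dt)
    p_ri <- cc$p_ri_hat; p_re <- cc$p_re_hat
    flag <- ""
    if (!is.finite(p_ri) || p_ri <= 0 || p_ri >= 1) {
      p_ri <- shrunk_freq(cc$n_rev_interior, cc$n_interior); flag <- "pseudocount"
    }
    if (!is.finite(p_re) || p_re <= 0 || p_re >= 1) {
      p_re <- shrunk_freq(cc$n_rev_edge, cc$n_edge); flag <- "pseudocount"
    }
    if (!is.finite(p_ri) || !is.finite(p_re)) return(base)
    est <- invert_params(p_ri, p_re)
    data.frame(cell_id = id, L_ref = L, n_interior = cc$n_interior,
               n_edge = cc$n_edge, p_ri_hat = p_ri, p_re_hat = p_re,
               k_hat = est$k, beta_hat = est$beta, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
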