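## Track-table CSV format and run configuration.
##
## A track table is a CSV with header and columns cell_id, t_h, and x_um
## (1D) or x_um + y_um (2D); optional edge columns x_left_um, x_right_um.
## Units are fixed by the column names (hours, micrometres).

track_cols <- c("cell_id", "t_h", "x_um", "y_um", "x_left_um", "x_right_um")

#' Read a track-table CSV
#'
#' Validates the file: required columns present, per-cell times strictly
#' increasing, left edge never beyond right edge. Validation errors name
#' the offending cell and row.
#'
#' @param path CSV file path.
#' @return data.frame sorted by \code{cell_id} then \code{t_h}, one row
#'   per frame. Split by \code{cell_id} to get per-cell tracks.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tracks(df)
}

#' Validate an in-memory track table
#' @param df data.frame in the track-table layout.
#' @return The validated data.frame, sorted by cell and time.
#' @export
validate_tracks <- function(df) {
  need <- c("cell_id", "t_h", "x_um")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("track table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$cell_id, df$t_h), , drop = FALSE]
  rownames(df) <- NULL
  for (id in unique(df$cell_id)) {
    rows <- which(df$cell_id == id)
    tt <- df$t_h[rows]
    bad <- which(diff(tt) <= 0)
    if (length(bad) > 0L)
      stop(sprintf("cell '%s': time not strictly increasing at row %d",
                   id, rows[bad[1L] + 1L]), call. = FALSE)
    if (all(c("x_left_um", "x_right_um") %in% names(df))) {
      wrong <- rows[df$x_left_um[rows] > df$x_right_um[rows]]
      if (length(wrong) > 0L)
        stop(sprintf("cell '%s': x_left_um > x_right_um at row %d",
                     id, wrong[1L]), call. = FALSE)
    }
  }
  df
}

#' Write a track-table CSV
#'
#' Deterministic column order and 10-significant-digit float formatting, so
#' a write/read round trip reproduces values to better than 1e-9 relative.
#'
#' @param df track table (see \code{\link{read_tracks}}).
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_tracks <- function(df, path) {
  cols <- intersect(track_cols, names(df))
  if (!all(c("cell_id", "t_h", "x_um") %in% cols) && nrow(df) > 0L)
    stop("track table needs cell_id, t_h, x_um", call. = FALSE)
  if (nrow(df) == 0L) {
    writeLines(paste(if (length(cols)) cols else c("cell_id", "t_h", "x_um"),
                     collapse = ","), path)
    return(invisible(path))
  }
  out <- df[, cols, drop = FALSE]
  for (nm in setdiff(cols, "cell_id"))
    out[[nm]] <- sprintf("%.10g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## default run configuration: one section per pipeline stage
default_config <- function() {
  list(
    model = list(k = 0, beta = 0, dim = 1, n_steps = 1000, n_walkers = 1),
    discretisation = list(L_ref = NULL, smooth_window = 3),
    statistics = list(window = NULL, s_range = c(1e-3, 1e-1),
                      min_excursion = 10, msd_squared = TRUE),
    synthesis = list(preset = "control", n_cells = 100, duration_h = 90),
    seed = 1
  )
}

#' Resolve a nested run configuration
#'
#' Merges user settings over the package defaults, rejecting unknown keys
#' at either level; every run driven by \code{\link{satwalk_cli}} logs the
#' resolved configuration so results are reproducible from the manifest
#' alone.
#'
#' @param config nested named list (sections \code{model},
#'   \code{discretisation}, \code{statistics}, \code{synthesis},
#'   \code{seed}).
#' @return The resolved configuration list.
#' @export
resolve_config <- function(config = list()) {
  base <- default_config()
  if (length(config) == 0L) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0L)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    if (is.list(base[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(base[[sec]]))
      if (length(bad) > 0L)
        stop(sprintf("unknown key(s) in section '%s': %s", sec,
                     paste(bad, collapse = ", ")), call. = FALSE)
      base[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      base[[sec]] <- config[[sec]]
    }
  }
  base
}
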