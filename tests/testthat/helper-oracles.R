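# Independent oracles and small fixture builders used across the suite.

# Exhaustive enumeration of the 1D persistent self-attracting walk: walks
# every direction sequence of length n_steps with its exact probability,
# written directly from the model's two reversal rules (independent of the
# package's simulator). Returns the exact distribution of a path statistic.
enumerate_psatw <- function(k, beta, n_steps, stat = function(path) path[length(path)]) {
  p_ri <- exp(-k) / (exp(-k) + exp(k))
  p_re <- exp(-k - beta) / (exp(-k - beta) + exp(k))
  acc <- new.env(parent = emptyenv())
  tally <- function(key, p) {
    key <- as.character(key)
    old <- if (exists(key, envir = acc, inherits = FALSE))
      get(key, envir = acc) else 0
    assign(key, old + p, envir = acc)
  }
  recurse <- function(path, dir, visited, prob) {
    if (length(path) == n_steps + 1L) {
      tally(stat(path), prob)
      return(invisible())
    }
    pos <- path[length(path)]
    edge <- !((pos + dir) %in% visited)
    p_rev <- if (edge) p_re else p_ri
    for (nd in c(dir, -dir)) {
      p <- if (nd == dir) 1 - p_rev else p_rev
      npos <- pos + nd
      recurse(c(path, npos), nd, union(visited, npos), prob * p)
    }
  }
  for (d0 in c(1L, -1L)) recurse(0L, d0, 0L, 0.5)
  vals <- as.list(acc)
  p <- unlist(vals)
  p[order(as.numeric(names(p)))]
}

# Wrap a unit-hop lattice site sequence as a discrete trajectory (hop times
# taken as the step index), bypassing the continuous rendering.
lattice_as_discrete <- function(sites) {
  keep <- c(TRUE, diff(sites) != 0)
  X <- sites[keep]
  structure(list(X = X, T_hop = seq_along(X)[-1L],
                 t_jump = rep(1, length(X) - 2L), L_ref = 1),
            class = "discrete_trajectory")
}

# Minimal 1D track builder with a constant cell length.
make_track <- function(t_h, x_um, length_um = 20, cell_id = "c1") {
  data.frame(cell_id = cell_id, t_h = t_h, x_um = x_um,
             x_left_um = x_um - length_um / 2,
             x_right_um = x_um + length_um / 2,
             stringsAsFactors = FALSE)
}
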