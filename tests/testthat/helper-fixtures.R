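# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk.

# Temperature map with a vertical ridge: T = peak - slope * |col - axis|,
# constant along rows. The exact isotherm of value v on the right side is
# the column axis + (peak - v) / slope.
ridge_map <- function(rows = 20L, cols = 65L, axis_col = 32L, peak = 60,
                      slope = 2, baseline = 21) {
  vals <- matrix(0, rows, cols)
  for (c0 in seq_len(cols) - 1L)
    vals[, c0 + 1L] <- peak - slope * abs(c0 - axis_col)
  temperature_map(vals, slice_frame(0, c(rows, cols), 1,
                                    axis_column = axis_col),
                  baseline_T0 = baseline)
}

# Radial-profile map: T = baseline + amp * exp(-r^2 / (2 sigma^2)) with
# r the lateral distance to the axis column (constant along rows). The
# analytic radius of isovalue v is sigma * sqrt(2 log(amp / (v -
# baseline))).
radial_map <- function(rows = 40L, cols = 65L, axis_col = 32L, amp = 60,
                       sigma = 8, baseline = 21, noise_sd = 0) {
  r <- abs(seq_len(cols) - 1L - axis_col)
  prof <- baseline + amp * exp(-r^2 / (2 * sigma^2))
  vals <- matrix(rep(prof, each = rows), rows, cols)
  if (noise_sd > 0) vals <- vals + rnorm(length(vals), 0, noise_sd)
  temperature_map(vals, slice_frame(0, c(rows, cols), 1,
                                    axis_column = axis_col),
                  baseline_T0 = baseline)
}

radial_isovalue_radius <- function(v, amp = 60, sigma = 8, baseline = 21) {
  sigma * sqrt(2 * log(amp / (v - baseline)))
}

# Exhaustive enumeration of all monotone paths (one vertex per row,
# lateral step <= connectivity) on a small cost grid; the brute-force
# oracle for the shortest-path isotherm filter.
brute_force_min_path <- function(costs, connectivity = 1L) {
  nr <- nrow(costs); nc <- ncol(costs)
  best <- Inf
  recurse <- function(r, col, acc) {
    acc <- acc + costs[r, col]
    if (acc >= best) return()
    if (r == nr) { best <<- acc; return() }
    for (nxt in seq(col - connectivity, col + connectivity))
      if (nxt >= 1 && nxt <= nc) recurse(r + 1L, nxt, acc)
  }
  for (start in seq_len(nc)) recurse(1L, start, 0)
  best
}

# Hand-built isotherm set with prescribed radial distances per row
# (right side), for exercising the axial source profile without running
# the extractor.
synthetic_iso_set <- function(radii_by_row, axis_col = 5L, isovalue = 30,
                              ps = 1) {
  nr <- length(radii_by_row)
  frame <- slice_frame(0, c(nr, 2L * axis_col + 1L), ps,
                       axis_column = axis_col)
  iso <- structure(list(isovalue = isovalue, side = "right",
                        vertices = data.frame(
                          row = seq_len(nr) - 1L,
                          col = axis_col + radii_by_row / ps),
                        total_cost = 0, extrapolated = FALSE),
                   class = "isotherm")
  structure(list(isotherms = list(iso), isovalues = isovalue,
                 frame = frame, time_index = 0L), class = "isotherm_set")
}

# Small, fast phantom for pipeline-level tests.
tiny_phantom_spec <- function(seed = 1L, ...) {
  args <- modifyList(list(n_timepoints = 4L, acquisition_interval = 2,
                          grid = volume_grid(c(30L, 30L, 30L), 1),
                          axial_half_length = 8, noise_sigma = 0.5,
                          seed = seed), list(...))
  do.call(phantom_spec, args)
}
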