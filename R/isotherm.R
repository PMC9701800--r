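#' Relative-temperature cost map
#'
#' Per-pixel absolute deviation `|T - isovalue|` between the measured
#' temperature and a temperature isovalue. Pixels outside the valid mask
#' get infinite cost so the path finder never crosses them while the
#' one-vertex-per-row structure is preserved.
#'
#' @param map a [temperature_map()].
#' @param isovalue temperature of interest, degrees C.
#' @return An object of class `cost_map` with elements `values` (the cost
#'   grid), `isovalue`, and `max_valid_T` (largest valid temperature, used
#'   to flag extrapolated isotherms).
#' @export
cost_map <- function(map, isovalue) {
  stopifnot(inherits(map, "temperature_map"), is.finite(isovalue))
  costs <- abs(map$values - isovalue)
  costs[!map$valid_mask] <- Inf
  costs[is.na(costs)] <- Inf
  structure(list(values = costs, isovalue = isovalue,
                 axis_column = map$frame$axis_column,
                 max_valid_T = suppressWarnings(
                   max(map$values[map$valid_mask], -Inf))),
            class = "cost_map")
}

# Monotone minimum-cost path through a cost matrix: exactly one vertex per
# row, consecutive columns differ by at most `connectivity`, node-weighted
# costs, virtual zero-cost source/sink. Ties broken toward the smallest
# column; costs within `tie_tol` count as tied, so float round-off in
# analytically flat regions cannot steer the path. Returns 1-based column
# index per row plus the total cost.
monotone_path <- function(costs, connectivity = 1L, tie_tol = 1e-9) {
  nr <- nrow(costs); nc <- ncol(costs)
  if (any(apply(is.finite(costs), 1L, sum) == 0L))
    stop("no valid pixel in at least one image row", call. = FALSE)
  dp <- costs[1L, ]
  prev <- matrix(0L, nr, nc)
  shifts <- seq.int(-connectivity, connectivity)   # predecessor col offsets
  for (r in seq_len(nr)[-1L]) {
    best <- rep(Inf, nc)
    arg <- rep(NA_integer_, nc)
    for (s in shifts) {                 # ascending: smaller pred col wins ties
      from <- seq_len(nc) + s
      ok <- from >= 1L & from <= nc
      cand <- rep(Inf, nc)
      cand[ok] <- dp[from[ok]]
      take <- is.finite(cand) & cand < best - tie_tol
      best[take] <- cand[take]
      arg[take] <- from[take]
    }
    dp <- best + costs[r, ]
    prev[r, ] <- arg
  }
  fin <- which(dp <= min(dp) + tie_tol)
  end <- if (length(fin)) fin[1L] else which.min(dp)
  if (!is.finite(dp[end]))
    stop("no finite-cost monotone path exists", call. = FALSE)
  path <- integer(nr)
  path[nr] <- end
  for (r in rev(seq_len(nr))[-1L]) path[r] <- prev[r + 1L, path[r + 1L]]
  list(cols = path, total_cost = dp[end])
}

#' Extract one isotherm as an axis-aligned monotone shortest path
#'
#' Finds the minimum-total-cost path through the cost map on one side of
#' the applicator axis, forced in the direction of the needle axis: the
#' path visits every image row exactly once (top to bottom between virtual
#' zero-cost source and sink) and may drift laterally by at most
#' `connectivity` columns per row. Summing signed temperature deviations
#' along the whole path averages out pixel noise, so the extracted contour
#' is far more stable than per-row thresholding; isolated outliers cost
#' too much to attract the path.
#'
#' @param costs a [cost_map()].
#' @param axis_column 0-based axis column separating the two sides.
#' @param side `"left"` or `"right"` of the axis.
#' @param connectivity maximum lateral step per row, pixels.
#' @return An object of class `isotherm`: `isovalue`, `side`, `vertices`
#'   (data.frame of 0-based `row`, `col`), `total_cost`, and
#'   `extrapolated` (TRUE when the isovalue exceeds every valid
#'   temperature, i.e. the path hugs the hottest ridge).
#' @export
extract_isotherm <- function(costs, axis_column = costs$axis_column,
                             side = c("right", "left"), connectivity = 1L) {
  stopifnot(inherits(costs, "cost_map"), connectivity >= 1)
  side <- match.arg(side)
  nc <- ncol(costs$values)
  cols0 <- seq_len(nc) - 1L                        # 0-based
  keep <- if (side == "right") cols0 > axis_column else cols0 < axis_column
  if (!any(keep))
    stop("no columns on the requested side of the axis", call. = FALSE)
  # order columns axis-outward so the deterministic tie-break prefers the
  # axis-nearest pixel symmetrically on both sides
  ord <- if (side == "right") which(keep) else rev(which(keep))
  sub <- costs$values[, ord, drop = FALSE]
  p <- monotone_path(sub, as.integer(connectivity))
  full_cols <- cols0[ord][p$cols]
  structure(list(isovalue = costs$isovalue, side = side,
                 vertices = data.frame(row = seq_len(nrow(sub)) - 1L,
                                       col = full_cols),
                 total_cost = p$total_cost,
                 extrapolated = costs$isovalue > costs$max_valid_T),
            class = "isotherm")
}

#' Extract the full isotherm set of a temperature map
#'
#' Runs [extract_isotherm()] for every isovalue on both sides of the axis
#' (the two half-images are treated as separate isotherm instances, so a
#' set of M isovalues yields up to 2M polylines). A side on which no valid
#' path exists (e.g. fully dropped-out data) is skipped with a warning;
#' extraction fails only when no isotherm can be recovered at all.
#'
#' @param map a [temperature_map()].
#' @param isovalues strictly increasing temperatures, degrees C.
#' @param axis_column 0-based axis column; defaults to the frame's.
#' @param connectivity lateral step bound per row, pixels.
#' @return An object of class `isotherm_set` with elements `isotherms`
#'   (list of [extract_isotherm()] results), `isovalues`, `frame`, and
#'   `time_index`.
#' @export
extract_isotherm_set <- function(map, isovalues,
                                 axis_column = map$frame$axis_column,
                                 connectivity = 1L) {
  stopifnot(inherits(map, "temperature_map"), length(isovalues) >= 1)
  if (is.unsorted(isovalues, strictly = TRUE))
    stop("isovalues must be strictly increasing", call. = FALSE)
  isos <- list()
  failed <- character(0)
  for (side in c("left", "right")) {
    for (v in isovalues) {
      res <- tryCatch(
        extract_isotherm(cost_map(map, v), axis_column, side, connectivity),
        error = function(e) NULL)
      if (is.null(res)) {
        failed <- union(failed, side)
      } else {
        # measured temperature at each vertex: the "real temperatures"
        # the inverse fit compares the simulation against
        res$vertices$value <- map$values[cbind(res$vertices$row + 1L,
                                               res$vertices$col + 1L)]
        isos[[length(isos) + 1L]] <- res
      }
    }
  }
  if (length(isos) == 0L)
    stop("no valid isotherm data on either side of the axis", call. = FALSE)
  if (length(failed))
    warning("no valid isotherm path on side: ",
            paste(failed, collapse = ", "), call. = FALSE)
  structure(list(isotherms = isos, isovalues = isovalues, frame = map$frame,
                 time_index = map$time_index), class = "isotherm_set")
}

#' Default isovalue ladder
#'
#' Uniformly spaced isovalues spanning `span` degrees C anchored at the
#' baseline temperature (the anchor is configurable through `anchor`);
#' with the defaults, a baseline of 21 gives 21, 24.43, ..., 45 degrees C
#' in steps of 24/7.
#'
#' @param baseline_T0 baseline temperature, degrees C.
#' @param span ladder range, degrees C.
#' @param count number of isovalues M.
#' @param anchor lowest isovalue; defaults to `baseline_T0`.
#' @return Numeric vector of `count` isovalues.
#' @export
default_isovalues <- function(baseline_T0, span = 24, count = 8L,
                              anchor = baseline_T0) {
  if (count < 1) stop("count must be >= 1", call. = FALSE)
  if (span <= 0) stop("span must be positive", call. = FALSE)
  if (count == 1L) return(anchor)
  anchor + seq(0, span, length.out = count)
}

#' Serialize an isotherm set to CSV
#'
#' One row per vertex: isovalue, side, row, col.
#' @param set an [extract_isotherm_set()] result.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_isotherms <- function(set, file) {
  stopifnot(inherits(set, "isotherm_set"))
  rows <- do.call(rbind, lapply(set$isotherms, function(it)
    data.frame(isovalue = it$isovalue, side = it$side,
               row = it$vertices$row, col = it$vertices$col)))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
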