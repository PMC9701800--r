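#' Threshold a temperature volume into a binary coagulation mask
#'
#' Coagulation necrosis is approximated by `T >= threshold`; thresholds
#' are conventionally chosen in `[50, 60]` degrees C per phantom (a
#' warning is issued outside that range in global mode).
#'
#' @param volume 3D temperature array (or a [solver_state()]).
#' @param threshold degrees C.
#' @param mode `"global"` (one threshold per phantom) or `"median"`
#'   (median of per-orientation best thresholds, see
#'   [median_threshold()]).
#' @return An object of class `necrosis_mask`.
#' @export
necrosis_mask <- function(volume, threshold, mode = c("global", "median")) {
  mode <- match.arg(mode)
  if (inherits(volume, "solver_state")) volume <- volume$field
  if (any(!is.finite(volume)))
    stop("non-finite temperatures in volume", call. = FALSE)
  if (mode == "global" && (threshold < 50 || threshold > 60))
    warning("necrosis threshold outside the conventional [50, 60] C range",
            call. = FALSE)
  structure(list(mask = volume >= threshold, threshold = threshold,
                 mode = mode), class = "necrosis_mask")
}

#' Median of per-orientation best thresholds
#'
#' @param per_orientation_best numeric vector of thresholds, degrees C
#'   (one per orientation).
#' @return Their median (mean of the middle two for even counts).
#' @export
median_threshold <- function(per_orientation_best) {
  if (length(per_orientation_best) < 1L)
    stop("at least one threshold required", call. = FALSE)
  median(per_orientation_best)
}

#' Dice similarity between two binary masks
#'
#' `2 TP / (2 TP + FP + FN)`; two empty masks are defined as identical
#' (score 1).
#'
#' @param a,b [necrosis_mask()] objects or logical arrays of equal shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (inherits(a, "necrosis_mask")) a <- a$mask
  if (inherits(b, "necrosis_mask")) b <- b$mask
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  tp <- sum(a & b)
  denom <- 2 * tp + sum(a & !b) + sum(!a & b)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Sample standard deviation and 95% standard error of the mean
#'
#' `sigma = sqrt(sum((x - mean)^2) / (n - 1))` and
#' `sem_95 = sigma / sqrt(n) * 1.96` (1.96 approximating the 97.5th
#' percentile of the standard normal).
#'
#' @param samples numeric vector, length >= 2.
#' @return List with `sigma` and `sem_95`.
#' @export
sem_ci <- function(samples) {
  n <- length(samples)
  if (n < 2L) stop("at least two samples required", call. = FALSE)
  sigma <- sd(samples)
  list(sigma = sigma, sem_95 = sigma / sqrt(n) * 1.96)
}

# Best 2D threshold for one orientation: the tau in [50, 60] (0.5 C
# steps) maximizing the 2D Dice between the thresholded simulated slice
# and the thresholded measured map.
best_threshold_2d <- function(sim_slice, measured, valid,
                              grid_tau = seq(50, 60, by = 0.5)) {
  scores <- vapply(grid_tau, function(tau) {
    a <- sim_slice >= tau & valid
    b <- measured >= tau & valid
    tp <- sum(a & b); denom <- 2 * tp + sum(xor(a, b))
    if (denom == 0) 1 else 2 * tp / denom
  }, numeric(1L))
  grid_tau[which.max(scores)]
}

#' Median-mode necrosis threshold from the final map of each orientation
#'
#' For every orientation the final acquired map is compared with the
#' reconstructed volume resampled onto that frame; the threshold in
#' `[50, 60]` degrees C (0.5 steps) maximizing their 2D Dice is selected,
#' and the median over orientations is returned.
#'
#' @param state final reconstructed [solver_state()].
#' @param series list of [temperature_map()] objects.
#' @return Median threshold, degrees C.
#' @export
median_mode_threshold <- function(state, series) {
  angles <- vapply(series, function(m) m$frame$angle, numeric(1L))
  best <- vapply(unique(angles), function(a) {
    m <- series[[max(which(angles == a))]]       # latest map per angle
    px <- as.matrix(expand.grid(row = seq_len(m$frame$matrix[1L]) - 1L,
                                col = seq_len(m$frame$matrix[2L]) - 1L))
    sim <- matrix(sample_volume(state$field, state$grid,
                                slice_to_world(m$frame, px),
                                outside_value = state$boundary_T),
                  m$frame$matrix[1L], m$frame$matrix[2L])
    best_threshold_2d(sim, m$values, m$valid_mask)
  }, numeric(1L))
  median_threshold(best)
}

#' Robustness test configuration
#'
#' The evaluation protocol varies, on one hand, the amount of real-time
#' data (orientation subsets, configs 1-5) and, on the other hand, the a
#' priori knowledge about the parameters (configs 6-7): config 1 =
#' (0, 22.5, 45, 67.5), config 2 = (90, 112.5, 135, 157.5), config 3 =
#' (0, 22.5), config 4 = (90), config 5 = (22.5) degrees; config 6 =
#' unrestricted search ranges `[0.1, 1000]` for both parameters; config 7
#' = unrealistic initial values D = 10 mm^2/s, T_max = 500 C.
#'
#' @param id `"reference"` or 1..7.
#' @return An object of class `robustness_config`.
#' @export
robustness_config <- function(id = "reference") {
  subsets <- list(`1` = c(0, 22.5, 45, 67.5), `2` = c(90, 112.5, 135, 157.5),
                  `3` = c(0, 22.5), `4` = 90, `5` = 22.5)
  cfg <- list(id = id, orientation_subset = NULL, bounds_D = NULL,
              bounds_Tmax = NULL, initial_D = NULL, initial_Tmax = NULL)
  if (identical(id, "reference")) {
  } else if (id %in% 1:5) {
    cfg$orientation_subset <- subsets[[as.character(id)]]
  } else if (id == 6) {
    cfg$bounds_D <- c(0.1, 1000); cfg$bounds_Tmax <- c(0.1, 1000)
  } else if (id == 7) {
    cfg$initial_D <- 10; cfg$initial_Tmax <- 500
  } else stop("unknown robustness config id: ", id, call. = FALSE)
  structure(cfg, class = "robustness_config")
}

#' Run the adaptive pipeline under one robustness configuration
#'
#' Filters the series to the configuration's orientation subset (0.5
#' degree matching tolerance), applies any parameter overrides, runs the
#' full sequential reconstruction, and evaluates the Dice overlap with
#' the ground-truth necrosis under both threshold modes.
#'
#' @param phantom result of [generate_series()].
#' @param config a [robustness_config()].
#' @param grid fitting [volume_grid()].
#' @param dt solver step, s.
#' @param threshold global-mode necrosis threshold, degrees C.
#' @param use_sink pass the phantom's known perfused-tube mask and
#'   perfusion rate to the reconstruction (a priori vessel knowledge).
#' @param opts extra options for [adaptive_update()].
#' @return One-row data.frame: config id, n_maps, fitted D and T_max,
#'   Dice under the global and median threshold modes.
#' @export
robustness_run <- function(phantom, config = robustness_config(),
                           grid = phantom$spec$grid, dt = phantom$spec$dt,
                           threshold = phantom$spec$necrosis_threshold,
                           use_sink = !is.null(phantom$spec$heat_sink),
                           opts = list()) {
  stopifnot(inherits(config, "robustness_config"))
  series <- phantom$maps
  if (!is.null(config$orientation_subset)) {
    keep <- vapply(series, function(m)
      any(abs(m$frame$angle - config$orientation_subset) < 0.5),
      logical(1L))
    if (!any(keep)) stop("orientation subset matches no acquired map",
                         call. = FALSE)
    series <- series[keep]
  }
  baseline <- series[[1L]]$baseline_T0
  P <- parameter_set(
    D = if (is.null(config$initial_D)) 1 else config$initial_D,
    T_max = if (is.null(config$initial_Tmax)) baseline else
      config$initial_Tmax,
    bounds_D = if (is.null(config$bounds_D)) c(0.1, 5) else config$bounds_D,
    bounds_Tmax = if (is.null(config$bounds_Tmax)) c(80, 300) else
      config$bounds_Tmax)
  tp <- tissue_params(D = clamp_params(P)$D)
  smask <- NULL
  if (use_sink && !is.null(phantom$spec$heat_sink)) {
    tp <- heat_sink_params(grid, phantom$spec$heat_sink, tp)
    smask <- sink_mask_for(grid, phantom$spec$heat_sink)
  }
  opts$interval <- phantom$spec$acquisition_interval
  rec <- run_reconstruction(series, grid = grid, P_init = P, dt = dt,
                            params = tp, sink_mask = smask, opts = opts)
  # a filtered series ends before the full protocol does; advance the
  # accepted state to the common evaluation time under the final fit
  t_end <- phantom$spec$n_timepoints * phantom$spec$acquisition_interval
  if (rec$state$time < t_end - 1e-9)
    rec$state <- simulate_bioheat(rec$state, t_end - rec$state$time)
  d_global <- dice(necrosis_mask(rec$state$field, threshold),
                   phantom$true_mask)
  tau_med <- median_mode_threshold(rec$state, series)
  d_median <- dice(necrosis_mask(rec$state$field, tau_med, "median"),
                   phantom$true_mask)
  data.frame(config = as.character(config$id), n_maps = length(series),
             D = rec$params$D, T_max = rec$params$T_max,
             dice_global = d_global, dice_median = d_median,
             median_tau = tau_med, stringsAsFactors = FALSE)
}
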