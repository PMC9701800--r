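#' Specification of a synthetic rotated-thermometry phantom
#'
#' Defines the study conditions the generator emulates: an MR-monitored
#' ablation of a homogeneous (optionally perfused) gel phantom, imaged as
#' 2D temperature maps on planes uniformly rotated around the applicator
#' axis, with Gaussian pixel noise and a corrupted band along the
#' applicator artifact. The forward model is this package's own solver
#' run at twice the spatial and four times the temporal resolution of the
#' fitting configuration, so the inverse problem is never tested on data
#' produced by its own discretization.
#'
#' @param true_D ground-truth thermal diffusivity, mm^2/s.
#' @param true_Tmax ground-truth peak source temperature, degrees C.
#' @param baseline_T0 baseline temperature, degrees C.
#' @param n_orientations uniformly distributed slice orientations.
#' @param n_timepoints acquired images (cycling through orientations).
#' @param acquisition_interval seconds between images.
#' @param noise_sigma i.i.d. Gaussian pixel noise, degrees C.
#' @param artifact_half_width corrupted applicator band half width, px.
#' @param heat_sink optional list `(offset_mm, radius_mm, flow_rate)`
#'   describing a water-perfused tube parallel to the axis.
#' @param seed integer fixing all randomness.
#' @param grid fitting-resolution [volume_grid()] the truth is reported
#'   on; generation runs at `refine` times this resolution.
#' @param dt fitting-configuration solver step, s (generation uses
#'   `dt / dt_refine`).
#' @param refine,dt_refine generation refinement factors (space, time).
#' @param axial_half_length axial half-length of the true ellipsoidal
#'   heating profile, mm.
#' @param ramp_fraction fraction of the series over which the source
#'   power ramps up linearly before holding.
#' @param necrosis_threshold ground-truth coagulation temperature,
#'   degrees C.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(true_D = 1, true_Tmax = 150, baseline_T0 = 21,
                         n_orientations = 8L, n_timepoints = 24L,
                         acquisition_interval = 2, noise_sigma = 1,
                         artifact_half_width = 2L, heat_sink = NULL,
                         seed = 1L, grid = volume_grid(), dt = 0.5,
                         refine = 2L, dt_refine = 4L,
                         axial_half_length = 18,
                         ramp_fraction = 0.2, necrosis_threshold = 55) {
  stopifnot(noise_sigma >= 0, n_orientations >= 1, n_timepoints >= 1,
            acquisition_interval > 0, refine >= 1, dt_refine >= 1)
  structure(as.list(environment()), class = "phantom_spec")
}

# Fine generation grid covering the same physical extent as `grid`.
refine_grid <- function(grid, refine) {
  volume_grid((grid$shape - 1L) * refine + 1L, grid$spacing / refine,
              grid$origin)
}

# Elliptical-cap axial profile centered on the grid's axial midpoint:
# the axial section of an ellipsoidal heat zone of the given half-length,
# used as the shape prior for the pilot run.
true_axial_q <- function(z_mm, grid, axial_half_length) {
  zc <- grid$origin[3L] + (grid$shape[3L] - 1L) / 2 * grid$spacing
  sqrt(pmax(0, 1 - ((z_mm - zc) / axial_half_length)^2))
}

# The phantom's true axial source profile: the fixed point of the
# isotherm-distance profile estimator. Starting from an elliptical-cap
# prior, a coarse-grid pilot ablation is run and the axial profile is
# re-estimated from the pilot's final noiseless maps with the same
# machinery the reconstruction uses (sum of radial isotherm distances);
# the estimate becomes the next pilot's source until the profile stops
# changing. The ground truth then lies in — and is self-consistent
# under — the family of profiles the model class can represent, so
# parameter recovery probes the inverse optimization rather than the
# profile estimator's shape bias; the data are still generated at finer
# space/time resolution than any fit.
pilot_axial_profile <- function(spec, frames, max_iter = 6L, tol = 0.02) {
  g <- spec$grid
  z <- grid_coords(g, 3L)
  qcap <- true_axial_q(z, g, spec$axial_half_length)
  tp <- tissue_params(D = spec$true_D)
  smask <- NULL
  if (!is.null(spec$heat_sink)) {
    tp <- heat_sink_params(g, spec$heat_sink, tp)
    smask <- sink_mask_for(g, spec$heat_sink)
  }
  total_time <- spec$n_timepoints * spec$acquisition_interval
  ramp_end <- spec$ramp_fraction * total_time
  isovals <- default_isovalues(spec$baseline_T0, anchor =
                                 spec$baseline_T0 + 3)
  q_prior <- qcap
  for (iter in seq_len(max_iter)) {
    st <- solver_state(g, dt = spec$dt, boundary_T = spec$baseline_T0,
                       params = tp, sink_mask = smask)
    while (st$time < total_time - 1e-9) {
      power <- min(1, (st$time + st$dt) / max(ramp_end, st$dt))
      st$source <- structure(list(rows = seq_along(z) - 1L, z_mm = z,
                                  q = q_prior, q_max = 1,
                                  T_abs = q_prior * spec$true_Tmax * power),
                             class = "source_profile")
      st <- adi_step(st)
    }
    sets <- lapply(frames, function(frame) {
      px <- as.matrix(expand.grid(row = seq_len(frame$matrix[1L]) - 1L,
                                  col = seq_len(frame$matrix[2L]) - 1L))
      vals <- matrix(sample_volume(st$field, g, slice_to_world(frame, px),
                                   outside_value = spec$baseline_T0),
                     frame$matrix[1L], frame$matrix[2L])
      tm <- mask_applicator_band(
        temperature_map(vals, frame, baseline_T0 = spec$baseline_T0),
        spec$artifact_half_width)
      extract_isotherm_set(tm, isovals)
    })
    q_est <- source_profile(sets)$q
    if (max(abs(q_est - q_prior)) < tol) return(q_est)
    q_prior <- q_est
  }
  q_prior
}

sink_mask_for <- function(grid, heat_sink) {
  x <- grid_coords(grid, 1L); y <- grid_coords(grid, 2L)
  r2 <- outer((x - heat_sink$offset_mm)^2, y^2, `+`)
  array(rep(r2 <= heat_sink$radius_mm^2, grid$shape[3L]), grid$shape)
}

heat_sink_params <- function(grid, heat_sink, base = tissue_params()) {
  l_m <- (grid$shape[3L] - 1L) * grid$spacing * 1e-3
  base$w_b <- perfusion_rate(heat_sink$flow_rate,
                             heat_sink$radius_mm * 1e-3, l_m)
  base
}

#' Generate a synthetic rotated thermometry series with ground truth
#'
#' Runs the forward bioheat model at fine resolution under the true
#' parameters, samples one rotated frame per acquisition time (cycling
#' through the orientations), adds Gaussian pixel noise and invalidates
#' the applicator band. Returns the maps together with the noiseless
#' ground truth resampled onto the fitting grid and the thresholded true
#' necrosis mask.
#'
#' @param spec a [phantom_spec()].
#' @param store_trajectory keep the coarse-sampled noiseless volume at
#'   every acquisition time (memory-heavy; default FALSE keeps only the
#'   final one).
#' @return List: `maps` (list of [temperature_map()]), `truth` (list with
#'   `final_coarse` 3D array, optional `trajectory`, `params`,
#'   `sink_mask`), `true_mask` (a [necrosis_mask()]), `noiseless_maps`
#'   (noise-free pixel matrices, consumed by [renoise_series()]),
#'   `frames`, `spec`.
#' @export
generate_series <- function(spec, store_trajectory = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  fine <- refine_grid(spec$grid, spec$refine)
  frames <- build_slice_frames(
    spec$n_orientations,
    matrix = c(spec$grid$shape[3L],
               2L * floor((spec$grid$shape[1L] - 1L) / 2) + 1L),
    pixel_spacing = spec$grid$spacing,
    axis_origin = c(0, 0, spec$grid$origin[3L]))
  tp <- tissue_params(D = spec$true_D)
  smask <- NULL
  if (!is.null(spec$heat_sink)) {
    tp <- heat_sink_params(fine, spec$heat_sink, tp)
    smask <- sink_mask_for(fine, spec$heat_sink)
  }
  zf <- grid_coords(fine, 3L)
  qf <- stats::approx(grid_coords(spec$grid, 3L),
                      pilot_axial_profile(spec, frames), zf,
                      rule = 2)$y
  st <- solver_state(fine, dt = spec$dt / spec$dt_refine,
                     boundary_T = spec$baseline_T0, params = tp,
                     sink_mask = smask)
  total_time <- spec$n_timepoints * spec$acquisition_interval
  ramp_end <- spec$ramp_fraction * total_time
  maps <- vector("list", spec$n_timepoints)
  noiseless <- vector("list", spec$n_timepoints)
  traj <- if (store_trajectory) vector("list", spec$n_timepoints) else NULL
  coarse_pts <- as.matrix(expand.grid(grid_coords(spec$grid, 1L),
                                      grid_coords(spec$grid, 2L),
                                      grid_coords(spec$grid, 3L)))
  for (i in seq_len(spec$n_timepoints)) {
    t_target <- i * spec$acquisition_interval
    while (st$time < t_target - 1e-9) {
      power <- min(1, (st$time + st$dt) / max(ramp_end, st$dt))
      st$source <- structure(list(rows = seq_along(zf) - 1L, z_mm = zf,
                                  q = qf, q_max = 1,
                                  T_abs = qf * spec$true_Tmax * power),
                             class = "source_profile")
      st <- adi_step(st)
    }
    frame <- frames[[(i - 1L) %% spec$n_orientations + 1L]]
    px <- as.matrix(expand.grid(row = seq_len(frame$matrix[1L]) - 1L,
                                col = seq_len(frame$matrix[2L]) - 1L))
    vals <- sample_volume(st$field, fine, slice_to_world(frame, px),
                          outside_value = spec$baseline_T0)
    clean <- matrix(vals, frame$matrix[1L], frame$matrix[2L])
    noiseless[[i]] <- clean
    m <- clean
    if (spec$noise_sigma > 0)
      m <- m + matrix(rnorm(length(m), 0, spec$noise_sigma), nrow(m))
    tm <- temperature_map(m, frame, time_index = i - 1L,
                          baseline_T0 = spec$baseline_T0)
    maps[[i]] <- mask_applicator_band(tm, spec$artifact_half_width)
    if (store_trajectory)
      traj[[i]] <- array(sample_volume(st$field, fine, coarse_pts,
                                       outside_value = spec$baseline_T0),
                         spec$grid$shape)
  }
  final_coarse <- array(sample_volume(st$field, fine, coarse_pts,
                                      outside_value = spec$baseline_T0),
                        spec$grid$shape)
  truth <- list(final_coarse = final_coarse, trajectory = traj,
                params = tp,
                sink_mask = if (is.null(smask)) NULL else
                  sink_mask_for(spec$grid, spec$heat_sink))
  list(maps = maps, truth = truth,
       true_mask = necrosis_mask(final_coarse, spec$necrosis_threshold),
       noiseless_maps = noiseless, frames = frames, spec = spec)
}

#' Regenerate a phantom series with a fresh noise realization
#'
#' Replays the acquisition of an existing phantom: the same (expensive)
#' fine-grid forward simulation and ground truth, but new i.i.d.
#' Gaussian pixel noise drawn under `seed`. This is the natural way to
#' study acquisition-noise variability — the phantom and its heating are
#' fixed, only the measurement noise changes.
#'
#' @param phantom a [generate_series()] result.
#' @param seed integer seed for the new noise realization.
#' @param noise_sigma noise level, degrees C; defaults to the phantom's.
#' @return The phantom with `maps` replaced.
#' @export
renoise_series <- function(phantom, seed,
                           noise_sigma = phantom$spec$noise_sigma) {
  stopifnot(!is.null(phantom$noiseless_maps))
  set.seed(seed)
  phantom$maps <- lapply(seq_along(phantom$noiseless_maps), function(i) {
    clean <- phantom$noiseless_maps[[i]]
    m <- clean + matrix(rnorm(length(clean), 0, noise_sigma),
                        nrow(clean))
    tm <- temperature_map(m, phantom$maps[[i]]$frame,
                          time_index = i - 1L,
                          baseline_T0 = phantom$spec$baseline_T0)
    mask_applicator_band(tm, phantom$spec$artifact_half_width)
  })
  phantom
}

#' Closed-form diffused Gaussian temperature field
#'
#' Analytic solution of the homogeneous 3D diffusion equation for an
#' initial isotropic Gaussian bump: after time t the per-axis variance is
#' `width0^2 + 2 D t` and the amplitude is rescaled so the integral above
#' baseline is conserved; at `2 D t = width0^2` the peak has dropped to
#' `amplitude / 2^(3/2)`. Used as the independent oracle for the
#' finite-difference solver.
#'
#' @param grid a [volume_grid()].
#' @param t time, s (>= 0).
#' @param D diffusivity, mm^2/s.
#' @param amplitude initial peak height above baseline, degrees C.
#' @param width0 initial Gaussian standard deviation, mm (> 0).
#' @param baseline background temperature, degrees C.
#' @param center mm center; default the grid center.
#' @return 3D array of temperatures on the grid.
#' @export
analytic_gaussian_field <- function(grid, t, D, amplitude, width0,
                                    baseline = 21, center = NULL) {
  stopifnot(t >= 0, width0 > 0)
  if (is.null(center))
    center <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  s2 <- width0^2 + 2 * D * t
  amp <- amplitude * (width0^2 / s2)^(3 / 2)
  gx <- exp(-(grid_coords(grid, 1L) - center[1L])^2 / (2 * s2))
  gy <- exp(-(grid_coords(grid, 2L) - center[2L])^2 / (2 * s2))
  gz <- exp(-(grid_coords(grid, 3L) - center[3L])^2 / (2 * s2))
  baseline + amp * outer(outer(gx, gy), gz)
}

#' Inject synthetic corruption into a temperature map
#'
#' Robustness-test helper: either salt-noise outlier pixels (valid pixels
#' shifted by `magnitude`) or a zeroed-out dropout region marked invalid.
#'
#' @param map a [temperature_map()].
#' @param mode `"outlier"` or `"dropout"`.
#' @param magnitude outlier temperature offset, degrees C (0 = identity).
#' @param n_pixels number of outlier pixels.
#' @param region 0-based pixel bounds `c(row0, row1, col0, col1)` for
#'   dropout; default the upper-left quadrant.
#' @param seed RNG seed for outlier placement.
#' @return The corrupted map.
#' @export
corrupt_image <- function(map, mode = c("outlier", "dropout"),
                          magnitude = 30, n_pixels = 5L, region = NULL,
                          seed = 1L) {
  stopifnot(inherits(map, "temperature_map"), is.finite(magnitude))
  mode <- match.arg(mode)
  if (magnitude == 0 && mode == "outlier") return(map)
  if (mode == "outlier") {
    set.seed(seed)
    idx <- sample(which(map$valid_mask), n_pixels)
    map$values[idx] <- map$values[idx] + magnitude
  } else {
    if (is.null(region))
      region <- c(0L, nrow(map$values) %/% 2L, 0L, ncol(map$values) %/% 2L)
    rows <- (region[1L]:region[2L]) + 1L
    cols <- (region[3L]:region[4L]) + 1L
    map$values[rows, cols] <- 0
    map$valid_mask[rows, cols] <- FALSE
  }
  map
}
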