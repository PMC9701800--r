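#' Resolved run configuration
#'
#' A single serializable object from which an end-to-end run is
#' reproducible: phantom/generator settings, fitting grid, solver step,
#' isotherm ladder, optimizer bounds and initial values, evaluation
#' threshold, and seed. Persisted as JSON in every output directory.
#'
#' @param ... overrides of the defaults (see the listed fields).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    grid_shape = c(60L, 60L, 60L), grid_spacing = 1,
    dt = 0.5, baseline_T0 = 21,
    n_orientations = 8L, n_timepoints = 24L, acquisition_interval = 2,
    noise_sigma = 1, artifact_half_width = 2L,
    true_D = 1, true_Tmax = 150, heat_sink = NULL,
    iso_span = 24, iso_count = 8L,
    initial_D = 1, initial_Tmax = NULL,
    bounds_D = c(0.1, 5), bounds_Tmax = c(80, 300),
    necrosis_threshold = 55, threshold_mode = "global")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(modifyList(cfg, over, keep.null = TRUE), class = "run_config")
}

config_to_spec <- function(cfg) {
  phantom_spec(true_D = cfg$true_D, true_Tmax = cfg$true_Tmax,
               baseline_T0 = cfg$baseline_T0,
               n_orientations = cfg$n_orientations,
               n_timepoints = cfg$n_timepoints,
               acquisition_interval = cfg$acquisition_interval,
               noise_sigma = cfg$noise_sigma,
               artifact_half_width = cfg$artifact_half_width,
               heat_sink = cfg$heat_sink, seed = cfg$seed,
               grid = volume_grid(cfg$grid_shape, cfg$grid_spacing),
               dt = cfg$dt,
               necrosis_threshold = cfg$necrosis_threshold)
}

write_config <- function(cfg, out_dir) {
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Read a run configuration from JSON
#' @param path path to a `config.json`.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Generate synthetic series artifacts
#'
#' Writes the synthetic rotated-thermometry series (CSV maps + JSON
#' manifest), the noiseless ground-truth volume and necrosis mask
#' (NIfTI), and the resolved configuration into `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_series(config_to_spec(config))
  write_series(ph$maps, file.path(out_dir, "series"))
  RNifti::writeNifti(RNifti::asNifti(ph$truth$final_coarse),
                     file.path(out_dir, "truth_volume.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(ph$true_mask$mask * 1),
                     file.path(out_dir, "truth_necrosis.nii.gz"))
  write_config(config, out_dir)
  invisible(out_dir)
}

#' Reconstruct a 3D heat map from a stored series
#'
#' Reads the series from `in_dir`, runs the sequential adaptive loop and
#' writes the per-update fit log (CSV), the final parameters (JSON), the
#' final volume and the thresholded necrosis mask (NIfTI).
#'
#' @param config a [run_config()].
#' @param in_dir directory produced by [cmd_simulate()] (or an external
#'   series in the same layout).
#' @param out_dir output directory; defaults to `in_dir`.
#' @return The [run_reconstruction()] result, invisibly.
#' @export
cmd_reconstruct <- function(config, in_dir, out_dir = in_dir) {
  stopifnot(inherits(config, "run_config"))
  series <- read_series(file.path(in_dir, "series"))
  if (length(series) == 0L)
    stop("no temperature maps found under ", in_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  baseline <- series[[1L]]$baseline_T0
  P <- parameter_set(D = config$initial_D,
                     T_max = if (is.null(config$initial_Tmax)) baseline
                     else config$initial_Tmax,
                     bounds_D = config$bounds_D,
                     bounds_Tmax = config$bounds_Tmax)
  grid <- volume_grid(config$grid_shape, config$grid_spacing)
  tp <- tissue_params(D = clamp_params(P)$D)
  smask <- NULL
  if (!is.null(config$heat_sink)) {
    tp <- heat_sink_params(grid, config$heat_sink, tp)
    smask <- sink_mask_for(grid, config$heat_sink)
  }
  t0 <- proc.time()[["elapsed"]]
  rec <- run_reconstruction(series, grid = grid, P_init = P,
                            dt = config$dt, params = tp, sink_mask = smask,
                            opts = list(span = config$iso_span,
                                        n_isovalues = config$iso_count,
                                        interval =
                                          config$acquisition_interval))
  elapsed <- proc.time()[["elapsed"]] - t0
  fits <- rec$fits
  fits$mean_update_s <- elapsed / nrow(fits)
  write.csv(fits, file.path(out_dir, "fit_log.csv"), row.names = FALSE)
  jsonlite::write_json(list(D = rec$params$D, T_max = rec$params$T_max,
                            n_updates = nrow(fits),
                            mean_update_s = elapsed / nrow(fits)),
                       file.path(out_dir, "final_params.json"),
                       auto_unbox = TRUE, digits = NA)
  RNifti::writeNifti(RNifti::asNifti(rec$state$field),
                     file.path(out_dir, "reconstructed_volume.nii.gz"))
  mask <- necrosis_mask(rec$state$field, config$necrosis_threshold)
  RNifti::writeNifti(RNifti::asNifti(mask$mask * 1),
                     file.path(out_dir, "reconstructed_necrosis.nii.gz"))
  write_config(config, out_dir)
  invisible(rec)
}

#' Evaluate reconstruction artifacts against the ground truth
#'
#' Compares the reconstructed necrosis mask with the stored truth by the
#' Dice score (global threshold mode; the median mode is available
#' through [robustness_run()], which re-runs the pipeline) and writes a
#' JSON metrics summary.
#'
#' @param config a [run_config()].
#' @param dir directory holding both simulate and reconstruct artifacts.
#' @return List of metrics, invisibly.
#' @export
cmd_evaluate <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  need <- c("truth_necrosis.nii.gz", "reconstructed_necrosis.nii.gz")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing artifact: ", file.path(dir, f), call. = FALSE)
  truth <- as.array(RNifti::readNifti(file.path(dir,
                                                "truth_necrosis.nii.gz")))
  rec <- as.array(RNifti::readNifti(
    file.path(dir, "reconstructed_necrosis.nii.gz")))
  metrics <- list(dice_global = dice(truth > 0.5, rec > 0.5),
                  threshold = config$necrosis_threshold,
                  n_voxels = length(truth))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}
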