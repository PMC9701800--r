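#' Temperature map on a rotated slice frame
#'
#' One absolute-temperature image (degrees C) at one acquisition time.
#' `valid_mask` marks pixels carrying usable thermal information; the band
#' corrupted by the applicator artifact and any user-flagged pixels are
#' `FALSE` and are excluded from isotherm extraction.
#'
#' @param values rows x cols numeric matrix of temperatures, degrees C.
#' @param frame the [slice_frame()] the map was acquired on.
#' @param time_index 0-based acquisition ordinal within the series.
#' @param baseline_T0 pre-ablation baseline temperature, degrees C.
#' @param valid_mask logical matrix; defaults to `is.finite(values)`.
#' @return An object of class `temperature_map`.
#' @export
temperature_map <- function(values, frame, time_index = 0L,
                            baseline_T0 = 21, valid_mask = NULL) {
  stopifnot(is.matrix(values), inherits(frame, "slice_frame"))
  if (!all(dim(values) == frame$matrix))
    stop("temperature grid shape must equal frame$matrix", call. = FALSE)
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == dim(values)))
  if (any(!is.finite(values[valid_mask])))
    stop("non-finite temperatures inside the valid mask", call. = FALSE)
  structure(list(values = values, frame = frame,
                 time_index = as.integer(time_index),
                 baseline_T0 = baseline_T0, valid_mask = valid_mask),
            class = "temperature_map")
}

#' Convert a PRFS phase-difference image to temperature
#'
#' Proton-resonance-frequency-shift thermometry: the phase change of a
#' gradient-echo image is proportional to the temperature change,
#' `delta_T = delta_phi / (gamma * alpha * B0 * TE)` with gyromagnetic
#' ratio `gamma = 2 pi * 42.576e6` rad/(s T) and thermal coefficient
#' `alpha` (ppm per degree C, negative for aqueous tissue).
#'
#' @param phase_diff matrix of phase differences, radians.
#' @param echo_time TE in ms.
#' @param field_strength B0 in tesla.
#' @param thermal_coeff PRFS coefficient in ppm per degree C; default -0.01.
#' @param baseline_T0 baseline temperature added to the temperature change.
#' @param frame,time_index passed to [temperature_map()].
#' @return A [temperature_map()].
#' @export
phase_to_temperature <- function(phase_diff, echo_time = 3.69,
                                 field_strength = 1.5,
                                 thermal_coeff = -0.01, baseline_T0 = 21,
                                 frame = NULL, time_index = 0L) {
  if (echo_time <= 0 || field_strength <= 0 || thermal_coeff == 0)
    stop("echo_time and field_strength must be positive and thermal_coeff non-zero",
         call. = FALSE)
  gamma <- 2 * pi * 42.576e6                       # rad / (s T)
  dT <- phase_diff / (gamma * thermal_coeff * 1e-6 * field_strength *
                        echo_time * 1e-3)
  if (is.null(frame)) frame <- slice_frame(0, dim(phase_diff))
  temperature_map(baseline_T0 + dT, frame, time_index, baseline_T0)
}

#' Invalidate the applicator-artifact band
#'
#' The interaction between applicator and magnetic field erases or
#' distorts thermal information around the needle; pixels within
#' `half_width` columns of the axis column are marked invalid.
#'
#' @param map a [temperature_map()].
#' @param half_width band half width in pixels (>= 0); 0 is the identity.
#' @return The map with an updated `valid_mask`.
#' @export
mask_applicator_band <- function(map, half_width = 2L) {
  stopifnot(inherits(map, "temperature_map"), half_width >= 0)
  if (half_width == 0) return(map)
  cols <- seq_len(ncol(map$values)) - 1L           # 0-based
  band <- abs(cols - map$frame$axis_column) <= half_width
  map$valid_mask[, band] <- FALSE
  map
}

frame_meta <- function(frame) {
  list(angle = frame$angle, matrix = frame$matrix,
       pixel_spacing = frame$pixel_spacing,
       slice_thickness = frame$slice_thickness,
       axis_column = frame$axis_column, axis_origin = frame$axis_origin)
}

frame_from_meta <- function(m) {
  slice_frame(m$angle, unlist(m$matrix), m$pixel_spacing,
              m$slice_thickness, m$axis_column, unlist(m$axis_origin))
}

#' Write a temperature-map series to disk
#'
#' Each map is stored as a plain CSV matrix (invalid pixels written as
#' `NA`) or as NIfTI, together with a JSON manifest carrying the frame
#' metadata, acquisition ordering and baseline temperature. The layout is
#' the one [read_series()] consumes.
#'
#' @param maps list of [temperature_map()] objects.
#' @param path output directory (created if missing).
#' @param format `"csv"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(maps, path, format = c("csv", "nifti")) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(maps, function(m) {
    ext <- if (format == "csv") "csv" else "nii.gz"
    fn <- sprintf("map_%03d.%s", m$time_index, ext)
    vals <- m$values
    vals[!m$valid_mask] <- NA_real_
    if (format == "csv") {
      write.csv(vals, file.path(path, fn), row.names = FALSE)
    } else {
      RNifti::writeNifti(RNifti::asNifti(vals), file.path(path, fn))
    }
    c(list(file = fn, time_index = m$time_index,
           baseline_T0 = m$baseline_T0), frame_meta(m$frame))
  })
  jsonlite::write_json(list(format = format, maps = entries),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a temperature-map series
#'
#' Reads the manifest written by [write_series()] (or an equivalent one
#' describing externally converted data), loads each map and returns them
#' sorted by `time_index`. Pixels stored as `NA`/non-finite become invalid
#' in the map's mask.
#'
#' @param path directory containing `manifest.json` and the map files.
#' @return List of [temperature_map()] objects ordered by time.
#' @export
read_series <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!dir.exists(path)) stop("series directory not found: ", path,
                              call. = FALSE)
  if (!file.exists(mf)) {
    if (length(list.files(path)) == 0L) return(list())
    stop("missing manifest.json in ", path, call. = FALSE)
  }
  man <- jsonlite::read_json(mf)
  maps <- lapply(man$maps, function(e) {
    fp <- file.path(path, e$file)
    if (!file.exists(fp)) stop("series file not found: ", fp, call. = FALSE)
    vals <- if (identical(man$format, "nifti")) {
      v <- as.array(RNifti::readNifti(fp)); dim(v) <- dim(v)[1:2]; v
    } else {
      as.matrix(read.csv(fp, header = TRUE))
    }
    dimnames(vals) <- NULL
    storage.mode(vals) <- "double"
    temperature_map(vals, frame_from_meta(e), e$time_index,
                    e$baseline_T0, valid_mask = is.finite(vals))
  })
  maps[order(vapply(maps, `[[`, integer(1L), "time_index"))]
}
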