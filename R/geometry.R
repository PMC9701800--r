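#' Slice frame on a plane rotated around the applicator axis
#'
#' A slice frame describes one 2D acquisition plane. All frames of a series
#' share the applicator axis as a common line; each frame is rotated about
#' that axis by `angle` degrees. Pixel indices are 0-based; image rows run
#' parallel to the axis (row k maps to axial position `k * pixel_spacing`
#' from `axis_origin`), and `axis_column` is the in-plane column that lies
#' on the axis for every angle.
#'
#' @param angle rotation about the axis, degrees in `[0, 180)`.
#' @param matrix image dimensions `c(rows, cols)` in pixels.
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness through-plane thickness, mm (metadata only; the
#'   plane is sampled as infinitely thin).
#' @param axis_column 0-based column index of the applicator axis.
#' @param axis_origin mm point on the axis that row 0 maps to.
#' @return An object of class `slice_frame`.
#' @export
slice_frame <- function(angle, matrix = c(60L, 61L), pixel_spacing = 1,
                        slice_thickness = 5, axis_column = NULL,
                        axis_origin = c(0, 0, 0)) {
  stopifnot(length(matrix) == 2L, all(matrix >= 1), pixel_spacing > 0,
            length(axis_origin) == 3L)
  if (is.null(axis_column)) axis_column <- (matrix[2L] - 1) / 2
  if (axis_column < 0 || axis_column > matrix[2L] - 1)
    stop("axis_column outside the image matrix", call. = FALSE)
  structure(list(angle = angle %% 180, matrix = as.integer(matrix),
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 axis_column = axis_column,
                 axis_origin = as.numeric(axis_origin)),
            class = "slice_frame")
}

#' Build uniformly rotated slice frames
#'
#' For `n_orientations` frames the rotation angles are `k * 180 / n`,
#' `k = 0 .. n-1` (e.g. eight orientations give 0, 22.5, ..., 157.5
#' degrees). Every frame contains the applicator axis.
#'
#' @inheritParams slice_frame
#' @param n_orientations number of uniformly distributed orientations.
#' @return List of [slice_frame()] objects.
#' @export
build_slice_frames <- function(n_orientations, matrix = c(60L, 61L),
                               pixel_spacing = 1, slice_thickness = 5,
                               axis_column = NULL, axis_origin = c(0, 0, 0)) {
  if (length(n_orientations) != 1L || n_orientations < 1)
    stop("n_orientations must be >= 1", call. = FALSE)
  n <- as.integer(n_orientations)
  lapply(seq_len(n) - 1L, function(k)
    slice_frame(k * 180 / n, matrix, pixel_spacing, slice_thickness,
                axis_column, axis_origin))
}

#' Map slice pixels to volume coordinates
#'
#' Rotates the in-plane lateral offset about the applicator axis by the
#' frame angle. Pixels on `axis_column` map onto the axis for every angle.
#'
#' @param frame a [slice_frame()].
#' @param pixels matrix (or length-2 vector) of 0-based `(row, col)` pixel
#'   indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
slice_to_world <- function(frame, pixels) {
  stopifnot(inherits(frame, "slice_frame"))
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2L)
  if (any(pixels[, 1L] < 0 | pixels[, 1L] > frame$matrix[1L] - 1 |
          pixels[, 2L] < 0 | pixels[, 2L] > frame$matrix[2L] - 1))
    stop("pixel outside the image matrix", call. = FALSE)
  th <- frame$angle * pi / 180
  u <- (pixels[, 2L] - frame$axis_column) * frame$pixel_spacing
  z <- pixels[, 1L] * frame$pixel_spacing
  cbind(frame$axis_origin[1L] + u * cos(th),
        frame$axis_origin[2L] + u * sin(th),
        frame$axis_origin[3L] + z)
}

#' Map volume coordinates back onto a slice frame
#'
#' Inverse of [slice_to_world()] for points lying on (or projected onto)
#' the frame plane: the signed lateral offset along the rotated in-plane
#' direction becomes the column, the axial offset the row.
#'
#' @param frame a [slice_frame()].
#' @param points n x 3 matrix of mm coordinates.
#' @return n x 2 matrix of fractional 0-based `(row, col)` indices.
#' @export
world_to_slice <- function(frame, points) {
  stopifnot(inherits(frame, "slice_frame"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  th <- frame$angle * pi / 180
  dx <- points[, 1L] - frame$axis_origin[1L]
  dy <- points[, 2L] - frame$axis_origin[2L]
  u <- dx * cos(th) + dy * sin(th)
  cbind((points[, 3L] - frame$axis_origin[3L]) / frame$pixel_spacing,
        frame$axis_column + u / frame$pixel_spacing)
}

#' Regular 3D voxel grid with the applicator axis through its center
#'
#' Voxel centers sit at `origin + index * spacing` (0-based indices,
#' isotropic spacing). The default origin centers the x/y extent on the
#' axis line x = y = 0 and starts z at 0, so the axis runs through the
#' middle of the grid along the z dimension.
#'
#' @param shape voxel counts `c(nx, ny, nz)`; default 60 x 60 x 60.
#' @param spacing voxel edge length, mm.
#' @param origin mm coordinate of voxel (0, 0, 0); default centers the
#'   axis.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape = c(60L, 60L, 60L), spacing = 1,
                        origin = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 3), spacing > 0)
  shape <- as.integer(shape)
  if (is.null(origin))
    origin <- c(-(shape[1L] - 1) / 2 * spacing,
                -(shape[2L] - 1) / 2 * spacing, 0)
  structure(list(shape = shape, spacing = spacing,
                 origin = as.numeric(origin)), class = "volume_grid")
}

#' Voxel-center coordinates of a grid along one dimension
#' @param grid a [volume_grid()].
#' @param dim dimension index 1..3.
#' @return Numeric vector of mm coordinates.
#' @export
grid_coords <- function(grid, dim) {
  stopifnot(inherits(grid, "volume_grid"), dim %in% 1:3)
  grid$origin[dim] + (seq_len(grid$shape[dim]) - 1) * grid$spacing
}

#' Trilinear sampling of a scalar field
#'
#' Samples a 3D field at arbitrary mm points by trilinear interpolation;
#' exact at voxel centers. Points outside the grid return `outside_value`
#' and are flagged in the `"outside"` attribute of the result.
#'
#' @param field 3D array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @param points n x 3 matrix of mm coordinates.
#' @param outside_value value returned for out-of-bounds points (typically
#'   the Dirichlet boundary temperature).
#' @return Numeric vector of sampled values with attribute `outside`.
#' @export
sample_volume <- function(field, grid, points, outside_value = NA_real_) {
  stopifnot(inherits(grid, "volume_grid"),
            identical(dim(field), as.integer(grid$shape)) ||
              all(dim(field) == grid$shape))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  n <- nrow(points)
  v <- sweep(points, 2L, grid$origin) / grid$spacing   # fractional voxel
  sh <- grid$shape
  outside <- v[, 1L] < 0 | v[, 1L] > sh[1L] - 1 |
    v[, 2L] < 0 | v[, 2L] > sh[2L] - 1 |
    v[, 3L] < 0 | v[, 3L] > sh[3L] - 1
  v[outside, ] <- 0
  i0 <- pmin(floor(v[, 1L]), sh[1L] - 2); fx <- v[, 1L] - i0
  j0 <- pmin(floor(v[, 2L]), sh[2L] - 2); fy <- v[, 2L] - j0
  k0 <- pmin(floor(v[, 3L]), sh[3L] - 2); fz <- v[, 3L] - k0
  lin <- function(i, j, k) field[1L + i + sh[1L] * (j + sh[2L] * k)]
  out <- (1 - fx) * (1 - fy) * (1 - fz) * lin(i0, j0, k0) +
    fx * (1 - fy) * (1 - fz) * lin(i0 + 1, j0, k0) +
    (1 - fx) * fy * (1 - fz) * lin(i0, j0 + 1, k0) +
    fx * fy * (1 - fz) * lin(i0 + 1, j0 + 1, k0) +
    (1 - fx) * (1 - fy) * fz * lin(i0, j0, k0 + 1) +
    fx * (1 - fy) * fz * lin(i0 + 1, j0, k0 + 1) +
    (1 - fx) * fy * fz * lin(i0, j0 + 1, k0 + 1) +
    fx * fy * fz * lin(i0 + 1, j0 + 1, k0 + 1)
  out[outside] <- outside_value
  attr(out, "outside") <- outside
  if (n != length(out)) stop("internal sampling error")
  out
}

#' In-plane radial distance from an axis point to an isotherm vertex
#'
#' The isotherm path has exactly one vertex per image row and rows run
#' parallel to the axis, so each axis point pairs with the vertex in the
#' same row; the orthogonal (radial) distance is the lateral pixel offset
#' scaled by the pixel spacing.
#'
#' @param frame a [slice_frame()].
#' @param vertex 0-based `(row, col)` pixel of the isotherm vertex (or an
#'   n x 2 matrix).
#' @param axis_row 0-based row index of the paired axis point(s).
#' @return Radial distance(s) in mm, always >= 0.
#' @export
orthogonal_distance <- function(frame, vertex, axis_row) {
  stopifnot(inherits(frame, "slice_frame"))
  if (is.null(dim(vertex))) vertex <- matrix(vertex, ncol = 2L)
  if (any(vertex[, 1L] != axis_row))
    stop("isotherm vertex row does not match the axis point row",
         call. = FALSE)
  abs(vertex[, 2L] - frame$axis_column) * frame$pixel_spacing
}
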