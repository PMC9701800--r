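test_that("uniformly rotated frames cover k * 180 / n degrees", {
  expect_equal(vapply(build_slice_frames(8), `[[`, numeric(1), "angle"),
               c(0, 22.5, 45, 67.5, 90, 112.5, 135, 157.5))
  expect_equal(build_slice_frames(1)[[1]]$angle, 0)
  expect_equal(vapply(build_slice_frames(4), `[[`, numeric(1), "angle"),
               c(0, 45, 90, 135))
  expect_error(build_slice_frames(0), "n_orientations")
})

test_that("slice_to_world rotates about the shared axis", {
  frames <- build_slice_frames(8, matrix = c(10L, 11L), pixel_spacing = 2)
  # axis-column pixels land on the axis line for every angle
  for (fr in frames) {
    p <- slice_to_world(fr, c(3, fr$axis_column))
    expect_equal(p[1, 1:2], c(0, 0))
    expect_equal(p[1, 3], 3 * 2)
  }
  # identity rotation: one spacing right of the axis
  f0 <- frames[[1]]
  p0 <- slice_to_world(f0, c(0, f0$axis_column + 1))
  expect_equal(drop(p0), c(2, 0, 0))
  # 90 degrees: the 0-degree result rotated by the rotation matrix
  f90 <- frames[[5]]
  expect_equal(f90$angle, 90)
  p90 <- slice_to_world(f90, c(0, f90$axis_column + 1))
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)   # 90 deg about z
  expect_equal(drop(p90), drop(R %*% p0[1, ]), tolerance = 1e-12)
  expect_error(slice_to_world(f0, c(0, 99)), "outside")
})

test_that("world_to_slice inverts slice_to_world to sub-pixel precision", {
  fr <- slice_frame(67.5, c(40L, 33L), 1.25, axis_column = 16)
  px <- cbind(row = c(0, 5, 39, 17), col = c(0, 16, 32, 3))
  back <- world_to_slice(fr, slice_to_world(fr, px))
  expect_lt(max(abs(back - px)), 1e-9)
})

test_that("trilinear sampling is exact at voxel centers and interpolates", {
  g <- volume_grid(c(5L, 5L, 5L), 2)
  f <- array(7, g$shape)
  pts <- cbind(runif(20, g$origin[1], -g$origin[1]),
               runif(20, g$origin[2], -g$origin[2]),
               runif(20, 0, 8))
  expect_equal(as.numeric(sample_volume(f, g, pts)), rep(7, 20))
  f2 <- array(rnorm(125), g$shape)
  centers <- cbind(grid_coords(g, 1)[c(1, 3, 5)],
                   grid_coords(g, 2)[c(2, 4, 1)],
                   grid_coords(g, 3)[c(5, 2, 3)])
  expect_equal(sample_volume(f2, g, centers),
               f2[cbind(c(1, 3, 5), c(2, 4, 1), c(5, 2, 3))],
               ignore_attr = TRUE)
  # midpoint between two voxels valued 10 and 20 samples to 15
  f3 <- array(10, g$shape); f3[3, 3, 3] <- 10; f3[4, 3, 3] <- 20
  mid <- c(mean(grid_coords(g, 1)[3:4]), grid_coords(g, 2)[3],
           grid_coords(g, 3)[3])
  expect_equal(drop(sample_volume(f3, g, mid)), 15, ignore_attr = TRUE)
  # outside points return the fallback and are flagged
  out <- sample_volume(f2, g, c(99, 0, 0), outside_value = -1)
  expect_equal(drop(out), -1, ignore_attr = TRUE)
  expect_true(attr(out, "outside"))
})

test_that("rotationally symmetric fields look identical from every frame", {
  g <- volume_grid(c(31L, 31L, 21L), 1)
  xs <- grid_coords(g, 1); ys <- grid_coords(g, 2)
  # smooth radial profile so trilinear interpolation error is small
  r2 <- outer(xs^2, ys^2, `+`)
  f <- array(rep(21 + 50 * exp(-r2 / 200), 21), g$shape)
  frames <- build_slice_frames(4, matrix = c(21L, 25L), pixel_spacing = 1)
  px <- as.matrix(expand.grid(row = 0:20, col = 0:24))
  maps <- lapply(frames, function(fr)
    sample_volume(f, g, slice_to_world(fr, px), outside_value = 21))
  # 90 degrees maps grid points onto grid points: exact agreement
  expect_lt(max(abs(maps[[3]] - maps[[1]])), 1e-9)
  # oblique angles agree to trilinear interpolation accuracy
  for (m in maps[c(2, 4)]) expect_lt(max(abs(m - maps[[1]])), 0.15)
})

test_that("orthogonal distance is the scaled lateral pixel offset", {
  fr <- slice_frame(0, c(10L, 65L), 1, axis_column = 32)
  expect_equal(orthogonal_distance(fr, c(4, 32), 4), 0)
  expect_equal(orthogonal_distance(fr, c(2, 37), 2), 5)
  fr2 <- slice_frame(0, c(10L, 65L), 2, axis_column = 32)
  expect_equal(orthogonal_distance(fr2, c(7, 29), 7), 6)
  expect_error(orthogonal_distance(fr, c(3, 40), 4), "row")
})
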