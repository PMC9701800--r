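test_that("the generator is deterministic under a fixed seed", {
  a <- generate_series(tiny_phantom_spec(seed = 9L))
  b <- generate_series(tiny_phantom_spec(seed = 9L))
  for (i in seq_along(a$maps))
    expect_identical(a$maps[[i]]$values, b$maps[[i]]$values)
  expect_identical(a$truth$final_coarse, b$truth$final_coarse)
  c2 <- generate_series(tiny_phantom_spec(seed = 10L))
  expect_false(identical(a$maps[[1]]$values, c2$maps[[1]]$values))
})

test_that("far-field pixels stay at baseline without noise", {
  ph <- generate_series(tiny_phantom_spec(noise_sigma = 0))
  m <- ph$maps[[1]]
  corner <- m$values[1:4, 1:4]
  expect_true(all(abs(corner - 21) < 1e-4))
})

test_that("noise statistics match the configured sigma", {
  ph <- generate_series(tiny_phantom_spec(noise_sigma = 2, seed = 3L))
  m <- ph$maps[[1]]
  patch <- m$values[1:6, 1:6]            # unheated far-field block
  expect_lt(abs(mean(patch) - 21), 3 * 2 / sqrt(length(patch)))
  expect_gt(sd(patch), 1)                # noise is present
})

test_that("the analytic Gaussian field obeys its closed-form identities", {
  n <- 25
  g <- volume_grid(rep(n, 3), 1, origin = rep(-(n - 1) / 2, 3))
  f0 <- analytic_gaussian_field(g, 0, 2, 30, 3, 21)
  expect_equal(max(f0), 51, tolerance = 1e-9)
  # integral above baseline is conserved under diffusion
  f1 <- analytic_gaussian_field(g, 2, 2, 30, 3, 21)
  expect_equal(sum(f1 - 21), sum(f0 - 21), tolerance = 0.02)
  # at 2 D t = width0^2 the peak has fallen to amplitude / 2^(3/2)
  t_half <- 3^2 / (2 * 2)
  fh <- analytic_gaussian_field(g, t_half, 2, 30, 3, 21)
  expect_equal(max(fh) - 21, 30 / 2^(3 / 2), tolerance = 1e-9)
})

test_that("image corruption modes behave as configured", {
  m <- radial_map()
  expect_identical(corrupt_image(m, "outlier", magnitude = 0), m)
  m5 <- corrupt_image(m, "outlier", magnitude = 30, n_pixels = 5, seed = 2)
  expect_equal(sum(m5$values != m$values), 5)
  # quadrant dropout leaves the other side extractable
  md <- corrupt_image(m, "dropout")
  expect_true(any(!md$valid_mask))
  expect_warning(s <- extract_isotherm_set(md, c(30, 40)), "left")
  expect_true(all(vapply(s$isotherms, `[[`, character(1), "side") ==
                    "right"))
})

test_that("ground truth resampled onto a frame reproduces isotherm radii", {
  # radially symmetric analytic field placed on the volume: extracting
  # isotherms from any rotated frame must recover the closed-form radius
  g <- volume_grid(c(41L, 41L, 21L), 1)
  xs <- grid_coords(g, 1)
  prof <- 21 + 60 * exp(-outer(xs^2, grid_coords(g, 2)^2, `+`) /
                          (2 * 8^2))
  f <- array(rep(prof, 21), g$shape)
  for (ang_k in c(1L, 4L)) {
    fr <- build_slice_frames(6, matrix = c(21L, 33L),
                             pixel_spacing = 1)[[ang_k]]
    px <- as.matrix(expand.grid(row = 0:20, col = 0:32))
    vals <- matrix(sample_volume(f, g, slice_to_world(fr, px),
                                 outside_value = 21), 21, 33)
    tm <- temperature_map(vals, fr, baseline_T0 = 21)
    it <- extract_isotherm(cost_map(tm, 45), side = "right")
    analytic <- 8 * sqrt(2 * log(60 / (45 - 21)))
    expect_lt(max(abs((it$vertices$col - 16) - analytic)), 1)
  }
})

test_that("a perfused tube dents the necrosis zone asymmetrically", {
  sink <- list(offset_mm = 6, radius_mm = 2.5, flow_rate = 1.5e-7)
  sp_h <- phantom_spec(n_timepoints = 10L, acquisition_interval = 6,
                       grid = volume_grid(c(40L, 40L, 40L), 1),
                       noise_sigma = 0, seed = 2L)
  sp_p <- phantom_spec(n_timepoints = 10L, acquisition_interval = 6,
                       grid = volume_grid(c(40L, 40L, 40L), 1),
                       noise_sigma = 0, seed = 2L, heat_sink = sink)
  mh <- generate_series(sp_h)$true_mask$mask
  mp <- generate_series(sp_p)$true_mask$mask
  # homogeneous zone is x-mirror symmetric, perfused one is indented on
  # the tube side (+x)
  expect_equal(mh, mh[dim(mh)[1]:1, , ])
  expect_lt(sum(mp), sum(mh))
  xs <- grid_coords(sp_p$grid, 1)
  expect_lt(sum(mp[xs > 2, , ]), sum(mp[xs < -2, , ]))
})
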