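test_that("perfusion rate follows the pump formula", {
  expect_equal(perfusion_rate(1e-6, 5e-3, 0.1),
               1e-3 / (pi * 2.5e-5 * 0.1), tolerance = 1e-12)
  expect_equal(perfusion_rate(1e-6, 5e-3, 0.1), 127.324, tolerance = 1e-4)
  expect_equal(perfusion_rate(0, 5e-3, 0.1), 0)
  expect_equal(perfusion_rate(2e-6, 5e-3, 0.1),
               2 * perfusion_rate(1e-6, 5e-3, 0.1))
  expect_error(perfusion_rate(1e-6, 0, 0.1), "positive")
})

test_that("relative strengths normalize by the maximum total distance", {
  expect_equal(relative_strengths(c(10, 20, 5)), c(0.5, 1, 0.25),
               tolerance = 1e-15)
  expect_equal(relative_strengths(c(3, 3, 3)), c(1, 1, 1))
  expect_equal(relative_strengths(7), 1)
})

test_that("the axial source profile peaks where isotherms bulge widest", {
  radii <- c(2, 2, 4, 8, 6, 2, 2)
  s <- source_profile(synthetic_iso_set(radii), min_radius = 0)
  expect_equal(s$q, radii / 8)
  expect_equal(s$q_max, 8)
  # default min-radius correction removes the band floor
  s2 <- source_profile(synthetic_iso_set(radii))
  expect_equal(s2$q, (radii - 2) / 6)
  # equal distances with no correction -> uniform unit strength
  su <- source_profile(synthetic_iso_set(rep(5, 4)), min_radius = 0)
  expect_equal(su$q, rep(1, 4))
  # equal distances under the default correction mean no heating evidence
  s0 <- source_profile(synthetic_iso_set(rep(5, 4)))
  expect_equal(s0$q, rep(0, 4))
  expect_error(source_profile(list()), "no isotherm")
})

test_that("absolute source scales strengths by T_max", {
  s <- source_profile(synthetic_iso_set(c(2, 8, 4)), min_radius = 0)
  a <- absolute_source(s, 300)
  expect_equal(a$T_abs, c(0.25, 1, 0.5) * 300)
  expect_equal(absolute_source(s, 80)$T_abs[3], 40)
})

test_that("the sink term cools perfused voxels toward the coolant", {
  g <- volume_grid(c(8L, 8L, 8L), 1)
  mask <- array(FALSE, g$shape); mask[3:4, 3:4, ] <- TRUE
  tp <- tissue_params(D = 1, w_b = 127.324, c_b = 4182, T_a = 25,
                      rho_c = 4e6)
  st <- solver_state(g, field = array(60, g$shape), boundary_T = 60,
                     params = tp, sink_mask = mask)
  P <- sink_term(st)
  expect_equal(P[3, 3, 3], 127.324 * 4182 * (25 - 60) / 4e6,
               tolerance = 1e-9)
  expect_equal(P[3, 3, 3], -4.659, tolerance = 1e-3)
  expect_true(all(P[!mask] == 0))
  st$field[] <- 25
  expect_true(all(sink_term(st) == 0))
  st$params$w_b <- 0
  expect_true(all(sink_term(st) == 0))
  expect_error(solver_state(g, params = tp), "sink_mask")
})

test_that("the Thomas solver matches dense solves", {
  expect_equal(thomas_solve(c(0, 0), c(1, 1, 1), c(0, 0), c(4, 5, 6)),
               c(4, 5, 6))
  A <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  expect_equal(thomas_solve(c(1, 1), c(2, 2, 2), c(1, 1), c(1, 2, 3)),
               drop(solve(A, c(1, 2, 3))), tolerance = 1e-12)
  set.seed(3)
  n <- 50
  lo <- runif(n - 1, -1, 1); up <- runif(n - 1, -1, 1)
  dg <- 2 + c(0, abs(lo)) + c(abs(up), 0) + runif(n)
  rhs <- rnorm(n)
  A <- diag(dg)
  A[cbind(2:n, 1:(n - 1))] <- lo
  A[cbind(1:(n - 1), 2:n)] <- up
  expect_lt(max(abs(thomas_solve(lo, dg, up, rhs) - solve(A, rhs))),
            1e-10)
})

test_that("a uniform field at the boundary temperature is a fixed point", {
  g <- volume_grid(c(12L, 12L, 12L), 1)
  st <- solver_state(g, boundary_T = 21, dt = 1,
                     params = tissue_params(D = 2))
  st2 <- simulate_bioheat(st, 10)
  expect_equal(st2$field, st$field)
  expect_equal(st2$time, 10)
})

test_that("free diffusion follows the analytic Gaussian kernel", {
  n <- 31
  g <- volume_grid(rep(n, 3), 1, origin = rep(-(n - 1) / 2, 3))
  f0 <- analytic_gaussian_field(g, 0, 2, 25, 3, 21)
  st <- solver_state(g, field = f0, dt = 0.25, boundary_T = 21,
                     params = tissue_params(D = 2))
  st <- simulate_bioheat(st, 3)
  expect_lt(max(abs(st$field - analytic_gaussian_field(g, 3, 2, 25, 3, 21))),
            0.12)
})

test_that("the scheme is bounded and symmetric with a clamped source", {
  g <- volume_grid(c(24L, 24L, 24L), 1)
  z <- grid_coords(g, 3)
  q <- exp(-0.5 * ((z - mean(z)) / 5)^2)
  src <- absolute_source(structure(list(rows = seq_along(z) - 1L,
                                        z_mm = z, q = q, q_max = 1,
                                        T_abs = NULL),
                                   class = "source_profile"), 120)
  for (dtv in c(0.1, 2)) {
    st <- solver_state(g, dt = dtv, boundary_T = 21, source = src,
                       params = tissue_params(D = 3))
    for (i in 1:20) st <- adi_step(st)
    expect_true(all(is.finite(st$field)))
    expect_gte(min(st$field), 21 - 1e-9)
    expect_lte(max(st$field), 120 + 1e-9)
    # mirror symmetry about the axis in x and y
    expect_lt(max(abs(st$field - st$field[24:1, , ])), 1e-9)
    expect_lt(max(abs(st$field - st$field[, 24:1, ])), 1e-9)
  }
})

test_that("simulate composes and honours zero duration", {
  g <- volume_grid(c(10L, 10L, 10L), 1)
  f0 <- analytic_gaussian_field(g, 0, 1, 10, 2, 21)
  st <- solver_state(g, field = f0, dt = 0.5, boundary_T = 21,
                     params = tissue_params(D = 1))
  expect_identical(simulate_bioheat(st, 0)$field, st$field)
  a <- simulate_bioheat(simulate_bioheat(st, 2), 2)
  b <- simulate_bioheat(st, 4)
  expect_equal(a$field, b$field)
  expect_equal(a$time, b$time)
})

test_that("a perfused tube depresses the steady temperature inside it", {
  g <- volume_grid(c(24L, 24L, 24L), 1)
  z <- grid_coords(g, 3)
  src <- absolute_source(structure(list(rows = seq_along(z) - 1L,
                                        z_mm = z, q = rep(1, length(z)),
                                        q_max = 1, T_abs = NULL),
                                   class = "source_profile"), 100)
  mask <- array(FALSE, g$shape)
  xs <- grid_coords(g, 1)
  mask[abs(xs - 6) <= 2, abs(grid_coords(g, 2)) <= 2, ] <- TRUE
  run <- function(wb, m) {
    st <- solver_state(g, dt = 1, boundary_T = 21, source = src,
                       params = tissue_params(D = 1.5, w_b = wb),
                       sink_mask = m)
    simulate_bioheat(st, 120)$field
  }
  hot <- run(0, NULL)
  cooled <- run(80, mask)
  expect_lt(mean(cooled[mask]), mean(hot[mask]) - 1)
  expect_true(all(cooled[mask] <= hot[mask] + 1e-9))
})
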