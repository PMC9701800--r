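test_that("bounded Levenberg-Marquardt finds closed-form minima", {
  # quadratic toy residual with minimum (2, 150) inside the bounds
  toy <- function(P) c(P$D - 2, (P$T_max - 150) / 50)
  fit <- lm_fit(toy, parameter_set(D = 0.5, T_max = 90))
  expect_equal(fit$params$D, 2, tolerance = 1e-6)
  expect_equal(fit$params$T_max, 150, tolerance = 1e-3)
  expect_lte(fit$record$sse_after, fit$record$sse_before)
  # already-converged start returns the start
  fit0 <- lm_fit(toy, parameter_set(D = 2, T_max = 150))
  expect_equal(fit0$params$D, 2, tolerance = 1e-8)
  expect_lte(fit0$record$n_iterations, 1)
  # unrealistic start outside the bounds is projected in first
  fit7 <- lm_fit(toy, parameter_set(D = 10, T_max = 500))
  expect_equal(fit7$params$D, 2, tolerance = 1e-6)
  expect_true(fit7$params$T_max >= 80 && fit7$params$T_max <= 300)
  # a minimum outside the box lands on the bound
  low <- function(P) c(P$D - 0.01, (P$T_max - 150) / 50)
  expect_equal(lm_fit(low, parameter_set())$params$D, 0.1)
})

test_that("residuals vanish for a simulation matching the measurements", {
  g <- volume_grid(c(20L, 21L, 20L), 1)
  st <- solver_state(g, field = array(30, g$shape), boundary_T = 30,
                     dt = 0.5, params = tissue_params(D = 1))
  iso <- synthetic_iso_set(rep(4, 20), axis_col = 10L, isovalue = 30)
  qp <- source_profile(iso, min_radius = 0)
  r <- residuals_thermo(parameter_set(D = 1, T_max = 100), st, iso, qp, 0)
  expect_equal(r, rep(0, 20), ignore_attr = TRUE)
  # a uniform +2 simulation offset appears as a constant residual
  st$field[] <- 32; st$boundary_T <- 32
  r2 <- residuals_thermo(parameter_set(D = 1, T_max = 100), st, iso, qp, 0)
  expect_equal(r2, rep(2, 20), ignore_attr = TRUE)
})

test_that("the forward model is self-consistent at the true parameters", {
  # synthetic series from the generator: SSE at the truth must beat a
  # substantially perturbed diffusivity
  sp <- tiny_phantom_spec(noise_sigma = 0)
  ph <- generate_series(sp)
  st <- solver_state(sp$grid, dt = sp$dt, boundary_T = sp$baseline_T0,
                     params = tissue_params(D = sp$true_D))
  m <- ph$maps[[2]]
  iso <- extract_isotherm_set(m, default_isovalues(sp$baseline_T0))
  qp <- source_profile(iso)
  sse <- function(D, Tm) sum(residuals_thermo(
    parameter_set(D = D, T_max = Tm), st, iso, qp,
    2 * sp$acquisition_interval)^2)
  expect_lt(sse(sp$true_D, sp$true_Tmax),
            sse(sp$true_D * 3, sp$true_Tmax))
})

test_that("adaptive updates fit every image and tolerate corrupt ones", {
  sp <- tiny_phantom_spec()
  ph <- generate_series(sp)
  # corrupt one map beyond use: every pixel invalid
  ph$maps[[3]]$valid_mask[] <- FALSE
  rec <- run_reconstruction(ph$maps, grid = sp$grid,
                            opts = list(interval = sp$acquisition_interval))
  expect_equal(nrow(rec$fits), length(ph$maps))
  expect_true(rec$fits$skipped[3])
  expect_false(any(rec$fits$skipped[-3]))
  ok <- !rec$fits$skipped
  expect_true(all(rec$fits$sse_after[ok] <= rec$fits$sse_before[ok] + 1e-9))
  expect_true(all(rec$fits$D >= 0.1 & rec$fits$D <= 5))
  expect_true(all(rec$fits$T_max >= 80 & rec$fits$T_max <= 300))
})

test_that("reconstruction is deterministic for identical series", {
  sp <- tiny_phantom_spec(seed = 5L)
  ph <- generate_series(sp)
  opts <- list(interval = sp$acquisition_interval)
  r1 <- run_reconstruction(ph$maps, grid = sp$grid, opts = opts)
  r2 <- run_reconstruction(ph$maps, grid = sp$grid, opts = opts)
  expect_identical(r1$fits, r2$fits)
  expect_identical(r1$state$field, r2$state$field)
})
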