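test_that("cost maps are absolute deviations with infinite invalid cost", {
  m <- ridge_map(rows = 6L, cols = 11L, axis_col = 5L, peak = 25, slope = 0)
  cm <- cost_map(m, 25)
  expect_true(all(cm$values == 0))
  m$values[2, 3] <- 37
  expect_equal(cost_map(m, 21)$values[2, 3], 16)
  mb <- mask_applicator_band(m, 1)
  expect_true(all(is.infinite(cost_map(mb, 25)$values[, 5:7])))
})

test_that("the ridge isotherm is recovered exactly and resists outliers", {
  m <- ridge_map()                       # T = 60 - 2|c - 32|
  it <- extract_isotherm(cost_map(m, 50), side = "right")
  expect_true(all(it$vertices$col == 37))         # (60-50)/2 = 5 right
  expect_equal(it$total_cost, 0)
  itl <- extract_isotherm(cost_map(m, 50), side = "left")
  expect_true(all(itl$vertices$col == 27))
  # a single outlier on the ridge detours the path by at most one column
  # at that row only
  m2 <- m; m2$values[10, 38] <- 300
  it2 <- extract_isotherm(cost_map(m2, 50), side = "right")
  expect_true(all(abs(it2$vertices$col - 37) <= 1))
  expect_true(all(it2$vertices$col[-10] == 37))
  # monotone structure: exactly one vertex per row, steps bounded
  expect_equal(it2$vertices$row, 0:19)
  expect_true(all(abs(diff(it2$vertices$col)) <= 1))
})

test_that("zero-cost maps give a zero-cost monotone path deterministically", {
  m <- ridge_map(rows = 8L, cols = 9L, axis_col = 4L, peak = 25, slope = 0)
  it <- extract_isotherm(cost_map(m, 25), side = "right")
  expect_equal(it$total_cost, 0)
  expect_true(all(it$vertices$col == 5))   # axis-nearest tie-break
  it2 <- extract_isotherm(cost_map(m, 25), side = "right")
  expect_identical(it$vertices, it2$vertices)
})

test_that("dynamic programming matches exhaustive path enumeration", {
  set.seed(42)
  for (dims in list(c(5L, 5L), c(8L, 8L), c(8L, 4L), c(6L, 8L))) {
    for (rep in 1:5) {
      costs <- matrix(sample(0:9, prod(dims), replace = TRUE), dims[1])
      dp <- adaptherm:::monotone_path(costs)
      expect_equal(dp$total_cost, brute_force_min_path(costs))
      # the reported path attains the reported cost
      expect_equal(sum(costs[cbind(seq_len(dims[1]), dp$cols)]),
                   dp$total_cost)
    }
  }
})

test_that("isovalue ladders are uniform and anchored", {
  expect_equal(default_isovalues(21, 24, 8, anchor = 21),
               21 + (0:7) * 24 / 7)
  expect_equal(default_isovalues(21, 24, 1, anchor = 21), 21)
  expect_equal(default_isovalues(21, 24, 2, anchor = 21), c(21, 45))
  expect_equal(default_isovalues(21)[1], 21)    # anchored at baseline
  expect_error(default_isovalues(21, count = 0), "count")
})

test_that("isotherm sets nest by isovalue on a radial field", {
  m <- radial_map()                       # Gaussian radial profile
  isovals <- default_isovalues(21, 24, 8, anchor = 25)
  s <- extract_isotherm_set(m, isovals)
  expect_length(s$isotherms, 16)
  right <- Filter(function(it) it$side == "right", s$isotherms)
  radii <- vapply(right, function(it) mean(it$vertices$col) - 32,
                  numeric(1))
  expect_true(all(diff(radii) < 0))       # hotter isotherms sit inward
  # extracted radii match the closed-form Gaussian radius within 1 px
  analytic <- radial_isovalue_radius(isovals)
  expect_lt(max(abs(radii - analytic)), 1)
  # single-isovalue set reduces to extract_isotherm on each side
  s1 <- extract_isotherm_set(m, isovals[1])
  direct <- extract_isotherm(cost_map(m, isovals[1]), side = "right")
  expect_equal(Filter(function(it) it$side == "right",
                      s1$isotherms)[[1]]$vertices[, c("row", "col")],
               direct$vertices)
  # isovalue above the maximum hugs the ridge and is flagged
  shot <- extract_isotherm_set(m, 200)
  expect_true(all(vapply(shot$isotherms, `[[`, logical(1),
                         "extrapolated")))
  expect_true(all(vapply(shot$isotherms, function(it)
    max(abs(it$vertices$col - 32)), numeric(1)) <= 1))
})

test_that("strictly increasing isovalues are enforced", {
  m <- radial_map(rows = 10L)
  expect_error(extract_isotherm_set(m, c(30, 30)), "increasing")
  expect_error(extract_isotherm_set(m, c(35, 30)), "increasing")
})

test_that("contour extraction stays within a pixel under moderate noise", {
  set.seed(11)
  iso <- 40
  analytic <- radial_isovalue_radius(iso)
  errs <- replicate(25, {
    m <- radial_map(noise_sd = 1)
    it <- extract_isotherm(cost_map(m, iso), side = "right")
    sqrt(mean((it$vertices$col - 32 - analytic)^2))
  })
  expect_lt(median(errs), 1.5)
  # and noiseless extraction is sub-half-pixel
  m0 <- radial_map()
  it0 <- extract_isotherm(cost_map(m0, iso), side = "right")
  expect_lt(max(abs(it0$vertices$col - 32 - analytic)), 0.5 + 1e-9)
})
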