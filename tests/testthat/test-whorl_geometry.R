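test_that("whorl radius anchors: two-organ whorl and the observed range", {
  expect_equal(whorl_radius(110, 2), 55)
  expect_equal(whorl_radius(110, 10), 110 / (2 * sin(pi / 10)))
  expect_equal(whorl_radius(110, 10), 178, tolerance = 0.005)
  expect_equal(whorl_radius(110, 4), 110 / (2 * sin(pi / 4)))
  expect_equal(whorl_radius(110, 4), 77.8, tolerance = 0.001)
  expect_error(whorl_radius(110, 1), ">= 2")
  expect_error(whorl_radius(-1, 4), "positive")
})

test_that("count prediction matches the observed anchors and handles small whorls", {
  expect_equal(predict_nc(95, 110), 5L)    # the commonly observed whorl
  expect_equal(predict_nc(55, 110), 2L)
  expect_lte(predict_nc(41, 110), 1L)      # too small for a two-organ ring
  expect_equal(predict_nc(41, 110, pin_value = 0L), 0L)
  expect_equal(predict_nc(0, 110), 0L)
  expect_error(predict_nc(-5, 110), "non-negative")
})

test_that("radius and count prediction are mutually consistent", {
  for (n in 2:12) {
    expect_equal(predict_nc(whorl_radius(110, n), 110), n)
    expect_equal(predict_nc(whorl_radius(73, n), 73), n)
  }
  r <- whorl_radius(110, 2:12)
  expect_true(all(diff(r) > 0))            # radius grows with count
})

test_that("radius ratio across the count range is spacing-independent", {
  for (lam in c(55, 110, 200)) {
    tab <- growth_corrected_radius_table(lam)
    expect_equal(tab$r_um[tab$n_c == 10] / tab$r_um[tab$n_c == 2],
                 sin(pi / 2) / sin(pi / 10), tolerance = 1e-12)
  }
  expect_equal(sin(pi / 2) / sin(pi / 10), 3.24, tolerance = 0.005)
  t1 <- growth_corrected_radius_table(110)
  expect_equal(t1$r_um[1], 55)
  t2 <- growth_corrected_radius_table(220)
  expect_equal(t2$r_um, 2 * t1$r_um)       # linear homogeneity in spacing
})

test_that("hemisphere arc conversion matches the printed correspondences", {
  expect_equal(meridional_arc(55, 180), 56, tolerance = 0.01)
  expect_equal(meridional_arc(180, 180), pi * 180 / 2)
  expect_equal(meridional_arc(180, 180), 283, tolerance = 0.001)
  expect_equal(meridional_arc(0, 180), 0)
  expect_equal(horizontal_radius(165, 165), 139, tolerance = 0.002)
  expect_error(meridional_arc(200, 180), "<= R")
  expect_error(horizontal_radius(300, 180), "quarter")
})

test_that("arc and radius conversions are mutually inverse and arc >= r", {
  r <- seq(0, 179.9, length.out = 25)
  s <- meridional_arc(r, 180)
  expect_equal(horizontal_radius(s, 180), r, tolerance = 1e-12)
  expect_true(all(s[-1] > r[-1]))
  expect_equal(s[1], r[1])
})

test_that("diameter regression recovers a noiseless specification line", {
  tab <- data.frame(n_c = rep(2:7, each = 2),
                    diameter_um = (110 / pi) * rep(2:7, each = 2))
  fit <- suppressWarnings(fit_diameter_regression(tab))
  expect_equal(fit$slope, 110 / pi, tolerance = 1e-9)
  expect_equal(fit$lambda_estimate, 110, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
  expect_equal(pi * 35.0, 110, tolerance = 0.001)   # slope 35 means 110-um spacing
})

test_that("diameter regression rejects degenerate designs", {
  expect_error(fit_diameter_regression(
    data.frame(n_c = c(5, 5, 5), diameter_um = c(170, 180, 190))),
    "degenerate")
  expect_error(fit_diameter_regression(
    data.frame(n_c = c(2, 3), diameter_um = c(70, 105))), "at least 3")
  expect_error(fit_diameter_regression(data.frame(n_c = 1:5)), "lacks column")
})

test_that("spacing regression recovers the onset intercept and applies the filter", {
  len <- seq(10, 290, length.out = 30)
  tab <- data.frame(spacing_um = 145 + 0.1 * len, cotyledon_length_um = len)
  fit <- suppressWarnings(fit_spacing_regression(tab))
  expect_equal(fit$intercept, 145, tolerance = 1e-9)
  expect_equal(fit$slope, 0.1, tolerance = 1e-9)
  # rows at or beyond the length cut are excluded
  tab2 <- rbind(tab, data.frame(spacing_um = c(250, 260),
                                cotyledon_length_um = c(350, 400)))
  fit2 <- suppressWarnings(fit_spacing_regression(tab2, max_cotyledon_length = 300))
  expect_equal(fit2$n_points, 30)
  expect_error(fit_spacing_regression(tab, max_cotyledon_length = 5),
               "filter")
})
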