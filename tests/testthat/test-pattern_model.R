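test_that("closed-form precursor gradient has the right amplitude and decay", {
  p <- model_params()
  pr <- precursor_profile(p)
  expect_equal(pr$value[1], 100)            # apex amplitude equals P0
  expect_equal(max(pr$value), 100)
  B <- decay_constant(p$kP, p$DP)
  half <- precursor_profile(p, grid = log(2) / B)
  expect_equal(half$value, 50, tolerance = 1e-10)
  at18 <- precursor_profile(p, grid = 1.8)$value
  expect_equal(at18, 100 * exp(-sqrt(2) * 1.8), tolerance = 1e-12)
  expect_equal(at18, 7.85, tolerance = 0.001)
  expect_error(precursor_profile(model_params(DP = 0), grid = 1),
               "closed-form")
})

test_that("numerically solved precursor profile is anchored and monotone", {
  p <- model_params(p_mode = "pde")
  pr <- precursor_profile(p)
  expect_equal(max(pr$value), 100)
  expect_equal(pr$value[1], 100, tolerance = 1e-6)
  basal <- pr$value[pr$x > p$se]
  expect_true(all(diff(basal) < 0))
  # away from source and the no-flux basal end the log-slope is exponential
  mid <- pr$x > 0.3 & pr$x < 1.2
  slope <- stats::coef(stats::lm(log(pr$value[mid]) ~ pr$x[mid]))[2]
  expect_equal(unname(slope), -sqrt(2), tolerance = 0.02)
})

test_that("steady state without apical production is the uninhibited basal state", {
  sol <- solve_cached(update_params(model_params(), prodH = 0))
  expect_true(all(abs(sol$H) < 1e-6))
  expect_true(all(abs(sol$K - 100) < 1e-4))
})

test_that("reference parameter set places the interface near 1.8", {
  sol <- table1_solution()
  expect_lt(sol$residual, 1e-6)
  expect_equal(find_interface(sol), 1.8, tolerance = 0.05 / 1.8)
})

test_that("profiles are bounded, non-negative, and the precursor decreases", {
  for (p in list(model_params(), fig5_baseline(),
                 fig5_baseline(prodK = 220))) {
    sol <- solve_cached(p)
    expect_true(all(sol$H >= 0) && all(sol$K >= 0))
    expect_true(all(sol$H <= p$prodH / p$kH + 1e-6))
    expect_true(all(sol$K <= p$prodK / p$kK + 1e-6))
    basal <- sol$P[sol$x > p$se]
    expect_true(all(diff(basal) < 0))
  }
})

test_that("interior concentrations match the pointwise fixed point away from the interface", {
  p <- fig5_baseline()
  sol <- solve_cached(p)
  for (x0 in c(0.3, 0.6, 1.5, 2.0)) {     # interface sits near 0.93
    i <- which.min(abs(sol$x - x0))
    fp <- pointwise_fixed_point(p, sol$P[i])
    expect_equal(sol$H[i], fp$H, tolerance = 0.01)
    expect_equal(sol$K[i], fp$K, tolerance = 0.01)
  }
})

test_that("the steady state is insensitive to the H/K boundary condition", {
  p <- fig5_baseline()
  cx_n <- find_interface(solve_steady_state(p, bc = "neumann"))
  cx_d <- find_interface(solve_steady_state(p, bc = "dirichlet_basal"))
  expect_lt(abs(cx_n - cx_d), 0.01)
})

test_that("the steady state is independent of the initial condition", {
  p <- fig5_baseline()
  ref <- find_interface(solve_cached(p))
  set.seed(42)
  init <- list(H = runif(p$n_grid, 0, 400), K = runif(p$n_grid, 0, 100))
  alt <- find_interface(solve_steady_state(p, init = init))
  expect_lt(abs(ref - alt), 1e-3)
})

test_that("interface detection interpolates, ignores touches, flags multiples", {
  x <- seq(0, 3, length.out = 301)
  # single clean crossing at exactly 1.5
  s1 <- fake_solution(x, H = 100 - 40 * x, K = rep(40, 301))
  expect_equal(as.numeric(find_interface(s1)), 1.5, tolerance = 1e-9)
  # tangential touch at x = 1.5 is not a crossing
  s2 <- fake_solution(x, H = 40 + (x - 1.5)^2, K = rep(40, 301))
  expect_true(is.na(find_interface(s2)))
  # no sign change at all
  s3 <- fake_solution(x, H = rep(80, 301), K = rep(40, 301))
  expect_true(is.na(find_interface(s3)))
  # oscillating difference: most apical crossing returned, warning raised
  s4 <- fake_solution(x, H = 40 + 10 * cos(2 * pi * x), K = rep(40, 301))
  expect_warning(cx <- find_interface(s4), "multiple")
  expect_equal(as.numeric(cx), 0.25, tolerance = 0.01)
})

test_that("trough extraction matches the reference width and edge concentrations", {
  sol <- fig5b_solution()
  tr <- find_trough(sol)
  expect_equal(nrow(tr), 1)
  expect_false(tr$unbounded_basal)
  expect_equal(tr$width, 0.29, tolerance = 0.03 / 0.29)
  # frozen from the quadratic H^2 - 49 H + 50 = 0 for H + K = 50 at K = 100/(1+H)
  H_at <- stats::approx(sol$x, sol$H, xout = c(tr$lower, tr$upper))$y
  K_at <- stats::approx(sol$x, sol$K, xout = c(tr$lower, tr$upper))$y
  expect_equal(H_at[1], 47.957, tolerance = 0.02)
  expect_equal(K_at[2], 48.957, tolerance = 0.02)
})

test_that("trough is empty when the basal factor is uniformly high", {
  sol <- solve_cached(update_params(model_params(), inhK = 0))
  expect_equal(nrow(find_trough(sol)), 0)    # K = 100 everywhere, H + K > 50
  expect_error(find_trough(sol, threshold = -1), "positive")
})

test_that("outcome classification covers shifts, elimination, and competence", {
  base <- fig5b_solution()
  expect_equal(classify_outcome(base, base)$outcome, "unchanged")
  expect_equal(classify_outcome(base, base)$delta_x, 0)

  up <- solve_cached(fig5_baseline(prodH = 1200))
  cls <- classify_outcome(up, base)
  expect_equal(cls$outcome, "basipetal_shift")
  expect_equal(cls$delta_x, 0.20, tolerance = 0.05 / 0.20)

  gone <- solve_cached(fig5_baseline(prodK = 300))
  expect_equal(classify_outcome(gone, base)$outcome, "interface_eliminated")

  basal <- solve_cached(fig5_baseline(prodK = 10))
  expect_equal(classify_outcome(basal, base)$outcome, "basal_boundary_removed")

  runaway <- solve_cached(fig5_baseline(inhH = 0, prodH = 60000,
                                        competence_limit = 2.0))
  expect_equal(classify_outcome(runaway, base)$outcome, "beyond_competence")
})

test_that("parameter validation rejects invalid configurations", {
  expect_error(model_params(kP = -1), ">= 0")
  expect_error(model_params(nH = 2.5), "integer")
  expect_error(model_params(se = 3), "se")
  expect_error(model_params(n_grid = 10), "n_grid")
  expect_error(update_params(model_params(), nope = 1), "unknown")
})
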