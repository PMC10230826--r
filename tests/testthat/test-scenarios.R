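test_that("the reference scenario reproduces position, trough and count consistency", {
  rep5 <- run_scenario("fig5B")
  expect_equal(rep5$crossing_x, 0.95, tolerance = 0.05 / 0.95)
  expect_equal(rep5$trough_width, 0.29, tolerance = 0.03 / 0.29)
  expect_equal(rep5$outcome, "acropetal_shift")   # relative to no inhibition
  expect_true(rep5$pass)
  # the count prediction is the geometric map of the computed position
  expect_equal(rep5$predicted_nc,
               predict_nc(100 * rep5$crossing_x, 110))
  expect_equal(predict_nc(95, 110), 5L)           # printed position -> 5 organs
})

test_that("unknown scenario ids fail with the available catalog listed", {
  expect_error(run_scenario("nope"), "fig5B")
})

test_that("perturbation scenarios reproduce the documented qualitative outcomes", {
  reports <- run_all_scenarios()
  expect_equal(reports$fig6C$outcome, "interface_eliminated")
  expect_equal(reports$fig7B$outcome, "interface_eliminated")
  expect_equal(reports$fig8B$outcome, "basal_boundary_removed")
  expect_true(any(reports$fig8B$trough$unbounded_basal))
  expect_equal(reports$fig8C$outcome, "beyond_competence")
  expect_true(reports$fig7C$outcome %in%
                c("acropetal_shift", "interface_eliminated"))
  # every catalog entry with printed expectations meets them
  tab <- scenario_summary_table(reports)
  expect_true(all(tab$pass[!is.na(tab$pass)]))
})

test_that("the H-inhibited zone extends past the competence limit when pushed", {
  sol <- solve_cached(fig5_baseline(inhH = 0, prodH = 60000,
                                    competence_limit = 2.0))
  edge <- whorlpos:::h_extent(sol, sol$params$trough_threshold)
  expect_gt(edge, 2.0)     # H > threshold beyond 200 um from the tip
})

test_that("PDE and mean-field crossings agree across the whole catalog", {
  reports <- run_all_scenarios()
  for (r in reports) {
    if (is.na(r$crossing_x) || is.na(r$crossing_oracle)) {
      expect_equal(is.na(r$crossing_x), is.na(r$crossing_oracle),
                   info = r$id)
    } else {
      expect_lt(abs(r$crossing_x - r$crossing_oracle), 0.05)
    }
  }
})

test_that("interface position responds monotonically to each regulator", {
  cross <- function(...) crossing_of(fig5_baseline(...))
  # stronger K-on-H inhibition pulls the interface apically
  expect_true(all(diff(vapply(c(1.4, 2.0, 2.4, 3.0, 4.9), function(v)
    cross(inhH = v), numeric(1))) < 0))
  # stronger apical production pushes it basally
  expect_true(all(diff(vapply(c(300, 450, 600, 900, 1200), function(v)
    cross(prodH = v), numeric(1))) > 0))
  # weaker activation affinity (larger KA) pulls it apically
  expect_true(all(diff(vapply(c(20, 26, 32, 40, 50), function(v)
    cross(KA = v), numeric(1))) < 0))
  # stronger basal production pulls it apically
  expect_true(all(diff(vapply(c(80, 100, 150, 200, 220), function(v)
    cross(prodK = v), numeric(1))) < 0))
})

test_that("balanced production rescaling leaves the interface in place", {
  x0 <- crossing_of(fig5_baseline())
  x2 <- crossing_of(fig5_baseline(prodH = 1200, prodK = 200))
  expect_lt(abs(x2 - x0), 0.1)
})

test_that("basal overexpression depresses the apical maximum about five-fold", {
  r0 <- run_scenario("fig5B")
  r1 <- run_scenario("fig6B")
  expect_equal(r0$h_max / r1$h_max, 5, tolerance = 0.25)
})

test_that("steepness sweep: reference row matches, inhibition demand grows with nH", {
  sw <- table2_sweep(method = "oracle")
  expect_true(all(sw$feasible))
  expect_true(all(diff(sw$inhH_needed) > 0))
  expect_equal(sw$prodH_rebased[sw$nH == 3], 600, tolerance = 1e-6)
  expect_equal(sw$inhH_needed[sw$nH == 3], 4.9, tolerance = 0.03)
  expect_equal(sw$trough_width[sw$nH == 3], 0.29, tolerance = 0.03 / 0.29)
  # steeper interfaces carry narrower troughs (counts >= 3 where domains are sharp)
  sharp <- sw[sw$nH >= 3, ]
  expect_true(all(diff(sharp$trough_width) < 0))
  # PDE refinement of the reference row agrees with the closed-form values
  sw3 <- table2_sweep(nH_values = 3, method = "pde")
  expect_equal(sw3$inhH_needed, 4.9, tolerance = 0.03)
  expect_equal(sw3$trough_width, 0.29, tolerance = 0.03 / 0.29)
})

test_that("shift summaries convert positions to micrometres and organ counts", {
  s <- shift_summary("fig5B", "expG")
  expect_equal(s$delta_x_um, 20, tolerance = 5 / 20)
  # a 20-um shift at the printed positions adds exactly one organ; the
  # computed crossings sit marginally apical of those, so allow the count
  # step to land on either side of the 5-organ boundary
  expect_equal(predict_nc(115, 110) - predict_nc(95, 110), 1L)
  expect_gte(s$delta_nc, 1L)
  same <- shift_summary("fig5B", "fig5B")
  expect_equal(same$delta_x_um, 0)
  expect_equal(same$delta_nc, 0L)
  gone <- shift_summary("fig5B", "fig7B")
  expect_true(is.na(gone$delta_x_um))
  expect_equal(gone$perturbed_outcome, "interface_eliminated")
  drop <- shift_summary("fig5B", "fig6B")
  expect_equal(drop$delta_x_um, -54, tolerance = 8 / 54)
  expect_lt(drop$perturbed_nc, 2)
})

test_that("scenario reports are deterministic", {
  a <- run_scenario("fig6B")
  b <- run_scenario("fig6B")
  expect_identical(scenario_summary_table(list(a)),
                   scenario_summary_table(list(b)))
})

test_that("config and report round-trips work for both formats", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("prodH: 600", "KA: 32", "inhH: 2.4"), cfg)
  p <- read_params_config(cfg)
  expect_equal(p$prodH, 600)
  expect_equal(p$KA, 32)
  cfgj <- tempfile(fileext = ".json")
  writeLines('{"DP": 0.045, "n_grid": 120}', cfgj)
  pj <- read_params_config(cfgj)
  expect_equal(pj$DP, 0.045)
  expect_equal(pj$n_grid, 120)
  expect_error(read_params_config(cfg <- {
    f <- tempfile(fileext = ".yaml"); writeLines("bogus: 1", f); f
  }), "unknown parameter")

  sol <- fig5b_solution()
  tsv <- tempfile(fileext = ".tsv")
  write_profile_tsv(sol, tsv)
  prof <- utils::read.delim(tsv)
  expect_equal(names(prof), c("x", "P", "H", "K"))
  expect_equal(nrow(prof), sol$params$n_grid)
  js <- tempfile(fileext = ".json")
  write_summary_json(sol, js)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$crossing_x, find_interface(sol), tolerance = 1e-9)
  expect_equal(parsed$oracle$crossing_x,
               mean_field_interface(sol$params)$crossing_x, tolerance = 1e-9)
})
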