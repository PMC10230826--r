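#' Catalog of perturbation scenarios
#'
#' Returns the built-in catalog of model configurations reproducing the
#' documented interface-positioning analyses: the precursor-gradient series
#' (reference crossing at `x = 1.8`, a 10/3-fold steeper gradient, a 5.6-fold
#' weaker activation affinity), the mutual-inhibition ladder
#' (`inhH = 0, 2.4, 4.9` on the `prodH = 600`, `KA = 32` baseline), and the
#' experimental perturbation set: basal-factor overexpression (2.2-fold and
#' 3-fold `prodK`), apical loss of function (6-fold and 3-fold `prodH`
#' decrease), basal loss of function (10-fold `prodK` decrease), inhibition-
#' resistant apical overexpression (`inhH = 0` with 100-fold `prodH`), and
#' apical gain of function (2-fold `prodH`).
#'
#' Each entry records the base parameter set, symbol overrides, the id of
#' the scenario it is classified against, expected printed values (with
#' tolerances) where these exist, and notes.
#'
#' @return Named list of scenario definitions.
#' @export
scenario_catalog <- function() {
  sc <- function(id, base, overrides = list(), baseline = NA_character_,
                 expected = NULL, notes = "") {
    list(id = id, base = base, overrides = overrides, baseline = baseline,
         expected = expected, notes = notes)
  }
  list(
    fig4A = sc("fig4A", "table1",
               expected = list(crossing_x = 1.8, tol = 0.05),
               notes = "reference gradient; interface at 180 um (n_c ~ 10)"),
    fig4B = sc("fig4B", "table1", list(DP = 0.045), baseline = "fig4A",
               expected = list(crossing_x = 0.54, tol = 0.05,
                               outcome = "acropetal_shift"),
               notes = "decay constant B x 10/3 via DP (B = sqrt(kP/DP))"),
    fig4C = sc("fig4C", "table1", list(KA = 98), baseline = "fig4A",
               expected = list(crossing_x = 0.55, tol = 0.05,
                               outcome = "acropetal_shift"),
               notes = "activation affinity KA x 5.6"),
    fig5A = sc("fig5A", "fig5", list(inhH = 0),
               expected = list(crossing_x = 1.8, tol = 0.05),
               notes = "inhibition ladder start; no K-on-H inhibition"),
    fig5B = sc("fig5B", "fig5", list(inhH = 2.4), baseline = "fig5A",
               expected = list(crossing_x = 0.95, tol = 0.05,
                               trough_width = 0.29, width_tol = 0.03,
                               outcome = "acropetal_shift"),
               notes = "reference pattern for all perturbation scenarios"),
    fig5C = sc("fig5C", "fig5", list(inhH = 4.9), baseline = "fig5A",
               expected = list(crossing_x = 0.55, tol = 0.05,
                               outcome = "acropetal_shift"),
               notes = "strong K-on-H inhibition; two-cotyledon position"),
    relief3p5 = sc("relief3p5", "fig5", list(inhH = 4.9 / 3.5),
                   baseline = "fig5C",
                   expected = list(crossing_x = 1.1, tol = 0.05,
                                   outcome = "basipetal_shift"),
                   notes = "3.5-fold inhH relief doubles the distance from 0.55"),
    fig6B = sc("fig6B", "fig5", list(inhH = 2.4, prodK = 220),
               baseline = "fig5B",
               expected = list(crossing_x = 0.41, tol = 0.05,
                               outcome = "acropetal_shift"),
               notes = "basal overexpression 2.2x (small-RNA proxy); 5-fold H_max drop"),
    fig6C = sc("fig6C", "fig5", list(inhH = 2.4, prodK = 300),
               baseline = "fig5B",
               expected = list(outcome = "interface_eliminated"),
               notes = "ectopic basal expression 3x eliminates the interface"),
    fig7B = sc("fig7B", "fig5", list(inhH = 2.4, prodH = 100),
               baseline = "fig5B",
               expected = list(outcome = "interface_eliminated"),
               notes = "apical loss of function: 6-fold prodH decrease"),
    fig7C = sc("fig7C", "fig5", list(inhH = 2.4, prodH = 200),
               baseline = "fig5B",
               expected = list(outcome = c("acropetal_shift",
                                           "interface_eliminated")),
               notes = paste("3-fold prodH decrease; qualitative only -- the",
                             "documented numeric position is not attainable",
                             "from this baseline (required occupancy > 1)")),
    fig8B = sc("fig8B", "fig5", list(inhH = 2.4, prodK = 10),
               baseline = "fig5B",
               expected = list(outcome = "basal_boundary_removed"),
               notes = "basal loss of function: 10-fold prodK decrease"),
    fig8C = sc("fig8C", "fig5",
               list(inhH = 0, prodH = 60000, competence_limit = 2.0),
               baseline = "fig5B",
               expected = list(outcome = "beyond_competence"),
               notes = paste("inhibition-resistant apical overexpression",
                             "(inhH = 0, prodH x 100); H > threshold beyond",
                             "the 200-um competence zone")),
    expG = sc("expG", "fig5", list(inhH = 2.4, prodH = 1200),
              baseline = "fig5B",
              expected = list(crossing_x = 1.15, tol = 0.05,
                              outcome = "basipetal_shift"),
              notes = "apical gain of function: 2-fold prodH, +20 um (one organ)")
  )
}

scenario_params <- function(sc) {
  base <- switch(sc$base,
                 table1 = model_params(),
                 fig5 = fig5_baseline(inhH = 0),
                 stop("unknown scenario base: ", sc$base))
  if (length(sc$overrides)) base <- do.call(update_params, c(list(base), sc$overrides))
  base
}

# Steady-state solve memoised on the parameter values (scenario catalogs and
# sweeps revisit identical configurations).
.solution_cache <- new.env(parent = emptyenv())
cached_solve <- function(params) {
  key <- paste(vapply(params, function(v) paste(format(v, digits = 15),
                                                collapse = ","),
                      character(1)), collapse = "|")
  sol <- .solution_cache[[key]]
  if (is.null(sol)) {
    sol <- solve_steady_state(params)
    .solution_cache[[key]] <- sol
  }
  sol
}

#' Run one scenario from the catalog
#'
#' Solves the scenario configuration to steady state, extracts the interface
#' position, permissive trough and `H` maximum, classifies the outcome
#' against the scenario's baseline, attaches the independent mean-field
#' (oracle) crossing prediction, converts the interface position into a
#' predicted cotyledon count (spacing 110 um, 1 spatial unit = 100 um), and
#' evaluates any expected printed values.
#'
#' @param id Scenario id (see [scenario_catalog()]).
#' @param catalog Scenario catalog; defaults to the built-in one.
#' @param lam Inter-cotyledon spacing (um) used for the count prediction.
#' @return A list of class `scenario_report`.
#' @examples
#' \donttest{
#' run_scenario("fig5B")
#' }
#' @export
run_scenario <- function(id, catalog = scenario_catalog(), lam = 110) {
  if (!id %in% names(catalog))
    stop("unknown scenario '", id, "'; available: ",
         paste(names(catalog), collapse = ", "))
  sc <- catalog[[id]]
  params <- scenario_params(sc)
  sol <- cached_solve(params)
  res <- interface_result(sol)
  oracle <- mean_field_interface(params)
  cls <- if (!is.na(sc$baseline)) {
    base_sol <- cached_solve(scenario_params(catalog[[sc$baseline]]))
    classify_outcome(sol, base_sol)
  } else {
    list(outcome = res$outcome, delta_x = NA_real_)
  }
  predicted_nc <- if (!is.na(res$crossing_x))
    predict_nc(100 * res$crossing_x, lam) else 0L
  pass <- evaluate_expected(sc$expected, res, cls)
  structure(list(id = id, params = params,
                 crossing_x = res$crossing_x,
                 crossing_oracle = oracle$crossing_x,
                 trough = res$trough,
                 trough_width = sum(res$trough$width[!res$trough$unbounded_basal]),
                 h_max = res$h_max,
                 outcome = cls$outcome, delta_x = cls$delta_x,
                 predicted_nc = predicted_nc,
                 expected = sc$expected, pass = pass, notes = sc$notes),
            class = "scenario_report")
}

evaluate_expected <- function(expected, res, cls) {
  if (is.null(expected)) return(NA)
  ok <- TRUE
  if (!is.null(expected$crossing_x)) {
    tol <- if (is.null(expected$tol)) 0.05 else expected$tol
    ok <- ok && !is.na(res$crossing_x) &&
      abs(res$crossing_x - expected$crossing_x) <= tol
  }
  if (!is.null(expected$trough_width)) {
    wtol <- if (is.null(expected$width_tol)) 0.03 else expected$width_tol
    w <- sum(res$trough$width[!res$trough$unbounded_basal])
    ok <- ok && abs(w - expected$trough_width) <= wtol
  }
  if (!is.null(expected$outcome))
    ok <- ok && cls$outcome %in% expected$outcome
  ok
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("Scenario %s: %s\n", x$id, x$notes))
  if (!is.na(x$crossing_x))
    cat(sprintf("  interface at x = %.3f (oracle %.3f), predicted n_c = %d\n",
                x$crossing_x, x$crossing_oracle, x$predicted_nc))
  else cat("  no H-K interface\n")
  cat(sprintf("  outcome: %s", x$outcome))
  if (!is.na(x$delta_x)) cat(sprintf(" (delta x = %+.3f)", x$delta_x))
  cat(sprintf("\n  trough width = %.3f, h_max = %.4g\n",
              x$trough_width, x$h_max))
  if (!is.na(x$pass)) cat(sprintf("  expected values: %s\n",
                                  if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Run every scenario in the catalog
#'
#' @param catalog Scenario catalog.
#' @param lam Inter-cotyledon spacing (um) for count predictions.
#' @return A list of `scenario_report`s, named by id.
#' @export
run_all_scenarios <- function(catalog = scenario_catalog(), lam = 110) {
  stats::setNames(lapply(names(catalog), run_scenario, catalog = catalog,
                         lam = lam), names(catalog))
}

#' Tabulate scenario reports
#'
#' @param reports A list of `scenario_report`s from [run_all_scenarios()].
#' @return A data.frame with one row per scenario (crossings, oracle
#'   crossings, trough width, `H` maximum, outcome, predicted count,
#'   pass/fail).
#' @export
scenario_summary_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(id = r$id,
               crossing_x = r$crossing_x,
               crossing_oracle = r$crossing_oracle,
               trough_width = r$trough_width,
               h_max = r$h_max,
               outcome = r$outcome,
               delta_x = r$delta_x,
               predicted_nc = r$predicted_nc,
               pass = r$pass,
               row.names = NULL)
  }))
}

#' Interface steepness sweep over Hill coefficients
#'
#' For each Hill coefficient, re-baselines the apical production rate so
#' that the no-inhibition interface sits at the reference position (the
#' `nH = 3`, `prodH = 600`, `KA = 32` crossing near `x = 1.8`; this recovers
#' `prodH = 600` exactly at `nH = 3`), then determines the inhibition
#' strength `inhH` that moves the crossing to `x = 0.55`, and the permissive
#' trough width when the crossing is placed at `x = 0.95`. Steeper apical
#' domains (larger `nH`) need disproportionately larger inhibition changes
#' for the same shift and carry narrower troughs.
#'
#' @param nH_values Hill coefficients to sweep. Default `1:6`.
#' @param method `"pde"` (default): root-solve `inhH` on the full
#'   reaction--diffusion crossing, seeded by the mean-field value;
#'   `"oracle"`: closed-form mean-field inversion only.
#' @param x_shift_target Crossing target of the inhibition column. Default
#'   0.55.
#' @param x_width_target Crossing position at which the trough width is
#'   measured. Default 0.95.
#' @return A data.frame with columns `nH`, `prodH_rebased`, `inhH_needed`,
#'   `trough_width`, `feasible`, `scheme`.
#' @export
table2_sweep <- function(nH_values = 1:6, method = c("pde", "oracle"),
                         x_shift_target = 0.55, x_width_target = 0.95) {
  method <- match.arg(method)
  ref <- fig5_baseline(inhH = 0)
  x_ref <- mean_field_interface(ref)$crossing_x
  B <- decay_constant(ref$kP, ref$DP)
  C <- crossing_concentration(ref)
  occ_at <- function(x, nH) {
    P <- ref$P0 * exp(-B * x)
    P^nH / (ref$KA^nH + P^nH)
  }
  inhH_for <- function(prodH, nH, x_target) {
    # mean-field inversion of the crossing condition at x_target
    a <- (prodH * occ_at(x_target, nH) / (C * ref$kH) - 1) / C
    if (a < 0) return(NA_real_)
    if (method == "oracle") return(a)
    f <- function(i) {
      p <- update_params(ref, nH = as.integer(nH), prodH = prodH, inhH = i)
      cx <- suppressWarnings(find_interface(cached_solve(p)))
      if (is.na(cx)) return(-x_target)   # eliminated: counts as far apical
      cx - x_target
    }
    tryCatch(stats::uniroot(f, lower = max(0, a / 2), upper = 2 * a + 0.5,
                            extendInt = "downX", tol = 1e-4)$root,
             error = function(e) NA_real_)
  }
  rows <- lapply(nH_values, function(nH) {
    prodH_n <- C * ref$kH / occ_at(x_ref, nH)
    i_shift <- inhH_for(prodH_n, nH, x_shift_target)
    i_width <- inhH_for(prodH_n, nH, x_width_target)
    width <- NA_real_
    if (!is.na(i_width)) {
      p <- update_params(ref, nH = as.integer(nH), prodH = prodH_n,
                         inhH = i_width)
      width <- if (method == "oracle") mean_field_trough(p)$width
      else {
        tr <- find_trough(cached_solve(p))
        sum(tr$width)
      }
    }
    data.frame(nH = as.integer(nH), prodH_rebased = prodH_n,
               inhH_needed = i_shift, trough_width = width,
               feasible = !is.na(i_shift))
  })
  out <- do.call(rbind, rows)
  out$scheme <- "rebase_prodH_keep_KA"
  out
}

#' Positional and cotyledon-count shift between two scenarios
#'
#' Signed displacement of the H--K interface between a baseline and a
#' perturbed scenario, in micrometres (1 spatial unit = 100 um), and the
#' implied change in predicted cotyledon count at the given spacing.
#'
#' @param baseline_id,perturbed_id Scenario ids.
#' @param catalog Scenario catalog.
#' @param lam Inter-cotyledon spacing (um). Default 110.
#' @return A list with `delta_x_um`, `delta_nc`, the two crossings (spatial
#'   units) and counts; when either scenario lacks a crossing, the outcome
#'   labels are returned instead of the deltas.
#' @examples
#' \donttest{
#' shift_summary("fig5B", "expG")   # +20 um, one extra cotyledon
#' }
#' @export
shift_summary <- function(baseline_id, perturbed_id,
                          catalog = scenario_catalog(), lam = 110) {
  r1 <- run_scenario(baseline_id, catalog, lam)
  r2 <- run_scenario(perturbed_id, catalog, lam)
  if (is.na(r1$crossing_x) || is.na(r2$crossing_x))
    return(list(delta_x_um = NA_real_, delta_nc = NA_integer_,
                baseline_outcome = r1$outcome, perturbed_outcome = r2$outcome))
  list(delta_x_um = 100 * (r2$crossing_x - r1$crossing_x),
       delta_nc = r2$predicted_nc - r1$predicted_nc,
       baseline_x = r1$crossing_x, perturbed_x = r2$crossing_x,
       baseline_nc = r1$predicted_nc, perturbed_nc = r2$predicted_nc)
}
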