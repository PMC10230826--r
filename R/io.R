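#' Read a model parameter configuration
#'
#' Loads a parameter set from a YAML or JSON mapping of parameter symbols
#' (`P0`, `se`, `kP`, `DP`, `prodH`, `nH`, `KA`, `inhH`, `kH`, `DH`,
#' `prodK`, `inhK`, `kK`, `DK`, `domain_length`, `n_grid`, `t_end`,
#' `trough_threshold`, `competence_limit`, `p_mode`). Unspecified symbols
#' keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `whorl_params` object.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping of parameter names")
  known <- names(formals(model_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "))
  do.call(model_params, cfg)
}

#' Write steady-state profiles as tab-separated text
#'
#' One row per grid point with columns `x` (spatial units, 1 unit = 100 um),
#' `P`, `H`, `K`.
#'
#' @param solution A `whorl_solution`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(solution, path) {
  stopifnot(inherits(solution, "whorl_solution"))
  utils::write.table(
    data.frame(x = solution$x, P = solution$P, H = solution$H, K = solution$K),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an interface summary as JSON
#'
#' Serialises the crossing position, trough intervals, `H` maximum and
#' outcome of a solution, with the mean-field prediction under an `oracle`
#' key.
#'
#' @param solution A `whorl_solution`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(solution, path) {
  stopifnot(inherits(solution, "whorl_solution"))
  res <- interface_result(solution)
  oracle <- mean_field_interface(solution$params)
  obj <- list(units = "spatial units (1 unit = 100 um)",
              crossing_x = res$crossing_x,
              trough = res$trough,
              h_max = res$h_max,
              outcome = res$outcome,
              residual = solution$residual,
              oracle = list(crossing_x = oracle$crossing_x,
                            C = oracle$C, h_star = oracle$h_star))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a scenario summary table as TSV
#'
#' @param reports List of `scenario_report`s ([run_all_scenarios()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_table <- function(reports, path) {
  utils::write.table(scenario_summary_table(reports), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a regression fit as JSON
#'
#' @param fit A `whorl_regression` from [fit_diameter_regression()] or
#'   [fit_spacing_regression()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_regression_json <- function(fit, path) {
  stopifnot(inherits(fit, "whorl_regression"))
  obj <- list(kind = fit$kind, slope = fit$slope, intercept = fit$intercept,
              slope_se = fit$slope_se, intercept_se = fit$intercept_se,
              lambda_estimate = fit$lambda_estimate,
              n_points = fit$n_points, r_squared = fit$r_squared,
              units = "um")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
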