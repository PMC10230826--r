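#' Model parameters for the precursor / apical / basal patterning system
#'
#' Builds and validates the full parameter set of the one-dimensional
#' patterning model: a precursor gradient `P` (source--diffusion--decay),
#' an apical factor `H` (HD-ZIP III class) activated by `P` through Hill
#' kinetics, and a basal factor `K` (KANADI class) produced constitutively.
#' `H` and `K` mutually inhibit each other through the `inhH` and `inhK`
#' terms. One spatial unit corresponds to 100 micrometres of tissue; the
#' default domain is 3 units (300 um) resolved on 300 grid points.
#'
#' @param P0 Precursor production rate (concentration/time) inside the source;
#'   also the apex amplitude of the closed-form gradient. Default 100.
#' @param se Spatial extent of the precursor source (spatial units). Default 0.1.
#' @param kP,kH,kK First-order decay constants (1/time). Defaults 1.
#' @param DP,DH,DK Diffusivities (space^2/time). Defaults 0.5, 1e-4, 1e-4.
#' @param prodH,prodK Production rate constants of the apical and basal factor.
#'   Defaults 100 each (the reference set); the inhibition-ladder baseline uses
#'   `prodH = 600`.
#' @param nH Hill coefficient of precursor activation of `H` (integer >= 1).
#'   Default 3.
#' @param KA Dissociation constant: precursor concentration at half-maximal
#'   `H` activation. Default 17.5 (32 in the inhibition-ladder baseline).
#' @param inhH Inhibition strength of `K` on `H` (1/concentration). Default 0.
#' @param inhK Inhibition strength of `H` on `K` (1/concentration). Default 1.
#' @param domain_length Length of the tissue axis (spatial units). Default 3.
#' @param n_grid Number of spatial grid points. Default 300.
#' @param t_end Integration horizon for the steady-state solve (time units).
#'   Default 200.
#' @param trough_threshold Combined `H + K` concentration below which tissue is
#'   permissive for primordium initiation. Default 50.
#' @param competence_limit Optional maximal distance from the tip (spatial
#'   units) at which tissue can still initiate primordia; `NA` disables the
#'   competence check.
#' @param p_mode How the precursor profile is computed: `"closed_form"`
#'   (exponential `P0 * exp(-B x)` with `B = sqrt(kP/DP)`; the default) or
#'   `"pde"` (numerical steady state of the source--diffusion--decay equation,
#'   rescaled so the apex concentration equals `P0`).
#'
#' @return An object of class `whorl_params`: a named list of validated
#'   parameters.
#'
#' @examples
#' p <- model_params()                      # reference parameter set
#' b <- fig5_baseline(inhH = 2.4)           # inhibition-ladder baseline
#' @seealso [fig5_baseline()], [solve_steady_state()]
#' @export
model_params <- function(P0 = 100, se = 0.1,
                         kP = 1, kH = 1, kK = 1,
                         DP = 0.5, DH = 1e-4, DK = 1e-4,
                         prodH = 100, prodK = 100,
                         nH = 3, KA = 17.5,
                         inhH = 0, inhK = 1,
                         domain_length = 3, n_grid = 300, t_end = 200,
                         trough_threshold = 50, competence_limit = NA_real_,
                         p_mode = c("closed_form", "pde")) {
  p_mode <- match.arg(p_mode)
  p <- list(P0 = P0, se = se, kP = kP, kH = kH, kK = kK,
            DP = DP, DH = DH, DK = DK,
            prodH = prodH, prodK = prodK,
            nH = nH, KA = KA, inhH = inhH, inhK = inhK,
            domain_length = domain_length, n_grid = n_grid, t_end = t_end,
            trough_threshold = trough_threshold,
            competence_limit = competence_limit,
            p_mode = p_mode)
  validate_params(p)
  class(p) <- "whorl_params"
  p
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("P0", "se", "kP", "kH", "kK", "DP", "DH", "DK",
               "prodH", "prodK", "nH", "KA", "inhH", "inhK",
               "domain_length", "n_grid", "t_end", "trough_threshold")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar")
  }
  nonneg <- c("P0", "kP", "kH", "kK", "DP", "DH", "DK",
              "prodH", "prodK", "KA", "inhH", "inhK")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) stop("parameters must be >= 0: ", paste(bad, collapse = ", "))
  if (p$nH < 1 || p$nH != round(p$nH)) stop("'nH' must be an integer >= 1")
  if (p$se < 0 || p$se >= p$domain_length)
    stop("'se' must satisfy 0 <= se < domain_length")
  if (p$domain_length <= 0) stop("'domain_length' must be positive")
  if (p$n_grid < 50) stop("'n_grid' must be at least 50")
  if (p$t_end <= 0) stop("'t_end' must be positive")
  if (p$trough_threshold <= 0) stop("'trough_threshold' must be positive")
  if (!is.na(p$competence_limit) && p$competence_limit <= 0)
    stop("'competence_limit' must be positive (or NA)")
  invisible(TRUE)
}

#' Baseline parameter set of the mutual-inhibition analyses
#'
#' The reference configuration used by the inhibition ladder and all
#' perturbation scenarios: `prodH = 600`, `KA = 32`, `inhK = 1`, everything
#' else at the [model_params()] defaults. With `inhH = 0` the H--K interface
#' sits near `x = 1.8`; `inhH = 2.4` places it at the commonly observed
#' `x = 0.95` (five-cotyledon whorl) and `inhH = 4.9` at `x = 0.55`
#' (two-cotyledon whorl).
#'
#' @param inhH Inhibition strength of `K` on `H`. Default 2.4, the reference
#'   pattern all perturbation scenarios start from.
#' @param ... Further overrides passed on to [model_params()].
#' @return A `whorl_params` object.
#' @export
fig5_baseline <- function(inhH = 2.4, ...) {
  args <- list(prodH = 600, KA = 32, inhH = inhH)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(model_params, args)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named values replaced, re-validated.
#'
#' @param params A `whorl_params` object.
#' @param ... Named parameter overrides (symbols as in [model_params()]).
#' @return A `whorl_params` object.
#' @examples
#' update_params(model_params(), DP = 0.045)   # steepen the precursor gradient
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "whorl_params"))
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(params))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    params[names(ov)] <- ov
  }
  validate_params(params)
  params
}

#' @export
print.whorl_params <- function(x, ...) {
  cat("Patterning model parameters (1 spatial unit = 100 um)\n")
  cat(sprintf("  P: P0 = %g, se = %g, kP = %g, DP = %g  (B = %.3f, mode = %s)\n",
              x$P0, x$se, x$kP, x$DP, sqrt(x$kP / x$DP), x$p_mode))
  cat(sprintf("  H: prodH = %g, nH = %d, KA = %g, inhH = %g, kH = %g, DH = %g\n",
              x$prodH, as.integer(x$nH), x$KA, x$inhH, x$kH, x$DH))
  cat(sprintf("  K: prodK = %g, inhK = %g, kK = %g, DK = %g\n",
              x$prodK, x$inhK, x$kK, x$DK))
  cat(sprintf("  domain: [0, %g] on %d points; t_end = %g; trough threshold = %g",
              x$domain_length, as.integer(x$n_grid), x$t_end, x$trough_threshold))
  if (!is.na(x$competence_limit))
    cat(sprintf("; competence limit = %g", x$competence_limit))
  cat("\n")
  invisible(x)
}
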