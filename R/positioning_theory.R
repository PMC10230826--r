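#' Exponential decay constant of a source--diffusion--decay gradient
#'
#' For a morphogen produced at a tip source, diffusing with diffusivity `DP`
#' and decaying at rate `kP`, the steady gradient is exponential with decay
#' constant `B = sqrt(kP / DP)` (1/spatial unit). `B` is the instantaneous
#' slope of the log-profile; larger `B` means a spatially shorter gradient.
#'
#' @param kP Decay rate constant (> 0).
#' @param DP Diffusivity (> 0).
#' @return The decay constant `B`.
#' @examples
#' decay_constant(1, 0.5)    # sqrt(2) ~ 1.414
#' @export
decay_constant <- function(kP, DP) {
  if (!is.numeric(kP) || !is.numeric(DP) || any(kP <= 0) || any(DP <= 0))
    stop("'kP' and 'DP' must be positive")
  sqrt(kP / DP)
}

#' Dosage factor for a three-fold positional shift
#'
#' On an exponential gradient `P = P0 exp(-B x)`, the amplitude fold-change
#' required to move the position of a fixed concentration from `x` to `3x` is
#' `a = exp(2 B x)`. The factor grows exponentially with both the decay
#' constant and the base position, which is why amplitude (dosage) variation
#' is an inefficient way to shift boundaries on steep gradients.
#'
#' @param B Decay constant (> 0).
#' @param x Base position of the shift (spatial units, > 0). Note the
#'   convention: the factor is evaluated at the *lower* position of the
#'   three-fold pair, so `dosage_factor(B, x)` moves `x` to `3x`.
#' @return The fold-change `a` (dimensionless).
#' @examples
#' dosage_factor(sqrt(2), 0.6)   # ~5.46 to shift from 0.6 to 1.8
#' @export
dosage_factor <- function(B, x) {
  if (!is.numeric(B) || any(B <= 0)) stop("'B' must be positive")
  if (!is.numeric(x) || any(x < 0)) stop("'x' must be non-negative")
  exp(B * 2 * x)
}

#' Decay constant placing a concentration a given factor farther from the tip
#'
#' Because position depends linearly on the gradient decay length, shifting
#' the location of a fixed concentration `shift_factor` times farther from
#' the tip requires `B2 = B1 / shift_factor` (for a three-fold shift,
#' `B1 = 3 B2`). Note `B` itself has a square-root dependence on the
#' underlying rate:diffusivity ratio, so a 9-fold change in `kP/DP` is needed
#' for a 3-fold change in position.
#'
#' @param B1 Starting decay constant (> 0).
#' @param shift_factor Positional fold-change (> 0).
#' @return The required decay constant `B2`.
#' @examples
#' decay_for_shift(sqrt(2), 3)   # B/3 moves the boundary 3x basally
#' @export
decay_for_shift <- function(B1, shift_factor) {
  if (!is.numeric(B1) || any(B1 <= 0)) stop("'B1' must be positive")
  if (!is.numeric(shift_factor) || any(shift_factor <= 0))
    stop("'shift_factor' must be positive")
  B1 / shift_factor
}

#' Pointwise mean-field prediction of the H--K interface
#'
#' Independent algebraic oracle for the crossing position, neglecting `H` and
#' `K` diffusion (their diffusion length `sqrt(DH/kH)` is 0.01 spatial units
#' at the defaults, far below reporting precision). At the crossing the two
#' steady concentrations are equal, `H = K = C`, where `C` solves
#' `C (1 + inhK C) = prodK / kK`. The Hill occupancy required of the
#' activation term is then `h* = C kH (1 + inhH C) / prodH`; if `h* >= 1` no
#' crossing is possible (the interface is eliminated). Otherwise the Hill
#' function and the exponential gradient are inverted:
#' `P* = KA (h*/(1-h*))^(1/nH)` and `x = log(P0/P*) / B`.
#'
#' @param params A `whorl_params` object (closed-form precursor mode).
#' @return A list with `crossing_x` (NA when no crossing exists or it falls
#'   outside the domain), the crossing concentration `C`, the required
#'   occupancy `h_star`, and the precursor concentration `P_star` at the
#'   crossing.
#' @examples
#' mean_field_interface(model_params())$crossing_x   # ~1.76
#' @export
mean_field_interface <- function(params) {
  stopifnot(inherits(params, "whorl_params"))
  C <- crossing_concentration(params)
  h_star <- C * params$kH * (1 + params$inhH * C) / params$prodH
  if (!is.finite(h_star) || h_star >= 1)
    return(list(crossing_x = NA_real_, C = C, h_star = h_star,
                P_star = NA_real_))
  P_star <- params$KA * (h_star / (1 - h_star))^(1 / params$nH)
  B <- decay_constant(params$kP, params$DP)
  x <- log(params$P0 / P_star) / B
  if (x < 0 || x > params$domain_length) x <- NA_real_
  list(crossing_x = x, C = C, h_star = h_star, P_star = P_star)
}

# Concentration at which H and K meet: C (1 + inhK C) = prodK / kK.
crossing_concentration <- function(params) {
  q <- params$prodK / params$kK
  if (params$inhK == 0) return(q)
  (-1 + sqrt(1 + 4 * params$inhK * q)) / (2 * params$inhK)
}

#' Mean-field prediction of the permissive trough
#'
#' Oracle counterpart of [find_trough()]: solves `H + K = threshold` for the
#' two pointwise steady `H` levels bracketing the crossing (with
#' `K = prodK / (kK (1 + inhK H))`), then inverts the activation balance and
#' the exponential gradient for the positions of both edges. Edges whose
#' required occupancy reaches 1 (apical edge above the attainable `H`) or
#' whose position leaves the domain are reported as `NA`/clipped.
#'
#' @param params A `whorl_params` object.
#' @param threshold Permissive threshold on `H + K`; defaults to
#'   `params$trough_threshold`.
#' @return A list with `lower`, `upper` (spatial units, `upper` clipped to
#'   the domain end when the basal edge lies beyond it), `width`, and the
#'   edge concentrations `H_apical`, `H_basal`.
#' @export
mean_field_trough <- function(params, threshold = params$trough_threshold) {
  stopifnot(inherits(params, "whorl_params"))
  C <- crossing_concentration(params)
  if (2 * C >= threshold)   # trough absent: even the crossing sits above it
    return(list(lower = NA_real_, upper = NA_real_, width = 0,
                H_apical = NA_real_, H_basal = NA_real_))
  total <- function(H) H + params$prodK / (params$kK * (1 + params$inhK * H)) -
    threshold
  # apical edge: H above C; basal edge: H below C
  H_hi <- tryCatch(stats::uniroot(total, c(C, threshold * 2), tol = 1e-10)$root,
                   error = function(e) NA_real_)
  H_lo <- tryCatch(stats::uniroot(total, c(1e-12, C), tol = 1e-10)$root,
                   error = function(e) NA_real_)
  x_lo <- mean_field_position(params, H_hi)
  x_hi <- mean_field_position(params, H_lo)
  if (is.na(x_lo)) x_lo <- 0        # apical edge unattainable: trough at tip
  upper_clip <- min(x_hi, params$domain_length, na.rm = TRUE)
  list(lower = x_lo, upper = upper_clip,
       width = max(0, upper_clip - x_lo),
       H_apical = H_hi, H_basal = H_lo)
}

# Position x at which the pointwise steady H equals H_target (NA when the
# required occupancy is >= 1 or x falls outside the domain).
mean_field_position <- function(params, H_target) {
  if (!is.finite(H_target)) return(NA_real_)
  K <- params$prodK / (params$kK * (1 + params$inhK * H_target))
  occ <- H_target * params$kH * (1 + params$inhH * K) / params$prodH
  if (occ <= 0 || occ >= 1) return(NA_real_)
  P <- params$KA * (occ / (1 - occ))^(1 / params$nH)
  B <- decay_constant(params$kP, params$DP)
  x <- log(params$P0 / P) / B
  if (x < 0 || x > params$domain_length) return(NA_real_)
  x
}
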