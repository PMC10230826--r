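#' Steady-state precursor gradient
#'
#' Computes the steady spatial profile of the precursor `P` on the tissue
#' axis. In the default closed-form mode this is the exponential
#' `P(x) = P0 * exp(-B x)` with decay constant `B = sqrt(kP/DP)` -- the exact
#' steady state of the source--diffusion--decay equation in the limit of a
#' point source, with the apex amplitude pinned at `P0`. In `"pde"` mode the
#' source--diffusion--decay equation is solved numerically with its finite
#' source (extent `se`) and no-flux boundaries, and the resulting profile is
#' rescaled so that the apex concentration equals `P0`.
#'
#' @param params A `whorl_params` object.
#' @param grid Optional vector of positions (spatial units, within the
#'   domain); defaults to the uniform model grid.
#' @param mode `"closed_form"` or `"pde"`; defaults to `params$p_mode`.
#' @return A data.frame of class `whorl_profile` with columns `x` and `value`.
#' @examples
#' pr <- precursor_profile(model_params())
#' pr$value[1]            # 100 at the apex
#' @export
precursor_profile <- function(params, grid = NULL, mode = params$p_mode) {
  stopifnot(inherits(params, "whorl_params"))
  mode <- match.arg(mode, c("closed_form", "pde"))
  if (is.null(grid)) grid <- model_grid(params)
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > params$domain_length))
    stop("'grid' positions must lie within [0, domain_length]")
  if (is.unsorted(grid, strictly = TRUE)) stop("'grid' must be strictly increasing")
  if (mode == "closed_form") {
    if (params$kP <= 0 || params$DP <= 0)
      stop("closed-form mode requires kP > 0 and DP > 0 (B undefined otherwise)")
    B <- decay_constant(params$kP, params$DP)
    value <- params$P0 * exp(-B * grid)
  } else {
    value <- precursor_pde_profile(params, grid)
  }
  structure(data.frame(x = grid, value = value),
            class = c("whorl_profile", "data.frame"))
}

model_grid <- function(params) {
  seq(0, params$domain_length, length.out = params$n_grid)
}

# Steady solve of dP/dt = src - kP*P + DP*P'' with no-flux ends (central
# differences, tridiagonal linear system), rescaled so the apex equals P0.
precursor_pde_profile <- function(params, grid) {
  n <- params$n_grid
  x <- model_grid(params)
  dx <- x[2] - x[1]
  src <- ifelse(x < params$se, params$P0, 0)
  a <- params$DP / dx^2
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, i] <- -2 * a - params$kP
    if (i > 1) A[i, i - 1] <- a
    if (i < n) A[i, i + 1] <- a
  }
  A[1, 2] <- 2 * a     # mirror ghost points (no-flux)
  A[n, n - 1] <- 2 * a
  p <- solve(A, -src)
  p <- p * params$P0 / max(p)
  stats::approx(x, p, xout = grid, rule = 2)$y
}

# Discrete Laplacian with no-flux (mirror) boundaries.
laplacian_neumann <- function(v, dx) {
  n <- length(v)
  out <- numeric(n)
  out[2:(n - 1)] <- (v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]) / dx^2
  out[1] <- 2 * (v[2] - v[1]) / dx^2
  out[n] <- 2 * (v[n - 1] - v[n]) / dx^2
  out
}

#' Solve the coupled apical/basal patterning system to steady state
#'
#' Integrates the reaction--diffusion equations for `H` and `K` by the method
#' of lines on the uniform model grid, with the precursor `P` held at its
#' steady profile, from `H = K = 0` (unless `init` is given) until `t_end`.
#' The apical factor is produced at rate
#' `prodH * P^nH / (KA^nH + P^nH) / (1 + inhH * K)` and the basal factor at
#' `prodK / (1 + inhK * H)`; both decay linearly and diffuse. Boundary
#' conditions are zero-flux at both ends (`bc = "neumann"`); an alternative
#' zero-Dirichlet basal end is available to verify that the boundary choice
#' is immaterial at the default diffusivities.
#'
#' @param params A `whorl_params` object.
#' @param init Optional list with numeric vectors `H` and `K` of length
#'   `n_grid` giving the initial condition (used to confirm that the steady
#'   state is initialization-independent).
#' @param bc Boundary condition for `H` and `K`: `"neumann"` (default,
#'   zero-flux) or `"dirichlet_basal"` (value clamped to zero at the basal
#'   end).
#' @param tol Convergence tolerance: the maximum absolute time derivative at
#'   `t_end`, relative to the concentration scale `max(1, max(H), max(K))`,
#'   must fall below `tol`. Default 1e-6.
#' @return An object of class `whorl_solution`: list with `params`, the grid
#'   `x`, profiles `P`, `H`, `K`, and `residual` (the scaled final-time
#'   derivative norm).
#' @examples
#' sol <- solve_steady_state(model_params())
#' find_interface(sol)     # about 1.8 spatial units from the tip
#' @export
solve_steady_state <- function(params, init = NULL,
                               bc = c("neumann", "dirichlet_basal"),
                               tol = 1e-6) {
  stopifnot(inherits(params, "whorl_params"))
  bc <- match.arg(bc)
  x <- model_grid(params)
  n <- length(x)
  dx <- x[2] - x[1]
  P <- precursor_profile(params, x)$value
  occ <- P^params$nH / (params$KA^params$nH + P^params$nH)

  rhs <- function(t, y, parms) {
    H <- y[1:n]
    K <- y[(n + 1):(2 * n)]
    dH <- params$prodH * occ / (1 + params$inhH * K) - params$kH * H +
      params$DH * laplacian_neumann(H, dx)
    dK <- params$prodK / (1 + params$inhK * H) - params$kK * K +
      params$DK * laplacian_neumann(K, dx)
    if (bc == "dirichlet_basal") {
      dH[n] <- -H[n] / 1e-3
      dK[n] <- -K[n] / 1e-3
    }
    list(c(dH, dK))
  }

  if (is.null(init)) {
    y0 <- numeric(2 * n)
  } else {
    stopifnot(is.list(init), length(init$H) == n, length(init$K) == n)
    y0 <- c(init$H, init$K)
  }
  out <- deSolve::ode.1D(y = y0, times = c(0, params$t_end), func = rhs,
                         parms = NULL, nspec = 2, dimens = n,
                         method = "lsoda", rtol = 1e-8, atol = 1e-8)
  yT <- unname(out[nrow(out), -1])
  H <- yT[1:n]
  K <- yT[(n + 1):(2 * n)]
  # lsoda can undershoot zero by ~atol; clamp genuine round-off only
  if (min(H, K) < -1e-5) stop("negative concentrations in steady-state solve")
  H <- pmax(H, 0)
  K <- pmax(K, 0)
  scale <- max(1, H, K)
  residual <- max(abs(unlist(rhs(params$t_end, c(H, K), NULL)))) / scale
  if (!is.finite(residual) || residual > tol)
    stop(sprintf(paste0("steady-state solve did not converge by t = %g ",
                        "(scaled residual %.3g > tol %.3g)"),
                 params$t_end, residual, tol))
  structure(list(params = params, x = x, P = P, H = H, K = K,
                 residual = residual, bc = bc),
            class = "whorl_solution")
}

#' @export
print.whorl_solution <- function(x, ...) {
  cat(sprintf("Steady-state patterning solution on [0, %g] (%d points)\n",
              x$params$domain_length, length(x$x)))
  cat(sprintf("  max P = %.4g, max H = %.4g, max K = %.4g, residual = %.2e\n",
              max(x$P), max(x$H), max(x$K), x$residual))
  cx <- find_interface(x)
  if (is.na(cx)) cat("  H-K interface: none\n")
  else cat(sprintf("  H-K interface at x = %.3f (%.0f um from the tip)\n",
                   cx, 100 * cx))
  invisible(x)
}

#' Locate the H--K interface
#'
#' Finds the most apical position at which the `H` and `K` profiles cross
#' (the sign change of `H - K` closest to the tip), refined by linear
#' interpolation between the bracketing grid points. A tangential touch where
#' `H - K` reaches zero without changing sign is not counted as a crossing.
#' Absence of a crossing is a valid result (`NA`), not an error; more than
#' one sign change raises a warning and the most apical one is returned.
#'
#' @param solution A `whorl_solution`.
#' @return The crossing position (spatial units), or `NA_real_` if `H - K`
#'   keeps a constant sign over the whole domain.
#' @export
find_interface <- function(solution) {
  stopifnot(inherits(solution, "whorl_solution"))
  d <- solution$H - solution$K
  x <- solution$x
  s <- sign(d)
  idx <- which(s[-length(s)] * s[-1] < 0)
  # grid point exactly zero: crossing only if strict sign change around it
  zero <- which(s == 0)
  for (i in zero) {
    if (i > 1 && i < length(s) && s[i - 1] * s[i + 1] < 0)
      idx <- sort(unique(c(idx, i - 1)))
  }
  if (!length(idx)) return(NA_real_)
  if (length(idx) > 1)
    warning("multiple H-K sign changes; returning the most apical")
  i <- idx[1]
  x[i] + (x[i + 1] - x[i]) * d[i] / (d[i] - d[i + 1])
}

#' Locate the permissive trough
#'
#' Returns the maximal interval(s) on which the combined concentration
#' `H + K` falls below the permissive threshold (the region in which
#' PIN1--auxin patterning can initiate primordia). Interval endpoints are
#' refined by linear interpolation; an interval reaching the basal end of the
#' domain is flagged as unbounded (the basal inhibitory boundary is absent).
#'
#' @param solution A `whorl_solution`.
#' @param threshold Permissive threshold on `H + K`; defaults to the
#'   `trough_threshold` in the solution's parameters.
#' @return A data.frame with columns `lower`, `upper`, `width`,
#'   `unbounded_basal`; zero rows when `H + K` is at or above the threshold
#'   everywhere.
#' @export
find_trough <- function(solution, threshold = solution$params$trough_threshold) {
  stopifnot(inherits(solution, "whorl_solution"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a positive scalar")
  f <- solution$H + solution$K - threshold
  x <- solution$x
  n <- length(x)
  below <- f < 0
  if (!any(below))
    return(data.frame(lower = numeric(0), upper = numeric(0),
                      width = numeric(0), unbounded_basal = logical(0)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  res <- lapply(which(r$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    lo <- if (i0 == 1) x[1] else
      x[i0 - 1] + (x[i0] - x[i0 - 1]) * f[i0 - 1] / (f[i0 - 1] - f[i0])
    hi <- if (i1 == n) x[n] else
      x[i1] + (x[i1 + 1] - x[i1]) * f[i1] / (f[i1] - f[i1 + 1])
    data.frame(lower = lo, upper = hi, width = hi - lo,
               unbounded_basal = (i1 == n))
  })
  do.call(rbind, res)
}

#' Interface summary of a steady-state solution
#'
#' Bundles the crossing position, permissive trough, `H` maximum and outcome
#' class of a solution into one record.
#'
#' @param solution A `whorl_solution`.
#' @param threshold Permissive threshold on `H + K`.
#' @return A list of class `whorl_interface` with elements `crossing_x`,
#'   `trough` (data.frame), `h_max`, and `outcome` (one of
#'   `interface_present`, `interface_eliminated`, `basal_boundary_removed`).
#' @export
interface_result <- function(solution,
                             threshold = solution$params$trough_threshold) {
  cx <- suppressWarnings(find_interface(solution))
  trough <- find_trough(solution, threshold)
  outcome <- if (nrow(trough) && any(trough$unbounded_basal)) {
    "basal_boundary_removed"
  } else if (is.na(cx)) {
    "interface_eliminated"
  } else {
    "interface_present"
  }
  structure(list(crossing_x = as.numeric(cx), trough = trough,
                 h_max = max(solution$H), outcome = outcome),
            class = "whorl_interface")
}

#' @export
print.whorl_interface <- function(x, ...) {
  cat("H-K interface summary\n")
  cat(sprintf("  outcome: %s\n", x$outcome))
  if (!is.na(x$crossing_x))
    cat(sprintf("  crossing at x = %.3f\n", x$crossing_x))
  if (nrow(x$trough))
    for (i in seq_len(nrow(x$trough)))
      cat(sprintf("  trough [%.3f, %.3f]%s (width %.3f)\n",
                  x$trough$lower[i], x$trough$upper[i],
                  if (x$trough$unbounded_basal[i]) " (unbounded basally)" else "",
                  x$trough$width[i]))
  cat(sprintf("  h_max = %.4g\n", x$h_max))
  invisible(x)
}

#' Classify a perturbed pattern against a baseline
#'
#' Encodes the standard verbal readouts of interface perturbations:
#' acropetal/basipetal shift of the crossing, elimination of the interface,
#' removal of the basal inhibitory boundary (unbounded trough), and
#' displacement beyond the competence zone.
#'
#' @param solution A converged `whorl_solution` for the perturbed condition.
#' @param baseline A `whorl_interface` (or `whorl_solution`) for the baseline
#'   condition.
#' @param competence_limit Optional maximal position (spatial units) at which
#'   tissue can initiate primordia; defaults to the value carried in the
#'   solution's parameters. When set, a crossing or an `H > threshold` zone
#'   extending past it yields `beyond_competence`.
#' @param tol Positional tolerance below which the interface counts as
#'   unchanged. Default 0.005 (half a grid cell).
#' @return A list with `outcome` (one of `acropetal_shift`,
#'   `basipetal_shift`, `unchanged`, `interface_eliminated`,
#'   `basal_boundary_removed`, `beyond_competence`) and `delta_x` (signed
#'   shift, spatial units; `NA` when either crossing is absent).
#' @export
classify_outcome <- function(solution, baseline,
                             competence_limit = solution$params$competence_limit,
                             tol = 0.005) {
  stopifnot(inherits(solution, "whorl_solution"))
  if (inherits(baseline, "whorl_solution")) baseline <- interface_result(baseline)
  stopifnot(inherits(baseline, "whorl_interface"))
  res <- interface_result(solution)
  thr <- solution$params$trough_threshold
  if (!is.na(competence_limit)) {
    h_edge <- h_extent(solution, thr)
    past <- (!is.na(res$crossing_x) && res$crossing_x > competence_limit) ||
      (!is.na(h_edge) && h_edge > competence_limit)
    if (past)
      return(list(outcome = "beyond_competence", delta_x = NA_real_,
                  interface = res))
  }
  if (res$outcome == "basal_boundary_removed")
    return(list(outcome = "basal_boundary_removed", delta_x = NA_real_,
                interface = res))
  if (res$outcome == "interface_eliminated")
    return(list(outcome = "interface_eliminated", delta_x = NA_real_,
                interface = res))
  if (is.na(baseline$crossing_x))
    return(list(outcome = "interface_present", delta_x = NA_real_,
                interface = res))
  dx <- res$crossing_x - baseline$crossing_x
  outcome <- if (abs(dx) <= tol) "unchanged"
  else if (dx > 0) "basipetal_shift" else "acropetal_shift"
  list(outcome = outcome, delta_x = dx, interface = res)
}

# Basal-most position where H is still above the threshold (NA if H never
# exceeds it); marks the outer edge of the H-inhibited zone.
h_extent <- function(solution, threshold) {
  f <- solution$H - threshold
  if (all(f <= 0)) return(NA_real_)
  x <- solution$x
  i <- max(which(f > 0))
  if (i == length(x)) return(x[i])
  x[i] + (x[i + 1] - x[i]) * f[i] / (f[i] - f[i + 1])
}

#' Plot the steady-state profiles
#'
#' Base-graphics view of the precursor, apical and basal profiles with the
#' interface and permissive trough marked.
#'
#' @param x A `whorl_solution`.
#' @param ... Passed to [graphics::matplot()].
#' @return The solution, invisibly.
#' @export
plot.whorl_solution <- function(x, ...) {
  graphics::matplot(x$x, cbind(x$P, x$H, x$K), type = "l", lty = 1,
                    col = c("goldenrod", "blue", "red"),
                    xlab = "distance from tip (spatial units; 1 = 100 um)",
                    ylab = "concentration", ...)
  tr <- find_trough(x)
  if (nrow(tr))
    graphics::rect(tr$lower, 0, tr$upper, x$params$trough_threshold,
                   col = grDevices::adjustcolor("green", 0.15), border = NA)
  cx <- suppressWarnings(find_interface(x))
  if (!is.na(cx)) graphics::abline(v = cx, lty = 2, col = "purple")
  graphics::legend("topright", c("P", "H", "K"), lty = 1,
                   col = c("goldenrod", "blue", "red"), bty = "n")
  invisible(x)
}
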