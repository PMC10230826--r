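#' Whorl radius for a given cotyledon count
#'
#' Radius of the circle on which `n_c` cotyledon centres sit with a fixed
#' chord (centre-to-centre) spacing `lam`: the circumradius of a regular
#' `n_c`-gon with side `lam`, `r = lam / (2 sin(pi/n_c))`. At `n_c = 2` the
#' whorl diameter equals the spacing, so `r = lam/2` (55 um at the spruce
#' spacing of 110 um).
#'
#' @param lam Inter-cotyledon spacing (um, > 0).
#' @param n_c Cotyledon count (integer >= 2); vectorised.
#' @return Whorl radius (um).
#' @examples
#' whorl_radius(110, 2)    # 55
#' whorl_radius(110, 10)   # ~178, the upper end of the observed range
#' @export
whorl_radius <- function(lam, n_c) {
  if (!is.numeric(lam) || any(lam <= 0)) stop("'lam' must be positive")
  if (!is.numeric(n_c) || any(n_c < 2) || any(n_c != round(n_c)))
    stop("'n_c' must be an integer >= 2 (no ring is defined below 2)")
  lam / (2 * sin(pi / n_c))
}

#' Cotyledon count fitting on a whorl of given radius
#'
#' Largest number of cotyledons that fit on a circle of radius `r` with
#' centre-to-centre spacing at least `lam`:
#' `floor(pi / asin(lam / (2 r)))` when `2 r >= lam`. Whorls too small for
#' two organs (`0 < 2 r < lam`) give the pin phenotype (`n_c = 1` by
#' default, configurable to 0); `r = 0` gives 0.
#'
#' @param r Whorl radius (um, >= 0); vectorised.
#' @param lam Inter-cotyledon spacing (um, > 0).
#' @param pin_value Count to report when the whorl is too small for two
#'   organs; default 1 (pin), set 0 to treat these as ring/no-organ.
#' @return Integer cotyledon count.
#' @examples
#' predict_nc(95, 110)   # 5, the commonly observed count
#' predict_nc(55, 110)   # 2
#' @export
predict_nc <- function(r, lam, pin_value = 1L) {
  if (!is.numeric(r) || any(r < 0)) stop("'r' must be non-negative")
  if (!is.numeric(lam) || any(lam <= 0)) stop("'lam' must be positive")
  out <- integer(length(r))
  ratio <- lam / (2 * r)
  fits <- is.finite(ratio) & ratio <= 1
  # 1e-9 guard keeps the exact regular-polygon radii on their own count
  out[fits] <- pmax(2L, as.integer(floor(pi / asin(ratio[fits]) + 1e-9)))
  out[!fits & r > 0] <- as.integer(pin_value)
  out[r == 0] <- 0L
  out
}

#' Meridional arc length on a hemispherical tip
#'
#' Converts the horizontal (straight-line) whorl radius `r` into the distance
#' measured along the surface of a hemisphere of radius `R` (along a line of
#' longitude): `s = R asin(r / R)`. The surface distance always exceeds the
#' horizontal radius, reaching a quarter circumference `pi R / 2` at the
#' hemispherical limit `r = R`.
#'
#' @param r Horizontal radius (um), `0 <= r <= R`.
#' @param R Hemisphere radius (um, > 0).
#' @return Surface (meridional) distance (um).
#' @examples
#' meridional_arc(55, 180)    # ~56
#' meridional_arc(180, 180)   # ~283, the quarter circumference
#' @export
meridional_arc <- function(r, R) {
  if (!is.numeric(R) || any(R <= 0)) stop("'R' must be positive")
  if (!is.numeric(r) || any(r < 0) || any(r > R))
    stop("'r' must satisfy 0 <= r <= R")
  R * asin(r / R)
}

#' Horizontal radius from a meridional arc length
#'
#' Inverse of [meridional_arc()]: `r = R sin(s / R)` for a surface distance
#' `s` on a hemisphere of radius `R` (valid up to the quarter circumference).
#'
#' @param s Surface distance (um), `0 <= s <= pi R / 2`.
#' @param R Hemisphere radius (um, > 0).
#' @return Horizontal radius (um).
#' @examples
#' horizontal_radius(165, 165)   # ~139: curvature shortens the radius
#' @export
horizontal_radius <- function(s, R) {
  if (!is.numeric(R) || any(R <= 0)) stop("'R' must be positive")
  if (!is.numeric(s) || any(s < 0) || any(s > pi * R / 2 + 1e-9))
    stop("'s' must satisfy 0 <= s <= pi*R/2 (quarter circumference)")
  R * sin(s / R)
}

#' Growth-corrected whorl radii by cotyledon count
#'
#' Tabulates the whorl radius for each cotyledon count at a fixed spacing.
#' The ratio `r(10)/r(2) = 1/sin(pi/10) / 2 * ... ~ 3.24` is independent of
#' the spacing -- the roughly three-fold radius increase across the observed
#' count range depends only on the inter-cotyledon angle.
#'
#' @param lam Inter-cotyledon spacing (um). Default 110.
#' @param n_range Integer counts to tabulate. Default `2:10`.
#' @return A data.frame with columns `n_c` and `r_um`.
#' @examples
#' growth_corrected_radius_table()
#' @export
growth_corrected_radius_table <- function(lam = 110, n_range = 2:10) {
  data.frame(n_c = as.integer(n_range),
             r_um = whorl_radius(lam, n_range))
}

check_embryo_table <- function(table, cols) {
  if (!is.data.frame(table)) stop("'table' must be a data.frame")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("embryo table lacks column(s): ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Diameter-vs-count regression estimating the inter-cotyledon spacing
#'
#' Ordinary least squares of embryo diameter on cotyledon count. On a whorl
#' whose circumference grows by one spacing per added organ, diameter follows
#' `D = (lam/pi) n_c + b`, so the spacing estimate is `pi` times the fitted
#' slope and the intercept `b` is the growth offset (diameter in excess of
#' the whorl diameter at specification).
#'
#' @param table Embryo measurement table with columns `n_c` and
#'   `diameter_um` (at least 3 embryos spanning at least 2 distinct counts).
#' @return A list of class `whorl_regression`: `slope`, `intercept`, their
#'   standard errors, `lambda_estimate` (`pi * slope`, um), `n_points`,
#'   `r_squared`, and the underlying `lm` fit.
#' @examples
#' tab <- data.frame(n_c = rep(2:6, each = 2),
#'                   diameter_um = (110 / pi) * rep(2:6, each = 2))
#' fit_diameter_regression(tab)$lambda_estimate   # 110
#' @export
fit_diameter_regression <- function(table) {
  check_embryo_table(table, c("n_c", "diameter_um"))
  table <- table[is.finite(table$n_c) & is.finite(table$diameter_um), ]
  if (nrow(table) < 3) stop("need at least 3 embryos")
  if (length(unique(table$n_c)) < 2)
    stop("degenerate design: all embryos share one cotyledon count")
  fit <- stats::lm(diameter_um ~ n_c, data = table)
  co <- summary(fit)$coefficients
  structure(list(slope = co["n_c", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 slope_se = co["n_c", "Std. Error"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 lambda_estimate = pi * co["n_c", "Estimate"],
                 n_points = nrow(table),
                 r_squared = summary(fit)$r.squared,
                 fit = fit, kind = "diameter"),
            class = "whorl_regression")
}

#' Spacing-vs-length regression estimating spacing at morphogenesis onset
#'
#' Ordinary least squares of per-embryo mean inter-cotyledon spacing on
#' cotyledon length, restricted to embryos whose cotyledons are shorter than
#' `max_cotyledon_length` (the early phase in which spacing grows linearly
#' with extension). The intercept extrapolates to cotyledon length zero,
#' i.e. the spacing at the onset of cotyledon morphogenesis.
#'
#' @param table Embryo measurement table with columns `spacing_um` and
#'   `cotyledon_length_um`.
#' @param max_cotyledon_length Length filter in um (default 300).
#' @return A `whorl_regression` list as in [fit_diameter_regression()] (the
#'   `lambda_estimate` field is `NA`; the quantity of interest is the
#'   `intercept`).
#' @export
fit_spacing_regression <- function(table, max_cotyledon_length = 300) {
  check_embryo_table(table, c("spacing_um", "cotyledon_length_um"))
  keep <- is.finite(table$spacing_um) & is.finite(table$cotyledon_length_um) &
    table$cotyledon_length_um < max_cotyledon_length
  table <- table[keep, ]
  if (nrow(table) < 3)
    stop("fewer than 3 embryos pass the cotyledon-length filter")
  fit <- stats::lm(spacing_um ~ cotyledon_length_um, data = table)
  co <- summary(fit)$coefficients
  structure(list(slope = co["cotyledon_length_um", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 slope_se = co["cotyledon_length_um", "Std. Error"],
                 intercept_se = co["(Intercept)", "Std. Error"],
                 lambda_estimate = NA_real_,
                 n_points = nrow(table),
                 r_squared = summary(fit)$r.squared,
                 fit = fit, kind = "spacing"),
            class = "whorl_regression")
}

#' @export
print.whorl_regression <- function(x, ...) {
  cat(sprintf("%s regression (n = %d, R^2 = %.3f)\n",
              if (x$kind == "diameter") "Diameter-vs-count" else
                "Spacing-vs-length", x$n_points, x$r_squared))
  cat(sprintf("  slope     = %.3f +/- %.3f\n", x$slope, x$slope_se))
  cat(sprintf("  intercept = %.2f +/- %.2f um\n", x$intercept, x$intercept_se))
  if (is.finite(x$lambda_estimate))
    cat(sprintf("  spacing estimate (pi * slope) = %.1f um\n",
                x$lambda_estimate))
  invisible(x)
}
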