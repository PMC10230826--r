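#' Specification of a synthetic embryo population
#'
#' Describes the statistical structure of a simulated conifer-embryo
#' measurement campaign: cotyledon counts drawn from a distribution peaked at
#' five; whorl diameter at specification set by the spacing relation
#' `D = (lam/pi) n_c`; observed diameter inflated by a non-negative per-embryo
#' growth offset (tissue expansion after the whorl is specified) plus
#' measurement noise; and per-embryo mean inter-cotyledon spacing increasing
#' linearly with cotyledon length from the onset value.
#'
#' @param n_embryos Number of embryos. Default 237.
#' @param lam_true True inter-cotyledon spacing at specification (um).
#'   Default 110.
#' @param nc_values,nc_weights Support and probability weights of the
#'   cotyledon-count distribution. Defaults: counts 2..10, peaked at 5.
#' @param growth_offset_scale Scale (um) of the half-normal per-embryo growth
#'   offset; 0 disables growth. Default 50.
#' @param spacing_intercept_true Spacing at cotyledon length zero for a
#'   110-um population (um); the effective intercept scales with
#'   `lam_true/110`. Default 145.
#' @param spacing_slope_true Spacing increase per um of cotyledon length
#'   (free parameter; not constrained by published data). Default 0.1.
#' @param cotyledon_length_range Range (um) from which cotyledon lengths are
#'   drawn uniformly. Default `c(20, 400)`.
#' @param noise_sd Gaussian measurement noise (um) on diameters and spacings.
#'   Default 5.
#' @param seed Integer seed; the generated table is a pure function of the
#'   spec (including the seed).
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_embryos = 237, lam_true = 110,
                            nc_values = 2:10,
                            nc_weights = c(0.03, 0.07, 0.15, 0.30, 0.20,
                                           0.12, 0.07, 0.04, 0.02),
                            growth_offset_scale = 50,
                            spacing_intercept_true = 145,
                            spacing_slope_true = 0.1,
                            cotyledon_length_range = c(20, 400),
                            noise_sd = 5, seed = 1L) {
  if (n_embryos < 1 || n_embryos != round(n_embryos))
    stop("'n_embryos' must be a positive integer")
  if (lam_true <= 0) stop("'lam_true' must be positive")
  if (length(nc_values) != length(nc_weights))
    stop("'nc_values' and 'nc_weights' must have equal length")
  if (any(nc_weights < 0) || sum(nc_weights) <= 0)
    stop("'nc_weights' must be non-negative and sum to a positive value")
  if (abs(sum(nc_weights) - 1) > 1e-8)
    stop("'nc_weights' must sum to 1")
  if (growth_offset_scale < 0) stop("'growth_offset_scale' must be >= 0")
  if (spacing_intercept_true <= 0) stop("'spacing_intercept_true' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(cotyledon_length_range) != 2 ||
      diff(cotyledon_length_range) < 0 || any(cotyledon_length_range < 0))
    stop("'cotyledon_length_range' must be a non-decreasing pair of lengths")
  structure(list(n_embryos = as.integer(n_embryos), lam_true = lam_true,
                 nc_values = as.integer(nc_values), nc_weights = nc_weights,
                 growth_offset_scale = growth_offset_scale,
                 spacing_intercept_true = spacing_intercept_true,
                 spacing_slope_true = spacing_slope_true,
                 cotyledon_length_range = cotyledon_length_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic embryo measurement table
#'
#' Draws a reproducible embryo population from a [population_spec()]. For
#' each embryo the cotyledon count is drawn from the count distribution, the
#' observed diameter is the specification-line diameter `(lam/pi) n_c` plus a
#' half-normal growth offset and Gaussian noise, cotyledon length is uniform
#' over its range, and spacing follows the linear relation
#' `intercept * (lam/110) + slope * length` plus noise. Growth offsets are
#' drawn independently of the count (observed growth does not correlate with
#' cotyledon number).
#'
#' @param spec A `population_spec`.
#' @return A data.frame with columns `embryo_id`, `n_c`, `diameter_um`,
#'   `cotyledon_length_um`, `spacing_um`, with the generating seed attached
#'   as attribute `seed`. Byte-for-byte reproducible from the spec.
#' @examples
#' tab <- generate_population(population_spec(n_embryos = 50, seed = 7))
#' fit_diameter_regression(tab)$lambda_estimate
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_embryos
  out <- withr_seed(spec$seed, {
    n_c <- sample(spec$nc_values, n, replace = TRUE, prob = spec$nc_weights)
    base_diam <- (spec$lam_true / pi) * n_c
    growth <- if (spec$growth_offset_scale > 0)
      abs(stats::rnorm(n, 0, spec$growth_offset_scale)) else numeric(n)
    diameter <- base_diam + growth + stats::rnorm(n, 0, spec$noise_sd)
    len <- stats::runif(n, spec$cotyledon_length_range[1],
                        spec$cotyledon_length_range[2])
    spacing <- spec$spacing_intercept_true * (spec$lam_true / 110) +
      spec$spacing_slope_true * len + stats::rnorm(n, 0, spec$noise_sd)
    data.frame(embryo_id = sprintf("emb%03d", seq_len(n)),
               n_c = as.integer(n_c),
               diameter_um = diameter,
               cotyledon_length_um = len,
               spacing_um = spacing)
  })
  attr(out, "seed") <- spec$seed
  out
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-count minimum observed diameter
#'
#' The lower envelope of the diameter-vs-count scatter: for each observed
#' cotyledon count, the smallest observed diameter. With growth offsets and
#' noise approaching zero the envelope converges on the specification line
#' `(lam/pi) n_c`, i.e. the smallest embryos at each count carry the
#' uninflated whorl diameter.
#'
#' @param table Embryo measurement table (columns `n_c`, `diameter_um`).
#' @return A data.frame with columns `n_c` and `min_diameter_um`, one row per
#'   observed count. Counts with no finite diameter are skipped with a
#'   warning.
#' @export
minimum_envelope <- function(table) {
  check_embryo_table(table, c("n_c", "diameter_um"))
  if (!nrow(table)) stop("empty embryo table")
  counts <- sort(unique(table$n_c))
  rows <- lapply(counts, function(nc) {
    d <- table$diameter_um[table$n_c == nc]
    d <- d[is.finite(d)]
    if (!length(d)) {
      warning("no finite diameter for n_c = ", nc, "; group skipped")
      return(NULL)
    }
    data.frame(n_c = nc, min_diameter_um = min(d))
  })
  do.call(rbind, rows)
}

#' Write an embryo measurement table as CSV
#'
#' Standard on-disk form of the measurement table: comma-separated with a
#' header line, preceded by a `# seed:` comment when the table records its
#' generating seed.
#'
#' @param table Embryo measurement table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embryo_table <- function(table, path) {
  check_embryo_table(table, c("embryo_id", "n_c", "diameter_um",
                              "cotyledon_length_um", "spacing_um"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(attr(table, "seed")))
    writeLines(sprintf("# seed: %d", attr(table, "seed")), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an embryo measurement table from CSV
#'
#' @param path CSV file with columns `embryo_id`, `n_c`, `diameter_um`,
#'   `cotyledon_length_um`, `spacing_um`; leading `#` comment lines are
#'   ignored.
#' @return The measurement table as a data.frame.
#' @export
read_embryo_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  check_embryo_table(tab, c("embryo_id", "n_c", "diameter_um",
                            "cotyledon_length_um", "spacing_um"))
  tab
}
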