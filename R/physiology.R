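# Parameter-derivation procedures: Pirt partitioning of chemostat data into
# true yield and maintenance, conversion of the maintenance substrate demand
# into an ATP-maintenance coefficient via the model's maximum ATP yield, and
# cell-geometry based dry-weight estimation for turning cell counts into
# biomass fractions.

#' Pirt partitioning of chemostat data
#'
#' Fits the linear Pirt relation `q_S = mu / Y_true + m_S` by ordinary
#' least squares: the specific substrate uptake rate at a set of dilution
#' (growth) rates decomposes into a growth-proportional part (slope
#' `1/Y_true`) and a growth-independent maintenance part (intercept
#' `m_S`, the uptake extrapolated to zero growth).
#'
#' @param data Data frame with columns `mu` (1/h) and `q_s`
#'   (mmol/gDW/h); at least two distinct `mu` values.
#' @return A `pirt_fit` object; see [tidy.pirt_fit()].
#' @examples
#' d <- tibble::tibble(mu = seq(0.01, 0.1, length.out = 5),
#'                     q_s = mu / 0.01 + 2)
#' tidy(pirt_fit(d))
#' @export
pirt_fit <- function(data) {
  stopifnot(all(c("mu", "q_s") %in% names(data)))
  data <- tibble::as_tibble(data)[, c("mu", "q_s")]
  if (length(unique(data$mu)) < 2L) {
    stop("need at least two distinct growth rates")
  }
  if (any(data$mu < 0) || any(data$q_s < 0)) {
    stop("growth and uptake rates must be nonnegative")
  }
  fit <- stats::lm(q_s ~ mu, data = data)
  cf <- stats::coef(fit)
  m_s <- unname(cf[1])
  slope <- unname(cf[2])
  if (slope <= 0) stop("non-positive slope: data inconsistent with growth")
  if (m_s < 0) {
    warning("negative maintenance intercept (", format(m_s, digits = 3),
            ") clipped to 0", call. = FALSE)
    m_s <- 0
  }
  structure(list(true_yield = 1 / slope, maintenance_uptake = m_s,
                 lm = fit, data = data),
            class = "pirt_fit")
}

#' @export
print.pirt_fit <- function(x, ...) {
  cat(sprintf(
    "<pirt_fit> Y_true = %.4g gDW/mmol   m_S = %.4g mmol/gDW/h   (n = %d)\n",
    x$true_yield, x$maintenance_uptake, nrow(x$data)))
  invisible(x)
}

#' Estimates of a Pirt fit
#'
#' @param x A [pirt_fit()].
#' @param ... Unused.
#' @return Tibble with `true_yield` (gDW/mmol), `maintenance_uptake`
#'   (mmol/gDW/h) and their standard errors.
#' @method tidy pirt_fit
#' @export
tidy.pirt_fit <- function(x, ...) {
  se <- sqrt(diag(stats::vcov(x$lm)))
  slope <- unname(stats::coef(x$lm)[2])
  tibble::tibble(
    true_yield = x$true_yield,
    true_yield_se = unname(se[2]) / slope^2,  # delta method on 1/slope
    maintenance_uptake = x$maintenance_uptake,
    maintenance_uptake_se = unname(se[1]))
}

#' @method glance pirt_fit
#' @export
glance.pirt_fit <- function(x, ...) {
  tibble::tibble(true_yield = x$true_yield,
                 maintenance_uptake = x$maintenance_uptake,
                 r_squared = suppressWarnings(summary(x$lm)$r.squared),
                 n = nrow(x$data))
}

#' ATP-maintenance coefficient from the maintenance substrate demand
#'
#' Lower bound on the non-growth-associated ATP demand: the substrate
#' uptake extrapolated to zero growth multiplied by the organism's maximum
#' ATP yield on that substrate. The ATP yield can be given directly (e.g.,
#' from a published table) or computed from a model as the maximal ATP
#' hydrolysis flux per unit substrate uptake at zero growth.
#'
#' @param m_s Maintenance substrate uptake (mmol/gDW/h), e.g. from
#'   [pirt_fit()].
#' @param atp_yield Maximum ATP yield (mol ATP/mol substrate); either a
#'   number or computed when `model` is given.
#' @param model Optional [stoich_model()] used to compute the ATP yield.
#' @param atp_rxn Id of the ATP-hydrolysis reaction (flux = ATP available
#'   for maintenance).
#' @param substrate_rxn Uptake reaction id(s) of the substrate.
#' @param biomass_rxn Optional biomass reaction pinned to zero growth for
#'   the yield computation.
#' @return ATPmaint in mmol ATP/gDW/h.
#' @export
atp_maintenance <- function(m_s, atp_yield = NULL, model = NULL,
                            atp_rxn = NULL, substrate_rxn = NULL,
                            biomass_rxn = NULL) {
  stopifnot(m_s >= 0)
  if (is.null(atp_yield)) {
    stopifnot(!is.null(model), !is.null(atp_rxn), !is.null(substrate_rxn))
    if (!is.null(biomass_rxn)) {
      model <- set_bounds(model, biomass_rxn, lb = 0, ub = 0)
    }
    atp_yield <- max_yield(model, biomass_rxn = atp_rxn,
                           substrate_rxn = substrate_rxn)
    if (is.na(atp_yield)) stop("model yields no ATP on that substrate")
  }
  m_s * atp_yield
}

#' Cell volume from shape and dimensions
#'
#' Spheres: `pi d^3 / 6`. Rods are modeled as a cylinder with
#' hemispherical caps; `length` is the total cell length including the
#' caps, so the cylindrical section has length `length - diameter`. A rod
#' with `length == diameter` degenerates to a sphere.
#'
#' @param shape `"sphere"` or `"rod"`.
#' @param diameter Cell diameter in micrometers.
#' @param length Total cell length in micrometers (rods only).
#' @return Volume in cubic micrometers.
#' @export
cell_volume <- function(shape = c("sphere", "rod"), diameter, length = NULL) {
  shape <- match.arg(shape)
  stopifnot(diameter > 0)
  if (shape == "sphere") return(pi * diameter^3 / 6)
  stopifnot(!is.null(length), length >= diameter)
  r <- diameter / 2
  pi * r^2 * (length - diameter) + 4 / 3 * pi * r^3
}

#' Cell dry weight from volume
#'
#' Allometric volume-to-dry-weight relation `m = 435 V^0.85` (m in
#' femtograms, V in cubic micrometers).
#'
#' @param volume Cell volume(s) in cubic micrometers.
#' @return Dry weight in femtograms.
#' @export
dry_weight <- function(volume) {
  stopifnot(all(volume > 0))
  435 * volume^0.85
}

#' Biomass fractions from cell counts and geometries
#'
#' Converts a cell-count ratio into a dry-weight (biomass fraction) ratio:
#' `F_i` proportional to `count_i * dry_weight_i`, normalized to the
#' simplex.
#'
#' @param counts Named numeric vector of cell counts (or concentrations)
#'   per species.
#' @param weights Dry weight per cell (fg), same length/names; compute
#'   from geometry via [cell_volume()] and [dry_weight()].
#' @return Named composition vector summing to one.
#' @export
counts_to_fractions <- function(counts, weights) {
  stopifnot(length(counts) == length(weights),
            all(counts >= 0), all(weights > 0), sum(counts) > 0)
  if (!is.null(names(weights)) && !is.null(names(counts))) {
    weights <- weights[names(counts)]
  }
  mass <- counts * weights
  mass / sum(mass)
}
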