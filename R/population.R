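#' Living area per person in a dasymetric zone
#'
#' Ratio of totals over the field-survey samples:
#' \code{LA_t = sum(A_i) / sum(P_i)} (living area over persons), not the
#' mean of per-sample ratios.
#'
#' @param samples data frame with columns \code{A} (living area, m2) and
#'   \code{P} (persons).
#' @return scalar LA_t in m2 per person.
#' @export
estimate_la <- function(samples) {
  stopifnot(all(c("A", "P") %in% names(samples)))
  if (sum(samples$P) <= 0) stop("total surveyed persons must be positive")
  sum(samples$A) / sum(samples$P)
}

#' Height per floor in a dasymetric zone
#'
#' \code{AH_t = sum(H_i - RH_i) / sum(F_i)}: total above-roof-corrected
#' height over total floor count across the survey samples.
#'
#' @param samples data frame with columns \code{H} (total height, m),
#'   \code{RH} (roof height, m) and \code{F} (floor count).
#' @return scalar AH_t in metres per floor.
#' @export
estimate_ah <- function(samples) {
  stopifnot(all(c("H", "RH", "F") %in% names(samples)))
  if (any(samples$H < samples$RH)) stop("H must be >= RH for every sample")
  if (sum(samples$F) <= 0) stop("total floor count must be positive")
  sum(samples$H - samples$RH) / sum(samples$F)
}

#' Raw per-building population before volume preservation
#'
#' \code{(FS / LA_t) * (BH / AH_t)}: floor space over living area per person
#' times the (real-valued) floor count. Rounding the floor count is exposed
#' as an option but off by default.
#'
#' @param FS building floor space (footprint area), m2.
#' @param BH building height, m.
#' @param LA_t living area per person in the building's zone, m2.
#' @param AH_t height per floor in the building's zone, m.
#' @param round_floors round \code{BH / AH_t} to whole floors first.
#' @return persons (real-valued), same length as \code{FS}.
#' @export
raw_population <- function(FS, BH, LA_t, AH_t, round_floors = FALSE) {
  stopifnot(all(LA_t > 0), all(AH_t > 0))
  floors <- BH / AH_t
  if (round_floors) floors <- round(floors)
  (FS / LA_t) * floors
}

#' Volume-preserving adjustment (pycnophylactic constraint)
#'
#' Adds the uniform constant \code{C = (census_total - sum(raw)) / N} to
#' every building so that the total matches the census. Buildings pushed
#' negative are clamped to zero and the deficit is re-spread uniformly over
#' the still-positive buildings (at most 10 rounds, then a proportional
#' rescale), so the result is non-negative and sums exactly to the census
#' total.
#'
#' @param raw numeric vector of raw per-building estimates.
#' @param census_total census population of the constrained region (>= 0).
#' @return list with \code{population} (adjusted vector) and \code{C}.
#' @export
apply_volume_constraint <- function(raw, census_total) {
  if (length(raw) < 1) stop("need at least one building")
  if (census_total < 0) stop("census_total must be non-negative")
  C <- (census_total - sum(raw)) / length(raw)
  pop <- raw + C
  for (i in seq_len(10L)) {
    if (all(pop >= 0)) break
    pop[pop < 0] <- 0
    pos <- pop > 0
    deficit <- census_total - sum(pop)
    if (!any(pos)) break
    pop[pos] <- pop[pos] + deficit / sum(pos)
  }
  pop[pop < 0] <- 0
  if (sum(pop) > 0) pop <- pop * census_total / sum(pop)
  list(population = pop, C = C)
}

#' Per-zone error-correction term from field surveys
#'
#' Least-squares per-zone scalar minimising
#' \code{sum((observed - raw - C - eps_t)^2)} over the surveyed buildings:
#' the zone mean of the survey residuals. Zones without surveyed buildings
#' get 0.
#'
#' @param observed observed populations of the surveyed buildings.
#' @param raw_plus_C model values (raw + C) for the same buildings.
#' @param zone zone id per surveyed building.
#' @param zones zone ids to report (default: those present in \code{zone}).
#' @return named numeric vector of eps_t per zone.
#' @export
fit_epsilon <- function(observed, raw_plus_C, zone,
                        zones = sort(unique(zone))) {
  eps <- stats::setNames(numeric(length(zones)), zones)
  if (length(observed) == 0) return(eps)
  res <- observed - raw_plus_C
  m <- tapply(res, zone, mean)
  eps[names(m)] <- m
  eps
}

#' Aggregate per-building populations to administrative units
#'
#' @param population per-building persons.
#' @param unit administrative-unit id per building.
#' @return named numeric vector of per-unit totals.
#' @export
aggregate_to_units <- function(population, unit) {
  x <- tapply(population, unit, sum)
  stats::setNames(as.numeric(x), names(x))
}

#' Dasymetric per-building population estimation
#'
#' Runs the full population model: per-building raw estimates
#' \code{(FS / LA_t) (BH / AH_t)}, optional per-zone least-squares error
#' correction from a survey, then the volume-preserving constant \code{C}
#' (computed last so the census constraint holds exactly).
#'
#' @param buildings data frame with columns \code{FS_m2}, \code{BH_m} and
#'   \code{zone} (and optionally \code{unit}).
#' @param zones data frame with columns \code{zone}, \code{LA}, \code{AH}.
#' @param census_total census population of the whole constrained region.
#' @param survey optional data frame with columns \code{building} (row index
#'   into \code{buildings}) and \code{observed}.
#' @param round_floors see \code{\link{raw_population}}.
#' @return An object of class \code{dasypop_estimate}: \code{buildings} with
#'   a \code{population} column, plus \code{C}, \code{epsilon},
#'   \code{census_total} and per-unit totals when units are present.
#' @export
estimate_population <- function(buildings, zones, census_total, survey = NULL,
                                round_floors = FALSE) {
  stopifnot(all(c("FS_m2", "BH_m", "zone") %in% names(buildings)),
            all(c("zone", "LA", "AH") %in% names(zones)))
  zi <- match(buildings$zone, zones$zone)
  if (anyNA(zi)) stop("building zone not found in the zone table")
  raw <- raw_population(buildings$FS_m2, buildings$BH_m,
                        zones$LA[zi], zones$AH[zi], round_floors)
  eps <- stats::setNames(numeric(nrow(zones)), zones$zone)
  if (!is.null(survey) && nrow(survey) > 0) {
    b <- survey$building
    C0 <- (census_total - sum(raw)) / length(raw)
    eps_fit <- fit_epsilon(survey$observed, raw[b] + C0, buildings$zone[b],
                           zones$zone)
    eps[names(eps_fit)] <- eps_fit
  }
  raw_eps <- raw + eps[as.character(buildings$zone)]
  adj <- apply_volume_constraint(raw_eps, census_total)
  buildings$population <- adj$population
  out <- list(buildings = buildings, C = adj$C, epsilon = eps,
              census_total = census_total)
  if ("unit" %in% names(buildings))
    out$unit_totals <- aggregate_to_units(buildings$population, buildings$unit)
  structure(out, class = "dasypop_estimate")
}

#' @export
print.dasypop_estimate <- function(x, ...) {
  cat(sprintf("Dasymetric population estimate: %d buildings, census total %.0f\n",
              nrow(x$buildings), x$census_total))
  cat(sprintf("  volume-preserving constant C = %.4f persons/building\n", x$C))
  cat(sprintf("  model total = %.3f (constraint residual %.2e)\n",
              sum(x$buildings$population),
              sum(x$buildings$population) - x$census_total))
  if (!is.null(x$unit_totals)) {
    cat(sprintf("  %d administrative units, populations %.1f to %.1f\n",
                length(x$unit_totals), min(x$unit_totals), max(x$unit_totals)))
  }
  invisible(x)
}

#' @export
summary.dasypop_estimate <- function(object, ...) {
  p <- object$buildings$population
  out <- list(n_buildings = length(p), census_total = object$census_total,
              model_total = sum(p), C = object$C, epsilon = object$epsilon,
              population_quartiles = stats::quantile(p),
              unit_totals = object$unit_totals)
  class(out) <- "summary.dasypop_estimate"
  out
}

#' @export
print.summary.dasypop_estimate <- function(x, ...) {
  cat("Dasymetric population estimate\n")
  cat(sprintf("  buildings: %d, census total: %.0f, model total: %.3f\n",
              x$n_buildings, x$census_total, x$model_total))
  cat(sprintf("  C = %.4f; epsilon: %s\n", x$C,
              paste(sprintf("%s=%.3f", names(x$epsilon), x$epsilon),
                    collapse = ", ")))
  print(x$population_quartiles)
  invisible(x)
}
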