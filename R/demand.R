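#' National daily consumption of the food vehicle
#'
#' Sums stratum-level consumption: each stratum contributes
#' `population x share x reach x intake` grams per day, where `reach` is
#' the fraction of the stratum population consuming the vehicle and
#' `intake` the average daily amount among consumers.
#'
#' @param population National population, persons.
#' @param strata Tibble of consumption strata (`population_share`,
#'   `reach`, `intake`).
#' @return Total national consumption, g/day.
#' @export
national_daily_consumption <- function(population, strata) {
  if (is.null(strata) || nrow(strata) == 0L) {
    abort("`strata` must contain at least one stratum",
          class = "lsff_domain_error")
  }
  sum(population * strata$population_share * strata$reach * strata$intake)
}

#' Per-capita availability of the vehicle
#'
#' Returns the scenario's availability override if present, otherwise
#' derives availability as national daily consumption divided by the
#' base-year population. Fixtures carry an override computed from survey
#' totals at full precision, because re-deriving it from rounded stratum
#' values shifts annual volumes.
#'
#' @param sc An `lsff_scenario`.
#' @return g vehicle per capita per day.
#' @export
availability <- function(sc) {
  stopifnot(inherits(sc, "lsff_scenario"))
  if (!is.null(sc$availability_override)) {
    return(sc$availability_override)
  }
  pop0 <- sc$population$totals[1]
  national_daily_consumption(pop0, sc$strata) / pop0
}

#' Project annual vehicle volumes over the model horizon
#'
#' Converts per-capita availability and the population series into annual
#' vehicle volumes (365-day years, g to MT), then splits each year's
#' volume into domestic and imported streams and, within each stream,
#' the fortified portion (`industrial_share x compliance`). Reach, intake
#' and the programme shares are held constant; only population varies
#' over time.
#'
#' @param sc An `lsff_scenario`.
#' @return An `lsff_demand` tibble with one row per model year: `year`,
#'   `calendar_year`, `population`, `consuming_population`,
#'   `annual_volume`, `domestic_volume`, `imported_volume`,
#'   `fortified_domestic`, `fortified_imported` (volumes in MT). The
#'   availability used is stored in attribute `"availability"`.
#' @export
project_demand <- function(sc) {
  stopifnot(inherits(sc, "lsff_scenario"))
  avail <- availability(sc)
  pop <- sc$population$totals
  annual <- avail * pop * 365 * 1e-6       # g/day -> MT/year
  domestic <- annual * sc$domestic_share
  imported <- annual - domestic            # exact complement
  fort <- sc$industrial_share * sc$compliance
  out <- tibble(
    year = seq_len(sc$horizon),
    calendar_year = sc$population$years,
    population = pop,
    consuming_population = pop * sc$population$consuming_fraction,
    annual_volume = annual,
    domestic_volume = domestic,
    imported_volume = imported,
    fortified_domestic = domestic * fort,
    fortified_imported = imported * fort
  )
  attr(out, "availability") <- avail
  class(out) <- c("lsff_demand", class(out))
  out
}
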