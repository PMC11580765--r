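#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort
NULL

# Internal: raise a validation error that names the offending field.
validation_error <- function(field, msg) {
  abort(
    sprintf("invalid scenario field `%s`: %s", field, msg),
    class = "lsff_validation_error",
    field = field
  )
}

check_fraction <- function(x, field, upper = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > upper) {
    validation_error(field, sprintf("must be a single number in [0, %s]", upper))
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    validation_error(field, "must be non-negative")
  }
  invisible(x)
}

#' Define a micronutrient line of the premix
#'
#' A nutrient specification couples a fortificant compound with the
#' fortification target for the food vehicle: the activity level (mass
#' fraction of the micronutrient in the compound), the target concentration
#' in the vehicle, an overage fraction added on top of the target to
#' compensate for fortificant degradation (used for vitamins), and the
#' fortificant price.
#'
#' @param name Nutrient name, e.g. `"iron"`.
#' @param compound Fortificant compound, e.g.
#'   `"micronized ferric pyrophosphate"`.
#' @param activity Mass fraction of micronutrient in the fortificant, in
#'   `(0, 1]`.
#' @param target_level Target micronutrient concentration, mg per kg of
#'   food vehicle.
#' @param overage_fraction Fraction of `target_level` added to compensate
#'   degradation (>= 0; typically 0 for minerals, 0.30 for vitamins).
#' @param price Fortificant price, USD per kg of fortificant.
#' @return A one-row tibble with the validated fields.
#' @examples
#' nutrient_spec("iron", "micronized ferric pyrophosphate",
#'   activity = 0.25, target_level = 2640, overage_fraction = 0, price = 11.5)
#' @export
nutrient_spec <- function(name, compound, activity, target_level,
                          overage_fraction = 0, price = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    validation_error("nutrient.name", "must be a non-empty string")
  }
  if (!is.numeric(activity) || length(activity) != 1L || is.na(activity) ||
      activity <= 0 || activity > 1) {
    validation_error(paste0("nutrient.", name, ".activity"),
                     "must be in (0, 1]")
  }
  check_nonneg(target_level, paste0("nutrient.", name, ".target_level"))
  check_nonneg(overage_fraction, paste0("nutrient.", name, ".overage_fraction"))
  check_nonneg(price, paste0("nutrient.", name, ".price"))
  tibble(
    name = name, compound = as.character(compound), activity = activity,
    target_level = target_level, overage_fraction = overage_fraction,
    price = price
  )
}

#' Premix channel parameters
#'
#' Adders applied to the base premix price to obtain the landed price for a
#' supply channel: an import duty (fraction of the base price) and a flat
#' transport/distribution/storage charge per kg.
#'
#' @param duty_fraction Import duty on premix, fraction >= 0.
#' @param transport_per_kg Transport/distribution/storage, USD per kg.
#' @return A list with the two validated fields.
#' @export
premix_channel <- function(duty_fraction = 0, transport_per_kg = 0) {
  check_nonneg(duty_fraction, "channel.duty_fraction")
  check_nonneg(transport_per_kg, "channel.transport_per_kg")
  list(duty_fraction = duty_fraction, transport_per_kg = transport_per_kg)
}

#' One priced activity or investment of the cost schedules
#'
#' A cost line item is one activity or investment of the program budget:
#' a quantity, a unit price, the actor that pays (firm or government),
#' the program phase it belongs to, the scope it is repeated over
#' (per factory, per port of entry, or national), optional percentage
#' markups that combine additively (e.g. duty + shipping + VAT), and a
#' per-model-year schedule of multipliers (1 = full cost that year,
#' 0.5 = halved, 0 = inactive).
#'
#' @param label Item label (unique within a scenario).
#' @param actor `"firm"` or `"government"`.
#' @param phase `"startup"` or `"operational"`.
#' @param category Reporting category, e.g. `"equipment"`,
#'   `"import_monitoring"`.
#' @param scope `"per_factory"`, `"per_port"` or `"national"`.
#' @param quantity Units (count, FTE, tests, ...) per unit of scope.
#' @param unit_price USD per unit.
#' @param markups Named numeric vector of markup fractions applied
#'   additively to the base cost, or `NULL`.
#' @param year_schedule Numeric vector of per-model-year multipliers
#'   (length = scenario horizon).
#' @param mgmt_base Logical; whether the item enters the base on which the
#'   government management/overhead rate is charged (monitoring items do,
#'   social marketing and training do not).
#' @return A one-row tibble (list-columns for `markups` and
#'   `year_schedule`).
#' @export
cost_line_item <- function(label, actor, phase, category, scope,
                           quantity, unit_price, markups = NULL,
                           year_schedule, mgmt_base = FALSE) {
  actor <- match.arg(actor, c("firm", "government"))
  phase <- match.arg(phase, c("startup", "operational"))
  scope <- match.arg(scope, c("per_factory", "per_port", "national"))
  check_nonneg(quantity, paste0("cost_item.", label, ".quantity"))
  check_nonneg(unit_price, paste0("cost_item.", label, ".unit_price"))
  check_nonneg(year_schedule, paste0("cost_item.", label, ".year_schedule"))
  if (!is.null(markups)) {
    markups <- unlist(markups)
    check_nonneg(markups, paste0("cost_item.", label, ".markups"))
  } else {
    markups <- stats::setNames(numeric(0), character(0))
  }
  tibble(
    label = label, actor = actor, phase = phase, category = category,
    scope = scope, quantity = quantity, unit_price = unit_price,
    markups = list(markups), year_schedule = list(as.numeric(year_schedule)),
    mgmt_base = isTRUE(mgmt_base)
  )
}

#' Assemble a country scenario
#'
#' A scenario is the complete configuration of one hypothetical national
#' fortification program: the population series over the model horizon,
#' subnational consumption strata, the structure of the bouillon industry,
#' the premix specification, per-channel premix price adders, management
#' rates, and the start-up and operational cost schedules. Model years are
#' indexed 1..`horizon`; years 1..`startup_years` are the start-up phase
#' (no fortification, hence no premix cost), the remainder the operational
#' phase.
#'
#' @param name Scenario name.
#' @param population List with `years` (contiguous calendar years,
#'   length = horizon), `totals` (persons per year) and
#'   `consuming_fraction` (national share of the population ever reached
#'   by bouillon, used for per-consumer metrics).
#' @param strata Tibble of consumption strata
#'   (`name`, `population_share`, `reach`, `intake` in g/day per consumer);
#'   see [nutrient_spec()] for the premix side.
#' @param premix List with `nutrients` (tibble of nutrient specs),
#'   `addition_rate` (mg premix per kg vehicle), `excipient_price`
#'   (USD/kg) and `upcharge_per_kg` (blender margin, USD per kg premix).
#' @param channels List with elements `domestic_production` and
#'   `imported_product`, each a [premix_channel()].
#' @param cost_items Tibble of [cost_line_item()] rows.
#' @param horizon Model horizon in years (default 10).
#' @param startup_years Length of the start-up phase (default 2).
#' @param availability_override Per-capita availability of the vehicle,
#'   g/capita/day, or `NULL` to derive it from the strata in the base year.
#' @param domestic_share Fraction of national consumption produced
#'   domestically.
#' @param industrial_share Fraction of domestic production that is
#'   industrially produced and hence fortifiable.
#' @param compliance Fraction of fortifiable product fortified to 100% of
#'   the standard.
#' @param n_factories,n_ports,production_days Industry structure: number of
#'   factories, ports of entry, and production days per year.
#' @param firm_mgmt_rate Firm management/overhead/administration cost as a
#'   fraction of the domestic-channel premix value.
#' @param gov_mgmt_rate Government management cost as a fraction of the
#'   monitoring subtotal.
#' @param approximate Logical flag for fixtures whose full parameter sets
#'   are reconstructed only approximately.
#' @return A validated object of class `lsff_scenario`.
#' @seealso [load_scenario()], [build_fixture()], [random_scenario()]
#' @export
scenario <- function(name, population, strata, premix, channels, cost_items,
                     horizon = 10L, startup_years = 2L,
                     availability_override = NULL,
                     domestic_share = 1, industrial_share = 1,
                     compliance = 1, n_factories = 1L, n_ports = 1L,
                     production_days = 250L,
                     firm_mgmt_rate = 0, gov_mgmt_rate = 0,
                     approximate = FALSE) {
  sc <- structure(
    list(
      name = name, horizon = as.integer(horizon),
      startup_years = as.integer(startup_years),
      population = population, strata = as_tibble(strata),
      availability_override = availability_override,
      domestic_share = domestic_share, industrial_share = industrial_share,
      compliance = compliance, n_factories = as.integer(n_factories),
      n_ports = as.integer(n_ports),
      production_days = as.integer(production_days),
      premix = premix, channels = channels,
      firm_mgmt_rate = firm_mgmt_rate, gov_mgmt_rate = gov_mgmt_rate,
      cost_items = as_tibble(cost_items),
      approximate = isTRUE(approximate)
    ),
    class = "lsff_scenario"
  )
  validate_scenario(sc)
}

#' Validate a scenario against the model invariants
#'
#' Checks every structural invariant of the configuration: fractions within
#' bounds, strictly increasing contiguous calendar years, strata shares
#' summing to one, a feasible premix (addition rate at least the total
#' fortificant mass), non-negative prices and schedules of the right
#' length. Called by [scenario()] and [load_scenario()]; exported so that
#' programmatically altered scenarios (e.g. in sweeps) can be re-checked.
#'
#' @param sc An `lsff_scenario`.
#' @return `sc`, invisibly unchanged, if valid; otherwise an error of class
#'   `lsff_validation_error` naming the field.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "lsff_scenario"))
  if (!is.character(sc$name) || !nzchar(sc$name)) {
    validation_error("name", "must be a non-empty string")
  }
  if (sc$horizon < 1L) validation_error("horizon", "must be >= 1")
  if (sc$startup_years < 0L || sc$startup_years >= sc$horizon) {
    validation_error("startup_years", "must be in [0, horizon)")
  }

  pop <- sc$population
  if (length(pop$years) != sc$horizon) {
    validation_error("population.years", "length must equal horizon")
  }
  if (any(diff(pop$years) != 1L)) {
    validation_error("population.years",
                     "must be strictly increasing and contiguous")
  }
  if (length(pop$totals) != sc$horizon || any(pop$totals <= 0)) {
    validation_error("population.totals",
                     "must be positive, one entry per model year")
  }
  check_fraction(pop$consuming_fraction, "population.consuming_fraction")

  st <- sc$strata
  needed <- c("name", "population_share", "reach", "intake")
  if (!all(needed %in% names(st)) || nrow(st) == 0L) {
    validation_error("strata", "must have at least one row with columns name, population_share, reach, intake")
  }
  for (col in c("population_share", "reach")) {
    if (any(st[[col]] < 0 | st[[col]] > 1)) {
      validation_error(paste0("strata.", col), "entries must be in [0, 1]")
    }
  }
  check_nonneg(st$intake, "strata.intake")
  if (abs(sum(st$population_share) - 1) > 1e-6) {
    validation_error("strata.population_share", "shares must sum to 1")
  }

  if (!is.null(sc$availability_override)) {
    check_nonneg(sc$availability_override, "availability_override")
  }
  check_fraction(sc$domestic_share, "domestic_share")
  check_fraction(sc$industrial_share, "industrial_share")
  check_fraction(sc$compliance, "compliance")
  if (sc$n_factories < 0L) validation_error("n_factories", "must be >= 0")
  if (sc$n_ports < 0L) validation_error("n_ports", "must be >= 0")
  if (sc$production_days < 0L) {
    validation_error("production_days", "must be >= 0")
  }

  pm <- sc$premix
  if (nrow(pm$nutrients) < 1L) {
    validation_error("premix.nutrients", "must contain at least one nutrient")
  }
  for (i in seq_len(nrow(pm$nutrients))) {
    row <- pm$nutrients[i, ]
    nutrient_spec(row$name, row$compound, row$activity, row$target_level,
                  row$overage_fraction, row$price)
  }
  check_nonneg(pm$addition_rate, "premix.addition_rate")
  check_nonneg(pm$excipient_price, "premix.excipient_price")
  check_nonneg(pm$upcharge_per_kg, "premix.upcharge_per_kg")
  subtotal <- sum(fortificant_amount(pm$nutrients))
  if (pm$addition_rate + 1e-9 < subtotal) {
    validation_error(
      "premix.addition_rate",
      sprintf("addition rate %.1f mg/kg is below the fortificant mass subtotal %.1f mg/kg",
              pm$addition_rate, subtotal)
    )
  }

  for (ch in c("domestic_production", "imported_product")) {
    if (is.null(sc$channels[[ch]])) {
      validation_error(paste0("channels.", ch), "channel is missing")
    }
    premix_channel(sc$channels[[ch]]$duty_fraction,
                   sc$channels[[ch]]$transport_per_kg)
  }
  check_fraction(sc$firm_mgmt_rate, "firm_mgmt_rate")
  check_fraction(sc$gov_mgmt_rate, "gov_mgmt_rate")

  it <- sc$cost_items
  if (nrow(it) > 0L) {
    if (anyDuplicated(it$label)) {
      validation_error("cost_items.label", "labels must be unique")
    }
    for (i in seq_len(nrow(it))) {
      if (length(it$year_schedule[[i]]) != sc$horizon) {
        validation_error(
          paste0("cost_items.", it$label[i], ".year_schedule"),
          "length must equal horizon"
        )
      }
      cost_line_item(it$label[i], it$actor[i], it$phase[i], it$category[i],
                     it$scope[i], it$quantity[i], it$unit_price[i],
                     it$markups[[i]], it$year_schedule[[i]], it$mgmt_base[i])
    }
  }
  invisible(sc)
}

#' @export
print.lsff_scenario <- function(x, ...) {
  cat(sprintf("<lsff_scenario> %s%s\n", x$name,
              if (x$approximate) " (approximate fixture)" else ""))
  cat(sprintf("  horizon: %d years (%d-%d), start-up years: %d\n",
              x$horizon, x$population$years[1],
              x$population$years[x$horizon], x$startup_years))
  cat(sprintf("  base-year population: %s (consuming fraction %.3f)\n",
              format(x$population$totals[1], big.mark = ","),
              x$population$consuming_fraction))
  cat(sprintf("  strata: %d; nutrients: %d; cost items: %d\n",
              nrow(x$strata), nrow(x$premix$nutrients), nrow(x$cost_items)))
  cat(sprintf("  domestic share %.2f, industrial share %.2f, compliance %.2f\n",
              x$domestic_share, x$industrial_share, x$compliance))
  cat(sprintf("  factories: %d, ports: %d, production days: %d\n",
              x$n_factories, x$n_ports, x$production_days))
  invisible(x)
}

# Model-year helpers.
operational_years <- function(sc) seq(sc$startup_years + 1L, sc$horizon)
startup_year_seq <- function(sc) seq_len(sc$startup_years)
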