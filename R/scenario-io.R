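# Scenario configuration files: a YAML 1.1 subset (JSON also accepted),
# all keys snake_case, monetary values plain numbers in constant USD.

scenario_to_list <- function(sc) {
  items <- lapply(seq_len(nrow(sc$cost_items)), function(i) {
    row <- sc$cost_items[i, ]
    out <- list(
      label = row$label, actor = row$actor, phase = row$phase,
      category = row$category, scope = row$scope,
      quantity = row$quantity, unit_price = row$unit_price,
      year_schedule = as.numeric(row$year_schedule[[1]]),
      mgmt_base = row$mgmt_base
    )
    if (length(row$markups[[1]]) > 0) {
      out$markups <- as.list(row$markups[[1]])
    }
    out
  })
  out <- list(
    name = sc$name, horizon = sc$horizon, startup_years = sc$startup_years,
    approximate = sc$approximate,
    population = list(
      years = as.integer(sc$population$years),
      totals = as.numeric(sc$population$totals),
      consuming_fraction = sc$population$consuming_fraction
    ),
    strata = lapply(seq_len(nrow(sc$strata)), function(i) {
      as.list(sc$strata[i, ])
    }),
    domestic_share = sc$domestic_share,
    industrial_share = sc$industrial_share,
    compliance = sc$compliance,
    n_factories = sc$n_factories, n_ports = sc$n_ports,
    production_days = sc$production_days,
    premix = list(
      nutrients = lapply(seq_len(nrow(sc$premix$nutrients)), function(i) {
        as.list(sc$premix$nutrients[i, ])
      }),
      addition_rate = sc$premix$addition_rate,
      excipient_price = sc$premix$excipient_price,
      upcharge_per_kg = sc$premix$upcharge_per_kg
    ),
    channels = sc$channels,
    firm_mgmt_rate = sc$firm_mgmt_rate,
    gov_mgmt_rate = sc$gov_mgmt_rate,
    cost_items = items
  )
  if (!is.null(sc$availability_override)) {
    out$availability_override <- sc$availability_override
  }
  out
}

list_to_scenario <- function(x) {
  need <- function(field) {
    if (is.null(x[[field]])) {
      validation_error(field, "required field is missing")
    }
    x[[field]]
  }
  strata <- dplyr::bind_rows(lapply(need("strata"), as_tibble))
  nutrients <- dplyr::bind_rows(lapply(need("premix")$nutrients, function(n) {
    nutrient_spec(n$name, n$compound, n$activity, n$target_level,
                  n$overage_fraction %||% 0, n$price %||% 0)
  }))
  items <- lapply(x$cost_items %||% list(), function(it) {
    cost_line_item(
      it$label, it$actor, it$phase, it$category %||% "other", it$scope,
      it$quantity, it$unit_price, it$markups,
      as.numeric(unlist(it$year_schedule)), it$mgmt_base %||% FALSE
    )
  })
  items <- if (length(items)) dplyr::bind_rows(items) else empty_cost_items()
  pop <- need("population")
  scenario(
    name = need("name"),
    population = list(
      years = as.integer(unlist(pop$years)),
      totals = as.numeric(unlist(pop$totals)),
      consuming_fraction = pop$consuming_fraction %||% 1
    ),
    strata = strata,
    premix = list(
      nutrients = nutrients,
      addition_rate = need("premix")$addition_rate,
      excipient_price = x$premix$excipient_price %||% 0,
      upcharge_per_kg = x$premix$upcharge_per_kg %||% 0
    ),
    channels = list(
      domestic_production = premix_channel(
        x$channels$domestic_production$duty_fraction %||% 0,
        x$channels$domestic_production$transport_per_kg %||% 0
      ),
      imported_product = premix_channel(
        x$channels$imported_product$duty_fraction %||% 0,
        x$channels$imported_product$transport_per_kg %||% 0
      )
    ),
    cost_items = items,
    horizon = x$horizon %||% 10L,
    startup_years = x$startup_years %||% 2L,
    availability_override = x$availability_override,
    domestic_share = x$domestic_share %||% 1,
    industrial_share = x$industrial_share %||% 1,
    compliance = x$compliance %||% 1,
    n_factories = x$n_factories %||% 1L,
    n_ports = x$n_ports %||% 1L,
    production_days = x$production_days %||% 250L,
    firm_mgmt_rate = x$firm_mgmt_rate %||% 0,
    gov_mgmt_rate = x$gov_mgmt_rate %||% 0,
    approximate = x$approximate %||% FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_cost_items <- function() {
  tibble(
    label = character(), actor = character(), phase = character(),
    category = character(), scope = character(), quantity = numeric(),
    unit_price = numeric(), markups = list(), year_schedule = list(),
    mgmt_base = logical()
  )
}

#' Load a scenario configuration file
#'
#' Reads a scenario from YAML (or JSON, by `.json` extension), fills
#' documented defaults, and validates every invariant. Parse failures are
#' reported as a format error carrying the parser's message (with line
#' information where the parser provides it); invariant violations as a
#' validation error naming the field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A validated `lsff_scenario`.
#' @seealso [save_scenario()] for the inverse; the two round-trip.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("scenario file not found: %s", path),
          class = "lsff_format_error")
  }
  raw <- tryCatch(
    {
      if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = FALSE)
      } else {
        yaml::read_yaml(path)
      }
    },
    error = function(e) {
      abort(sprintf("cannot parse scenario file %s: %s", path,
                    conditionMessage(e)),
            class = "lsff_format_error", parent = e)
    }
  )
  list_to_scenario(raw)
}

#' Write a scenario as normalized YAML
#'
#' @param sc An `lsff_scenario`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(sc, path) {
  validate_scenario(sc)
  yaml::write_yaml(scenario_to_list(sc), path, precision = 15L)
  invisible(path)
}
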