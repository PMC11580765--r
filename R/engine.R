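#' Cost of one line item in one model year
#'
#' `quantity x unit_price`, multiplied over the item's scope (number of
#' factories for `per_factory`, ports of entry for `per_port`, 1 for
#' `national`), by the year's schedule multiplier, and by
#' `(1 + sum of markup fractions)` - markups combine additively, matching
#' the convention in which a duty, a shipping charge and a VAT each apply
#' to the same pre-markup base.
#'
#' @param item One row of the `cost_items` tibble.
#' @param sc The scenario (supplies `n_factories` / `n_ports`).
#' @param year Model year, 1..horizon.
#' @return Cost in USD.
#' @export
line_item_cost <- function(item, sc, year) {
  sched <- item$year_schedule[[1]]
  if (year < 1L || year > length(sched)) {
    abort(sprintf("year %d outside the schedule of item `%s`", year,
                  item$label), class = "lsff_domain_error")
  }
  scope_mult <- switch(item$scope,
    per_factory = sc$n_factories,
    per_port = sc$n_ports,
    national = 1
  )
  base <- item$quantity * item$unit_price * scope_mult * sched[year]
  base * (1 + sum(item$markups[[1]]))
}

# Internal: per-year cost vector (length horizon) for a subset of items.
items_cost_by_year <- function(items, sc) {
  out <- numeric(sc$horizon)
  if (nrow(items) == 0L) return(out)
  for (i in seq_len(nrow(items))) {
    for (t in seq_len(sc$horizon)) {
      out[t] <- out[t] + line_item_cost(items[i, ], sc, t)
    }
  }
  out
}

#' Start-up costs per year for one actor
#'
#' Sums every start-up line item of the actor over the start-up years
#' (no fortification occurs in this phase, so there is no premix cost).
#'
#' @param sc An `lsff_scenario`.
#' @param actor `"firm"` or `"government"`.
#' @return Named numeric vector of length `startup_years` (USD per year).
#' @export
startup_costs <- function(sc, actor = c("firm", "government")) {
  actor <- match.arg(actor)
  items <- sc$cost_items[sc$cost_items$phase == "startup" &
                           sc$cost_items$actor == actor, ]
  by_year <- items_cost_by_year(items, sc)
  stats::setNames(by_year[startup_year_seq(sc)],
                  sc$population$years[startup_year_seq(sc)])
}

#' Annual premix requirements by channel
#'
#' For each operational year and supply channel, the fortified stream
#' volume, the premix mass it requires (volume x addition rate), and its
#' cost at the channel's landed per-MT price. Start-up years carry no
#' premix.
#'
#' @param sc An `lsff_scenario`.
#' @param demand An `lsff_demand` projection ([project_demand()]).
#' @param formulation An `lsff_formulation` ([build_formulation()]).
#' @return Tibble with columns `year`, `calendar_year`, `channel`,
#'   `fortified_volume` (MT vehicle), `premix_mass` (MT premix),
#'   `cost` (USD).
#' @export
premix_requirements <- function(sc, demand, formulation) {
  op <- operational_years(sc)
  ar <- formulation$addition_rate
  base <- formulation$base_price_per_kg
  rows <- lapply(c("domestic_production", "imported_product"), function(ch) {
    landed <- landed_price_per_kg(base, sc$channels[[ch]])
    per_mt <- cost_per_mt_vehicle(landed, ar)
    vol <- if (ch == "domestic_production") {
      demand$fortified_domestic[op]
    } else {
      demand$fortified_imported[op]
    }
    tibble(
      year = op, calendar_year = demand$calendar_year[op], channel = ch,
      fortified_volume = vol,
      premix_mass = vol * ar * 1e-6,  # kg premix per MT vehicle / 1000
      cost = vol * per_mt
    )
  })
  dplyr::bind_rows(rows)
}

# Internal: domestic-channel premix cost for one model year (0 in start-up).
domestic_premix_cost_year <- function(sc, demand, formulation, year) {
  if (year <= sc$startup_years) return(0)
  landed <- landed_price_per_kg(formulation$base_price_per_kg,
                                sc$channels$domestic_production)
  demand$fortified_domestic[year] *
    cost_per_mt_vehicle(landed, formulation$addition_rate)
}

#' Firm operational costs in one model year
#'
#' Fixed components (fortification labour, equipment maintenance, internal
#' QA/QC reagents and personnel, external testing, training) come from the
#' firm's operational line items; management/overhead/administration is
#' charged as `firm_mgmt_rate` times that year's domestic-channel premix
#' value (premix embedded in imported product is managed by the foreign
#' producer).
#'
#' @param sc An `lsff_scenario`.
#' @param demand An `lsff_demand` projection.
#' @param formulation An `lsff_formulation`.
#' @param year Operational model year.
#' @return Cost in USD.
#' @export
operational_costs_firm <- function(sc, demand, formulation, year) {
  items <- sc$cost_items[sc$cost_items$phase == "operational" &
                           sc$cost_items$actor == "firm", ]
  fixed <- sum(vapply(seq_len(nrow(items)),
                      function(i) line_item_cost(items[i, ], sc, year),
                      numeric(1)))
  fixed + sc$firm_mgmt_rate *
    domestic_premix_cost_year(sc, demand, formulation, year)
}

#' Government operational costs in one model year
#'
#' Sums the government's operational line items (factory inspections and
#' their sample reagents on the inspection-intensity schedule, import and
#' commercial monitoring, periodic household monitoring and surveillance,
#' social marketing, training) plus management/overhead charged as
#' `gov_mgmt_rate` times the monitoring subtotal - the items flagged
#' `mgmt_base` (monitoring activities; social marketing and training are
#' excluded). Government costs do not depend on industry compliance.
#'
#' @param sc An `lsff_scenario`.
#' @param year Operational model year.
#' @return Cost in USD.
#' @export
operational_costs_gov <- function(sc, year) {
  items <- sc$cost_items[sc$cost_items$phase == "operational" &
                           sc$cost_items$actor == "government", ]
  costs <- vapply(seq_len(nrow(items)),
                  function(i) line_item_cost(items[i, ], sc, year),
                  numeric(1))
  mgmt <- sc$gov_mgmt_rate * sum(costs[items$mgmt_base])
  sum(costs) + mgmt
}

#' Run the full cost engine for a scenario
#'
#' Orchestrates demand projection, premix formulation, the start-up and
#' operational schedules and premix accounting, and assembles the annual
#' cost cells and the five component totals. The total program cost is
#' exactly the sum of firm and government start-up costs, firm and
#' government operational costs, and premix cost.
#'
#' @param sc An `lsff_scenario`.
#' @return An object of class `lsff_cost_report`: `cells` (tibble `year`,
#'   `calendar_year`, `actor`, `category`, `amount`), `totals` (list with
#'   `SUC_F`, `SUC_G`, `OPC_F`, `OPC_G`, `PMX`, `TPC`), plus the `demand`
#'   projection and `formulation` used.
#' @examples
#' \donttest{
#' rep <- total_program_cost(build_fixture("nigeria"))
#' rep$totals$TPC
#' }
#' @export
total_program_cost <- function(sc) {
  validate_scenario(sc)
  demand <- project_demand(sc)
  formulation <- build_formulation(
    sc$premix$nutrients, sc$premix$addition_rate,
    sc$premix$excipient_price, sc$premix$upcharge_per_kg
  )

  cells <- list()
  add_cell <- function(year, actor, category, amount) {
    cells[[length(cells) + 1L]] <<- tibble(
      year = year, calendar_year = sc$population$years[year],
      actor = actor, category = category, amount = amount
    )
  }

  items <- sc$cost_items
  for (t in seq_len(sc$horizon)) {
    phase <- if (t <= sc$startup_years) "startup" else "operational"
    sub <- items[items$phase == phase, ]
    for (i in seq_len(nrow(sub))) {
      amt <- line_item_cost(sub[i, ], sc, t)
      if (amt != 0) {
        add_cell(t, paste(sub$actor[i], phase, sep = "_"),
                 sub$category[i], amt)
      }
    }
    if (phase == "operational") {
      dom_pmx <- domestic_premix_cost_year(sc, demand, formulation, t)
      firm_mgmt <- sc$firm_mgmt_rate * dom_pmx
      if (firm_mgmt != 0) {
        add_cell(t, "firm_operational", "management", firm_mgmt)
      }
      gov_items <- sub[sub$actor == "government", ]
      gov_costs <- vapply(seq_len(nrow(gov_items)),
                          function(i) line_item_cost(gov_items[i, ], sc, t),
                          numeric(1))
      gov_mgmt <- sc$gov_mgmt_rate * sum(gov_costs[gov_items$mgmt_base])
      if (gov_mgmt != 0) {
        add_cell(t, "government_operational", "management", gov_mgmt)
      }
    }
  }

  pmx <- premix_requirements(sc, demand, formulation)
  for (i in seq_len(nrow(pmx))) {
    if (pmx$cost[i] != 0) {
      add_cell(pmx$year[i],
               if (pmx$channel[i] == "domestic_production") {
                 "premix_domestic"
               } else {
                 "premix_imported"
               },
               "premix", pmx$cost[i])
    }
  }

  empty_cells <- tibble(
    year = integer(), calendar_year = integer(), actor = character(),
    category = character(), amount = numeric()
  )
  cells <- dplyr::bind_rows(empty_cells, cells)
  total_for <- function(actor) sum(cells$amount[cells$actor == actor])
  totals <- list(
    SUC_F = total_for("firm_startup"),
    SUC_G = total_for("government_startup"),
    OPC_F = total_for("firm_operational"),
    OPC_G = total_for("government_operational"),
    PMX = total_for("premix_domestic") + total_for("premix_imported")
  )
  totals$TPC <- totals$SUC_F + totals$SUC_G + totals$OPC_F +
    totals$OPC_G + totals$PMX

  structure(
    list(scenario_name = sc$name, cells = cells, totals = totals,
         demand = demand, formulation = formulation,
         premix_schedule = pmx),
    class = "lsff_cost_report"
  )
}

#' @export
print.lsff_cost_report <- function(x, ...) {
  cat(sprintf("<lsff_cost_report> %s\n", x$scenario_name))
  t <- x$totals
  fmt <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  cat(sprintf("  start-up   firm $%s  government $%s\n",
              fmt(t$SUC_F), fmt(t$SUC_G)))
  cat(sprintf("  operational firm $%s  government $%s\n",
              fmt(t$OPC_F), fmt(t$OPC_G)))
  cat(sprintf("  premix $%s\n", fmt(t$PMX)))
  cat(sprintf("  total program cost $%s\n", fmt(t$TPC)))
  invisible(x)
}
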