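# Independent brute-force re-implementation of the cost model, used as an
# oracle in property tests. Deliberately written as plain year-by-year,
# item-by-item loops over the raw scenario fields, sharing no code with
# the package's engine.

oracle_premix_price_per_kg <- function(sc) {
  ar <- sc$premix$addition_rate
  total <- 0
  mass <- 0
  for (i in seq_len(nrow(sc$premix$nutrients))) {
    n <- sc$premix$nutrients[i, ]
    amt <- n$target_level * (1 + n$overage_fraction) / n$activity
    mass <- mass + amt
    total <- total + (amt / ar) * n$price
  }
  total <- total + ((ar - mass) / ar) * sc$premix$excipient_price
  total + sc$premix$upcharge_per_kg
}

oracle_availability <- function(sc) {
  if (!is.null(sc$availability_override)) return(sc$availability_override)
  pop0 <- sc$population$totals[1]
  tot <- 0
  for (i in seq_len(nrow(sc$strata))) {
    s <- sc$strata[i, ]
    tot <- tot + pop0 * s$population_share * s$reach * s$intake
  }
  tot / pop0
}

oracle_item_cost <- function(sc, i, t) {
  it <- sc$cost_items[i, ]
  mult <- 1
  if (it$scope == "per_factory") mult <- sc$n_factories
  if (it$scope == "per_port") mult <- sc$n_ports
  mk <- 0
  for (m in it$markups[[1]]) mk <- mk + m
  it$quantity * it$unit_price * mult * it$year_schedule[[1]][t] * (1 + mk)
}

oracle_total_program_cost <- function(sc) {
  avail <- oracle_availability(sc)
  base <- oracle_premix_price_per_kg(sc)
  ar <- sc$premix$addition_rate

  suc_f <- 0; suc_g <- 0; opc_f <- 0; opc_g <- 0; pmx <- 0
  for (t in seq_len(sc$horizon)) {
    startup <- t <= sc$startup_years
    vol <- avail * sc$population$totals[t] * 365 / 1e6
    fort_dom <- vol * sc$domestic_share * sc$industrial_share * sc$compliance
    fort_imp <- vol * (1 - sc$domestic_share) * sc$industrial_share *
      sc$compliance

    gov_mgmt_base <- 0
    for (i in seq_len(nrow(sc$cost_items))) {
      it <- sc$cost_items[i, ]
      cost <- oracle_item_cost(sc, i, t)
      if (it$phase == "startup" && startup) {
        if (it$actor == "firm") suc_f <- suc_f + cost
        else suc_g <- suc_g + cost
      }
      if (it$phase == "operational" && !startup) {
        if (it$actor == "firm") {
          opc_f <- opc_f + cost
        } else {
          opc_g <- opc_g + cost
          if (it$mgmt_base) gov_mgmt_base <- gov_mgmt_base + cost
        }
      }
    }
    if (!startup) {
      ch <- sc$channels$domestic_production
      landed_dom <- base * (1 + ch$duty_fraction) + ch$transport_per_kg
      ch <- sc$channels$imported_product
      landed_imp <- base * (1 + ch$duty_fraction) + ch$transport_per_kg
      pmx_dom <- fort_dom * landed_dom * ar / 1000
      pmx_imp <- fort_imp * landed_imp * ar / 1000
      pmx <- pmx + pmx_dom + pmx_imp
      opc_f <- opc_f + sc$firm_mgmt_rate * pmx_dom
      opc_g <- opc_g + sc$gov_mgmt_rate * gov_mgmt_base
    }
  }
  list(SUC_F = suc_f, SUC_G = suc_g, OPC_F = opc_f, OPC_G = opc_g,
       PMX = pmx, TPC = suc_f + suc_g + opc_f + opc_g + pmx)
}

# Scale every monetary unit value of a scenario by c (prices, transport,
# upcharge, excipient; rates and markups are scale-free).
scale_prices <- function(sc, c) {
  sc$premix$nutrients$price <- sc$premix$nutrients$price * c
  sc$premix$excipient_price <- sc$premix$excipient_price * c
  sc$premix$upcharge_per_kg <- sc$premix$upcharge_per_kg * c
  sc$channels$domestic_production$transport_per_kg <-
    sc$channels$domestic_production$transport_per_kg * c
  sc$channels$imported_product$transport_per_kg <-
    sc$channels$imported_product$transport_per_kg * c
  sc$cost_items$unit_price <- sc$cost_items$unit_price * c
  sc
}

# The reference five-nutrient premix used across the packaged fixtures.
table_premix <- function() build_fixture("nigeria")$premix
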