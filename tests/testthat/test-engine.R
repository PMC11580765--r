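nigeria_report <- local({
  sc <- build_fixture("nigeria")
  rep <- total_program_cost(sc)
  list(sc = sc, rep = rep)
})

test_that("line items price scope, schedule and additive markups", {
  sc <- nigeria_report$sc
  item_row <- function(label) sc$cost_items[sc$cost_items$label == label, ]

  # 8 factories x $5,000 feeder, before markups: $40,000
  feeders <- item_row("feeder")
  feeders$markups <- list(setNames(numeric(0), character(0)))
  expect_equal(line_item_cost(feeders, sc, 1), 40000)

  # the lab set is (8690 + 3373 + 476) x 8 = 100,312; with the feeders
  # the equipment base is 140,312, and 10% + 10% + 8% additive markups
  # give the published 179,599 (multiplicative stacking would not)
  equip <- sc$cost_items[sc$cost_items$category == "equipment" &
                           sc$cost_items$actor == "firm", ]
  lab_base <- sum((equip$quantity * equip$unit_price * 8)[
    equip$label != "feeder"])
  expect_equal(lab_base, 100312)
  total_equip <- sum(vapply(seq_len(nrow(equip)), function(i) {
    line_item_cost(equip[i, ], sc, 1)
  }, numeric(1)))
  expect_equal(total_equip, 140312 * 1.28)
  expect_lt(abs(total_equip - 179599), 1)

  # an inactive year costs nothing
  expect_equal(line_item_cost(feeders, sc, 5), 0)
  expect_error(line_item_cost(feeders, sc, 11), class = "lsff_domain_error")
})

test_that("factory start-up years reproduce the published schedule", {
  suc_f <- startup_costs(nigeria_report$sc, "firm")
  expect_lt(abs(suc_f[["2021"]] - 188195), 10)
  expect_lt(abs(suc_f[["2022"]] - 5979), 1)

  # a scenario with no start-up items has a zero start-up phase
  sc <- random_scenario(7)
  sc$cost_items <- sc$cost_items[sc$cost_items$phase != "startup", ]
  expect_equal(unname(startup_costs(sc, "firm")), c(0, 0))
  expect_equal(unname(startup_costs(sc, "government")), c(0, 0))
})

test_that("premix requirements reproduce the published domestic cost series", {
  rep <- nigeria_report$rep
  pmx <- rep$premix_schedule
  dom <- pmx[pmx$channel == "domestic_production", ]

  printed_k <- c(64065, 65659, 67283, 68935, 70616, 72325, 74062, 75828)
  expect_equal(dom$cost / 1000, printed_k, tolerance = 5e-4)

  # premix mass follows from the addition rate
  expect_equal(pmx$premix_mass,
               pmx$fortified_volume * rep$formulation$addition_rate * 1e-6)

  # start-up years carry no premix
  expect_true(all(pmx$year > nigeria_report$sc$startup_years))
})

test_that("factory operational years reproduce the published totals", {
  sc <- nigeria_report$sc
  rep <- nigeria_report$rep
  y2023 <- operational_costs_firm(sc, rep$demand, rep$formulation, 3)
  y2026 <- operational_costs_firm(sc, rep$demand, rep$formulation, 6)
  expect_equal(y2023, 3447914, tolerance = 1e-4)
  expect_equal(y2026, 3691432, tolerance = 1e-4)

  # in-house reagents: 3 tests/day x 250 days x $8 x 8 factories, exact
  reag <- sc$cost_items[sc$cost_items$label == "qa_reagents", ]
  expect_equal(line_item_cost(reag, sc, 3), 48000)

  # with no premix flowing, only the fixed components remain
  sc0 <- sc
  sc0$compliance <- 0
  rep0 <- total_program_cost(sc0)
  fixed <- operational_costs_firm(sc0, rep0$demand, rep0$formulation, 3)
  expect_lt(abs(fixed - 244682), 1)
})

test_that("government operational years reproduce the published totals", {
  sc <- nigeria_report$sc
  expect_lt(abs(operational_costs_gov(sc, 3) - 158517), 1)   # 2023
  expect_lt(abs(operational_costs_gov(sc, 4) - 190017), 1)   # 2024, household monitoring year
  expect_lt(abs(operational_costs_gov(sc, 5) - 158517), 1)   # 2025
  expect_lt(abs(operational_costs_gov(sc, 6) - 148340), 1)   # 2026, halved inspections
})

test_that("the two-year start-up total matches the published program total", {
  t <- nigeria_report$rep$totals
  expect_equal(t$SUC_F + t$SUC_G, 910730, tolerance = 1e-3)
})

test_that("the component identity holds exactly for every random scenario", {
  for (seed in 1:200) {
    t <- total_program_cost(random_scenario(seed))$totals
    expect_identical(t$TPC, t$SUC_F + t$SUC_G + t$OPC_F + t$OPC_G + t$PMX)
  }
})

test_that("the engine agrees with an independent brute-force oracle", {
  for (seed in 1:100) {
    sc <- random_scenario(seed)
    t <- total_program_cost(sc)$totals
    o <- oracle_total_program_cost(sc)
    for (comp in c("SUC_F", "SUC_G", "OPC_F", "OPC_G", "PMX", "TPC")) {
      denom <- max(abs(o[[comp]]), 1)
      expect_lt(abs(t[[comp]] - o[[comp]]) / denom, 1e-9)
    }
  }
})

test_that("total cost is homogeneous of degree one in unit prices", {
  for (seed in c(5, 23, 77)) {
    sc <- random_scenario(seed)
    t1 <- total_program_cost(sc)$totals$TPC
    t2 <- total_program_cost(scale_prices(sc, 2.5))$totals$TPC
    expect_equal(t2, 2.5 * t1, tolerance = 1e-12)
  }
})

test_that("total cost is monotone in compliance, population and prices", {
  for (seed in c(11, 31)) {
    sc <- random_scenario(seed)
    base <- total_program_cost(sc)$totals$TPC

    sc_up <- sc
    sc_up$compliance <- min(1, sc$compliance + 0.1)
    expect_gte(total_program_cost(sc_up)$totals$TPC, base)

    sc_up <- sc
    sc_up$population$totals[4] <- sc_up$population$totals[4] * 1.5
    expect_gte(total_program_cost(sc_up)$totals$TPC, base)

    sc_up <- sc
    sc_up$cost_items$unit_price <- sc_up$cost_items$unit_price * 1.2
    expect_gte(total_program_cost(sc_up)$totals$TPC, base)
  }
})

test_that("zero compliance removes premix and its management but nothing else", {
  sc <- build_fixture("nigeria")
  sc$compliance <- 0
  rep <- total_program_cost(sc)
  expect_equal(rep$totals$PMX, 0)
  expect_equal(sum(rep$cells$amount[rep$cells$category == "management" &
                                      rep$cells$actor == "firm_operational"]),
               0)
  # government costs do not depend on industry adherence
  full <- nigeria_report$rep$totals
  expect_equal(rep$totals$OPC_G, full$OPC_G)
  expect_equal(rep$totals$SUC_F, full$SUC_F)
  expect_equal(rep$totals$SUC_G, full$SUC_G)
})

test_that("totals equal the sum of their per-year cells", {
  rep <- nigeria_report$rep
  cells <- rep$cells
  by_actor <- tapply(cells$amount, cells$actor, sum)
  t <- rep$totals
  expect_equal(unname(by_actor[["firm_startup"]]), t$SUC_F)
  expect_equal(unname(by_actor[["government_startup"]]), t$SUC_G)
  expect_equal(unname(by_actor[["firm_operational"]]), t$OPC_F)
  expect_equal(unname(by_actor[["government_operational"]]), t$OPC_G)
  expect_equal(unname(by_actor[["premix_domestic"]] +
                        by_actor[["premix_imported"]]), t$PMX)
  expect_equal(sum(cells$amount), t$TPC)
})

test_that("a scenario with all prices zero costs nothing", {
  sc <- scale_prices(random_scenario(13), 0)
  expect_equal(total_program_cost(sc)$totals$TPC, 0)
})
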