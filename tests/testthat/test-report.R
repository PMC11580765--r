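nigeria_summary <- local({
  rep <- total_program_cost(build_fixture("nigeria"))
  list(rep = rep, summ = summarize_costs(rep))
})

test_that("summary metrics reproduce the published program profile", {
  s <- nigeria_summary$summ
  expect_lt(abs(s$fortified_mt_per_year - 240925), 1)
  expect_lt(abs(s$premix_mt_per_year - 3915), 1)
  expect_lt(abs(s$cost_per_mt - 333), 1)
  expect_lt(abs(s$cost_per_consumer - 0.34), 0.02)

  # stakeholder shares: ~0.3% government, ~4.7% industry, ~95% premix
  sh <- s$shares
  expect_equal(sum(sh), 1, tolerance = 1e-9)
  expect_lt(abs(sh[["government_startup"]] + sh[["government_operational"]]
                - 0.003), 0.002)
  expect_lt(abs(sh[["firm_startup"]] + sh[["firm_operational"]] - 0.047),
            0.005)
  expect_lt(abs(sh[["premix"]] - 0.95), 0.01)
})

test_that("per-consumer costs for the approximate country fixtures stay near the published values", {
  sen <- summarize_costs(total_program_cost(build_fixture("senegal")))
  expect_lt(abs(sen$cost_per_consumer - 0.20), 0.02)
  bfa <- summarize_costs(total_program_cost(build_fixture("burkina_faso")))
  expect_lt(abs(bfa$cost_per_consumer - 0.13), 0.02)
})

test_that("zero fortified volume flags cost per MT instead of failing", {
  sc <- build_fixture("nigeria")
  sc$compliance <- 0
  s <- summarize_costs(total_program_cost(sc))
  expect_true(s$zero_fortified)
  expect_true(is.na(s$cost_per_mt))
})

test_that("sweeps rerun the engine without touching the input scenario", {
  sc <- build_fixture("nigeria")
  before <- lsffcost:::scenario_to_list(sc)
  base_tpc <- nigeria_summary$rep$totals$TPC

  # idempotence at the scenario's own value
  tab <- sweep_parameter(sc, "compliance", c(0, 0.75))
  expect_equal(tab$TPC[tab$value == 0.75], base_tpc)
  expect_equal(tab$PMX[tab$value == 0], 0)
  expect_identical(lsffcost:::scenario_to_list(sc), before)

  # doubling the iron fortificant price raises the premix price by
  # amount/addition_rate x delta = 10,560/16,250 x 11.50 = 7.47 $/kg
  f0 <- nigeria_summary$rep$formulation
  tab2 <- sweep_parameter(sc, "premix.nutrients.iron.price", c(11.5, 23))
  sc23 <- sc
  sc23$premix$nutrients$price[sc23$premix$nutrients$name == "iron"] <- 23
  f23 <- build_formulation(sc23$premix$nutrients, 16250, 1.5, 1)
  expect_equal(f23$base_price_per_kg - f0$base_price_per_kg,
               10560 / 16250 * 11.5, tolerance = 1e-9)
  expect_lt(abs(f23$base_price_per_kg - 23.83), 0.01)
  expect_gt(tab2$TPC[2], tab2$TPC[1])

  # sweeping any price upward never lowers total cost
  tab3 <- sweep_parameter(sc, "channels.domestic_production.duty_fraction",
                          c(0, 0.1, 0.2, 0.3))
  expect_true(all(diff(tab3$TPC) >= 0))

  expect_error(sweep_parameter(sc, "premix.nutrients.unobtainium.price", 1),
               class = "lsff_path_error")
})

test_that("writers emit deterministic, re-readable files", {
  rep <- nigeria_summary$rep
  summ <- nigeria_summary$summ
  dir <- withr::local_tempdir()

  p1 <- file.path(dir, "a.csv")
  p2 <- file.path(dir, "b.csv")
  write_cost_report(rep, p1)
  write_cost_report(rep, p2)
  expect_identical(readLines(p1), readLines(p2))
  cells <- utils::read.csv(p1)
  expect_equal(sum(cells$amount_usd), rep$totals$TPC)

  pj <- file.path(dir, "summary.json")
  write_summary_json(summ, pj)
  parsed <- jsonlite::read_json(pj)
  expect_equal(parsed$TPC, rep$totals$TPC)

  pp <- file.path(dir, "proj.csv")
  write_projection(rep$demand, pp)
  proj <- utils::read.csv(pp)
  expect_equal(nrow(proj), 10)
  expect_equal(proj$annual_volume_mt,
               proj$domestic_mt + proj$imported_mt)

  ps <- file.path(dir, "sweep.csv")
  write_sweep(sweep_parameter(build_fixture("nigeria"), "compliance",
                              c(0, 0.75)), ps)
  sw <- utils::read.csv(ps)
  expect_equal(nrow(sw), 6)  # 2 values x 3 metrics, long format
})
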