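test_that("fortification levels follow from reference intake values", {
  # 30% of a 22 mg iron NRV in a 2.5 g serving
  expect_equal(level_from_nrv(22, 0.30, 2.5), 2640)
  # 30% of a 0.8 mg vitamin A NRV in a 2.5 g serving
  expect_equal(level_from_nrv(0.8, 0.30, 2.5), 96)
  expect_equal(level_from_nrv(22, 0, 2.5), 0)
  # explicit conversion factor scales linearly
  expect_equal(level_from_nrv(22, 0.30, 2.5, conversion_factor = 0.6),
               2640 * 0.6)
  expect_error(level_from_nrv(22, 0.30, 0), class = "lsff_domain_error")
})

test_that("fortificant amounts combine target, overage and activity", {
  iron <- nutrient_spec("iron", "ferric pyrophosphate", 0.25, 2640, 0, 11.5)
  expect_equal(fortificant_amount(iron), 10560)
  vita <- nutrient_spec("vitamin_a", "retinyl palmitate", 0.075, 96, 0.30, 55)
  expect_equal(fortificant_amount(vita), 1664)
  ident <- nutrient_spec("x", "y", 1, 123.4, 0, 1)
  expect_equal(fortificant_amount(ident), 123.4)
  bad <- iron; bad$activity <- 0
  expect_error(fortificant_amount(bad), class = "lsff_domain_error")
})

test_that("suggested addition rate is the smallest granule above 110% of the subtotal", {
  expect_equal(suggest_addition_rate(14740), 16250)
  expect_equal(suggest_addition_rate(10000), 11000)
  expect_equal(suggest_addition_rate(100), 250)
})

test_that("the five-nutrient reference formulation reproduces the published cost chain", {
  pm <- table_premix()
  f <- build_formulation(pm$nutrients, pm$addition_rate,
                         pm$excipient_price, pm$upcharge_per_kg)

  amounts <- setNames(f$nutrients$amount, f$nutrients$name)
  expect_equal(amounts[["iron"]], 10560, tolerance = 0.1 / 10560)
  expect_equal(amounts[["vitamin_a"]], 1664)
  expect_equal(amounts[["zinc"]], 2100)
  expect_equal(amounts[["vitamin_b12"]], 374.4)
  expect_equal(amounts[["folic_acid"]], 41.6)
  expect_equal(f$nutrient_mass_subtotal, 14740)
  expect_equal(f$excipient_mass, 1510)

  contrib <- setNames(f$nutrients$cost_contribution, f$nutrients$name)
  expect_equal(contrib[["iron"]], 7.47, tolerance = 0.005 / 7.47)

  expect_lt(abs(f$base_price_per_kg - 16.35), 0.01)
  expect_lt(abs(cost_per_mt_vehicle(f$base_price_per_kg,
                                    f$addition_rate) - 265.73), 0.01)
})

test_that("degenerate formulations behave", {
  free <- nutrient_spec("x", "y", 0.5, 100, 0, 0)
  f <- build_formulation(free, 1000, 0, 2.5)
  expect_equal(f$base_price_per_kg, 2.5)
  expect_error(
    build_formulation(free, 100, 0, 0),  # amount 200 > addition rate 100
    class = "lsff_infeasible_formulation"
  )
})

test_that("landed prices add duty then transport; per-MT cost scales with the addition rate", {
  pm <- table_premix()
  f <- build_formulation(pm$nutrients, pm$addition_rate,
                         pm$excipient_price, pm$upcharge_per_kg)
  landed <- landed_price_per_kg(f$base_price_per_kg,
                                premix_channel(0.20, 0.20))
  expect_lt(abs(landed - 19.82), 0.01)
  expect_lt(abs(cost_per_mt_vehicle(landed, 16250) - 322.12), 0.01)
  expect_equal(landed_price_per_kg(7.7, premix_channel(0, 0)), 7.7)
  expect_equal(cost_per_mt_vehicle(19.82, 0), 0)
})

test_that("formulation properties hold on random premixes", {
  for (seed in 1:25) {
    pm <- random_scenario(seed)$premix
    f <- build_formulation(pm$nutrients, pm$addition_rate,
                           pm$excipient_price, pm$upcharge_per_kg)

    # mass conservation: nutrient amounts + excipient fill the premix
    expect_equal(sum(f$nutrients$amount) + f$excipient_mass,
                 f$addition_rate)
    # proportions sum to one
    expect_equal(sum(f$nutrients$proportion) + f$excipient_proportion, 1,
                 tolerance = 1e-9)

    # homogeneity: scaling all prices by c scales the per-kg and per-MT
    # cost by exactly c
    c_ <- 3.7
    pm2 <- pm
    pm2$nutrients$price <- pm2$nutrients$price * c_
    f2 <- build_formulation(pm2$nutrients, pm2$addition_rate,
                            pm2$excipient_price * c_,
                            pm2$upcharge_per_kg * c_)
    expect_equal(f2$base_price_per_kg, c_ * f$base_price_per_kg,
                 tolerance = 1e-12)

    # monotonicity: raising one fortificant price raises the base price
    # with slope amount / addition_rate (finite-difference check)
    k <- 1L
    delta <- 1.0
    pm3 <- pm
    pm3$nutrients$price[k] <- pm3$nutrients$price[k] + delta
    f3 <- build_formulation(pm3$nutrients, pm3$addition_rate,
                            pm3$excipient_price, pm3$upcharge_per_kg)
    expect_gt(f3$base_price_per_kg, f$base_price_per_kg)
    expect_equal((f3$base_price_per_kg - f$base_price_per_kg) / delta,
                 f$nutrients$amount[k] / f$addition_rate,
                 tolerance = 1e-9)

    # oracle equivalence: independent scalar recomputation
    sc <- random_scenario(seed)
    expect_equal(f$base_price_per_kg, oracle_premix_price_per_kg(sc),
                 tolerance = 1e-12)
  }
})
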