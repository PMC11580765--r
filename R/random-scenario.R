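#' Seeded random scenario generator
#'
#' Draws a syntactically arbitrary but always-valid scenario for
#' property-style testing: population between 1 and 300 million with a
#' smooth growth path, 1-15 consumption strata with shares summing to
#' one, 1-6 nutrients with positive prices, shares and fractions within
#' their bounds, a handful of random cost line items per actor and phase,
#' and an addition rate of `ceiling(1.1 x fortificant subtotal)` so the
#' formulation is always feasible. Deterministic for a given seed; the
#' global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @return A validated `lsff_scenario`.
#' @export
random_scenario <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)

  horizon <- 10L
  startup_years <- 2L
  pop0 <- runif(1, 1e6, 3e8)
  growth <- runif(1, 0.99, 1.03)

  n_strata <- sample.int(15L, 1L)
  shares <- runif(n_strata, 0.05, 1)
  strata <- tibble(
    name = paste0("stratum_", seq_len(n_strata)),
    population_share = shares / sum(shares),
    reach = runif(n_strata),
    intake = runif(n_strata, 0, 5)
  )

  n_nutr <- sample.int(6L, 1L)
  nutrients <- dplyr::bind_rows(lapply(seq_len(n_nutr), function(k) {
    nutrient_spec(
      paste0("nutrient_", k), paste0("compound_", k),
      activity = runif(1, 0.05, 1),
      target_level = runif(1, 1, 3000),
      overage_fraction = runif(1, 0, 0.5),
      price = runif(1, 0.5, 100)
    )
  }))
  subtotal <- sum(fortificant_amount(nutrients))
  addition_rate <- ceiling(1.1 * subtotal)

  random_schedule <- function(phase) {
    s <- numeric(horizon)
    if (phase == "startup") {
      s[seq_len(startup_years)] <- sample(c(0, 0.5, 1), startup_years,
                                          replace = TRUE, prob = c(1, 1, 3))
      if (all(s == 0)) s[1] <- 1
    } else {
      op <- (startup_years + 1L):horizon
      s[op] <- sample(c(0, 0.5, 1), length(op), replace = TRUE,
                      prob = c(1, 1, 4))
    }
    s
  }
  n_items <- sample(2:8, 1L)
  items <- dplyr::bind_rows(lapply(seq_len(n_items), function(i) {
    actor <- sample(c("firm", "government"), 1L)
    phase <- sample(c("startup", "operational"), 1L)
    markups <- if (runif(1) < 0.4) {
      m <- runif(sample.int(3L, 1L), 0, 0.3)
      stats::setNames(m, paste0("markup_", seq_along(m)))
    } else {
      NULL
    }
    cost_line_item(
      label = paste0("item_", i), actor = actor, phase = phase,
      category = sample(c("equipment", "training", "factory_monitoring",
                          "import_monitoring", "social_marketing"), 1L),
      scope = sample(c("per_factory", "per_port", "national"), 1L),
      quantity = runif(1, 0, 100), unit_price = runif(1, 0, 1e4),
      markups = markups, year_schedule = random_schedule(phase),
      mgmt_base = actor == "government" && runif(1) < 0.5
    )
  }))

  scenario(
    name = sprintf("random_seed_%d", seed),
    population = list(
      years = 2021L + 0:(horizon - 1L),
      totals = pop0 * growth^(0:(horizon - 1L)),
      consuming_fraction = runif(1, 0.3, 1)
    ),
    strata = strata,
    premix = list(
      nutrients = nutrients, addition_rate = addition_rate,
      excipient_price = runif(1, 0, 3), upcharge_per_kg = runif(1, 0, 2)
    ),
    channels = list(
      domestic_production = premix_channel(runif(1, 0, 0.5), runif(1, 0, 1)),
      imported_product = premix_channel(runif(1, 0, 0.5), runif(1, 0, 1))
    ),
    cost_items = items,
    horizon = horizon, startup_years = startup_years,
    availability_override = if (runif(1) < 0.5) runif(1, 0.1, 5) else NULL,
    domestic_share = runif(1), industrial_share = runif(1, 0.3, 1),
    compliance = runif(1),
    n_factories = sample.int(20L, 1L), n_ports = sample.int(12L, 1L),
    production_days = sample(200:300, 1L),
    firm_mgmt_rate = runif(1, 0, 0.1), gov_mgmt_rate = runif(1, 0, 0.1)
  )
}
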