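#' Fortification level implied by a nutrient reference value
#'
#' Converts a fraction of a reference daily intake, delivered in one
#' serving of the vehicle, into a concentration in the vehicle. With a
#' 2.5 g serving and a 30% share of a 22 mg iron reference value, the
#' level is 22 x 0.30 / 2.5 x 1000 = 2640 mg/kg.
#'
#' @param nrv_amount Reference intake of the micronutrient, mg.
#' @param fraction Fraction of the reference value to deliver per serving.
#' @param serving Serving size of the vehicle, g (> 0).
#' @param conversion_factor Optional unit/equivalence conversion (e.g.
#'   folic acid to dietary folate equivalents); default 1.
#' @return Target level in mg micronutrient per kg vehicle.
#' @export
level_from_nrv <- function(nrv_amount, fraction, serving,
                           conversion_factor = 1) {
  if (any(serving <= 0)) {
    abort("`serving` must be > 0", class = "lsff_domain_error")
  }
  check_nonneg(nrv_amount, "nrv_amount")
  check_nonneg(fraction, "fraction")
  check_nonneg(conversion_factor, "conversion_factor")
  nrv_amount * fraction * conversion_factor / serving * 1000
}

#' Fortificant mass required per kg of vehicle
#'
#' The amount of fortificant compound needed to deliver the target
#' micronutrient level, inflated by the overage and divided by the
#' activity level (micronutrient mass fraction of the compound).
#'
#' @param spec A nutrient spec (one or more rows as returned by
#'   [nutrient_spec()]).
#' @return mg fortificant per kg vehicle, one value per row.
#' @export
fortificant_amount <- function(spec) {
  if (any(spec$activity <= 0)) {
    abort("`activity` must be > 0", class = "lsff_domain_error")
  }
  spec$target_level * (1 + spec$overage_fraction) / spec$activity
}

#' Advisory premix addition rate
#'
#' Suggests the smallest multiple of `granularity` that is at least 110%
#' of the fortificant mass subtotal, leaving headroom for the excipient.
#' Advisory only: the addition rate actually used is always an explicit
#' scenario input.
#'
#' @param nutrient_mass_subtotal Sum of fortificant amounts, mg/kg.
#' @param granularity Rounding granule, mg/kg (default 250).
#' @return Suggested addition rate, mg premix per kg vehicle.
#' @export
suggest_addition_rate <- function(nutrient_mass_subtotal, granularity = 250) {
  stopifnot(nutrient_mass_subtotal > 0, granularity > 0)
  ceiling(1.10 * nutrient_mass_subtotal / granularity) * granularity
}

#' Build a premix formulation and cost it per kg
#'
#' Assembles the premix from its nutrient lines: each fortificant occupies
#' `amount / addition_rate` of the premix mass and contributes
#' `proportion x price` to the per-kg cost; an inert excipient fills the
#' remaining mass at its own price; a flat blender up-charge is added per
#' kg of finished premix. All arithmetic is kept at full precision;
#' rounding happens only in display methods.
#'
#' @param nutrients Tibble of nutrient specs ([nutrient_spec()] rows).
#' @param addition_rate mg premix per kg vehicle; must be at least the
#'   fortificant mass subtotal.
#' @param excipient_price USD per kg of excipient.
#' @param upcharge USD per kg of finished premix.
#' @return An object of class `lsff_formulation`: the per-nutrient table
#'   (amount, proportion, cost contribution), the excipient line, and
#'   `base_price_per_kg`.
#' @examples
#' iron <- nutrient_spec("iron", "micronized ferric pyrophosphate",
#'   activity = 0.25, target_level = 2640, price = 11.5)
#' f <- build_formulation(iron, addition_rate = 11000,
#'   excipient_price = 1.5, upcharge = 1)
#' f$base_price_per_kg
#' @export
build_formulation <- function(nutrients, addition_rate, excipient_price,
                              upcharge) {
  check_nonneg(addition_rate, "addition_rate")
  check_nonneg(excipient_price, "excipient_price")
  check_nonneg(upcharge, "upcharge")
  amount <- fortificant_amount(nutrients)
  subtotal <- sum(amount)
  if (addition_rate + 1e-9 < subtotal) {
    abort(
      sprintf("infeasible formulation: addition rate %.1f mg/kg < fortificant subtotal %.1f mg/kg",
              addition_rate, subtotal),
      class = "lsff_infeasible_formulation"
    )
  }
  proportion <- amount / addition_rate
  contribution <- proportion * nutrients$price
  excipient_mass <- addition_rate - subtotal
  excipient_proportion <- excipient_mass / addition_rate
  excipient_cost <- excipient_proportion * excipient_price
  structure(
    list(
      nutrients = tibble::add_column(
        nutrients, amount = amount, proportion = proportion,
        cost_contribution = contribution
      ),
      nutrient_mass_subtotal = subtotal,
      addition_rate = addition_rate,
      excipient_mass = excipient_mass,
      excipient_proportion = excipient_proportion,
      excipient_price = excipient_price,
      excipient_cost = excipient_cost,
      upcharge = upcharge,
      base_price_per_kg = sum(contribution) + excipient_cost + upcharge
    ),
    class = "lsff_formulation"
  )
}

#' @export
print.lsff_formulation <- function(x, ...) {
  cat("<lsff_formulation>\n")
  tab <- x$nutrients
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-11s %-38s act %5.1f%%  level %9.3f  amount %9.1f mg/kg  prop %6.4f  $%6.2f/kg premix\n",
                tab$name[i], tab$compound[i], 100 * tab$activity[i],
                tab$target_level[i], tab$amount[i], tab$proportion[i],
                tab$cost_contribution[i]))
  }
  cat(sprintf("  fortificant subtotal %9.1f mg/kg\n", x$nutrient_mass_subtotal))
  cat(sprintf("  excipient            %9.1f mg/kg  prop %6.4f  $%6.2f/kg premix\n",
              x$excipient_mass, x$excipient_proportion, x$excipient_cost))
  cat(sprintf("  addition rate        %9.1f mg premix per kg vehicle\n",
              x$addition_rate))
  cat(sprintf("  up-charge  $%.2f/kg\n", x$upcharge))
  cat(sprintf("  base price $%.2f per kg premix ($%.2f per MT vehicle)\n",
              x$base_price_per_kg,
              cost_per_mt_vehicle(x$base_price_per_kg, x$addition_rate)))
  invisible(x)
}

#' Landed premix price for a supply channel
#'
#' Applies the channel's import duty (on the base price) and flat
#' transport/distribution/storage charge.
#'
#' @param base Base premix price, USD per kg.
#' @param channel A [premix_channel()].
#' @return Landed price, USD per kg premix.
#' @export
landed_price_per_kg <- function(base, channel) {
  check_nonneg(base, "base")
  base * (1 + channel$duty_fraction) + channel$transport_per_kg
}

#' Premix cost per metric ton of fortified vehicle
#'
#' The addition rate in mg premix per kg vehicle equals kg premix per MT
#' of vehicle divided by 1000, so the per-MT premix cost is
#' `landed x addition_rate / 1000`.
#'
#' @param landed Landed premix price, USD per kg.
#' @param addition_rate mg premix per kg vehicle.
#' @return USD per MT of fortified vehicle.
#' @export
cost_per_mt_vehicle <- function(landed, addition_rate) {
  check_nonneg(landed, "landed")
  check_nonneg(addition_rate, "addition_rate")
  landed * addition_rate * 1e-3
}

#' Formulation table in long form
#'
#' @param f An `lsff_formulation`.
#' @return Tibble mirroring the premix calculator layout: one row per
#'   nutrient plus an excipient row, with amounts, proportions and cost
#'   contributions.
#' @export
formulation_table <- function(f) {
  stopifnot(inherits(f, "lsff_formulation"))
  n <- f$nutrients
  dplyr::bind_rows(
    tibble(
      component = n$name, compound = n$compound, activity = n$activity,
      target_level = n$target_level, overage_fraction = n$overage_fraction,
      amount_mg_kg = n$amount, proportion = n$proportion,
      price_per_kg = n$price, cost_per_kg_premix = n$cost_contribution
    ),
    tibble(
      component = "excipient", compound = "filler", activity = NA_real_,
      target_level = NA_real_, overage_fraction = NA_real_,
      amount_mg_kg = f$excipient_mass, proportion = f$excipient_proportion,
      price_per_kg = f$excipient_price, cost_per_kg_premix = f$excipient_cost
    )
  )
}
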