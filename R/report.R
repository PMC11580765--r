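#' Summary metrics for a cost report
#'
#' Condenses a full cost report into the headline program metrics:
#' 10-year total and annual average cost, cost per MT of fortified
#' vehicle (total program cost over cumulative fortified volume), cost
#' per consumer reached, stakeholder cost shares, and average annual
#' product requirements. Cost per consumer is defined over the
#' operational phase: mean annual operational spending (firm +
#' government + premix) divided by the mean consuming population over
#' operational years - start-up years deliver no fortified product, so
#' they are excluded from the per-consumer denominator and numerator.
#'
#' @param report An `lsff_cost_report` from [total_program_cost()].
#' @param demand Optional `lsff_demand`; defaults to the one inside
#'   `report`.
#' @param formulation Optional `lsff_formulation`; defaults likewise.
#' @return An object of class `lsff_summary` with fields
#'   `total_10yr_cost`, `annual_average`, `cost_per_mt` (`NA` and a
#'   `zero_fortified` flag when no product is fortified),
#'   `cost_per_consumer`, `shares` (named fractions summing to 1:
#'   firm/government start-up and operational, premix), and
#'   `fortified_mt_per_year` / `premix_mt_per_year`.
#' @export
summarize_costs <- function(report, demand = report$demand,
                            formulation = report$formulation) {
  stopifnot(inherits(report, "lsff_cost_report"))
  t <- report$totals
  horizon <- max(demand$year)
  op <- report$premix_schedule$year
  op_years <- sort(unique(op))
  n_op <- length(op_years)

  fortified_op <- demand$fortified_domestic[op_years] +
    demand$fortified_imported[op_years]
  cum_fortified <- sum(fortified_op)
  zero_fortified <- cum_fortified <= 0

  fortified_mt_per_year <- if (n_op > 0) cum_fortified / n_op else 0
  premix_mt_per_year <- fortified_mt_per_year *
    (formulation$addition_rate * 1e-3) * 1e-3

  op_cost_annual <- (t$OPC_F + t$OPC_G + t$PMX) / max(n_op, 1L)
  mean_consumers <- mean(demand$consuming_population[op_years])

  shares <- c(
    firm_startup = t$SUC_F, government_startup = t$SUC_G,
    firm_operational = t$OPC_F, government_operational = t$OPC_G,
    premix = t$PMX
  )
  shares <- if (t$TPC > 0) shares / t$TPC else shares * NA_real_

  structure(
    list(
      scenario_name = report$scenario_name,
      total_10yr_cost = t$TPC,
      annual_average = t$TPC / horizon,
      cost_per_mt = if (zero_fortified) NA_real_ else t$TPC / cum_fortified,
      zero_fortified = zero_fortified,
      cost_per_consumer = if (mean_consumers > 0) {
        op_cost_annual / mean_consumers
      } else {
        NA_real_
      },
      shares = shares,
      fortified_mt_per_year = fortified_mt_per_year,
      premix_mt_per_year = premix_mt_per_year,
      totals = t
    ),
    class = "lsff_summary"
  )
}

#' @export
print.lsff_summary <- function(x, ...) {
  dollar <- function(v) {
    if (is.na(v)) "NA" else format(round(v), big.mark = ",",
                                   scientific = FALSE)
  }
  cat(sprintf("<lsff_summary> %s\n", x$scenario_name))
  cat(sprintf("  total 10-year cost      $%s (annual average $%s)\n",
              dollar(x$total_10yr_cost), dollar(x$annual_average)))
  cat(sprintf("  cost per MT fortified   $%s\n", dollar(x$cost_per_mt)))
  cat(sprintf("  cost per consumer/year  $%.2f\n", x$cost_per_consumer))
  cat(sprintf("  fortified vehicle       %s MT/year\n",
              dollar(x$fortified_mt_per_year)))
  cat(sprintf("  premix                  %s MT/year\n",
              dollar(x$premix_mt_per_year)))
  sh <- round(100 * x$shares)
  cat(sprintf("  cost shares (%%): firm start-up %d, gov start-up %d, firm operational %d, gov operational %d, premix %d\n",
              sh[["firm_startup"]], sh[["government_startup"]],
              sh[["firm_operational"]], sh[["government_operational"]],
              sh[["premix"]]))
  invisible(x)
}

# Internal: walk a dotted parameter path through the scenario. Tibbles
# with a `name`/`label` column are indexed by that column's value.
resolve_path <- function(sc, parameter_path) {
  segs <- strsplit(parameter_path, ".", fixed = TRUE)[[1]]
  if (length(segs) < 1L) {
    abort("empty parameter path", class = "lsff_path_error")
  }
  segs
}

path_get <- function(node, segs) {
  if (length(segs) == 0L) return(node)
  seg <- segs[[1]]
  if (is.data.frame(node)) {
    key_col <- intersect(c("name", "label"), names(node))[1]
    if (!is.na(key_col) && seg %in% node[[key_col]]) {
      return(path_get(node[node[[key_col]] == seg, ], segs[-1]))
    }
    if (seg %in% names(node)) {
      val <- node[[seg]]
      if (nrow(node) == 1L) val <- val[[1]]
      return(path_get(val, segs[-1]))
    }
  } else if (is.list(node) && seg %in% names(node)) {
    return(path_get(node[[seg]], segs[-1]))
  }
  abort(sprintf("unknown parameter path segment `%s`", seg),
        class = "lsff_path_error")
}

path_set <- function(node, segs, value) {
  if (length(segs) == 0L) return(value)
  seg <- segs[[1]]
  if (is.data.frame(node)) {
    key_col <- intersect(c("name", "label"), names(node))[1]
    if (!is.na(key_col) && seg %in% node[[key_col]]) {
      idx <- which(node[[key_col]] == seg)
      node[idx, ] <- path_set(node[idx, ], segs[-1], value)
      return(node)
    }
    if (seg %in% names(node)) {
      if (length(segs) == 1L) {
        node[[seg]] <- value
        return(node)
      }
      node[[seg]][[1]] <- path_set(node[[seg]][[1]], segs[-1], value)
      return(node)
    }
  } else if (is.list(node) && seg %in% names(node)) {
    node[[seg]] <- path_set(node[[seg]], segs[-1], value)
    return(node)
  }
  abort(sprintf("unknown parameter path segment `%s`", seg),
        class = "lsff_path_error")
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs the full cost engine for each value of one numeric scenario
#' parameter, leaving the original scenario unmodified. Parameters are
#' addressed by a dotted path, e.g. `"compliance"`,
#' `"premix.nutrients.iron.price"`,
#' `"channels.domestic_production.duty_fraction"`, or
#' `"cost_items.feeder.unit_price"`.
#'
#' @param sc An `lsff_scenario`.
#' @param parameter_path Dotted path to a numeric scalar field.
#' @param values Numeric vector of values to evaluate.
#' @return Tibble with one row per value: `parameter`, `value`, `TPC`,
#'   `PMX`, `cost_per_mt`.
#' @examples
#' \donttest{
#' sweep_parameter(build_fixture("nigeria"), "compliance", c(0, 0.75))
#' }
#' @export
sweep_parameter <- function(sc, parameter_path, values) {
  segs <- resolve_path(sc, parameter_path)
  path_get(sc, segs)  # fail fast on unknown paths
  rows <- lapply(values, function(v) {
    sc2 <- path_set(sc, segs, v)
    class(sc2) <- class(sc)
    validate_scenario(sc2)
    rep <- total_program_cost(sc2)
    summ <- summarize_costs(rep)
    tibble(
      parameter = parameter_path, value = v,
      TPC = rep$totals$TPC, PMX = rep$totals$PMX,
      cost_per_mt = summ$cost_per_mt
    )
  })
  dplyr::bind_rows(rows)
}

#' Report writers
#'
#' Deterministic plain-text writers for the engine outputs: the per-year
#' long-format cost cells, the demand projection, the JSON summary, and
#' sweep results. Reruns on identical input produce byte-identical
#' files.
#'
#' @param report An `lsff_cost_report`.
#' @param demand An `lsff_demand`.
#' @param summary An `lsff_summary`.
#' @param sweep A tibble from [sweep_parameter()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_cost_report <- function(report, path) {
  cells <- report$cells[order(report$cells$year, report$cells$actor,
                              report$cells$category), ]
  utils::write.csv(
    data.frame(
      year = cells$year, calendar_year = cells$calendar_year,
      actor = cells$actor, category = cells$category,
      amount_usd = cells$amount
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writers
#' @export
write_projection <- function(demand, path) {
  utils::write.csv(
    data.frame(
      year = demand$calendar_year, population = demand$population,
      annual_volume_mt = demand$annual_volume,
      domestic_mt = demand$domestic_volume,
      imported_mt = demand$imported_volume,
      fortified_domestic_mt = demand$fortified_domestic,
      fortified_imported_mt = demand$fortified_imported
    ),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writers
#' @export
write_summary_json <- function(summary, path) {
  t <- summary$totals
  jsonlite::write_json(
    list(
      scenario = summary$scenario_name,
      SUC_F = t$SUC_F, SUC_G = t$SUC_G, OPC_F = t$OPC_F, OPC_G = t$OPC_G,
      PMX = t$PMX, TPC = t$TPC,
      total_10yr_cost = summary$total_10yr_cost,
      annual_average = summary$annual_average,
      cost_per_mt = summary$cost_per_mt,
      cost_per_consumer = summary$cost_per_consumer,
      fortified_mt_per_year = summary$fortified_mt_per_year,
      premix_mt_per_year = summary$premix_mt_per_year,
      shares = as.list(summary$shares)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname writers
#' @export
write_sweep <- function(sweep, path) {
  long <- dplyr::bind_rows(lapply(seq_len(nrow(sweep)), function(i) {
    tibble(
      parameter = sweep$parameter[i], value = sweep$value[i],
      metric = c("TPC", "PMX", "cost_per_mt"),
      amount = c(sweep$TPC[i], sweep$PMX[i], sweep$cost_per_mt[i])
    )
  }))
  utils::write.csv(as.data.frame(long), path, row.names = FALSE)
  invisible(path)
}
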