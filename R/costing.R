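# Micro-costing of screening modalities: apportioned salaries, annualized
# equipment, consumables and overheads -> annual cost, throughput, unit cost.

#' Annualize an equipment purchase
#'
#' Straight-line annualization over the device lifespan, undiscounted and with
#' no salvage value, matching a single-year analytic horizon.
#'
#' @param purchase_price Purchase price (INR). Vectorized.
#' @param lifespan_years Useful life in years (default 6). Must be > 0.
#' @return Annual equivalent cost (INR/year).
#' @examples
#' annualize_equipment(448416, 6) # 74736
#' @export
annualize_equipment <- function(purchase_price, lifespan_years = 6) {
  if (any(purchase_price < 0)) abort_invalid("`purchase_price` must be >= 0.")
  if (any(lifespan_years <= 0)) abort_invalid("`lifespan_years` must be > 0.")
  purchase_price / lifespan_years
}

#' Annual staff cost attributed to a screening program
#'
#' Salaries are apportioned: the monthly cost to the program is
#' `monthly_salary * apportioning_statistic`, where the apportioning statistic
#' is the fraction of the staff member's working time spent on screening
#' (typically screening hours per month over overall monthly hours).
#'
#' @param monthly_salary Gross monthly salary (INR/month). Vectorized.
#' @param apportioning_statistic Fraction of time on screening, in \[0, 1\].
#' @param months_per_year Months worked per year (default 12).
#' @return A tibble with columns `monthly_cost` and `annual_cost` (INR).
#' @examples
#' staff_annual_cost(90000, 0.25) # monthly 22500, annual 270000
#' @export
staff_annual_cost <- function(monthly_salary, apportioning_statistic,
                              months_per_year = 12) {
  if (any(monthly_salary < 0)) abort_invalid("`monthly_salary` must be >= 0.")
  if (any(apportioning_statistic < 0 | apportioning_statistic > 1)) {
    abort_invalid("`apportioning_statistic` must lie in [0, 1].")
  }
  monthly <- monthly_salary * apportioning_statistic
  tibble::tibble(monthly_cost = monthly, annual_cost = monthly * months_per_year)
}

#' Apportioning statistic from screening hours
#'
#' @param hours_per_day_on_screening Hours/day spent exclusively on screening.
#' @param working_days_per_month Screening days per month (default 22).
#' @param overall_monthly_hours Overall contracted hours/month (default 176).
#' @return Fraction of working time attributable to screening, in \[0, 1\].
#' @examples
#' apportioning_statistic(2) # 44/176 = 0.25
#' @export
apportioning_statistic <- function(hours_per_day_on_screening,
                                   working_days_per_month = 22,
                                   overall_monthly_hours = 176) {
  frac <- hours_per_day_on_screening * working_days_per_month /
    overall_monthly_hours
  if (any(frac < 0 | frac > 1)) {
    abort_invalid("screening hours exceed overall working hours.")
  }
  frac
}

inventory_categories <- c(
  "human_resource", "medical_consumables", "non_medical_consumables",
  "medical_equipment", "non_medical_equipment", "overheads"
)

#' Annual cost inventory of a screening modality
#'
#' Six cost components, all expressed in INR per year (equipment already
#' annualized). The inventory total is always the exact sum of the six
#' components.
#'
#' @param human_resource,medical_consumables,non_medical_consumables,medical_equipment,non_medical_equipment,overheads
#'   Annual cost of each component (INR/year, >= 0).
#' @return A one-row tibble of class `cost_inventory`.
#' @examples
#' cost_inventory(421000, 104520, 0, 74736, 0, 2400)
#' @export
cost_inventory <- function(human_resource = 0, medical_consumables = 0,
                           non_medical_consumables = 0, medical_equipment = 0,
                           non_medical_equipment = 0, overheads = 0) {
  out <- tibble::tibble(
    human_resource = human_resource,
    medical_consumables = medical_consumables,
    non_medical_consumables = non_medical_consumables,
    medical_equipment = medical_equipment,
    non_medical_equipment = non_medical_equipment,
    overheads = overheads
  )
  if (any(unlist(out) < 0)) {
    abort_invalid("all cost inventory components must be >= 0.")
  }
  class(out) <- c("cost_inventory", class(out))
  out
}

#' Total annual cost of a cost inventory
#'
#' @param inventory A [cost_inventory()].
#' @return Total annual cost (INR/year), the exact sum of the six components.
#' @examples
#' total_annual_cost(cost_inventory(421000, 104520, 0, 74736, 0, 2400)) # 602656
#' @export
total_annual_cost <- function(inventory) {
  comps <- unlist(inventory[1, inventory_categories])
  if (any(comps < 0)) abort_invalid("negative cost component.")
  sum(comps)
}

#' Define a screening modality
#'
#' A first-line or confirmatory hearing test with its duration, throughput
#' assumptions and annual cost inventory. Effective screening hours per day
#' default to 6 (a working day net of setup, documentation and breaks), which
#' together with test durations of 15/10/90 minutes yields the reference
#' throughputs of 24/36/4 newborns per day.
#'
#' @param name Modality label, e.g. "P-AABR", "OAE", "BERA".
#' @param test_duration_minutes Average duration of one test (minutes, > 0).
#' @param inventory A [cost_inventory()].
#' @param working_days_per_year Screening days per year (default 260).
#' @param effective_screening_hours_per_day Productive screening hours per day
#'   (default 6).
#' @param staff_lines,equipment_lines Optional tibbles of the underlying staff
#'   and equipment line items (provenance only; the inventory drives costs).
#' @return An object of class `screening_modality`.
#' @examples
#' paabr <- screening_modality("P-AABR", 15,
#'   cost_inventory(421000, 104520, 0, 74736, 0, 2400))
#' daily_throughput(paabr)  # 24
#' unit_cost(paabr)
#' @export
screening_modality <- function(name, test_duration_minutes, inventory,
                               working_days_per_year = 260,
                               effective_screening_hours_per_day = 6,
                               staff_lines = NULL, equipment_lines = NULL) {
  assert_number(test_duration_minutes, "test_duration_minutes",
                lower = 0, strict_lower = TRUE)
  assert_number(working_days_per_year, "working_days_per_year", lower = 0)
  assert_number(effective_screening_hours_per_day,
                "effective_screening_hours_per_day", lower = 0,
                strict_lower = TRUE)
  stopifnot(inherits(inventory, "cost_inventory"))
  structure(
    list(
      name = name,
      test_duration_minutes = test_duration_minutes,
      working_days_per_year = working_days_per_year,
      effective_screening_hours_per_day = effective_screening_hours_per_day,
      inventory = inventory,
      staff_lines = staff_lines,
      equipment_lines = equipment_lines
    ),
    class = "screening_modality"
  )
}

#' @export
print.screening_modality <- function(x, ...) {
  uc <- unit_cost(x)
  cat(sprintf(
    "<screening_modality> %s: %g min/test, %d/day, %d/year, total %s INR/yr, unit %s INR\n",
    x$name, x$test_duration_minutes, daily_throughput(x), annual_throughput(x),
    format(total_annual_cost(x$inventory), big.mark = ","),
    uc$unit_cost_reported
  ))
  invisible(x)
}

#' Daily screening throughput
#'
#' Number of newborns a modality can screen in one working day: whole tests
#' fitting into the effective screening hours.
#'
#' @param modality A [screening_modality()].
#' @return Integer count of screens per day.
#' @examples
#' paabr <- screening_modality("P-AABR", 15,
#'   cost_inventory(421000, 104520, 0, 74736, 0, 2400))
#' daily_throughput(paabr) # 24
#' @export
daily_throughput <- function(modality) {
  if (modality$test_duration_minutes <= 0) {
    abort_invalid("test duration must be positive.")
  }
  as.integer(floor(
    modality$effective_screening_hours_per_day * 60 /
      modality$test_duration_minutes
  ))
}

#' Annual screening throughput
#'
#' @param modality A [screening_modality()].
#' @return Screens per year: daily throughput times working days.
#' @export
annual_throughput <- function(modality) {
  daily_throughput(modality) * modality$working_days_per_year
}

#' Unit cost per screening
#'
#' Total annual modality cost divided by annual throughput. The unrounded
#' value is carried through all downstream cost accumulation; the reported
#' value is rounded half-up to whole INR.
#'
#' @param modality A [screening_modality()].
#' @return A one-row tibble: `modality`, `total_annual_cost`,
#'   `annual_throughput`, `unit_cost` (unrounded), `unit_cost_reported`.
#' @export
unit_cost <- function(modality) {
  vol <- annual_throughput(modality)
  if (vol <= 0) {
    abort_invalid(sprintf(
      "annual throughput of %s is zero; unit cost undefined.", modality$name
    ))
  }
  total <- total_annual_cost(modality$inventory)
  tibble::tibble(
    modality = modality$name,
    total_annual_cost = total,
    annual_throughput = vol,
    unit_cost = total / vol,
    unit_cost_reported = round_half_up(total / vol)
  )
}

#' Costing table for a set of modalities
#'
#' One row per modality with throughput, the six annual cost components,
#' total and unit costs — the shape of a standard program costing report.
#'
#' @param modalities A list of [screening_modality()] objects.
#' @return A tibble with one row per modality.
#' @export
costing_table <- function(modalities) {
  purrr::map_dfr(modalities, function(m) {
    dplyr::bind_cols(
      tibble::tibble(
        modality = m$name,
        test_duration_minutes = m$test_duration_minutes,
        daily_throughput = daily_throughput(m),
        working_days_per_year = m$working_days_per_year,
        annual_throughput = annual_throughput(m)
      ),
      tibble::as_tibble(m$inventory),
      unit_cost(m)[, c("total_annual_cost", "unit_cost", "unit_cost_reported")]
    )
  })
}

#' Read a cost-inventory line-item table
#'
#' Reads a CSV of raw cost lines with columns `modality`, `category`,
#' `description`, `amount`, `lifespan_years`, `monthly_salary`,
#' `apportioning_statistic`. Human-resource lines may either carry a direct
#' annual `amount` (e.g. a training cost amortized in the analysis year) or a
#' `monthly_salary` plus `apportioning_statistic`, in which case the annual
#' cost is salary x statistic x 12. Equipment lines with a `lifespan_years`
#' are straight-line annualized from their purchase `amount`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of line items with an `annual_cost` column appended.
#' @seealso [inventories_from_lines()] to aggregate into [cost_inventory()]s;
#'   the bundled reference table
#'   `system.file("extdata", "cost_inventory_2019_20.csv", package = "hearcea")`.
#' @export
read_cost_inventory <- function(path) {
  lines <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("modality", "category", "description", "amount",
              "lifespan_years", "monthly_salary", "apportioning_statistic")
  missing <- setdiff(needed, names(lines))
  if (length(missing)) {
    abort_invalid(paste("cost inventory CSV lacks columns:",
                        paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(lines$category), inventory_categories)
  if (length(bad)) {
    abort_invalid(paste("unknown cost categories:", paste(bad, collapse = ", ")))
  }
  is_staff <- !is.na(lines$monthly_salary) & !is.na(lines$apportioning_statistic)
  is_equip <- !is_staff & !is.na(lines$lifespan_years)
  is_direct <- !is_staff & !is_equip
  if (any(is.na(lines$amount[is_direct]))) {
    abort_invalid("non-staff, non-equipment lines need an `amount`.")
  }
  annual <- numeric(nrow(lines))
  annual[is_staff] <- staff_annual_cost(
    lines$monthly_salary[is_staff], lines$apportioning_statistic[is_staff]
  )$annual_cost
  annual[is_equip] <- annualize_equipment(lines$amount[is_equip],
                                          lines$lifespan_years[is_equip])
  annual[is_direct] <- lines$amount[is_direct]
  dplyr::mutate(lines, annual_cost = annual)
}

#' Aggregate cost line items into per-modality inventories
#'
#' @param lines A tibble as returned by [read_cost_inventory()].
#' @return A named list of [cost_inventory()] objects, one per modality.
#' @export
inventories_from_lines <- function(lines) {
  totals <- lines |>
    dplyr::group_by(modality, category) |>
    dplyr::summarise(annual_cost = sum(annual_cost), .groups = "drop") |>
    tidyr::pivot_wider(names_from = category, values_from = annual_cost,
                       values_fill = 0)
  for (cat in setdiff(inventory_categories, names(totals))) totals[[cat]] <- 0
  out <- purrr::map(seq_len(nrow(totals)), function(i) {
    do.call(cost_inventory, as.list(totals[i, inventory_categories]))
  })
  names(out) <- totals$modality
  out
}
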