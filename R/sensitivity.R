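# One-way deterministic sensitivity analysis: sweep one registered scalar
# input over a grid, re-running the full pipeline at each point.

sensitivity_parameters <- function(config) {
  c("prevalence_per_1000", "life_expectancy_years", "cohort_size",
    "utility_normal_hearing", "utility_hl", "wage_loss_per_visit",
    paste0("sensitivity:", config$strategies),
    paste0("specificity:", config$strategies),
    paste0("unit_cost:", names(config$modalities)),
    paste0("treatment_cost:",
           vapply(config$scenarios, function(s) s$name, character(1))))
}

#' Set a registered scalar model input on a configuration
#'
#' Parameter names are either plain (`"prevalence_per_1000"`,
#' `"life_expectancy_years"`, `"cohort_size"`, `"utility_normal_hearing"`,
#' `"utility_hl"`, `"wage_loss_per_visit"`) or qualified
#' (`"sensitivity:<strategy>"`, `"specificity:<strategy>"`,
#' `"unit_cost:<modality>"`, `"treatment_cost:<scenario>"`). Setting a
#' sensitivity or specificity switches that strategy's cascade to `sens_spec`
#' mode, since observed counts do not respond to accuracy parameters.
#'
#' @param config A `run_config`.
#' @param parameter Registered parameter name.
#' @param value New scalar value.
#' @return The modified `run_config`.
#' @export
set_config_parameter <- function(config, parameter, value) {
  known <- sensitivity_parameters(config)
  if (!parameter %in% known) {
    abort_invalid(paste0(
      "unknown parameter '", parameter, "'; registered parameters: ",
      paste(known, collapse = ", ")
    ))
  }
  parts <- strsplit(parameter, ":", fixed = TRUE)[[1]]
  key <- parts[1]
  target <- if (length(parts) > 1) parts[2] else NULL
  co <- config$cohort
  switch(
    key,
    prevalence_per_1000 = {
      config$cohort <- cohort_spec(co$size, value, co$life_expectancy_years)
    },
    life_expectancy_years = {
      config$cohort <- cohort_spec(co$size, co$prevalence_per_1000, value)
    },
    cohort_size = {
      config$cohort <- cohort_spec(value, co$prevalence_per_1000,
                                   co$life_expectancy_years)
    },
    utility_normal_hearing = {
      u <- config$utilities
      config$utilities <- utility_weights(value, u$hl_any, u$hl_unilateral,
                                          u$hl_bilateral)
    },
    utility_hl = {
      u <- config$utilities
      config$utilities <- utility_weights(u$normal_hearing, value,
                                          u$hl_unilateral, u$hl_bilateral)
    },
    wage_loss_per_visit = {
      config$oope$wage_loss_per_visit <- value
    },
    sensitivity = {
      config$performances[[target]]$sensitivity <- value
      config$cascade_modes[[target]] <- cascade_mode("sens_spec")
    },
    specificity = {
      config$performances[[target]]$specificity <- value
      config$cascade_modes[[target]] <- cascade_mode("sens_spec")
    },
    unit_cost = {
      ov <- config$unit_cost_overrides %||% numeric()
      ov[[target]] <- value
      config$unit_cost_overrides <- ov
    },
    treatment_cost = {
      ix <- which(vapply(config$scenarios, function(s) s$name,
                         character(1)) == target)
      config$scenarios[[ix]]$cost_per_treated_child <- value
    }
  )
  config
}

#' One-way sensitivity sweep
#'
#' Re-evaluates the deterministic pipeline on an equally spaced grid over one
#' registered input, holding everything else fixed, and reports the
#' incremental cost, incremental QALYs and ICER of the intervention versus
#' the comparator at each grid point. Monte-Carlo simulation is disabled
#' during sweeps. The externally stated QALY difference, if any, is ignored
#' here: a sweep only makes sense against the model-derived effect. Sweeps
#' over prevalence, cohort size or test accuracy switch every strategy to
#' `sens_spec` mode, because observed detection counts are fixed field
#' observations that cannot respond to those inputs.
#'
#' @param config A `run_config`.
#' @param parameter Registered parameter name (see [set_config_parameter()]).
#' @param lower,upper Sweep range.
#' @param steps Number of grid points (default 5).
#' @param perspective `"health_system"` (default) or `"societal"`.
#' @param scenario Treatment scenario name (default: the first configured).
#' @return A tibble of class `hearcea_sensitivity` with columns `parameter`,
#'   `value`, `delta_cost`, `delta_qaly`, `icer`, `status`.
#' @examples
#' sweep <- one_way_sensitivity(reference_config(), "prevalence_per_1000",
#'                              2, 10, steps = 3)
#' sweep$icer
#' @export
one_way_sensitivity <- function(config, parameter, lower, upper, steps = 5,
                                perspective = "health_system",
                                scenario = NULL) {
  assert_number(steps, "steps", lower = 1)
  scenario <- scenario %||% config$scenarios[[1]]$name
  config$simulation <- NULL
  # observed detection counts are fixed field observations: they cannot
  # respond to epidemiological or accuracy inputs, so sweeps over those
  # inputs use the self-consistent sens_spec tree for every strategy
  structural <- c("prevalence_per_1000", "cohort_size")
  if (grepl("^(sensitivity|specificity):", parameter) ||
      parameter %in% structural) {
    config$cascade_modes <- purrr::map(config$cascade_modes,
                                       ~ cascade_mode("sens_spec"))
  }
  grid <- seq(lower, upper, length.out = steps)
  rows <- purrr::map_dfr(grid, function(v) {
    cfg <- set_config_parameter(config, parameter, v)
    bundle <- run_pipeline(cfg)
    row <- bundle$cea_summary[
      bundle$cea_summary$perspective == perspective &
        bundle$cea_summary$scenario == scenario, ]
    tibble::tibble(
      parameter = parameter, value = v,
      delta_cost = row$delta_cost,
      delta_qaly = row$delta_qaly_model,
      icer = row$icer_model,
      status = row$status
    )
  })
  structure(rows, class = c("hearcea_sensitivity", class(rows)),
            perspective = perspective, scenario = scenario)
}

#' Tornado-style summary of several one-way sweeps
#'
#' @param sweeps A list of `hearcea_sensitivity` tibbles.
#' @param outcome Column to summarize (default `"icer"`).
#' @return A tibble with one row per parameter: the outcome at the low and
#'   high end of its sweep and the spanned range, sorted widest first.
#' @export
tornado_summary <- function(sweeps, outcome = "icer") {
  purrr::map_dfr(sweeps, function(s) {
    tibble::tibble(
      parameter = s$parameter[1],
      low_value = s$value[1],
      high_value = s$value[nrow(s)],
      outcome_low = s[[outcome]][1],
      outcome_high = s[[outcome]][nrow(s)],
      range = abs(s[[outcome]][nrow(s)] - s[[outcome]][1])
    )
  }) |>
    dplyr::arrange(dplyr::desc(range))
}
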