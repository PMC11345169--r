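# Run configuration: assembly, YAML/JSON loading, cross-reference validation.

required_config_keys <- c("cohort", "modalities", "performances",
                          "confirmatory", "strategies", "cascade_modes",
                          "utilities", "scenarios", "oope")

#' Assemble a run configuration
#'
#' The full parameter set of one cost-effectiveness comparison: cohort,
#' costed modalities, test accuracies, cascade parameterizations, utilities,
#' treatment scenarios and OOPE profile, plus optional Monte-Carlo settings.
#'
#' @param cohort A [cohort_spec()].
#' @param modalities Named list of [screening_modality()] objects; must
#'   include the confirmatory modality and every strategy.
#' @param performances Named list of [test_performance()] objects keyed like
#'   `modalities`.
#' @param confirmatory Name of the single confirmatory modality.
#' @param strategies Character vector of at least two first-line strategy
#'   names; the first is the intervention, the second the comparator.
#' @param cascade_modes Named list of [cascade_mode()] objects per strategy.
#' @param utilities A [utility_weights()].
#' @param scenarios List of [treatment_scenario()] objects.
#' @param oope An [oope_profile()].
#' @param simulation Optional [simulation_config()] enabling Monte-Carlo
#'   validation in [run_pipeline()].
#' @param delta_qaly_override Optional externally stated QALY difference
#'   (intervention minus comparator) used for reproduction runs alongside the
#'   model-derived difference; both are reported.
#' @param reported_values Optional named list of externally published values
#'   for the same quantities; [run_pipeline()] compares computed results
#'   against them and writes any disagreement to the discrepancy log.
#' @param unit_cost_overrides Optional named numeric vector replacing derived
#'   unit costs (used by [one_way_sensitivity()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort, modalities, performances, confirmatory,
                       strategies, cascade_modes, utilities, scenarios, oope,
                       simulation = NULL, delta_qaly_override = NULL,
                       reported_values = NULL, unit_cost_overrides = NULL) {
  cfg <- structure(
    list(cohort = cohort, modalities = modalities, performances = performances,
         confirmatory = confirmatory, strategies = strategies,
         cascade_modes = cascade_modes, utilities = utilities,
         scenarios = scenarios, oope = oope, simulation = simulation,
         delta_qaly_override = delta_qaly_override,
         reported_values = reported_values,
         unit_cost_overrides = unit_cost_overrides),
    class = "run_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Every violation is collected and reported at once, not just the first.
#'
#' @param config A `run_config`.
#' @return The config, invisibly, if valid; otherwise an error enumerating
#'   all violations.
#' @export
validate_config <- function(config) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (!inherits(config$cohort, "cohort_spec")) note("`cohort` is not a cohort_spec.")
  if (!length(config$modalities)) note("no modalities defined.")
  if (length(config$confirmatory) != 1 ||
      !config$confirmatory %in% names(config$modalities)) {
    note("exactly one confirmatory modality must be designated and defined.")
  }
  if (length(config$strategies) < 2) {
    note("at least two first-line strategies are required.")
  }
  for (s in config$strategies) {
    if (!s %in% names(config$modalities)) {
      note(sprintf("strategy '%s' has no costed modality.", s))
    }
    if (!s %in% names(config$performances)) {
      note(sprintf("strategy '%s' has no test performance.", s))
    }
    if (!s %in% names(config$cascade_modes)) {
      note(sprintf("strategy '%s' has no cascade mode.", s))
    }
  }
  if (any(config$strategies %in% config$confirmatory)) {
    note("a strategy cannot double as the confirmatory modality.")
  }
  if (!inherits(config$utilities, "utility_weights")) {
    note("`utilities` is not a utility_weights object.")
  }
  if (!length(config$scenarios) ||
      !all(vapply(config$scenarios, inherits, TRUE, "treatment_scenario"))) {
    note("`scenarios` must be a nonempty list of treatment_scenario objects.")
  }
  if (!inherits(config$oope, "oope_profile")) {
    note("`oope` is not an oope_profile object.")
  }
  if (length(problems)) {
    stop("invalid run configuration:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  invisible(config)
}

#' Load a run configuration from YAML or JSON
#'
#' The file carries the same fields as [run_config()]; cost inventories may
#' be given inline (six components per modality) or via a
#' `cost_inventory_csv` path (relative paths resolve against the config file)
#' in the format of [read_cost_inventory()]. Validation reports every
#' violation, not just the first.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated `run_config`.
#' @examples
#' cfg <- load_config(system.file("extdata", "unhs_india_2019_20.yaml",
#'                                package = "hearcea"))
#' cfg$cohort$size # 100000
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || !length(raw)) {
    abort_invalid(paste(
      "empty configuration; required keys:",
      paste(required_config_keys, collapse = ", ")
    ))
  }
  missing <- setdiff(required_config_keys, names(raw))
  if (length(missing)) {
    abort_invalid(paste("configuration lacks required keys:",
                        paste(missing, collapse = ", ")))
  }

  cohort <- do.call(cohort_spec, raw$cohort)

  inventories <- list()
  if (!is.null(raw$cost_inventory_csv)) {
    csv <- raw$cost_inventory_csv
    if (!file.exists(csv)) csv <- file.path(dirname(path), csv)
    inventories <- inventories_from_lines(read_cost_inventory(csv))
  }
  modalities <- purrr::imap(raw$modalities, function(m, name) {
    inv <- if (!is.null(m$inventory)) {
      do.call(cost_inventory, m$inventory)
    } else if (name %in% names(inventories)) {
      inventories[[name]]
    } else {
      abort_invalid(sprintf("modality '%s' has no cost inventory.", name))
    }
    screening_modality(
      name = name,
      test_duration_minutes = m$test_duration_minutes,
      inventory = inv,
      working_days_per_year = m$working_days_per_year %||% 260,
      effective_screening_hours_per_day =
        m$effective_screening_hours_per_day %||% 6
    )
  })

  performances <- purrr::map(raw$performances, function(p) {
    test_performance(p$sensitivity, p$specificity,
                     ppv = p$ppv %||% NA_real_, npv = p$npv %||% NA_real_)
  })
  cascade_modes <- purrr::map(raw$cascade_modes, function(m) {
    cascade_mode(m$mode %||% "sens_spec", referred = m$referred,
                 confirmed = m$confirmed, under_detected = m$under_detected)
  })
  utilities <- do.call(utility_weights, raw$utilities)
  if (is.data.frame(raw$scenarios)) { # JSON arrays of objects simplify to df
    raw$scenarios <- purrr::pmap(raw$scenarios, list)
  }
  scenarios <- purrr::map(raw$scenarios, function(s) {
    treatment_scenario(s$name,
                       cost_per_treated_child = s$cost_per_treated_child,
                       treated_utility = s$treated_utility)
  })
  oope_raw <- raw$oope
  oope_args <- list(
    wage_loss_per_visit = oope_raw$wage_loss_per_visit %||% 540.5,
    visits_per_screened = oope_raw$visits_per_screened %||% 1,
    visits_per_referred = oope_raw$visits_per_referred %||% 1
  )
  if (!is.null(oope_raw$transport_per_visit)) {
    oope_args$transport_per_visit <- unlist(oope_raw$transport_per_visit)
  }
  if (!is.null(oope_raw$facility_mix)) {
    oope_args$facility_mix <- unlist(oope_raw$facility_mix)
  }
  oope <- do.call(oope_profile, oope_args)
  simulation <- if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    simulation_config(
      n_newborns = sim$n_newborns %||% cohort$size,
      prevalence_per_1000 = sim$prevalence_per_1000 %||%
        cohort$prevalence_per_1000,
      first_line = performances[[sim$first_line %||% raw$strategies[[1]]]],
      confirmatory = performances[[raw$confirmatory]] %||% perfect_test(),
      seed = sim$seed %||% 1L,
      n_replicates = sim$n_replicates %||% 1L
    )
  }

  run_config(
    cohort = cohort, modalities = modalities, performances = performances,
    confirmatory = raw$confirmatory, strategies = unlist(raw$strategies),
    cascade_modes = cascade_modes, utilities = utilities,
    scenarios = scenarios, oope = oope, simulation = simulation,
    delta_qaly_override = raw$delta_qaly_override,
    reported_values = raw$reported_values
  )
}

#' Reference configuration: India 2019-20 UNHS costing scenario
#'
#' Loads the bundled configuration reproducing a published India 2019-20
#' universal-neonatal-hearing-screening cost-effectiveness analysis: a
#' 100,000-newborn cohort at 5/1,000 prevalence, P-AABR vs OAE first-line
#' screening with BERA confirmation, observed detection rates (262 / 26
#' confirmed cases), utility weights 0.95 / 0.77 and 69.2-year life
#' expectancy. Published totals travel along as `reported_values` so that
#' [run_pipeline()] can flag the source's internal inconsistencies in its
#' discrepancy log.
#'
#' @return A validated `run_config`.
#' @export
reference_config <- function() {
  load_config(system.file("extdata", "unhs_india_2019_20.yaml",
                          package = "hearcea"))
}
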