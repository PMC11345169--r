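# QALYs, perspective-specific total costs, ICERs, cost per case detected,
# and one-way deterministic sensitivity sweeps.

#' Health-state utility weights
#'
#' Annual utility weights on the 0-1 dead-to-perfect-health scale. The pooled
#' hearing-loss weight (`hl_any`) drives the default analysis; the
#' unilateral/bilateral weights are housed and selectable but unused unless a
#' caller opts in.
#'
#' @param normal_hearing Utility of a normal-hearing child (default 0.95).
#' @param hl_any Utility with untreated hearing loss, pooled over laterality
#'   (default 0.77).
#' @param hl_unilateral,hl_bilateral Laterality-specific weights
#'   (defaults 0.85 and 0.69).
#' @return A list of class `utility_weights`.
#' @export
utility_weights <- function(normal_hearing = 0.95, hl_any = 0.77,
                            hl_unilateral = 0.85, hl_bilateral = 0.69) {
  for (nm in c("normal_hearing", "hl_any", "hl_unilateral", "hl_bilateral")) {
    assert_fraction(get(nm), nm)
  }
  if (normal_hearing < hl_any) {
    abort_invalid("normal-hearing utility must be >= hearing-loss utility.")
  }
  structure(
    list(normal_hearing = normal_hearing, hl_any = hl_any,
         hl_unilateral = hl_unilateral, hl_bilateral = hl_bilateral),
    class = "utility_weights"
  )
}

# Lifetime treatment + rehabilitation cost per treated child, back-calculated
# from published program-level totals ((scenario total - screening total) /
# cases detected); the source never itemizes these, so they are derived
# defaults, not authoritative prices.
treatment_cost_defaults <- c(
  cochlear_implant = (332678772.18 - 10535915) / 262, # 1,229,552.89 INR
  hearing_aid      = (193869248.38 - 10535915) / 262  # 699,745.55 INR
)

#' Treatment scenario for detected cases
#'
#' @param name `"cochlear_implant"` or `"hearing_aid"` (free-text names are
#'   allowed if `cost_per_treated_child` is given).
#' @param cost_per_treated_child Lifetime treatment and rehabilitation cost
#'   per detected-and-treated child (INR). Defaults to derived values for the
#'   two named scenarios.
#' @param treated_utility Annual utility of a treated child; `NULL` (default)
#'   means treated children attain the normal-hearing utility.
#' @return A list of class `treatment_scenario`.
#' @export
treatment_scenario <- function(name, cost_per_treated_child = NULL,
                               treated_utility = NULL) {
  cost <- cost_per_treated_child %||%
    unname(treatment_cost_defaults[name])
  if (is.null(cost) || is.na(cost)) {
    abort_invalid(sprintf(
      "no default treatment cost for scenario '%s'; supply `cost_per_treated_child`.",
      name
    ))
  }
  assert_number(cost, "cost_per_treated_child", lower = 0)
  structure(
    list(name = name, cost_per_treated_child = cost,
         treated_utility = treated_utility),
    class = "treatment_scenario"
  )
}

#' Out-of-pocket expenditure profile
#'
#' Patient-side costs per screening or referral visit: facility-level mean
#' transport cost plus wage loss for the accompanying caregiver. Direct
#' medical charges are assumed covered by public maternal-and-child health
#' schemes, so transport and wage loss are the whole of OOPE.
#'
#' @param transport_per_visit Named vector of mean transport cost (INR) per
#'   visit by facility level.
#' @param wage_loss_per_visit Caregiver wage loss per visit (INR).
#' @param visits_per_screened First-line visits per screened newborn.
#' @param visits_per_referred Additional confirmation visits per referral.
#' @param facility_mix Fractions of visits at each facility level; must sum
#'   to 1 and align with `transport_per_visit`.
#' @return A list of class `oope_profile`.
#' @export
oope_profile <- function(transport_per_visit = c(medical_college = 440,
                                                 district = 300,
                                                 community_health_centre = 207,
                                                 primary_health_centre = 99),
                         wage_loss_per_visit = 540.5,
                         visits_per_screened = 1,
                         visits_per_referred = 1,
                         facility_mix = NULL) {
  if (is.null(facility_mix)) {
    facility_mix <- rep(1 / length(transport_per_visit),
                        length(transport_per_visit))
    names(facility_mix) <- names(transport_per_visit)
  }
  if (length(facility_mix) != length(transport_per_visit)) {
    abort_invalid("facility_mix must align with transport_per_visit.")
  }
  if (any(facility_mix < 0) || abs(sum(facility_mix) - 1) > 1e-9) {
    abort_invalid("facility_mix must be nonnegative and sum to 1.")
  }
  if (any(transport_per_visit < 0) || wage_loss_per_visit < 0 ||
      visits_per_screened < 0 || visits_per_referred < 0) {
    abort_invalid("OOPE components must be >= 0.")
  }
  structure(
    list(transport_per_visit = transport_per_visit,
         wage_loss_per_visit = wage_loss_per_visit,
         visits_per_screened = visits_per_screened,
         visits_per_referred = visits_per_referred,
         facility_mix = facility_mix),
    class = "oope_profile"
  )
}

#' Expected out-of-pocket expenditure of a strategy
#'
#' @param cohort A [cohort_spec()].
#' @param counts A `cascade_counts` object (supplies the referral volume).
#' @param oope An [oope_profile()].
#' @return A list with `total` (INR) and a `decomposition` tibble splitting
#'   transport from wage loss and screening visits from referral visits.
#' @export
expected_oope <- function(cohort, counts, oope) {
  stopifnot(inherits(oope, "oope_profile"))
  mean_transport <- sum(oope$transport_per_visit * oope$facility_mix)
  screen_visits <- cohort$size * oope$visits_per_screened
  referral_visits <- counts$referred * oope$visits_per_referred
  decomposition <- tibble::tibble(
    component = c("transport_screening", "wage_loss_screening",
                  "transport_referral", "wage_loss_referral"),
    cost = c(screen_visits * mean_transport,
             screen_visits * oope$wage_loss_per_visit,
             referral_visits * mean_transport,
             referral_visits * oope$wage_loss_per_visit)
  )
  list(total = sum(decomposition$cost), decomposition = decomposition)
}

#' Lifetime QALYs accrued by a screened cohort
#'
#' Undiscounted by default: each newborn accrues its annual utility weight
#' over the full life expectancy. Detected (hence treated) children attain
#' the treated utility (normal hearing unless overridden); hearing-impaired
#' children the cascade misses accrue the untreated hearing-loss utility.
#'
#' @param cohort A [cohort_spec()].
#' @param counts A `cascade_counts` object.
#' @param weights A [utility_weights()].
#' @param treated_utility Annual utility of detected-and-treated children
#'   (default: `weights$normal_hearing`).
#' @param discount_rate Annual discount rate applied to future life-years
#'   (default 0, i.e. undiscounted lifetime QALYs).
#' @return Total cohort QALYs (numeric scalar).
#' @examples
#' cc <- expected_cascade(cohort_spec(),
#'   mode = cascade_mode("observed", referred = 500, confirmed = 262,
#'                       under_detected = 0))
#' strategy_qalys(cohort_spec(), cc, utility_weights()) # 6574000
#' @export
strategy_qalys <- function(cohort, counts, weights,
                           treated_utility = NULL, discount_rate = 0) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(counts, "cascade_counts"),
            inherits(weights, "utility_weights"))
  u_treated <- treated_utility %||% weights$normal_hearing
  le <- cohort$life_expectancy_years
  years <- if (discount_rate == 0) le else {
    (1 - (1 + discount_rate)^(-le)) / discount_rate
  }
  missed <- counts$under_detected
  treated <- counts$confirmed_cases
  normal <- cohort$size - missed - treated
  (normal * weights$normal_hearing + treated * u_treated +
      missed * weights$hl_any) * years
}

#' Perspective-specific total strategy cost
#'
#' Health-system perspective: program screening cost plus lifetime treatment
#' cost of every confirmed case. Societal perspective: health-system cost plus
#' out-of-pocket expenditure (transport and wage loss over screening and
#' referral visits).
#'
#' @param perspective `"health_system"` or `"societal"`.
#' @param scenario A [treatment_scenario()].
#' @param screening_cost Program screening cost (INR), from
#'   [program_screening_cost()].
#' @param counts A `cascade_counts` object.
#' @param oope An [oope_profile()] (required for the societal perspective).
#' @param cohort A [cohort_spec()] (required for the societal perspective).
#' @return A list with `total` (INR) and a `decomposition` tibble.
#' @export
strategy_total_cost <- function(perspective = c("health_system", "societal"),
                                scenario, screening_cost, counts,
                                oope = NULL, cohort = NULL) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(scenario, "treatment_scenario"),
            inherits(counts, "cascade_counts"))
  treatment <- counts$confirmed_cases * scenario$cost_per_treated_child
  decomposition <- tibble::tibble(
    component = c("screening", "treatment"),
    cost = c(screening_cost, treatment)
  )
  if (perspective == "societal") {
    if (is.null(oope) || is.null(cohort)) {
      abort_invalid("societal perspective needs `oope` and `cohort`.")
    }
    oo <- expected_oope(cohort, counts, oope)
    decomposition <- dplyr::bind_rows(
      decomposition,
      tibble::tibble(component = "oope", cost = oo$total)
    )
  }
  list(total = sum(decomposition$cost), decomposition = decomposition)
}

#' Incremental cost-effectiveness ratio
#'
#' @param cost_a,cost_b Total cost of strategy A (intervention) and B
#'   (comparator), INR.
#' @param qaly_a,qaly_b Total QALYs of each strategy.
#' @param label_a,label_b Strategy labels for reporting.
#' @return An object of class `cea_result` with `delta_cost`, `delta_qaly`,
#'   `icer` and a `status` flag: `"icer"` when the ratio is informative,
#'   `"dominant"` when A is cheaper and more effective, `"dominated"` when A
#'   is costlier and less effective, `"cost_minimization"` when effects are
#'   equal, `"equivalent"` when both deltas are zero.
#' @examples
#' icer(10535915, 7256198, 6574000, 6574000 - 33.67)
#' @export
icer <- function(cost_a, cost_b, qaly_a, qaly_b,
                 label_a = "A", label_b = "B") {
  delta_cost <- cost_a - cost_b
  delta_qaly <- qaly_a - qaly_b
  status <- if (delta_qaly == 0 && delta_cost == 0) {
    "equivalent"
  } else if (delta_qaly == 0) {
    "cost_minimization"
  } else if (delta_cost <= 0 && delta_qaly > 0) {
    "dominant"
  } else if (delta_cost >= 0 && delta_qaly < 0) {
    "dominated"
  } else {
    "icer"
  }
  structure(
    list(label_a = label_a, label_b = label_b,
         cost_a = cost_a, cost_b = cost_b,
         qaly_a = qaly_a, qaly_b = qaly_b,
         delta_cost = delta_cost, delta_qaly = delta_qaly,
         icer = if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_,
         status = status),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  delta cost: %s INR, delta QALY: %s\n",
              format(round_half_up(x$delta_cost, 2), big.mark = ","),
              format(round_half_up(x$delta_qaly, 2))))
  if (x$status == "icer") {
    cat(sprintf("  ICER: %s INR/QALY\n",
                format(round_half_up(x$icer, 2), big.mark = ",")))
  } else {
    cat(sprintf("  status: %s\n", x$status))
  }
  invisible(x)
}

#' @rdname icer
#' @param x A `cea_result`.
#' @param ... Unused.
#' @export
tidy.cea_result <- function(x, ...) {
  tibble::tibble(
    strategy = c(x$label_a, x$label_b),
    cost = c(x$cost_a, x$cost_b),
    qaly = c(x$qaly_a, x$qaly_b)
  )
}

#' @rdname icer
#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    delta_cost = x$delta_cost,
    delta_qaly = x$delta_qaly,
    icer = x$icer,
    status = x$status
  )
}

#' Program cost per case detected
#'
#' @param total_screening_cost Program screening cost (INR).
#' @param confirmed_cases Number of confirmed (detected) cases; must be > 0.
#' @return Cost per detected case (INR/case).
#' @export
cost_per_case_detected <- function(total_screening_cost, confirmed_cases) {
  if (confirmed_cases <= 0) {
    abort_invalid("cost per case detected undefined with zero detected cases.")
  }
  total_screening_cost / confirmed_cases
}
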