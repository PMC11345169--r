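# Individual-level Monte-Carlo cohort simulator: the stochastic counterpart
# of the deterministic decision tree, used to validate its expectations and
# to generate OOPE microdata.

#' Configure a cohort simulation
#'
#' @param n_newborns Number of simulated newborns per replicate.
#' @param prevalence_per_1000 Hearing-loss prevalence per 1,000 births.
#' @param first_line [test_performance()] of the first-line screen.
#' @param confirmatory [test_performance()] of the confirmatory test
#'   (default [perfect_test()]).
#' @param seed Integer seed; a fixed seed makes every simulated cohort
#'   bitwise-reproducible. The global random state is left untouched.
#' @param n_replicates Number of independent replicates (default 1).
#' @param facility_mix Named fractions over facility levels, summing to 1;
#'   defaults to the equal mix of the default [oope_profile()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_newborns = 100000, prevalence_per_1000 = 5,
                              first_line = test_performance(1, 0.97),
                              confirmatory = perfect_test(),
                              seed = 1L, n_replicates = 1L,
                              facility_mix = NULL) {
  assert_number(n_newborns, "n_newborns", lower = 0)
  assert_number(prevalence_per_1000, "prevalence_per_1000", 0, 1000)
  assert_number(n_replicates, "n_replicates", lower = 1)
  stopifnot(inherits(first_line, "test_performance"),
            inherits(confirmatory, "test_performance"))
  if (is.null(facility_mix)) {
    facility_mix <- oope_profile()$facility_mix
  }
  if (any(facility_mix < 0) || abs(sum(facility_mix) - 1) > 1e-9) {
    abort_invalid("facility_mix must be nonnegative and sum to 1.")
  }
  structure(
    list(n_newborns = n_newborns, prevalence_per_1000 = prevalence_per_1000,
         first_line = first_line, confirmatory = confirmatory,
         seed = as.integer(seed), n_replicates = as.integer(n_replicates),
         facility_mix = facility_mix),
    class = "simulation_config"
  )
}

#' Simulate an individual-level birth cohort
#'
#' Draws the statistical structure the decision tree assumes: hearing-loss
#' status is Bernoulli at the stated prevalence; the screen refers a diseased
#' newborn with probability `sensitivity` and a normal-hearing newborn with
#' probability `1 - specificity`; the confirmatory test is applied only to
#' referred newborns, with its own accuracy, conditionally independent of the
#' screen given true status. Screen-passers are never confirmation-tested.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per infant: `id`, `hl_status` (logical),
#'   `screen_result` ("pass"/"refer"), `confirmation_result` ("confirmed",
#'   "not_confirmed", "not_tested"), `facility_level`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_newborns = 1000, seed = 7))
#' table(cohort$screen_result)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$prevalence_per_1000 / 1000
  withr::with_seed(config$seed, {
    n <- config$n_newborns
    hl <- stats::runif(n) < p
    p_refer <- ifelse(hl, config$first_line$sensitivity,
                      1 - config$first_line$specificity)
    refer <- stats::runif(n) < p_refer
    p_confirm <- ifelse(hl, config$confirmatory$sensitivity,
                        1 - config$confirmatory$specificity)
    confirm_draw <- stats::runif(n) < p_confirm
    facility <- sample(names(config$facility_mix), n, replace = TRUE,
                       prob = config$facility_mix)
    tibble::tibble(
      id = seq_len(n),
      hl_status = hl,
      screen_result = ifelse(refer, "refer", "pass"),
      confirmation_result = dplyr::case_when(
        !refer ~ "not_tested",
        confirm_draw ~ "confirmed",
        TRUE ~ "not_confirmed"
      ),
      facility_level = facility
    )
  })
}

#' Empirical test performance and cascade counts from a simulated cohort
#'
#' Cross-tabulates simulated truth against outcomes to recover the empirical
#' sensitivity, specificity, PPV and NPV, and assembles the empirical
#' four-branch counts in the same `cascade_counts` shape the deterministic
#' model produces, so the two can be compared directly.
#'
#' @param infants A tibble from [simulate_cohort()].
#' @return A list with `performance` (a [test_performance()]; undefined
#'   metrics are `NA` rather than errors, e.g. sensitivity with zero diseased
#'   infants) and `counts` (a `cascade_counts`).
#' @export
estimate_metrics <- function(infants) {
  if (nrow(infants) == 0) abort_invalid("empty cohort.")
  n <- nrow(infants)
  d <- sum(infants$hl_status)
  refer <- infants$screen_result == "refer"
  tp <- sum(infants$hl_status & refer)
  fn <- sum(infants$hl_status & !refer)
  fp <- sum(!infants$hl_status & refer)
  tn <- sum(!infants$hl_status & !refer)
  confirmed <- sum(infants$confirmation_result == "confirmed" &
                     infants$hl_status)
  referred <- sum(refer)
  perf <- structure(
    list(
      sensitivity = if (d > 0) tp / d else NA_real_,
      specificity = if (n - d > 0) tn / (n - d) else NA_real_,
      ppv = if (referred > 0) tp / referred else NA_real_,
      npv = if (n - referred > 0) tn / (tn + fn) else NA_real_
    ),
    class = "test_performance"
  )
  counts <- new_cascade_counts(list(
    mode = "empirical",
    cohort_size = n,
    diseased = d,
    screen_true_positive = tp,
    screen_false_negative = fn,
    screen_false_positive = fp,
    screen_true_negative = tn,
    referred = referred,
    confirmed_cases = confirmed,
    false_referrals = referred - confirmed,
    under_detected = fn + (tp - confirmed),
    confirmation_false_negative = tp - confirmed
  ))
  list(performance = perf, counts = counts)
}

#' Simulate out-of-pocket expenditure for a cohort
#'
#' Each screened infant accrues the transport cost of its facility level plus
#' the caregiver wage loss, per first-line visit; referred infants accrue the
#' same per additional confirmation visit. Costs are deterministic given the
#' facility level (no between-family dispersion is modeled).
#'
#' @param infants A tibble from [simulate_cohort()].
#' @param oope An [oope_profile()].
#' @return The input tibble with an `oope_incurred` column (INR) appended;
#'   `sum(out$oope_incurred)` is the cohort OOPE total.
#' @export
simulate_oope <- function(infants, oope) {
  stopifnot(inherits(oope, "oope_profile"))
  transport <- oope$transport_per_visit[infants$facility_level]
  per_visit <- unname(transport) + oope$wage_loss_per_visit
  visits <- oope$visits_per_screened +
    ifelse(infants$screen_result == "refer", oope$visits_per_referred, 0)
  dplyr::mutate(infants, oope_incurred = per_visit * visits)
}

#' Monte-Carlo validation of the deterministic cascade
#'
#' Runs `n_replicates` independent cohorts and compares the mean empirical
#' branch counts against the deterministic expectations from
#' [expected_cascade()], reporting each deviation in binomial standard-error
#' units.
#'
#' @param config A [simulation_config()]; replicate `r` uses seed
#'   `config$seed + r - 1`.
#' @return A tibble with one row per tracked count: `quantity`, `expected`,
#'   `mean_simulated`, `se` (standard error of the replicate mean, from the
#'   binomial variance of a single cohort), `z` (deviation in SE units).
#' @export
validate_cascade <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- cohort_spec(config$n_newborns, config$prevalence_per_1000)
  expected <- expected_cascade(cohort, config$first_line, config$confirmatory)
  reps <- purrr::map(seq_len(config$n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    est <- estimate_metrics(simulate_cohort(cfg))
    unlist(est$counts[c("screen_true_positive", "screen_false_negative",
                        "screen_false_positive", "screen_true_negative",
                        "referred", "confirmed_cases")])
  })
  sims <- do.call(rbind, reps)
  n <- config$n_newborns
  p <- config$prevalence_per_1000 / 1000
  sens <- config$first_line$sensitivity
  spec <- config$first_line$specificity
  # per-cohort binomial variance of each count, over the joint draw of
  # status and test outcome (marginal per-infant event probabilities)
  probs <- c(
    screen_true_positive = p * sens,
    screen_false_negative = p * (1 - sens),
    screen_false_positive = (1 - p) * (1 - spec),
    screen_true_negative = (1 - p) * spec,
    referred = p * sens + (1 - p) * (1 - spec),
    confirmed_cases = p * sens * config$confirmatory$sensitivity
  )
  exp_vals <- c(
    expected$screen_true_positive, expected$screen_false_negative,
    expected$screen_false_positive, expected$screen_true_negative,
    expected$referred, expected$confirmed_cases
  )
  se <- sqrt(n * probs * (1 - probs) / config$n_replicates)
  tibble::tibble(
    quantity = names(probs),
    expected = exp_vals,
    mean_simulated = colMeans(sims)[names(probs)],
    se = unname(se),
    z = ifelse(se > 0, (colMeans(sims)[names(probs)] - exp_vals) / se, 0)
  )
}

#' Write / read simulated cohorts as CSV
#'
#' @param infants A tibble from [simulate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort tibble.
#' @export
write_cohort <- function(infants, path) {
  readr::write_csv(infants, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(hl_status = readr::col_logical()))
}
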