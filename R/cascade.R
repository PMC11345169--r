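# Four-branch diagnostic decision tree: first-line screen -> confirmatory
# test on referrals; expected counts and program screening cost.

#' Specify a birth cohort
#'
#' @param size Number of newborns entering the model (default 100,000).
#' @param prevalence_per_1000 Congenital hearing-loss prevalence per 1,000
#'   births (default 5).
#' @param life_expectancy_years Life expectancy at birth, used for lifetime
#'   QALY accumulation (default 69.2).
#' @return A list of class `cohort_spec`; `$diseased` holds the expected
#'   number of hearing-impaired newborns.
#' @examples
#' cohort_spec()$diseased # 500
#' @export
cohort_spec <- function(size = 100000, prevalence_per_1000 = 5,
                        life_expectancy_years = 69.2) {
  assert_number(size, "size", lower = 0)
  assert_number(prevalence_per_1000, "prevalence_per_1000", 0, 1000)
  assert_number(life_expectancy_years, "life_expectancy_years", lower = 0)
  structure(
    list(
      size = size,
      prevalence_per_1000 = prevalence_per_1000,
      life_expectancy_years = life_expectancy_years,
      diseased = size * prevalence_per_1000 / 1000
    ),
    class = "cohort_spec"
  )
}

#' Diagnostic accuracy of a test
#'
#' @param sensitivity Probability the test refers a truly hearing-impaired
#'   newborn, in \[0, 1\].
#' @param specificity Probability the test passes a truly normal-hearing
#'   newborn, in \[0, 1\].
#' @param ppv,npv Optional observed positive/negative predictive values.
#' @return A list of class `test_performance`.
#' @export
test_performance <- function(sensitivity, specificity, ppv = NA_real_,
                             npv = NA_real_) {
  assert_fraction(sensitivity, "sensitivity")
  assert_fraction(specificity, "specificity")
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         ppv = ppv, npv = npv),
    class = "test_performance"
  )
}

#' Perfect gold-standard test
#' @return A [test_performance()] with sensitivity = specificity = 1.
#' @export
perfect_test <- function() test_performance(1, 1)

#' Choose how the cascade is parameterized
#'
#' `sens_spec` builds the self-consistent textbook tree from sensitivity and
#' specificity. `observed` instead takes referral and confirmed-case counts as
#' observed in the field (feasibility-study detection rates); this exists
#' because observed program counts are frequently *not* reproducible from the
#' same program's quoted sensitivity/specificity, and both views are useful.
#'
#' @param mode `"sens_spec"` or `"observed"`.
#' @param referred,confirmed Observed referral and confirmed-case counts
#'   (required in `observed` mode).
#' @param under_detected Observed count of hearing-impaired newborns missed by
#'   the cascade. Defaults to `max(diseased - referred, 0)` at evaluation time.
#' @return A list of class `cascade_mode`.
#' @export
cascade_mode <- function(mode = c("sens_spec", "observed"), referred = NULL,
                         confirmed = NULL, under_detected = NULL) {
  mode <- match.arg(mode)
  if (mode == "observed") {
    if (is.null(referred) || is.null(confirmed)) {
      abort_invalid("observed mode requires `referred` and `confirmed`.")
    }
    assert_number(referred, "referred", lower = 0)
    assert_number(confirmed, "confirmed", lower = 0)
    if (confirmed > referred) {
      abort_invalid("`confirmed` cannot exceed `referred`.")
    }
  }
  structure(
    list(mode = mode, referred = referred, confirmed = confirmed,
         under_detected = under_detected),
    class = "cascade_mode"
  )
}

new_cascade_counts <- function(fields) {
  structure(fields, class = "cascade_counts")
}

#' Expected counts through the screening cascade
#'
#' Propagates a cohort through a first-line screen and a confirmatory test.
#' The tree has four branches per device: A (screen true positive, confirmed),
#' B (screen false negative), C (screen false positive, referred but not
#' diseased), D (screen true negative). Screen-negative newborns are terminal:
#' they receive no further testing, cost, or chance of detection.
#'
#' In `sens_spec` mode all counts follow from prevalence, sensitivity and
#' specificity; the confirmatory test defaults to a perfect gold standard.
#' In `observed` mode, referral and confirmation counts are taken as given and
#' the remaining quantities are back-filled where the arithmetic allows:
#' `false_referrals = referred - confirmed` and
#' `confirmation_false_negative = diseased - confirmed - under_detected`
#' (referred hearing-impaired newborns not confirmed by the gold standard).
#' A back-fill that would go negative signals inconsistent inputs and errors.
#'
#' Counts are expectations, kept as real numbers so conservation identities
#' hold exactly; use [tidy()] for a per-branch table with a rounded view.
#'
#' @param cohort A [cohort_spec()].
#' @param first_line [test_performance()] of the first-line screen.
#' @param confirmatory [test_performance()] of the confirmatory test
#'   (default [perfect_test()]).
#' @param mode A [cascade_mode()] (default `sens_spec`).
#' @return An object of class `cascade_counts` with fields
#'   `screen_true_positive`, `screen_false_negative`, `screen_false_positive`,
#'   `screen_true_negative`, `referred`, `confirmed_cases`, `false_referrals`,
#'   `under_detected`, `confirmation_false_negative`, plus the cohort totals
#'   and the mode label.
#' @examples
#' cc <- expected_cascade(cohort_spec(), test_performance(1, 0.97))
#' cc$referred        # 3485
#' cc$confirmed_cases # 500
#' @export
expected_cascade <- function(cohort, first_line,
                             confirmatory = perfect_test(),
                             mode = cascade_mode("sens_spec")) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(mode, "cascade_mode"))
  n <- cohort$size
  d <- cohort$diseased

  if (mode$mode == "sens_spec") {
    stopifnot(inherits(first_line, "test_performance"))
    tp <- d * first_line$sensitivity
    fn <- d * (1 - first_line$sensitivity)
    fp <- (n - d) * (1 - first_line$specificity)
    tn <- (n - d) * first_line$specificity
    referred <- tp + fp
    confirmed <- tp * confirmatory$sensitivity
    conf_fn <- tp * (1 - confirmatory$sensitivity)
    false_ref <- referred - confirmed
    under <- fn + conf_fn
  } else {
    referred <- mode$referred
    confirmed <- mode$confirmed
    if (d == 0 && confirmed > 0) {
      abort_invalid("confirmed cases observed at zero prevalence.")
    }
    under <- mode$under_detected %||% max(d - referred, 0)
    assert_number(under, "under_detected", lower = 0)
    false_ref <- referred - confirmed
    conf_fn <- d - confirmed - under
    if (conf_fn < -1e-9) {
      abort_invalid(
        "observed counts inconsistent: confirmed + under_detected exceed the diseased cohort."
      )
    }
    conf_fn <- max(conf_fn, 0)
    # branch view: A carries confirmed cases, B the cascade misses; C is the
    # rest of the referral stream, D everyone untouched downstream
    tp <- confirmed
    fn <- under
    fp <- referred - confirmed
    tn <- n - referred - under
    if (tn < 0) abort_invalid("observed referrals exceed cohort size.")
  }

  new_cascade_counts(list(
    mode = mode$mode,
    cohort_size = n,
    diseased = d,
    screen_true_positive = tp,
    screen_false_negative = fn,
    screen_false_positive = fp,
    screen_true_negative = tn,
    referred = referred,
    confirmed_cases = confirmed,
    false_referrals = false_ref,
    under_detected = under,
    confirmation_false_negative = conf_fn
  ))
}

#' @export
print.cascade_counts <- function(x, ...) {
  cat(sprintf("<cascade_counts> mode=%s, N=%s, diseased=%s\n",
              x$mode, format(x$cohort_size, big.mark = ","), x$diseased))
  print(generics::tidy(x))
  invisible(x)
}

#' Tidy a cascade into a per-branch table
#'
#' @param x A `cascade_counts` object.
#' @param ... Unused.
#' @return A tibble with one row per branch (A-D) plus summary rows, with
#'   exact expected counts and a half-up-rounded reporting view.
#' @export
tidy.cascade_counts <- function(x, ...) {
  tbl <- tibble::tibble(
    branch = c("A", "B", "C", "D",
               "referred", "confirmed_cases", "false_referrals",
               "under_detected"),
    description = c(
      "screen positive, hearing loss", "screen negative, hearing loss",
      "screen positive, normal hearing", "screen negative, normal hearing",
      "referred to confirmation", "confirmed hearing loss",
      "referred, not confirmed", "hearing loss missed by cascade"
    ),
    expected = c(x$screen_true_positive, x$screen_false_negative,
                 x$screen_false_positive, x$screen_true_negative,
                 x$referred, x$confirmed_cases, x$false_referrals,
                 x$under_detected)
  )
  dplyr::mutate(tbl, reported = round_half_up(expected))
}

#' @export
as_tibble.cascade_counts <- function(x, ...) {
  tibble::as_tibble(x[setdiff(names(x), "mode")])
}

#' Predictive values of the referral stream
#'
#' PPV is the probability a referred newborn truly has hearing loss, taken at
#' the confirmation level (confirmed cases over referrals); NPV is the
#' probability a screen-negative newborn truly has normal hearing.
#'
#' @param counts A `cascade_counts` object.
#' @return A [test_performance()] with `ppv` and `npv` filled (sensitivity
#'   and specificity carried over as `NA` placeholders are not meaningful
#'   here, so the screen-level proportions are recomputed from counts).
#' @examples
#' cc <- expected_cascade(cohort_spec(),
#'   mode = cascade_mode("observed", referred = 500, confirmed = 262))
#' derived_ppv_npv(cc)$ppv # 0.524
#' @export
derived_ppv_npv <- function(counts) {
  stopifnot(inherits(counts, "cascade_counts"))
  if (counts$referred <= 0) abort_invalid("PPV undefined: nobody referred.")
  neg <- counts$screen_true_negative + counts$screen_false_negative
  if (neg <= 0) abort_invalid("NPV undefined: nobody screen-negative.")
  perf <- test_performance(
    sensitivity = if (counts$diseased > 0) {
      min(counts$screen_true_positive / counts$diseased, 1)
    } else NA_real_,
    specificity = if (counts$cohort_size - counts$diseased > 0) {
      min(counts$screen_true_negative /
            (counts$cohort_size - counts$diseased), 1)
    } else NA_real_
  )
  perf$ppv <- counts$confirmed_cases / counts$referred
  perf$npv <- counts$screen_true_negative / neg
  perf
}

#' Program-level screening cost
#'
#' Every newborn receives the first-line screen at its unrounded unit cost;
#' every referred newborn additionally receives the confirmatory test.
#' Branches A and C therefore carry screening plus confirmation cost; branches
#' B and D carry screening cost only.
#'
#' @param cohort A [cohort_spec()].
#' @param first_line_unit_cost Unrounded unit cost of the first-line screen
#'   (INR/screen).
#' @param confirmatory_unit_cost Unrounded unit cost of the confirmatory test.
#' @param counts A `cascade_counts` object.
#' @return A list with `total` (INR) and `branches`, a tibble decomposing the
#'   total over the four branches.
#' @export
program_screening_cost <- function(cohort, first_line_unit_cost,
                                   confirmatory_unit_cost, counts) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(counts, "cascade_counts"))
  n_branch <- c(A = counts$screen_true_positive,
                B = counts$screen_false_negative,
                C = counts$screen_false_positive,
                D = counts$screen_true_negative)
  per_head <- c(A = first_line_unit_cost + confirmatory_unit_cost,
                B = first_line_unit_cost,
                C = first_line_unit_cost + confirmatory_unit_cost,
                D = first_line_unit_cost)
  branches <- tibble::tibble(
    branch = names(n_branch),
    n = unname(n_branch),
    cost = unname(n_branch * per_head)
  )
  # total defined on the full cohort + referral stream; in observed mode the
  # branch counts need not span the whole cohort, so the closed form is used
  total <- cohort$size * first_line_unit_cost +
    counts$referred * confirmatory_unit_cost
  list(total = total, branches = branches)
}
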