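# Shared fixture builders. Everything is constructed in code; the only file
# fixtures are the bundled reference CSV/YAML under extdata.

ref_config <- function() reference_config()

paabr_inventory <- function() cost_inventory(421000, 104520, 0, 74736, 0, 2400)
bera_inventory <- function() {
  cost_inventory(1291000, 174720, 4000, 187107, 139354, 30000)
}

paabr_modality <- function() screening_modality("P-AABR", 15, paabr_inventory())
bera_modality <- function() screening_modality("BERA", 90, bera_inventory())

# minimal self-consistent two-strategy config in sens_spec mode, with plain
# round-number costs, for property tests that should not depend on the
# reference scenario
toy_config <- function(prevalence = 5, sens_a = 0.9, spec_a = 0.95,
                       sens_b = 0.6, spec_b = 0.7, treatment_cost = 100000) {
  inv <- function(total) cost_inventory(human_resource = total)
  run_config(
    cohort = cohort_spec(10000, prevalence, 60),
    modalities = list(
      A = screening_modality("A", 15, inv(62400)),   # unit cost 10
      B = screening_modality("B", 10, inv(46800)),   # unit cost 5
      CONF = screening_modality("CONF", 90, inv(104000)) # unit cost 100
    ),
    performances = list(
      A = test_performance(sens_a, spec_a),
      B = test_performance(sens_b, spec_b),
      CONF = perfect_test()
    ),
    confirmatory = "CONF",
    strategies = c("A", "B"),
    cascade_modes = list(A = cascade_mode("sens_spec"),
                         B = cascade_mode("sens_spec")),
    utilities = utility_weights(),
    scenarios = list(
      treatment_scenario("hearing_aid", cost_per_treated_child = treatment_cost)
    ),
    oope = oope_profile(wage_loss_per_visit = 100)
  )
}
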