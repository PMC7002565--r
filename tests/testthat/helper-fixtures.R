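# Shared fixtures and cached expensive runs for the test suite.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# 10-trial verification sweep over the bundled cohorts (used by several
# acceptance blocks); computed once per session
verify_10 <- function() cached("verify10", verify_cohorts(n_trials = 10,
                                                          seed = 1))

# minimal synthetic simulation_result for NCA unit tests
fake_result <- function(times, plasma) {
  structure(list(times = times, plasma = plasma), class = "simulation_result")
}

# a variability-free imatinib-like drug without MBI or compensatory
# clearance, for linearity and cancellation tests
drug_no_mbi <- function() {
  d <- builtin_imatinib()
  d$mbi <- NULL
  d$additional_hlm_clint <- 0
  d
}

# neutral reference modulator: no induction, no inhibition
null_modulator <- function() {
  perpetrator_model(
    modulator_parameters("null_mod", fu_plasma = 1),
    perpetrator_exposure("constant_css", css = 10, fu_perpetrator = 1))
}

typical_400 <- function(duration = 96, mbi = "auto", comp = FALSE,
                        dose = 400) {
  st <- simulation_settings(duration = duration, output_dt = 0.1,
                            mbi = mbi, steady_state_compensation = comp)
  simulate_pbpk(build_model(builtin_imatinib(), reference_adult(),
                            settings = st),
                list(dose_event(0, dose, "oral")))
}
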