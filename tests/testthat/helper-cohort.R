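# Shared cohorts, generated once per test run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, cfg) {
  if (is.null(.cohort_cache[[key]]))
    assign(key, generate_cohort(cfg), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# Cohort at the published study conditions (rates as calibrated).
default_cohort <- function(n = 20000)
  cached_cohort(paste0("default", n),
                generator_config(n_participants = n, seed = 42))

# Event- and uptake-enriched configuration used for recovery experiments:
# the published rates leave too few treated events per cohort for any
# estimator to be evaluated, so recovery runs raise the event rate, the
# return-visit probability and the uptake probability while keeping the
# confounded-uptake structure intact.
enriched_config <- function(n = 20000, seed = 1, scenario = "I",
                            true_rr = 0.8, ...) {
  generator_config(n_participants = n, seed = seed, scenario = scenario,
                   true_rr = true_rr, cvd_risk_5y = 0.12,
                   followup_prob_base = 0.6, uptake_prob = 0.4, ...)
}

enriched_cohort <- function(n = 20000, seed = 1, scenario = "I",
                            true_rr = 0.8) {
  cached_cohort(sprintf("enriched_%d_%d_%s_%g", n, seed, scenario, true_rr),
                enriched_config(n, seed, scenario, true_rr))
}

# A hand-checkable two-stratum treatment table: within L = 0, 40 of 100 are
# treated; within L = 1, 80 of 100.
two_stratum_data <- function() {
  L <- rep(c(0, 1), each = 100)
  A <- c(rep(c(1, 0), c(40, 60)), rep(c(1, 0), c(80, 20)))
  data.frame(id = seq_along(L), L = L, A = A)
}
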