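# Desk-scale study cohorts (32 agents x 24 trials per scheme per task),
# computed once and shared by the acceptance tests. The master seeds are
# fixed so the whole suite is deterministic.

.cohort_cache <- new.env(parent = emptyenv())

study_cohorts <- function() {
  if (!exists("res", envir = .cohort_cache)) {
    res <- list(
      tmaze_ai = run_cohort("tmaze", "active_inference", n_agents = 32L,
                            n_trials = 24L, master_seed = 101L),
      tmaze_ng = run_cohort("tmaze", "natural_gradient", n_agents = 32L,
                            n_trials = 24L, master_seed = 101L),
      rule_ai = run_cohort("rule", "active_inference", n_agents = 32L,
                           n_trials = 24L, master_seed = 102L),
      rule_ng = run_cohort("rule", "natural_gradient", n_agents = 32L,
                           n_trials = 24L, master_seed = 102L))
    assign("res", res, envir = .cohort_cache)
  }
  get("res", envir = .cohort_cache)
}
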