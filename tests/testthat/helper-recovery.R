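# The three-cluster recovery study shared by the end-to-end tests:
# n = 300 respondents, three equally weighted clusters with well-separated
# profiles (gamma = 0.05) over the default item block, analysed with the
# reduced-scale protocol (burn-in 50, thinning 5, S = 200, two chains).
# Computed once per test run and memoized.

.recovery_cache <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (!exists("fit", envir = .recovery_cache)) {
    gen <- generator_config(n = 300L, scheme = "weights", weights = c(1, 1, 1),
                            separation = 0.05, seed = 101L)
    survey <- generate_survey(gen)
    cfg <- sampler_config(alpha = 1, beta = 1, burn_in = 50L, thinning = 5L,
                          n_samples = 200L, n_chains = 2L, seed = 202L)
    report <- run_analysis(survey$dataset, cfg)
    assign("fit", list(survey = survey, report = report),
           envir = .recovery_cache)
  }
  get("fit", envir = .recovery_cache)
}
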