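# Reference parameter set used throughout the tests: produces a mixture of
# fast reflexive errors and slower correct antisaccades.
reference_params <- function() {
  race_params(v_pre = 8, v_inhib = 4, v_exec = 6, a_mean = 1.5,
              t = 0.2, t_exec = 0.1)
}

# A behaviourally realistic setting (control-like accuracy ~ 0.7).
control_params <- function() {
  race_params(v_pre = 6.5, v_inhib = 8, v_exec = 7, a_mean = 1.2,
              t = 0.15, t_exec = 0.08)
}

# Fast fitting profile for tests: reduced simulation count and search effort.
test_fit_config <- function(seed = 1, ...) {
  fit_config(n_sims = 2000, n_hops = 2, maxit = 400, restarts = 2,
             seed = seed, ...)
}

# Small synthetic cohort for pipeline-level tests.
test_cohort_spec <- function(n_per_stage = c(6, 3, 3, 3, 3),
                             n_pro = 40, n_anti = 40) {
  default_cohort_spec(n_per_stage = n_per_stage, n_pro = n_pro,
                      n_anti = n_anti)
}
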