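# Small fixtures shared across test files; everything is built in code.

# a compact config: fewer participants, no deaths, deterministic seed
small_config <- function(seed = 11,
                         n_per_arm = c(intervention = 30, control = 30),
                         ...) {
  cohort_config(n_per_arm = n_per_arm,
                death_prob = c(intervention = 0, control = 0),
                seed = seed, ...)
}

# analysis table for a complete (attrition-free) small cohort
small_complete_table <- function(seed = 11) {
  analysis_table(generate_cohort(small_config(seed)))
}

# three-assessment trajectory shorthand
traj <- function(u0, u10, u20) list(weeks = c(0, 10, 20),
                                    utilities = c(u0, u10, u20))

# count models with every rate zero (silences resource generation)
silent_count_models <- function() {
  cm <- default_count_models()
  cm$rate_intervention <- 0
  cm$rate_control <- 0
  cm$zero_intervention[cm$family == "zero_inflated_poisson"] <- 1
  cm$zero_control[cm$family == "zero_inflated_poisson"] <- 1
  cm
}
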