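# shared fixtures built in code

# producer parameters on the tabulated (unscaled) rate scale
table_producer <- function(...) {
  producer_base_params(rate_scale = 1, ...)
}

# a population with given genotypes and exact (noise-free) phenotypes
noise_free_pop <- function(G, params, birth = 0) {
  params$noise_cv <- 0
  new_population(G, params, birth = birth, parent_birth = NA_real_)
}

# a small two-level community configuration (noise and mutation off unless
# stated); producer rates on the calibrated scale so dynamics are lively
micro_config <- function(n1 = 12, n2 = 6, noise_cv = 0, mutation_prob = 0) {
  p1 <- producer_base_params(noise_cv = noise_cv)
  p2 <- derive_level_params(p1, 2, noise_cv = noise_cv)
  community_config(list(p1, p2), init_sizes = c(n1, n2),
                   resource = list(R_max = 50, r = 1, graze_scale = 1),
                   mutation = list(prob = mutation_prob, sd = 0.05))
}

# default 4-level baseline plan (no evolution) at a reduced phase scale
baseline_plan <- function(...) {
  experiment_plan(scenario = "baseline", evolve = integer(0), ...)
}
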