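# shared fixtures built in code

# a small cached noise-free experiment for identity checks
zero_noise_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(noise_free_params(), seed = 11)
    cache
  }
})

# factorial data with an injected substrate effect and iid residual noise
factorial_data <- function(seed, substrate_effect = 0, sd = 1) {
  set.seed(seed)
  d <- design_grid()
  d$y <- 10 + substrate_effect * (d$substrate == "high_forage") +
    rnorm(nrow(d), 0, sd)
  d
}

# forward simulate a metabolite lineage with known per-transfer production
forward_concs <- function(production, inoculum_conc, v, vt = 40) {
  conc <- numeric(length(production))
  donor <- inoculum_conc
  for (t in seq_along(production)) {
    conc[t] <- (donor * v + production[t]) / vt
    donor <- conc[t]
  }
  conc
}
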