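# Shared fixtures: everything is generated in code at test time.

# Short-chain MCMC settings for replicate-heavy checks; posterior summaries at
# 1500 kept draws carry ~0.013 Monte-Carlo s.e. on an exceedance probability,
# adequate for banded assertions.
fast_fit <- function(x, graph, seed = 1L, ...) {
  fit_bym(x, graph, n_iter = 1500, n_burnin = 600, n_chains = 1,
          seed = seed, ...)
}

halland_sized_graph <- function() grid_geography(6, 11)$graph

# Two unit squares sharing an edge / a corner / nothing.
square <- function(x0, y0) {
  cbind(x = x0 + c(0, 1, 1, 0), y = y0 + c(0, 0, 1, 1))
}

# Hand-built area table: one area, two sexes.
tiny_table <- function() {
  data.frame(area_id = "a", sex = c("M", "F"),
             n_examined = c(100, 100), n_cases = c(10, 20),
             stringsAsFactors = FALSE)
}

# A flat (true RR = 1) single-wave simulated table.
flat_wave <- function(graph, seed, mean_children = 150) {
  cfg <- sim_config(mean_children_per_area = mean_children,
                    sigma_u = 0, sigma_v = 0, seed = seed)
  surf <- simulate_risk_surface(graph, 0, 0, seed = seed)
  simulate_cases(simulate_population(graph, cfg, wave = 1), surf, cfg, wave = 1)
}

# Build a certainty_map directly from given probabilities/smrrs (no MCMC).
manual_map <- function(ids, pr, smrr = rep(1, length(ids)), wave = "w") {
  build_certainty_map(data.frame(area_id = ids, pr_exceed = pr, smrr = smrr,
                                 stringsAsFactors = FALSE),
                      wave_label = wave)
}
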