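# Shared fixtures. Heavy simulations are computed once per test run and
# cached in this environment so several test files can reuse them.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# a tiny two-neuron circuit (1 STN -> 1 GPe, 1 GPe -> 1 STN) with all
# stochastic inputs silenced
tiny_circuit <- function(seed = 2) {
  cfg <- network_config(n_stn = 2, n_gpe = 2, gpe_stn_indegree = 1,
                        stn_gpe_indegree = 1, g_ampa_gpe_int = 0,
                        g_ampa_ctx_stn = 0, ctx_rate_hz = 0,
                        gpe_int_rate_hz = 0)
  build_network(cfg, seed = seed)
}

# reference state-point runs shared between the acceptance tests: two
# replicates of the published eight, at the default epoch
state_runs <- function() {
  cached("state_runs", {
    list(normal = run_state_point(normal_state(), n_replicates = 2,
                                  seed = 11),
         park = run_state_point(parkinsonian_state(), n_replicates = 2,
                                seed = 11, keep_spikes = TRUE))
  })
}

summary_of <- function(run, pop) {
  s <- run$summary
  s[s$population == pop, ]
}
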