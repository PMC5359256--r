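# The clock-driven engine: Poisson drives, delayed delivery, stimulation
# protocols, determinism.

test_that("Poisson train counts match their rate", {
  expect_length(poisson_train(0, 1000, seed = 1), 0)
  n <- length(poisson_train(100, 100000, seed = 2))
  expect_lt(abs(n - 1e4), 4 * sqrt(1e4))
})

test_that("a step rate profile produces matching rates before and after the step", {
  prof <- stimulus_profile(breaks_ms = 5000, rates_hz = c(100, 1000))
  tr <- poisson_train(prof, 10000, seed = 3)
  n1 <- sum(tr < 5000); n2 <- sum(tr >= 5000)
  expect_lt(abs(n1 - 500), 4 * sqrt(500))
  expect_lt(abs(n2 - 5000), 4 * sqrt(5000))
  expect_equal(profile_rate(prof, c(0, 4999, 5000, 9000)),
               c(100, 100, 1000, 1000))
})

test_that("synaptic events arrive exactly one conduction delay after the spike", {
  net <- tiny_circuit()
  sim <- simulation_config(duration_ms = 120, warmup_ms = 10,
                           record_gpe = 1:2, seed = 5, trace_fs_hz = 4000)
  res <- simulate_network(net, sim)
  stn1 <- res$spikes$time_ms[res$spikes$population == "STN" &
                               res$spikes$neuron == 1]
  first <- min(stn1)   # the STN model fires autonomously
  g <- res$traces$gpe[[as.character(net$stn_to_gpe$target[
    net$stn_to_gpe$source == 1][1])]]$g_ampa
  tm <- (seq_along(g) - 1) * 0.25
  onset <- tm[which(g > 1e-12)[1]]
  expect_lt(abs(onset - (first + 5)), 0.25 + 1e-9)
  # the isolated first kernel reaches the configured amplitude at its peak
  second <- sort(stn1)[2]
  seg <- g[tm >= first + 5 & tm < min(second + 5, first + 25, na.rm = TRUE)]
  expect_equal(max(seg), net$config$g_ampa_stn_gpe, tolerance = 1e-3)
})

test_that("identical configuration and seeds give bitwise-identical rasters", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 21)
  sim <- simulation_config(duration_ms = 1500, warmup_ms = 100, seed = 22)
  a <- simulate_network(net, sim)
  b <- simulate_network(net, sim)
  expect_identical(a$spikes, b$spikes)
})

test_that("seed streams are independent: the graph ignores simulation seeds", {
  net1 <- build_network(network_config(), seed = 31)
  sim_a <- simulation_config(duration_ms = 1200, warmup_ms = 100, seed = 1)
  sim_b <- simulation_config(duration_ms = 1200, warmup_ms = 100, seed = 2)
  a <- simulate_network(net1, sim_a)
  b <- simulate_network(net1, sim_b)
  expect_identical(a$network$gpe_to_stn, b$network$gpe_to_stn)
  expect_false(identical(a$spikes, b$spikes))
})

test_that("with no drive of any kind the GPe population is silent", {
  cfg <- network_config(g_ampa_gpe_int = 0, g_ampa_ctx_stn = 0,
                        ctx_rate_hz = 0, gpe_int_rate_hz = 0,
                        g_ampa_stn_gpe = 0, g_gaba_gpe_stn = 0)
  net <- build_network(cfg, seed = 41)
  res <- simulate_network(net, simulation_config(duration_ms = 1000,
                                                 warmup_ms = 100, seed = 42))
  expect_equal(sum(res$spikes$population == "GPe"), 0)
})

test_that("PT stimulation configures a step window and rejects conflicts", {
  sim <- simulation_config(duration_ms = 5000, warmup_ms = 500)
  sim2 <- apply_pt_stimulation(sim, 2000, 1000, 1000)
  expect_equal(profile_rate(sim2$ctx_profile, c(1999, 2000, 2999, 3000)),
               c(100, 1000, 1000, 100))
  expect_error(apply_pt_stimulation(sim2, 2500, 500, 250), "already")
  expect_error(apply_pt_stimulation(sim, 4500, 1000, 1000), "fit inside")
  # stimulation at the baseline rate is the identity protocol
  net <- build_network(network_config(), seed = 51)
  base <- simulation_config(duration_ms = 1500, warmup_ms = 100, seed = 52)
  null_pt <- apply_pt_stimulation(
    simulation_config(duration_ms = 1500, warmup_ms = 100, seed = 52),
    500, 500, 100)
  expect_identical(simulate_network(net, base)$spikes,
                   simulate_network(net, null_pt)$spikes)
})

test_that("feedback lines with zero transmission never alter conductances", {
  net <- tiny_circuit()
  fb <- build_feedback_loop(2, n_afferent = 1, p_transmit = 0,
                            delay_ms = 20, gmax = 1, seed = 3)
  fb$source <- 1; fb$target <- 2; fb <- fb[1, ]
  attr(fb, "p_transmit") <- 0
  sim <- simulation_config(duration_ms = 80, warmup_ms = 10,
                           record_stn = 2, seed = 6, trace_fs_hz = 4000)
  res <- simulate_network(net, sim, feedback = fb,
                          forced_stn_spikes = list(c(20), numeric()))
  expect_true(all(res$traces$stn[["2"]]$g_ampa == 0))
  # and with certain transmission the increment lands at exactly t + delay
  attr(fb, "p_transmit") <- 1
  res2 <- simulate_network(net, sim, feedback = fb,
                           forced_stn_spikes = list(c(20), numeric()))
  g <- res2$traces$stn[["2"]]$g_ampa
  tm <- (seq_along(g) - 1) * 0.25
  stn1 <- res2$spikes$time_ms[res2$spikes$population == "STN" &
                                res2$spikes$neuron == 1]
  expected_onsets <- sort(stn1 + 20)
  onset <- tm[which(g > 1e-12)[1]]
  expect_lt(abs(onset - expected_onsets[1]), 0.25 + 1e-9)
})

test_that("population rates are robust to halving the integration step", {
  cfg <- stngpe:::apply_state_point(network_config(), parkinsonian_state())
  net <- build_network(cfg, seed = 61)
  rates <- lapply(c(0.025, 0.0125), function(dt) {
    sim <- simulation_config(dt = dt, duration_ms = 9000, warmup_ms = 1000,
                             seed = 62)
    res <- simulate_network(net, sim)
    sp <- res$spikes[res$spikes$time_ms >= 1000, ]
    c(stn = sum(sp$population == "STN") / 64 / 8,
      gpe = sum(sp$population == "GPe") / 192 / 8)
  })
  expect_lt(abs(rates[[1]]["stn"] - rates[[2]]["stn"]) / rates[[2]]["stn"],
            0.02)
  expect_lt(abs(rates[[1]]["gpe"] - rates[[2]]["gpe"]) / rates[[2]]["gpe"],
            0.05)
})

test_that("rasters round-trip through the TSV interchange format", {
  net <- build_network(network_config(), seed = 71)
  res <- simulate_network(net, simulation_config(duration_ms = 800,
                                                 warmup_ms = 100, seed = 72))
  path <- tempfile(fileext = ".tsv")
  write_raster_tsv(res, path)
  back <- read_raster_tsv(path)
  expect_equal(back$time_ms, res$spikes$time_ms)
  expect_equal(back$population, res$spikes$population)
  unlink(path)
})
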