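# Synaptic kernels, short-term depression with stochastic multi-contact
# release, and the facilitation x depression model.

test_that("alpha kernel has its maximum g/e at t = tau (printed form)", {
  expect_equal(alpha_kernel(0, tau = 1, gmax = 2, normalize = FALSE), 0)
  expect_equal(alpha_kernel(1, tau = 1, gmax = 2, normalize = FALSE),
               2 * exp(-1))
  # normalised form peaks at gmax
  expect_equal(alpha_kernel(1, tau = 1, gmax = 2, normalize = TRUE), 2)
  grid <- seq(0, 10, by = 1e-3)
  expect_equal(max(alpha_kernel(grid, tau = 1, gmax = 2, normalize = FALSE)),
               2 * exp(-1), tolerance = 1e-6)
  expect_error(alpha_kernel(-1), "t >= 0")
})

test_that("beta kernel peaks at the closed-form time and decays to nothing", {
  tr <- 0.380; td <- 7.7
  expect_equal(beta_kernel(0, tr, td), 0)
  tpk <- beta_peak_time(tr, td)
  expect_equal(tpk, tr * td / (td - tr) * log(td / tr))
  grid <- seq(0, 40, by = 1e-3)
  v <- beta_kernel(grid, tr, td, gmax = 3, normalize = FALSE)
  expect_equal(grid[which.max(v)], tpk, tolerance = 1e-2)
  # normalised kernel reaches gmax at the peak
  expect_equal(beta_kernel(tpk, tr, td, gmax = 3, normalize = TRUE), 3)
  expect_lt(beta_kernel(10 * td, tr, td, gmax = 1, normalize = FALSE), 1e-3)
  expect_error(beta_kernel(1, 5, 5), "tau_rise < tau_decay")
})

test_that("superposed kernels equal direct summation of shifted kernels", {
  times <- seq(0, 30, by = 0.01)
  direct <- alpha_kernel(times, 1, 1) +
    ifelse(times >= 1, alpha_kernel(pmax(times - 1, 0), 1, 1), 0)
  via_fun <- conductance_from_spikes(c(0, 1), times, kernel = "alpha",
                                     tau = 1)
  expect_equal(via_fun, direct, tolerance = 1e-12)
})

test_that("the state-space kernel realisation equals brute-force summation", {
  tr <- gpe_intrinsic_conductance(rate_hz = 200, gmax = 1.125,
                                  duration_ms = 2000, dt = 0.5, seed = 7)
  ev <- attr(tr, "events")
  direct <- conductance_from_spikes(ev, tr$time_ms, kernel = "beta",
                                    tau_rise = 5, tau_decay = 12.4,
                                    gmax = 1.125)
  expect_lt(max(abs(tr$g - direct)), 1e-9 * 1.125)
})

test_that("intrinsic conductance time-average obeys Campbell's theorem", {
  gmax <- 1.125; rate <- 100
  tr <- gpe_intrinsic_conductance(rate, gmax, duration_ms = 60000,
                                  dt = 0.5, seed = 3)
  peak <- beta_kernel(beta_peak_time(5, 12.4), 5, 12.4, 1, normalize = FALSE)
  expected_mean <- rate / 1000 * gmax / peak * (12.4 - 5)
  expect_lt(abs(mean(tr$g) - expected_mean) / expected_mean, 0.05)
  # halving gmax and doubling the rate preserves the mean, reduces variance
  tr2 <- gpe_intrinsic_conductance(2 * rate, gmax / 2, duration_ms = 60000,
                                   dt = 0.5, seed = 4)
  expect_lt(abs(mean(tr2$g) - expected_mean) / expected_mean, 0.05)
  expect_lt(var(tr2$g), var(tr$g))
  # degenerate cases
  expect_true(all(gpe_intrinsic_conductance(0, 1, 100, seed = 1)$g == 0))
  expect_true(all(gpe_intrinsic_conductance(100, 0, 100, seed = 1)$g == 0))
})

test_that("depression recovery follows the exact exponential toward 1", {
  st <- depression_state(p = 1)
  expect_equal(depression_decay(st, 500)$p, 1)
  st <- depression_state(p = 0.5, tau_d = 100)
  expect_equal(depression_decay(st, 100)$p, 1 - 0.5 * exp(-1))
  # long waits recover fully
  expect_equal(depression_decay(st, 1e7)$p, 1)
})

test_that("the spike decrement respects its closed forms and bounds", {
  st <- depression_state(p = 1, f_d = 0.6, p_bound = 0.05, n_bound = 1.3)
  expect_equal(depression_on_spike(st)$p, 0.6)
  at_bound <- depression_state(p = 0.05, f_d = 0.6, p_bound = 0.05,
                               n_bound = 1.3)
  expect_equal(depression_on_spike(at_bound)$p, 0.05)
  # stays within [p_bound, 1] over random event sequences
  set.seed(8)
  st <- depression_state()
  for (i in 1:300) {
    st <- if (runif(1) < 0.5) depression_on_spike(st) else
      depression_decay(st, rexp(1, 1 / 50))
    expect_gte(st$p, st$p_bound)
    expect_lte(st$p, 1)
  }
})

test_that("periodic-drive steady state equals the decay-spike fixed point", {
  st <- depression_state(tau_d = 1000, f_d = 0.7, p_bound = 0.1,
                         n_bound = 1)
  tr <- depression_train(seq(0, 60000, by = 100), st)  # 10 Hz
  simulated <- tail(tr$p_before, 1)
  # independent fixed-point iteration of decay(on_spike(P))
  p <- 1
  for (i in 1:5000) {
    frac <- max((p - 0.1) / 0.9, 0)
    p_post <- p * (1 + (0.7 - 1) * frac)
    p <- 1 - (1 - p_post) * exp(-100 / 1000)
  }
  expect_equal(simulated, p, tolerance = 1e-6)
})

test_that("per-contact release reproduces the projection-level probability", {
  expect_equal(contact_release(depression_state(p = 0.5), 1)$mu, 0.5)
  st0 <- depression_state(p = 0.01)
  st0$p <- 0  # force the degenerate case
  r <- contact_release(st0, 10)
  expect_equal(r$mu, 0)
  expect_identical(r$successes, 0L)
  st <- depression_state(p = 0.64)
  expect_equal(contact_release(st, 2)$mu, 0.4)
  set.seed(11)
  succ <- rbinom(1e5, 2, 0.4)
  p_hat <- mean(succ >= 1)
  se <- sqrt(0.64 * 0.36 / 1e5)
  expect_lt(abs(p_hat - 0.64), 3 * se)
  expect_error(contact_release(st, 0), "n_contact")
})

test_that("facilitation saturates at its bound and first-spike amplitude is 1", {
  st <- facdep_state(type = 1, f_bound = 2)
  st$f <- 2
  up <- facdep_on_spike(st)
  expect_equal(up$state$f, 2)
  st <- facdep_state(type = 1, f_bound = 2)
  up <- facdep_on_spike(st)
  expect_equal(up$amplitude, 1)
  expect_equal(up$state$f, 1 + (1.4 - 1) * (2 - 1) / 2)
  expect_equal(up$state$d, 0.9)
})

test_that("paired-pulse ratio of the depression-dominant type matches hand iteration", {
  # type 3: f_F = 1.64, f_D = 0.55, tau_F = 148, tau_D = 764; 20 Hz spacing
  fb <- 2
  tr <- facdep_train(c(0, 50), facdep_state(type = 3, f_bound = fb))
  # hand computation
  a1 <- 1
  f1 <- 1 * (1 + 0.64 * (fb - 1) / fb); d1 <- 0.55
  f_dec <- 1 + (f1 - 1) * exp(-50 / 148)
  d_dec <- 1 + (d1 - 1) * exp(-50 / 764)
  a2 <- f_dec * d_dec
  expect_equal(tr$amplitude, c(a1, a2))
  # invariant bounds over a random train
  set.seed(12)
  tr2 <- facdep_train(cumsum(rexp(300, 1 / 30)), facdep_state(type = 2))
  expect_true(all(tr2$f >= 1 & tr2$f <= 2))
  expect_true(all(tr2$d > 0 & tr2$d <= 1))
  expect_true(all(tr2$amplitude > 0))
})

test_that("depression calibration recovers a known parameter set", {
  true <- list(tau_d = 1000, f_d = 0.6, p_bound = 0.2, n_bound = 1)
  st <- depression_state(tau_d = true$tau_d, f_d = true$f_d,
                         p_bound = true$p_bound, n_bound = true$n_bound)
  freqs <- c(1, 10, 20, 33, 100)
  ss <- vapply(freqs, function(f)
    tail(simulate_depression_protocol(f, 10, st)$during$p, 1), numeric(1))
  rec_t <- c(0.5, 1, 2, 5, 10)
  rec <- simulate_depression_protocol(100, 10, st, recovery_s = rec_t)$recovery$p
  targets <- rbind(
    data.frame(protocol = "steady_state", freq_hz = freqs, time_s = NA,
               value = ss),
    data.frame(protocol = "recovery", freq_hz = 100, time_s = rec_t,
               value = rec))
  fit <- calibrate_depression_params(
    targets, init = list(tau_d = 1500, f_d = 0.5, p_bound = 0.15,
                         n_bound = 1.4), maxit = 600)
  for (nm in names(true))
    expect_lt(abs(fit$params[[nm]] - true[[nm]]) / true[[nm]], 0.05)
})

test_that("low-frequency stimulation depresses less than high-frequency", {
  st <- depression_state()
  p1 <- tail(simulate_depression_protocol(1, 10, st)$during$p, 1)
  p100 <- tail(simulate_depression_protocol(100, 10, st)$during$p, 1)
  expect_gt(p1, p100)
  expect_lt(p1, 1)  # even 1 Hz shows mild steady-state depression
})
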