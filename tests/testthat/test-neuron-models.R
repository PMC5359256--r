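# Membrane dynamics of the STN (conductance-based) and GPe (LIF) model
# neurons.

test_that("a constructed leak/ionic equilibrium is stationary to machine precision", {
  # The cell is spontaneously active under its default leak reversal, so a
  # quiescent fixed point is built by construction: hold V*, put every
  # gate at its steady state, bring calcium to its current-driven
  # equilibrium, then solve the leak reversal that balances the ionic sum.
  p <- stn_params()
  v_star <- -65
  ca <- 0.005
  for (it in 1:200) {
    st <- stn_steady_state(v_star, ca, p)
    cur <- stngpe:::stn_currents(st, p)
    ca_new <- max(-p$alpha_ca * (cur$i_lca + cur$i_t) / p$k_ca, 0)
    if (abs(ca_new - ca) < 1e-14) break
    ca <- ca_new
  }
  st <- stn_steady_state(v_star, ca, p)
  cur <- stngpe:::stn_currents(st, p)
  ionic_other <- cur$i_na + cur$i_k + cur$i_a + cur$i_lca + cur$i_t +
    cur$i_cak
  p$v_leak <- v_star + ionic_other / p$g_leak
  d <- stn_derivatives(st, params = p)
  expect_lt(abs(d$v), 1e-10)
  expect_true(all(abs(unlist(d)[stn_kinetics()$gates]) < 1e-12))
  expect_lt(abs(d$ca), 1e-10)
  # one integration step barely moves the state
  step <- advance_stn(st, dt = 0.025, params = p)
  expect_lt(abs(step$state$v - st$v), 1e-8)
  expect_false(step$spike)
})

test_that("GABAergic conductance hyperpolarises whenever V is above its reversal", {
  p <- stn_params()
  st <- stn_steady_state(-60, 0.005, p)
  d0 <- stn_derivatives(st, g_gaba = 0, params = p)
  d1 <- stn_derivatives(st, g_gaba = 20, params = p)
  expect_lt(d1$v, d0$v)
  # and depolarises when held below the reversal
  st2 <- stn_steady_state(-90, 0.005, p)
  expect_gt(stn_derivatives(st2, g_gaba = 20, params = p)$v,
            stn_derivatives(st2, g_gaba = 0, params = p)$v)
})

test_that("non-finite state values raise an integration-failure error", {
  st <- stn_steady_state(-60)
  st$v <- NaN
  expect_error(stn_derivatives(st), "non-finite")
})

test_that("the fixed-step integrator matches an adaptive reference integration", {
  p <- stn_params()
  st0 <- stn_steady_state(-60, 0.005, p)
  nm <- names(st0)
  rhs <- function(t, y, parms) {
    st <- as.list(y)
    names(st) <- nm
    list(unlist(stn_derivatives(st, params = p)))
  }
  times <- seq(0, 2000, by = 0.05)
  ref <- deSolve::lsoda(unlist(st0), times, rhs, NULL,
                        rtol = 1e-8, atol = 1e-8)
  v <- ref[, "v"]
  up <- which(v[-1] >= -10 & v[-length(v)] < -10)
  # drop crossings within 1 ms of the previous one (same spike)
  tt <- times[up]
  ref_spikes <- tt[c(TRUE, diff(tt) > 1)]
  tr <- stn_trajectory(2000, dt = 0.025, record = FALSE, params = p)
  rate <- attr(tr, "rate_hz")
  ref_rate <- length(ref_spikes) / 2
  expect_lt(abs(rate - ref_rate) / ref_rate, 0.01)
})

test_that("STN spiking converges as the step size is halved (Cauchy criterion)", {
  sp <- lapply(c(0.025, 0.0125, 0.00625), function(dt)
    attr(stn_trajectory(1000, dt = dt, i_app = 5, record = FALSE),
         "spike_times"))
  # the first spike time converges at first order
  first <- vapply(sp, `[`, numeric(1), 1)
  expect_lt(abs(first[1] - first[2]), 0.1)
  expect_lt(abs(first[2] - first[3]), abs(first[1] - first[2]))
  # the mean inter-spike interval is a Cauchy sequence in dt
  isi <- vapply(sp, function(s) mean(diff(s)), numeric(1))
  d1 <- abs(isi[1] - isi[2]); d2 <- abs(isi[2] - isi[3])
  expect_lt(d2, d1)
  expect_lt(d1 / isi[3], 0.06)  # per-cycle discretisation error at dt = 0.025
})

test_that("gating variables stay in [0,1] and calcium non-negative under random input", {
  set.seed(42)
  p <- stn_params()
  st <- stn_steady_state(-60, 0.005, p)
  for (i in 1:400) {
    st <- advance_stn(st, 0.025, g_ampa = runif(1, 0, 20),
                      g_gaba = runif(1, 0, 60), t = i * 0.025,
                      params = p)$state
    gates <- unlist(st[stn_kinetics()$gates])
    expect_true(all(gates >= 0 & gates <= 1))
    expect_gte(st$ca, 0)
    expect_gte(st$d2, 0); expect_lte(st$d2, 1)
    expect_gte(st$r, 0); expect_lte(st$r, 1)
  }
})

test_that("release from sustained inhibition triggers a rebound burst", {
  dt <- 0.025
  n <- round(1500 / dt)
  g_gaba <- numeric(n)
  g_gaba[seq(round(500 / dt), round(1000 / dt))] <- 10
  tr <- stn_trajectory(1500, dt = dt, g_gaba = g_gaba, record = FALSE)
  sp <- attr(tr, "spike_times")
  post <- sum(sp > 1000 & sp <= 1200)
  pre_windows <- vapply(seq(0, 300, by = 50), function(s)
    sum(sp > s & sp <= s + 200), numeric(1))
  expect_gt(post, max(pre_windows))
})

test_that("the f-I curve is silent under hyperpolarisation and rises monotonically", {
  fi <- stn_fi_curve(c(-10, -5, 0, 4, 8, 16), duration = 1200,
                     discard = 200)
  expect_true(all(fi$converged))
  expect_equal(fi$rate_hz[fi$current == -10], 0)
  expect_equal(fi$rate_hz[fi$current == -5], 0)
  depol <- fi$rate_hz[fi$current >= 0]
  expect_true(all(diff(depol) >= 0))
  # zero current reproduces the autonomous firing rate
  sp <- attr(stn_trajectory(1200, record = FALSE), "spike_times")
  auto_rate <- sum(sp >= 200) / 1.0
  expect_equal(fi$rate_hz[fi$current == 0], auto_rate)
  expect_gt(auto_rate, 0)
})

test_that("GPe neuron relaxes toward its leak reversal without input", {
  st <- list(v = -60, refractory_left = 0)
  p <- gpe_params()
  vs <- numeric(200)
  for (i in 1:200) {
    r <- advance_gpe(st, 0.5, g_total = 0, params = p)
    st <- r$state
    vs[i] <- st$v
    expect_false(r$spike)
  }
  expect_true(all(diff(vs) < 0))
  expect_lt(abs(vs[200] - p$v_leak), 0.05)
})

test_that("GPe firing under constant drive matches the analytic LIF solution", {
  p <- gpe_params()
  for (g in c(6, 10, 20)) {
    tr <- gpe_trajectory(3000, dt = 0.025, g_exc = g, params = p)
    sp <- attr(tr, "spike_times")
    isi <- diff(sp)
    expect_lt(abs(mean(isi) - gpe_isi_analytic(g, p)), 0.025 + 1e-9)
  }
  # subthreshold equilibrium never fires
  expect_identical(gpe_isi_analytic(2, p), Inf)
})

test_that("GPe is refractory for exactly 2 ms after a spike", {
  p <- gpe_params()
  # under overwhelming drive the neuron fires as fast as the refractory
  # period permits: every spike pair is separated by at least 2 ms
  tr <- gpe_trajectory(200, dt = 0.1, g_exc = 1000, params = p)
  isi <- diff(attr(tr, "spike_times"))
  expect_gt(length(isi), 50)
  expect_true(all(isi >= p$refractory - 1e-9))
  expect_lt(min(isi), p$refractory + 0.2 + 1e-9)
  # stepwise: the membrane is held at reset while the clock runs
  st <- list(v = -55.5, refractory_left = 0)
  r <- advance_gpe(st, 0.1, g_total = 1000, params = p)
  expect_true(r$spike)
  st <- r$state
  for (k in 1:19) {  # 1.9 ms of hold at dt = 0.1
    r <- advance_gpe(st, 0.1, g_total = 1000, params = p)
    expect_false(r$spike)
    expect_equal(r$state$v, p$reset)
    st <- r$state
  }
})
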