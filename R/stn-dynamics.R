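# Membrane dynamics of the STN model neuron: a pure-R reference
# implementation of the right-hand side and a single exponential-Euler step,
# plus fast trajectory integration through the compiled engine.

gate_inf <- function(v, th, k) 1 / (1 + exp(-(v - th) / k))

gate_tau_r <- function(v, row) {
  row[["tau0"]] + row[["tau1"]] /
    (exp(-(v - row[["th1"]]) / row[["s1"]]) +
       exp(-(v - row[["th2"]]) / row[["s2"]]))
}

#' Steady-state STN neuron state at a holding potential
#'
#' All gating variables are set to their voltage (or calcium) dependent
#' steady-state values at the given membrane potential.
#'
#' @param v Membrane potential (mV).
#' @param ca Intracellular calcium concentration (uM).
#' @param params STN parameters from [stn_params()].
#' @return A named list with elements `v`, the eleven gating variables, and
#'   `ca`.
#' @export
stn_steady_state <- function(v = -60, ca = 0.005, params = stn_params()) {
  kin <- params$kinetics
  vg <- kin$vgates
  gates <- stats::setNames(
    vapply(kin$gates, function(g) gate_inf(v, vg[g, "th_inf"], vg[g, "k_inf"]),
           numeric(1)),
    kin$gates)
  cg <- kin$cagates
  c(list(v = v), as.list(gates),
    list(d2 = gate_inf(ca, cg[["d2_th"]], cg[["d2_k"]]),
         r = gate_inf(ca, cg[["r_th"]], cg[["r_k"]]),
         ca = ca))
}

stn_check_state <- function(state) {
  vals <- unlist(state)
  if (any(!is.finite(vals)))
    abort("non-finite value in STN state: integration failure")
  gates <- vals[!names(vals) %in% c("v", "ca")]
  if (any(gates < -1e-12) || any(gates > 1 + 1e-12))
    abort("STN gating variable outside [0, 1]")
  if (state$ca < 0) abort("intracellular calcium must be >= 0")
  invisible(state)
}

stn_currents <- function(state, params) {
  p <- params
  v <- state$v
  vca <- 13.27 * log(p$ca_out / max(state$ca, 1e-9))
  list(
    i_na = p$g_na * state$m^3 * state$h * (v - p$v_na),
    i_k = p$g_k * state$n^4 * (v - p$v_k),
    i_a = p$g_a * state$a^2 * state$b * (v - p$v_k),
    i_lca = p$g_lca * state$c^2 * state$d1 * state$d2 * (v - vca),
    i_t = p$g_t * state$p^2 * state$q * (v - vca),
    i_cak = p$g_cak * state$r^2 * (v - p$v_k),
    i_leak = p$g_leak * (v - p$v_leak),
    v_ca = vca
  )
}

#' Time derivatives of the STN membrane equation
#'
#' Evaluates the right-hand side of the conductance-based STN model:
#' the membrane equation with sodium, potassium (delayed-rectifier and
#' A-type), L-like and T-type calcium, calcium-activated potassium and leak
#' currents, synaptic AMPA/GABA-A conductances, and first-order kinetics for
#' all gating variables and intracellular calcium. With zero synaptic
#' conductance the dynamics reduce to the autonomous source model.
#'
#' @param state Named list as returned by [stn_steady_state()].
#' @param g_ampa,g_gaba Synaptic conductances (nS), scaled onto the
#'   membrane-normalised currents through the area term of `params`.
#' @param i_app Applied current density (uA/cm^2).
#' @param params STN parameters.
#' @return Named list of time derivatives (per ms) for every state variable.
#' @export
stn_derivatives <- function(state, g_ampa = 0, g_gaba = 0, i_app = 0,
                            params = stn_params()) {
  stn_check_state(state)
  if (g_ampa < 0 || g_gaba < 0) abort("synaptic conductances must be >= 0")
  p <- params
  cur <- stn_currents(state, p)
  v <- state$v
  i_syn <- p$syn_scale * (g_ampa * (v - p$v_exc) + g_gaba * (v - p$v_inh))
  dv <- (-cur$i_na - cur$i_k - cur$i_a - cur$i_lca - cur$i_t - cur$i_cak -
           cur$i_leak - i_syn + i_app) / p$cm
  kin <- p$kinetics
  vg <- kin$vgates
  dgate <- stats::setNames(
    vapply(kin$gates, function(g) {
      xinf <- gate_inf(v, vg[g, "th_inf"], vg[g, "k_inf"])
      (xinf - state[[g]]) / gate_tau_r(v, as.list(vg[g, ]))
    }, numeric(1)),
    kin$gates)
  cg <- kin$cagates
  dd2 <- (gate_inf(state$ca, cg[["d2_th"]], cg[["d2_k"]]) - state$d2) /
    cg[["d2_tau"]]
  dr <- (gate_inf(state$ca, cg[["r_th"]], cg[["r_k"]]) - state$r) /
    cg[["r_tau"]]
  dca <- -p$alpha_ca * (cur$i_lca + cur$i_t) - p$k_ca * state$ca
  c(list(v = dv), as.list(dgate), list(d2 = dd2, r = dr, ca = dca))
}

#' Advance an STN neuron by one time step
#'
#' One integration step of the STN model: exponential Euler for the gating
#' variables and calcium, forward update for the membrane potential. Gating
#' variables are clamped to `[0, 1]`; a spike is flagged when the membrane
#' potential crosses the detection threshold upward outside the detection
#' guard.
#'
#' @inheritParams stn_derivatives
#' @param dt Time step (ms); must be positive and below the stability bound
#'   (0.05 ms: the forward membrane update is the binding constraint during
#'   strong synaptic volleys).
#' @param t Current time (ms), used for the refractory guard.
#' @return A list with the advanced `state` and logical `spike`.
#' @export
advance_stn <- function(state, dt, g_ampa = 0, g_gaba = 0, i_app = 0,
                        t = 0, params = stn_params()) {
  if (dt <= 0) abort("dt must be > 0")
  if (dt > 0.05)
    abort("dt above the documented stability bound (0.05 ms) for the STN model")
  stn_check_state(state)
  p <- params
  v <- state$v
  cur <- stn_currents(state, p)
  i_syn <- p$syn_scale * (g_ampa * (v - p$v_exc) + g_gaba * (v - p$v_inh))
  dv <- (-cur$i_na - cur$i_k - cur$i_a - cur$i_lca - cur$i_t - cur$i_cak -
           cur$i_leak - i_syn + i_app) / p$cm
  kin <- p$kinetics
  vg <- kin$vgates
  new <- state
  for (g in kin$gates) {
    xinf <- gate_inf(v, vg[g, "th_inf"], vg[g, "k_inf"])
    tau <- gate_tau_r(v, as.list(vg[g, ]))
    x <- xinf + (state[[g]] - xinf) * exp(-dt / tau)
    new[[g]] <- min(max(x, 0), 1)
  }
  cg <- kin$cagates
  d2inf <- gate_inf(state$ca, cg[["d2_th"]], cg[["d2_k"]])
  new$d2 <- d2inf + (state$d2 - d2inf) * exp(-dt / cg[["d2_tau"]])
  rinf <- gate_inf(state$ca, cg[["r_th"]], cg[["r_k"]])
  new$r <- rinf + (state$r - rinf) * exp(-dt / cg[["r_tau"]])
  ca_inf <- max(-p$alpha_ca * (cur$i_lca + cur$i_t) / p$k_ca, 0)
  new$ca <- ca_inf + (state$ca - ca_inf) * exp(-p$k_ca * dt)
  new$v <- v + dt * dv
  if (!is.finite(new$v)) abort("STN membrane potential diverged")
  last <- if (is.null(state$last_spike)) -Inf else state$last_spike
  spike <- v < p$spike_threshold && new$v >= p$spike_threshold &&
    (t - last) > p$spike_refractory
  if (spike) new$last_spike <- t
  list(state = new, spike = spike)
}

#' Integrate a single STN neuron trajectory
#'
#' Runs the compiled integrator for one neuron under prescribed applied
#' current and synaptic conductance time courses.
#'
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param i_app Applied current density (uA/cm^2); scalar or per-step vector.
#' @param g_ampa,g_gaba Synaptic conductances (nS); scalar or per-step.
#' @param v0 Initial membrane potential (mV); gates start at steady state.
#' @param record Keep the full voltage trace.
#' @param params STN parameters.
#' @return A tibble with columns `time_ms` and `v` (empty when
#'   `record = FALSE`), with attributes `spike_times` (ms) and `rate_hz`.
#' @export
stn_trajectory <- function(duration, dt = 0.025, i_app = 0, g_ampa = 0,
                           g_gaba = 0, v0 = -60, record = TRUE,
                           params = stn_params()) {
  n <- round(duration / dt)
  res <- cpp_stn_trajectory(stn_params_for_engine(params),
                            params$kinetics, dt, n,
                            as.numeric(i_app), as.numeric(g_ampa),
                            as.numeric(g_gaba), v0, 0.005, record)
  out <- if (record) {
    tibble(time_ms = seq_len(n) * dt, v = res$v)
  } else {
    tibble(time_ms = numeric(), v = numeric())
  }
  attr(out, "spike_times") <- res$spike_times
  attr(out, "rate_hz") <- length(res$spike_times) / duration * 1000
  out
}

#' Firing rate versus applied current of the STN model
#'
#' Integrates the model across a grid of applied currents and reports the
#' mean firing rate of each trajectory after discarding a transient. This is
#' the calibration instrument for the membrane-area scale: the area term is
#' chosen so the rate-current relationship matches the source model's
#' experimental constraint.
#'
#' @param currents Applied current densities (uA/cm^2), hyperpolarising to
#'   depolarising.
#' @param duration Integration time per grid point (ms).
#' @param discard Initial transient to drop (ms).
#' @param dt Time step (ms).
#' @param params STN parameters.
#' @return A tibble with `current`, `rate_hz`, and a logical `converged` flag
#'   (FALSE when integration produced non-finite values).
#' @export
stn_fi_curve <- function(currents, duration = 2000, discard = 500,
                         dt = 0.025, params = stn_params()) {
  purrr::map_dfr(currents, function(i) {
    res <- tryCatch({
      tr <- stn_trajectory(duration, dt = dt, i_app = i, record = FALSE,
                           params = params)
      sp <- attr(tr, "spike_times")
      sp <- sp[sp >= discard]
      tibble(current = i,
             rate_hz = length(sp) / (duration - discard) * 1000,
             converged = TRUE)
    }, error = function(e) tibble(current = i, rate_hz = NA_real_,
                                  converged = FALSE))
    res
  })
}

#' Write an f-I curve as a two-column CSV
#'
#' @param fi Tibble from [stn_fi_curve()].
#' @param path Output file.
#' @export
write_fi_csv <- function(fi, path) {
  write.csv(fi[, c("current", "rate_hz")], path, row.names = FALSE)
  invisible(path)
}
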