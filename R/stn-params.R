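#' Parameters of the conductance-based STN model neuron
#'
#' Single-compartment membrane model of a subthalamic nucleus (STN) projection
#' neuron with sodium, delayed-rectifier and A-type potassium, L-like and
#' T-type calcium, calcium-activated potassium, and leak currents. Ionic
#' conductances are expressed per unit membrane area (mS/cm^2) while synaptic
#' conductances arrive in absolute units (nS); `area_cm2` converts between the
#' two, playing the role of the membrane-area scale chosen to match the
#' firing-rate versus injected-current relationship of the source model (see
#' [stn_fi_curve()]).
#'
#' The voltage-dependent gating kinetics (steady-state activation curves and
#' voltage-dependent time constants for m, h, n, a, b, c, d1, p, q, plus the
#' calcium-dependent gates d2 and r) are stored as a swappable table built by
#' [stn_kinetics()].
#'
#' @param cm Specific membrane capacitance (uF/cm^2).
#' @param g_na,g_k,g_a,g_lca,g_t,g_cak,g_leak Maximal conductances (mS/cm^2)
#'   of the sodium, delayed-rectifier potassium, A-type potassium, L-like
#'   calcium, T-type calcium, calcium-activated potassium, and leak currents.
#' @param v_na,v_k,v_leak Reversal potentials (mV). The calcium reversal is
#'   computed from the Nernst relation at each step using `ca_out`.
#' @param v_exc,v_inh Excitatory and inhibitory synaptic reversal potentials
#'   (mV).
#' @param area_cm2 Membrane area (cm^2) used to convert nanosiemens synaptic
#'   conductances into membrane-normalised densities.
#' @param alpha_ca Calcium influx factor (uM per uA/cm^2 per ms).
#' @param k_ca Calcium removal rate (1/ms).
#' @param ca_out Extracellular calcium concentration (uM).
#' @param spike_threshold Upward-crossing detection threshold (mV). Spikes in
#'   this model overshoot 0 mV, so a threshold of -10 mV detects every action
#'   potential without triggering on subthreshold events.
#' @param spike_refractory Detection guard (ms) preventing double counting
#'   within one action potential.
#' @param kinetics Gating-kinetics table from [stn_kinetics()].
#'
#' @return An object of class `stn_params`.
#' @seealso [stn_derivatives()], [advance_stn()], [stn_fi_curve()]
#' @export
stn_params <- function(cm = 1,
                       g_na = 49, g_k = 57, g_a = 5, g_lca = 15,
                       g_t = 5, g_cak = 1, g_leak = 0.35,
                       v_na = 60, v_k = -90, v_leak = -60,
                       v_exc = 0, v_inh = -84,
                       area_cm2 = 1.5e-5,
                       alpha_ca = 5.18e-3, k_ca = 2, ca_out = 2000,
                       spike_threshold = -10, spike_refractory = 1,
                       kinetics = stn_kinetics()) {
  g <- c(g_na = g_na, g_k = g_k, g_a = g_a, g_lca = g_lca, g_t = g_t,
         g_cak = g_cak, g_leak = g_leak)
  if (any(g < 0)) abort("all maximal conductances must be >= 0")
  if (!(v_inh < v_leak && v_leak < v_exc))
    abort("reversal potentials must satisfy v_inh < v_leak < v_exc")
  if (area_cm2 <= 0) abort("area_cm2 must be > 0")
  p <- list(cm = cm, g_na = g_na, g_k = g_k, g_a = g_a, g_lca = g_lca,
            g_t = g_t, g_cak = g_cak, g_leak = g_leak,
            v_na = v_na, v_k = v_k, v_leak = v_leak,
            v_exc = v_exc, v_inh = v_inh,
            area_cm2 = area_cm2,
            syn_scale = 1e-6 / area_cm2,  # nS -> mS/cm^2
            alpha_ca = alpha_ca, k_ca = k_ca, ca_out = ca_out,
            spike_threshold = spike_threshold,
            spike_refractory = spike_refractory,
            kinetics = kinetics)
  structure(p, class = "stn_params")
}

#' Gating-kinetics table of the STN model
#'
#' Steady-state activation/inactivation curves and voltage-dependent time
#' constants of the nine voltage-gated variables, plus the calcium-dependent
#' L-current inactivation gate (d2) and calcium-activated potassium gate (r).
#' Steady states are Boltzmann functions `1 / (1 + exp(-(V - theta) / k))`
#' (inactivation gates carry a negative slope `k`); time constants follow
#' `tau0 + tau1 / (exp(-(V - th1)/s1) + exp(-(V - th2)/s2))`, where an
#' infinite slope reduces the corresponding exponential to the constant 1.
#'
#' The table is data, not code: alternative kinetics can be supplied to
#' [stn_params()] for sensitivity analyses.
#'
#' @return A list with a `vgates` matrix (one row per voltage-gated variable,
#'   columns `th_inf, k_inf, tau0, tau1, th1, s1, th2, s2`), a `cagates`
#'   vector for d2 and r, and a `gates` character vector of gate names.
#' @export
stn_kinetics <- function() {
  gates <- c("m", "h", "n", "a", "b", "c", "d1", "p", "q")
  vg <- rbind(
    m  = c(-40.0,   8.0, 0.2,   3.0,   0, Inf, -53, -0.7),
    h  = c(-45.5,  -6.4, 0.0,  24.5, -50, -15, -50, 16.0),
    n  = c(-41.0,  14.0, 0.0,  11.0, -40, -40, -40, 50.0),
    a  = c(-45.0,  14.7, 1.0,   1.0,   0, Inf, -40, -0.5),
    b  = c(-90.0,  -7.5, 0.0, 200.0, -60, -30, -40, 10.0),
    c  = c(-30.6,   5.0, 45.0, 10.0, -27, -20, -50, 15.0),
    d1 = c(-60.0,  -7.5, 400.0, 500.0, -40, -15, -20, 20.0),
    p  = c(-56.0,   6.7, 5.0,   0.33, -27, -10, -102, 15.0),
    q  = c(-85.0,  -5.8, 0.0, 400.0, -50, -15, -50, 16.0)
  )
  colnames(vg) <- c("th_inf", "k_inf", "tau0", "tau1", "th1", "s1", "th2", "s2")
  list(vgates = vg,
       # d2: theta (uM), slope, tau (ms); r: theta, slope, tau
       cagates = c(d2_th = 0.1, d2_k = -0.02, d2_tau = 130,
                   r_th = 0.17, r_k = 0.08, r_tau = 2),
       gates = gates)
}

#' Parameters of the leaky integrate-and-fire GPe model neuron
#'
#' External globus pallidus (GPe) neurons are conductance-based
#' integrate-and-fire units driven by an excitatory conductance that pools
#' synaptic input from STN afferents with an intrinsic noisy conductance
#' standing in for autonomous pacemaking.
#'
#' The default membrane capacitance of 0.25 nF together with a 16.66 nS leak
#' gives a 15 ms membrane time constant, in the physiological range for
#' pallidal neurons. A capacitance of 0.25 pF (`cm = 2.5e-4`) would shrink
#' the time constant to 15 microseconds, making the membrane track its input
#' instantaneously; that reading remains available through the `cm` argument
#' for sensitivity checks.
#'
#' @param cm Membrane capacitance (nF).
#' @param g_leak Leak conductance (nS).
#' @param v_leak Leak reversal potential (mV).
#' @param v_exc Excitatory synaptic reversal potential (mV).
#' @param threshold Spike threshold (mV).
#' @param reset Post-spike reset potential (mV).
#' @param refractory Absolute refractory period (ms) during which the
#'   membrane is held at the reset potential.
#'
#' @return An object of class `gpe_params`.
#' @export
gpe_params <- function(cm = 0.25, g_leak = 16.66, v_leak = -70,
                       v_exc = 0, threshold = -55, reset = -60,
                       refractory = 2) {
  if (reset >= threshold) abort("reset must be below threshold")
  if (refractory <= 0) abort("refractory must be > 0")
  if (cm <= 0 || g_leak < 0) abort("cm must be > 0 and g_leak >= 0")
  structure(list(cm = cm, g_leak = g_leak, v_leak = v_leak, v_exc = v_exc,
                 threshold = threshold, reset = reset,
                 refractory = refractory),
            class = "gpe_params")
}

# strip non-scalar fields for the C++ engine
stn_params_for_engine <- function(params) {
  params[c("cm", "g_na", "g_k", "g_a", "g_lca", "g_t", "g_cak", "g_leak",
           "v_na", "v_k", "v_leak", "v_exc", "v_inh", "syn_scale",
           "alpha_ca", "k_ca", "ca_out", "spike_threshold",
           "spike_refractory")]
}
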