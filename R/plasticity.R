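# Short-term synaptic plasticity:
#  - depression of the transmission probability P of a unitary GPe->STN
#    projection, with stochastic per-contact release, and
#  - the three-type facilitation x depression (F*D) model of STN->GPe
#    synapses.

# Package defaults for the GPe->STN depression model. The four constants are
# not biophysical givens; they ship from calibrate_depression_params() run
# against the packaged depression/recovery target profile (see
# depression_targets()).
dep_defaults <- list(tau_d = 3000, f_d = 0.45, p_bound = 0.01, n_bound = 1.3)

#' Short-term depression state of a unitary GPe to STN projection
#'
#' The transmission probability `P` recovers exponentially toward 1 between
#' presynaptic spikes (`tau_d`) and is multiplied on each spike by a
#' decrement factor that relaxes smoothly from `f_d` to 1 as `P` approaches
#' the lower bound `p_bound`; `n_bound` controls how late that relaxation
#' sets in (smaller values depress harder).
#'
#' @param p Initial transmission probability.
#' @param tau_d Recovery time constant (ms).
#' @param f_d Decrement factor (< 1).
#' @param p_bound Lower bound of `P` in `[0, 1)`.
#' @param n_bound Exponent (> 0) shaping the approach to the bound.
#' @return An object of class `depression_state`.
#' @export
depression_state <- function(p = 1, tau_d = dep_defaults$tau_d,
                             f_d = dep_defaults$f_d,
                             p_bound = dep_defaults$p_bound,
                             n_bound = dep_defaults$n_bound) {
  if (f_d >= 1 || f_d < 0) abort("f_d must lie in [0, 1)")
  if (p_bound < 0 || p_bound >= 1) abort("p_bound must lie in [0, 1)")
  if (n_bound <= 0) abort("n_bound must be > 0")
  if (p < p_bound || p > 1) abort("p must lie in [p_bound, 1]")
  if (tau_d <= 0) abort("tau_d must be > 0")
  structure(list(p = p, tau_d = tau_d, f_d = f_d, p_bound = p_bound,
                 n_bound = n_bound),
            class = "depression_state")
}

#' Recovery of the transmission probability between spikes
#'
#' Exact exponential relaxation of `P` toward 1 with time constant `tau_d`.
#'
#' @param state A [depression_state()].
#' @param dt Elapsed time (ms); must be >= 0.
#' @return The updated state.
#' @export
depression_decay <- function(state, dt) {
  if (dt < 0) abort("dt must be >= 0")
  state$p <- 1 - (1 - state$p) * exp(-dt / state$tau_d)
  state
}

#' Depression of the transmission probability on a presynaptic spike
#'
#' `P <- P * (1 + (f_d - 1) * ((P - p_bound) / (1 - p_bound))^n_bound)`.
#' At `P = p_bound` the decrement factor equals 1 (no further depression);
#' at `P = 1` it equals `f_d`.
#'
#' @param state A [depression_state()].
#' @return The updated state; `P` stays within `[p_bound, 1]`.
#' @export
depression_on_spike <- function(state) {
  frac <- max((state$p - state$p_bound) / (1 - state$p_bound), 0)
  state$p <- state$p * (1 + (state$f_d - 1) * frac^state$n_bound)
  state$p <- min(max(state$p, state$p_bound), 1)
  state
}

#' Stochastic release across the contacts of a unitary projection
#'
#' A unitary GPe projection makes `n_contact` synaptic contacts; each
#' transmits independently with probability
#' `mu = 1 - (1 - P)^(1 / n_contact)`, so that the probability of at least
#' one successful contact equals the projection-level `P`. Uses the current
#' R random number stream.
#'
#' @param state A [depression_state()].
#' @param n_contact Number of synaptic contacts (>= 1).
#' @return List with `mu` (per-contact probability) and integer `successes`.
#' @export
contact_release <- function(state, n_contact) {
  if (n_contact < 1) abort("n_contact must be >= 1")
  mu <- 1 - (1 - state$p)^(1 / n_contact)
  list(mu = mu, successes = rbinom(1, n_contact, mu))
}

#' Transmission-probability trajectory over a spike train
#'
#' Applies [depression_decay()] and [depression_on_spike()] through an
#' ordered presynaptic spike train and records `P` immediately before and
#' after each spike.
#'
#' @param spike_times Ordered spike times (ms).
#' @param state Initial [depression_state()].
#' @param t0 Time at which `state` holds (ms).
#' @return Tibble with `time_ms`, `p_before`, `p_after`.
#' @export
depression_train <- function(spike_times, state = depression_state(), t0 = 0) {
  n <- length(spike_times)
  p_before <- p_after <- numeric(n)
  p <- state$p
  last <- t0
  for (i in seq_len(n)) {
    p <- 1 - (1 - p) * exp(-(spike_times[i] - last) / state$tau_d)
    p_before[i] <- p
    frac <- max((p - state$p_bound) / (1 - state$p_bound), 0)
    p <- p * (1 + (state$f_d - 1) * frac^state$n_bound)
    p <- min(max(p, state$p_bound), 1)
    p_after[i] <- p
    last <- spike_times[i]
  }
  tibble(time_ms = spike_times, p_before = p_before, p_after = p_after)
}

#' The three short-term plasticity types of STN to GPe synapses
#'
#' Facilitation-dominant (type 1), intermediate (type 2), and
#' depression-dominant (type 3) parameter sets of the facilitation x
#' depression model; each STN->GPe synapse is assigned one type uniformly at
#' random.
#'
#' @return Tibble with columns `type, f_f, f_d, tau_f, tau_d`.
#' @export
stp_type_table <- function() {
  tibble(type = 1:3,
         f_f = c(1.40, 1.34, 1.64),
         f_d = c(0.90, 0.86, 0.55),
         tau_f = c(241.0, 345.0, 148.0),
         tau_d = c(491.0, 700.0, 764.0))
}

#' Facilitation x depression state of an STN to GPe synapse
#'
#' Response amplitude `A = F * D` with facilitation `F in [1, f_bound]` and
#' depression `D in (0, 1]`, both relaxing exponentially to 1 between
#' spikes. On each spike `F` grows by a bounded multiplicative rule and `D`
#' is multiplied by `f_d`.
#'
#' @param type Plasticity type 1, 2 or 3 (see [stp_type_table()]); ignored
#'   when the four constants are given explicitly.
#' @param f_f,f_d,tau_f,tau_d Model constants.
#' @param f_bound Upper bound for `F`.
#' @return An object of class `facdep_state`.
#' @export
facdep_state <- function(type = 1, f_f = NULL, f_d = NULL, tau_f = NULL,
                         tau_d = NULL, f_bound = 2) {
  if (is.null(f_f)) {
    tt <- stp_type_table()
    row <- tt[tt$type == type, ]
    if (nrow(row) != 1) abort("type must be 1, 2 or 3")
    f_f <- row$f_f; f_d <- row$f_d; tau_f <- row$tau_f; tau_d <- row$tau_d
  }
  if (f_f <= 1) abort("f_f must be > 1")
  if (f_d >= 1 || f_d <= 0) abort("f_d must lie in (0, 1)")
  if (f_bound <= 1) abort("f_bound must be > 1")
  structure(list(f = 1, d = 1, f_f = f_f, f_d = f_d, tau_f = tau_f,
                 tau_d = tau_d, f_bound = f_bound),
            class = "facdep_state")
}

#' Relaxation of facilitation and depression between spikes
#'
#' @param state A [facdep_state()].
#' @param dt Elapsed time (ms).
#' @return The updated state (`F` and `D` relax toward 1).
#' @export
facdep_decay <- function(state, dt) {
  if (dt < 0) abort("dt must be >= 0")
  state$f <- 1 + (state$f - 1) * exp(-dt / state$tau_f)
  state$d <- 1 + (state$d - 1) * exp(-dt / state$tau_d)
  state
}

#' Spike update of the facilitation x depression synapse
#'
#' Returns the amplitude `A = F * D` that scales this spike's conductance
#' increment, then applies the facilitation increment
#' `F <- F * (1 + (f_f - 1) * (f_bound - F) / f_bound)` and the depression
#' decrement `D <- D * f_d`.
#'
#' @param state A [facdep_state()].
#' @return List with the updated `state` and the spike `amplitude`.
#' @export
facdep_on_spike <- function(state) {
  amplitude <- state$f * state$d
  state$f <- state$f * (1 + (state$f_f - 1) * (state$f_bound - state$f) /
                          state$f_bound)
  state$f <- min(state$f, state$f_bound)
  state$d <- state$d * state$f_d
  list(state = state, amplitude = amplitude)
}

#' Amplitude sequence of the facilitation x depression synapse over a train
#'
#' @param spike_times Ordered presynaptic spike times (ms).
#' @param state Initial [facdep_state()].
#' @param t0 Time at which `state` holds (ms).
#' @return Tibble with `time_ms`, `amplitude`, `f`, `d`.
#' @export
facdep_train <- function(spike_times, state = facdep_state(), t0 = 0) {
  n <- length(spike_times)
  amp <- fv <- dv <- numeric(n)
  last <- t0
  for (i in seq_len(n)) {
    state <- facdep_decay(state, spike_times[i] - last)
    up <- facdep_on_spike(state)
    state <- up$state
    amp[i] <- up$amplitude; fv[i] <- state$f; dv[i] <- state$d
    last <- spike_times[i]
  }
  tibble(time_ms = spike_times, amplitude = amp, f = fv, d = dv)
}

# ---------------------------------------------------------------------------
# Calibration of the depression constants
# ---------------------------------------------------------------------------

#' Simulate a constant-frequency stimulation and recovery protocol
#'
#' Drives the depression model at `freq_hz` for `duration_s`, then probes
#' recovery at the given wait times (each probe reads `P` without
#' depressing it).
#'
#' @param freq_hz Stimulation frequency (Hz).
#' @param duration_s Stimulation duration (s).
#' @param state Initial [depression_state()].
#' @param recovery_s Wait times (s) after the last stimulus at which `P` is
#'   probed.
#' @return List with `during` (tibble: `pulse`, `time_s`, `p`) giving `P`
#'   immediately before each stimulus, and `recovery` (tibble: `time_s`,
#'   `p`).
#' @export
simulate_depression_protocol <- function(freq_hz, duration_s = 10,
                                         state = depression_state(),
                                         recovery_s = numeric()) {
  stim <- seq(0, duration_s * 1000, by = 1000 / freq_hz)
  tr <- depression_train(stim, state)
  end_state <- depression_state(p = tr$p_after[nrow(tr)],
                                tau_d = state$tau_d, f_d = state$f_d,
                                p_bound = state$p_bound,
                                n_bound = state$n_bound)
  rec <- tibble(time_s = recovery_s,
                p = vapply(recovery_s, function(w)
                  depression_decay(end_state, w * 1000)$p, numeric(1)))
  list(during = tibble(pulse = seq_along(stim), time_s = stim / 1000,
                       p = tr$p_before),
       recovery = rec)
}

#' Packaged calibration targets for the GPe to STN depression model
#'
#' Reads the synthetic depression/recovery target profile shipped with the
#' package: steady-state transmission probabilities after 10 s of 1, 10, 20,
#' 33 and 100 Hz stimulation and the recovery time course after the 100-Hz
#' train. The values are representative of slice recordings of GPe-STN
#' GABAergic transmission (strong frequency-dependent depression, recovery
#' over seconds); they are synthesised, not digitised from any publication.
#'
#' @return Tibble with columns `protocol` ("steady_state" or "recovery"),
#'   `freq_hz`, `time_s`, `value`.
#' @export
depression_targets <- function() {
  path <- system.file("extdata", "gpe_stn_depression_targets_synthetic.csv",
                      package = "stngpe")
  as_tibble(read.csv(path))
}

#' Calibrate the depression constants against target curves
#'
#' Least-squares fit of `(tau_d, f_d, p_bound, n_bound)` to steady-state
#' depression and recovery targets, by simulating the stimulation protocols
#' under candidate parameters (Nelder-Mead on log/logit-transformed
#' parameters).
#'
#' @param targets Tibble in the format of [depression_targets()].
#' @param init Initial parameter list with elements `tau_d, f_d, p_bound,
#'   n_bound`.
#' @param maxit Optimiser iteration budget.
#' @return List with the fitted `params`, the achieved `sse`, the optimiser
#'   `convergence` code (0 = converged), and `fitted` values aligned with
#'   `targets`.
#' @export
calibrate_depression_params <- function(targets = depression_targets(),
                                        init = list(tau_d = 1000, f_d = 0.7,
                                                    p_bound = 0.1,
                                                    n_bound = 1.5),
                                        maxit = 400) {
  ss <- targets[targets$protocol == "steady_state", ]
  rec <- targets[targets$protocol == "recovery", ]
  logit <- function(x) log(x / (1 - x))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  pack <- function(p) c(log(p$tau_d), logit(p$f_d), logit(p$p_bound),
                        log(p$n_bound))
  unpack <- function(th) list(tau_d = exp(th[1]), f_d = inv_logit(th[2]),
                              p_bound = inv_logit(th[3]),
                              n_bound = exp(th[4]))
  predict_all <- function(p) {
    st <- depression_state(tau_d = p$tau_d, f_d = p$f_d,
                           p_bound = p$p_bound, n_bound = p$n_bound)
    ss_hat <- vapply(ss$freq_hz, function(f) {
      sim <- simulate_depression_protocol(f, 10, st)
      tail(sim$during$p, 1)
    }, numeric(1))
    sim100 <- simulate_depression_protocol(100, 10, st,
                                           recovery_s = rec$time_s)
    c(ss_hat, sim100$recovery$p)
  }
  obs <- c(ss$value, rec$value)
  obj <- function(th) {
    p <- unpack(th)
    sum((predict_all(p) - obs)^2)
  }
  fit <- optim(pack(init), obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  if (fit$convergence != 0)
    warn(sprintf("depression calibration did not converge (code %d, sse %.3g)",
                 fit$convergence, fit$value))
  params <- unpack(fit$par)
  list(params = params, sse = fit$value, convergence = fit$convergence,
       fitted = predict_all(params), observed = obs)
}
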