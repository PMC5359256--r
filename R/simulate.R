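# Whole-network simulation: configuration objects, stimulation protocols,
# Poisson input generators, and the wrapper around the compiled clock-driven
# engine.

#' Simulation configuration
#'
#' Integration step, duration, warm-up discard, seeds and recording lists
#' for one network simulation. The analysis epoch is
#' `[warmup_ms, duration_ms)`; spikes during the warm-up are recorded but
#' discarded by the analysis helpers.
#'
#' @param dt Integration step (ms), shared by both populations and all
#'   kernels.
#' @param duration_ms Total simulated time (ms).
#' @param warmup_ms Initial interval excluded from analysis (ms).
#' @param seed Base seed; the independent cortex/noise/release streams are
#'   derived from it unless given explicitly in `seeds`.
#' @param seeds Optional named list (`cortex`, `noise`, `release`)
#'   overriding the derived stream seeds.
#' @param record_stn,record_gpe Neuron indices (1-based) whose state traces
#'   (membrane potential, conductances, T-current variables) are recorded,
#'   decimated to `trace_fs_hz`.
#' @param trace_fs_hz Trace sampling rate (Hz).
#' @param ctx_profile Optional [stimulus_profile()] for the cortical drive;
#'   defaults to the constant background rate of the network configuration.
#' @param gpe_int_deterministic Replace the intrinsic Poisson-driven
#'   conductance by its constant time-average (the zero-variance control).
#' @param stn_v0 Initial STN membrane potential (mV).
#' @return An object of class `stngpe_sim_config`.
#' @export
simulation_config <- function(dt = 0.025, duration_ms = 11000,
                              warmup_ms = 1000, seed = 1, seeds = NULL,
                              record_stn = integer(), record_gpe = integer(),
                              trace_fs_hz = 1000, ctx_profile = NULL,
                              gpe_int_deterministic = FALSE, stn_v0 = -60) {
  if (warmup_ms >= duration_ms) abort("warmup must be shorter than duration")
  if (dt <= 0) abort("dt must be > 0")
  if (is.null(seeds)) {
    seeds <- list(cortex = seed * 3L + 1L, noise = seed * 3L + 2L,
                  release = seed * 3L + 3L)
  }
  structure(list(dt = dt, duration_ms = duration_ms, warmup_ms = warmup_ms,
                 seed = seed, seeds = seeds,
                 record_stn = as.integer(record_stn),
                 record_gpe = as.integer(record_gpe),
                 trace_fs_hz = trace_fs_hz, ctx_profile = ctx_profile,
                 gpe_int_deterministic = gpe_int_deterministic,
                 stn_v0 = stn_v0),
            class = "stngpe_sim_config")
}

#' Piecewise-constant stimulus rate profile
#'
#' Describes the time course of the cortical Poisson drive: `rates_hz[i]`
#' applies on `[breaks_ms[i-1], breaks_ms[i])` with implicit boundaries at 0
#' and infinity.
#'
#' @param breaks_ms Ordered interior breakpoints (ms).
#' @param rates_hz Rates (Hz), one more than there are breakpoints.
#' @return An object of class `stimulus_profile`.
#' @export
stimulus_profile <- function(breaks_ms = numeric(), rates_hz = 100) {
  if (length(rates_hz) != length(breaks_ms) + 1)
    abort("need one more rate than breakpoints")
  if (any(rates_hz < 0)) abort("rates must be >= 0")
  if (is.unsorted(breaks_ms, strictly = TRUE) && length(breaks_ms) > 1)
    abort("breakpoints must be strictly increasing")
  structure(list(breaks_ms = breaks_ms, rates_hz = rates_hz),
            class = "stimulus_profile")
}

#' Rate of a stimulus profile at given times
#'
#' @param profile A [stimulus_profile()].
#' @param t_ms Times (ms).
#' @return Rates (Hz).
#' @export
profile_rate <- function(profile, t_ms) {
  idx <- findInterval(t_ms, profile$breaks_ms) + 1
  profile$rates_hz[idx]
}

#' Add a phasic cortical stimulation window to a simulation
#'
#' Raises the cortical drive to `peak_rate_hz` over
#' `[onset_ms, onset_ms + duration_ms)`, modelling the peri-movement phasic
#' activation of layer-V pyramidal-tract neurons ("PT stimulation"); the
#' baseline rate applies elsewhere.
#'
#' @param sim A [simulation_config()].
#' @param onset_ms Stimulation onset (ms).
#' @param duration_ms Stimulation duration (ms).
#' @param peak_rate_hz Stimulation rate (Hz), e.g. 250, 500 or 1000.
#' @param baseline_hz Background rate outside the window (Hz).
#' @return The configuration with the stimulation profile attached.
#' @export
apply_pt_stimulation <- function(sim, onset_ms, duration_ms = 1000,
                                 peak_rate_hz = 1000, baseline_hz = 100) {
  if (onset_ms + duration_ms > sim$duration_ms)
    abort("stimulation window must fit inside the simulation")
  if (!is.null(sim$ctx_profile))
    abort("a cortical stimulation profile is already configured")
  sim$ctx_profile <- stimulus_profile(
    breaks_ms = c(onset_ms, onset_ms + duration_ms),
    rates_hz = c(baseline_hz, peak_rate_hz, baseline_hz))
  sim
}

#' Homogeneous or rate-modulated Poisson spike trains
#'
#' `poisson_train()` draws event times of a (piecewise) homogeneous Poisson
#' process; `modulated_poisson_train()` thins a homogeneous train by a
#' sinusoidal rate modulation, producing the oscillatory surrogate trains
#' used to validate the spectral analysis.
#'
#' @param rate_hz Mean rate (Hz), or a [stimulus_profile()].
#' @param duration_ms Train duration (ms).
#' @param seed Optional seed for the R random number stream.
#' @return Ordered event times (ms).
#' @export
poisson_train <- function(rate_hz, duration_ms, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  if (inherits(rate_hz, "stimulus_profile")) {
    prof <- rate_hz
    rmax <- max(prof$rates_hz)
    if (rmax == 0) return(numeric())
    base <- poisson_train_hom(rmax, duration_ms)
    keep <- runif(length(base)) < profile_rate(prof, base) / rmax
    return(base[keep])
  }
  poisson_train_hom(rate_hz, duration_ms)
}

poisson_train_hom <- function(rate_hz, duration_ms) {
  if (rate_hz < 0) abort("rate must be >= 0")
  if (rate_hz == 0) return(numeric())
  n_exp <- max(10, ceiling(rate_hz * duration_ms / 1000 * 1.25) + 20)
  t <- cumsum(rexp(n_exp, rate_hz / 1000))
  while (length(t) > 0 && t[length(t)] < duration_ms) {
    t <- c(t, t[length(t)] + cumsum(rexp(n_exp, rate_hz / 1000)))
  }
  t[t < duration_ms]
}

#' @rdname poisson_train
#' @param mod_freq_hz Modulation frequency (Hz).
#' @param depth Modulation depth in `[0, 1]`: the instantaneous rate is
#'   `rate_hz * (1 + depth * sin(2 pi f t))`.
#' @export
modulated_poisson_train <- function(rate_hz, duration_ms, mod_freq_hz = 14,
                                    depth = 0.8, seed = NULL) {
  if (depth < 0 || depth > 1) abort("depth must lie in [0, 1]")
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  rmax <- rate_hz * (1 + depth)
  base <- poisson_train_hom(rmax, duration_ms)
  lambda <- rate_hz * (1 + depth * sin(2 * pi * mod_freq_hz * base / 1000))
  base[runif(length(base)) < lambda / rmax]
}

#' Poisson-driven intrinsic conductance trace of a GPe neuron
#'
#' Convolves a Poisson pseudo spike train with the GPe excitatory beta
#' kernel; this pseudo-synaptic conductance stands in for the autonomous
#' pacemaking drive of GPe neurons.
#'
#' @param rate_hz Pseudo spike train rate (Hz).
#' @param gmax Maximal conductance per event (nS).
#' @param duration_ms Trace duration (ms).
#' @param dt Sampling step (ms).
#' @param tau_rise,tau_decay Kernel time constants (ms).
#' @param normalize Peak-normalise the kernel.
#' @param seed Optional seed.
#' @return Tibble with `time_ms` and `g` (nS); event times in attribute
#'   `"events"`.
#' @export
gpe_intrinsic_conductance <- function(rate_hz = 100, gmax = 1.125,
                                      duration_ms = 1000, dt = 0.1,
                                      tau_rise = 5.0, tau_decay = 12.4,
                                      normalize = TRUE, seed = NULL) {
  if (rate_hz < 0) abort("rate must be >= 0")
  ev <- poisson_train(rate_hz, duration_ms, seed = seed)
  times <- seq(0, duration_ms - dt, by = dt)
  amp <- if (normalize) gmax / beta_peak_value(tau_rise, tau_decay) else gmax
  # state-space evaluation (exact between events)
  g <- numeric(length(times))
  if (length(ev) > 0 && gmax > 0) {
    sd_ <- 0; sr_ <- 0; iev <- 1
    dec_d <- exp(-dt / tau_decay); dec_r <- exp(-dt / tau_rise)
    for (i in seq_along(times)) {
      while (iev <= length(ev) && ev[iev] <= times[i]) {
        del_d <- exp(-(times[i] - ev[iev]) / tau_decay)
        del_r <- exp(-(times[i] - ev[iev]) / tau_rise)
        sd_ <- sd_ + amp * del_d
        sr_ <- sr_ + amp * del_r
        iev <- iev + 1
      }
      g[i] <- max(sd_ - sr_, 0)
      sd_ <- sd_ * dec_d; sr_ <- sr_ * dec_r
    }
  }
  out <- tibble(time_ms = times, g = g)
  attr(out, "events") <- ev
  out
}

#' Simulate the STN-GPe network
#'
#' Runs the clock-driven engine: conductance-based STN neurons and
#' integrate-and-fire GPe neurons coupled through delayed, depressing /
#' facilitating synapses, driven by independent cortical and intrinsic
#' Poisson streams. Every synaptic event takes effect exactly one conduction
#' delay after its presynaptic spike; the run is fully reproducible from the
#' configuration seeds.
#'
#' @param network A [build_network()] result.
#' @param sim A [simulation_config()].
#' @param feedback Optional feedback delay lines from
#'   [build_feedback_loop()].
#' @param forced_stn_spikes Optional list (one numeric vector of times per
#'   STN neuron) of spikes injected irrespective of the membrane state;
#'   a testing aid for delay and synapse contracts.
#' @param stn,gpe Neuron parameter sets ([stn_params()], [gpe_params()]).
#' @return An object of class `stngpe_sim`: list with `spikes` (tibble
#'   `population`, `neuron`, `time_ms`), `traces` (named lists of sampled
#'   state traces, when recording was requested), `network`, and `sim`.
#' @export
simulate_network <- function(network, sim = simulation_config(),
                             feedback = NULL, forced_stn_spikes = NULL,
                             stn = stn_params(), gpe = gpe_params()) {
  cfg <- network$config
  dt <- sim$dt
  n_steps <- round(sim$duration_ms / dt)
  delay_steps <- function(d) {
    s <- round(d / dt)
    if (any(abs(s * dt - d) > 1e-9))
      warn(sprintf("delay rounded to the dt grid (%.3f ms)", s[1] * dt))
    as.integer(pmax(s, 1))
  }
  prof <- sim$ctx_profile
  if (is.null(prof)) prof <- stimulus_profile(rates_hz = cfg$ctx_rate_hz)
  fb <- feedback
  if (is.null(fb)) {
    fb_list <- list(src = integer(), tgt = integer(),
                    delay_steps = integer(), amp = numeric(),
                    p_transmit = 0)
  } else {
    fb_list <- list(src = as.integer(fb$source - 1L),
                    tgt = as.integer(fb$target - 1L),
                    delay_steps = delay_steps(fb$delay_ms),
                    amp = as.numeric(fb$gmax),
                    p_transmit = attr(fb, "p_transmit"))
  }
  forced <- list()
  if (!is.null(forced_stn_spikes)) {
    forced <- lapply(seq_len(cfg$n_stn), function(i) {
      if (i <= length(forced_stn_spikes) && length(forced_stn_spikes[[i]]))
        as.integer(round(forced_stn_spikes[[i]] / dt))
      else integer()
    })
  }
  stn_p <- stn
  engine_cfg <- list(
    dt = dt, n_steps = as.integer(n_steps),
    n_stn = cfg$n_stn, n_gpe = cfg$n_gpe,
    stn_params = stn_params_for_engine(stn_p),
    stn_kinetics = stn_p$kinetics,
    gpe_params = unclass(gpe),
    kernels = list(gaba_tau_rise = 0.380, gaba_tau_decay = 7.7,
                   gpe_ampa_tau_rise = 5.0, gpe_ampa_tau_decay = 12.4,
                   ctx_tau = 1.0, peak_normalize = cfg$peak_normalize),
    amplitudes = list(g_gaba_gpe_stn = cfg$g_gaba_gpe_stn,
                      g_ampa_stn_gpe = cfg$g_ampa_stn_gpe,
                      g_ampa_gpe_int = cfg$g_ampa_gpe_int *
                        (cfg$gpe_int_scale %||% 1),
                      g_ampa_ctx_stn = cfg$g_ampa_ctx_stn),
    stp = c(cfg$depression,
            list(f_bound = cfg$f_bound,
                 per_contact = cfg$per_contact_release)),
    network = list(
      gs_src = as.integer(network$gpe_to_stn$source - 1L),
      gs_tgt = as.integer(network$gpe_to_stn$target - 1L),
      gs_n_contact = as.integer(network$gpe_to_stn$n_contact),
      gs_delay_steps = delay_steps(network$gpe_to_stn$delay_ms),
      sg_src = as.integer(network$stn_to_gpe$source - 1L),
      sg_tgt = as.integer(network$stn_to_gpe$target - 1L),
      sg_type = as.integer(network$stn_to_gpe$stp_type),
      sg_delay_steps = delay_steps(network$stn_to_gpe$delay_ms),
      stp_type_params = as.matrix(cfg$stp_types[, c("f_f", "f_d", "tau_f",
                                                    "tau_d")])),
    feedback = fb_list,
    cortex = list(break_steps = as.numeric(round(prof$breaks_ms / dt)),
                  rates = as.numeric(prof$rates_hz)),
    gpe_int_rate = cfg$gpe_int_rate_hz,
    gpe_int_deterministic = isTRUE(sim$gpe_int_deterministic),
    seeds = lapply(sim$seeds, as.numeric),
    forced_stn_spikes = forced,
    record_stn = as.integer(sim$record_stn - 1L),
    record_gpe = as.integer(sim$record_gpe - 1L),
    trace_decim = as.integer(max(round(1000 / (sim$trace_fs_hz * dt)), 1)),
    stn_v0 = sim$stn_v0)
  res <- cpp_simulate(engine_cfg)
  spikes <- dplyr::bind_rows(
    purrr::imap_dfr(res$stn_spikes, function(s, i)
      tibble(population = "STN", neuron = as.integer(i),
             time_ms = as.numeric(s))),
    purrr::imap_dfr(res$gpe_spikes, function(s, i)
      tibble(population = "GPe", neuron = as.integer(i),
             time_ms = as.numeric(s))))
  traces <- res$traces
  if (!is.null(traces) && length(sim$record_stn) + length(sim$record_gpe) > 0) {
    names(traces$stn) <- as.character(sim$record_stn)
    names(traces$gpe) <- as.character(sim$record_gpe)
  }
  structure(list(spikes = spikes, traces = traces, network = network,
                 sim = sim),
            class = "stngpe_sim")
}

#' Write or read a spike raster as TSV
#'
#' Plain-text raster interchange format: `neuron_label`, `neuron_index`,
#' `spike_time_ms`, one row per spike.
#'
#' @param x An `stngpe_sim` or a spikes tibble (`population`, `neuron`,
#'   `time_ms`).
#' @param path File path.
#' @return `read_raster_tsv()` returns a spikes tibble.
#' @export
write_raster_tsv <- function(x, path) {
  spikes <- if (inherits(x, "stngpe_sim")) x$spikes else x
  df <- data.frame(neuron_label = spikes$population,
                   neuron_index = spikes$neuron,
                   spike_time_ms = spikes$time_ms)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_tsv
#' @export
read_raster_tsv <- function(path) {
  df <- read.delim(path)
  tibble(population = df$neuron_label, neuron = as.integer(df$neuron_index),
         time_ms = as.numeric(df$spike_time_ms))
}
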