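# Scripted computational experiments: reference state points, conductance
# sweeps, cortical-input manipulations, and feedback delay lines.

#' A network state point
#'
#' A state of the STN-GPe circuit is set by three maximal conductances: the
#' GPe intrinsic noisy conductance (intrinsic excitability, reduced by
#' dopamine depletion), the GPe->STN GABAergic conductance, and the
#' STN->GPe AMPA conductance.
#'
#' @param g_ampa_gpe_int,g_gaba_gpe_stn,g_ampa_stn_gpe Conductances (nS).
#' @param label State label.
#' @return An object of class `stngpe_state_point`.
#' @export
state_point <- function(g_ampa_gpe_int, g_gaba_gpe_stn, g_ampa_stn_gpe,
                        label = "custom") {
  if (any(c(g_ampa_gpe_int, g_gaba_gpe_stn, g_ampa_stn_gpe) < 0))
    abort("conductances must be >= 0")
  structure(list(g_ampa_gpe_int = g_ampa_gpe_int,
                 g_gaba_gpe_stn = g_gaba_gpe_stn,
                 g_ampa_stn_gpe = g_ampa_stn_gpe, label = label),
            class = "stngpe_state_point")
}

#' Reference state points of the model
#'
#' `normal_state()` is the regime matching healthy basal-ganglia activity
#' (high GPe intrinsic drive, moderate coupling); `parkinsonian_state()`
#' is the dopamine-depleted regime (no intrinsic drive, doubled GPe->STN
#' inhibition, strengthened STN->GPe excitation) that sustains 8-15 Hz
#' oscillatory bursting.
#'
#' @return A [state_point()].
#' @export
normal_state <- function() {
  state_point(g_ampa_gpe_int = 1.125, g_gaba_gpe_stn = 3.65,
              g_ampa_stn_gpe = 1.05, label = "normal")
}

#' @rdname normal_state
#' @export
parkinsonian_state <- function() {
  state_point(g_ampa_gpe_int = 0.0, g_gaba_gpe_stn = 7.3,
              g_ampa_stn_gpe = 1.35, label = "parkinsonian")
}

apply_state_point <- function(config, point) {
  config$g_ampa_gpe_int <- point$g_ampa_gpe_int
  config$g_gaba_gpe_stn <- point$g_gaba_gpe_stn
  config$g_ampa_stn_gpe <- point$g_ampa_stn_gpe
  config
}

# deterministic replicate seed derivation (kept below 2^31)
replicate_seed <- function(base_seed, replicate, stream = 0L) {
  (as.integer(base_seed) %% 100000L) * 10000L + replicate * 10L + stream
}

#' Simulate and analyse one network state point
#'
#' Builds `n_replicates` independent network realisations (distinct graph
#' and noise seeds derived from `seed`), simulates each, computes
#' per-neuron metrics over the analysis epoch, and pools them into a
#' population summary.
#'
#' @param point A [state_point()].
#' @param n_replicates Number of independent simulations.
#' @param seed Base seed.
#' @param config Network configuration template (conductances are
#'   overridden by `point`).
#' @param duration_ms,warmup_ms,dt Simulation epoch parameters.
#' @param n_shuffle Surrogates per neuron PSD.
#' @param keep_spikes Retain the spike rasters of all replicates.
#' @return An object of class `stngpe_state_result`: list with `summary`
#'   (pooled [summarize_population()]), `metrics` (per neuron, with
#'   replicate labels), `point`, `seeds`, and optionally `rasters`.
#' @export
run_state_point <- function(point, n_replicates = 8, seed = 1,
                            config = network_config(),
                            duration_ms = 11000, warmup_ms = 1000,
                            dt = 0.025, n_shuffle = 50,
                            keep_spikes = FALSE) {
  config <- apply_state_point(config, point)
  epoch <- c(warmup_ms, duration_ms)
  metrics <- vector("list", n_replicates)
  rasters <- if (keep_spikes) vector("list", n_replicates) else NULL
  seeds <- integer(n_replicates)
  for (k in seq_len(n_replicates)) {
    gseed <- replicate_seed(seed, k, 0L)
    seeds[k] <- gseed
    net <- build_network(config, seed = gseed)
    sim <- simulation_config(dt = dt, duration_ms = duration_ms,
                             warmup_ms = warmup_ms,
                             seed = replicate_seed(seed, k, 1L))
    res <- simulate_network(net, sim)
    metrics[[k]] <- neuron_metrics(res$spikes, epoch,
                                   n_shuffle = n_shuffle,
                                   seed = replicate_seed(seed, k, 2L),
                                   replicate = k)
    if (keep_spikes) rasters[[k]] <- res$spikes
  }
  metrics <- dplyr::bind_rows(metrics)
  structure(list(summary = summarize_population(metrics),
                 metrics = metrics, point = point, seeds = seeds,
                 rasters = rasters),
            class = "stngpe_state_result")
}

#' Sweep the conductance plane
#'
#' Runs [run_state_point()] on a rectangular grid over the GPe intrinsic
#' conductance and the GPe->STN conductance (optionally crossed with
#' several STN->GPe conductances) and collects the per-point summaries —
#' the data behind state-space contour maps.
#'
#' @param g_gaba_values,g_int_values,g_stn_gpe_values Grid axes (nS).
#' @param n_replicates Replicates per grid point.
#' @param seed Base seed (varied per point).
#' @param ... Passed to [run_state_point()].
#' @return Tibble of class `stngpe_sweep`: one row per population per grid
#'   point with the summary statistics.
#' @export
run_sweep <- function(g_gaba_values, g_int_values, g_stn_gpe_values = 1.35,
                      n_replicates = 8, seed = 1, ...) {
  grid <- expand.grid(g_gaba_gpe_stn = g_gaba_values,
                      g_ampa_gpe_int = g_int_values,
                      g_ampa_stn_gpe = g_stn_gpe_values)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    pt <- state_point(grid$g_ampa_gpe_int[i], grid$g_gaba_gpe_stn[i],
                      grid$g_ampa_stn_gpe[i],
                      label = sprintf("grid_%03d", i))
    res <- tryCatch(
      run_state_point(pt, n_replicates = n_replicates,
                      seed = seed + 131L * i, ...),
      error = function(e) NULL)
    if (is.null(res)) return(tibble())
    mutate(res$summary,
           g_gaba_gpe_stn = grid$g_gaba_gpe_stn[i],
           g_ampa_gpe_int = grid$g_ampa_gpe_int[i],
           g_ampa_stn_gpe = grid$g_ampa_stn_gpe[i])
  })
  class(out) <- c("stngpe_sweep", class(out))
  out
}

#' Sweep the strength of cortical background input
#'
#' Repeats a state point under different maximal conductances of the
#' tonic cortical AMPA input to STN neurons. In the dopamine-depleted
#' regime, reducing this background excitation strengthens 8-15 Hz STN
#' oscillations, because tonic depolarisation antagonises the
#' hyperpolarisation needed for rebound bursting.
#'
#' @param g_ctx_values Background conductances (nS).
#' @param point State point (default parkinsonian).
#' @param n_replicates,seed,... Passed to [run_state_point()].
#' @return Tibble: per-population summary per background strength.
#' @export
run_background_input_sweep <- function(g_ctx_values,
                                       point = parkinsonian_state(),
                                       n_replicates = 8, seed = 1, ...) {
  purrr::map_dfr(seq_along(g_ctx_values), function(i) {
    cfg <- network_config(g_ampa_ctx_stn = g_ctx_values[i])
    res <- run_state_point(point, n_replicates = n_replicates,
                           seed = seed, config = cfg, ...)
    mutate(res$summary, g_ampa_ctx_stn = g_ctx_values[i])
  })
}

#' Phasic cortical stimulation experiment
#'
#' Raises the cortical drive to `peak_rate_hz` for 1 s and compares the
#' 8-15 Hz band power of every STN and GPe neuron across three 1-s
#' windows: before onset, just after onset, and 1 s after onset, each
#' normalised to the before-window. Paired statistics follow the
#' convention for this protocol: a Friedman rank-sum test across the three
#' windows and pairwise Wilcoxon signed-rank tests.
#'
#' @param point State point.
#' @param peak_rate_hz Stimulation rate (Hz).
#' @param n_replicates,seed Replication controls.
#' @param config Network configuration.
#' @param warmup_ms Discarded warm-up (ms); stimulation onset is
#'   `warmup_ms + 1000`.
#' @param n_shuffle Surrogates per window PSD.
#' @return List of class `stngpe_pt_result`: `power` (per neuron per
#'   window, normalised), `tests` (Friedman and pairwise Wilcoxon p-values
#'   per population), `onset_ms`.
#' @export
run_pt_experiment <- function(point = parkinsonian_state(),
                              peak_rate_hz = 1000, n_replicates = 2,
                              seed = 1, config = network_config(),
                              warmup_ms = 1000, n_shuffle = 50) {
  config <- apply_state_point(config, point)
  onset <- warmup_ms + 1000
  duration <- onset + 2000
  windows <- list(before = c(onset - 1000, onset),
                  just_after = c(onset, onset + 1000),
                  after_1s = c(onset + 1000, onset + 2000))
  rows <- purrr::map_dfr(seq_len(n_replicates), function(k) {
    net <- build_network(config, seed = replicate_seed(seed, k, 0L))
    sim <- simulation_config(duration_ms = duration, warmup_ms = warmup_ms,
                             seed = replicate_seed(seed, k, 1L))
    sim <- apply_pt_stimulation(sim, onset, 1000, peak_rate_hz,
                                baseline_hz = config$ctx_rate_hz)
    res <- simulate_network(net, sim)
    by_neuron <- split(res$spikes$time_ms,
                       list(res$spikes$population, res$spikes$neuron),
                       drop = TRUE)
    purrr::imap_dfr(by_neuron, function(tr, key) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      pw <- vapply(windows, function(w)
        window_band_power(tr, w, n_shuffle = n_shuffle,
                          seed = replicate_seed(seed, k, 3L)),
        numeric(1))
      tibble(replicate = k, population = parts[1],
             neuron = as.integer(parts[2]),
             window = names(windows), power = unname(pw),
             norm_power = unname(pw) / pw[["before"]])
    })
  })
  wide <- rows |>
    tidyr::pivot_wider(names_from = "window",
                       values_from = c("power", "norm_power"))
  wide <- wide[stats::complete.cases(
    wide[, c("norm_power_before", "norm_power_just_after",
             "norm_power_after_1s")]), ]
  tests <- purrr::map_dfr(split(wide, wide$population), function(d) {
    m <- as.matrix(d[, c("norm_power_before", "norm_power_just_after",
                         "norm_power_after_1s")])
    tibble(population = d$population[1], n = nrow(d),
           friedman_p = friedman.test(m)$p.value,
           wilcoxon_before_vs_after_p = wilcox.test(
             m[, 1], m[, 2], paired = TRUE)$p.value,
           median_norm_just_after = median(m[, 2]))
  })
  structure(list(power = rows, tests = tests, onset_ms = onset,
                 peak_rate_hz = peak_rate_hz, point = point),
            class = "stngpe_pt_result")
}

#' Feedback-delay sweep of the cortico-STN loop
#'
#' Adds STN->STN delay lines that abstract the STN-GPi-thalamus-cortex
#' loop and measures, per delay, the pooled STN 8-15 Hz peak power
#' alongside a no-feedback control. Delays near the oscillation cycle
#' (60-80 ms in the parkinsonian regime) amplify the oscillation; others
#' suppress it.
#'
#' @param delays_ms Feedback delays (ms); `NA` encodes the no-feedback
#'   control.
#' @param point State point.
#' @param n_replicates,seed Replication controls.
#' @param config Network configuration.
#' @param with_background Keep the tonic cortical background input.
#' @param ... Passed to [run_state_point()]-style internals (duration etc.).
#' @param duration_ms,warmup_ms Epoch.
#' @param n_shuffle Surrogates per PSD.
#' @return Tibble: per delay condition, pooled STN metrics (mean peak
#'   power, sd, n) plus the per-neuron metrics in attribute `"metrics"`.
#' @export
run_feedback_delay_sweep <- function(delays_ms, point = parkinsonian_state(),
                                     n_replicates = 8, seed = 1,
                                     config = network_config(),
                                     with_background = TRUE,
                                     duration_ms = 11000, warmup_ms = 1000,
                                     n_shuffle = 50) {
  config <- apply_state_point(config, point)
  if (!with_background) config$g_ampa_ctx_stn <- 0
  epoch <- c(warmup_ms, duration_ms)
  all_metrics <- purrr::map_dfr(seq_along(delays_ms), function(d) {
    delay <- delays_ms[d]
    purrr::map_dfr(seq_len(n_replicates), function(k) {
      net <- build_network(config, seed = replicate_seed(seed, k, 0L))
      fb <- NULL
      if (!is.na(delay))
        fb <- build_feedback_loop(config$n_stn, delay_ms = delay,
                                  gmax = network_config()$g_ampa_ctx_stn,
                                  seed = replicate_seed(seed, k, 4L))
      sim <- simulation_config(duration_ms = duration_ms,
                               warmup_ms = warmup_ms,
                               seed = replicate_seed(seed, k, 1L))
      res <- simulate_network(net, sim, feedback = fb)
      m <- neuron_metrics(res$spikes, epoch, n_shuffle = n_shuffle,
                          seed = replicate_seed(seed, k, 2L),
                          replicate = k)
      mutate(filter(m, .data$population == "STN"), delay_ms = delay)
    })
  })
  out <- all_metrics |>
    group_by(.data$delay_ms) |>
    summarise(n = n(),
              peak_power_mean = mean(.data$peak_power),
              peak_power_sd = sd(.data$peak_power),
              pct_oscillatory = 100 * mean(.data$oscillatory),
              .groups = "drop")
  attr(out, "metrics") <- all_metrics
  out
}
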