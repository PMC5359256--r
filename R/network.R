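# Construction of the random sparse STN-GPe graph.

#' Configuration of the STN-GPe network
#'
#' Population sizes, in-degrees, delays, contact-count distribution,
#' maximal conductances and input rates of the recurrent circuit. Defaults
#' are the reference network: 64 STN and 192 GPe neurons, 12 GPe afferents
#' per STN neuron, 6 STN afferents per GPe neuron, 5-ms conduction delays,
#' and log-normally distributed GABAergic contact counts.
#'
#' @param n_stn,n_gpe Population sizes.
#' @param gpe_stn_indegree GABAergic afferents per STN neuron.
#' @param stn_gpe_indegree Glutamatergic afferents per GPe neuron.
#' @param delay_ms Axonal conduction delay of both pathways (ms).
#' @param contact_mean,contact_sd Mean and SD of the log-normal distribution
#'   of synaptic contacts per unitary GPe projection (of the variate itself,
#'   not of its logarithm).
#' @param g_gaba_gpe_stn Maximal conductance of a GPe->STN GABAergic contact
#'   (nS).
#' @param g_ampa_stn_gpe Maximal conductance of an STN->GPe synapse (nS).
#' @param g_ampa_gpe_int Maximal conductance of the GPe intrinsic noisy
#'   conductance (nS); the dopamine-depletion control parameter.
#' @param g_ampa_ctx_stn Maximal conductance of the cortical background
#'   AMPA input to STN neurons (nS).
#' @param ctx_rate_hz Mean rate of the cortical background Poisson train.
#' @param gpe_int_rate_hz Mean rate of the intrinsic pseudo spike train.
#' @param gpe_int_scale Amplitude scale of intrinsic pseudo-synaptic events
#'   relative to `g_ampa_gpe_int`. The intrinsic conductance stands in for
#'   autonomous pacemaking whose absolute drive is not printed alongside the
#'   kernel form; this scale is calibrated once so that the reference normal
#'   state reproduces the published pallidal firing rate, and all experiments
#'   share it.
#' @param peak_normalize Scale synaptic kernels so each event's peak equals
#'   its configured amplitude (the convention of common simulator synapse
#'   models and the package default; `FALSE` uses the literal
#'   difference-of-exponentials amplitudes).
#' @param per_contact_release Draw a binomial number of released contacts
#'   per GPe spike, each contributing a full-amplitude conductance
#'   increment; `FALSE` collapses the projection to a single Bernoulli(P)
#'   release.
#' @param stp_types Plasticity-type table, see [stp_type_table()].
#' @param f_bound Facilitation upper bound of the STN->GPe model.
#' @param depression Depression constants (list with `tau_d, f_d, p_bound,
#'   n_bound`); defaults to the package calibration.
#' @return An object of class `stngpe_config`.
#' @export
network_config <- function(n_stn = 64, n_gpe = 192,
                           gpe_stn_indegree = 12, stn_gpe_indegree = 6,
                           delay_ms = 5,
                           contact_mean = 15.50, contact_sd = 14.53,
                           g_gaba_gpe_stn = 3.65, g_ampa_stn_gpe = 1.05,
                           g_ampa_gpe_int = 1.125, g_ampa_ctx_stn = 1.0,
                           ctx_rate_hz = 100, gpe_int_rate_hz = 100,
                           gpe_int_scale = 1.45,
                           peak_normalize = TRUE,
                           per_contact_release = TRUE,
                           stp_types = stp_type_table(),
                           f_bound = 4.6,
                           depression = dep_defaults) {
  if (gpe_stn_indegree > n_gpe || stn_gpe_indegree > n_stn)
    abort("in-degrees cannot exceed the source-population size")
  rates_g <- c(g_gaba_gpe_stn, g_ampa_stn_gpe, g_ampa_gpe_int,
               g_ampa_ctx_stn, ctx_rate_hz, gpe_int_rate_hz)
  if (any(rates_g < 0)) abort("rates and conductances must be >= 0")
  structure(list(n_stn = n_stn, n_gpe = n_gpe,
                 gpe_stn_indegree = gpe_stn_indegree,
                 stn_gpe_indegree = stn_gpe_indegree,
                 delay_ms = delay_ms,
                 contact_mean = contact_mean, contact_sd = contact_sd,
                 g_gaba_gpe_stn = g_gaba_gpe_stn,
                 g_ampa_stn_gpe = g_ampa_stn_gpe,
                 g_ampa_gpe_int = g_ampa_gpe_int,
                 g_ampa_ctx_stn = g_ampa_ctx_stn,
                 ctx_rate_hz = ctx_rate_hz,
                 gpe_int_rate_hz = gpe_int_rate_hz,
                 gpe_int_scale = gpe_int_scale,
                 peak_normalize = peak_normalize,
                 per_contact_release = per_contact_release,
                 stp_types = stp_types, f_bound = f_bound,
                 depression = depression),
            class = "stngpe_config")
}

#' Moment-matched log-normal parameters for contact counts
#'
#' Converts the mean and SD of the contact-count variate into the location
#' and scale of the underlying normal distribution of its logarithm.
#'
#' @param mean,sd Mean and standard deviation of the log-normal variate.
#' @return List with `mu_log` and `sigma_log`.
#' @export
contact_lognormal_params <- function(mean = 15.50, sd = 14.53) {
  if (mean <= 0 || sd <= 0) abort("mean and sd must be > 0")
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu_log = log(mean) - sigma2 / 2, sigma_log = sqrt(sigma2))
}

#' Sample synaptic contact counts of unitary GPe projections
#'
#' Draws from the moment-matched log-normal distribution, rounds to the
#' nearest integer and floors at 1. Uses the current R random number stream.
#'
#' @param n Number of projections.
#' @param mean,sd Target mean and SD of the (pre-rounding) distribution.
#' @return Integer counts (>= 1) with the pre-rounding draws in attribute
#'   `"raw"`.
#' @export
sample_contact_counts <- function(n, mean = 15.50, sd = 14.53) {
  if (n < 1) abort("n must be >= 1")
  lp <- contact_lognormal_params(mean, sd)
  raw <- stats::rlnorm(n, lp$mu_log, lp$sigma_log)
  counts <- pmax(1L, as.integer(round(raw)))
  attr(counts, "raw") <- raw
  counts
}

#' Assign short-term plasticity types to STN to GPe projections
#'
#' Each projection is labelled type 1, 2 or 3 independently with equal
#' probability, irrespective of its postsynaptic neuron.
#'
#' @param projections Tibble of STN->GPe projections (must not carry
#'   GABAergic contact counts).
#' @param seed Optional seed applied to the R random number stream.
#' @return The tibble with an integer `stp_type` column.
#' @export
assign_stp_types <- function(projections, seed = NULL) {
  if ("n_contact" %in% names(projections))
    abort("plasticity types apply to STN->GPe projections only")
  if (!is.null(seed)) set.seed(seed)
  projections$stp_type <- sample.int(3L, nrow(projections), replace = TRUE)
  projections
}

#' Build a random sparse STN-GPe network
#'
#' Samples, for every STN neuron, its fixed number of distinct GPe
#' afferents (each a unitary projection with a log-normal contact count)
#' and, for every GPe neuron, its fixed number of distinct STN afferents
#' (each a single-contact synapse with a random plasticity type). Sampling
#' is without replacement, so no source-target pair is duplicated.
#'
#' @param config A [network_config()].
#' @param seed Integer seed; the graph depends on nothing else.
#' @return An object of class `stngpe_network`: list with the `config`, the
#'   `gpe_to_stn` tibble (`source`, `target`, `n_contact`, `delay_ms`), the
#'   `stn_to_gpe` tibble (`source`, `target`, `stp_type`, `delay_ms`) and
#'   the `seed`.
#' @export
build_network <- function(config = network_config(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gs <- purrr::map_dfr(seq_len(config$n_stn), function(tgt) {
    tibble(source = sample.int(config$n_gpe, config$gpe_stn_indegree),
           target = tgt)
  })
  gs$n_contact <- sample_contact_counts(nrow(gs), config$contact_mean,
                                        config$contact_sd)
  attr(gs$n_contact, "raw") <- NULL
  gs$delay_ms <- config$delay_ms
  sg <- purrr::map_dfr(seq_len(config$n_gpe), function(tgt) {
    tibble(source = sample.int(config$n_stn, config$stn_gpe_indegree),
           target = tgt)
  })
  sg <- assign_stp_types(sg)
  sg$delay_ms <- config$delay_ms
  structure(list(config = config, gpe_to_stn = gs, stn_to_gpe = sg,
                 seed = seed),
            class = "stngpe_network")
}

# save/restore the global RNG state so builders are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Validate the structural invariants of a network
#'
#' Checks in-degrees, duplicate projections, and contact-count positivity.
#'
#' @param network A [build_network()] result.
#' @return `TRUE` invisibly; aborts on violation.
#' @export
validate_network <- function(network) {
  cfg <- network$config
  gs <- network$gpe_to_stn
  sg <- network$stn_to_gpe
  deg_gs <- table(factor(gs$target, levels = seq_len(cfg$n_stn)))
  if (any(deg_gs != cfg$gpe_stn_indegree))
    abort("every STN neuron must have exactly the configured GPe in-degree")
  deg_sg <- table(factor(sg$target, levels = seq_len(cfg$n_gpe)))
  if (any(deg_sg != cfg$stn_gpe_indegree))
    abort("every GPe neuron must have exactly the configured STN in-degree")
  if (anyDuplicated(gs[, c("source", "target")]) ||
      anyDuplicated(sg[, c("source", "target")]))
    abort("duplicated source->target projection")
  if (any(gs$n_contact < 1)) abort("all contact counts must be >= 1")
  invisible(TRUE)
}

#' Fraction of reciprocally connected STN to GPe projections
#'
#' The proportion of STN->GPe projections whose target GPe neuron projects
#' back onto the source STN neuron.
#'
#' @param network A [build_network()] result.
#' @return A proportion in `[0, 1]`.
#' @export
reciprocal_fraction <- function(network) {
  gs_keys <- paste(network$gpe_to_stn$source, network$gpe_to_stn$target)
  sg_back <- paste(network$stn_to_gpe$target, network$stn_to_gpe$source)
  mean(sg_back %in% gs_keys)
}

#' Rewire the proportion of reciprocal STN-GPe pairs
#'
#' Adjusts the reciprocal fraction by degree-preserving swaps on the
#' STN->GPe edge set only (the GPe->STN edges are untouched), so all
#' in-degrees and the connection probability stay fixed. Swaps are accepted
#' when they move the realised fraction toward the requested one.
#'
#' @param network A [build_network()] result.
#' @param fraction Requested reciprocal fraction in `[0, 1]`.
#' @param seed Seed for the swap sequence.
#' @param max_iter Swap-attempt budget.
#' @return The rewired network; aborts with the feasible range when the
#'   requested fraction cannot be reached within one edge.
#' @export
rewire_reciprocal_fraction <- function(network, fraction, seed = 1,
                                       max_iter = 200000) {
  if (fraction < 0 || fraction > 1) abort("fraction must lie in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sg <- network$stn_to_gpe
  n_edge <- nrow(sg)
  gs_keys <- paste(network$gpe_to_stn$source, network$gpe_to_stn$target)
  is_recip <- function(src, tgt) paste(tgt, src) %in% gs_keys
  recip <- is_recip(sg$source, sg$target)
  target_n <- fraction * n_edge
  tol <- 1.0  # within one edge
  it <- 0
  while (abs(sum(recip) - target_n) > tol && it < max_iter) {
    it <- it + 1
    i <- sample.int(n_edge, 1)
    j <- sample.int(n_edge, 1)
    if (i == j || sg$target[i] == sg$target[j]) next
    # proposed swap: sources exchanged between the two target GPe neurons
    s_i <- sg$source[i]; s_j <- sg$source[j]
    if (s_i == s_j) next
    # no duplicate edges after swap
    if (any(sg$source == s_j & sg$target == sg$target[i]) ||
        any(sg$source == s_i & sg$target == sg$target[j])) next
    new_ri <- is_recip(s_j, sg$target[i])
    new_rj <- is_recip(s_i, sg$target[j])
    delta <- (new_ri + new_rj) - (recip[i] + recip[j])
    gap <- sum(recip) - target_n
    if ((gap < 0 && delta > 0) || (gap > 0 && delta < 0)) {
      sg$source[i] <- s_j; sg$source[j] <- s_i
      recip[i] <- new_ri; recip[j] <- new_rj
    }
  }
  if (abs(sum(recip) - target_n) > tol) {
    feas <- feasible_reciprocal_range(network)
    abort(sprintf(
      "requested reciprocal fraction %.3f not reachable (achieved %.3f); feasible range is about [%.3f, %.3f]",
      fraction, mean(recip), feas[1], feas[2]))
  }
  network$stn_to_gpe <- sg
  validate_network(network)
  network
}

# upper bound: each GPe neuron can host at most min(indegree, #STN targets
# of its own outgoing projections) reciprocal edges
feasible_reciprocal_range <- function(network) {
  cfg <- network$config
  gs <- network$gpe_to_stn
  out_by_gpe <- table(factor(gs$source, levels = seq_len(cfg$n_gpe)))
  upper <- sum(pmin(as.integer(out_by_gpe), cfg$stn_gpe_indegree)) /
    nrow(network$stn_to_gpe)
  c(0, upper)
}

#' Scale the network size at fixed in-degrees
#'
#' Multiplies both population sizes while holding per-neuron in-degrees
#' constant, so pairwise connection probability falls by the same factor —
#' the sparseness manipulation.
#'
#' @param config A [network_config()].
#' @param factor Positive integer scale factor.
#' @return The scaled configuration.
#' @export
scale_network <- function(config, factor) {
  if (factor != round(factor) || factor < 1)
    abort("factor must be a positive integer")
  config$n_stn <- config$n_stn * factor
  config$n_gpe <- config$n_gpe * factor
  config
}

#' Build cortico-STN feedback delay lines
#'
#' Abstracts the STN-GPi-thalamus-cortex loop as direct STN->STN delay
#' lines: each STN neuron is connected from afferent STN neurons sampled so
#' the mean afferent count matches `n_afferent`; each presynaptic spike is
#' transmitted independently with probability `p_transmit` and arrives after
#' `delay_ms` as an AMPA event of the background-input strength.
#'
#' @param n_stn STN population size.
#' @param n_afferent Mean number of afferent delay lines per neuron.
#' @param p_transmit Per-spike transmission probability.
#' @param delay_ms Loop delay (ms).
#' @param gmax Synaptic strength (nS); by convention equal to the background
#'   cortical input strength.
#' @param seed Sampling seed.
#' @return Tibble with `source`, `target`, `delay_ms`, `gmax` and attribute
#'   `p_transmit`.
#' @export
build_feedback_loop <- function(n_stn = 64, n_afferent = 16,
                                p_transmit = 0.25, delay_ms = 70,
                                gmax = 1.0, seed = 1) {
  if (n_afferent > n_stn - 1) abort("n_afferent cannot exceed n_stn - 1")
  if (delay_ms <= 0) abort("delay must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p_edge <- n_afferent / (n_stn - 1)
  pairs <- expand.grid(source = seq_len(n_stn), target = seq_len(n_stn))
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p_edge
  out <- as_tibble(pairs[keep, ])
  out$delay_ms <- delay_ms
  out$gmax <- gmax
  attr(out, "p_transmit") <- p_transmit
  out
}

#' Export a network as an edge-list TSV
#'
#' One row per projection (`source_pop, source_id, target_pop, target_id,
#' delay_ms, attr`), where `attr` is the contact count of GPe->STN
#' projections or the plasticity type of STN->GPe projections. The
#' configuration and seed travel in a JSON header comment.
#'
#' @param network A [build_network()] result.
#' @param path Output file.
#' @export
write_network_tsv <- function(network, path) {
  gs <- network$gpe_to_stn
  sg <- network$stn_to_gpe
  edges <- rbind(
    data.frame(source_pop = "GPe", source_id = gs$source,
               target_pop = "STN", target_id = gs$target,
               delay_ms = gs$delay_ms, attr = gs$n_contact),
    data.frame(source_pop = "STN", source_id = sg$source,
               target_pop = "GPe", target_id = sg$target,
               delay_ms = sg$delay_ms, attr = sg$stp_type))
  hdr <- sprintf("# %s", jsonlite::toJSON(
    c(network$config[c("n_stn", "n_gpe", "gpe_stn_indegree",
                       "stn_gpe_indegree")], list(seed = network$seed)),
    auto_unbox = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(edges, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_network_tsv()]
#'
#' @param path Edge-list TSV file.
#' @param config The [network_config()] the edge list belongs to.
#' @return An `stngpe_network`.
#' @export
read_network_tsv <- function(path, config = network_config()) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  edges <- read.delim(text = paste(body, collapse = "\n"))
  gs <- edges[edges$source_pop == "GPe", ]
  sg <- edges[edges$source_pop == "STN", ]
  structure(list(
    config = config,
    gpe_to_stn = tibble(source = gs$source_id, target = gs$target_id,
                        n_contact = as.integer(gs$attr),
                        delay_ms = gs$delay_ms),
    stn_to_gpe = tibble(source = sg$source_id, target = sg$target_id,
                        stp_type = as.integer(sg$attr),
                        delay_ms = sg$delay_ms),
    seed = NA_integer_), class = "stngpe_network")
}
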