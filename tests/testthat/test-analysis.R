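# Spike-train analysis: binning, surrogates, compensated spectra,
# classification, phases, bursts, summaries.

test_that("binning follows the floor convention and clips doubled bins", {
  expect_true(all(bin_spike_train(numeric(), c(0, 100)) == 0))
  x <- bin_spike_train(10.4, c(0, 100))
  expect_equal(which(x == 1), 11)  # bin index 10 zero-based
  expect_length(x, 100)
  x2 <- bin_spike_train(c(50.1, 50.4), c(0, 100))
  expect_equal(sum(x2), 1)
  expect_equal(attr(x2, "clipped"), 1)
  expect_error(bin_spike_train(1, c(10, 10)), "empty")
})

test_that("local shuffling preserves spike counts and the slow rate profile", {
  set.seed(21)
  tr <- modulated_poisson_train(20, 20000, mod_freq_hz = 0.5, depth = 0.9)
  for (m in c("uniform", "isi")) {
    s <- local_shuffle(tr, c(0, 20000), method = m)
    expect_length(s, length(tr))
    expect_true(all(s >= 0 & s <= 20000))
  }
  # 500-ms-smoothed rate of surrogates tracks the original
  smooth_counts <- function(t) {
    as.numeric(table(cut(t, seq(0, 20000, by = 500))))
  }
  orig <- smooth_counts(tr)
  surr <- rowMeans(replicate(50, smooth_counts(local_shuffle(tr, c(0, 20000)))))
  expect_gt(cor(orig, surr), 0.95)
})

test_that("ISI permutation of an equal-interval train is identity up to boundaries", {
  tr <- seq(10, 9990, by = 20)
  set.seed(3)
  s <- local_shuffle(tr, c(0, 10000), method = "isi")
  # all intervals equal -> permuting them preserves the comb inside windows
  expect_equal(length(s), length(tr))
  isis <- diff(s)
  expect_gt(mean(abs(isis - 20) < 1e-9), 0.7)
})

test_that("compensated PSD of a Poisson train is flat with band mean near 1", {
  tr <- poisson_train(20, 10000, seed = 31)
  psd <- compensated_psd(tr, c(0, 10000), seed = 32)
  inb <- psd$frequency >= 8 & psd$frequency <= 15
  expect_gt(mean(psd$density[inb]), 0.8)
  expect_lt(mean(psd$density[inb]), 1.2)
  broad <- psd$frequency >= 20 & psd$frequency <= 250
  expect_gt(mean(psd$density[broad]), 0.9)
  expect_lt(mean(psd$density[broad]), 1.1)
  # determinism: identical train and seed give identical results
  psd2 <- compensated_psd(tr, c(0, 10000), seed = 32)
  expect_identical(psd$density, psd2$density)
  expect_error(compensated_psd(c(1), c(0, 1000)), "fewer than 2")
})

test_that("a 14-Hz rate-modulated train peaks at the 14-Hz bin", {
  hits <- 0
  for (k in 1:10) {
    tr <- modulated_poisson_train(20, 10000, 14, 0.8, seed = 40 + k)
    psd <- compensated_psd(tr, c(0, 10000), seed = k)
    inb <- psd$frequency >= 8 & psd$frequency <= 15
    pk <- psd$frequency[inb][which.max(psd$density[inb])]
    hits <- hits + (abs(pk - 14) <= 1000 / 2048 + 1e-9)
  }
  expect_gte(hits, 9)
})

test_that("the confidence level follows the one-sided normal construction", {
  d <- tibble::tibble(frequency = seq(270, 300, length.out = 31),
                      density = rep(2, 31))
  expect_equal(confidence_level(d), 2)
  set.seed(5)
  vals <- rnorm(31, 1, 0.1)
  d2 <- tibble::tibble(frequency = seq(270, 300, length.out = 31),
                       density = vals)
  expect_equal(confidence_level(d2),
               mean(vals) + qnorm(0.99) * sd(vals))
  expect_equal(confidence_level(d2, p = 0.5), mean(vals))
  expect_error(confidence_level(d2, reference_band = c(400, 500)),
               "no frequency bins")
})

test_that("oscillatory classification needs two adjacent supra-threshold bins", {
  freq <- 1:300
  base <- tibble::tibble(frequency = freq, density = rep(1, 300))
  lone <- base; lone$density[12] <- 5
  expect_false(classify_oscillatory(lone, c(8, 15), level = 2))
  expect_false(classify_oscillatory(base, c(8, 15), level = 2))
  trio <- base; trio$density[13:15] <- 5
  expect_true(classify_oscillatory(trio, c(8, 15), level = 2))
  outside <- base; outside$density[30:40] <- 5
  expect_false(classify_oscillatory(outside, c(8, 15), level = 2))
})

test_that("cross-spectral phase obeys the shift theorem with the stated sign", {
  tr <- modulated_poisson_train(25, 12000, 14.4, 0.9, seed = 55)
  delayed <- tr + 17
  csd <- compensated_csd(tr, delayed, c(0, 12000), seed = 56)
  expect_true(attr(csd, "correlated"))
  pd <- phase_difference(csd)
  expected <- 360 * pd$frequency * 0.017
  expect_lt(abs(pd$phase_deg - expected), 15)
  expect_gt(pd$phase_deg, 0)  # b lagging a is positive by convention
  expect_equal(pd$lag_ms, pd$phase_deg / 360 / pd$frequency * 1000)
  # identical trains: zero phase at the peak bin
  csd0 <- compensated_csd(tr, tr, c(0, 12000), seed = 57)
  pd0 <- phase_difference(csd0)
  expect_lt(abs(pd0$phase_deg), 1)
})

test_that("independent Poisson pairs are rarely classified as correlated", {
  flags <- vapply(1:60, function(k) {
    a <- poisson_train(20, 10000, seed = 600 + k)
    b <- poisson_train(20, 10000, seed = 900 + k)
    isTRUE(attr(compensated_csd(a, b, c(0, 10000), seed = k), "correlated"))
  }, logical(1))
  expect_lte(mean(flags), 0.1)
})

test_that("Poisson surprise matches the closed-form tail probability", {
  expect_equal(poisson_surprise(10, 50, 2),
               -ppois(9, 2 * 0.05, lower.tail = FALSE, log.p = TRUE))
  # larger clusters in shorter windows are more surprising
  expect_gt(poisson_surprise(10, 50, 2), poisson_surprise(10, 500, 2))
  expect_gt(poisson_surprise(12, 50, 2), poisson_surprise(10, 50, 2))
})

test_that("a dense cluster in sparse background is detected as exactly one burst", {
  set.seed(61)
  background <- sort(runif(10, 0, 10000))
  cluster <- seq(5000, 5045, by = 5)  # 10 spikes in 45 ms
  train <- sort(c(background[background < 4900 | background > 5200],
                  cluster))
  bursts <- detect_bursts(train, epoch = c(0, 10000))
  expect_equal(nrow(bursts), 1)
  expect_lte(bursts$start_ms, 5000)
  expect_gte(bursts$end_ms, 5045)
  rate <- length(train) / 10
  expect_equal(bursts$surprise,
               poisson_surprise(bursts$n_spikes,
                                bursts$end_ms - bursts$start_ms, rate),
               tolerance = 1e-9)
  expect_gte(bursts$surprise, 3)
})

test_that("fewer than three spikes can never form a burst", {
  expect_equal(nrow(detect_bursts(c(100, 101), epoch = c(0, 1000))), 0)
  expect_equal(nrow(detect_bursts(numeric(), epoch = c(0, 1000))), 0)
})

test_that("burst-structured trains burst more than rate-matched Poisson trains", {
  set.seed(62)
  # 14-Hz burst structure: 3-spike bursts every ~71 ms
  onsets <- seq(0, 99900, by = 1000 / 14)
  bursty <- sort(unlist(lapply(onsets, function(o) o + c(0, 6, 12))))
  hom <- poisson_train(length(bursty) / 100, 100000, seed = 63)
  b1 <- detect_bursts(bursty, epoch = c(0, 1e5))
  b2 <- detect_bursts(hom, epoch = c(0, 1e5))
  expect_gt(nrow(b1), nrow(b2))
})

test_that("the detector recovers injected clusters at five-fold density", {
  set.seed(64)
  recovered <- 0; injected <- 0
  for (rep in 1:5) {
    bg <- poisson_train(4, 60000)
    onsets <- seq(3000, 57000, by = 3000)
    clusters <- lapply(onsets, function(o) o + cumsum(rexp(6, 1 / 50)))
    train <- sort(c(bg, unlist(clusters)))
    bursts <- detect_bursts(train, epoch = c(0, 60000))
    injected <- injected + length(onsets)
    for (o in seq_along(onsets)) {
      lo <- min(clusters[[o]]); hi <- max(clusters[[o]])
      hit <- any(bursts$start_ms <= hi & bursts$end_ms >= lo)
      recovered <- recovered + hit
    }
  }
  expect_gte(recovered / injected, 0.9)
})

test_that("population summaries pool replicate metrics correctly", {
  set.seed(65)
  spikes <- dplyr::bind_rows(
    tibble::tibble(population = "STN", neuron = 1L,
                   time_ms = sort(runif(300, 0, 10000))),
    tibble::tibble(population = "STN", neuron = 2L,
                   time_ms = sort(runif(150, 0, 10000))),
    tibble::tibble(population = "STN", neuron = 3L, time_ms = 5000))
  m <- neuron_metrics(spikes, c(0, 10000), n_shuffle = 10, seed = 1)
  expect_equal(nrow(m), 2)  # the single-spike neuron is excluded
  expect_equal(attr(m, "n_excluded"), 1L)
  s <- summarize_population(m)
  expect_equal(s$n_cells, 2)
  expect_equal(s$rate_mean, mean(c(30, 15)))
  # pooling a duplicated set leaves the means unchanged
  m2 <- dplyr::bind_rows(m, dplyr::mutate(m, replicate = 2L))
  s2 <- summarize_population(m2)
  expect_equal(s2$rate_mean, s$rate_mean)
  expect_equal(s2$pct_oscillatory, s$pct_oscillatory)
})
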