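# Random sparse network construction, contact counts, plasticity-type
# assignment, rewiring and scaling.

test_that("the default network has the expected projection counts and invariants", {
  net <- build_network(network_config(), seed = 1)
  expect_equal(nrow(net$gpe_to_stn), 64 * 12)
  expect_equal(nrow(net$stn_to_gpe), 192 * 6)
  expect_true(validate_network(net))
})

test_that("the same seed reproduces the identical graph", {
  a <- build_network(network_config(), seed = 7)
  b <- build_network(network_config(), seed = 7)
  expect_identical(a$gpe_to_stn, b$gpe_to_stn)
  expect_identical(a$stn_to_gpe, b$stn_to_gpe)
  c <- build_network(network_config(), seed = 8)
  expect_false(identical(a$gpe_to_stn, c$gpe_to_stn))
})

test_that("reciprocal pair frequency matches the random-convergence expectation", {
  # probability that an (STN, GPe) pair is connected in both directions
  hits <- 0; pairs <- 0
  for (s in 1:12) {
    net <- build_network(network_config(), seed = 100 + s)
    gs <- paste(net$gpe_to_stn$source, net$gpe_to_stn$target)
    sg <- paste(net$stn_to_gpe$target, net$stn_to_gpe$source)
    both <- intersect(gs, sg)
    hits <- hits + length(both)
    pairs <- pairs + 64 * 192
  }
  p_exp <- (12 / 192) * (6 / 64)
  se <- sqrt(p_exp * (1 - p_exp) / pairs)
  expect_lt(abs(hits / pairs - p_exp), 4 * se)
})

test_that("contact counts match the printed log-normal moments before rounding", {
  set.seed(5)
  counts <- sample_contact_counts(1e5)
  raw <- attr(counts, "raw")
  expect_lt(abs(mean(raw) - 15.50), 4 * sd(raw) / sqrt(1e5))
  expect_lt(abs(sd(raw) - 14.53) / 14.53, 0.03)
  expect_true(all(counts >= 1))
})

test_that("plasticity types are assigned uniformly and reproducibly", {
  proj <- tibble::tibble(source = rep(1:100, each = 100),
                         target = rep(1:100, times = 100))
  a <- assign_stp_types(proj, seed = 3)
  b <- assign_stp_types(proj, seed = 3)
  expect_identical(a$stp_type, b$stp_type)
  freq <- table(a$stp_type) / nrow(a)
  se <- sqrt((1 / 3) * (2 / 3) / nrow(a))
  expect_true(all(abs(freq - 1 / 3) < 4 * se))
  one <- assign_stp_types(proj[1, ], seed = 1)
  expect_length(one$stp_type, 1)
  net <- build_network(network_config(), seed = 1)
  expect_error(assign_stp_types(net$gpe_to_stn), "STN->GPe")
})

test_that("rewiring reaches the requested reciprocal fraction with degrees intact", {
  net <- build_network(network_config(), seed = 3)
  before <- reciprocal_fraction(net)
  expect_lt(before, 0.15)
  rewired <- rewire_reciprocal_fraction(net, 0.5, seed = 4)
  expect_lt(abs(reciprocal_fraction(rewired) - 0.5), 1 / 1152 + 1e-12)
  # degree histograms identical before and after
  expect_identical(table(rewired$stn_to_gpe$target),
                   table(net$stn_to_gpe$target))
  expect_identical(sort(table(rewired$stn_to_gpe$source)),
                   sort(table(net$stn_to_gpe$source)))
  # an unreachable fraction reports the feasible range
  expect_error(rewire_reciprocal_fraction(net, 1, seed = 4, max_iter = 5000),
               "feasible")
})

test_that("network scaling preserves in-degrees and halves connection probability", {
  cfg <- scale_network(network_config(), 2)
  expect_equal(cfg$n_stn, 128)
  expect_equal(cfg$n_gpe, 384)
  expect_equal(cfg$stn_gpe_indegree, 6)
  expect_equal(cfg$gpe_stn_indegree, 12)
  expect_identical(scale_network(network_config(), 1)$n_stn, 64)
  net <- build_network(cfg, seed = 2)
  # empirical pairwise STN->GPe connection probability = indegree / n_stn
  p_hat <- nrow(net$stn_to_gpe) / (cfg$n_stn * cfg$n_gpe)
  expect_equal(p_hat, 6 / 128)
  expect_error(scale_network(network_config(), 1.5), "integer")
})

test_that("feedback delay lines average the requested afferent count", {
  counts <- vapply(1:20, function(s) {
    fb <- build_feedback_loop(64, n_afferent = 16, seed = s)
    nrow(fb) / 64
  }, numeric(1))
  expect_lt(abs(mean(counts) - 16), 1)
  fb <- build_feedback_loop(64, delay_ms = 70, gmax = 1, seed = 1)
  expect_true(all(fb$delay_ms == 70))
  expect_equal(attr(fb, "p_transmit"), 0.25)
  expect_error(build_feedback_loop(10, n_afferent = 10), "n_afferent")
})

test_that("a network round-trips through the edge-list TSV format", {
  net <- build_network(network_config(), seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read_network_tsv(path, net$config)
  expect_equal(back$gpe_to_stn$source, net$gpe_to_stn$source)
  expect_equal(back$gpe_to_stn$n_contact, net$gpe_to_stn$n_contact)
  expect_equal(back$stn_to_gpe$stp_type, net$stn_to_gpe$stp_type)
  unlink(path)
})
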