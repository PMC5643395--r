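test_that("burst detection honours the photon-count and gap thresholds exactly", {
  # 49 photons, all gaps 100 us: below the size threshold
  s <- photon_stream((0:48) * 100, rep("D", 49))
  expect_equal(nrow(detect_bursts(s)), 0)
  # 50 photons: exactly at threshold -> one burst
  s <- photon_stream((0:49) * 100, rep("D", 50))
  bt <- detect_bursts(s)
  expect_equal(nrow(bt), 1)
  expect_equal(bt$n_donor_raw, 50)
  # a gap of exactly 120 us splits; 119.9 us does not
  t_split <- c((0:49) * 100, 4900 + 120 + (0:49) * 100)
  s <- photon_stream(t_split, rep("D", 100))
  expect_equal(nrow(detect_bursts(s)), 2)
  t_join <- c((0:49) * 100, 4900 + 119.9 + (0:49) * 100)
  s <- photon_stream(t_join, rep("D", 100))
  expect_equal(nrow(detect_bursts(s)), 1)
})

test_that("two well-separated clusters give two time-ordered disjoint bursts", {
  t1 <- (0:59) * 50
  t2 <- max(t1) + 1000 + (0:59) * 50
  s <- photon_stream(c(t1, t2), rep(c("D", "A"), 60))
  bt <- detect_bursts(s)
  expect_equal(nrow(bt), 2)
  expect_true(bt$end_us[1] < bt$start_us[2])
  expect_equal(bt$n_donor_raw + bt$n_acceptor_raw, c(60, 60))
})

test_that("burst detection agrees exactly with the independent reference clusterer", {
  for (seed in 1:50) {
    n <- sample(500:10000, 1)
    rs <- random_stream(n, seed)
    s <- photon_stream(rs$t_us, rs$channel)
    got <- detect_bursts(s, min_photons = 30, max_gap_us = 120)
    ref <- brute_force_bursts(rs$t_us, rs$channel, min_photons = 30,
                              max_gap_us = 120)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(got$start_us, ref$start_us)
    expect_equal(got$end_us, ref$end_us)
    expect_equal(got$n_donor_raw, ref$n_donor_raw)
    expect_equal(got$n_acceptor_raw, ref$n_acceptor_raw)
  }
})

test_that("isolated photons around a burst do not change it, and no photon is double-counted", {
  core <- 1e5 + (0:59) * 50
  s0 <- photon_stream(core, rep("D", 60))
  # prepend/append isolated photons separated by >= max_gap on both sides
  t <- c(10, 500, core, max(core) + 200, max(core) + 900)
  s1 <- photon_stream(t, rep("D", 64))
  b0 <- detect_bursts(s0); b1 <- detect_bursts(s1)
  expect_equal(b1$start_us, b0$start_us)
  expect_equal(b1$n_donor_raw, b0$n_donor_raw)
  # total photons in bursts never exceeds stream photons
  for (seed in 1:5) {
    rs <- random_stream(3000, seed + 100)
    bt <- detect_bursts(photon_stream(rs$t_us, rs$channel), 30, 120)
    expect_lte(sum(bt$n_donor_raw + bt$n_acceptor_raw), 3000)
  }
})

test_that("unsorted streams are rejected and empty streams give empty results", {
  expect_error(photon_stream(c(3, 1, 2), c("D", "D", "D")), "sorted")
  s <- photon_stream(numeric(0), character(0))
  expect_equal(nrow(detect_bursts(s)), 0)
})

test_that("per-burst proximity uses duration-scaled background and crosstalk", {
  bt <- structure(data.frame(start_us = c(0, 0), end_us = c(1e6, 1e6),
                             n_donor_raw = c(60, 70),
                             n_acceptor_raw = c(0, 30)),
                  class = c("burst_table", "data.frame"))
  expect_equal(burst_proximity(bt)$p, c(0, 0.3))
  # expected acceptor background: 3 counts/s over a 1-second burst
  bt <- structure(data.frame(start_us = 0, end_us = 1e6,
                             n_donor_raw = 70, n_acceptor_raw = 33),
                  class = c("burst_table", "data.frame"))
  out <- burst_proximity(bt, correction_set(bkg_acceptor = 3))
  expect_equal(out$p, 0.3)
  # zero corrected total is flagged and excluded
  bt <- structure(data.frame(start_us = 0, end_us = 1e6,
                             n_donor_raw = 2, n_acceptor_raw = 1),
                  class = c("burst_table", "data.frame"))
  expect_warning(out <- burst_proximity(bt, correction_set(bkg_donor = 2,
                                                           bkg_acceptor = 1)),
                 "excluded")
  expect_equal(nrow(out), 0)
})

test_that("histogram uses half-open 0.02 bins on [-0.1, 1.1) and normalises to 1", {
  h <- build_histogram(rep(0.5, 100))
  expect_equal(sum(h$counts), 100)
  hot <- which(h$counts > 0)
  expect_length(hot, 1)
  expect_equal(h$bin_lo[hot], 0.50)
  expect_equal(h$frequency[hot], 1)
  # left-closed edges: 0.00, 0.02, 0.04 land in three adjacent bins
  h <- build_histogram(c(0.0, 0.02, 0.04))
  expect_equal(sum(h$counts > 0), 3)
  expect_equal(h$frequency[h$counts > 0], rep(1 / 3, 3))
  expect_equal(diff(which(h$counts > 0)), c(1, 1))
  # out-of-range values accumulate in the edge bins
  h <- build_histogram(c(-5, 5))
  expect_equal(h$counts[1], 1)
  expect_equal(h$counts[length(h$counts)], 1)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-12)
})

test_that("uniform samples fill the [0,1) bins at the binomial-expected rate", {
  set.seed(202)
  n <- 1e4
  h <- build_histogram(runif(n))
  inside <- h$bin_lo >= 0 & h$bin_hi <= 1
  p <- 0.02 / 1          # each 0.02 bin captures 2% of a U[0,1) sample
  sigma <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(h$frequency[inside] - p) < 5 * sigma))
  # empty input: zero counts, flagged, NA frequencies
  h0 <- build_histogram(numeric(0))
  expect_true(h0$empty)
  expect_true(all(h0$counts == 0))
  expect_true(all(is.na(h0$frequency)))
})

test_that("photon streams round-trip through CSV/TSV files", {
  rs <- random_stream(500, 9)
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(timestamp_us = rs$t_us, channel = rs$channel), f,
            row.names = FALSE)
  s <- read_photon_stream(f)
  expect_equal(s$timestamp_us, rs$t_us)
  expect_equal(s$channel, rs$channel)
  unlink(f)
})
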