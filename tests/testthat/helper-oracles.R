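# Independent reference implementations used as oracles in the tests.
# They deliberately share no code with the package internals.

# Reference burst clustering: plain forward-scan loop over photons,
# growing a cluster while the next gap is < max_gap, then emitting it
# if it has >= min_photons members. Returns a data.frame like
# detect_bursts() (start, end, per-channel counts).
brute_force_bursts <- function(t_us, channel, min_photons = 50,
                               max_gap_us = 120) {
  n <- length(t_us)
  out <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && (t_us[j + 1] - t_us[j]) < max_gap_us) j <- j + 1
    if (j - i + 1 >= min_photons) {
      ch <- channel[i:j]
      out[[length(out) + 1]] <- data.frame(
        start_us = t_us[i], end_us = t_us[j],
        n_donor_raw = sum(ch == "D"), n_acceptor_raw = sum(ch == "A"))
    }
    i <- j + 1
  }
  if (!length(out))
    return(data.frame(start_us = numeric(0), end_us = numeric(0),
                      n_donor_raw = integer(0), n_acceptor_raw = integer(0)))
  do.call(rbind, out)
}

# Reference O(|A| x |B|) contact count for one frame of coordinates.
brute_force_contacts <- function(xyz, idx_a, idx_b, d_cut = 0.35) {
  cnt <- 0L
  for (a in idx_a) for (b in idx_b) {
    if (a == b) next
    if (sqrt(sum((xyz[a, ] - xyz[b, ])^2)) < d_cut) cnt <- cnt + 1L
  }
  cnt
}

# Random photon stream with bursty structure for oracle comparisons:
# mixture of short and long gaps so clusters of all sizes occur.
random_stream <- function(n_photons, seed) {
  set.seed(seed)
  gaps <- ifelse(runif(n_photons) < 0.9,
                 rexp(n_photons, 1 / 15),     # intra-burst-like
                 rexp(n_photons, 1 / 600))    # separating
  t_us <- cumsum(gaps)
  channel <- sample(c("D", "A"), n_photons, replace = TRUE)
  list(t_us = t_us, channel = channel)
}

# Apply a random rigid rotation + translation to every frame of a
# trajectory (same transform for all atoms of a frame).
rigid_transform_traj <- function(traj, seed = 1) {
  set.seed(seed)
  coords <- traj$coords
  for (f in seq_along(traj$times_ps)) {
    # random rotation via QR of a Gaussian matrix (det forced to +1)
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    shift <- rnorm(3, 0, 5)
    coords[f, , ] <- sweep(coords[f, , , drop = TRUE] %*% R, 2, -shift)
  }
  trajectory(traj$structure, traj$times_ps, coords)
}
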