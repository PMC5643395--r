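#' Species mixture specification for photon-stream simulation
#'
#' Describes the FRET species mixture emulated by
#' [simulate_photon_stream()]: the three canonical nucleosome
#' subpopulations are low-FRET (open nucleosome / free DNA, P ~ 0.12),
#' mid-FRET (intact, P ~ 0.39) and high-FRET (partially disassembled,
#' P ~ 0.64).
#'
#' @param label Species labels.
#' @param mean_p True mean proximity ratio per species, in `[0, 1]`.
#' @param weight Mixing weights; must sum to 1.
#' @param extra_width Per-burst Gaussian spread of the true P beyond
#'   shot noise (default 0: pure shot noise).
#' @param burst_size_range Burst sizes are drawn uniformly from this
#'   integer range, default `c(50, 150)` photons.
#' @param intra_gap_mean_us Mean exponential gap between photons inside
#'   a burst (default 10 us).
#' @param inter_gap_mean_us Mean exponential gap between bursts
#'   (default 1e4 us = 10 ms).
#' @param bkg_rate_donor,bkg_rate_acceptor Background Poisson rates in
#'   counts/s (default 0).
#' @return An object of class `species_mixture_spec`.
#' @export
species_mixture_spec <- function(label = c("LF", "MF", "HF"),
                                 mean_p = c(0.12, 0.39, 0.64),
                                 weight = c(1, 1, 1) / 3,
                                 extra_width = 0,
                                 burst_size_range = c(50, 150),
                                 intra_gap_mean_us = 10,
                                 inter_gap_mean_us = 1e4,
                                 bkg_rate_donor = 0,
                                 bkg_rate_acceptor = 0) {
  stopifnot(length(label) == length(mean_p), length(mean_p) == length(weight))
  if (abs(sum(weight) - 1) > 1e-9) stop("species weights must sum to 1")
  if (any(mean_p < 0 | mean_p > 1)) stop("mean_p must lie in [0, 1]")
  if (burst_size_range[1] < 1) stop("minimum burst size must be >= 1")
  extra_width <- rep_len(extra_width, length(label))
  structure(list(label = label, mean_p = mean_p, weight = weight,
                 extra_width = extra_width,
                 burst_size_range = burst_size_range,
                 intra_gap_mean_us = intra_gap_mean_us,
                 inter_gap_mean_us = inter_gap_mean_us,
                 bkg_rate_donor = bkg_rate_donor,
                 bkg_rate_acceptor = bkg_rate_acceptor),
            class = "species_mixture_spec")
}

# normal draw truncated to [0, 1] by inverse-CDF sampling
rnorm_trunc01 <- function(n, mean, sd) {
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm((0 - mean[pos]) / sd[pos])
    hi <- stats::pnorm((1 - mean[pos]) / sd[pos])
    u <- stats::runif(sum(pos), lo, hi)
    out <- ifelse(pos, NA_real_, mean)
    out[pos] <- mean[pos] + sd[pos] * stats::qnorm(u)
  }
  rep_len(out, n)
}

#' Simulate a diffusion spFRET photon stream
#'
#' Generates a photon-arrival stream from a known species mixture. Per
#' burst: the species is drawn by weight, the burst size uniformly
#' from the configured range, and the burst's true P from a normal
#' with the species mean and its `extra_width`, truncated to `[0, 1]`.
#' Each photon is assigned to the acceptor channel with probability
#' equal to that true P (binomial shot noise). Intra-burst photon gaps
#' are exponential with the intra-burst mean, inter-burst gaps
#' exponential with the (much larger) inter-burst mean; optional
#' background photons are superposed as homogeneous Poisson processes
#' per channel.
#'
#' @param spec A [species_mixture_spec()].
#' @param n_bursts Number of bursts to generate.
#' @param seed Random seed (reproducible: same seed, same stream).
#' @param max_gap_us Burst-search gap the stream must be resolvable
#'   under; generation is refused when the mean intra-burst gap is not
#'   below it.
#' @return List with `stream` (a [photon_stream()]) and `truth`
#'   (data.frame: burst, label, true_p, n_photons, n_acceptor,
#'   start_us, end_us).
#' @export
simulate_photon_stream <- function(spec, n_bursts, seed = 1,
                                   max_gap_us = 120) {
  stopifnot(inherits(spec, "species_mixture_spec"), n_bursts >= 1)
  if (spec$intra_gap_mean_us >= max_gap_us)
    stop("mean intra-burst gap (", spec$intra_gap_mean_us,
         " us) must be below max_gap_us (", max_gap_us,
         " us): burst and background regimes indistinguishable")
  set.seed(as.integer(seed))
  k <- length(spec$label)
  sp <- sample.int(k, n_bursts, replace = TRUE, prob = spec$weight)
  size_vals <- spec$burst_size_range[1]:spec$burst_size_range[2]
  sizes <- size_vals[sample.int(length(size_vals), n_bursts, replace = TRUE)]
  true_p <- rnorm_trunc01(n_bursts, spec$mean_p[sp], spec$extra_width[sp])
  n_a <- stats::rbinom(n_bursts, sizes, true_p)
  n_tot <- sum(sizes)
  # arrival times: exponential intra-burst gaps, exponential inter-burst gaps
  gaps <- stats::rexp(n_tot, 1 / spec$intra_gap_mean_us)
  burst_id <- rep.int(seq_len(n_bursts), sizes)
  first <- c(1L, cumsum(sizes)[-n_bursts] + 1L)
  gaps[first] <- stats::rexp(n_bursts, 1 / spec$inter_gap_mean_us)
  t_us <- cumsum(gaps)
  # channel assignment: within each burst, which photons are acceptor
  chan <- rep("D", n_tot)
  acc_idx <- unlist(lapply(seq_len(n_bursts), function(b) {
    if (n_a[b] == 0) return(integer(0))
    first[b] - 1L + sample.int(sizes[b], n_a[b])
  }))
  chan[acc_idx] <- "A"
  start_us <- t_us[first]
  end_us <- t_us[cumsum(sizes)]
  duration <- end_us[n_bursts] + stats::rexp(1, 1 / spec$inter_gap_mean_us)
  # superpose background photons
  if (spec$bkg_rate_donor > 0 || spec$bkg_rate_acceptor > 0) {
    dur_s <- duration * 1e-6
    nb_d <- stats::rpois(1, spec$bkg_rate_donor * dur_s)
    nb_a <- stats::rpois(1, spec$bkg_rate_acceptor * dur_s)
    bt <- stats::runif(nb_d + nb_a, 0, duration)
    t_us <- c(t_us, bt)
    chan <- c(chan, rep(c("D", "A"), c(nb_d, nb_a)))
    ord <- order(t_us)
    t_us <- t_us[ord]; chan <- chan[ord]
  }
  truth <- data.frame(burst = seq_len(n_bursts),
                      label = spec$label[sp],
                      true_p = true_p,
                      n_photons = sizes,
                      n_acceptor = n_a,
                      start_us = start_us,
                      end_us = end_us)
  list(stream = photon_stream(t_us, chan,
                              bkg_rate_donor = spec$bkg_rate_donor,
                              bkg_rate_acceptor = spec$bkg_rate_acceptor,
                              duration_us = duration),
       truth = truth)
}

#' Simulate a salt-titration series with known parameters
#'
#' Evaluates the 4-parameter logistic disassembly model at the given
#' NaCl concentrations and adds independent Gaussian noise per
#' replicate.
#'
#' @param p0,p_inf Low- and high-salt plateaus of the proximity ratio.
#' @param c_half_mm True inflection point (mM).
#' @param slope_b Transition width parameter (mM).
#' @param noise_sd Gaussian noise SD per replicate measurement
#'   (default 0.02).
#' @param n_replicates Replicates per concentration (default 3).
#' @param concentrations_mm NaCl concentrations; default 13 points
#'   spanning 5-1200 mM.
#' @param seed Random seed.
#' @return List with `points` (a [titration_series()]), `replicates`
#'   (long-format data.frame) and `truth` (the generating parameters).
#' @export
simulate_titration <- function(p0 = 1, p_inf = 0.1, c_half_mm = 800,
                               slope_b = 60, noise_sd = 0.02,
                               n_replicates = 3,
                               concentrations_mm = c(5, 100, 200, 300, 400,
                                                     500, 600, 700, 800, 900,
                                                     1000, 1100, 1200),
                               seed = 1) {
  if (anyDuplicated(concentrations_mm) || any(concentrations_mm < 0))
    stop("concentrations must be distinct and >= 0")
  set.seed(as.integer(seed))
  x <- rep(concentrations_mm, each = n_replicates)
  mu <- p0 + (p_inf - p0) / (1 + exp((c_half_mm - x) / slope_b))
  p <- mu + stats::rnorm(length(x), 0, noise_sd)
  reps <- data.frame(nacl_mm = x,
                     replicate_id = rep(seq_len(n_replicates),
                                        times = length(concentrations_mm)),
                     p = p)
  list(points = titration_series(reps$nacl_mm, reps$p),
       replicates = reps,
       truth = list(p0 = p0, p_inf = p_inf, c_half_mm = c_half_mm,
                    slope_b = slope_b, noise_sd = noise_sd,
                    n_replicates = n_replicates))
}

#' Build a toy trajectory from a script
#'
#' Turns a scripted set of atoms and per-frame positions into a
#' [trajectory()]. Positions may be given as a ready
#' `n_frames x n_atoms x 3` array or as a function of time (ps)
#' returning the `n_atoms x 3` coordinate matrix of that frame.
#'
#' @param atoms Atom table as for [structure_model()].
#' @param times_ps Frame times.
#' @param positions Array or `function(t)`.
#' @return A [trajectory()].
#' @export
make_toy_trajectory <- function(atoms, times_ps, positions) {
  sm <- structure_model(atoms)
  if (is.function(positions)) {
    coords <- array(0, c(length(times_ps), sm$n_atoms, 3))
    for (f in seq_along(times_ps)) {
      m <- positions(times_ps[f])
      stopifnot(nrow(m) == sm$n_atoms, ncol(m) == 3)
      coords[f, , ] <- m
    }
  } else coords <- positions
  trajectory(sm, times_ps, coords)
}

#' Toy hydrogen-bond trajectory with scripted occupancy
#'
#' Three atoms: a donor nitrogen with its hydrogen (residue 1, chain
#' "X") and an acceptor oxygen (residue 2, chain "Y"). In "bonded"
#' frames the acceptor sits 0.30 nm from the donor along the
#' donor-hydrogen axis (distance and angle criteria met); otherwise it
#' sits 1.0 nm away. The true occupancy over any frame window is the
#' fraction of bonded frames in it.
#'
#' @param bonded Logical vector, one element per frame: is the H-bond
#'   formed in that frame?
#' @param dt_ps Frame spacing (default 1 ps, first frame at t = 0).
#' @return List with `traj` and `truth` (the `bonded` vector).
#' @export
toy_hbond_trajectory <- function(bonded, dt_ps = 1) {
  atoms <- data.frame(atom_name = c("N", "H", "O"),
                      element = c("N", "H", "O"),
                      mass = c(14.007, 1.008, 15.999),
                      residue_name = c("ASN", "ASN", "SER"),
                      residue_index = c(1L, 1L, 2L),
                      chain_id = c("X", "X", "Y"),
                      stringsAsFactors = FALSE)
  nf <- length(bonded)
  coords <- array(0, c(nf, 3, 3))
  for (f in seq_len(nf)) {
    coords[f, 1, ] <- c(0, 0, 0)          # donor
    coords[f, 2, ] <- c(0.10, 0, 0)       # hydrogen on the D-A axis
    coords[f, 3, ] <- if (bonded[f]) c(0.30, 0, 0) else c(1.0, 0, 0)
  }
  list(traj = trajectory(structure_model(atoms),
                         (seq_len(nf) - 1) * dt_ps, coords),
       truth = bonded)
}

#' Toy DNA duplex trajectory with known arm-segment distances
#'
#' A mock duplex of `n_bp` base pairs (one C1' pseudo-atom per strand
#' residue). The first half of the base pairs (counted from end 1)
#' sits at the origin and the second half at `separation_nm` along x,
#' so every terminal segment and its counterpart from the opposite end
#' are exactly `separation_nm` apart in every frame.
#'
#' @param n_bp Base pairs (default 20).
#' @param separation_nm True segment-pair COM distance (default 4).
#' @param n_frames Frames (default 10, 1-ps spacing).
#' @return List with `traj` and `truth` (the separation).
#' @export
toy_duplex_trajectory <- function(n_bp = 20, separation_nm = 4,
                                  n_frames = 10) {
  stopifnot(n_bp %% 2 == 0)
  # strand 1 residues 1..n (5'->3'); strand 2 residues 1..n; bp i from
  # end 1 = (s1 res i, s2 res n+1-i), colocated at position u_i
  u <- ifelse(seq_len(n_bp) <= n_bp / 2, 0, separation_nm)
  atoms <- data.frame(atom_name = rep("C1'", 2 * n_bp),
                      element = rep("C", 2 * n_bp),
                      mass = rep(12.011, 2 * n_bp),
                      residue_name = rep(c("DA", "DT"), each = n_bp),
                      residue_index = c(seq_len(n_bp), seq_len(n_bp)),
                      chain_id = rep(c("I", "J"), each = n_bp),
                      stringsAsFactors = FALSE)
  pos <- matrix(0, 2 * n_bp, 3)
  pos[seq_len(n_bp), 1] <- u                      # strand 1, res i at u_i
  pos[n_bp + seq_len(n_bp), 1] <- rev(u)          # strand 2, res j at u_{n+1-j}
  coords <- array(0, c(n_frames, 2 * n_bp, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- pos
  list(traj = trajectory(structure_model(atoms),
                         seq_len(n_frames) - 1, coords),
       truth = separation_nm)
}

#' Toy random-walk trajectory for contact-oracle tests
#'
#' Heavy atoms performing independent Gaussian random walks in a box,
#' split across two chains; contact counts have no closed form and are
#' checked against a brute-force pairwise oracle.
#'
#' @param n_atoms Total atoms (split evenly over chains "A" and "B").
#' @param n_frames Frames.
#' @param step_nm Per-frame displacement SD (default 0.1 nm).
#' @param box_nm Initial positions uniform in `[0, box_nm]^3`
#'   (default 1.5).
#' @param seed Random seed.
#' @return A [trajectory()].
#' @export
toy_walk_trajectory <- function(n_atoms = 20, n_frames = 50, step_nm = 0.1,
                                box_nm = 1.5, seed = 1) {
  set.seed(as.integer(seed))
  atoms <- data.frame(atom_name = paste0("C", seq_len(n_atoms)),
                      element = "C", mass = 12.011,
                      residue_name = "LIG",
                      residue_index = seq_len(n_atoms),
                      chain_id = rep(c("A", "B"), length.out = n_atoms),
                      stringsAsFactors = FALSE)
  coords <- array(0, c(n_frames, n_atoms, 3))
  coords[1, , ] <- matrix(stats::runif(3 * n_atoms, 0, box_nm), n_atoms, 3)
  if (n_frames > 1)
    for (f in 2:n_frames)
      coords[f, , ] <- coords[f - 1, , ] +
        matrix(stats::rnorm(3 * n_atoms, 0, step_nm), n_atoms, 3)
  trajectory(structure_model(atoms), seq_len(n_frames) - 1, coords)
}
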