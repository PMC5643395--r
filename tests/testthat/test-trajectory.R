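test_that("hydrogen-bond occupancy equals the scripted bonded-frame fraction", {
  set.seed(21)
  bonded <- seq_len(100) %in% sample(100, 37)
  toy <- toy_hbond_trajectory(bonded)
  occ <- hbond_occupancy(toy$traj,
                         donors = atom_selection(chain = "X", element = "N"),
                         acceptors = atom_selection(chain = "Y", element = "O"),
                         t_start_ps = 0, t_end_ps = 99)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occupancy, 0.37)
  # never bonded -> 0; always bonded -> 1
  expect_equal(hbond_occupancy(toy_hbond_trajectory(rep(FALSE, 20))$traj,
                               atom_selection(chain = "X"),
                               atom_selection(chain = "Y"),
                               t_start_ps = 0, t_end_ps = 19)$occupancy, 0)
  expect_equal(hbond_occupancy(toy_hbond_trajectory(rep(TRUE, 20))$traj,
                               atom_selection(chain = "X"),
                               atom_selection(chain = "Y"),
                               t_start_ps = 0, t_end_ps = 19)$occupancy, 1)
})

test_that("the H-bond angle criterion rejects bent geometries within the distance cutoff", {
  # donor at origin, H perpendicular to the D->A axis: angle = 90 degrees
  atoms <- data.frame(atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
                      mass = c(14, 1, 16), residue_name = "X",
                      residue_index = c(1L, 1L, 2L), chain_id = c("X", "X", "Y"))
  coords <- array(0, c(1, 3, 3))
  coords[1, 2, ] <- c(0, 0.10, 0)   # H off-axis
  coords[1, 3, ] <- c(0.30, 0, 0)   # acceptor within distance cutoff
  tr <- trajectory(structure_model(atoms), 0, coords)
  occ <- hbond_occupancy(tr, atom_selection(chain = "X"),
                         atom_selection(chain = "Y"),
                         t_start_ps = 0, t_end_ps = 0)
  expect_equal(occ$occupancy, 0)
  # analysis window outside the trajectory errors
  expect_error(hbond_occupancy(tr, atom_selection(chain = "X"),
                               atom_selection(chain = "Y"),
                               t_start_ps = 0, t_end_ps = 100), "window")
  expect_error(hbond_occupancy(tr, atom_selection(chain = "Q"),
                               atom_selection(chain = "Y"),
                               t_start_ps = 0, t_end_ps = 0), "donors")
})

test_that("contact counting uses a strict 0.35 nm cutoff on heavy atoms", {
  atoms <- data.frame(atom_name = c("C1", "C2", "H1"),
                      element = c("C", "C", "H"), mass = c(12, 12, 1),
                      residue_name = "LIG", residue_index = c(1L, 2L, 2L),
                      chain_id = c("A", "B", "B"))
  mk <- function(d) {
    coords <- array(0, c(1, 3, 3))
    coords[1, 2, 1] <- d
    coords[1, 3, 1] <- d / 2   # hydrogen between them, must be ignored
    trajectory(structure_model(atoms), 0, coords)
  }
  a <- atom_selection(chain = "A"); b <- atom_selection(chain = "B")
  expect_equal(count_contacts(mk(0.34), a, b)$n_contacts, 1L)
  expect_equal(count_contacts(mk(0.35), a, b)$n_contacts, 0L)
  # empty partner group -> all zero
  expect_equal(count_contacts(mk(0.1), a, atom_selection(chain = "Z"))$n_contacts,
               0L)
})

test_that("contact counts match the brute-force pairwise oracle on random frames", {
  tr <- toy_walk_trajectory(n_atoms = 20, n_frames = 50, seed = 31)
  ia <- resolve_selection(atom_selection(chain = "A"), tr$structure)
  ib <- resolve_selection(atom_selection(chain = "B"), tr$structure)
  got <- count_contacts(tr, atom_selection(chain = "A"),
                        atom_selection(chain = "B"))
  ref <- vapply(1:50, function(f)
    brute_force_contacts(tr$coords[f, , ], ia, ib), integer(1))
  expect_equal(got$n_contacts, ref)
  # symmetry for disjoint selections
  rev <- count_contacts(tr, atom_selection(chain = "B"),
                        atom_selection(chain = "A"))
  expect_equal(got$n_contacts, rev$n_contacts)
  # overlapping selections: self-pairs excluded with a warning
  expect_warning(
    self <- count_contacts(tr, atom_selection(chain = "A"),
                           atom_selection()),
    "overlap")
  ref_self <- vapply(1:50, function(f)
    brute_force_contacts(tr$coords[f, , ], ia, seq_len(20)), integer(1))
  expect_equal(self$n_contacts, ref_self)
})

test_that("contact probability is the per-neighbour-residue contact frame fraction", {
  # two residues: in contact in exactly 50 of 100 frames
  atoms <- data.frame(atom_name = c("CA", "CB"), element = "C",
                      mass = 12, residue_name = c("ARG", "GLN"),
                      residue_index = c(81L, 55L), chain_id = c("C", "A"))
  coords <- array(0, c(100, 2, 3))
  coords[1:50, 2, 1] <- 0.2   # close
  coords[51:100, 2, 1] <- 2.0 # far
  tr <- trajectory(structure_model(atoms), 0:99, coords)
  pr <- contact_probability(tr, c("C", 81), atom_selection())
  expect_equal(nrow(pr), 1)  # the residue itself is excluded
  expect_equal(pr$probability, 0.5)
  # never-contacting neighbour
  coords[, 2, 1] <- 5
  tr <- trajectory(structure_model(atoms), 0:99, coords)
  expect_equal(contact_probability(tr, c("C", 81),
                                   atom_selection())$probability, 0)
})

test_that("segment COM distances reproduce constructed geometry and its invariances", {
  toy <- toy_duplex_trajectory(n_bp = 20, separation_nm = 4, n_frames = 5)
  d <- arm_segment_distances(toy$traj, "I", "J")
  expect_equal(sort(unique(d$segment)),
               sort(c("1-5 bp", "6-10 bp", "11-15 bp", "16-20 bp")))
  expect_equal(d$distance_nm, rep(4, nrow(d)), tolerance = 1e-12)
  # translation invariance
  tr2 <- toy$traj
  tr2$coords <- tr2$coords + 7.3
  d2 <- arm_segment_distances(tr2, "I", "J")
  expect_equal(d2$distance_nm, d$distance_nm, tolerance = 1e-12)
  # doubling all masses leaves the COM distance unchanged
  tr3 <- toy$traj
  tr3$structure$atoms$mass <- tr3$structure$atoms$mass * 2
  expect_equal(arm_segment_distances(tr3, "I", "J")$distance_nm,
               d$distance_nm, tolerance = 1e-12)
  expect_error(arm_segment_distances(toy$traj, "I", "J",
                                     windows = list(c(1, 30))), "exceeds")
})

test_that("distance operators are invariant under rigid motions of every frame", {
  toy <- toy_duplex_trajectory(n_frames = 4)
  moved <- rigid_transform_traj(toy$traj, seed = 5)
  d0 <- arm_segment_distances(toy$traj, "I", "J")
  d1 <- arm_segment_distances(moved, "I", "J")
  expect_equal(d1$distance_nm, d0$distance_nm, tolerance = 1e-9)

  tr <- toy_walk_trajectory(n_atoms = 12, n_frames = 20, seed = 6)
  trm <- rigid_transform_traj(tr, seed = 7)
  c0 <- count_contacts(tr, atom_selection(chain = "A"),
                       atom_selection(chain = "B"))
  c1 <- count_contacts(trm, atom_selection(chain = "A"),
                       atom_selection(chain = "B"))
  expect_equal(c1$n_contacts, c0$n_contacts)

  hb <- toy_hbond_trajectory(rep(c(TRUE, FALSE), 10))
  hbm <- rigid_transform_traj(hb$traj, seed = 8)
  o0 <- hbond_occupancy(hb$traj, atom_selection(chain = "X"),
                        atom_selection(chain = "Y"),
                        t_start_ps = 0, t_end_ps = 19)
  o1 <- hbond_occupancy(hbm, atom_selection(chain = "X"),
                        atom_selection(chain = "Y"),
                        t_start_ps = 0, t_end_ps = 19)
  expect_equal(o1$occupancy, o0$occupancy)
})

test_that("running average is a trailing mean that preserves constants and stationary means", {
  t <- (0:49) * 100
  expect_equal(running_average(t, rep(2.5, 50), 200), rep(2.5, 50))
  # alternating 0/1 at 100-ps spacing with a 200-ps window settles at 0.5
  v <- rep(c(0, 1), 25)
  ra <- running_average(t, v, 200)
  expect_equal(ra[-1], rep(0.5, 49))
  # window shorter than the frame spacing is rejected
  expect_error(running_average(t, v, 50), "spacing")
  expect_warning(running_average(0, 1, 200), "single-frame")
  # stationary signal: smoothed mean equals raw mean within sampling error
  set.seed(41)
  x <- rnorm(500, 3, 0.2)
  tt <- (0:499) * 10
  expect_equal(mean(running_average(tt, x, 200)), mean(x), tolerance = 0.01)
  # data.frame interface smooths per segment
  toy <- toy_duplex_trajectory(n_frames = 10)
  d <- arm_segment_distances(toy$traj, "I", "J")
  sm <- running_average(d, window_ps = 2)
  expect_equal(sm$distance_nm, d$distance_nm, tolerance = 1e-12)
})

test_that("multi-model PDB files round-trip into trajectories with nm coordinates", {
  toy <- toy_hbond_trajectory(c(TRUE, FALSE))
  f <- tempfile(fileext = ".pdb")
  lines <- character(0)
  for (m in 1:2) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in 1:3) {
      a <- toy$traj$structure$atoms[i, ]
      xyz <- toy$traj$coords[m, i, ] * 10  # nm -> Angstrom
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, a$atom_name, a$residue_name, a$chain_id, a$residue_index,
        xyz[1], xyz[2], xyz[3], a$element))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), f)
  tr <- read_trajectory_pdb(f)
  expect_equal(length(tr$times_ps), 2)
  expect_equal(tr$structure$n_atoms, 3)
  expect_equal(tr$coords[1, 3, 1], 0.30, tolerance = 1e-6)
  expect_equal(tr$coords[2, 3, 1], 1.0, tolerance = 1e-6)
  occ <- hbond_occupancy(tr, atom_selection(chain = "X"),
                         atom_selection(chain = "Y"),
                         t_start_ps = 0, t_end_ps = 1)
  expect_equal(occ$occupancy, 0.5)
  unlink(f)
})
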