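#' Structure model
#'
#' Minimal topology for trajectory geometry: one row per atom with
#' name, element, mass and residue/chain identity. Chains identify the
#' two copies of each histone and the two DNA strands.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `mass`,
#'   `residue_name`, `residue_index`, `chain_id`.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("atom_name", "element", "mass", "residue_name",
            "residue_index", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("atom masses must be > 0")
  structure(list(atoms = atoms, n_atoms = nrow(atoms)),
            class = "structure_model")
}

#' Trajectory
#'
#' Frames of timestamped coordinates (nm) over a [structure_model()].
#'
#' @param structure A `structure_model`.
#' @param times_ps Frame times in ps, strictly increasing.
#' @param coords Numeric array `n_frames x n_atoms x 3`, coordinates in
#'   nm.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(structure, times_ps, coords) {
  stopifnot(inherits(structure, "structure_model"))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[1] != length(times_ps))
    stop("frame count disagrees with times_ps length")
  if (dim(coords)[2] != structure$n_atoms)
    stop("coordinate count per frame disagrees with atom count")
  if (length(times_ps) > 1 && any(diff(times_ps) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(structure = structure, times_ps = as.numeric(times_ps),
                 coords = coords),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", length(x$times_ps), " frames, ",
      x$structure$n_atoms, " atoms, ",
      min(x$times_ps), " - ", max(x$times_ps), " ps\n", sep = "")
  invisible(x)
}

#' Atom selection
#'
#' A declarative predicate over a structure's atoms; resolves to a
#' deterministic, order-stable atom index list.
#'
#' @param chain Chain id(s) to keep (NULL = any).
#' @param resid Residue index/indices to keep (NULL = any).
#' @param atom_names Atom name(s) to keep (NULL = any).
#' @param element Element(s) to keep (NULL = any).
#' @param heavy_only Drop hydrogens (element "H").
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(chain = NULL, resid = NULL, atom_names = NULL,
                           element = NULL, heavy_only = FALSE) {
  structure(list(chain = chain, resid = resid, atom_names = atom_names,
                 element = element, heavy_only = heavy_only),
            class = "atom_selection")
}

#' Resolve an atom selection to indices
#'
#' @param sel An [atom_selection()] (or an integer index vector, passed
#'   through).
#' @param structure A [structure_model()].
#' @param name Label used in error messages.
#' @param allow_empty Return `integer(0)` instead of erroring when
#'   nothing matches.
#' @return Sorted integer atom indices.
#' @export
resolve_selection <- function(sel, structure, name = "selection",
                              allow_empty = FALSE) {
  stopifnot(inherits(structure, "structure_model"))
  if (is.numeric(sel)) return(sort(as.integer(sel)))
  stopifnot(inherits(sel, "atom_selection"))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain_id %in% sel$chain
  if (!is.null(sel$resid)) keep <- keep & a$residue_index %in% sel$resid
  if (!is.null(sel$atom_names)) keep <- keep & a$atom_name %in% sel$atom_names
  if (!is.null(sel$element)) keep <- keep & a$element %in% sel$element
  if (sel$heavy_only) keep <- keep & a$element != "H"
  idx <- which(keep)
  if (!length(idx) && !allow_empty) stop("empty atom selection: ", name)
  idx
}

# pairwise distance matrix (nm) between two coordinate blocks of one frame
cross_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

frame_window <- function(t, t_start_ps, t_end_ps) {
  if (t_start_ps < min(t) - 1e-9 || t_end_ps > max(t) + 1e-9)
    stop("analysis window [", t_start_ps, ", ", t_end_ps,
         "] ps lies outside the trajectory span [", min(t), ", ", max(t), "] ps")
  which(t >= t_start_ps & t <= t_end_ps)  # endpoints inclusive
}

#' Hydrogen-bond occupancy over a trajectory window
#'
#' For every donor-residue / acceptor-residue pair, the fraction of
#' frames in the analysis window in which at least one qualifying
#' hydrogen bond exists. The geometric criterion is the conventional
#' one: donor-acceptor heavy-atom distance <= `d_cut_nm` and
#' hydrogen-donor-acceptor angle (at the donor) <= `angle_cut_deg`.
#' Hydrogens are associated with a donor heavy atom when they belong to
#' the same residue and sit within 0.12 nm of it in that frame.
#'
#' @param t A [trajectory()].
#' @param donors,acceptors [atom_selection()]s resolving to the donor
#'   and acceptor heavy atoms (hydrogens are excluded automatically).
#' @param d_cut_nm Donor-acceptor distance cutoff (default 0.35 nm).
#' @param angle_cut_deg H-donor-acceptor angle cutoff (default 30).
#' @param t_start_ps,t_end_ps Analysis window, endpoints inclusive;
#'   defaults 20000-150000 ps (the equilibrated 20-150 ns stretch of a
#'   150-ns production run). Must lie within the trajectory span.
#' @return data.frame `donor_chain`, `donor_resid`, `acceptor_chain`,
#'   `acceptor_resid`, `occupancy` with occupancy in `[0, 1]`.
#' @export
hbond_occupancy <- function(t, donors, acceptors, d_cut_nm = 0.35,
                            angle_cut_deg = 30,
                            t_start_ps = 20000, t_end_ps = 150000) {
  stopifnot(inherits(t, "trajectory"))
  a <- t$structure$atoms
  di <- resolve_selection(donors, t$structure, "donors")
  ai <- resolve_selection(acceptors, t$structure, "acceptors")
  di <- di[a$element[di] != "H"]
  ai <- ai[a$element[ai] != "H"]
  if (!length(di)) stop("empty atom selection: donors (no heavy atoms)")
  if (!length(ai)) stop("empty atom selection: acceptors (no heavy atoms)")
  hi <- which(a$element == "H")
  frames <- frame_window(t$times_ps, t_start_ps, t_end_ps)
  drk <- paste(a$chain_id[di], a$residue_index[di])
  ark <- paste(a$chain_id[ai], a$residue_index[ai])
  pair_key <- function(dk, ak) paste(dk, "->", ak)
  # residue-pair universe
  univ <- unique(unlist(lapply(unique(drk), function(dk)
    pair_key(dk, unique(ark)))))
  hits <- stats::setNames(numeric(length(univ)), univ)
  cosmin <- cos(angle_cut_deg * pi / 180)
  for (f in frames) {
    xyz <- t$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    dmat <- cross_dist(xyz[di, , drop = FALSE], xyz[ai, , drop = FALSE])
    cand <- which(dmat <= d_cut_nm, arr.ind = TRUE)
    if (!nrow(cand)) next
    seen <- character(0)
    for (r in seq_len(nrow(cand))) {
      d_at <- di[cand[r, 1]]; a_at <- ai[cand[r, 2]]
      if (d_at == a_at) next
      key <- pair_key(paste(a$chain_id[d_at], a$residue_index[d_at]),
                      paste(a$chain_id[a_at], a$residue_index[a_at]))
      if (key %in% seen) next
      # hydrogens covalently attached to this donor in this frame
      hs <- hi[a$chain_id[hi] == a$chain_id[d_at] &
               a$residue_index[hi] == a$residue_index[d_at]]
      if (!length(hs)) next
      hd <- sqrt(colSums((base::t(xyz[hs, , drop = FALSE]) - xyz[d_at, ])^2))
      hs <- hs[hd < 0.12]
      if (!length(hs)) next
      vda <- xyz[a_at, ] - xyz[d_at, ]
      nda <- sqrt(sum(vda^2))
      for (h_at in hs) {
        vdh <- xyz[h_at, ] - xyz[d_at, ]
        ca <- sum(vdh * vda) / (sqrt(sum(vdh^2)) * nda)
        if (ca >= cosmin) { seen <- c(seen, key); break }
      }
    }
    if (length(seen)) hits[seen] <- hits[seen] + 1
  }
  parts <- strsplit(names(hits), " -> ", fixed = TRUE)
  dparts <- strsplit(vapply(parts, `[`, "", 1), " ", fixed = TRUE)
  aparts <- strsplit(vapply(parts, `[`, "", 2), " ", fixed = TRUE)
  data.frame(donor_chain = vapply(dparts, `[`, "", 1),
             donor_resid = as.integer(vapply(dparts, `[`, "", 2)),
             acceptor_chain = vapply(aparts, `[`, "", 1),
             acceptor_resid = as.integer(vapply(aparts, `[`, "", 2)),
             occupancy = unname(hits) / length(frames))
}

#' Per-frame heavy-atom contact counts
#'
#' Counts, per frame, the number of atom pairs (one from each group)
#' whose distance is strictly less than `d_cut_nm`. Hydrogens are
#' excluded automatically; a pair consisting of the same atom twice
#' (overlapping selections) is excluded with a warning.
#'
#' @param t A [trajectory()].
#' @param group_a,group_b [atom_selection()]s (or index vectors).
#' @param d_cut_nm Contact cutoff, default 0.35 nm (strict `<`).
#' @return data.frame `time_ps`, `n_contacts`.
#' @export
count_contacts <- function(t, group_a, group_b, d_cut_nm = 0.35) {
  stopifnot(inherits(t, "trajectory"))
  a <- t$structure$atoms
  ia <- resolve_selection(group_a, t$structure, "group_a")
  ib <- resolve_selection(group_b, t$structure, "group_b", allow_empty = TRUE)
  ia <- ia[a$element[ia] != "H"]
  ib <- ib[a$element[ib] != "H"]
  if (!length(ia)) stop("empty atom selection: group_a (no heavy atoms)")
  if (!length(ib)) return(data.frame(time_ps = t$times_ps,
                                     n_contacts = rep(0L, length(t$times_ps))))
  overlap <- intersect(ia, ib)
  if (length(overlap))
    warning("selections overlap in ", length(overlap),
            " atom(s); self-pairs excluded")
  n <- vapply(seq_along(t$times_ps), function(f) {
    xyz <- t$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    dmat <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    cnt <- sum(dmat < d_cut_nm)
    if (length(overlap)) # remove self-pairs (distance 0 < cutoff)
      cnt <- cnt - length(overlap)
    as.integer(cnt)
  }, integer(1))
  data.frame(time_ps = t$times_ps, n_contacts = n)
}

#' Contact probability of a residue with its neighbours
#'
#' For one residue (on one chain, i.e. one histone copy), the fraction
#' of frames in which at least one heavy-atom pair between that
#' residue and each neighbour residue lies within the cutoff. The
#' residue itself is excluded.
#'
#' @param t A [trajectory()].
#' @param residue `c(chain, index)`: chain id and residue index.
#' @param neighbors An [atom_selection()] defining the surrounding
#'   atoms to scan (grouped per residue in the output).
#' @param d_cut_nm Cutoff, default 0.35 nm (strict `<`).
#' @return data.frame `chain`, `resid`, `probability`.
#' @export
contact_probability <- function(t, residue, neighbors, d_cut_nm = 0.35) {
  stopifnot(inherits(t, "trajectory"), length(residue) == 2)
  a <- t$structure$atoms
  ri <- which(a$chain_id == residue[1] &
              a$residue_index == as.integer(residue[2]) & a$element != "H")
  if (!length(ri)) stop("residue ", residue[1], ":", residue[2], " not found")
  ni <- resolve_selection(neighbors, t$structure, "neighbors")
  ni <- ni[a$element[ni] != "H"]
  # exclude the residue itself
  ni <- ni[!(a$chain_id[ni] == residue[1] &
             a$residue_index[ni] == as.integer(residue[2]))]
  if (!length(ni)) return(data.frame(chain = character(0), resid = integer(0),
                                     probability = numeric(0)))
  key <- paste(a$chain_id[ni], a$residue_index[ni])
  ukey <- unique(key)
  hits <- stats::setNames(numeric(length(ukey)), ukey)
  for (f in seq_along(t$times_ps)) {
    xyz <- t$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    dmat <- cross_dist(xyz[ri, , drop = FALSE], xyz[ni, , drop = FALSE])
    close_any <- apply(dmat < d_cut_nm, 2, any)
    in_contact <- unique(key[close_any])
    if (length(in_contact)) hits[in_contact] <- hits[in_contact] + 1
  }
  parts <- strsplit(ukey, " ", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1),
             resid = as.integer(vapply(parts, `[`, "", 2)),
             probability = unname(hits) / length(t$times_ps))
}

#' DNA-arm segment centre-of-mass distances
#'
#' Classifies the terminal base pairs of a DNA duplex into segments
#' (default 1-5, 6-10, 11-15 and 16-20 bp, counted 1-based inward from
#' each DNA end) and, per frame, computes the Euclidean distance
#' between the mass-weighted centre of mass of each segment and its
#' counterpart on the opposite arm. Base pair i counted from one end
#' pairs residue i (5'->3') of strand 1 with residue N+1-i of strand
#' 2; the counterpart segment is the mirror window counted from the
#' other end. Each segment comprises all atoms (heavy and hydrogen, or
#' heavy only via `heavy_only`) of its base pairs on both strands.
#'
#' @param t A [trajectory()].
#' @param strand1,strand2 Chain ids of the two DNA strands.
#' @param windows List of 1-based base-pair windows, default
#'   `list(c(1,5), c(6,10), c(11,15), c(16,20))`; must be disjoint.
#' @param heavy_only Use only heavy atoms for the COM (default FALSE:
#'   all atoms).
#' @return data.frame of class `distance_series`: `time_ps`, `segment`
#'   (e.g. "1-5 bp"), `distance_nm`.
#' @export
arm_segment_distances <- function(t, strand1, strand2,
                                  windows = list(c(1, 5), c(6, 10),
                                                 c(11, 15), c(16, 20)),
                                  heavy_only = FALSE) {
  stopifnot(inherits(t, "trajectory"))
  a <- t$structure$atoms
  covered <- unlist(lapply(windows, function(w) w[1]:w[2]))
  if (anyDuplicated(covered)) stop("segment windows must be disjoint")
  r1 <- sort(unique(a$residue_index[a$chain_id == strand1]))
  r2 <- sort(unique(a$residue_index[a$chain_id == strand2]))
  if (!length(r1) || !length(r2)) stop("DNA strands not found: ", strand1, ", ", strand2)
  if (length(r1) != length(r2))
    stop("strands have different residue counts (", length(r1), " vs ", length(r2), ")")
  nbp <- length(r1)
  # atom indices of bp i counted from end 1 (arm = FALSE) or end 2 (TRUE)
  bp_atoms <- function(i, from_end2) {
    j <- if (from_end2) nbp + 1 - i else i
    s1_res <- r1[j]; s2_res <- r2[nbp + 1 - j]
    idx <- which((a$chain_id == strand1 & a$residue_index == s1_res) |
                 (a$chain_id == strand2 & a$residue_index == s2_res))
    if (heavy_only) idx <- idx[a$element[idx] != "H"]
    if (!length(idx)) stop("no atoms resolve for base pair ", i,
                           " (strand residues ", s1_res, "/", s2_res, ")")
    idx
  }
  out <- vector("list", length(windows))
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    if (max(w) > nbp) stop("window ", w[1], "-", w[2],
                           " exceeds duplex length of ", nbp, " bp")
    seg1 <- unlist(lapply(w[1]:w[2], bp_atoms, from_end2 = FALSE))
    seg2 <- unlist(lapply(w[1]:w[2], bp_atoms, from_end2 = TRUE))
    m1 <- a$mass[seg1]; m2 <- a$mass[seg2]
    d <- vapply(seq_along(t$times_ps), function(f) {
      xyz <- t$coords[f, , , drop = TRUE]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      com1 <- colSums(xyz[seg1, , drop = FALSE] * m1) / sum(m1)
      com2 <- colSums(xyz[seg2, , drop = FALSE] * m2) / sum(m2)
      sqrt(sum((com1 - com2)^2))
    }, numeric(1))
    out[[wi]] <- data.frame(time_ps = t$times_ps,
                            segment = sprintf("%d-%d bp", w[1], w[2]),
                            distance_nm = d)
  }
  res <- do.call(rbind, out)
  class(res) <- c("distance_series", "data.frame")
  res
}

#' Trailing running average of a time series
#'
#' Replaces each value by the mean over all frames whose time lies in
#' the half-open trailing window `(t - window_ps, t]`. The output time
#' base is unchanged. The default 200-ps window matches the smoothing
#' used for DNA-arm distance traces.
#'
#' @param time_ps Frame times (strictly increasing), or a data.frame
#'   with `time_ps` and `value`/`distance_nm` columns.
#' @param value Values; omit when `time_ps` is a data.frame.
#' @param window_ps Averaging window in ps (default 200); must exceed
#'   the frame spacing.
#' @return Smoothed values (vector), or the data.frame with its value
#'   column smoothed.
#' @export
running_average <- function(time_ps, value = NULL, window_ps = 200) {
  if (is.data.frame(time_ps)) {
    df <- time_ps
    vcol <- intersect(c("value", "distance_nm", "n_contacts"), names(df))[1]
    if (is.na(vcol)) stop("data.frame needs a value/distance_nm/n_contacts column")
    if ("segment" %in% names(df) && length(unique(df$segment)) > 1) {
      sp <- split(seq_len(nrow(df)), df$segment)
      for (idx in sp)
        df[[vcol]][idx] <- running_average(df$time_ps[idx], df[[vcol]][idx],
                                           window_ps)
      return(df)
    }
    df[[vcol]] <- running_average(df$time_ps, df[[vcol]], window_ps)
    return(df)
  }
  t <- time_ps
  if (length(t) != length(value)) stop("time and value lengths differ")
  if (length(t) < 2) {
    warning("single-frame series: running average is the identity")
    return(value)
  }
  if (window_ps <= min(diff(t)))
    stop("window_ps (", window_ps, ") must exceed the frame spacing")
  vapply(seq_along(t), function(i) {
    sel <- t > t[i] - window_ps & t <= t[i]
    mean(value[sel])
  }, numeric(1))
}

#' Read a structure or multi-model trajectory from PDB
#'
#' Uses bio3d to parse the PDB; multi-model files become trajectory
#' frames. Coordinates are converted from Angstrom to nm; atomic
#' masses are assigned from the element.
#'
#' @param path PDB file path.
#' @param times_ps Frame times; defaults to 0, 1, 2, ... ps per model.
#' @return A [trajectory()] (single-model files give one frame).
#' @export
read_trajectory_pdb <- function(path, times_ps = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  ele <- tryCatch(bio3d::atom2ele(pdb), error = function(e)
    toupper(substr(gsub("[0-9']", "", at$elety), 1, 1)))
  mass <- tryCatch(bio3d::atom2mass(pdb), error = function(e) {
    m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
           S = 32.06)
    unname(m[ele])
  })
  sm <- structure_model(data.frame(atom_name = at$elety, element = ele,
                                   mass = mass, residue_name = at$resid,
                                   residue_index = at$resno,
                                   chain_id = at$chain,
                                   stringsAsFactors = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(0, c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  if (is.null(times_ps)) times_ps <- seq_len(nf) - 1
  trajectory(sm, times_ps, coords)
}

#' Write a tidy distance/contact series to CSV
#'
#' @param x data.frame with a time column and value columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
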