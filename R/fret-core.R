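#' Dye pair photophysics
#'
#' Describes a donor/acceptor dye pair by its Forster radius, channel
#' detection efficiencies and quantum yields. The detection factor
#' gamma = (eta_A * phi_A) / (eta_D * phi_D) converts between the
#' apparent proximity ratio and the true FRET efficiency.
#'
#' @param forster_radius_nm Forster radius R0 in nm (distance at which
#'   E = 0.5). Must be > 0.
#' @param det_eff_donor,det_eff_acceptor Detection efficiencies eta_D,
#'   eta_A of the two channels (dimensionless, > 0).
#' @param qy_donor,qy_acceptor Fluorescence quantum yields phi_D, phi_A
#'   (dimensionless, > 0).
#' @param gamma Optional explicit gamma factor. If omitted it is derived
#'   from the efficiencies and quantum yields; if given it must agree
#'   with the derived value when those are also supplied.
#' @return An object of class `dye_pair`.
#' @examples
#' dp <- dye_pair(forster_radius_nm = 5.6,
#'                det_eff_donor = 0.3, det_eff_acceptor = 0.4,
#'                qy_donor = 0.8, qy_acceptor = 0.6)
#' dp$gamma
#' @export
dye_pair <- function(forster_radius_nm,
                     det_eff_donor = NULL, det_eff_acceptor = NULL,
                     qy_donor = NULL, qy_acceptor = NULL,
                     gamma = NULL) {
  stopifnot(is.numeric(forster_radius_nm), forster_radius_nm > 0)
  have_factors <- !is.null(det_eff_donor) && !is.null(det_eff_acceptor) &&
    !is.null(qy_donor) && !is.null(qy_acceptor)
  if (have_factors) {
    vals <- c(det_eff_donor, det_eff_acceptor, qy_donor, qy_acceptor)
    if (any(!is.finite(vals)) || any(vals <= 0))
      stop("detection efficiencies and quantum yields must all be finite and > 0")
    derived <- (det_eff_acceptor * qy_acceptor) / (det_eff_donor * qy_donor)
    if (!is.null(gamma) && abs(gamma - derived) > 1e-12)
      stop("supplied gamma (", gamma, ") disagrees with (eta_A*phi_A)/(eta_D*phi_D) = ",
           derived)
    gamma <- derived
  }
  if (is.null(gamma)) gamma <- 1
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be finite and > 0")
  structure(list(forster_radius_nm = forster_radius_nm,
                 det_eff_donor = det_eff_donor,
                 det_eff_acceptor = det_eff_acceptor,
                 qy_donor = qy_donor, qy_acceptor = qy_acceptor,
                 gamma = gamma),
            class = "dye_pair")
}

#' Detection-factor gamma of a dye pair
#'
#' gamma = (eta_A * phi_A) / (eta_D * phi_D).
#'
#' @param dye A [dye_pair()] with detection efficiencies and quantum
#'   yields set.
#' @return The gamma factor (dimensionless scalar).
#' @export
gamma_factor <- function(dye) {
  stopifnot(inherits(dye, "dye_pair"))
  f <- c(dye$det_eff_acceptor, dye$qy_acceptor, dye$det_eff_donor, dye$qy_donor)
  if (any(vapply(list(dye$det_eff_acceptor, dye$qy_acceptor,
                      dye$det_eff_donor, dye$qy_donor), is.null, logical(1))))
    stop("dye pair lacks detection efficiencies and/or quantum yields")
  if (any(!is.finite(f)) || any(f <= 0))
    stop("all four detection/quantum-yield factors must be > 0")
  (dye$det_eff_acceptor * dye$qy_acceptor) / (dye$det_eff_donor * dye$qy_donor)
}

#' Channel correction parameters
#'
#' Bundles the per-channel background levels, the donor-to-acceptor
#' crosstalk fraction alpha and the direct-acceptor-excitation fraction
#' delta used to correct raw FRET intensities.
#'
#' @param bkg_donor,bkg_acceptor,bkg_acceptor_aex Background counts (or
#'   count rates, for burst correction) in the donor channel, the
#'   acceptor channel under donor excitation, and the acceptor channel
#'   under acceptor excitation. All >= 0.
#' @param crosstalk_alpha Fraction of (background-subtracted) donor
#'   signal leaking into the acceptor channel; in `[0, 1)`.
#' @param direct_exc_delta Fraction of the (background-subtracted)
#'   acceptor-excitation signal subtracted to remove direct excitation
#'   of the acceptor by the donor laser; in `[0, 1)`.
#' @return An object of class `correction_set`.
#' @export
correction_set <- function(bkg_donor = 0, bkg_acceptor = 0,
                           bkg_acceptor_aex = 0,
                           crosstalk_alpha = 0, direct_exc_delta = 0) {
  b <- c(bkg_donor, bkg_acceptor, bkg_acceptor_aex)
  if (any(!is.finite(b)) || any(b < 0))
    stop("background terms must be finite and >= 0")
  if (!is.finite(crosstalk_alpha) || crosstalk_alpha < 0 || crosstalk_alpha >= 1)
    stop("crosstalk_alpha must lie in [0, 1)")
  if (!is.finite(direct_exc_delta) || direct_exc_delta < 0 || direct_exc_delta >= 1)
    stop("direct_exc_delta must lie in [0, 1)")
  structure(list(bkg_donor = bkg_donor, bkg_acceptor = bkg_acceptor,
                 bkg_acceptor_aex = bkg_acceptor_aex,
                 crosstalk_alpha = crosstalk_alpha,
                 direct_exc_delta = direct_exc_delta),
            class = "correction_set")
}

#' Raw microplate well intensities
#'
#' One well of a microplate-scanning FRET experiment: donor emission
#' under donor excitation (I_D_Dex), acceptor emission under donor
#' excitation (I_A_Dex) and acceptor emission under direct acceptor
#' excitation (I_A_Aex).
#'
#' @param i_d_dex,i_a_dex,i_a_aex Raw fluorescence counts, all >= 0.
#' @param well_id Well label.
#' @param nacl_mm NaCl concentration of the well in mM.
#' @return An object of class `well_intensities`.
#' @export
well_intensities <- function(i_d_dex, i_a_dex, i_a_aex = 0,
                             well_id = NA_character_, nacl_mm = NA_real_) {
  v <- c(i_d_dex, i_a_dex, i_a_aex)
  if (any(!is.finite(v))) stop("raw intensities must be finite")
  if (any(v < 0)) stop("raw intensities must be >= 0")
  structure(list(i_d_dex = i_d_dex, i_a_dex = i_a_dex, i_a_aex = i_a_aex,
                 well_id = well_id, nacl_mm = nacl_mm),
            class = "well_intensities")
}

#' Correct raw well intensities
#'
#' Applies the three standard corrections in order: background
#' subtraction per channel, donor crosstalk into the acceptor channel
#' (alpha times the background-subtracted donor signal) and direct
#' acceptor excitation (delta times the background-subtracted
#' acceptor-excitation signal):
#'
#' \deqn{I_D^{corr} = I_D^{Dex} - b_D}
#' \deqn{I_A^{corr} = I_A^{Dex} - b_A - \alpha I_D^{corr} -
#'       \delta (I_A^{Aex} - b_{AA})}
#'
#' Corrected values may be negative; they are deliberately not clamped
#' so that downstream proximity-ratio histograms can extend below zero.
#'
#' @param w A [well_intensities()] object.
#' @param c A [correction_set()].
#' @return A list with `i_d_corr` and `i_a_corr`.
#' @export
correct_intensities <- function(w, c = correction_set()) {
  stopifnot(inherits(w, "well_intensities"), inherits(c, "correction_set"))
  i_d_corr <- w$i_d_dex - c$bkg_donor
  i_a_corr <- w$i_a_dex - c$bkg_acceptor -
    c$crosstalk_alpha * i_d_corr -
    c$direct_exc_delta * (w$i_a_aex - c$bkg_acceptor_aex)
  list(i_d_corr = i_d_corr, i_a_corr = i_a_corr)
}

#' Proximity ratio
#'
#' P = I_A / (I_A + I_D) on corrected intensities (or raw photon counts
#' for bursts). The proximity ratio is the gamma-uncorrected apparent
#' FRET efficiency and is the primary observable of the analysis.
#'
#' @param i_a_corr,i_d_corr Corrected acceptor and donor intensities.
#'   May be negative after correction; P is then unbounded.
#' @param id Optional well/burst identifier used in error messages.
#' @return The proximity ratio (vectorised over its inputs).
#' @export
proximity_ratio <- function(i_a_corr, i_d_corr, id = NULL) {
  tot <- i_a_corr + i_d_corr
  if (any(!is.finite(tot))) stop("non-finite intensities")
  if (any(tot == 0)) {
    bad <- which(tot == 0)
    lab <- if (!is.null(id)) paste0(" (id: ", paste(id[bad], collapse = ", "), ")") else ""
    stop("proximity ratio undefined: corrected total intensity is zero", lab)
  }
  i_a_corr / tot
}

#' FRET efficiency from photon counts
#'
#' E = N_A / (N_A + gamma * N_D). With gamma = 1 this equals the
#' proximity ratio.
#'
#' @param n_a,n_d Acceptor and donor counts.
#' @param gamma Detection factor, > 0.
#' @return FRET efficiency.
#' @export
efficiency_from_counts <- function(n_a, n_d, gamma = 1) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  den <- n_a + gamma * n_d
  if (any(den <= 0)) stop("n_a + gamma * n_d must be > 0")
  n_a / den
}

#' FRET efficiency from dye separation
#'
#' E = 1 / (1 + (R/R0)^6).
#'
#' @param r_nm Dye separation in nm, > 0.
#' @param r0_nm Forster radius in nm, > 0.
#' @return FRET efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r_nm, r0_nm) {
  if (any(r_nm <= 0) || any(r0_nm <= 0)) stop("distances must be > 0")
  1 / (1 + (r_nm / r0_nm)^6)
}

#' Dye separation from FRET efficiency
#'
#' Inverse of [efficiency_from_distance()]: R = R0 * (1/E - 1)^(1/6).
#'
#' @param e FRET efficiency, strictly inside (0, 1).
#' @param r0_nm Forster radius in nm.
#' @return Distance in nm.
#' @export
distance_from_efficiency <- function(e, r0_nm) {
  if (any(e <= 0) || any(e >= 1))
    stop("efficiency must lie strictly in (0, 1) to invert for distance")
  if (any(r0_nm <= 0)) stop("r0_nm must be > 0")
  r0_nm * (1 / e - 1)^(1 / 6)
}

#' Proximity ratio from efficiency (and back)
#'
#' P = gamma / (gamma - 1 + 1/E). For gamma = 1, P equals E.
#'
#' @param e FRET efficiency in (0, 1].
#' @param gamma Detection factor, > 0.
#' @return Proximity ratio.
#' @export
p_from_efficiency <- function(e, gamma = 1) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (any(e <= 0) || any(e > 1)) stop("efficiency must lie in (0, 1]")
  # algebraically identical to gamma / (gamma - 1 + 1/e) but exact at
  # the e = 1 limit for every gamma
  gamma * e / (gamma * e + (1 - e))
}

#' @rdname p_from_efficiency
#' @param p Proximity ratio in (0, 1].
#' @export
efficiency_from_p <- function(p, gamma = 1) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (any(p <= 0) || any(p > 1)) stop("proximity ratio must lie in (0, 1]")
  # inverse of P = gamma E / (gamma E + 1 - E)
  p / (p + gamma * (1 - p))
}

#' Read a plate CSV
#'
#' Expects columns `well_id, nacl_mm, i_d_dex, i_a_dex, i_a_aex, role`
#' with role one of sample, donor_only, acceptor_only, no_fret_control,
#' buffer. Control wells feed [estimate_corrections()].
#'
#' @param path CSV file path.
#' @return A data.frame with the columns above.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "nacl_mm", "i_d_dex", "i_a_dex", "i_a_aex", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate CSV missing columns: ", paste(miss, collapse = ", "))
  ok <- c("sample", "donor_only", "acceptor_only", "no_fret_control", "buffer")
  bad <- setdiff(unique(df$role), ok)
  if (length(bad)) stop("unknown well roles: ", paste(bad, collapse = ", "))
  df
}

#' Estimate corrections from control wells
#'
#' Buffer wells give the per-channel backgrounds (means); donor-only
#' wells give the crosstalk fraction alpha as the ratio of
#' background-subtracted acceptor to donor signal; acceptor-only wells
#' give the direct-excitation fraction delta as the ratio of
#' background-subtracted acceptor (donor excitation) to
#' acceptor-excitation signal.
#'
#' @param plate A plate data.frame as returned by [read_plate_csv()].
#' @return A [correction_set()].
#' @export
estimate_corrections <- function(plate) {
  buf <- plate[plate$role == "buffer", , drop = FALSE]
  if (nrow(buf) == 0) stop("no buffer wells: cannot estimate backgrounds")
  b_d <- mean(buf$i_d_dex); b_a <- mean(buf$i_a_dex); b_aa <- mean(buf$i_a_aex)
  alpha <- 0
  don <- plate[plate$role == "donor_only", , drop = FALSE]
  if (nrow(don) > 0) {
    num <- mean(don$i_a_dex) - b_a
    den <- mean(don$i_d_dex) - b_d
    if (den <= 0) stop("donor-only wells have no donor signal above background")
    alpha <- max(0, num / den)
  }
  delta <- 0
  acc <- plate[plate$role == "acceptor_only", , drop = FALSE]
  if (nrow(acc) > 0) {
    den <- mean(acc$i_a_aex) - b_aa
    if (den <= 0) stop("acceptor-only wells have no acceptor-excitation signal above background")
    delta <- max(0, (mean(acc$i_a_dex) - b_a) / den)
  }
  correction_set(bkg_donor = b_d, bkg_acceptor = b_a, bkg_acceptor_aex = b_aa,
                 crosstalk_alpha = alpha, direct_exc_delta = delta)
}

#' Per-well proximity ratios for a plate
#'
#' Corrects every sample well and computes its proximity ratio.
#'
#' @param plate Plate data.frame ([read_plate_csv()]).
#' @param corrections A [correction_set()]; estimated from the plate's
#'   control wells when `NULL`.
#' @return The sample rows with added `i_d_corr`, `i_a_corr`, `p`.
#' @export
plate_proximity_ratios <- function(plate, corrections = NULL) {
  if (is.null(corrections)) corrections <- estimate_corrections(plate)
  s <- plate[plate$role == "sample", , drop = FALSE]
  i_d <- s$i_d_dex - corrections$bkg_donor
  i_a <- s$i_a_dex - corrections$bkg_acceptor -
    corrections$crosstalk_alpha * i_d -
    corrections$direct_exc_delta * (s$i_a_aex - corrections$bkg_acceptor_aex)
  s$i_d_corr <- i_d
  s$i_a_corr <- i_a
  s$p <- proximity_ratio(i_a, i_d, id = s$well_id)
  s
}
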