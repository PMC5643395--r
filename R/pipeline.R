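#' Pipeline run configuration
#'
#' Collects every tunable of the spFRET / titration pipeline with its
#' standard default: bursts of at least 50 photons separated by less
#' than 120 us, 0.02-wide proximity-ratio bins, mixture initialisation
#' at the canonical LF/MF/HF means, 100 mM low-salt normalisation
#' plateau, 0.35 nm contact cutoff, 200 ps running-average window and
#' the 20-150 ns trajectory analysis window.
#'
#' @param min_photons,max_gap_us Burst-search parameters.
#' @param bin_width Histogram bin width.
#' @param init_means Mixture initialisation means.
#' @param corrections A [correction_set()].
#' @param plateau_max_mm Titration normalisation threshold (mM).
#' @param weighted Weight titration fits by 1/sd^2.
#' @param d_cut_nm,angle_cut_deg,window_ps,t_start_ps,t_end_ps MD
#'   cutoffs and windows.
#' @param seed Seed for any stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(min_photons = 50, max_gap_us = 120,
                       bin_width = 0.02,
                       init_means = c(0.12, 0.39, 0.64),
                       corrections = correction_set(),
                       plateau_max_mm = 100, weighted = TRUE,
                       d_cut_nm = 0.35, angle_cut_deg = 30,
                       window_ps = 200,
                       t_start_ps = 20000, t_end_ps = 150000,
                       seed = 1) {
  structure(list(min_photons = min_photons, max_gap_us = max_gap_us,
                 bin_width = bin_width, init_means = init_means,
                 corrections = corrections,
                 plateau_max_mm = plateau_max_mm, weighted = weighted,
                 d_cut_nm = d_cut_nm, angle_cut_deg = angle_cut_deg,
                 window_ps = window_ps,
                 t_start_ps = t_start_ps, t_end_ps = t_end_ps,
                 seed = seed),
            class = "run_config")
}

#' Run the spFRET salt-series pipeline
#'
#' For each salt condition: burst search, per-burst proximity ratios,
#' 0.02-bin histogram, three-Gaussian LF/MF/HF decomposition and the
#' HF/(MF+HF) disassembly-intermediate fraction. Assembles the
#' conditions into the salt-vs-P contour matrix.
#'
#' @param streams Named list of [photon_stream()]s (or file paths read
#'   via [read_photon_stream()]); names are NaCl concentrations in mM.
#'   At least 2 conditions.
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes
#'   `contour.csv`, `hf_fractions.csv` and one `fit_<salt>mM.json` per
#'   condition. On any stage failure partial outputs are removed.
#' @return List with `histograms`, `fits`, `hf` (data.frame nacl_mm,
#'   hf_fraction, converged), `contour`.
#' @export
run_spfret_series <- function(streams, config = run_config(),
                              out_dir = NULL) {
  if (length(streams) < 2) stop("need >= 2 salt conditions")
  if (is.null(names(streams)) || any(!nzchar(names(streams))))
    stop("streams must be named by NaCl concentration (mM)")
  written <- character(0)
  cleanup <- function() if (length(written)) unlink(written)
  hists <- list(); fits <- list()
  for (nm in names(streams)) {
    res <- tryCatch({
      s <- streams[[nm]]
      if (is.character(s)) {
        if (!file.exists(s)) stop("stream file not found: ", s)
        s <- read_photon_stream(s)
      }
      bt <- detect_bursts(s, config$min_photons, config$max_gap_us)
      bt <- burst_proximity(bt, config$corrections)
      h <- build_histogram(bt$p, config$bin_width)
      fit <- fit_three_gaussians(h, config$init_means)
      list(h = h, fit = fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      cleanup()
      stop("spFRET pipeline failed at condition ", nm, " mM: ",
           conditionMessage(res))
    }
    hists[[nm]] <- res$h
    fits[[nm]] <- res$fit
  }
  hf <- data.frame(nacl_mm = as.numeric(names(streams)),
                   hf_fraction = vapply(fits, hf_fraction, numeric(1)),
                   converged = vapply(fits, function(f) f$converged,
                                      logical(1)))
  contour <- contour_matrix(hists)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(out_dir, "contour.csv")
    utils::write.csv(contour, f, row.names = FALSE); written <- c(written, f)
    f <- file.path(out_dir, "hf_fractions.csv")
    utils::write.csv(hf, f, row.names = FALSE); written <- c(written, f)
    for (nm in names(fits)) {
      f <- file.path(out_dir, paste0("fit_", nm, "mM.json"))
      jsonlite::write_json(list(nacl_mm = as.numeric(nm),
                                components = fits[[nm]]$components,
                                converged = fits[[nm]]$converged,
                                hf_fraction = hf_fraction(fits[[nm]])),
                           f, auto_unbox = TRUE, digits = NA)
      written <- c(written, f)
    }
  }
  list(histograms = hists, fits = fits, hf = hf, contour = contour)
}

#' Run the salt-titration pipeline
#'
#' Per construct: normalises each replicate series to its low-salt
#' plateau, fits the sigmoidal disassembly model, averages c1/2 over
#' replicates (SE = SEM over replicates when >= 2, otherwise the fit
#' covariance SE) and compares all constructs pairwise.
#'
#' @param data Long-format data.frame with columns `nacl_mm`, `p`,
#'   `replicate_id`, `construct` (see [read_titration_csv()]), or a
#'   path to such a CSV.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for `fits.json` and
#'   `comparison.csv`.
#' @return List with `fits` (per construct, per replicate), `table`
#'   (construct, c_half_mm, se_c_half, n_replicates), `comparison`.
#' @export
run_titration <- function(data, config = run_config(), out_dir = NULL) {
  if (is.character(data)) data <- read_titration_csv(data)
  need <- c("nacl_mm", "p", "replicate_id", "construct")
  stopifnot(all(need %in% names(data)))
  constructs <- unique(data$construct)
  fits <- list(); rows <- list()
  for (cn in constructs) {
    d <- data[data$construct == cn, , drop = FALSE]
    reps <- unique(d$replicate_id)
    rep_fits <- lapply(reps, function(r) {
      dr <- d[d$replicate_id == r, , drop = FALSE]
      ser <- titration_series(dr$nacl_mm, dr$p)
      ser <- normalize_series(ser, config$plateau_max_mm)
      fit_titration(ser, weighted = FALSE)  # single replicate: no SDs
    })
    names(rep_fits) <- as.character(reps)
    ch <- vapply(rep_fits, function(f) f$c_half_mm, numeric(1))
    if (length(ch) >= 2) {
      c_half <- mean(ch); se <- stats::sd(ch) / sqrt(length(ch))
    } else {
      c_half <- ch[[1]]; se <- rep_fits[[1]]$se_c_half
    }
    fits[[cn]] <- rep_fits
    rows[[cn]] <- data.frame(construct = cn, c_half_mm = c_half,
                             se_c_half = se, n_replicates = length(ch))
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  comparison <- if (nrow(tab) >= 2) compare_constructs(tab) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(tab, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(comparison))
      utils::write.csv(comparison$pairs,
                       file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
  }
  list(fits = fits, table = tab, comparison = comparison)
}
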