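#' Assemble a titration series from replicate measurements
#'
#' Collapses per-replicate proximity ratios to per-concentration mean,
#' SD and replicate count.
#'
#' @param nacl_mm NaCl concentration per measurement (mM).
#' @param p Proximity ratio per measurement.
#' @param replicate_id Optional replicate labels (unused beyond
#'   counting).
#' @return A data.frame of class `titration_series` with columns
#'   `nacl_mm`, `p_mean`, `p_sd`, `n_replicates`, ordered by
#'   concentration.
#' @export
titration_series <- function(nacl_mm, p, replicate_id = NULL) {
  stopifnot(length(nacl_mm) == length(p))
  if (any(nacl_mm < 0)) stop("nacl_mm must be >= 0")
  sp <- split(p, nacl_mm)
  out <- data.frame(nacl_mm = as.numeric(names(sp)),
                    p_mean = vapply(sp, mean, numeric(1)),
                    p_sd = vapply(sp, function(v)
                      if (length(v) > 1) stats::sd(v) else 0, numeric(1)),
                    n_replicates = lengths(sp))
  out <- out[order(out$nacl_mm), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Normalise a salt-titration series to its low-salt plateau
#'
#' Divides all mean proximity ratios and their SDs by the mean P over
#' the points at <= `plateau_max_mm` NaCl, so the low-salt plateau sits
#' at 1. Idempotent on an already-normalised series.
#'
#' @param points A `titration_series` (or data.frame with `nacl_mm`,
#'   `p_mean`, `p_sd`).
#' @param plateau_max_mm Concentration ceiling defining the low-salt
#'   plateau (default 100 mM).
#' @return The series with `p_mean` and `p_sd` rescaled.
#' @export
normalize_series <- function(points, plateau_max_mm = 100) {
  stopifnot(all(c("nacl_mm", "p_mean") %in% names(points)))
  low <- points$nacl_mm <= plateau_max_mm
  if (!any(low)) stop("no points at <= ", plateau_max_mm, " mM to define the plateau")
  ref <- mean(points$p_mean[low])
  if (!is.finite(ref) || ref <= 0) stop("low-salt plateau mean is not positive")
  points$p_mean <- points$p_mean / ref
  if ("p_sd" %in% names(points)) points$p_sd <- points$p_sd / ref
  points
}

#' Fit the sigmoidal salt-disassembly model
#'
#' Fits the 4-parameter logistic
#' \deqn{P(x) = P(0) + \frac{P(\infty) - P(0)}{1 + e^{(c_{1/2} - x)/b}}}
#' to a titration series by (weighted) nonlinear least squares. The
#' inflection point c1/2 is the NaCl concentration of half decay and is
#' the nucleosome-stability readout; b sets the width of the
#' transition. P at the fitted c1/2 equals (P(0) + P(inf)) / 2
#' regardless of the sign convention of b.
#'
#' @param points A `titration_series`; needs >= 5 distinct
#'   concentrations spanning the transition.
#' @param weighted Use weights 1 / p_sd^2 when all SDs are positive
#'   (default TRUE). Ignored (with unweighted fall-back) when any SD is
#'   zero or missing.
#' @return An object of class `titration_fit`: `p0`, `p_inf`,
#'   `c_half_mm`, `slope_b`, `se_c_half`, `covariance`, `converged`,
#'   `extrapolated` (c1/2 outside the fitted concentration span) and
#'   the fitted `points`.
#' @export
fit_titration <- function(points, weighted = TRUE) {
  stopifnot(all(c("nacl_mm", "p_mean") %in% names(points)))
  x <- points$nacl_mm
  y <- points$p_mean
  if (length(unique(x)) < 5)
    stop("need >= 5 distinct concentrations to fit the sigmoid")
  if (max(y) - min(y) < 1e-8 * max(abs(y), 1))
    stop("no transition: series is flat")
  w <- rep(1, length(y))
  if (weighted && "p_sd" %in% names(points) &&
      all(is.finite(points$p_sd)) && all(points$p_sd > 0))
    w <- 1 / points$p_sd^2
  # starting values: plateaus from the extremes, c1/2 from the
  # concentration nearest the half-decay level
  p0_0 <- y[which.min(x)]
  pinf_0 <- y[which.max(x)]
  half <- (p0_0 + pinf_0) / 2
  c0 <- x[which.min(abs(y - half))]
  b0 <- diff(range(x)) / 10
  df <- data.frame(x = x, y = y)
  do_fit <- function(wts) tryCatch(
    minpack.lm::nlsLM(y ~ p0 + (p_inf - p0) / (1 + exp((c_half - x) / b)),
                      data = df, weights = wts,
                      start = list(p0 = p0_0, p_inf = pinf_0,
                                   c_half = c0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  fit <- do_fit(w)
  if (is.null(fit) && !all(w == 1)) {
    # replicate-SD weights can be ill-conditioned (tiny SDs from few
    # replicates); fall back to the unweighted fit rather than abort
    warning("weighted sigmoid fit failed; refitting unweighted")
    fit <- do_fit(rep(1, length(y)))
  }
  converged <- !is.null(fit)
  if (!converged)
    stop("sigmoid fit failed to converge")
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  out <- structure(list(p0 = unname(cf["p0"]), p_inf = unname(cf["p_inf"]),
                        c_half_mm = unname(cf["c_half"]),
                        slope_b = unname(cf["b"]),
                        se_c_half = unname(sqrt(vc["c_half", "c_half"])),
                        covariance = vc,
                        converged = converged,
                        extrapolated = cf["c_half"] < min(x) || cf["c_half"] > max(x),
                        points = points,
                        model = fit),
                   class = "titration_fit")
  out
}

#' Predict from a titration fit
#'
#' @param object A `titration_fit`.
#' @param nacl_mm Concentrations at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Predicted proximity ratios.
#' @export
predict.titration_fit <- function(object, nacl_mm, ...) {
  with(object, p0 + (p_inf - p0) / (1 + exp((c_half_mm - nacl_mm) / slope_b)))
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("sigmoidal titration fit: c1/2 = %.1f +/- %.1f mM (b = %.1f, P0 = %.3f, Pinf = %.3f)\n",
              x$c_half_mm, x$se_c_half, x$slope_b, x$p0, x$p_inf))
  invisible(x)
}

#' Compare c1/2 values across constructs
#'
#' Builds a pairwise comparison table of fitted c1/2 values. For each
#' pair the z-score is the difference divided by the pooled standard
#' error; pairs with |z| < 2 are flagged "coinciding" (the signature
#' used to detect indistinguishable disassembly steps, e.g. the
#' H2B-Ia vs H2B-Dya constructs of RE mutants), otherwise "distinct".
#'
#' @param fits Named list of `titration_fit`s (names are construct
#'   labels), or a data.frame with columns `construct`, `c_half_mm`,
#'   `se_c_half` (e.g. replicate-averaged values).
#' @return A list with `table` (construct, c_half_mm, se_c_half) and
#'   `pairs` (construct_1, construct_2, delta_mm, z, verdict).
#' @export
compare_constructs <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits[, c("construct", "c_half_mm", "se_c_half")]
  } else {
    stopifnot(length(fits) >= 2, !is.null(names(fits)))
    tab <- data.frame(construct = names(fits),
                      c_half_mm = vapply(fits, function(f) f$c_half_mm, numeric(1)),
                      se_c_half = vapply(fits, function(f) f$se_c_half, numeric(1)))
  }
  if (nrow(tab) < 2) stop("need >= 2 constructs to compare")
  rownames(tab) <- NULL
  idx <- utils::combn(nrow(tab), 2)
  pairs <- data.frame(construct_1 = tab$construct[idx[1, ]],
                      construct_2 = tab$construct[idx[2, ]])
  d <- tab$c_half_mm[idx[1, ]] - tab$c_half_mm[idx[2, ]]
  se2 <- tab$se_c_half[idx[1, ]]^2 + tab$se_c_half[idx[2, ]]^2
  pairs$delta_mm <- d
  pairs$z <- ifelse(is.finite(se2) & se2 > 0, d / sqrt(se2), NA_real_)
  pairs$verdict <- ifelse(is.na(pairs$z), "skipped (missing SE)",
                          ifelse(abs(pairs$z) < 2, "coinciding", "distinct"))
  if (any(is.na(pairs$z)))
    warning("pairwise comparison skipped for pairs with missing SE")
  list(table = tab, pairs = pairs)
}

#' Read a titration CSV
#'
#' Expects columns `nacl_mm, p, replicate_id, construct` and optionally
#' `labeling_scheme` (IbIa, H2B-Ia or H2B-Dya).
#'
#' @param path CSV path.
#' @return A data.frame with those columns.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nacl_mm", "p", "replicate_id", "construct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("titration CSV missing columns: ", paste(miss, collapse = ", "))
  df
}
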