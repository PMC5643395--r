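#' Photon stream
#'
#' A time-ordered stream of single-photon detection events from a
#' diffusion spFRET measurement, with per-channel background rates and
#' the acquisition duration as metadata.
#'
#' @param timestamp_us Photon arrival times in microseconds, sorted
#'   non-decreasing, all >= 0.
#' @param channel Detection channel per photon, `"D"` (donor) or `"A"`
#'   (acceptor).
#' @param bkg_rate_donor,bkg_rate_acceptor Background count rates per
#'   channel in counts/s.
#' @param duration_us Acquisition duration; defaults to the last
#'   timestamp. Must be >= the last timestamp.
#' @return An object of class `photon_stream`.
#' @export
photon_stream <- function(timestamp_us, channel,
                          bkg_rate_donor = 0, bkg_rate_acceptor = 0,
                          duration_us = NULL) {
  if (length(timestamp_us) != length(channel))
    stop("timestamp and channel lengths differ")
  channel <- as.character(channel)
  if (length(channel) && !all(channel %in% c("D", "A")))
    stop("channel must be 'D' or 'A'")
  if (length(timestamp_us)) {
    if (any(!is.finite(timestamp_us)) || any(timestamp_us < 0))
      stop("timestamps must be finite and >= 0")
    if (is.unsorted(timestamp_us)) stop("photon stream is not sorted by timestamp")
  }
  if (is.null(duration_us))
    duration_us <- if (length(timestamp_us)) timestamp_us[length(timestamp_us)] else 0
  if (duration_us < (if (length(timestamp_us)) timestamp_us[length(timestamp_us)] else 0))
    stop("duration_us is shorter than the last timestamp")
  structure(list(timestamp_us = as.numeric(timestamp_us),
                 channel = channel,
                 bkg_rate_donor = bkg_rate_donor,
                 bkg_rate_acceptor = bkg_rate_acceptor,
                 duration_us = duration_us),
            class = "photon_stream")
}

#' Read a photon stream from CSV/TSV
#'
#' Expects a header `timestamp_us,channel` with channel D or A.
#'
#' @param path File path; comma- or tab-separated.
#' @param ... Passed to [photon_stream()] (background rates, duration).
#' @return A `photon_stream`.
#' @export
read_photon_stream <- function(path, ...) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("timestamp_us", "channel") %in% names(df)))
    stop("photon stream file needs columns timestamp_us, channel")
  photon_stream(df$timestamp_us, df$channel, ...)
}

#' Detect single-molecule bursts
#'
#' Partitions the merged (donor + acceptor) photon sequence into
#' maximal clusters in which every consecutive inter-photon gap is
#' strictly less than `max_gap_us`; clusters with at least
#' `min_photons` photons are reported as bursts. A gap exactly equal to
#' `max_gap_us` splits. Bursts are disjoint and time-ordered.
#'
#' @param s A [photon_stream()].
#' @param min_photons Minimum photons per burst (default 50).
#' @param max_gap_us Maximum inter-photon separation within a burst in
#'   microseconds (default 120).
#' @return A data.frame of class `burst_table` with columns `start_us`,
#'   `end_us`, `n_donor_raw`, `n_acceptor_raw` plus the background
#'   rates carried over as attributes.
#' @export
detect_bursts <- function(s, min_photons = 50, max_gap_us = 120) {
  stopifnot(inherits(s, "photon_stream"))
  if (min_photons < 1) stop("min_photons must be >= 1")
  if (max_gap_us <= 0) stop("max_gap_us must be > 0")
  t <- s$timestamp_us
  out <- data.frame(start_us = numeric(0), end_us = numeric(0),
                    n_donor_raw = integer(0), n_acceptor_raw = integer(0))
  if (length(t)) {
    # cluster id increments at every gap >= max_gap_us
    cl <- cumsum(c(1L, as.integer(diff(t) >= max_gap_us)))
    size <- tabulate(cl)
    keep <- which(size >= min_photons)
    if (length(keep)) {
      is_a <- s$channel == "A"
      # first/last photon index of each cluster via cumulative sizes
      ends_idx <- cumsum(size)
      starts_idx <- c(1L, ends_idx[-length(ends_idx)] + 1L)
      start <- t[starts_idx[keep]]
      end <- t[ends_idx[keep]]
      n_a <- as.integer(rowsum(as.numeric(is_a), cl)[keep, 1])
      n_tot <- size[keep]
      out <- data.frame(start_us = start, end_us = end,
                        n_donor_raw = n_tot - n_a, n_acceptor_raw = n_a)
    }
  }
  attr(out, "bkg_rate_donor") <- s$bkg_rate_donor
  attr(out, "bkg_rate_acceptor") <- s$bkg_rate_acceptor
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Per-burst proximity ratios
#'
#' Corrects each burst's raw counts for channel background (expected
#' counts = background rate x burst duration) and donor crosstalk, then
#' computes P = N_A_corr / (N_A_corr + N_D_corr). Bursts whose
#' corrected total is zero are dropped with a warning.
#'
#' @param bursts A `burst_table` from [detect_bursts()].
#' @param corrections A [correction_set()]; backgrounds are interpreted
#'   as count rates in counts/s. When the burst table carries stream
#'   background rates and `corrections` leaves them zero, the stream
#'   rates are used.
#' @return The burst table with added `n_donor_corr`, `n_acceptor_corr`
#'   and `p` columns (flagged bursts removed).
#' @export
burst_proximity <- function(bursts, corrections = correction_set()) {
  stopifnot(inherits(bursts, "burst_table"))
  rate_d <- corrections$bkg_donor
  rate_a <- corrections$bkg_acceptor
  if (rate_d == 0 && !is.null(attr(bursts, "bkg_rate_donor")))
    rate_d <- attr(bursts, "bkg_rate_donor")
  if (rate_a == 0 && !is.null(attr(bursts, "bkg_rate_acceptor")))
    rate_a <- attr(bursts, "bkg_rate_acceptor")
  dur_s <- (bursts$end_us - bursts$start_us) * 1e-6
  n_d <- bursts$n_donor_raw - rate_d * dur_s
  n_a <- bursts$n_acceptor_raw - rate_a * dur_s -
    corrections$crosstalk_alpha * n_d
  tot <- n_a + n_d
  bad <- tot == 0
  if (any(bad)) {
    warning(sum(bad), " burst(s) with zero corrected total excluded")
    keep <- !bad
    bursts <- bursts[keep, , drop = FALSE]
    n_d <- n_d[keep]; n_a <- n_a[keep]; tot <- tot[keep]
  }
  bursts$n_donor_corr <- n_d
  bursts$n_acceptor_corr <- n_a
  bursts$p <- n_a / tot
  bursts
}

#' Proximity-ratio histogram
#'
#' Bins proximity ratios on the fixed range `[-0.1, 1.1)` with
#' half-open, left-closed bins of width `bin_width` (default 0.02, the
#' convention used for spFRET probability distributions). Values
#' outside the range accumulate in the nearest edge bin.
#'
#' @param ps Numeric vector of per-burst proximity ratios.
#' @param bin_width Bin width (default 0.02).
#' @param range Histogram range, default `c(-0.1, 1.1)`.
#' @return An object of class `p_histogram`: list with `bin_lo`,
#'   `bin_hi`, `mid`, `counts`, `frequency` (counts normalised to sum
#'   1; all-NA when the input is empty, with an `empty` flag).
#' @export
build_histogram <- function(ps, bin_width = 0.02, range = c(-0.1, 1.1)) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  nb <- as.integer(round((range[2] - range[1]) / bin_width))
  edges <- range[1] + (0:nb) * bin_width
  if (length(ps)) {
    # left-closed bins [lo, lo + width); the small forward shift keeps
    # values sitting exactly on an edge in the bin to their right
    # despite floating-point edge representation
    idx <- floor((ps - range[1]) / bin_width + 1e-9) + 1L
    idx[idx < 1] <- 1L
    idx[idx > nb] <- nb
    counts <- tabulate(idx, nbins = nb)
  } else counts <- integer(nb)
  total <- sum(counts)
  freq <- if (total > 0) counts / total else rep(NA_real_, nb)
  structure(list(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                 mid = (edges[-length(edges)] + edges[-1]) / 2,
                 counts = counts, frequency = freq,
                 bin_width = bin_width, empty = total == 0),
            class = "p_histogram")
}

#' @export
print.p_histogram <- function(x, ...) {
  cat("proximity-ratio histogram: ", sum(x$counts), " values in ",
      length(x$counts), " bins of width ", x$bin_width, "\n", sep = "")
  invisible(x)
}

#' Write a burst table or histogram to CSV
#'
#' @param x A `burst_table` or `p_histogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bursts_csv <- function(x, path) {
  stopifnot(inherits(x, "burst_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bursts_csv
#' @export
write_histogram_csv <- function(x, path) {
  stopifnot(inherits(x, "p_histogram"))
  utils::write.csv(data.frame(bin_lo = x$bin_lo, bin_hi = x$bin_hi,
                              count = x$counts, frequency = x$frequency),
                   path, row.names = FALSE)
  invisible(path)
}
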