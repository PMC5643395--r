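#' Three-Gaussian decomposition of a proximity-ratio histogram
#'
#' Fits the binned frequency curve with a sum of three Gaussian
#' components and labels them LF / MF / HF (low-, mid-, high-FRET) by
#' ascending fitted mean. The LF state corresponds to open nucleosomes
#' or free DNA, MF to the intact nucleosome and HF to the partially
#' disassembled intermediate with the dyes brought closer together.
#' Component weights are the areas under each peak
#' (amplitude x sigma x sqrt(2*pi)), not the amplitudes.
#'
#' The model evaluated at the bin centres x is
#' \deqn{f(x) = \sum_i a_i \, N(x; \mu_i, \sigma_i) \, \Delta}
#' with \eqn{\Delta} the bin width, so the fitted areas `a_i` are on
#' the frequency scale and the derived fractions `a_i / sum(a)` are
#' invariant under rescaling of the histogram counts. Means are
#' bounded to the histogram range `[-0.1, 1.1]` and sigmas to
#' `[0.01, 0.3]`.
#'
#' @param h A [build_histogram()] result with at least 3 nonzero bins.
#' @param init_means Initial component means, strictly increasing;
#'   default `c(0.12, 0.39, 0.64)`, the canonical LF/MF/HF positions.
#' @param init_sigmas Initial widths (default 0.05 each).
#' @return An object of class `mixture_fit`: data.frame `components`
#'   (label, mean, sigma, area, fraction), `residual_sse`, `converged`,
#'   `degenerate` (TRUE when two fitted means fall within 0.02) and
#'   `small_component` (labels whose area is < 1e-3 of the total, also
#'   checked by a two-component re-fit stored in `refit2`).
#' @export
fit_three_gaussians <- function(h, init_means = c(0.12, 0.39, 0.64),
                                init_sigmas = rep(0.05, 3)) {
  stopifnot(inherits(h, "p_histogram"))
  if (h$empty || sum(h$counts > 0) < 3)
    stop("histogram must have at least 3 nonzero bins")
  if (is.unsorted(init_means, strictly = TRUE))
    stop("init_means must be strictly increasing")
  fit <- gauss_mix_ls(h, init_means, init_sigmas)
  ord <- order(fit$means)
  comp <- data.frame(label = c("LF", "MF", "HF"),
                     mean = fit$means[ord],
                     sigma = fit$sigmas[ord],
                     area = fit$areas[ord])
  comp$fraction <- comp$area / sum(comp$area)
  degenerate <- any(diff(comp$mean) < 0.02)
  small <- comp$label[comp$area < 1e-3 * sum(comp$area)]
  refit2 <- NULL
  if (length(small)) {
    # robustness check: re-fit with the two dominant components only
    big <- order(comp$area, decreasing = TRUE)[1:2]
    m2 <- sort(comp$mean[big]); s2 <- comp$sigma[big][order(comp$mean[big])]
    refit2 <- tryCatch(gauss_mix_ls(h, m2, s2), error = function(e) NULL)
  }
  structure(list(components = comp,
                 residual_sse = fit$sse,
                 converged = fit$converged,
                 degenerate = degenerate,
                 small_component = small,
                 refit2 = refit2),
            class = "mixture_fit")
}

# least-squares Gaussian mixture on binned frequencies; k = length(means)
gauss_mix_ls <- function(h, means, sigmas) {
  k <- length(means)
  x <- h$mid
  y <- h$frequency
  bw <- h$bin_width
  model <- function(par) {
    m <- par[1:k]; s <- par[(k + 1):(2 * k)]; a <- par[(2 * k + 1):(3 * k)]
    rowSums(vapply(seq_len(k),
                   function(i) a[i] * stats::dnorm(x, m[i], s[i]) * bw,
                   numeric(length(x))))
  }
  resid_fn <- function(par) y - model(par)
  start <- c(means, sigmas, rep(1 / k, k))
  lower <- c(rep(-0.1, k), rep(0.01, k), rep(0, k))
  upper <- c(rep(1.1, k), rep(0.3, k), rep(Inf, k))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(means = means, sigmas = sigmas, areas = rep(1 / k, k),
                sse = NA_real_, converged = FALSE))
  }
  par <- fit$par
  list(means = par[1:k], sigmas = par[(k + 1):(2 * k)],
       areas = par[(2 * k + 1):(3 * k)],
       sse = sum(resid_fn(par)^2),
       converged = fit$info %in% 1:4)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("three-Gaussian mixture fit (converged: ", x$converged, ")\n", sep = "")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Disassembly-intermediate fraction HF / (MF + HF)
#'
#' The fraction of partially disassembled nucleosomes (HF) relative to
#' the sum of intact (MF) plus partially disassembled nucleosomes.
#' Open nucleosomes / free DNA (LF) are excluded by construction.
#'
#' @param m A [fit_three_gaussians()] result.
#' @return Scalar fraction in `[0, 1]`.
#' @export
hf_fraction <- function(m) {
  stopifnot(inherits(m, "mixture_fit"))
  if (!m$converged) stop("mixture fit did not converge")
  a <- stats::setNames(m$components$area, m$components$label)
  den <- a[["MF"]] + a[["HF"]]
  if (den == 0) stop("HF fraction undefined: MF + HF area is zero")
  unname(a[["HF"]] / den)
}

#' Export a salt-series contour matrix
#'
#' Assembles per-condition histograms into the matrix representation of
#' a salt-series contour plot: one row per NaCl concentration, one
#' column per proximity-ratio bin, values the bin frequencies.
#'
#' @param hists Named list of `p_histogram`s; names are the NaCl
#'   concentrations in mM.
#' @return A data.frame with `nacl_mm` followed by one column per bin
#'   (named by bin centre).
#' @export
contour_matrix <- function(hists) {
  stopifnot(length(hists) > 0, !is.null(names(hists)))
  mids <- hists[[1]]$mid
  rows <- lapply(hists, function(h) {
    stopifnot(inherits(h, "p_histogram"), length(h$mid) == length(mids))
    h$frequency
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- sprintf("p_%.2f", mids)
  cbind(data.frame(nacl_mm = as.numeric(names(hists))), out)
}
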