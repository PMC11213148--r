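#' Histogram of normalized participation ratios
#'
#' Equal-width bins spanning the observed range of `p`. The automatic bin
#' rule uses `ceiling(sqrt(N_tot))` bins (64 bins for a 64x64 image), which
#' resolves the delocalized peak well enough for the Lorentzian fit without
#' starving individual bins.
#'
#' @param p Vector of normalized participation ratios in `(0, 1]`.
#' @param n_bins Number of bins, or `"auto"` for the square-root rule.
#' @return An object of class `pr_histogram`: list with `bin_edges`,
#'   `bin_centers`, `counts`, `bin_rule`.
#' @export
pr_histogram <- function(p, n_bins = "auto") {
  if (length(p) == 0L) stop("empty participation vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1 + 1e-12)) {
    stop("normalized participation ratios must lie in (0, 1]", call. = FALSE)
  }
  rule <- if (identical(n_bins, "auto")) "sqrt" else "fixed"
  nb <- if (rule == "sqrt") ceiling(sqrt(length(p))) else as.integer(n_bins)
  if (nb < 1L) stop("need at least one bin", call. = FALSE)
  lo <- min(p); hi <- max(p)
  if (hi - lo < .Machine$double.eps * 4) {
    # degenerate (near-constant) distribution: open a token span around it
    half <- max(abs(lo), 1) * 1e-8
    lo <- lo - half; hi <- hi + half
  }
  edges <- seq(lo, hi, length.out = nb + 1L)
  counts <- tabulate(pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), nb),
                     nbins = nb)
  structure(
    list(bin_edges = edges,
         bin_centers = (edges[-1L] + edges[-(nb + 1L)]) / 2,
         counts = counts,
         bin_rule = rule),
    class = "pr_histogram"
  )
}

#' Fit a Lorentzian to the participation-ratio distribution
#'
#' The bulk of an image's modes are delocalized and pile up in a single peak
#' of the normalized-participation-ratio histogram; a Lorentzian (Cauchy)
#' profile describes that peak well. The fit is peak-normalized,
#' `count(b) ~ A * Gamma^2 / ((p_b - lambda0)^2 + Gamma^2)` over bin centers
#' `p_b` - the same shape as the normalized Lorentzian density up to the
#' amplitude scale `A`, which is free because the data are counts.
#' Levenberg-Marquardt least squares is initialized at the max-count bin
#' (`lambda0`), the max count (`A`) and half the naive FWHM read off the
#' histogram (`Gamma`); if it fails to converge, a 200 x 200 grid search over
#' `(lambda0, Gamma)` with `A` solved in closed form is used instead.
#'
#' Because the premise of the method is that the delocalized modes are the
#' majority, the peak search is anchored to the majority cluster: the
#' initial bin and the admissible `lambda0` range are restricted to
#' participation values at or above the count-weighted median of the
#' distribution. For a unimodal histogram this coincides with the global
#' max-count bin; when a narrow spike of localized modes coexists with the
#' broad delocalized peak, it keeps the fit on the peak the selection rule
#' is defined against.
#'
#' @param hist A [pr_histogram()] with at least 5 non-empty bins.
#' @return An object of class `lorentzian_fit`: list with `amplitude`,
#'   `lambda0` (peak location), `gamma` (half width at half maximum),
#'   `converged`, `residual_norm`, `method`.
#' @export
fit_lorentzian <- function(hist) {
  stopifnot(inherits(hist, "pr_histogram"))
  x <- hist$bin_centers
  y <- as.numeric(hist$counts)
  if (sum(y > 0) < 5L) {
    stop("degenerate histogram: fewer than 5 non-empty bins; ",
         "use more bins or check for a near-constant participation ratio",
         call. = FALSE)
  }
  bw <- mean(diff(hist$bin_edges))
  # majority anchor: the delocalized cluster holds at least half the modes
  med <- weighted_median(x, y)
  floor_l0 <- med - bw
  eligible <- which(x >= floor_l0)
  a0 <- max(y[eligible])
  l0 <- x[eligible[which.max(y[eligible])]]
  g0 <- max(naive_fwhm(x[eligible], y[eligible]) / 2, bw / 2)

  fit <- NULL
  ok <- FALSE
  try({
    fit <- minpack.lm::nlsLM(
      y ~ A * G^2 / ((x - l0)^2 + G^2),
      start = list(A = a0, l0 = l0, G = g0),
      lower = c(A = 0, l0 = floor_l0, G = bw / 100),
      upper = c(A = 10 * a0, l0 = max(x) + 10 * bw, G = diff(range(x)) + bw),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    ok <- fit$convInfo$isConv
  }, silent = TRUE)

  if (ok) {
    cf <- stats::coef(fit)
    res <- sqrt(sum(stats::resid(fit)^2))
    out <- list(amplitude = unname(cf["A"]), lambda0 = unname(cf["l0"]),
                gamma = abs(unname(cf["G"])), converged = TRUE,
                residual_norm = res, method = "levenberg-marquardt")
  } else {
    out <- lorentzian_grid_search(x, y, l0_floor = floor_l0)
  }
  structure(out, class = "lorentzian_fit")
}

# median of bin centers weighted by counts
weighted_median <- function(x, w) {
  o <- order(x)
  cs <- cumsum(w[o]) / sum(w)
  x[o][which(cs >= 0.5)[1L]]
}

# FWHM read directly from the histogram: span of bins above half the peak
naive_fwhm <- function(x, y) {
  above <- which(y >= max(y) / 2)
  diff(range(x[above]))
}

# fallback: exhaustive search over (lambda0, gamma); amplitude in closed form
lorentzian_grid_search <- function(x, y, n_grid = 200L, l0_floor = min(x)) {
  l_grid <- seq(max(min(x), l0_floor), max(x), length.out = n_grid)
  g_grid <- seq(diff(range(x)) / (4 * n_grid), diff(range(x)),
                length.out = n_grid)
  best <- list(rss = Inf)
  for (g in g_grid) {
    for (l in l_grid) {
      f <- g^2 / ((x - l)^2 + g^2)
      a <- sum(y * f) / sum(f^2)   # least-squares amplitude given the shape
      rss <- sum((y - a * f)^2)
      if (rss < best$rss) best <- list(rss = rss, A = a, l0 = l, G = g)
    }
  }
  list(amplitude = best$A, lambda0 = best$l0, gamma = best$G,
       converged = FALSE, residual_norm = sqrt(best$rss),
       method = "grid-search")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat("Lorentzian fit (", x$method, "):\n",
      "  lambda0 = ", format(x$lambda0),
      ", gamma (HWHM) = ", format(x$gamma),
      ", amplitude = ", format(x$amplitude), "\n",
      "  residual norm = ", format(x$residual_norm), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.lorentzian_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, lambda0 = x$lambda0,
                 gamma = x$gamma, converged = x$converged,
                 residual_norm = x$residual_norm, method = x$method)
}

#' Select localized modes from the Lorentzian threshold
#'
#' The participation threshold is the lower bound of the fitted peak,
#' `p* = lambda0 - k * gamma` (with the default `k = 1`, the half-maximum
#' point of the Lorentzian). A running median of width `smooth_window`
#' is applied to the normalized participation ratios in eigenvalue order,
#' and the maximal initial contiguous run of smoothed values below `p*`
#' defines the low-eigenvalue localized band (its last eigenvalue is
#' `E_low`); the symmetric scan from the top defines `E_high`. Modes with
#' eigenvalue `<= E_low` or `>= E_high` are kept; the delocalized
#' mid-spectrum band in between - the noise carrier - is discarded.
#'
#' @param spectrum A `mode_spectrum`.
#' @param fit A `lorentzian_fit`.
#' @param k Threshold width multiplier in `p* = lambda0 - k * gamma`.
#' @param smooth_window Odd integer width of the running median (default 5);
#'   guards the contiguity scan against single-mode outliers.
#' @return An object of class `mode_selection`: list with `p_star`, `E_low`,
#'   `E_high`, `keep_mask`, `n_kept`, `compression_fraction`
#'   (`1 - n_kept / N_tot`), `warning_flag` (TRUE when the threshold was
#'   uninformative: every mode kept or every mode discarded), `k`,
#'   `smooth_window`.
#' @export
select_modes <- function(spectrum, fit, k = 1, smooth_window = 5L) {
  stopifnot(inherits(spectrum, "mode_spectrum"), inherits(fit, "lorentzian_fit"))
  if (fit$gamma <= 0) stop("fit has nonpositive gamma", call. = FALSE)
  if (smooth_window %% 2L != 1L || smooth_window < 1L) {
    stop("smooth_window must be a positive odd integer", call. = FALSE)
  }
  ev <- spectrum$eigenvalues
  p <- spectrum$normalized_participation
  n <- spectrum$n_tot
  p_star <- fit$lambda0 - k * fit$gamma

  sm <- if (n > smooth_window) as.numeric(stats::runmed(p, smooth_window)) else p

  below <- sm < p_star
  run_low <- run_length_from(below, from_start = TRUE)
  run_high <- run_length_from(below, from_start = FALSE)
  E_low <- if (run_low > 0L) ev[run_low] else -Inf
  E_high <- if (run_high > 0L) ev[n - run_high + 1L] else Inf

  keep <- ev <= E_low | ev >= E_high
  n_kept <- sum(keep)
  warn <- n_kept == 0L || n_kept == n
  if (warn) {
    warning("mode-selection threshold is uninformative (",
            if (n_kept == 0L) "no" else "all", " modes kept)", call. = FALSE)
  }
  structure(
    list(p_star = p_star, E_low = E_low, E_high = E_high,
         keep_mask = keep, n_kept = n_kept,
         compression_fraction = 1 - n_kept / n,
         warning_flag = warn, k = k, smooth_window = as.integer(smooth_window)),
    class = "mode_selection"
  )
}

run_length_from <- function(flag, from_start = TRUE) {
  if (!from_start) flag <- rev(flag)
  if (!flag[1L]) return(0L)
  r <- rle(flag)
  r$lengths[1L]
}

#' @export
print.mode_selection <- function(x, ...) {
  cat("Mode selection: p* =", format(x$p_star),
      "\n  bands: E <=", format(x$E_low), " or E >=", format(x$E_high),
      "\n  kept", x$n_kept, "modes; compression fraction",
      format(x$compression_fraction), "\n")
  if (x$warning_flag) cat("  [threshold uninformative]\n")
  invisible(x)
}

#' @export
glance.mode_selection <- function(x, ...) {
  tibble::tibble(p_star = x$p_star, E_low = x$E_low, E_high = x$E_high,
                 n_kept = x$n_kept,
                 compression_fraction = x$compression_fraction,
                 warning_flag = x$warning_flag)
}

#' Export a mode selection to CSV
#'
#' Writes one row per mode with header
#' `mode_index,eigenvalue,normalized_participation,kept` (`kept` in 0/1).
#'
#' @param spectrum The `mode_spectrum` the selection was computed from.
#' @param selection The corresponding `mode_selection`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_selection_csv <- function(spectrum, selection, path) {
  df <- data.frame(
    mode_index = seq_len(spectrum$n_tot),
    eigenvalue = spectrum$eigenvalues,
    normalized_participation = spectrum$normalized_participation,
    kept = as.integer(selection$keep_mask)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
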