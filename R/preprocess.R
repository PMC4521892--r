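#' Average a set of spectra sharing one m/z grid
#'
#' Datasets usually contain many replicate spectra on a common grid; the
#' mixture model is fitted to their pointwise mean.
#'
#' @param spectra A long-format tibble with columns `spectrum` (identifier),
#'   `mz` and `intensity`; all member spectra must share an identical m/z
#'   grid.
#' @return A spectrum tibble with the shared grid and the pointwise mean
#'   intensity.
#' @export
average_spectra <- function(spectra) {
  grid <- spectrum_set_grid(spectra)
  out <- spectra |>
    group_by(.data$mz) |>
    summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    arrange(.data$mz)
  # group_by sorts mz; grid is already strictly increasing per member
  as_spectrum(out, sort = FALSE)
}

#' Per-point bin widths of an m/z grid
#'
#' Detector counts represent ions in intervals centered at the grid points;
#' the interval width at interior points is half the distance between the two
#' flanking points, and one-sided differences are used at the ends.  For ToF
#' data the widths typically grow with m/z.
#'
#' @param mz Strictly increasing numeric vector (length >= 2).
#' @return A numeric vector of bin widths, same length as `mz`, all > 0.
#' @export
#' @examples
#' compute_bin_widths(c(1, 2, 4)) # 1, 1.5, 2
compute_bin_widths <- function(mz) {
  n <- length(mz)
  if (n < 2L) abort("need at least 2 m/z points.")
  if (any(diff(mz) <= 0)) abort("m/z grid must be strictly increasing.")
  delta <- numeric(n)
  if (n > 2L) delta[2:(n - 1)] <- (mz[3:n] - mz[1:(n - 2)]) / 2
  delta[1] <- mz[2] - mz[1]
  delta[n] <- mz[n] - mz[n - 1]
  delta
}

#' Subtract a smooth baseline from a spectrum
#'
#' The baseline (a wide, slowly varying additive component of the signal) is
#' estimated as a running quantile of the intensities over a sliding window,
#' smoothed by a moving average of the same width, and subtracted; negative
#' residuals are clipped to zero so intensities remain valid counts.  After
#' baseline removal the remaining spectral components are narrow, which is
#' what the partitioned mixture decomposition assumes.
#'
#' @param spectrum A spectrum data frame.
#' @param window Window width in Da (default 200).
#' @param quantile Baseline quantile in (0, 0.5] (default 0.10).
#' @return A baseline-corrected spectrum tibble.
#' @export
remove_baseline <- function(spectrum, window = 200, quantile = 0.10) {
  s <- as_spectrum(spectrum)
  if (quantile <= 0 || quantile > 0.5) {
    abort("`quantile` must be in (0, 0.5].")
  }
  span <- s$mz[nrow(s)] - s$mz[1]
  if (window > span) abort("baseline window is larger than the spectrum span.")
  w_pts <- max(3L, as.integer(round(window / median(diff(s$mz)))))
  if (w_pts %% 2L == 0L) w_pts <- w_pts + 1L
  est <- function(y) {
    b <- zoo::rollapply(
      y, width = w_pts,
      FUN = stats::quantile, probs = quantile, names = FALSE,
      partial = TRUE, align = "center"
    )
    as.numeric(zoo::rollapply(b, width = w_pts, FUN = mean,
                              partial = TRUE, align = "center"))
  }
  # a single quantile pass under-estimates curved baselines, so iterate on
  # the residual until the increment is negligible — this also makes the
  # whole operation idempotent
  r <- s$intensity
  tol <- 0.002 * max(s$intensity)
  for (i in 1:5) {
    b <- est(r)
    r <- r - b
    if (max(abs(b)) < tol) break
  }
  tibble(mz = s$mz, intensity = pmax(0, r))
}
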