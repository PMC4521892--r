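#' Match detected peaks against a ground-truth peak list
#'
#' Pairs within the relative tolerance (`|detected - true| / true <= tol`)
#' are matched greedily in ascending order of relative distance, each true
#' and each detected peak used at most once (one-to-one matching).
#'
#' @param detected,truth Peak-list data frames with an `mz` column.
#' @param tol Relative m/z tolerance; default 0.003 (the 0.3% detection
#'   threshold conventional for low-resolution MALDI-ToF).
#' @return A list of class `msgmm_match`: counts `tp`, `fp`, `fn` and a
#'   `pairs` tibble (`truth_mz`, `detected_mz`, `rel_err`).
#' @export
match_peaks <- function(detected, truth, tol = 0.003) {
  if (tol <= 0) abort("`tol` must be positive.")
  dmz <- sort(detected$mz)
  tmz <- sort(truth$mz)
  if (length(dmz) == 0L || length(tmz) == 0L) {
    out <- list(
      tp = 0L, fp = length(dmz), fn = length(tmz),
      pairs = tibble(truth_mz = numeric(), detected_mz = numeric(),
                     rel_err = numeric())
    )
    return(structure(out, class = "msgmm_match"))
  }
  rel <- abs(outer(tmz, dmz, "-")) / tmz
  cand <- which(rel <= tol, arr.ind = TRUE)
  pairs <- tibble(truth_mz = numeric(), detected_mz = numeric(),
                  rel_err = numeric())
  if (nrow(cand) > 0L) {
    ord <- order(rel[cand])
    cand <- cand[ord, , drop = FALSE]
    used_t <- logical(length(tmz))
    used_d <- logical(length(dmz))
    ti <- integer(0); di <- integer(0)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!used_t[i] && !used_d[j]) {
        used_t[i] <- TRUE
        used_d[j] <- TRUE
        ti <- c(ti, i); di <- c(di, j)
      }
    }
    pairs <- tibble(
      truth_mz = tmz[ti], detected_mz = dmz[di],
      rel_err = abs(dmz[di] - tmz[ti]) / tmz[ti]
    ) |> arrange(.data$truth_mz)
  }
  tp <- nrow(pairs)
  structure(
    list(tp = tp, fp = length(dmz) - tp, fn = length(tmz) - tp, pairs = pairs),
    class = "msgmm_match"
  )
}

#' Detection performance indexes: FDR, sensitivity, F1
#'
#' FDR is the fraction of detected peaks not matching any true peak
#' (defined as 0 when nothing was detected); sensitivity S is the fraction
#' of true peaks detected; F1 is the harmonic mean of (1 - FDR) and S:
#' `F1 = 2 (1 - FDR) S / ((1 - FDR) + S)`, 0 when the denominator is 0.
#'
#' @param match An `msgmm_match` from [match_peaks()].
#' @return A one-row tibble: `fdr`, `sensitivity`, `f1`, `n_detected`,
#'   `tp`, `fp`, `fn`.
#' @export
performance_indexes <- function(match) {
  stopifnot(inherits(match, "msgmm_match"))
  if (match$tp + match$fn == 0L) abort("empty truth set.")
  n_det <- match$tp + match$fp
  fdr <- if (n_det == 0L) 0 else match$fp / n_det
  s <- match$tp / (match$tp + match$fn)
  denom <- (1 - fdr) + s
  f1 <- if (denom == 0) 0 else 2 * (1 - fdr) * s / denom
  tibble(
    fdr = fdr, sensitivity = s, f1 = f1, n_detected = n_det,
    tp = match$tp, fp = match$fp, fn = match$fn
  )
}

#' Absolute relative error of an m/z estimate
#'
#' `RE = |estimated - true| / true`.
#'
#' @param mz_estimated,mz_true Estimated and true m/z (Da, `mz_true > 0`).
#' @return The relative error (vectorized).
#' @export
relative_error <- function(mz_estimated, mz_true) {
  if (any(mz_true <= 0)) abort("`mz_true` must be positive.")
  abs(mz_estimated - mz_true) / mz_true
}

#' Sweep a detector parameter and tabulate FDR / sensitivity / F1
#'
#' Applies a parameterized peak-producing procedure at every value of a
#' parameter grid and scores each result against the truth, yielding the
#' data behind an ROC-style (FDR versus sensitivity) curve.
#'
#' @param detector A function taking one parameter value and returning a
#'   peak-list data frame.
#' @param truth Ground-truth peak list.
#' @param grid Numeric vector of parameter values (nonempty).
#' @param tol Matching tolerance passed to [match_peaks()].
#' @return A tibble with one row per grid point (`parameter`, `fdr`,
#'   `sensitivity`, `f1`, `n_detected`, `ok`), sorted by `fdr`; a detector
#'   failure flags its row `ok = FALSE` and the sweep continues.
#' @export
roc_sweep <- function(detector, truth, grid, tol = 0.003) {
  if (length(grid) == 0L) abort("empty parameter grid.")
  rows <- purrr::map(grid, function(p) {
    res <- tryCatch(detector(p), error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("detector failed at parameter %g: %s",
                   p, conditionMessage(res)))
      return(tibble(parameter = p, fdr = NA_real_, sensitivity = NA_real_,
                    f1 = NA_real_, n_detected = NA_integer_, ok = FALSE))
    }
    idx <- performance_indexes(match_peaks(res, truth, tol))
    tibble(parameter = p, fdr = idx$fdr, sensitivity = idx$sensitivity,
           f1 = idx$f1, n_detected = as.integer(idx$n_detected), ok = TRUE)
  })
  bind_rows(rows) |> arrange(.data$fdr)
}

#' Simple threshold peak detector (maxima picking)
#'
#' A conventional non-model detector used as a comparator: smoothed local
#' maxima whose raw height exceeds `snr` times a robust noise level (the
#' scaled median absolute deviation of the signal minus its smoothed
#' trace).
#'
#' @param spectrum A spectrum data frame.
#' @param snr Signal-to-noise threshold (default 5).
#' @param smooth_window Moving-average window in points (default 5).
#' @return A peak-list tibble.
#' @export
detect_peaks_maxima <- function(spectrum, snr = 5, smooth_window = 5) {
  s <- as_spectrum(spectrum)
  cand <- detect_candidate_peaks(s, smooth_window)
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  smooth <- as.numeric(stats::filter(s$intensity, rep(1 / w, w), sides = 2))
  resid <- s$intensity - smooth
  noise <- mad(resid[!is.na(resid)], center = 0)
  if (!is.finite(noise) || noise <= 0) noise <- .Machine$double.eps
  cand[cand$intensity >= snr * noise, ]
}
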