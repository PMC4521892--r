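#' Partitioning configuration
#'
#' Parameters of the splitter-based spectrum partitioning.  Gap and width
#' defaults are expressed in multiples of the median grid spacing so that
#' one set of defaults serves grids of different resolution.
#'
#' @param quality_thr Minimum peak quality (ratio of the peak height to the
#'   higher of the two neighboring valley heights) for a candidate to count
#'   as a clear (splitting) peak.  Default 3.
#' @param min_gap_pts,halfwidth_pts,max_gap_pts Minimum spacing between
#'   clear peaks, splitter-segment half width, and the segment-length
#'   warning threshold, all in grid points (converted to Da via the median
#'   spacing).  Defaults 50, 25 and 2000.
#' @param smooth_window Moving-average window (points) used before local
#'   maxima detection.  Default 5.
#' @param k_max Per-fragment cap on the number of Gaussian components.
#'   Default 6.
#' @param em A [fit_config()] used for every fragment fit (its `k_range` is
#'   overridden per fragment, capped at `k_max`).
#' @return A list of class `msgmm_partition_config`.
#' @export
partition_config <- function(quality_thr = 3,
                             min_gap_pts = 50,
                             halfwidth_pts = 25,
                             max_gap_pts = 2000,
                             smooth_window = 5,
                             k_max = 6,
                             em = fit_config()) {
  stopifnot(quality_thr >= 1, min_gap_pts > 0, halfwidth_pts > 0, k_max >= 1)
  structure(
    list(
      quality_thr = quality_thr, min_gap_pts = min_gap_pts,
      halfwidth_pts = halfwidth_pts, max_gap_pts = max_gap_pts,
      smooth_window = as.integer(smooth_window), k_max = as.integer(k_max),
      em = em
    ),
    class = "msgmm_partition_config"
  )
}

# sentinel quality for peaks whose valleys are exactly zero
QUALITY_CAP <- 1e6

#' Detect candidate peaks as smoothed local maxima
#'
#' First stage of clear-peak selection.  The intensity trace is smoothed
#' with a centered moving average and local maxima of the smoothed trace
#' are reported with their apex m/z and raw (unsmoothed) height; any peak
#' detection algorithm could stand in here.
#'
#' @param spectrum A spectrum data frame.
#' @param smooth_window Moving-average window in points (odd; default 5).
#' @return A peak-list tibble (`mz`, `intensity`); empty for a flat signal.
#' @export
detect_candidate_peaks <- function(spectrum, smooth_window = 5) {
  s <- as_spectrum(spectrum)
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  ys <- if (w > 1L) {
    as.numeric(stats::filter(s$intensity, rep(1 / w, w), sides = 2))
  } else {
    s$intensity
  }
  ys[is.na(ys)] <- s$intensity[is.na(ys)]
  n <- length(ys)
  if (n < 3L) return(peak_list(numeric()))
  # strict rise from the left (beyond float noise), non-rise to the right;
  # constant stretches yield no maxima
  eps <- 1e-9 * max(abs(ys))
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] + eps &
                ys[2:(n - 1)] >= ys[3:n], FALSE)
  idx <- which(is_max & s$intensity > 0)
  peak_list(s$mz[idx], intensity = s$intensity[idx])
}

#' Select clear (splitting) peaks from candidates
#'
#' A clear peak must be of sufficient quality and neither too close nor too
#' far from its neighbors.  Quality is the ratio of the peak height to the
#' higher of the two valley heights, where each valley is the lowest signal
#' point between the peak and its neighboring candidate (or the spectrum
#' edge).  Candidates below `quality_thr` are discarded; the remainder are
#' scanned in descending quality and any peak closer than `min_gap` to an
#' already kept peak is dropped.  Gaps wider than `max_gap` only trigger a
#' warning about long segments.
#'
#' @param candidates A peak list from [detect_candidate_peaks()].
#' @param spectrum The spectrum the candidates came from.
#' @param quality_thr Minimum quality ratio.
#' @param min_gap,max_gap Spacing limits in Da.
#' @return A tibble of clear peaks (`mz`, `height`, `quality`), sorted by
#'   `mz`; may be empty, in which case the whole spectrum is one segment.
#' @export
select_splitting_peaks <- function(candidates, spectrum, quality_thr = 3,
                                   min_gap, max_gap = Inf) {
  s <- as_spectrum(spectrum)
  cand <- candidates[order(candidates$mz), ]
  nc <- nrow(cand)
  if (nc == 0L) return(tibble(mz = numeric(), height = numeric(), quality = numeric()))
  idx <- findInterval(cand$mz, s$mz)
  bounds <- c(1L, idx, nrow(s))
  quality <- numeric(nc)
  for (i in seq_len(nc)) {
    left <- min(s$intensity[bounds[i]:idx[i]])
    right <- min(s$intensity[idx[i]:bounds[i + 2L]])
    v <- max(left, right)
    quality[i] <- if (v <= 0) QUALITY_CAP else min(cand$intensity[i] / v, QUALITY_CAP)
  }
  keep <- quality >= quality_thr
  cand <- cand[keep, ]
  quality <- quality[keep]
  if (nrow(cand) == 0L) {
    return(tibble(mz = numeric(), height = numeric(), quality = numeric()))
  }
  ord <- order(-quality, cand$mz)
  kept_mz <- numeric(0)
  kept <- logical(nrow(cand))
  for (i in ord) {
    if (length(kept_mz) == 0L || all(abs(cand$mz[i] - kept_mz) >= min_gap)) {
      kept[i] <- TRUE
      kept_mz <- c(kept_mz, cand$mz[i])
    }
  }
  out <- tibble(
    mz = cand$mz[kept], height = cand$intensity[kept], quality = quality[kept]
  ) |> arrange(.data$mz)
  if (is.finite(max_gap) && nrow(out) > 1L && any(diff(out$mz) > max_gap)) {
    warn(sprintf(
      "%d gap(s) between clear peaks exceed max_gap = %g Da; long segments ahead.",
      sum(diff(out$mz) > max_gap), max_gap
    ))
  }
  out
}

#' Fit the splitter anchored at one clear peak
#'
#' Cuts the splitter-segment (the signal within `halfwidth` of the clear
#' peak) out of the spectrum and decomposes it by [fit_fragment()].
#' Truncation makes the fit unreliable near the fragment boundaries, so
#' only components whose means fall in the central half of the fragment are
#' retained as the splitter — the reliable middle part of the local model.
#'
#' @param spectrum A spectrum data frame.
#' @param peak_mz Clear-peak position (Da).
#' @param halfwidth Splitter-segment half width (Da).
#' @param cfg A [fit_config()].
#' @return A list of class `msgmm_splitter` with elements `components`
#'   (tibble), `support` (the central-half interval) and `peak_mz`; or
#'   `NULL` (with a message) when no component mean lands in the central
#'   half and the peak is demoted.
#' @export
fit_splitter <- function(spectrum, peak_mz, halfwidth, cfg = fit_config()) {
  s <- as_spectrum(spectrum)
  stopifnot(halfwidth > 0)
  in_frag <- s$mz >= peak_mz - halfwidth & s$mz <= peak_mz + halfwidth
  if (sum(in_frag) < 10L) {
    abort("splitter-segment has fewer than 10 points.")
  }
  x <- s$mz[in_frag]
  y <- s$intensity[in_frag]
  fit <- fit_fragment(x, y, cfg)
  support <- c(peak_mz - halfwidth / 2, peak_mz + halfwidth / 2)
  central <- fit$components$mu >= support[1] & fit$components$mu <= support[2]
  if (!any(central)) {
    inform(sprintf(
      "no component mean in the central half around %.2f Da; peak demoted.",
      peak_mz
    ))
    return(NULL)
  }
  structure(
    list(
      components = fit$components[central, ],
      support = support,
      peak_mz = peak_mz
    ),
    class = "msgmm_splitter"
  )
}

#' Subtract splitter signals and cut the spectrum into segments
#'
#' The predicted signals of all splitters are subtracted from the spectrum
#' (negative residuals clipped at zero) and the residual is cut at the
#' midpoints of the splitter supports, yielding one segment per interval
#' between neighboring splitters plus the two edge intervals.  Segments
#' whose total residual intensity falls below `1e-3 * mean(y)` per point
#' are dropped as empty.
#'
#' @param spectrum A spectrum data frame.
#' @param splitters A list of `msgmm_splitter` objects with non-overlapping
#'   supports (overlaps are an error).
#' @param empty_floor Per-point residual floor multiplier (default 1e-3).
#' @return A list of segments, each a list with `x`, `y` and `bounds`.
#'   With no splitters the whole spectrum is the single segment.
#' @export
subtract_splitters <- function(spectrum, splitters, empty_floor = 1e-3) {
  s <- as_spectrum(spectrum)
  if (length(splitters) == 0L) {
    return(list(list(
      x = s$mz, y = s$intensity, bounds = range(s$mz)
    )))
  }
  centers <- vapply(splitters, function(sp) mean(sp$support), numeric(1))
  splitters <- splitters[order(centers)]
  supports <- vapply(splitters, function(sp) sp$support, numeric(2))
  if (ncol(supports) > 1L &&
      any(supports[1, -1] < supports[2, -ncol(supports)])) {
    abort("splitter supports overlap.")
  }
  cmp <- bind_rows(lapply(splitters, function(sp) sp$components))
  resid <- pmax(0, s$intensity - components_signal(s$mz, cmp))
  mids <- colMeans(supports)
  cuts <- c(s$mz[1], mids, s$mz[length(s$mz)])
  floor_per_pt <- empty_floor * mean(s$intensity)
  segs <- list()
  for (i in seq_len(length(cuts) - 1L)) {
    in_seg <- s$mz >= cuts[i] & s$mz <= cuts[i + 1L]
    if (sum(in_seg) < 2L) next
    y <- resid[in_seg]
    if (sum(y) < floor_per_pt * sum(in_seg)) next
    segs[[length(segs) + 1L]] <- list(
      x = s$mz[in_seg], y = y, bounds = c(cuts[i], cuts[i + 1L])
    )
  }
  segs
}

#' Whole-spectrum Gaussian mixture decomposition by signal partitioning
#'
#' The complete two-phase algorithm.  Phase 1: detect candidate peaks,
#' select clear peaks, and fit a splitter (the reliable central components
#' of a local mixture fit) around each.  Phase 2: subtract the splitter
#' signals, cut the residual into segments between splitters, and decompose
#' each segment independently.  Finally all splitter and segment components
#' are aggregated — sorted by mean, local weights kept from their fragment
#' fits, and global mixing proportions recomputed as `w_k / sum(w)` — into
#' one whole-spectrum mixture model.
#'
#' Per-segment model order is selected by BIC over `1 .. min(k_max,
#' candidates-in-segment + 2)`.  A segment whose fit fails is skipped with
#' a warning; a spectrum with no usable clear peak degenerates gracefully
#' to a single whole-signal fit.
#'
#' @param spectrum A baseline-corrected spectrum data frame (use
#'   `remove_baseline = TRUE` to correct internally first).
#' @param cfg A [partition_config()].
#' @param remove_baseline If `TRUE`, run [remove_baseline()] with default
#'   parameters before decomposing.
#' @return An `msgmm_model` for the whole spectrum, with attributes
#'   `"n_splitters"` and `"n_segments"`.
#' @export
decompose_spectrum <- function(spectrum, cfg = partition_config(),
                               remove_baseline = FALSE) {
  s <- as_spectrum(spectrum)
  if (remove_baseline) s <- remove_baseline(s)
  if (sum(s$intensity) <= 0) {
    warn("spectrum has no positive intensity; returning an empty model.")
    return(mixture_model(tibble(
      alpha = numeric(), weight = numeric(), mu = numeric(), sigma = numeric()
    ), tic_eta = 0))
  }
  dx <- median(diff(s$mz))
  min_gap <- cfg$min_gap_pts * dx
  halfwidth <- cfg$halfwidth_pts * dx
  max_gap <- cfg$max_gap_pts * dx

  cand <- detect_candidate_peaks(s, cfg$smooth_window)
  clear <- select_splitting_peaks(
    cand, s, quality_thr = cfg$quality_thr,
    min_gap = min_gap, max_gap = max_gap
  )

  splitters <- list()
  for (i in seq_len(nrow(clear))) {
    sp <- tryCatch(
      fit_splitter(s, clear$mz[i], halfwidth,
                   splitter_fit_config(cfg)),
      error = function(e) {
        warn(sprintf("splitter at %.2f Da failed: %s",
                     clear$mz[i], conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(sp)) splitters[[length(splitters) + 1L]] <- sp
  }

  segments <- subtract_splitters(s, splitters)
  seg_components <- list()
  total_ll <- 0
  for (seg in segments) {
    if (sum(seg$y) <= 0) next
    n_cand <- sum(cand$mz >= seg$bounds[1] & cand$mz <= seg$bounds[2])
    k_hi <- max(1L, min(cfg$k_max, n_cand + 2L))
    seg_cfg <- cfg$em
    seg_cfg$k_range <- seq_len(k_hi)
    fit <- tryCatch(
      fit_fragment(seg$x, seg$y, seg_cfg),
      error = function(e) {
        warn(sprintf("segment [%.1f, %.1f] Da skipped: %s",
                     seg$bounds[1], seg$bounds[2], conditionMessage(e)))
        NULL
      }
    )
    if (is.null(fit)) next
    seg_components[[length(seg_components) + 1L]] <- fit$components
    total_ll <- total_ll + fit$loglik
  }

  cmp <- bind_rows(c(
    lapply(splitters, function(sp) sp$components),
    seg_components
  ))
  if (nrow(cmp) == 0L) {
    warn("decomposition produced no components.")
    return(mixture_model(tibble(
      alpha = numeric(), weight = numeric(), mu = numeric(), sigma = numeric()
    ), tic_eta = sum(s$intensity)))
  }
  cmp <- cmp[order(cmp$mu), ]
  cmp$alpha <- cmp$weight / sum(cmp$weight)
  out <- mixture_model(
    cmp,
    tic_eta = sum(s$intensity),
    loglik = total_ll,
    converged = TRUE
  )
  attr(out, "n_splitters") <- length(splitters)
  attr(out, "n_segments") <- length(segments)
  out
}

# splitter-segment fits explore the full 1..k_max range
splitter_fit_config <- function(cfg) {
  em <- cfg$em
  em$k_range <- seq_len(cfg$k_max)
  em
}
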