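#' Drop low-weight mixture components
#'
#' Components carrying less than `weight_thr` of the model's total local
#' weight are removed (EM tends to spend a few "dust" components on noise),
#' and the mixing proportions of the survivors are renormalized.
#'
#' @param model An `msgmm_model`.
#' @param weight_thr Minimum relative weight, a fraction of `sum(w)` in
#'   `[0, 1)`.  Default 1e-3.
#' @return A filtered `msgmm_model`.
#' @export
filter_components <- function(model, weight_thr = 1e-3) {
  stopifnot(inherits(model, "msgmm_model"), weight_thr >= 0, weight_thr < 1)
  cmp <- model$components
  if (nrow(cmp) == 0L) return(model)
  rel <- cmp$weight / sum(cmp$weight)
  keep <- rel >= weight_thr
  if (!any(keep)) {
    warn("all components fall below the weight threshold; returning an empty model.")
    return(mixture_model(cmp[0, ], tic_eta = model$tic_eta))
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) inform(sprintf("dropped %d low-weight component(s).", n_drop))
  cmp <- cmp[keep, ]
  cmp$alpha <- cmp$weight / sum(cmp$weight)
  mixture_model(cmp, scale_s = model$scale_s, tic_eta = model$tic_eta,
                loglik = model$loglik, loglik_trace = model$loglik_trace,
                converged = model$converged)
}

#' Merge mixture components closer than MZ-thr
#'
#' Neighboring Gaussian components often model one underlying species.
#' Components are grouped by single linkage on their means — adjacent means
#' closer than the merge distance join one group — and each group is
#' replaced by a single moment-matched Gaussian: `w = sum(w_i)`,
#' `mu = sum(w_i mu_i) / w`, `sigma^2 = sum(w_i (sigma_i^2 + mu_i^2)) / w -
#' mu^2`, which preserves the zeroth, first and second moments of the
#' modeled signal exactly.
#'
#' @param model An `msgmm_model`.
#' @param mz_thr Merge distance parameter MZ-thr.  Interpreted as a
#'   fraction of the local m/z when `relative = TRUE` (default, 3e-4 —
#'   ToF peak widths scale with m/z), or as an absolute distance in Da.
#' @param relative Whether `mz_thr` is relative (default) or absolute Da.
#' @return A merged `msgmm_model`.
#' @export
merge_components <- function(model, mz_thr = 3e-4, relative = TRUE) {
  stopifnot(inherits(model, "msgmm_model"), mz_thr > 0)
  cmp <- model$components
  if (nrow(cmp) <= 1L) return(model)
  gap <- diff(cmp$mu)
  thr <- if (relative) {
    mz_thr * (head(cmp$mu, -1) + tail(cmp$mu, -1)) / 2
  } else {
    rep(mz_thr, length(gap))
  }
  group <- cumsum(c(1L, as.integer(gap > thr)))
  merged <- tibble(group = group, w = cmp$weight, mu = cmp$mu, s = cmp$sigma) |>
    group_by(.data$group) |>
    summarise(
      weight = sum(.data$w),
      mu_new = sum(.data$w * .data$mu) / sum(.data$w),
      sigma = sqrt(
        sum(.data$w * (.data$s^2 + .data$mu^2)) / sum(.data$w) - .data$mu_new[1]^2
      ),
      .groups = "drop"
    )
  out <- tibble(
    alpha = merged$weight / sum(merged$weight),
    weight = merged$weight,
    mu = merged$mu_new,
    sigma = pmax(merged$sigma, .Machine$double.eps)
  )
  mixture_model(out, scale_s = model$scale_s, tic_eta = model$tic_eta,
                loglik = model$loglik, loglik_trace = model$loglik_trace,
                converged = model$converged)
}

#' Extract a peak list from a mixture model
#'
#' Spectral peaks are the m/z values of the Gaussian component means; each
#' peak's intensity is the component's apex height
#' `w_k / (sigma_k sqrt(2 pi))`.
#'
#' @param model An `msgmm_model`.
#' @return A peak-list tibble (`mz`, `intensity`), sorted by `mz`; empty
#'   for an empty model.
#' @export
model_to_peaks <- function(model) {
  stopifnot(inherits(model, "msgmm_model"))
  cmp <- model$components
  peak_list(cmp$mu, intensity = cmp$weight / (cmp$sigma * sqrt(2 * pi)))
}

#' Run the standard post-processing pipeline
#'
#' Filter low-weight components, merge components closer than MZ-thr, and
#' extract peaks — in that order, so dust components cannot drag merged
#' means.
#'
#' @inheritParams filter_components
#' @inheritParams merge_components
#' @return A peak-list tibble.
#' @export
postprocess_model <- function(model, weight_thr = 1e-3, mz_thr = 3e-4,
                              relative = TRUE) {
  model |>
    filter_components(weight_thr) |>
    merge_components(mz_thr, relative = relative) |>
    model_to_peaks()
}

#' Higher-narrower component m/z estimate for a skewed peak
#'
#' A skewed spectral peak is modeled by two (or more) Gaussian components;
#' the mean of the taller-and-narrower component is a better estimate of
#' the species m/z than the apex of the raw signal.  Among components with
#' mean inside `window`, the one maximizing the apex height
#' `w_k / (sigma_k sqrt(2 pi))` is chosen; ties prefer smaller sigma, then
#' smaller mu.
#'
#' @param model An `msgmm_model`.
#' @param window Length-2 numeric m/z interval.
#' @return The chosen component mean (Da).
#' @export
higher_narrower_mz <- function(model, window) {
  stopifnot(inherits(model, "msgmm_model"), length(window) == 2)
  cmp <- model$components
  inw <- cmp$mu >= window[1] & cmp$mu <= window[2]
  if (!any(inw)) abort("no component mean inside the window.")
  cmp <- cmp[inw, ]
  apex <- cmp$weight / (cmp$sigma * sqrt(2 * pi))
  ord <- order(-apex, cmp$sigma, cmp$mu)
  cmp$mu[ord[1]]
}
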