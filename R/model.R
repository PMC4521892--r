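#' Create a Gaussian mixture model object
#'
#' A fitted mixture model bundles the component table with its scale
#' bookkeeping.  Components are Gaussians `f_k(x; mu_k, sigma_k)`; the model
#' predicts intensities as `sum_k w_k f_k(x)`, where the local weight
#' `w_k = s * alpha_k` converts the probability-scale mixing proportions
#' `alpha_k` (summing to 1) into count scale via the local scale factor `s`.
#'
#' @param components A data frame with columns `alpha`, `weight`, `mu`,
#'   `sigma` (one row per component).  Zero rows give an empty model.
#' @param scale_s Local scale factor `s` (counts x Da), or `NA` for
#'   aggregated whole-spectrum models where scaling was done per fragment.
#' @param tic_eta Total ion current of the fitted signal (sum of counts).
#' @param loglik Final weighted log-likelihood.
#' @param loglik_trace Numeric vector of per-iteration objective values.
#' @param converged Logical, did EM reach its stopping tolerance.
#'
#' @return An object of class `msgmm_model`.
#' @export
mixture_model <- function(components,
                          scale_s = NA_real_,
                          tic_eta = NA_real_,
                          loglik = NA_real_,
                          loglik_trace = numeric(),
                          converged = NA) {
  components <- as_tibble(components)
  needed <- c("alpha", "weight", "mu", "sigma")
  if (nrow(components) == 0L) {
    components <- tibble(
      alpha = numeric(), weight = numeric(),
      mu = numeric(), sigma = numeric()
    )
  }
  if (!all(needed %in% names(components))) {
    abort("`components` needs columns alpha, weight, mu, sigma.")
  }
  components <- components[order(components$mu), needed]
  m <- structure(
    list(
      components = components,
      K = nrow(components),
      scale_s = scale_s,
      tic_eta = tic_eta,
      loglik = loglik,
      loglik_trace = loglik_trace,
      converged = converged
    ),
    class = "msgmm_model"
  )
  validate_model(m)
  m
}

validate_model <- function(m) {
  cmp <- m$components
  if (nrow(cmp) == 0L) {
    return(invisible(m))
  }
  if (any(cmp$sigma <= 0)) abort("component sigma must be > 0.")
  if (any(cmp$alpha < 0)) abort("component alpha must be >= 0.")
  if (any(cmp$weight < 0)) abort("component weight must be >= 0.")
  if (abs(sum(cmp$alpha) - 1) > 1e-6) {
    abort(sprintf(
      "component alphas must sum to 1 (got %.10g).", sum(cmp$alpha)
    ))
  }
  if (is.unsorted(cmp$mu)) abort("components must be sorted by mu.")
  invisible(m)
}

#' @export
print.msgmm_model <- function(x, ...) {
  cat(sprintf(
    "<msgmm_model: %d Gaussian component%s>\n",
    x$K, if (x$K == 1) "" else "s"
  ))
  if (!is.na(x$loglik)) cat(sprintf("  weighted log-likelihood: %.6g\n", x$loglik))
  if (!is.na(x$tic_eta)) cat(sprintf("  total ion current: %.6g\n", x$tic_eta))
  if (x$K > 0) print(x$components, n = 10)
  invisible(x)
}

#' Tidy a fitted mixture model into its component table
#'
#' @param x An `msgmm_model`.
#' @param ... Unused.
#' @return A tibble with one row per Gaussian component: `component` index,
#'   mixing proportion `alpha`, local weight `weight`, mean `mu` (Da) and
#'   standard deviation `sigma` (Da), plus the apex `height = weight /
#'   (sigma * sqrt(2*pi))`.
#' @method tidy msgmm_model
#' @export
tidy.msgmm_model <- function(x, ...) {
  cmp <- x$components
  tibble(
    component = seq_len(nrow(cmp)),
    alpha = cmp$alpha,
    weight = cmp$weight,
    mu = cmp$mu,
    sigma = cmp$sigma,
    height = cmp$weight / (cmp$sigma * sqrt(2 * pi))
  )
}

#' One-row summary of a fitted mixture model
#'
#' @param x An `msgmm_model`.
#' @param ... Unused.
#' @return A tibble with columns `K`, `loglik`, `iterations`, `converged`,
#'   `scale_s`, `tic_eta`, `total_weight`.
#' @method glance msgmm_model
#' @export
glance.msgmm_model <- function(x, ...) {
  tibble(
    K = x$K,
    loglik = x$loglik,
    iterations = length(x$loglik_trace),
    converged = x$converged,
    scale_s = x$scale_s,
    tic_eta = x$tic_eta,
    total_weight = sum(x$components$weight)
  )
}
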