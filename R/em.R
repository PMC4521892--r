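#' EM fitting configuration
#'
#' @param k_range Integer vector of candidate component counts for
#'   model-order selection (default `1:6`).
#' @param max_iter Iteration cap per EM run (default 5000).
#' @param tol Relative change of the weighted log-likelihood below which EM
#'   stops (default 1e-8).
#' @param min_sigma Lower bound on component standard deviations (Da).
#'   `NULL` (default) means half the median grid spacing of the fitted
#'   fragment, which prevents components collapsing onto single grid points.
#' @param seed Optional seed for multi-start experiments; the default
#'   initialization is deterministic and ignores it.
#' @return A list of class `msgmm_fit_config`.
#' @export
fit_config <- function(k_range = 1:6, max_iter = 5000, tol = 1e-8,
                       min_sigma = NULL, seed = NULL) {
  stopifnot(max_iter >= 1, tol > 0, length(k_range) >= 1, all(k_range >= 1))
  if (!is.null(min_sigma)) stopifnot(min_sigma > 0)
  structure(
    list(
      k_range = sort(unique(as.integer(k_range))),
      max_iter = as.integer(max_iter), tol = tol,
      min_sigma = min_sigma, seed = seed
    ),
    class = "msgmm_fit_config"
  )
}

# Gaussian density matrix: n x K, f[n, k] = dnorm(x[n], mu[k], sigma[k])
dens_matrix <- function(x, mu, sigma) {
  K <- length(mu)
  z <- outer(x, mu, "-") / rep(sigma, each = length(x))
  exp(-0.5 * z * z) / rep(sigma * sqrt(2 * pi), each = length(x))
}

#' Evaluate a mixture model's predicted intensities
#'
#' Predicts `yhat(x) = sum_k w_k f_k(x; mu_k, sigma_k)` with `f_k` the
#' Gaussian probability density, i.e. the locally scaled mixture signal.
#'
#' @param model An `msgmm_model`.
#' @param mz Numeric vector of m/z values.
#' @return Numeric vector of predicted intensities, same length as `mz`.
#' @export
evaluate_mixture <- function(model, mz) {
  stopifnot(inherits(model, "msgmm_model"))
  cmp <- model$components
  if (nrow(cmp) == 0L) {
    warn("evaluating an empty model; returning zeros.")
    return(numeric(length(mz)))
  }
  components_signal(mz, cmp)
}

# sum of w_k * N(mu_k, sigma_k) over components, evaluated sparsely: each
# component only contributes within +/- 8 sigma of its mean
components_signal <- function(x, cmp, nsigma = 8) {
  y <- numeric(length(x))
  n <- length(x)
  for (k in seq_len(nrow(cmp))) {
    lo <- findInterval(cmp$mu[k] - nsigma * cmp$sigma[k], x) + 1L
    hi <- findInterval(cmp$mu[k] + nsigma * cmp$sigma[k], x)
    if (lo > hi) next
    idx <- lo:hi
    y[idx] <- y[idx] + cmp$weight[k] * dnorm(x[idx], cmp$mu[k], cmp$sigma[k])
  }
  y
}

#' Total ion current of a signal
#'
#' @param y Numeric vector of intensities.
#' @return The sum of counts, `eta = sum_n y_n` — the global scale of the
#'   mixture model.
#' @export
total_ion_current <- function(y) {
  if (length(y) == 0L) abort("empty intensity vector.")
  sum(y)
}

#' Local scale factor of a mixture over a signal fragment
#'
#' Converts a probability-scale mixture (alphas summing to 1) into count
#' scale: `s = sum_n y_n / sum_n sum_k alpha_k f_k(x_n)`.  Setting
#' `w_k = s * alpha_k` makes the predicted intensities sum exactly to the
#' observed intensities over the fragment.
#'
#' @param alpha,mu,sigma Component parameter vectors (alphas on probability
#'   scale).
#' @param x,y The fragment's m/z grid and intensities.
#' @return The scalar scale factor `s` (counts x Da); 0 when the fragment is
#'   all-zero.
#' @export
local_scale <- function(alpha, mu, sigma, x, y) {
  if (length(x) == 0L) abort("empty fragment.")
  dens <- as.numeric(dens_matrix(x, mu, sigma) %*% alpha)
  denom <- sum(dens)
  if (sum(y) == 0) return(0)
  if (denom <= 0) abort("mixture density is zero over the fragment.")
  sum(y) / denom
}

#' Deterministic initialization of mixture parameters
#'
#' Places the K component means at intensity-weighted quantiles of the
#' fragment (the m/z where the cumulative intensity crosses `(k - 0.5) / K`
#' of its total), uses equal mixing proportions, and starts all standard
#' deviations at `span / (4 K)`, floored at `min_sigma`.  Being
#' deterministic, repeated fits of the same fragment are identical.
#'
#' @param x,y Fragment grid and intensities (`sum(y) > 0`).
#' @param K Number of components (at most the number of points with
#'   positive intensity).
#' @param min_sigma Standard deviation floor (Da).
#' @return A list with numeric vectors `alpha`, `mu`, `sigma`.
#' @export
initialize_components <- function(x, y, K, min_sigma) {
  stopifnot(K >= 1)
  tot <- sum(y)
  if (tot <= 0) abort("fragment has no positive intensity.")
  if (K > sum(y > 0)) {
    abort(sprintf(
      "K = %d exceeds the %d points with positive intensity.", K, sum(y > 0)
    ))
  }
  cum <- cumsum(y) / tot
  probs <- (seq_len(K) - 0.5) / K
  mu <- x[vapply(probs, function(p) which(cum >= p)[1], integer(1))]
  span <- x[length(x)] - x[1]
  sigma <- rep(max(span / (4 * K), min_sigma), K)
  list(alpha = rep(1 / K, K), mu = mu, sigma = sigma)
}

default_min_sigma <- function(x) median(diff(x)) / 2

#' EM algorithm for a Gaussian mixture on binned count data
#'
#' Intensities `y_n` are counts over dense bins centered at `x_n`, so the
#' bin probabilities are well approximated by the density at the bin center
#' times the bin width and EM reduces to a multiplicity-weighted mixture
#' fit: each grid point enters the E- and M-steps with weight `y_n`.  The
#' objective is the weighted log-likelihood
#' `sum_n y_n log sum_k alpha_k f_k(x_n)`, which is non-decreasing over
#' iterations.  Components whose mixing proportion collapses below 1e-12
#' are dropped (with a message) and the remaining alphas renormalized.
#'
#' @param x,y Fragment grid and intensities.
#' @param init Initial parameters (list with `alpha`, `mu`, `sigma`), e.g.
#'   from [initialize_components()].
#' @param cfg A [fit_config()].
#' @param delta Optional bin widths (defaults to [compute_bin_widths()] of
#'   `x`); enters the objective only as an additive constant under the
#'   dense-bin approximation and is kept for the scale bookkeeping.
#' @return An `msgmm_model` with local weights `w_k = s * alpha_k` from
#'   [local_scale()], so the fitted signal conserves the fragment's total
#'   intensity.
#' @export
em_binned <- function(x, y, init, cfg = fit_config(), delta = NULL) {
  stopifnot(length(x) == length(y))
  if (sum(y) <= 0) abort("fragment has no positive intensity.")
  if (any(y < 0)) abort("intensities must be non-negative.")
  min_sigma <- cfg$min_sigma %||% default_min_sigma(x)

  alpha <- init$alpha / sum(init$alpha)
  mu <- init$mu
  sigma <- pmax(init$sigma, min_sigma)
  tot <- sum(y)
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  tiny <- .Machine$double.xmin

  for (it in seq_len(cfg$max_iter)) {
    f <- dens_matrix(x, mu, sigma)
    fa <- sweep(f, 2L, alpha, "*")
    dens <- rowSums(fa)
    ll <- sum(y * log(pmax(dens, tiny)))
    if (!is.finite(ll)) abort("non-finite EM objective.")
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - ll_prev) < cfg$tol * (abs(ll_prev) + tiny)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # E-step: responsibilities; M-step: weighted moments
    resp <- fa / pmax(dens, tiny)
    nk <- as.numeric(crossprod(resp, y))
    alpha <- nk / tot
    keep <- alpha > 1e-12
    if (!all(keep)) {
      inform(sprintf("dropping %d collapsed component(s).", sum(!keep)))
      alpha <- alpha[keep] / sum(alpha[keep])
      mu <- mu[keep]
      sigma <- sigma[keep]
      nk <- nk[keep]
      resp <- resp[, keep, drop = FALSE]
    }
    wy <- resp * y
    mu <- as.numeric(crossprod(wy, x)) / nk
    v <- vapply(
      seq_along(mu),
      function(k) sum(wy[, k] * (x - mu[k])^2) / nk[k],
      numeric(1)
    )
    sigma <- sqrt(pmax(v, min_sigma^2))
  }

  s <- local_scale(alpha, mu, sigma, x, y)
  mixture_model(
    tibble(alpha = alpha, weight = s * alpha, mu = mu, sigma = sigma),
    scale_s = s,
    tic_eta = tot,
    loglik = trace[length(trace)],
    loglik_trace = trace,
    converged = converged
  )
}

#' Fit a signal fragment with model-order selection
#'
#' Runs [em_binned()] for each candidate K in `cfg$k_range` (all from the
#' same deterministic initialization scheme) and returns the fit minimizing
#' `BIC = -2 loglik + (3K - 1) log(sum(y))`; ties and failures resolve
#' toward smaller K.
#'
#' @inheritParams em_binned
#' @param cfg A [fit_config()]; `k_range` is the candidate set.
#' @return The selected `msgmm_model`, with the BIC table attached as
#'   attribute `"order_selection"`.
#' @export
fit_fragment <- function(x, y, cfg = fit_config(), delta = NULL) {
  if (sum(y) <= 0) abort("fragment has no positive intensity.")
  min_sigma <- cfg$min_sigma %||% default_min_sigma(x)
  n_eff <- sum(y)
  ks <- cfg$k_range[cfg$k_range <= sum(y > 0)]
  if (length(ks) == 0L) abort("no feasible K for this fragment.")
  best <- NULL
  best_bic <- Inf
  rows <- list()
  for (K in ks) {
    fit <- tryCatch(
      em_binned(x, y, initialize_components(x, y, K, min_sigma), cfg,
                delta = delta),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    bic <- -2 * fit$loglik + (3 * fit$K - 1) * log(n_eff)
    rows[[length(rows) + 1L]] <- tibble(K = K, loglik = fit$loglik, bic = bic)
    if (bic < best_bic) {
      best <- fit
      best_bic <- bic
    }
  }
  if (is.null(best)) abort("all candidate fits failed for this fragment.")
  attr(best, "order_selection") <- bind_rows(rows)
  best
}
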