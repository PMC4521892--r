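# shared fixture builders: small synthetic fragments and spectra

# gaussian-shaped fragment with given apex height(s)
gauss_fragment <- function(mu, sigma, apex, lo, hi, step = NULL) {
  step <- step %||% (min(sigma) / 5)
  x <- seq(lo, hi, by = step)
  y <- numeric(length(x))
  for (i in seq_along(mu)) {
    y <- y + apex[i] * exp(-(x - mu[i])^2 / (2 * sigma[i]^2))
  }
  tibble::tibble(mz = x, intensity = y)
}

# closed-form weighted mean / SD of binned data (independent oracle for
# the K = 1 EM fit)
weighted_moments <- function(x, y) {
  m <- sum(y * x) / sum(y)
  v <- sum(y * (x - m)^2) / sum(y)
  list(mean = m, sd = sqrt(v))
}

# a quiet model fit (drop the informational messages)
quiet <- function(expr) suppressMessages(suppressWarnings(expr))
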