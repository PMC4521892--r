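test_that("evaluate_mixture reproduces Gaussian density values", {
  m <- mixture_model(tibble::tibble(alpha = 1, weight = 1, mu = 0, sigma = 1))
  expect_equal(evaluate_mixture(m, 0), 0.3989423, tolerance = 1e-6)
  at_pm1 <- evaluate_mixture(m, c(-1, 1))
  expect_equal(at_pm1, c(0.2419707, 0.2419707), tolerance = 1e-6)

  # mirror-image pair is symmetric about its center
  m2 <- mixture_model(tibble::tibble(
    alpha = c(0.5, 0.5), weight = c(2, 2), mu = c(90, 110), sigma = c(3, 3)
  ))
  x <- seq(80, 120, by = 0.5)
  yhat <- evaluate_mixture(m2, x)
  expect_equal(yhat, rev(yhat), tolerance = 1e-12)

  empty <- mixture_model(tibble::tibble(
    alpha = numeric(), weight = numeric(), mu = numeric(), sigma = numeric()
  ))
  expect_warning(z <- evaluate_mixture(empty, x), "empty")
  expect_equal(z, numeric(length(x)))
})

test_that("total_ion_current sums counts", {
  expect_equal(total_ion_current(c(1, 2, 3)), 6)
  expect_equal(total_ion_current(rep(0, 5)), 0)
  expect_equal(total_ion_current(5), 5)
  expect_error(total_ion_current(numeric()), "empty")
})

test_that("local_scale is the intensity/density ratio and conserves area", {
  # unscaled density sums to 0.5, signal sums to 100 -> s = 200
  x <- c(0, 1)
  f <- dnorm(x, 0, 1)
  y <- 100 * f / sum(f) # sums to 100
  s <- local_scale(1, 0, 1, x, y)
  expect_equal(s, 100 / sum(f))

  # y built from a known scaled model: recovered s matches within 1e-10
  x <- seq(990, 1010, by = 0.1)
  alpha <- c(0.3, 0.7)
  mu <- c(995, 1005)
  sig <- c(1, 2)
  s_true <- 123.456
  y <- as.numeric(s_true * (
    alpha[1] * dnorm(x, mu[1], sig[1]) + alpha[2] * dnorm(x, mu[2], sig[2])
  ))
  expect_equal(local_scale(alpha, mu, sig, x, y), s_true, tolerance = 1e-10)

  # scaling forces exact area conservation
  w <- local_scale(alpha, mu, sig, x, y) * alpha
  m <- mixture_model(tibble::tibble(alpha = alpha, weight = w, mu = mu,
                                    sigma = sig))
  expect_equal(sum(evaluate_mixture(m, x)), sum(y), tolerance = 1e-9)

  expect_equal(local_scale(1, 1000, 1, x, rep(0, length(x))), 0)
})

test_that("initialization places means at intensity-weighted quantiles", {
  x <- seq(1, 100, by = 1)
  y <- rep(1, 100)
  init <- initialize_components(x, y, 1, min_sigma = 0.5)
  # weighted median by cumulative-sum oracle
  expect_equal(init$mu, x[which(cumsum(y) / sum(y) >= 0.5)[1]])

  # symmetric bimodal -> symmetric initial means
  xb <- seq(0, 10, by = 0.01)
  yb <- exp(-(xb - 3)^2 / 0.5) + exp(-(xb - 7)^2 / 0.5)
  init2 <- initialize_components(xb, yb, 2, min_sigma = 0.01)
  expect_equal(mean(init2$mu), 5, tolerance = 0.02)

  y3 <- c(0, 1, 1, 1, 0)
  expect_error(initialize_components(1:5, y3, 5, 0.1), "positive intensity")
})

test_that("K=1 binned EM matches closed-form weighted moments", {
  x <- seq(990, 1010, by = 0.1)
  y <- 100 * exp(-(x - 1000)^2 / (2 * 2^2))
  or <- weighted_moments(x, y)
  fit <- em_binned(x, y, initialize_components(x, y, 1, 0.05), fit_config(1))
  expect_equal(fit$components$mu, or$mean, tolerance = 0.01 * 2 / or$mean)
  expect_equal(fit$components$sigma, or$sd, tolerance = 0.02)
  expect_lt(abs(fit$components$mu - 1000), 0.01 * 2)
})

test_that("K=2 EM at 10 sigma separation recovers per-cluster moments", {
  x <- seq(980, 1060, by = 0.1)
  y <- 100 * exp(-(x - 1000)^2 / (2 * 2^2)) +
    60 * exp(-(x - 1040)^2 / (2 * 2^2))
  fit <- em_binned(x, y, initialize_components(x, y, 2, 0.05), fit_config(2))
  # independent oracle: weighted moments per half, split at the midpoint
  left <- x < 1020
  orl <- weighted_moments(x[left], y[left])
  orr <- weighted_moments(x[!left], y[!left])
  expect_lt(abs(fit$components$mu[1] - orl$mean), 0.05 * orl$sd)
  expect_lt(abs(fit$components$mu[2] - orr$mean), 0.05 * orr$sd)
  expect_lt(abs(fit$components$sigma[1] - orl$sd), 0.05 * orl$sd)
  expect_lt(abs(fit$components$sigma[2] - orr$sd), 0.05 * orr$sd)
})

test_that("EM objective is monotone and alphas stay normalized", {
  set.seed(3)
  for (rep in 1:5) {
    x <- seq(0, 100, by = 0.25)
    mu <- sort(runif(3, 10, 90))
    y <- numeric(length(x))
    for (m in mu) y <- y + runif(1, 20, 80) * exp(-(x - m)^2 / (2 * 1.5^2))
    y <- y + abs(rnorm(length(x), 0, 0.3))
    fit <- quiet(em_binned(x, y, initialize_components(x, y, 3, 0.1),
                           fit_config(3)))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8 * abs(fit$loglik)))
    expect_equal(sum(fit$components$alpha), 1, tolerance = 1e-9)
  }
})

test_that("EM agrees with an independent mixture fitter on clean data", {
  skip_if_not_installed("mclust")
  # pseudo-counts from a 2-component mixture; mclust fits the expanded
  # sample, our EM fits the binned rendition of the same density
  mclustBIC <- mclust::mclustBIC
  x <- seq(0, 40, by = 0.2)
  y <- 30 * exp(-(x - 12)^2 / (2 * 1.2^2)) + 50 * exp(-(x - 28)^2 / (2 * 2^2))
  fit <- em_binned(x, y, initialize_components(x, y, 2, 0.1), fit_config(2))
  expanded <- rep(x, times = round(y))
  mc <- mclust::Mclust(expanded, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$components$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
})

test_that("dense-bin fits are insensitive to grid refinement", {
  f <- function(step) {
    x <- seq(980, 1020, by = step)
    y <- 80 * exp(-(x - 1000)^2 / (2 * 2^2))
    em_binned(x, y, initialize_components(x, y, 1, 0.01), fit_config(1))
  }
  coarse <- f(0.4)
  fine <- f(0.2)
  expect_lt(abs(coarse$components$mu - fine$components$mu) /
              fine$components$mu, 0.001)
  expect_lt(abs(coarse$components$sigma - fine$components$sigma) /
              fine$components$sigma, 0.001)
})

test_that("fit_fragment selects the true model order by BIC", {
  x <- seq(980, 1020, by = 0.1)
  y1 <- 100 * exp(-(x - 1000)^2 / (2 * 2^2))
  f1 <- fit_fragment(x, y1, fit_config(1:3))
  expect_equal(f1$K, 1L)
  sel <- attr(f1, "order_selection")
  # the BIC table itself confirms the choice
  expect_equal(sel$K[which.min(sel$bic)], 1)

  y2 <- y1 + 70 * exp(-(x - 1012)^2 / (2 * 1^2))
  f2 <- fit_fragment(x, y2, fit_config(1:4))
  expect_equal(f2$K, 2L)

  expect_error(fit_fragment(x, numeric(length(x)), fit_config(1:2)),
               "positive intensity")
})

test_that("parameter recovery holds for well-separated components", {
  set.seed(9)
  for (rep in 1:5) {
    sig <- runif(1, 0.5, 2)
    mus <- c(1000, 1000 + runif(1, 6, 12) * sig)
    x <- seq(1000 - 5 * sig, mus[2] + 5 * sig, by = sig / 8)
    y <- 100 * exp(-(x - mus[1])^2 / (2 * sig^2)) +
      80 * exp(-(x - mus[2])^2 / (2 * sig^2))
    y <- pmax(0, y + rnorm(length(x), 0, 2)) # SNR >= 40
    fit <- quiet(fit_fragment(x, y, fit_config(1:3)))
    for (mu in mus) {
      expect_lt(min(abs(fit$components$mu - mu)), 0.1 * sig)
    }
  }
})
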