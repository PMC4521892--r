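# run code under a local RNG state derived from `seed`, restoring the
# caller's stream afterwards; seed = NULL leaves the global stream alone
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Sample a ground-truth species table
#'
#' Draws a table of peptide/protein species for the virtual-spectrometer
#' style simulator.  Positions are uniform over the m/z range with a
#' minimum spacing enforced by rejection; mean peak intensities are
#' log-normal; per-species intensity SD is a fixed coefficient of
#' variation; peak widths grow linearly with m/z (ToF-like); prevalences
#' (the fraction of samples containing the species) are uniform over
#' `prevalence_range`.
#'
#' @param n_species Number of species (>= 1).
#' @param mz_range Length-2 m/z range in Da; default `c(960, 11169)`, a
#'   typical low-resolution serum profiling range.
#' @param seed Seed making the draw reproducible (local to this call).
#' @param min_spacing Minimum distance between species positions (Da,
#'   default 1.5).
#' @param intensity_meanlog,intensity_sdlog Log-normal parameters of the
#'   mean intensities (defaults `log(50)`, 0.7).
#' @param intensity_cv Per-species SD as a fraction of the mean (default
#'   0.2).
#' @param min_intensity Floor on the mean intensities (counts, default 0);
#'   set it to a multiple of the noise SD to guarantee a minimum
#'   signal-to-noise ratio in rendered spectra.
#' @param width_coeff Peak sigma per Da of m/z (default 1e-3, i.e. a
#'   ToF resolving power m/FWHM of roughly 400, typical of linear-mode
#'   MALDI profiling).
#' @param prevalence_range Range of species prevalences (default
#'   `c(0.5, 1)`).
#' @return A truth tibble: `species`, `mz`, `prevalence`,
#'   `mean_intensity`, `sd_intensity`, `sigma_peak`, sorted by `mz`.
#' @export
sample_truth <- function(n_species, mz_range = c(960, 11169), seed = NULL,
                         min_spacing = 1.5,
                         intensity_meanlog = log(50), intensity_sdlog = 0.7,
                         intensity_cv = 0.2, min_intensity = 0,
                         width_coeff = 1e-3,
                         prevalence_range = c(0.5, 1)) {
  stopifnot(n_species >= 1, length(mz_range) == 2, mz_range[2] > mz_range[1])
  span <- diff(mz_range)
  if ((n_species - 1) * min_spacing >= span) {
    abort("m/z range too small for the requested species count and spacing.")
  }
  with_local_seed(seed, {
    mz <- numeric(0)
    attempts <- 0L
    while (length(mz) < n_species) {
      cand <- runif(1, mz_range[1], mz_range[2])
      if (length(mz) == 0L || min(abs(cand - mz)) >= min_spacing) {
        mz <- c(mz, cand)
      }
      attempts <- attempts + 1L
      if (attempts > 1000L * n_species) {
        abort("m/z range too small for the requested species count and spacing.")
      }
    }
    mz <- sort(mz)
    mean_int <- pmax(
      stats::rlnorm(n_species, intensity_meanlog, intensity_sdlog),
      min_intensity
    )
    tibble(
      species = seq_len(n_species),
      mz = mz,
      prevalence = runif(n_species, prevalence_range[1], prevalence_range[2]),
      mean_intensity = mean_int,
      sd_intensity = intensity_cv * mean_int,
      sigma_peak = width_coeff * mz
    )
  })
}

#' Baseline and noise model for simulated spectra
#'
#' Simulated signals carry the same nuisance structure as real profile
#' spectra: a smooth additive baseline (exponential decay), zero-mean
#' Gaussian noise whose SD is a smooth (linear) function of m/z, and a
#' per-spectrum log-normal multiplicative factor of unit mean modeling the
#' random amount of analyte ionized.
#'
#' @param baseline_amplitude Baseline height at the low-m/z end (counts,
#'   default 20).
#' @param baseline_tau Baseline decay scale (Da, default 3000).
#' @param noise_sd_intercept,noise_sd_slope Noise SD at the low-m/z end and
#'   its growth per Da (defaults 1 and 1e-4).
#' @param multiplicative_sd SD of the log of the per-spectrum factor
#'   (default 0.2); 0 disables it.
#' @return A list of class `msgmm_noise_model`.
#' @export
noise_model <- function(baseline_amplitude = 20, baseline_tau = 3000,
                        noise_sd_intercept = 1, noise_sd_slope = 1e-4,
                        multiplicative_sd = 0.2) {
  stopifnot(baseline_amplitude >= 0, baseline_tau > 0,
            noise_sd_intercept >= 0, noise_sd_slope >= 0,
            multiplicative_sd >= 0)
  structure(
    list(
      baseline_amplitude = baseline_amplitude, baseline_tau = baseline_tau,
      noise_sd_intercept = noise_sd_intercept,
      noise_sd_slope = noise_sd_slope,
      multiplicative_sd = multiplicative_sd
    ),
    class = "msgmm_noise_model"
  )
}

noise_baseline <- function(noise, x) {
  noise$baseline_amplitude * exp(-(x - x[1]) / noise$baseline_tau)
}

noise_sd_at <- function(noise, x) {
  noise$noise_sd_intercept + noise$noise_sd_slope * (x - x[1])
}

#' Render one spectrum from a truth table
#'
#' The noiseless signal is the sum over present species of Gaussian-shaped
#' peaks `intensity_i * exp(-(x - mz_i)^2 / (2 sigma_i^2))` (apex height =
#' species intensity).  The rendered spectrum is that signal times a random
#' per-spectrum multiplicative factor, plus the baseline and heteroscedastic
#' Gaussian noise of the `noise` model, clipped at zero.
#'
#' @param truth A truth tibble from [sample_truth()].
#' @param grid Monotone m/z grid.
#' @param noise A [noise_model()]; `noise_model(0, 1, 0, 0, 0)` renders the
#'   clean signal.
#' @param present Logical vector (one per species); defaults to all
#'   present.  Per-species intensities are drawn as
#'   `N(mean_intensity, sd_intensity)` truncated at 0.
#' @param seed Seed for the per-spectrum randomness (local to this call).
#' @return A spectrum tibble on `grid`.
#' @export
render_spectrum <- function(truth, grid, noise = noise_model(),
                            present = NULL, seed = NULL) {
  if (any(diff(grid) <= 0)) abort("grid must be strictly increasing.")
  n_sp <- nrow(truth)
  present <- present %||% rep(TRUE, n_sp)
  stopifnot(length(present) == n_sp)
  with_local_seed(seed, {
    y <- numeric(length(grid))
    if (any(present)) {
      tt <- truth[present, ]
      amp <- pmax(0, rnorm(nrow(tt), tt$mean_intensity, tt$sd_intensity))
      cmp <- tibble(
        # apex-parameterized: weight = apex * sigma * sqrt(2 pi)
        weight = amp * tt$sigma_peak * sqrt(2 * pi),
        mu = tt$mz, sigma = tt$sigma_peak
      )
      y <- components_signal(grid, cmp)
    }
    m <- if (noise$multiplicative_sd > 0) {
      stats::rlnorm(1, -noise$multiplicative_sd^2 / 2, noise$multiplicative_sd)
    } else {
      1
    }
    y <- m * y + noise_baseline(noise, grid)
    sd <- noise_sd_at(noise, grid)
    if (any(sd > 0)) y <- y + rnorm(length(grid), 0, sd)
    tibble(mz = grid, intensity = pmax(0, y))
  })
}

#' Generate a dataset of simulated spectra with known truth
#'
#' Each species enters each spectrum independently with its prevalence
#' probability; all per-spectrum randomness (presence, intensities,
#' multiplicative factor, noise) flows from `seed`, so an identical seed
#' reproduces the dataset exactly.
#'
#' @param truth A truth tibble from [sample_truth()].
#' @param M Number of spectra (>= 1).
#' @param grid Monotone m/z grid shared by all spectra.
#' @param noise A [noise_model()].
#' @param seed Master seed.
#' @return A list: `spectra` (long tibble with columns `spectrum`, `mz`,
#'   `intensity`) and `present` (M x n_species logical matrix of
#'   per-spectrum presence masks).
#' @export
generate_dataset <- function(truth, M, grid, noise = noise_model(),
                             seed = NULL) {
  stopifnot(M >= 1)
  n_sp <- nrow(truth)
  with_local_seed(seed, {
    present <- matrix(
      rbinom(M * n_sp, 1L, rep(truth$prevalence, each = M)) == 1L,
      nrow = M, ncol = n_sp
    )
    sub_seeds <- if (is.null(seed)) rep(list(NULL), M) else {
      as.list(sample.int(.Machine$integer.max - 1L, M))
    }
    spectra <- purrr::map(seq_len(M), function(m) {
      sp <- render_spectrum(truth, grid, noise, present[m, ],
                            seed = sub_seeds[[m]])
      sp$spectrum <- sprintf("sim_%03d", m)
      sp[, c("spectrum", "mz", "intensity")]
    })
    list(spectra = bind_rows(spectra), present = present)
  })
}
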