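#' Full pipeline configuration with documented defaults
#'
#' Collects every tunable of the pipeline in one nested list.  Any element
#' can be overridden by name via `...`, e.g.
#' `msgmm_config(postprocess = list(weight_thr = 1e-2))`; unknown keys are
#' an error listing the valid ones.
#'
#' @param ... Named overrides merged (recursively for the nested lists)
#'   into the defaults.
#' @return A list of class `msgmm_config` with elements `preprocess`
#'   (baseline window / quantile, whether to remove the baseline),
#'   `partition` (see [partition_config()]), `postprocess` (weight_thr,
#'   mz_thr, relative), `evaluate` (tol), `simulate` (n_species, mz_range,
#'   grid_step, m_spectra, noise), and `seed`.
#' @export
msgmm_config <- function(...) {
  defaults <- list(
    preprocess = list(baseline = TRUE, window = 200, quantile = 0.10),
    partition = unclass(partition_config()),
    postprocess = list(weight_thr = 1e-3, mz_thr = 3e-4, relative = TRUE),
    evaluate = list(tol = 0.003),
    simulate = list(
      n_species = 200, mz_range = c(960, 11169), grid_step = 1,
      m_spectra = 10, min_spacing = 1.5, width_coeff = 1e-3,
      noise = unclass(noise_model())
    ),
    seed = 1L
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown config key(s): %s. Valid keys: %s.",
      paste(bad, collapse = ", "), paste(names(defaults), collapse = ", ")
    ))
  }
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      bad2 <- setdiff(names(overrides[[key]]), names(defaults[[key]]))
      if (length(bad2) > 0) {
        abort(sprintf(
          "unknown config key(s) under '%s': %s. Valid keys: %s.",
          key, paste(bad2, collapse = ", "),
          paste(names(defaults[[key]]), collapse = ", ")
        ))
      }
      defaults[[key]][names(overrides[[key]])] <- overrides[[key]]
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  structure(defaults, class = "msgmm_config")
}

config_partition <- function(config) {
  p <- config$partition
  partition_config(
    quality_thr = p$quality_thr, min_gap_pts = p$min_gap_pts,
    halfwidth_pts = p$halfwidth_pts, max_gap_pts = p$max_gap_pts,
    smooth_window = p$smooth_window, k_max = p$k_max,
    em = if (inherits(p$em, "msgmm_fit_config")) p$em else
      fit_config(
        k_range = p$em$k_range, max_iter = p$em$max_iter, tol = p$em$tol,
        min_sigma = p$em$min_sigma, seed = p$em$seed
      )
  )
}

config_noise <- function(config) {
  n <- config$simulate$noise
  if (inherits(n, "msgmm_noise_model")) return(n)
  noise_model(
    baseline_amplitude = n$baseline_amplitude, baseline_tau = n$baseline_tau,
    noise_sd_intercept = n$noise_sd_intercept,
    noise_sd_slope = n$noise_sd_slope,
    multiplicative_sd = n$multiplicative_sd
  )
}

#' Run one pipeline stage, writing its artifacts to a directory
#'
#' A file-level orchestration of the package's functions, mirroring the
#' shell entry point in `inst/cli/msgmm.R`.  Every run writes a
#' `manifest_<command>.json` (configuration, seed, package version)
#' alongside its outputs so results are reproducible.
#'
#' @param command One of `"simulate"` (write simulated spectra + truth +
#'   presence masks), `"decompose"` (average the input spectra, optionally
#'   remove the baseline, fit the whole-spectrum model, write
#'   `model.tsv`), `"peaks"` (post-process `model.tsv` into `peaks.tsv`),
#'   `"evaluate"` (score `peaks.tsv` against `truth.tsv`, write
#'   `metrics.tsv`), or `"benchmark"` (simulate datasets of several sizes
#'   and tabulate FDR / sensitivity / F1 for the mixture-model detector
#'   and a maxima-picking comparator into `benchmark.tsv`).
#' @param config A [msgmm_config()].
#' @param dir Working directory for inputs and outputs (created if
#'   needed).
#' @param input Optional explicit input path(s) (spectra for
#'   `decompose`, a model for `peaks`); defaults to the artifacts a
#'   previous stage left in `dir`.
#' @param sizes Species counts for `benchmark` (default
#'   `c(100, 200, 300)`).
#' @return Invisibly, the primary artifact of the stage (tibble or model).
#' @export
run_pipeline <- function(command = c("simulate", "decompose", "peaks",
                                     "evaluate", "benchmark"),
                         config = msgmm_config(), dir = ".", input = NULL,
                         sizes = c(100, 200, 300)) {
  command <- match.arg(command)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- switch(
    command,
    simulate = pipeline_simulate(config, dir),
    decompose = pipeline_decompose(config, dir, input),
    peaks = pipeline_peaks(config, dir, input),
    evaluate = pipeline_evaluate(config, dir),
    benchmark = pipeline_benchmark(config, dir, sizes)
  )
  write_manifest(config, dir, command)
  invisible(res)
}

write_manifest <- function(config, dir, command) {
  path <- file.path(dir, sprintf("manifest_%s.json", command))
  unclass_deep <- function(x) {
    if (is.list(x)) lapply(unclass(x), unclass_deep) else x
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(command = command, config = unclass_deep(config),
           package_version = as.character(utils::packageVersion("msgmm"))),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    dput(list(command = command, config = unclass(config)), file = path)
  }
  invisible(path)
}

pipeline_simulate <- function(config, dir) {
  sc <- config$simulate
  truth <- sample_truth(sc$n_species, sc$mz_range, seed = config$seed,
                        min_spacing = sc$min_spacing,
                        width_coeff = sc$width_coeff)
  grid <- seq(sc$mz_range[1], sc$mz_range[2], by = sc$grid_step)
  ds <- generate_dataset(truth, sc$m_spectra, grid, config_noise(config),
                         seed = config$seed + 1L)
  for (id in unique(ds$spectra$spectrum)) {
    one <- ds$spectra[ds$spectra$spectrum == id, c("mz", "intensity")]
    write_spectrum(one, file.path(dir, paste0(id, ".tsv")))
  }
  write_peaks(
    tibble(mz = truth$mz, intensity = truth$mean_intensity),
    file.path(dir, "truth.tsv")
  )
  readr::write_tsv(as_tibble(ds$present, .name_repair = ~ sprintf(
    "species_%03d", seq_len(ncol(ds$present))
  )), file.path(dir, "masks.tsv"), progress = FALSE)
  invisible(ds$spectra)
}

pipeline_decompose <- function(config, dir, input = NULL) {
  paths <- input %||% list.files(dir, pattern = "^sim_.*\\.tsv$",
                                 full.names = TRUE)
  if (length(paths) == 0L) abort("no input spectra for `decompose`.")
  spectra <- bind_rows(lapply(paths, function(p) {
    s <- read_spectrum(p)
    s$spectrum <- basename(p)
    s
  }))
  avg <- average_spectra(spectra)
  if (isTRUE(config$preprocess$baseline)) {
    avg <- remove_baseline(avg, config$preprocess$window,
                           config$preprocess$quantile)
  }
  model <- decompose_spectrum(avg, config_partition(config))
  write_model(model, file.path(dir, "model.tsv"))
  write_spectrum(avg, file.path(dir, "corrected.tsv"))
  invisible(model)
}

pipeline_peaks <- function(config, dir, input = NULL) {
  model <- read_model(input %||% file.path(dir, "model.tsv"))
  pc <- config$postprocess
  peaks <- postprocess_model(model, pc$weight_thr, pc$mz_thr, pc$relative)
  write_peaks(peaks, file.path(dir, "peaks.tsv"))
  invisible(peaks)
}

pipeline_evaluate <- function(config, dir) {
  detected <- read_peaks(file.path(dir, "peaks.tsv"))
  truth <- read_peaks(file.path(dir, "truth.tsv"))
  idx <- performance_indexes(
    match_peaks(detected, truth, config$evaluate$tol)
  )
  readr::write_tsv(idx, file.path(dir, "metrics.tsv"), progress = FALSE)
  invisible(idx)
}

# each detector is operated at the F1-optimal value of its adjustable
# parameter, found by an ROC-style sweep — the comparison convention for
# peak detectors, which all expose a sensitivity/FDR trade-off knob
pipeline_benchmark <- function(config, dir, sizes = c(100, 200, 300),
                               weight_grid = 10^seq(-4, -1.5, length.out = 9),
                               snr_grid = c(2, 3, 5, 8, 12, 20)) {
  rows <- list()
  for (n_sp in sizes) {
    sub <- file.path(dir, sprintf("n%03d", n_sp))
    cfg <- config
    cfg$simulate$n_species <- n_sp
    run_pipeline("simulate", cfg, sub)
    model <- run_pipeline("decompose", cfg, sub)
    truth <- read_peaks(file.path(sub, "truth.tsv"))
    corrected <- read_spectrum(file.path(sub, "corrected.tsv"))
    pc <- config$postprocess
    mz_grid <- pc$mz_thr * c(1, 3, 10)
    gmm_sweep <- bind_rows(lapply(mz_grid, function(mzt) {
      sw <- roc_sweep(
        function(wt) postprocess_model(model, wt, mzt, pc$relative),
        truth, weight_grid, tol = cfg$evaluate$tol
      )
      sw$mz_thr <- mzt
      sw
    }))
    naive_sweep <- roc_sweep(
      function(snr) detect_peaks_maxima(corrected, snr),
      truth, snr_grid, tol = cfg$evaluate$tol
    )
    best <- function(sw, name) {
      row <- sw[which.max(sw$f1), ]
      tibble(
        detector = name, n_species = n_sp, parameter = row$parameter,
        fdr = row$fdr, sensitivity = row$sensitivity, f1 = row$f1,
        n_detected = row$n_detected
      )
    }
    rows[[length(rows) + 1L]] <- bind_rows(
      best(gmm_sweep, "msgmm"), best(naive_sweep, "maxima")
    )
  }
  out <- bind_rows(rows)
  readr::write_tsv(out, file.path(dir, "benchmark.tsv"), progress = FALSE)
  invisible(out)
}
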