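#' Plot a fitted mixture model, optionally over its spectrum
#'
#' Draws each Gaussian component and their sum; when the spectrum is
#' supplied it is shown underneath for comparison.
#'
#' @param object An `msgmm_model`.
#' @param spectrum Optional spectrum data frame the model was fitted to.
#' @param n_grid Number of evaluation points when no spectrum is given.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msgmm_model
#' @export
autoplot.msgmm_model <- function(object, spectrum = NULL, n_grid = 2000, ...) {
  cmp <- object$components
  if (nrow(cmp) == 0L) abort("cannot plot an empty model.")
  grid <- if (!is.null(spectrum)) {
    as_spectrum(spectrum)$mz
  } else {
    lo <- min(cmp$mu - 4 * cmp$sigma)
    hi <- max(cmp$mu + 4 * cmp$sigma)
    seq(lo, hi, length.out = n_grid)
  }
  comp_df <- purrr::map_dfr(seq_len(nrow(cmp)), function(k) {
    tibble(
      component = factor(k), mz = grid,
      intensity = cmp$weight[k] * dnorm(grid, cmp$mu[k], cmp$sigma[k])
    )
  })
  p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$mz,
                                              y = .data$intensity))
  if (!is.null(spectrum)) {
    p <- p + ggplot2::geom_line(data = as_spectrum(spectrum),
                                color = "grey30", linewidth = 0.3)
  }
  p +
    ggplot2::geom_line(
      data = comp_df,
      ggplot2::aes(group = .data$component),
      color = "red", alpha = 0.6, linewidth = 0.3
    ) +
    ggplot2::geom_line(
      data = tibble(mz = grid, intensity = evaluate_mixture(object, grid)),
      color = "red", linewidth = 0.5
    ) +
    ggplot2::labs(x = "m/z (Da)", y = "intensity (counts)") +
    ggplot2::theme_minimal()
}

#' Plot detector performance versus dataset size
#'
#' Companion plot for [run_pipeline()]'s `benchmark` table: F1,
#' sensitivity and FDR per detector across the simulated species counts.
#'
#' @param benchmark A tibble with columns `detector`, `n_species`, `fdr`,
#'   `sensitivity`, `f1`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(benchmark) {
  long <- tidyr::pivot_longer(
    benchmark[, c("detector", "n_species", "fdr", "sensitivity", "f1")],
    c("fdr", "sensitivity", "f1"),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$n_species, y = .data$value,
    color = .data$detector
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = "true number of species", y = NULL) +
    ggplot2::theme_minimal()
}
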