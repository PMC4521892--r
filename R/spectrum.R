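#' Construct and validate a spectrum tibble
#'
#' A spectrum is an ordinary tibble with columns `mz` (mass-to-charge, Da,
#' strictly increasing) and `intensity` (non-negative ion counts).  All
#' functions in msgmm accept any data frame with these two columns;
#' `as_spectrum()` checks the invariants and normalizes column order.
#'
#' @param x A data frame with numeric columns `mz` and `intensity`, or a
#'   two-column numeric data frame taken as (mz, intensity).
#' @param meta Optional free-form identifier attached as the `"meta"`
#'   attribute.
#' @param sort If `TRUE` (default), rows are sorted by `mz` before
#'   validation; duplicated `mz` values are always an error.
#'
#' @return A tibble with columns `mz`, `intensity` satisfying the spectrum
#'   invariants: strictly increasing `mz`, at least 2 rows, finite
#'   non-negative `intensity`.
#' @export
#' @examples
#' as_spectrum(data.frame(mz = c(100, 101, 102), intensity = c(0, 5, 1)))
as_spectrum <- function(x, meta = NULL, sort = TRUE) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame with columns `mz` and `intensity`.")
  }
  if (!all(c("mz", "intensity") %in% names(x)) && ncol(x) == 2L) {
    names(x) <- c("mz", "intensity")
  }
  if (!all(c("mz", "intensity") %in% names(x))) {
    abort("spectrum must have columns `mz` and `intensity`.")
  }
  s <- as_tibble(x)[, c("mz", "intensity")]
  if (!is.numeric(s$mz) || !is.numeric(s$intensity)) {
    abort("`mz` and `intensity` must be numeric.")
  }
  if (sort) s <- s[order(s$mz), ]
  validate_spectrum(s)
  if (!is.null(meta)) attr(s, "meta") <- meta
  s
}

validate_spectrum <- function(s, arg = "spectrum") {
  if (nrow(s) < 2L) {
    abort(sprintf("%s has too few points (%d); need at least 2.", arg, nrow(s)))
  }
  if (anyNA(s$mz) || any(!is.finite(s$mz))) {
    abort(sprintf("%s has non-finite m/z values.", arg))
  }
  d <- diff(s$mz)
  if (any(d <= 0)) {
    abort(sprintf(
      "%s m/z values must be strictly increasing (duplicate or decreasing at row %d).",
      arg, which(d <= 0)[1] + 1L
    ))
  }
  if (anyNA(s$intensity) || any(!is.finite(s$intensity))) {
    abort(sprintf("%s has non-finite intensities.", arg))
  }
  if (any(s$intensity < 0)) {
    abort(sprintf(
      "%s has negative intensities (first at row %d).",
      arg, which(s$intensity < 0)[1]
    ))
  }
  invisible(s)
}

# check a long-format spectrum set (columns spectrum, mz, intensity) shares
# one m/z grid; returns the common grid
spectrum_set_grid <- function(spectra) {
  if (!all(c("spectrum", "mz", "intensity") %in% names(spectra))) {
    abort("a spectrum set needs columns `spectrum`, `mz`, `intensity`.")
  }
  ids <- unique(spectra$spectrum)
  ref <- spectra$mz[spectra$spectrum == ids[1]]
  for (id in ids[-1]) {
    g <- spectra$mz[spectra$spectrum == id]
    if (length(g) != length(ref) || any(g != ref)) {
      abort(sprintf("spectrum '%s' is not on the shared m/z grid.", id))
    }
  }
  ref
}

#' Construct a peak list tibble
#'
#' Peak lists (detected peaks or ground-truth species positions) are tibbles
#' with a sorted `mz` column and optional `intensity` and `label` columns.
#'
#' @param mz Numeric vector of peak positions (Da).
#' @param intensity Optional numeric vector of peak heights.
#' @param label Optional character vector of per-peak labels.
#' @return A tibble sorted by `mz`.
#' @export
peak_list <- function(mz, intensity = NULL, label = NULL) {
  out <- tibble(mz = as.numeric(mz))
  if (!is.null(intensity)) out$intensity <- as.numeric(intensity)
  if (!is.null(label)) out$label <- as.character(label)
  out[order(out$mz), ]
}
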