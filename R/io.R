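#' Read a spectrum from disk
#'
#' Text formats are two-column delimited files (m/z, intensity) with '.' as
#' the decimal mark and no thousands separators; lines starting with `#` are
#' skipped.  Rows out of m/z order are sorted; duplicated m/z values are an
#' error.  mzML reading (via the mzR package, if installed) extracts one
#' profile-mode spectrum.
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"csv"`, `"mzml"`.  Default guesses from
#'   the file extension, falling back to `"tsv"`.
#' @param index For mzML, which spectrum to read (default first).
#' @return A spectrum tibble (see [as_spectrum()]).
#' @export
read_spectrum <- function(path, format = NULL, index = 1L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "mzml")) ext else "tsv"
  }
  format <- arg_match0(format, c("tsv", "csv", "mzml"))
  if (format == "mzml") {
    return(read_spectrum_mzml(path, index))
  }
  delim <- if (format == "csv") "," else "\t"
  raw <- suppressWarnings(readr::read_delim(
    path,
    delim = delim, comment = "#", col_names = FALSE,
    col_types = readr::cols(.default = readr::col_double()),
    trim_ws = TRUE, progress = FALSE
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "unparseable rows in %s (first problem at line %d: %s).",
      path, prob$row[1], prob$expected[1]
    ))
  }
  if (ncol(raw) < 2L) abort(sprintf("%s: need two numeric columns.", path))
  s <- tibble(mz = raw[[1]], intensity = raw[[2]])
  if (anyNA(s$mz) || anyNA(s$intensity)) {
    bad <- which(is.na(s$mz) | is.na(s$intensity))[1]
    abort(sprintf("%s: unparseable values at data row %d.", path, bad))
  }
  as_spectrum(s, meta = basename(path))
}

read_spectrum_mzml <- function(path, index = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("mzML support needs the mzR package.")
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h), add = TRUE)
  pk <- mzR::peaks(h, index)
  as_spectrum(
    tibble(mz = pk[, 1], intensity = pk[, 2]),
    meta = sprintf("%s#%d", basename(path), index)
  )
}

#' Write a spectrum to a delimited text file
#'
#' @param spectrum A spectrum data frame (columns `mz`, `intensity`).
#' @param path Output path; the delimiter follows `format`.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  s <- as_spectrum(spectrum)
  write_full_precision(s, path, delim = if (format == "csv") "," else "\t",
                       col_names = FALSE)
  invisible(path)
}

#' Write a mixture model's component table
#'
#' The on-disk schema is a delimited table with header columns
#' `component_index`, `alpha`, `weight_w`, `mu_Da`, `sigma_Da`, written at
#' full floating precision so that [read_model()] round-trips losslessly.
#'
#' @param model An `msgmm_model`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "msgmm_model"))
  cmp <- model$components
  if (nrow(cmp) == 0L) warn("writing an empty model (header-only file).")
  out <- tibble(
    component_index = seq_len(nrow(cmp)),
    alpha = cmp$alpha,
    weight_w = cmp$weight,
    mu_Da = cmp$mu,
    sigma_Da = cmp$sigma
  )
  write_full_precision(out, path, delim = "\t", col_names = TRUE)
  invisible(path)
}

#' Read a mixture model component table
#'
#' Accepts tables with the [write_model()] schema.  Components are sorted by
#' mean; mixing proportions off from summing to 1 by at most 1e-6 are
#' renormalized, larger deviations are an error.
#'
#' @param path Path to a model TSV.
#' @return An `msgmm_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  needed <- c("alpha", "weight_w", "mu_Da", "sigma_Da")
  if (!all(needed %in% names(tab))) {
    abort(sprintf(
      "model table must have columns %s.", paste(needed, collapse = ", ")
    ))
  }
  if (nrow(tab) == 0L) {
    return(mixture_model(tibble(
      alpha = numeric(), weight = numeric(), mu = numeric(), sigma = numeric()
    )))
  }
  if (any(tab$sigma_Da <= 0)) abort("model table has sigma_Da <= 0.")
  if (any(tab$alpha < 0)) abort("model table has negative alpha.")
  a <- sum(tab$alpha)
  if (abs(a - 1) > 1e-6) {
    abort(sprintf("alphas sum to %.10g; must be 1 within 1e-6.", a))
  }
  mixture_model(tibble(
    alpha = tab$alpha / a,
    weight = tab$weight_w,
    mu = tab$mu_Da,
    sigma = tab$sigma_Da
  ))
}

#' Read or write a peak list
#'
#' Peak and ground-truth lists share one schema: a delimited table with
#' columns `mz_Da` and optionally `intensity` and `label`.
#'
#' @param path File path.
#' @return For `read_peaks()`, a peak-list tibble sorted by `mz`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      mz_Da = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  if (!"mz_Da" %in% names(tab)) abort("peak table must have a mz_Da column.")
  peak_list(
    tab$mz_Da,
    intensity = if ("intensity" %in% names(tab)) tab$intensity,
    label = if ("label" %in% names(tab)) tab$label
  )
}

#' @param peaks A peak-list data frame with column `mz` and optional
#'   `intensity`, `label`.
#' @rdname read_peaks
#' @export
write_peaks <- function(peaks, path) {
  out <- tibble(mz_Da = peaks$mz)
  if ("intensity" %in% names(peaks)) out$intensity <- peaks$intensity
  if ("label" %in% names(peaks)) out$label <- peaks$label
  write_full_precision(out, path, delim = "\t", col_names = TRUE)
  invisible(path)
}

# doubles are printed as %.17g so that reading them back is bitwise exact
write_full_precision <- function(df, path, delim, col_names) {
  df <- as_tibble(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }))
  readr::write_delim(df, path, delim = delim, col_names = col_names,
                     progress = FALSE)
}
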