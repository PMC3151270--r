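#' Multichannel time-series container
#'
#' A `ts_set` holds `N` channels of equal length `N_s` as the rows of a
#' numeric matrix, together with the sampling rate and provenance metadata.
#' It is the raw material for all interdependence estimators and the
#' synthetic-data generators.
#'
#' @param data numeric matrix, one channel per row, one sample per column.
#' @param fs sampling rate in Hz (default 1).
#' @param labels character vector of channel names; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param meta named list of provenance information (generator, filter size,
#'   seed, ...).
#' @return An object of class `ts_set` with fields `data`, `fs`, `labels`,
#'   `meta`.
#' @examples
#' x <- ts_set(matrix(rnorm(20), nrow = 2), fs = 10)
#' n_channels(x); n_samples(x)
#' @export
ts_set <- function(data, fs = 1, labels = NULL, meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2L) stop("a ts_set needs at least 2 samples per channel")
  if (nrow(data) < 1L) stop("a ts_set needs at least 1 channel")
  if (anyNA(data) || any(!is.finite(data))) stop("ts_set data must be finite, no missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("labels length must match number of channels")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = as.character(labels), meta = meta),
            class = "ts_set")
}

#' @rdname ts_set
#' @param x a `ts_set`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname ts_set
#' @export
n_samples <- function(x) ncol(x$data)

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("<ts_set> %d channels x %d samples @ %g Hz\n",
              n_channels(x), n_samples(x), x$fs))
  if (length(x$meta)) {
    keys <- paste(names(x$meta), collapse = ", ")
    cat("  meta:", keys, "\n")
  }
  invisible(x)
}

#' Normalize channels to zero mean (and optionally unit variance)
#'
#' Each channel is shifted to zero mean; with `unit_variance = TRUE` it is
#' additionally scaled to unit standard deviation.  The population (1/N)
#' standard deviation is used throughout the package so that the lag-0
#' cross-covariance of normalized channels reproduces the Pearson correlation
#' exactly.
#'
#' @param x a `ts_set`.
#' @param unit_variance also scale each channel to unit (population) SD?
#' @return the normalized `ts_set`; `meta$normalized` records what was done.
#' @export
normalize_ts <- function(x, unit_variance = TRUE) {
  stopifnot(inherits(x, "ts_set"))
  d <- x$data
  mu <- rowMeans(d)
  d <- d - mu
  if (unit_variance) {
    s <- sqrt(rowMeans(d^2))
    if (any(s <= 0)) {
      bad <- x$labels[which(s <= 0)[1L]]
      stop(sprintf("channel '%s' is constant: cannot normalize to unit variance", bad))
    }
    d <- d / s
  }
  x$data <- d
  x$meta$normalized <- if (unit_variance) "zero-mean-unit-variance" else "zero-mean"
  x
}

#' Write / read a `ts_set` as delimited text
#'
#' The on-disk format is a TSV with one header row of channel labels and one
#' sample per row ('.' decimal, UTF-8).  The sampling rate and metadata go to
#' a JSON sidecar `<path>.json`.
#'
#' @param x a `ts_set`.
#' @param path output TSV path.
#' @return `write_ts_tsv` returns `path` invisibly; `read_ts_tsv` a `ts_set`.
#' @export
write_ts_tsv <- function(x, path) {
  stopifnot(inherits(x, "ts_set"))
  tab <- as.data.frame(t(x$data))
  names(tab) <- x$labels
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  side <- list(fs = x$fs, meta = x$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ts_tsv
#' @export
read_ts_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  side_path <- paste0(path, ".json")
  fs <- 1; meta <- list()
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    fs <- side$fs %||% 1
    meta <- as.list(side$meta %||% list())
  }
  ts_set(t(as.matrix(tab)), fs = fs, labels = names(tab), meta = meta)
}
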