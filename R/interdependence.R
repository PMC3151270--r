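#' Pairwise interdependence matrices
#'
#' An `interdep_matrix` is a symmetric N x N matrix of interdependence values
#' in \[0, 1\] with unit diagonal (the diagonal is never used for
#' thresholding), tagged with the estimator that produced it.
#'
#' @param values symmetric numeric matrix in \[0, 1\].
#' @param estimator `"corr"` (absolute correlation coefficient) or
#'   `"maxcross"` (maximum absolute cross-correlation).
#' @param labels channel labels.
#' @param max_lag lag range used by the `"maxcross"` estimator (NULL for
#'   `"corr"`).
#' @return an object of class `interdep_matrix`.
#' @export
interdep_matrix <- function(values, estimator = c("corr", "maxcross"),
                            labels = NULL, max_lag = NULL) {
  estimator <- match.arg(estimator)
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("values must be square")
  if (max(abs(values - t(values))) > 1e-12) stop("values must be symmetric")
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 1
  if (is.null(labels)) labels <- rownames(values) %||% sprintf("ch%02d", seq_len(n))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, estimator = estimator,
                 labels = as.character(labels), max_lag = max_lag),
            class = "interdep_matrix")
}

#' @export
print.interdep_matrix <- function(x, ...) {
  cat(sprintf("<interdep_matrix> %s, %d channels", x$estimator, nrow(x$values)))
  if (!is.null(x$max_lag)) cat(sprintf(", max_lag = %d", x$max_lag))
  cat("\n")
  invisible(x)
}

.check_nondegenerate <- function(x) {
  s <- apply(x$data, 1L, stats::sd)
  if (any(s == 0)) {
    bad <- x$labels[which(s == 0)[1L]]
    stop(sprintf("channel '%s' is constant: interdependence undefined", bad))
  }
}

#' Absolute correlation matrix
#'
#' Entry (i, j) is the absolute value of the Pearson correlation coefficient
#' of channels i and j.  High values indicate strongly interdependent
#' channels; for independent channels the values concentrate near zero as
#' the series length grows.
#'
#' @param x a [ts_set]; every channel must have nonzero sample SD.
#' @return an [interdep_matrix] with estimator `"corr"`.
#' @examples
#' ts <- ts_set(rbind(1:4, c(1, 3, 2, 4)))
#' corr_matrix(ts)$values[1, 2]  # 0.8
#' @export
corr_matrix <- function(x) {
  stopifnot(inherits(x, "ts_set"))
  .check_nondegenerate(x)
  r <- abs(stats::cor(t(x$data)))
  interdep_matrix(r, "corr", labels = x$labels)
}

#' Maximum absolute cross-correlation matrix
#'
#' Channels are first normalized to zero mean and unit population variance;
#' entry (i, j) is then the maximum over lags `tau` in
#' `[-max_lag, max_lag]` of the absolute cross-covariance
#' `|1/N_s * sum_t x_i(t + tau) x_j(t)|` with non-circular (zero-padded)
#' lags.  At `tau = 0` this equals the absolute correlation coefficient, so
#' the maximum dominates [corr_matrix] entrywise.
#'
#' @param x a [ts_set].
#' @param max_lag maximum lag in samples, `0 <= max_lag <= N_s - 1`; default
#'   the full range `N_s - 1`.
#' @return an [interdep_matrix] with estimator `"maxcross"`.
#' @export
maxcrosscorr_matrix <- function(x, max_lag = NULL) {
  stopifnot(inherits(x, "ts_set"))
  .check_nondegenerate(x)
  n <- n_channels(x)
  ns <- n_samples(x)
  if (is.null(max_lag)) max_lag <- ns - 1L
  if (max_lag < 0 || max_lag >= ns) stop("max_lag must satisfy 0 <= max_lag <= N_s - 1")
  max_lag <- as.integer(max_lag)
  xn <- normalize_ts(x, unit_variance = TRUE)$data
  nfft <- stats::nextn(2L * ns, 2)
  # one FFT per channel; cross-covariances via products of spectra
  F <- stats::mvfft(rbind(t(xn), matrix(0, nfft - ns, n)))
  vals <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cc <- Re(stats::fft(F[, i] * Conj(F[, j]), inverse = TRUE)) / nfft / ns
      lags <- c(1L, if (max_lag > 0) c(2L:(max_lag + 1L), (nfft - max_lag + 1L):nfft))
      vals[i, j] <- vals[j, i] <- max(abs(cc[lags]))
    }
  }
  interdep_matrix(vals, "maxcross", labels = x$labels, max_lag = max_lag)
}

#' Write / read an interdependence matrix as CSV
#'
#' Square CSV with channel labels as header and row names; estimator and
#' `max_lag` go to a JSON sidecar `<path>.json`.
#'
#' @param m an [interdep_matrix].
#' @param path output CSV path.
#' @export
write_interdep_csv <- function(m, path) {
  stopifnot(inherits(m, "interdep_matrix"))
  utils::write.table(m$values, path, sep = ",", quote = FALSE,
                     col.names = NA, fileEncoding = "UTF-8")
  jsonlite::write_json(list(estimator = m$estimator, max_lag = m$max_lag),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_interdep_csv
#' @export
read_interdep_csv <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = ",", header = TRUE, row.names = 1,
                                   check.names = FALSE, fileEncoding = "UTF-8"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  interdep_matrix(v, side$estimator, labels = rownames(v),
                  max_lag = side$max_lag %||% NULL)
}
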