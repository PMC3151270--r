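#' Split a recording into normalized analysis windows
#'
#' Consecutive, non-overlapping windows of `round(window_seconds * fs)`
#' samples; a trailing partial window is dropped.  Every window's channels
#' are normalized to zero mean and unit (population) variance before any
#' estimation, matching standard practice for windowed field data.
#'
#' @param recording a [ts_set] with its sampling rate set.
#' @param window_seconds window duration in seconds (e.g. 2.5 s at 200 Hz
#'   gives 500-sample windows).
#' @return list of normalized [ts_set] windows; each carries
#'   `meta$window_start` (1-based first sample).
#' @export
window_series <- function(recording, window_seconds) {
  stopifnot(inherits(recording, "ts_set"))
  nw <- as.integer(round(window_seconds * recording$fs))
  if (nw < 2L) stop("window too short")
  total <- n_samples(recording)
  if (total < nw) stop("window longer than recording")
  n_win <- total %/% nw
  lapply(seq_len(n_win), function(w) {
    idx <- ((w - 1L) * nw + 1L):(w * nw)
    win <- ts_set(recording$data[, idx, drop = FALSE], fs = recording$fs,
                  labels = recording$labels,
                  meta = list(window_start = idx[1L], window_index = w))
    normalize_ts(win, unit_variance = TRUE)
  })
}

#' Windowed network analysis with tailored null ensembles
#'
#' For each window and each interdependence estimator: derives the observed
#' network at a single fixed edge density (so that edge-density effects are
#' excluded), measures clustering coefficient `C`, average shortest path
#' length `L` and component count `K`, builds the requested null ensembles,
#' and records the ensemble-normalized ratios.
#'
#' @param windows list of normalized [ts_set] windows (see [window_series]).
#' @param estimators subset of `c("corr", "maxcross")`.
#' @param rho_target fixed edge density in (0, 1).
#' @param ensembles subset of `c("spectrum", "iaaft")` (may be empty).
#' @param R null-ensemble realizations per window (default 20).
#' @param seed optional master seed.
#' @param max_lag lag range for `"maxcross"`.
#' @return an object of class `windowed_analysis`: a tidy data.frame
#'   `$table` with one row per (window, estimator, ensemble) holding the
#'   observed metrics, the null means/SDs and the ratios, plus the call
#'   parameters in `$params`.
#' @export
analyze_recording <- function(windows, estimators = c("corr", "maxcross"),
                              rho_target = 0.1,
                              ensembles = c("spectrum", "iaaft"),
                              R = 20, seed = NULL, max_lag = NULL) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (length(ensembles))
    ensembles <- match.arg(ensembles, c("spectrum", "iaaft"), several.ok = TRUE)
  if (!length(windows)) stop("need at least one window")
  if (rho_target <= 0 || rho_target >= 1) stop("rho_target must lie in (0, 1)")
  rows <- list()
  counter <- 0L
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    for (est in estimators) {
      m <- tryCatch({
        if (est == "corr") corr_matrix(win)
        else maxcrosscorr_matrix(win, max_lag = max_lag)
      }, error = function(e)
        stop(sprintf("window %d: %s", w, conditionMessage(e)), call. = FALSE))
      net <- threshold_by_density(m, rho_target)
      obs <- network_metrics(net)
      if (!length(ensembles)) {
        rows[[length(rows) + 1L]] <- data.frame(
          window = w, estimator = est, ensemble = NA_character_,
          C = obs$C, L = obs$L, K = obs$K, rho = obs$rho,
          null_C_mean = NA_real_, null_C_sd = NA_real_,
          null_L_mean = NA_real_, null_L_sd = NA_real_,
          C_ratio = NA_real_, L_ratio = NA_real_)
      }
      for (ens in ensembles) {
        counter <- counter + 1L
        null <- build_null_ensemble(win, method = ens, estimator = est,
                                    rho_target = rho_target, R = R,
                                    seed = derive_seed(seed, counter),
                                    max_lag = max_lag)
        ratios <- tryCatch(normalize_by_ensemble(obs, null), error = function(e) {
          warning(sprintf("window %d (%s/%s): %s", w, est, ens, conditionMessage(e)),
                  call. = FALSE)
          list(C_ratio = NA_real_, L_ratio = NA_real_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          window = w, estimator = est, ensemble = ens,
          C = obs$C, L = obs$L, K = obs$K, rho = obs$rho,
          null_C_mean = null$C_mean, null_C_sd = null$C_sd,
          null_L_mean = null$L_mean, null_L_sd = null$L_sd,
          C_ratio = ratios$C_ratio, L_ratio = ratios$L_ratio)
      }
    }
  }
  structure(list(table = do.call(rbind, rows),
                 params = list(estimators = estimators, rho_target = rho_target,
                               ensembles = ensembles, R = R, seed = seed,
                               max_lag = max_lag, n_windows = length(windows))),
            class = "windowed_analysis")
}

#' @export
print.windowed_analysis <- function(x, ...) {
  cat(sprintf("<windowed_analysis> %d windows, estimators: %s, ensembles: %s\n",
              x$params$n_windows, paste(x$params$estimators, collapse = "/"),
              if (length(x$params$ensembles)) paste(x$params$ensembles, collapse = "/")
              else "none"))
  invisible(x)
}

# proportional cut points: event window w (1..W) goes to bin k iff
# floor((k-1)*W/n_bins) < w <= floor(k*W/n_bins)
.bin_assignment <- function(W, n_bins) {
  cuts <- floor((0:n_bins) * W / n_bins)
  rep(seq_len(n_bins), times = diff(cuts))
}

#' Bin windowed metrics around a marked event
#'
#' Assigns the event windows (onset..end) to `n_bins` equidistant bins by
#' proportional cut points `floor(k * W / n_bins)`, plus one pre-event bin
#' of the `n_peri` windows before onset and one post-event bin of the
#' `n_peri` windows after the end, and reports the per-bin mean and standard
#' error of every metric column.  When several analyses are supplied the
#' windows are pooled across recordings within each bin.
#'
#' @param analysis a `windowed_analysis` or a list of them.
#' @param onset_window,end_window first and last event window (1-based,
#'   inclusive).
#' @param n_bins number of event bins (default 10).
#' @param n_peri windows pooled into each of the pre and post bins.
#' @param estimator,ensemble which rows of the analysis table to use.
#' @param metrics metric columns to summarize.
#' @return a data.frame of class `binned_profile`: bin label (pre, e01..e10,
#'   post), per-metric mean and standard error, and the window count.
#' @export
bin_event <- function(analysis, onset_window, end_window, n_bins = 10,
                      n_peri = 1, estimator = "corr", ensemble = NULL,
                      metrics = c("C", "L", "C_ratio", "L_ratio")) {
  analyses <- if (inherits(analysis, "windowed_analysis")) list(analysis) else analysis
  if (onset_window > end_window) stop("onset must not exceed end")
  pieces <- list()
  for (a in analyses) {
    tab <- a$table
    tab <- tab[tab$estimator == estimator, , drop = FALSE]
    if (!is.null(ensemble)) tab <- tab[tab$ensemble %in% ensemble, , drop = FALSE]
    n_win <- a$params$n_windows
    if (onset_window < 1 || end_window > n_win)
      stop("event markers outside the analyzed window range")
    if (onset_window - n_peri < 1 || end_window + n_peri > n_win)
      stop(sprintf("insufficient peri-event windows: need %d on both sides, have %d pre / %d post",
                   n_peri, onset_window - 1, n_win - end_window))
    W <- end_window - onset_window + 1L
    if (W < n_bins)
      warning("fewer event windows than bins: some bins will be empty")
    ev_bins <- .bin_assignment(W, n_bins)
    bin_of <- rep(NA_character_, n_win)
    bin_of[(onset_window - n_peri):(onset_window - 1L)] <- "pre"
    bin_of[onset_window:end_window] <- sprintf("e%02d", ev_bins)
    bin_of[(end_window + 1L):(end_window + n_peri)] <- "post"
    tab$bin <- bin_of[tab$window]
    pieces[[length(pieces) + 1L]] <- tab[!is.na(tab$bin), , drop = FALSE]
  }
  pooled <- do.call(rbind, pieces)
  levels <- c("pre", sprintf("e%02d", seq_len(n_bins)), "post")
  out <- lapply(levels, function(b) {
    sub <- pooled[pooled$bin == b, , drop = FALSE]
    row <- data.frame(bin = b, n_windows = nrow(sub))
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      row[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(m, "_se")]] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                                 else if (length(v) == 1) 0 else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("binned_profile", "data.frame")
  out
}

#' Trailing moving-average smoothing of a metric profile
#'
#' Presentation-only smoothing (as applied to plotted profiles): each value
#' is replaced by the mean of the last `window` values; the first
#' `window - 1` points average over the available prefix.  Never applied to
#' the metrics entering binned statistics.
#'
#' @param values numeric vector.
#' @param window smoothing window (default 4); `window = 1` is the identity.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, window = 4) {
  if (window < 1 || window != round(window)) stop("window must be a positive integer")
  if (window == 1) return(values)
  cs <- cumsum(values)
  n <- length(values)
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window + 1L)
    out[t] <- (cs[t] - if (lo > 1L) cs[lo - 1L] else 0) / (t - lo + 1L)
  }
  out
}

#' Write the tidy windowed-analysis table to CSV
#' @param analysis a `windowed_analysis`.
#' @param path output CSV path.
#' @export
write_analysis_csv <- function(analysis, path) {
  stopifnot(inherits(analysis, "windowed_analysis"))
  utils::write.table(analysis$table, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(analysis$params, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
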