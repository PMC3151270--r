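#' Generate independent uniform white-noise channels
#'
#' Draws `n_series` channels of `n_samples` i.i.d. samples from the uniform
#' distribution on (-0.5, 0.5) and shifts each channel to zero mean.  This is
#' the elementary non-interacting process from which all finite-sample
#' effects in this package are demonstrated; the support is a documented
#' constant (any centered interval is equivalent after normalization).
#'
#' @param n_series number of channels (>= 1).
#' @param n_samples samples per channel (>= 2).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @param fs sampling rate recorded on the result (default 1).
#' @return a [ts_set] with zero-mean rows.
#' @examples
#' x <- gen_uniform_series(3, 100, seed = 1)
#' rowMeans(x$data)  # ~ 0
#' @export
gen_uniform_series <- function(n_series, n_samples, seed = NULL, fs = 1) {
  if (!is.numeric(n_series) || n_series < 1) stop("n_series must be >= 1")
  if (!is.numeric(n_samples) || n_samples < 2) stop("n_samples must be >= 2")
  d <- with_seed(seed, matrix(stats::runif(n_series * n_samples, -0.5, 0.5),
                              nrow = n_series))
  d <- d - rowMeans(d)
  ts_set(d, fs = fs, meta = list(generator = "uniform", seed = seed))
}

#' Trailing moving-average filter
#'
#' Low-pass filters every channel with a trailing (causal) moving average of
#' size `M`: output sample `t` is the arithmetic mean of raw samples
#' `t-M+1, ..., t`.  Only full windows are kept, so the output has
#' `n_samples - M + 1` columns; generate `M - 1` extra raw samples when a
#' fixed output length is needed (see [gen_filtered_series]).  The window
#' size `M` controls the relative amount of low-frequency content.
#'
#' @param x a [ts_set].
#' @param M moving-average size (integer >= 1); `M = 1` is the identity.
#' @return a [ts_set] of the filtered channels.
#' @export
moving_average_filter <- function(x, M) {
  stopifnot(inherits(x, "ts_set"))
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("M must be a positive integer")
  M <- as.integer(M)
  if (M == 1L) return(x)
  if (n_samples(x) < M) stop("need at least M samples per channel")
  filt <- function(v) {
    out <- stats::filter(v, rep(1 / M, M), method = "convolution", sides = 1)
    as.numeric(out[M:length(v)])
  }
  d <- t(apply(x$data, 1L, filt))
  if (n_samples(x) - M + 1L == 1L) d <- matrix(d, nrow = n_channels(x))
  meta <- x$meta; meta$M <- M
  ts_set(d, fs = x$fs, labels = x$labels, meta = meta)
}

#' Moving-average filtered uniform noise at full length
#'
#' Convenience wrapper: draws `n_samples + M - 1` raw uniform samples per
#' channel so the trailing moving average has no partial windows, filters,
#' and re-centers each channel to zero mean.
#'
#' @inheritParams gen_uniform_series
#' @param M moving-average size (>= 1).
#' @return a [ts_set] with `n_samples` columns.
#' @export
gen_filtered_series <- function(n_series, n_samples, M, seed = NULL, fs = 1) {
  if (!is.numeric(M) || M < 1 || M != round(M)) stop("M must be a positive integer")
  raw <- gen_uniform_series(n_series, n_samples + M - 1, seed = seed, fs = fs)
  out <- moving_average_filter(raw, M)
  out$data <- out$data - rowMeans(out$data)
  out$meta <- list(generator = "ma-filtered-uniform", M = as.integer(M), seed = seed)
  out
}

#' Noise with a prescribed power spectrum
#'
#' Draws uniform white noise, transforms to the Fourier domain, scales the
#' coefficient at positive frequency bin `k` by `sqrt(target_spectrum[k])`
#' (DC is zeroed), inverse-transforms, and normalizes each channel to zero
#' mean and unit (population) variance.  The ensemble-mean periodogram is
#' proportional to `target_spectrum`; individual realizations fluctuate.
#'
#' @param target_spectrum non-negative weights on the positive-frequency grid
#'   of length `floor(n_samples / 2)`; rescaled to sum 1.
#' @inheritParams gen_uniform_series
#' @return a [ts_set] with zero-mean, unit-variance rows.
#' @export
gen_spectrum_filtered_noise <- function(target_spectrum, n_series, n_samples,
                                        seed = NULL, fs = 1) {
  if (!is.numeric(n_series) || n_series < 1) stop("n_series must be >= 1")
  if (!is.numeric(n_samples) || n_samples < 2) stop("n_samples must be >= 2")
  n <- as.integer(n_samples)
  nb <- n %/% 2L
  s <- as.numeric(target_spectrum)
  if (length(s) != nb)
    stop(sprintf("target_spectrum must have length floor(n_samples/2) = %d, got %d",
                 nb, length(s)))
  if (anyNA(s) || any(s < 0)) stop("target_spectrum must be non-negative")
  tot <- sum(s)
  if (tot <= 0) stop("target_spectrum must have positive total mass")
  s <- s / tot
  amp <- sqrt(s)
  d <- with_seed(seed, {
    m <- matrix(0, nrow = n_series, ncol = n)
    for (i in seq_len(n_series)) {
      w <- stats::runif(n, -0.5, 0.5)
      W <- stats::fft(w)
      X <- complex(length.out = n)
      X[1L] <- 0
      # positive frequencies 1..nb (bin nb is Nyquist when n is even)
      X[2L:(nb + 1L)] <- W[2L:(nb + 1L)] * amp
      if (n %% 2L == 0L) X[nb + 1L] <- complex(real = Re(X[nb + 1L]))
      neg <- if (n %% 2L == 0L) seq_len(nb - 1L) else seq_len(nb)
      X[n + 1L - neg] <- Conj(X[neg + 1L])
      m[i, ] <- Re(stats::fft(X, inverse = TRUE)) / n
    }
    m
  })
  out <- ts_set(d, fs = fs,
                meta = list(generator = "spectrum-filtered", seed = seed))
  normalize_ts(out, unit_variance = TRUE)
}

#' Band-power schedule for the seizure-like emulator
#'
#' One row per window: target relative powers of the classical EEG bands
#' (delta 0-4 Hz, theta 4-8, alpha 8-12, beta 12-20), summing to at most 1
#' (the remainder is spread over the residual band up to Nyquist), a
#' cross-channel coupling strength in [0, 1], and a phase label.
#'
#' @param delta,theta,alpha,beta per-window relative band powers (recycled).
#' @param coupling per-window coupling strength gamma in [0, 1]; 0 means the
#'   channels are generated independently, 1 means all channels share one
#'   latent signal.
#' @param label per-window phase labels, e.g. "pre"/"seizure"/"post".
#' @return a data.frame of class `band_schedule`.
#' @export
band_schedule <- function(delta, theta = 0.1, alpha = 0.1, beta = 0.1,
                          coupling = 0, label = "pre") {
  sched <- data.frame(delta = delta, theta = theta, alpha = alpha, beta = beta,
                      coupling = coupling, label = label,
                      stringsAsFactors = FALSE)
  pw <- as.matrix(sched[, c("delta", "theta", "alpha", "beta")])
  if (anyNA(pw) || any(pw < 0)) stop("band powers must be non-negative")
  if (any(rowSums(pw) > 1 + 1e-12)) stop("band powers must sum to <= 1 per window")
  if (any(sched$coupling < 0 | sched$coupling > 1)) stop("coupling must lie in [0, 1]")
  class(sched) <- c("band_schedule", "data.frame")
  sched
}

# canonical EEG band edges (Hz), half-open (lo, hi]
.bands <- list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 20))

# target spectrum for one schedule row on the positive-frequency grid
.schedule_spectrum <- function(row, n, fs) {
  nb <- n %/% 2L
  freq <- (1:nb) * fs / n
  s <- numeric(nb)
  used <- rep(FALSE, nb)
  for (b in names(.bands)) {
    e <- .bands[[b]]
    idx <- which(freq > e[1] & freq <= e[2])
    if (!length(idx)) stop(sprintf("band %s has no frequency bins at fs=%g, n=%d", b, fs, n))
    s[idx] <- s[idx] + row[[b]] / length(idx)
    used[idx] <- TRUE
  }
  rest <- 1 - (row$delta + row$theta + row$alpha + row$beta)
  if (rest > 1e-12) {
    idx <- which(!used)
    if (!length(idx)) idx <- seq_len(nb)
    s[idx] <- s[idx] + rest / length(idx)
  }
  s
}

#' Multichannel seizure-like recording emulator
#'
#' Concatenates windows of spectrum-filtered noise whose expected relative
#' band powers follow a [band_schedule], emulating the delta-dominant to
#' beta-shifted to delta-elevated power evolution seen across an epileptic
#' seizure.  With coupling `gamma > 0` a common latent signal with the same
#' spectrum is mixed into every channel as
#' `x_i = sqrt(1 - gamma^2) * noise_i + gamma * latent`, so the expected
#' pairwise correlation is about `gamma^2` and the band powers are unchanged.
#' This is a stand-in for real multichannel EEG: it controls band powers and
#' coupling only (no spikes, artifacts or 1/f structure).
#'
#' @param n_channels number of channels.
#' @param schedule a [band_schedule], one row per window.
#' @param window_len window length in seconds; `window_len * fs` must be an
#'   integer >= 8.
#' @param fs sampling rate in Hz; the beta band edge (20 Hz) must lie below
#'   Nyquist.
#' @param seed optional integer seed.
#' @return a [ts_set] of length `nrow(schedule) * window_len * fs`; the
#'   schedule is kept in `meta$schedule`.
#' @export
gen_seizure_like_recording <- function(n_channels, schedule, window_len, fs,
                                       seed = NULL) {
  stopifnot(inherits(schedule, "band_schedule"))
  if (n_channels < 1) stop("n_channels must be >= 1")
  nw <- window_len * fs
  if (abs(nw - round(nw)) > 1e-9 || round(nw) < 8)
    stop("window_len * fs must be an integer >= 8")
  nw <- as.integer(round(nw))
  if (max(vapply(.bands, `[`, numeric(1), 2L)) > fs / 2)
    stop("schedule band edges above Nyquist: increase fs")
  blocks <- vector("list", nrow(schedule))
  for (w in seq_len(nrow(schedule))) {
    row <- schedule[w, ]
    s <- .schedule_spectrum(row, nw, fs)
    sw <- derive_seed(seed, w)
    noise <- gen_spectrum_filtered_noise(s, n_channels, nw, seed = sw, fs = fs)
    g <- row$coupling
    if (g > 0) {
      lat <- gen_spectrum_filtered_noise(s, 1, nw, seed = derive_seed(seed, 100000 + w),
                                         fs = fs)
      mix <- sqrt(1 - g^2) * noise$data +
        g * matrix(lat$data[1L, ], n_channels, nw, byrow = TRUE)
      noise$data <- mix
      noise <- normalize_ts(noise, unit_variance = TRUE)
    }
    blocks[[w]] <- noise$data
  }
  d <- do.call(cbind, blocks)
  ts_set(d, fs = fs,
         meta = list(generator = "seizure-like", seed = seed,
                     window_samples = nw, schedule = as.data.frame(schedule)))
}
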