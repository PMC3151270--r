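#' Normalized periodogram
#'
#' Squared DFT amplitudes on the positive-frequency grid up to Nyquist,
#' normalized to sum 1.  The DC bin is excluded (the series is centered
#' before transforming), so the profile describes the relative distribution
#' of power over frequency.
#'
#' @param x numeric series, length >= 8 (a [ts_set] row, typically
#'   zero-mean).
#' @param fs sampling rate in Hz.
#' @return a list of class `spectral_profile`: `freq` (Hz, `(1:nb) * fs/n`),
#'   `power` (sums to 1), `fs`, `n`.
#' @export
periodogram <- function(x, fs = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("series must have length >= 8")
  if (anyNA(x) || any(!is.finite(x))) stop("series must be finite")
  x <- x - mean(x)
  nb <- n %/% 2L
  p <- Mod(stats::fft(x))[2L:(nb + 1L)]^2
  tot <- sum(p)
  if (tot <= 0) stop("degenerate series: no power off DC")
  structure(list(freq = (1:nb) * fs / n, power = p / tot, fs = fs, n = n),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> %d bins up to %.3g Hz\n", length(x$freq),
              max(x$freq)))
  invisible(x)
}

#' Relative power in a frequency band
#'
#' Sum of the normalized periodogram over the half-open band
#' `f_lo < f <= f_hi`, so the canonical EEG bands delta (0, 4\], theta
#' (4, 8\], alpha (8, 12\], beta (12, 20\] partition (0, 20\] without double
#' counting.
#'
#' @param p a [periodogram] profile.
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= Nyquist`.
#' @return relative power in \[0, 1\].
#' @export
band_power <- function(p, f_lo, f_hi) {
  stopifnot(inherits(p, "spectral_profile"))
  if (f_lo < 0 || f_hi <= f_lo) stop("band edges must satisfy 0 <= f_lo < f_hi")
  if (f_hi > p$fs / 2 + 1e-9) stop("f_hi above Nyquist")
  sum(p$power[p$freq > f_lo & p$freq <= f_hi])
}

#' @rdname band_power
#' @return `eeg_band_powers`: named vector of relative powers in the four
#'   canonical bands.
#' @export
eeg_band_powers <- function(p) {
  ok <- vapply(.bands, function(e) e[2] <= p$fs / 2 + 1e-9, logical(1))
  vapply(.bands[ok], function(e) band_power(p, e[1], e[2]), numeric(1))
}

#' Split frequency for the moving-average filter power
#'
#' Finds the frequency `f*` splitting the squared transfer function
#' `|H(f)|^2 = (sin(pi f M / fs) / (M sin(pi f / fs)))^2` of the size-`M`
#' moving average such that `fraction` (default 0.4) of its total power over
#' (0, Nyquist\] lies in the chosen range.  With `side = "upper"` (default)
#' the fraction refers to the upper range `[f*, Nyquist]`; `side = "lower"`
#' makes it refer to `(0, f*]`.  The exact convention does not sensitively
#' affect degree--power correlations as long as `f*` falls inside the
#' filter's roll-off; both are exposed.
#'
#' @param M moving-average size (>= 1).  `M = 1` has a flat transfer
#'   function and no meaningful split: the function warns and returns
#'   Nyquist/2.
#' @param fraction power fraction in (0, 1), default 0.4.
#' @param fs sampling rate in Hz (default 1).
#' @param n_grid resolution of the numerical quantile (default 8192).
#' @param side `"upper"` or `"lower"`.
#' @return `f*` in Hz.
#' @export
choose_fstar <- function(M, fraction = 0.4, fs = 1, n_grid = 8192,
                         side = c("upper", "lower")) {
  side <- match.arg(side)
  if (M < 1 || M != round(M)) stop("M must be a positive integer")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  if (M == 1) {
    warning("M = 1: flat filter, any split is trivial; returning Nyquist/2")
    return(fs / 4)
  }
  nu <- seq(0, 0.5, length.out = n_grid + 1L)[-1L]  # normalized frequency
  H2 <- (sin(pi * nu * M) / (M * sin(pi * nu)))^2
  cum <- cumsum(H2) / sum(H2)  # power fraction in (0, nu]
  target <- if (side == "upper") 1 - fraction else fraction
  idx <- which(cum >= target)[1L]
  nu[idx] * fs
}

#' Correlation between node degrees and low-frequency power
#'
#' For each network realization, computes the Pearson correlation between
#' the node degrees and each node's relative power below `f*` (`P_lower`);
#' since `P_lower + P_upper = 1`, the correlation with the upper-range power
#' is exactly the negative.  Realizations with constant degrees (empty or
#' complete networks) have no defined correlation and are flagged.
#'
#' @param nets list of [tsnet] realizations.
#' @param profiles list (same length) of per-node [periodogram] profile
#'   lists — `profiles[[r]][[i]]` is the profile of node i in realization r.
#' @param fstar split frequency in Hz (see [choose_fstar]).
#' @return list with per-realization `r_lower`, `r_lower_mean`,
#'   `r_lower_sd`, and `n_undefined`.
#' @export
degree_power_correlation <- function(nets, profiles, fstar) {
  stopifnot(length(nets) == length(profiles), length(nets) >= 1L)
  rs <- vapply(seq_along(nets), function(r) {
    k <- degrees(nets[[r]])
    pl <- vapply(profiles[[r]],
                 function(p) sum(p$power[p$freq <= fstar]), numeric(1))
    if (length(pl) != nets[[r]]$n) stop("one profile per node required")
    if (stats::sd(k) == 0 || stats::sd(pl) == 0) return(NA_real_)
    stats::cor(k, pl)
  }, numeric(1))
  ok <- !is.na(rs)
  list(r_lower = rs,
       r_lower_mean = mean(rs[ok]),
       r_lower_sd = if (sum(ok) > 1) stats::sd(rs[ok]) else NA_real_,
       n_undefined = sum(!ok))
}

#' Wilcoxon comparison of degree-power correlations against a reference
#'
#' Bonferroni-corrected pairwise Wilcoxon rank-sum tests of each condition's
#' per-realization correlations against the reference condition (typically
#' the unfiltered `M = 1` networks).
#'
#' @param r_ref numeric vector of reference correlations.
#' @param r_list named list of numeric vectors, one per condition.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame with condition, p_raw, p_bonf, significant.
#' @export
degree_power_significance <- function(r_ref, r_list, alpha = 0.05) {
  m <- length(r_list)
  p_raw <- vapply(r_list, function(r)
    stats::wilcox.test(r[!is.na(r)], r_ref[!is.na(r_ref)], exact = FALSE)$p.value,
    numeric(1))
  p_bonf <- pmin(1, p_raw * m)
  data.frame(condition = names(r_list) %||% seq_len(m),
             p_raw = p_raw, p_bonf = p_bonf,
             significant = p_bonf < alpha, row.names = NULL)
}

#' Write a spectral profile to CSV
#'
#' Columns frequency, power; the band summary goes to a JSON sidecar.
#'
#' @param p a `spectral_profile`.
#' @param path output CSV path.
#' @export
write_spectrum_csv <- function(p, path) {
  utils::write.table(data.frame(frequency = p$freq, power = p$power),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(eeg_band_powers(p)), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
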