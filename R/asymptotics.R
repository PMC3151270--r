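#' Variance-inflation factor of the moving-average filter
#'
#' For a trailing moving average of size `M` over white noise the lag-`tau`
#' autocorrelation is `r_M(tau) = (M - |tau|)/M`; the Bartlett factor
#' `c(M) = sum_tau r_M(tau)^2 = (2 M^2 + 1) / (3 M)` inflates the variance of
#' the correlation estimator between two independent filtered series by
#' `c(M)` relative to white noise of the same length.
#'
#' @param M moving-average size (>= 1); `c(1) = 1`.
#' @return the factor `c(M)` (vectorized).
#' @export
ma_variance_factor <- function(M) {
  if (any(M < 1 | M != round(M))) stop("M must be a positive integer")
  (2 * M^2 + 1) / (3 * M)
}

#' Effective length of moving-average filtered series
#'
#' The white-noise series length whose correlation-estimator variance
#' matches that of filtered series of length `n_samples`:
#' `N_eff = n_samples / c(M)` with the Bartlett factor [ma_variance_factor].
#' This reparametrization collapses the (length, filter-size) dependence of
#' all finite-sample network effects onto a single axis.
#'
#' @param n_samples series length (>= 2).
#' @param M moving-average size (>= 1).
#' @return a list of class `effective_length` with `n_samples`, `M`,
#'   `n_eff`.
#' @examples
#' effective_length(900, 2)$n_eff  # 600
#' @export
effective_length <- function(n_samples, M) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  structure(list(n_samples = n_samples, M = as.integer(M),
                 n_eff = n_samples / ma_variance_factor(M)),
            class = "effective_length")
}

#' @export
print.effective_length <- function(x, ...) {
  cat(sprintf("<effective_length> N_s = %g, M = %d -> N_eff = %.2f", x$n_samples,
              x$M, x$n_eff))
  if (!is.null(x$n_eff_fit))
    cat(sprintf(" (fitted %.2f, residual %.3g)", x$n_eff_fit, x$residual))
  cat("\n")
  invisible(x)
}

#' Asymptotic edge density of thresholded noise networks
#'
#' The asymptotic probability that the absolute correlation of two
#' independent moving-average filtered noise series exceeds `theta`:
#' `2 * (1 - Phi(theta * sqrt(N_eff)))` with `Phi` the standard normal CDF
#' and `N_eff` the [effective_length].  Equals the expected edge density of
#' a network thresholded at `theta`, independently of the network size.
#'
#' @param theta threshold(s), >= 0.
#' @param n_samples series length.
#' @param M moving-average size (default 1, plain white noise).
#' @return numeric vector of densities in \[0, 1\].
#' @export
asymptotic_edge_density <- function(theta, n_samples, M = 1) {
  if (any(theta < 0)) stop("theta must be >= 0")
  neff <- effective_length(n_samples, M)$n_eff
  2 * stats::pnorm(theta * sqrt(neff), lower.tail = FALSE)
}

.edge_density_curve <- function(theta, rho, provenance) {
  if (is.unsorted(theta)) {
    o <- order(theta); theta <- theta[o]; rho <- rho[o]
  }
  structure(list(theta = theta, rho = rho,
                 se = provenance$se %||% rep(NA_real_, length(theta)),
                 provenance = provenance),
            class = "edge_density_curve")
}

#' @export
print.edge_density_curve <- function(x, ...) {
  cat(sprintf("<edge_density_curve> %d thresholds, %s\n", length(x$theta),
              x$provenance$kind %||% "unknown"))
  invisible(x)
}

#' Monte-Carlo edge density of noise networks
#'
#' Simulates `n_pairs` independent pairs of moving-average filtered uniform
#' noise series and reports, for each threshold, the fraction of pairs whose
#' interdependence exceeds it — the numerically determined link probability,
#' which is independent of network size by construction.
#'
#' @param theta_grid thresholds in \[0, 1\].
#' @param n_samples series length.
#' @param M moving-average size.
#' @param n_pairs number of simulated pairs.
#' @param seed optional integer seed.
#' @param estimator `"corr"` (default, C++ kernel) or `"maxcross"` (slower R
#'   path).
#' @param max_lag lag range for `"maxcross"` (default full).
#' @return an `edge_density_curve` with binomial standard errors.
#' @export
mc_edge_density <- function(theta_grid, n_samples, M = 1, n_pairs = 10000,
                            seed = NULL, estimator = c("corr", "maxcross"),
                            max_lag = NULL) {
  estimator <- match.arg(estimator)
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  absr <- mc_pair_values(n_samples, M, n_pairs, seed, estimator, max_lag)
  rho <- vapply(theta_grid, function(th) mean(absr > th), numeric(1))
  se <- sqrt(rho * (1 - rho) / n_pairs)
  .edge_density_curve(theta_grid, rho,
                      list(kind = "monte-carlo", estimator = estimator,
                           n_samples = n_samples, M = M, n_pairs = n_pairs,
                           seed = seed, se = se))
}

# |interdependence| values of independent simulated pairs
mc_pair_values <- function(n_samples, M, n_pairs, seed = NULL,
                           estimator = c("corr", "maxcross"), max_lag = NULL) {
  estimator <- match.arg(estimator)
  if (estimator == "corr") {
    return(with_seed(seed, cpp_pair_abs_corr(as.integer(n_pairs),
                                             as.integer(n_samples),
                                             as.integer(M))))
  }
  vals <- numeric(n_pairs)
  for (p in seq_len(n_pairs)) {
    ts <- gen_filtered_series(2, n_samples, M, seed = derive_seed(seed, p))
    vals[p] <- maxcrosscorr_matrix(ts, max_lag = max_lag)$values[1L, 2L]
  }
  vals
}

#' Monte-Carlo clustering coefficient of noise networks
#'
#' Size-independent estimator of the clustering coefficient at given target
#' edge densities: over independent triples of filtered noise series it
#' estimates the conditional probability that pair (1,3) is linked given
#' that (1,2) and (2,3) are linked.  The density-to-threshold conversion
#' uses the empirical quantile of the pooled pair values (a monotone
#' inversion of the Monte-Carlo edge-density curve).  For white noise and
#' long series the dependence between the three pair estimates vanishes and
#' the estimate approaches the Erdos-Renyi value `rho`; short or strongly
#' filtered series inflate it.
#'
#' @param rho_grid target edge densities in (0, 1\].
#' @param n_samples series length.
#' @param M moving-average size.
#' @param n_triples number of simulated triples.
#' @param seed optional integer seed.
#' @return data.frame with columns rho, theta, C_hat, se, n_cond.
#' @export
mc_clustering <- function(rho_grid, n_samples, M = 1, n_triples = 10000,
                          seed = NULL) {
  if (n_triples < 1) stop("n_triples must be >= 1")
  if (any(rho_grid <= 0 | rho_grid > 1)) stop("rho_grid must lie in (0, 1]")
  tri <- with_seed(seed, cpp_triple_abs_corr(as.integer(n_triples),
                                             as.integer(n_samples),
                                             as.integer(M)))
  pooled <- as.numeric(tri)
  out <- lapply(rho_grid, function(rho) {
    theta <- if (rho >= 1) 0 else stats::quantile(pooled, 1 - rho, names = FALSE)
    cond <- tri[, 1L] > theta & tri[, 2L] > theta
    n_cond <- sum(cond)
    C_hat <- if (n_cond > 0) mean(tri[cond, 3L] > theta) else NA_real_
    se <- if (n_cond > 0) sqrt(C_hat * (1 - C_hat) / n_cond) else NA_real_
    data.frame(rho = rho, theta = theta, C_hat = C_hat, se = se, n_cond = n_cond)
  })
  do.call(rbind, out)
}

#' Monte-Carlo effective length (variance matching)
#'
#' The independent oracle for [effective_length]: estimates the variance of
#' the correlation estimator for filtered pairs at (`n_samples`, `M`) and
#' finds the white-noise length whose Monte-Carlo estimator variance
#' matches, by log-log interpolation over a grid of candidate lengths
#' (common random numbers across candidates).
#'
#' @inheritParams mc_edge_density
#' @param n_pairs replicates for both the filtered and the white-noise arms.
#' @return a list of class `effective_length` with the matched `n_eff` and
#'   the measured variances.
#' @export
mc_effective_length <- function(n_samples, M, n_pairs = 1e5, seed = NULL) {
  v_f <- with_seed(derive_seed(seed, 1) %||% NULL, {
    r <- cpp_pair_abs_corr(as.integer(n_pairs), as.integer(n_samples), as.integer(M))
    mean(r^2)
  })
  guess <- effective_length(n_samples, M)$n_eff
  cand <- unique(pmax(8L, as.integer(round(exp(seq(log(guess / 2.5),
                                                   log(min(2.5 * guess, n_samples * 1.2)),
                                                   length.out = 12L))))))
  vw <- with_seed(derive_seed(seed, 2) %||% NULL, {
    m <- cpp_white_abs_corr_prefix(as.integer(n_pairs), cand)
    colMeans(m^2)
  })
  # Var ~ 1/N: interpolate log(var) vs log(N)
  fitN <- exp(stats::approx(log(vw), log(cand), xout = log(v_f), rule = 2)$y)
  structure(list(n_samples = n_samples, M = as.integer(M), n_eff = fitN,
                 var_filtered = v_f, var_white = vw, candidates = cand,
                 kind = "mc-variance-matching"),
            class = "effective_length")
}

#' Fit the effective length from edge-density curves
#'
#' Finds the white-noise length whose Monte-Carlo edge-density curve matches,
#' in a least-squares sense over a threshold grid, the curve of filtered
#' series at (`n_samples`, `M`).  The white-noise curve family is evaluated
#' on nested prefixes of a single stream (common random numbers), making the
#' objective smooth in the candidate length; the minimizer is located on a
#' fine geometric grid.
#'
#' @param n_samples series length of the filtered arm.
#' @param M moving-average size of the filtered arm.
#' @param theta_grid thresholds; default 25 values spanning densities
#'   about 0.9 down to 0.005 for the filtered curve.
#' @param n_pairs Monte-Carlo pairs per curve.
#' @param seed optional integer seed.
#' @return a list of class `effective_length` with the analytic `n_eff`, the
#'   fitted `n_eff_fit` and the least-squares `residual`.
#' @export
fit_effective_length <- function(n_samples, M, theta_grid = NULL,
                                 n_pairs = 2e4, seed = NULL) {
  absr_f <- with_seed(derive_seed(seed, 1) %||% NULL,
                      cpp_pair_abs_corr(as.integer(n_pairs), as.integer(n_samples),
                                        as.integer(M)))
  if (is.null(theta_grid)) {
    dens <- exp(seq(log(0.9), log(0.005), length.out = 25L))
    theta_grid <- stats::quantile(absr_f, 1 - dens, names = FALSE)
  }
  rho_f <- vapply(theta_grid, function(th) mean(absr_f > th), numeric(1))
  guess <- effective_length(n_samples, M)$n_eff
  lo <- max(8, guess / 4); hi <- max(n_samples, guess * 2)
  cand <- unique(as.integer(round(exp(seq(log(lo), log(hi), length.out = 100L)))))
  white <- with_seed(derive_seed(seed, 2) %||% NULL,
                     cpp_white_abs_corr_prefix(as.integer(n_pairs), cand))
  obj <- vapply(seq_along(cand), function(k) {
    rho_w <- vapply(theta_grid, function(th) mean(white[, k] > th), numeric(1))
    sum((rho_f - rho_w)^2)
  }, numeric(1))
  best <- which.min(obj)
  if (!is.finite(obj[best])) stop("fit-error: objective not finite over the candidate grid")
  structure(list(n_samples = n_samples, M = as.integer(M),
                 n_eff = guess, n_eff_fit = as.numeric(cand[best]),
                 residual = obj[best], theta_grid = theta_grid,
                 candidates = cand, objective = obj),
            class = "effective_length")
}

#' Binomial degree law of Erdos-Renyi networks
#'
#' Probability that a node of an ER network with `n` nodes and edge density
#' `rho` has degree `k`: the Binomial(n-1, rho) pmf.  Degree distributions
#' of networks derived from unfiltered white noise match this law; strongly
#' filtered series depart from it (elevated probability of isolated nodes).
#'
#' @param n number of nodes (>= 1).
#' @param rho edge density in \[0, 1\].
#' @param k degree(s), 0 <= k <= n - 1.
#' @return pmf value(s).
#' @export
binomial_degree_pmf <- function(n, rho, k) {
  if (n < 1) stop("n must be >= 1")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  if (any(k < 0 | k > n - 1)) stop("k must lie in [0, n-1]")
  stats::dbinom(k, n - 1, rho)
}

#' Write an edge-density curve (or any theta/value curve) to CSV
#'
#' Long, figure-ready format: theta, value, se; provenance to a JSON
#' sidecar.
#'
#' @param curve an `edge_density_curve`.
#' @param path output CSV path.
#' @export
write_curve_csv <- function(curve, path) {
  tab <- data.frame(theta = curve$theta, value = curve$rho, se = curve$se)
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  prov <- curve$provenance
  prov$se <- NULL
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}
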