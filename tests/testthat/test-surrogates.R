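ar1 <- function(n, phi = 0.8, seed = NULL) {
  spurnet:::with_seed(seed, as.numeric(stats::arima.sim(list(ar = phi), n)))
}

test_that("IAAFT preserves amplitudes exactly and the spectrum approximately", {
  x <- ar1(512, seed = 81)
  s <- iaaft_surrogate(x, seed = 82)
  expect_identical(sort(s), sort(x))
  info <- attr(s, "iaaft")
  expect_true(info$converged)
  expect_lt(info$spec_err, 0.05)
  expect_identical(as.numeric(iaaft_surrogate(x, seed = 82)), as.numeric(s))
  expect_error(iaaft_surrogate(c(1, 2, 3)), "length")
})

test_that("distinct seeds give distinct, mutually independent surrogates", {
  x <- ar1(512, seed = 83)
  s1 <- iaaft_surrogate(x, seed = 1)
  s2 <- iaaft_surrogate(x, seed = 2)
  expect_false(identical(as.numeric(s1), as.numeric(s2)))
  # cross-correlation of two surrogates consistent with independence
  rs <- vapply(1:20, function(k) {
    a <- iaaft_surrogate(x, seed = 100 + k)
    b <- iaaft_surrogate(x, seed = 200 + k)
    abs(cor(as.numeric(a), as.numeric(b)))
  }, numeric(1))
  # AR(1) with phi=0.8 has c ~ (1+phi)/(1-phi) variance inflation; stay loose
  expect_lt(mean(rs), 6 / sqrt(512))
})

test_that("ensemble defaults and summary bookkeeping", {
  expect_equal(eval(formals(build_null_ensemble)$R), 20)
  win <- gen_filtered_series(10, 128, M = 2, seed = 84)
  ens <- build_null_ensemble(win, "spectrum", "corr", rho_target = 0.2, R = 4,
                             seed = 85)
  expect_equal(ens$R, 4)
  expect_length(ens$C, 4)
  expect_gte(min(ens$C), 0); expect_lte(max(ens$C), 1)
  expect_gte(ens$C_sd, 0); expect_gte(ens$L_sd, 0)
  bad <- ts_set(rbind(rep(1, 128), rnorm(128)), labels = c("flat", "ok"))
  expect_error(build_null_ensemble(bad, "iaaft", rho_target = 0.2, R = 2), "flat")
})

test_that("spectrum ensemble is self-consistent under the null", {
  nb <- 100; n <- 200
  target <- exp(-(1:nb) / 20); target <- target / sum(target)
  win <- gen_spectrum_filtered_noise(target, 12, n, seed = 86)
  ens <- build_null_ensemble(win, "spectrum", "corr", rho_target = 0.15, R = 15,
                             seed = 87)
  direct <- vapply(1:15, function(r) {
    fresh <- gen_spectrum_filtered_noise(target, 12, n, seed = 900 + r)
    clustering_coefficient(threshold_by_density(corr_matrix(fresh), 0.15))
  }, numeric(1))
  se <- sqrt(ens$C_sd^2 / ens$R + var(direct) / length(direct))
  expect_lt(abs(ens$C_mean - mean(direct)), 3 * se)
})

test_that("homogeneous window: spectrum and IAAFT ensembles agree for rho_c", {
  win <- gen_filtered_series(12, 256, M = 4, seed = 88)
  e1 <- build_null_ensemble(win, "spectrum", "corr", rho_target = 0.15, R = 15,
                            seed = 89)
  e2 <- build_null_ensemble(win, "iaaft", "corr", rho_target = 0.15, R = 15,
                            seed = 90)
  se <- sqrt(e1$C_sd^2 / e1$R + e2$C_sd^2 / e2$R)
  expect_lt(abs(e1$C_mean - e2$C_mean), 3 * se)
})

test_that("heterogeneous spectra: ensembles diverge under rho_m more than rho_c", {
  # half the channels white, half strongly low-pass filtered
  set.seed(91)
  n <- 12; ns <- 256
  white <- gen_uniform_series(n / 2, ns, seed = 92)$data
  slow <- gen_filtered_series(n / 2, ns, M = 16, seed = 93)$data
  win <- normalize_ts(ts_set(rbind(white, slow)))
  zstat <- function(est) {
    a <- build_null_ensemble(win, "spectrum", est, rho_target = 0.15, R = 12,
                             seed = 94, max_lag = 64)
    b <- build_null_ensemble(win, "iaaft", est, rho_target = 0.15, R = 12,
                             seed = 95, max_lag = 64)
    abs(a$C_mean - b$C_mean) / sqrt(a$C_sd^2 / a$R + b$C_sd^2 / b$R)
  }
  z_m <- zstat("maxcross")
  z_c <- zstat("corr")
  expect_gt(z_m, 3)      # the key rho_m sensitivity to spectral heterogeneity
  expect_lt(z_c, z_m)    # rho_c much less affected
})

test_that("normalize_by_ensemble ratios", {
  obs <- list(C = 0.4, L = 2)
  null <- ensemble_result("spectrum", C = rep(0.4, 3), L = rep(2, 3), R = 3, "corr")
  expect_equal(normalize_by_ensemble(obs, null), list(C_ratio = 1, L_ratio = 1))
  obs2 <- list(C = 0.8, L = 2)
  expect_equal(normalize_by_ensemble(obs2, null)$C_ratio, 2)
  null0 <- ensemble_result("spectrum", C = rep(0, 3), L = rep(2, 3), R = 3, "corr")
  expect_error(normalize_by_ensemble(obs, null0), "zero")
})

test_that("spectrum-ensemble channels reproduce the window's mean periodogram", {
  nb <- 64; n <- 128
  target <- (1:nb)^(-0.5); target <- target / sum(target)
  win <- gen_spectrum_filtered_noise(target, 8, n, seed = 96)
  specs <- vapply(1:8, function(i) periodogram(win$data[i, ])$power, numeric(nb))
  mean_spec <- rowMeans(specs); mean_spec <- mean_spec / sum(mean_spec)
  acc <- numeric(nb)
  for (r in 1:200) {
    z <- gen_spectrum_filtered_noise(mean_spec, 1, n, seed = 3000 + r)
    acc <- acc + periodogram(z$data[1, ])$power
  }
  acc <- acc / 200
  band <- function(v) vapply(split(v, rep(1:8, each = nb / 8)), sum, numeric(1))
  expect_lt(max(abs(band(acc) / band(mean_spec) - 1)), 0.10)
})

test_that("ensemble CSV writer", {
  null <- ensemble_result("iaaft", C = c(0.1, 0.2), L = c(1, 2), R = 2, "corr")
  path <- file.path(tempdir(), "ens.csv")
  write_ensemble_csv(list(null), path)
  tab <- read.csv(path)
  expect_equal(tab$method, "iaaft")
  expect_equal(tab$C_mean, 0.15)
})
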