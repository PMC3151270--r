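test_that("periodogram: pure tone, normalization, flat white-noise expectation", {
  n <- 256; fs <- 200
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 25 * t)       # 25 Hz sits on the grid (bin 32)
  p <- periodogram(x, fs)
  expect_gte(p$power[which.min(abs(p$freq - 25))], 0.99)
  expect_lt(abs(sum(p$power) - 1), 1e-10)

  set.seed(101)
  nb <- n %/% 2
  acc <- matrix(0, 200, nb)
  for (r in 1:200) acc[r, ] <- periodogram(runif(n) - 0.5, fs)$power
  mu <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(200)
  expect_gte(mean(abs(mu - 1 / nb) <= 3 * se), 0.95)

  expect_error(periodogram(c(1, NA, 3, 4, 5, 6, 7, 8)), "finite")
})

test_that("band powers: full band, alpha tone, white-noise fractions, additivity", {
  n <- 500; fs <- 200
  t <- (0:(n - 1)) / fs
  p_alpha <- periodogram(sin(2 * pi * 10 * t), fs)
  expect_gte(band_power(p_alpha, 8, 12), 0.99)
  expect_equal(band_power(p_alpha, 0, fs / 2), 1, tolerance = 1e-10)

  set.seed(102)
  tot <- replicate(100, {
    p <- periodogram(runif(n) - 0.5, fs)
    band_power(p, 0, 4) + band_power(p, 4, 8) + band_power(p, 8, 12) +
      band_power(p, 12, 20)
  })
  expect_lt(abs(mean(tot) - 0.2), 3 * sd(tot) / sqrt(100))

  # additivity of disjoint bands is exact
  p <- periodogram(runif(n) - 0.5, fs)
  expect_equal(band_power(p, 0, 8), band_power(p, 0, 4) + band_power(p, 4, 8),
               tolerance = 1e-14)
  expect_error(band_power(p, 12, 8), "band edges")
})

test_that("filtered-noise periodogram follows the boxcar transfer function", {
  M <- 8; n <- 512; nb <- n %/% 2
  nu <- (1:nb) / n
  H2 <- (sin(pi * nu * M) / (M * sin(pi * nu)))^2
  ref <- H2 / sum(H2)
  acc <- numeric(nb)
  nreal <- 1000
  for (r in seq_len(nreal)) {
    y <- gen_filtered_series(1, n, M, seed = 4000 + r)
    acc <- acc + periodogram(y$data[1, ])$power
  }
  acc <- acc / nreal
  band <- function(v) vapply(split(v, rep(1:8, each = nb / 8)), sum, numeric(1))
  expect_lt(max(abs(band(acc) - band(ref)) / pmax(band(ref), 1e-3)), 0.10)
})

test_that("choose_fstar: limits, brute-force quantile, M = 1 degenerate", {
  # fraction -> 0 pushes f* to Nyquist; fraction -> 1 pushes it to 0
  expect_gt(choose_fstar(8, 0.001), choose_fstar(8, 0.4))
  expect_lt(choose_fstar(8, 0.999), choose_fstar(8, 0.4))
  expect_gt(choose_fstar(8, 0.001), 0.45)          # near Nyquist (fs = 1)
  expect_lt(choose_fstar(8, 0.999), 0.05)

  # dense-grid brute force oracle, M = 8, upper-range convention
  M <- 8
  nu <- seq(1e-6, 0.5, length.out = 2e5)
  H2 <- (sin(pi * nu * M) / (M * sin(pi * nu)))^2
  cum <- cumsum(H2) / sum(H2)
  fstar_bf <- nu[which(cum >= 1 - 0.4)[1]]
  expect_lt(abs(choose_fstar(8, 0.4) - fstar_bf), 0.5 / 8192 + 0.5 / 2e5)

  expect_warning(f1 <- choose_fstar(1, 0.4, fs = 200), "flat")
  expect_equal(f1, 50)
})

test_that("degree-power correlation: null at M = 1, positive and significant at M = 16", {
  run_condition <- function(M, n_real = 60, n = 40, ns = 300, rho = 0.1) {
    nets <- vector("list", n_real); profs <- vector("list", n_real)
    for (r in seq_len(n_real)) {
      ts <- gen_filtered_series(n, ns, M, seed = M * 100000 + r)
      nets[[r]] <- threshold_by_density(corr_matrix(ts), rho)
      profs[[r]] <- lapply(seq_len(n), function(i) periodogram(ts$data[i, ]))
    }
    degree_power_correlation(nets, profs, fstar = suppressWarnings(choose_fstar(max(M, 2), 0.4)))
  }
  r1 <- run_condition(1)
  se1 <- r1$r_lower_sd / sqrt(sum(!is.na(r1$r_lower)))
  expect_lt(abs(r1$r_lower_mean), 3 * se1)

  r16 <- run_condition(16)
  expect_gt(r16$r_lower_mean, r1$r_lower_mean)
  expect_gt(r16$r_lower_mean, 0)

  sig <- degree_power_significance(r1$r_lower, list(M16 = r16$r_lower))
  expect_true(sig$significant[1])

  # r_upper = -r_lower by construction (P_lower + P_upper = 1)
  net <- threshold_by_density(corr_matrix(gen_filtered_series(20, 200, 8, seed = 5)), 0.1)
  ts <- gen_filtered_series(20, 200, 8, seed = 5)
  prof <- lapply(1:20, function(i) periodogram(ts$data[i, ]))
  fstar <- 0.1
  k <- degrees(net)
  pl <- vapply(prof, function(p) sum(p$power[p$freq <= fstar]), numeric(1))
  expect_equal(cor(k, 1 - pl), -cor(k, pl), tolerance = 1e-12)
})

test_that("spectrum CSV writer", {
  p <- periodogram(runif(64) - 0.5, fs = 200)
  path <- file.path(tempdir(), "spec.csv")
  write_spectrum_csv(p, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 32)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_true(all(c("delta", "theta", "alpha", "beta") %in% names(side)))
})
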