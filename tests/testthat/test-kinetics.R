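test_that("chromatogram generator obeys the first-order law and conserves area", {
  # closing law boundary values
  s0 <- generate_chromatogram_series(k = 1, times = 0, noise_sd = 0, seed = 1)
  f0 <- attr(s0, "truth")$f
  expect_equal(f0, 0)
  s_inf <- generate_chromatogram_series(k = 1, times = 100, noise_sd = 0)
  expect_lt(abs(attr(s_inf, "truth")$f - 0.95), 1e-3)
  # quadrature: closed-peak area fraction equals f(t) to 1e-6 (noise-free,
  # peaks separated by 10 sigma so the midpoint split loses no tail mass)
  s <- generate_chromatogram_series(k = 0.5, times = c(0.5, 2, 10),
                                    centers = c(10, 12.5),
                                    noise_sd = 0, volume_step = 0.002)
  truth <- attr(s, "truth")
  for (i in seq_along(s)) {
    ch <- s[[i]]
    mid <- mean(truth$centers)
    closed <- ch$volume_mL >= mid   # closed peak elutes later
    a_closed <- trapz_area(ch$volume_mL[closed], ch$signal[closed])
    a_tot <- trapz_area(ch$volume_mL, ch$signal)
    expect_lt(abs(a_closed / a_tot - truth$f[i]), 1e-6)
  }
  # total area invariant across time points
  areas <- vapply(s, function(ch) trapz_area(ch$volume_mL, ch$signal), 1)
  expect_lt(max(abs(areas - areas[1])) / areas[1], 1e-6)
  expect_error(generate_chromatogram_series(1, 0, centers = c(10, 10)),
               "degenerate")
})

test_that("bi-Gaussian deconvolution is exact on its generative model", {
  v <- seq(9, 12.5, by = 0.01)
  y <- fretcycle:::gauss_peak(v, 10.4, 0.25, 0.3) +
    fretcycle:::gauss_peak(v, 11.0, 0.25, 0.7)
  fit <- fit_bigaussian(chromatogram(v, y))
  expect_equal(fit$f_closed, 0.700, tolerance = 1e-3)
  expect_equal(fit$centers, c(10.4, 11.0), tolerance = 1e-3)
  # component areas sum to the integrated signal
  expect_lt(abs(sum(fit$areas) - trapz_area(v, y)) / trapz_area(v, y), 0.02)
  # single open peak: closed fraction collapses to ~0
  y1 <- fretcycle:::gauss_peak(v, 10.4, 0.25, 1)
  fit1 <- fit_bigaussian(chromatogram(v, y1))
  expect_lte(fit1$f_closed, 0.01)
})

test_that("noisy overlapping peaks stay within 0.03 of the generating fraction", {
  errs <- vapply(1:20, function(r) {
    s <- generate_chromatogram_series(k = 1, times = 1.2, f_inf = 0.9,
                                      centers = c(10.4, 10.4 + 1.5 * 0.25),
                                      sigmas = c(0.25, 0.25),
                                      noise_sd = 0.01, seed = 100 + r)
    fit <- fit_bigaussian(s[[1]], init = c(10.4, 10.775))
    abs(fit$f_closed - attr(s, "truth")$f)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.03)
})

test_that("global series fit recovers shared shapes and endpoint fractions", {
  s <- generate_chromatogram_series(k = 0.8, times = c(0, 0.5, 1, 2, 4, 8),
                                    noise_sd = 0.005, seed = 2)
  sf <- fit_bigaussian_series(s)
  expect_lt(max(abs(sf$centers - c(10.4, 11.0))), 0.01)
  truth <- attr(s, "truth")
  expect_lt(max(abs(sf$fractions$f_closed - truth$f)), 0.02)
  # rescaling the signal leaves the fractions unchanged
  s10 <- lapply(s, function(ch)
    chromatogram(ch$volume_mL, ch$signal * 10, ch$time_min))
  sf10 <- fit_bigaussian_series(s10)
  expect_equal(sf10$fractions$f_closed, sf$fractions$f_closed,
               tolerance = 1e-6)
  # all-open + all-closed profiles pin the extremes
  v <- s[[1]]$volume_mL
  ext <- list(chromatogram(v, fretcycle:::gauss_peak(v, 10.4, 0.25, 1), 0),
              chromatogram(v, fretcycle:::gauss_peak(v, 11.0, 0.25, 1), 60),
              s[[4]])
  sfe <- fit_bigaussian_series(ext, init = c(10.4, 11.0))
  expect_lt(sfe$fractions$f_closed[1], 0.01)
  expect_gt(sfe$fractions$f_closed[2], 0.99)
})

test_that("closing and opening fits are exact on noise-free model data", {
  t <- c(0, 0.5, 1, 2, 3, 5, 10)
  f <- 0.95 * (1 - exp(-1.0 * t))
  rf <- fit_closing(t, f)
  expect_equal(rf$k, 1.0, tolerance = 1e-6)
  expect_equal(rf$f_asym, 0.95, tolerance = 1e-6)
  expect_lt(max(abs(residuals(rf))), 1e-9)
  fo <- 0.05 + (0.9 - 0.05) * exp(-0.3 * t)
  ro <- fit_opening(t, fo)
  expect_equal(ro$k, 0.3, tolerance = 1e-6)
  expect_equal(ro$f0, 0.9, tolerance = 1e-6)
  expect_equal(ro$f_asym, 0.05, tolerance = 1e-6)
  expect_lt(max(abs(residuals(ro))), 1e-9)
  # degenerate inputs are flagged, not fitted
  expect_warning(rc <- fit_closing(t, rep(0, 7)), "unidentifiable")
  expect_true(is.na(rc$k))
  expect_warning(roc <- fit_opening(t, rep(0.5, 7)), "large uncertainty")
  expect_equal(roc$k, 0)
  expect_warning(fit_closing(t, 0.9 * exp(-t)), "mismatch")
})

test_that("seeded noisy recovery stays within 10 percent", {
  t_slow <- c(0, 2, 5, 10, 20, 40, 60)
  set.seed(4)
  f <- 0.9 * (1 - exp(-0.1 * t_slow)) + rnorm(7, 0, 0.02)
  rf <- fit_closing(t_slow, pmin(pmax(f, 0), 1))
  expect_lt(abs(rf$k - 0.1) / 0.1, 0.1)
  t_open <- c(0, 1, 2, 4, 8, 16, 30)
  set.seed(5)
  fo <- 0.05 + 0.85 * exp(-0.176 * t_open) + rnorm(7, 0, 0.02)
  ro <- fit_opening(t_open, pmin(pmax(fo, 0), 1))
  expect_lt(abs(ro$k - 0.176) / 0.176, 0.1)
})

test_that("end-to-end chromatogram pipeline recovers rates across regimes", {
  for (k in c(0.1, 0.3, 1.0, 2.0)) {
    times <- round(seq(0, 6 / k, length.out = 7), 3)
    s <- generate_chromatogram_series(k = k, times = times, noise_sd = 0.01,
                                      seed = round(1000 * k))
    sf <- fit_bigaussian_series(s)
    rf <- fit_closing(sf$fractions$time_min, sf$fractions$f_closed)
    expect_lt(abs(rf$k - k) / k, 0.1)
  }
})

test_that("gel band fractions and crosslink kinetics behave", {
  tbl <- data.frame(time_min = c(0, 1, 2),
                    dimer_intensity = c(70, 100, 0),
                    monomer_intensity = c(30, 0, 0))
  expect_warning(fr <- gel_band_fractions(tbl), "excluded")
  expect_equal(fr$fraction, c(0.7, 1.0))
  # synthetic lane series: f(t) = 0.8 (1 - exp(-1.6 t))
  g <- generate_gel_table(k = 1.6, times = c(0, 0.25, 0.5, 1, 1.5, 2.5, 4),
                          f_inf = 0.8, seed = 6)
  fr2 <- gel_band_fractions(data.frame(time_min = g$time_min,
                                       dimer_intensity = g$dimer_intensity,
                                       monomer_intensity = g$monomer_intensity))
  rf <- fit_closing(fr2$time_min, fr2$fraction)
  expect_lt(abs(rf$k - 1.6) / 1.6, 0.1)
})

test_that("chromatogram CSV + manifest round-trips", {
  s <- generate_chromatogram_series(k = 1, times = c(0, 1, 3), seed = 11,
                                    condition = "200 mM KCl")
  d <- file.path(tempdir(), "chromsier")
  man <- write_chromatogram_series(s, d)
  back <- read_chromatogram_series(man)
  expect_equal(length(back), 3L)
  expect_equal(back[[2]]$signal, s[[2]]$signal, tolerance = 1e-6)
  expect_equal(back[[2]]$time_min, 1)
  expect_identical(back[[3]]$condition, "200 mM KCl")
  unlink(d, recursive = TRUE)
})
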