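test_that("occupancy density integrates to 1 with exact endpoint masses", {
  # frozen mixture: pure point masses
  m0 <- two_state_model(0.2, 0.9, 0, 0, p1 = 0.4)
  oc0 <- occupancy_density(m0, T = 1)
  expect_equal(oc0$p[length(oc0$p)], 0.4)
  expect_equal(oc0$p[1], 0.6)
  expect_equal(sum(oc0$p), 1)
  expect_identical(sum(oc0$p > 0), 2L)
  # symmetric 1/ms rates over 1 ms: no-switch probability 0.5 e^-1
  m1 <- two_state_model(0.2, 0.9, 1, 1)
  oc1 <- occupancy_density(m1, T = 1)
  expect_equal(oc1$mass1, 0.5 * exp(-1), tolerance = 1e-12)
  expect_equal(oc1$mass0, 0.5 * exp(-1), tolerance = 1e-12)
  expect_equal(sum(oc1$p), 1, tolerance = 1e-12)
  # fast exchange concentrates mass near the equilibrium occupancy; the
  # analytic occupancy variance 2 p1 p2/(lambda T) (1 - (1-e^-lT)/(lT))
  # fixes how fast: sd = 0.070 at k = 50/ms (mass ~0.52 in +/-0.05),
  # dropping to 0.022 at k = 500/ms where the mass exceeds 0.95
  m2 <- two_state_model(0.2, 0.9, 500, 500)
  oc2 <- occupancy_density(m2, T = 1)
  expect_gt(sum(oc2$p[oc2$f >= 0.45 & oc2$f <= 0.55]), 0.95)
  m50 <- two_state_model(0.2, 0.9, 50, 50)
  oc50 <- occupancy_density(m50, T = 1)
  mass50 <- sum(oc50$p[oc50$f >= 0.45 & oc50$f <= 0.55])
  sd_th <- sqrt(2 * 0.25 / 100 * (1 - (1 - exp(-100)) / 100))
  mass_th <- stats::pnorm(0.05 / sd_th) - stats::pnorm(-0.05 / sd_th)
  expect_lt(abs(mass50 - mass_th), 0.05)
  # asymmetric rates on a grid of regimes
  for (k in list(c(0.2, 0.8), c(2, 5), c(10, 1))) {
    m <- two_state_model(0.1, 0.8, k[1], k[2])
    oc <- occupancy_density(m, T = 1)
    expect_equal(sum(oc$p), 1, tolerance = 1e-12)
    expect_equal(oc$mass1, m$p1 * exp(-k[1]), tolerance = 1e-12)
    expect_equal(oc$mass0, m$p2 * exp(-k[2]), tolerance = 1e-12)
  }
})

test_that("occupancy density matches the Monte-Carlo jump-chain oracle", {
  m <- two_state_model(0.2, 0.9, 0.5, 0.5)
  oc <- occupancy_density(m, T = 1)
  set.seed(55)
  f_mc <- ctmc_occupancy_oracle(c(0.5, 0.5), 0.5, T_ms = rep(1, 4000),
                                dt = 2e-3)
  br <- seq(0, 1, by = 0.1)
  # implementation mass per coarse cell (half-open, endpoints to the edges)
  cell <- pmin(findInterval(oc$f, br, rightmost.closed = TRUE), 10)
  h_imp <- as.vector(tapply(oc$p, factor(cell, levels = 1:10), sum))
  h_imp[is.na(h_imp)] <- 0
  cell_mc <- pmin(findInterval(f_mc, br, rightmost.closed = TRUE), 10)
  h_mc <- tabulate(cell_mc, 10) / length(f_mc)
  se <- sqrt(pmax(h_mc * (1 - h_mc), 1e-4) / length(f_mc))
  expect_true(all(abs(h_imp - h_mc) < 4 * se + 0.01))
})

test_that("expected histogram is pure shot noise for a static species", {
  cfg <- pda_config(n_bins_E = 40)
  h <- expected_histogram(0.2, count_dist = rep(50L, 100), cfg = cfg)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  # direct binomial reference
  k <- 0:50
  ref <- tapply(dbinom(k, 50, 0.2), pmin(floor(k / 50 * 40) + 1L, 40), sum)
  want <- numeric(40); want[as.integer(names(ref))] <- ref
  expect_equal(h, want, tolerance = 1e-12)
})

test_that("slow-exchange limit equals the weighted sum of static histograms", {
  cfg <- pda_config()
  cd <- data.frame(N = c(30L, 50L, 80L), w = c(0.3, 0.5, 0.2))
  m <- two_state_model(0.2, 0.9, 1e-7, 1.5e-7)   # p1 = 0.6, essentially frozen
  h_dyn <- expected_histogram(m, count_dist = cd, cfg = cfg)
  h_mix <- m$p1 * expected_histogram(0.2, count_dist = cd, cfg = cfg) +
    m$p2 * expected_histogram(0.9, count_dist = cd, cfg = cfg)
  expect_lt(sum(abs(h_dyn - h_mix)), 1e-5)
})

test_that("dynamic expected histogram matches the bin-level Monte-Carlo oracle", {
  cfg <- pda_config()
  m <- two_state_model(0.2, 0.9, 0.5, 0.5)
  h <- expected_histogram(m, count_dist = rep(50L, 10), cfg = cfg)
  set.seed(99)
  n_mc <- 2e4
  h_mc <- pda_histogram_oracle(0.2, 0.9, 0.5, 0.5, 0.5, 1, N = 50L,
                               n_bins = cfg$n_bins_E, n_mc = n_mc)
  se_l1 <- sum(sqrt(pmax(h, 1e-8) * (1 - pmin(h, 1)) / n_mc))
  expect_lt(sum(abs(h - h_mc)), 3 * se_l1)
})

test_that("fast exchange converges to the static histogram at the mean efficiency", {
  cfg <- pda_config()
  cd <- rep(50L, 10)
  m <- two_state_model(0.2, 0.9, 0.5, 0.5)
  Ebar <- m$p1 * 0.2 + m$p2 * 0.9
  h_stat <- expected_histogram(Ebar, count_dist = cd, cfg = cfg)
  l1 <- vapply(c(2, 20, 200), function(k) {
    hk <- expected_histogram(two_state_model(0.2, 0.9, k, k),
                             count_dist = cd, cfg = cfg)
    sum(abs(hk - h_stat))
  }, numeric(1))
  expect_true(all(diff(l1) < 0))   # monotone approach
  expect_lt(l1[3], 0.08)
})

test_that("binning cuts bursts into full windows and applies the count filter", {
  # hand-built burst: 90 photons over 3.0 ms starting at t = 0
  tms <- (0:89) / 30
  ch <- rep(c("GG", "GG", "GR"), 30)
  st <- make_stream(tms, channel = ch)
  bursts <- data.frame(start = 1L, end = 90L, n_photons = 90L)
  bins <- bin_photon_stream(st, pda_config(bin_duration = 1,
                                           count_range = c(5, 200)),
                            bursts = bursts)
  expect_identical(nrow(bins), 3L)
  expect_true(all(bins$N == 30))
  expect_true(all(bins$N_acc == 10))
  # count filter removes out-of-range windows
  bins2 <- bin_photon_stream(st, pda_config(bin_duration = 1,
                                            count_range = c(40, 200)),
                             bursts = bursts)
  expect_identical(nrow(bins2), 0L)
  # agreement with an independent re-binning on simulated data
  m <- two_state_model(0.2, 0.9, 0.5, 0.5)
  sim <- simulate_photon_stream(m, sim_burst_config(n_bursts = 50, seed = 8))
  fb <- find_bursts(sim)
  got <- bin_photon_stream(sim, pda_config(), bursts = fb)
  t_all <- sim$photons$macrotime * sim$tick_s * 1e3
  for (r in sample(seq_len(nrow(got)), min(10, nrow(got)))) {
    idx <- fb$start[got$burst[r]]:fb$end[got$burst[r]]
    tb <- t_all[idx]; cb <- sim$photons$channel[idx]
    don <- cb %in% c("GG", "GR")
    t0 <- tb[don][1]
    lo <- t0 + (got$bin[r] - 1); hi <- lo + 1
    inbin <- don & tb >= lo & tb < hi
    expect_identical(sum(inbin), got$N[r])
    expect_identical(sum(inbin & cb == "GR"), got$N_acc[r])
  }
})

test_that("PDA fit is a fixed point on noise-free data and flags static data", {
  cfg <- pda_config()
  truth <- two_state_model(0.2, 0.9, 0.5, 0.5)
  cd <- data.frame(N = 50L, w = 1)
  obs <- 1e5 * expected_histogram(truth, count_dist = cd, cfg = cfg)
  fit <- fit_pda_hist(obs, cd, truth, cfg = cfg)
  expect_equal(fit$model$E1, 0.2, tolerance = 1e-6)
  expect_equal(fit$model$E2, 0.9, tolerance = 1e-6)
  expect_equal(fit$model$k12, 0.5, tolerance = 1e-6)
  expect_equal(fit$model$k21, 0.5, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)
  # purely static data: dynamic amplitude collapses
  static_bins <- simulate_pda_bins(two_state_model(0.2, 0.2, 0, 0, p1 = 1),
                                   8000, seed = 17)
  sfit <- suppressWarnings(fit_pda(static_bins,
                                   two_state_model(0.15, 0.5, 0.5, 0.5)))
  expect_lt(sfit$amplitudes[["dynamic"]], 0.05)
})
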