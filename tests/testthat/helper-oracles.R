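# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the slowest, most transparent route available and
# share no code with the package internals they check.

# O(n^2) all-photon neighbourhood scan: for each photon count companions
# within +/- half window, then extract qualifying runs.
brute_force_bursts <- function(times_ms, window_T, min_in_window, min_total) {
  n <- length(times_ms)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  dense <- logical(n)
  for (i in seq_len(n))
    dense[i] <- sum(abs(times_ms - times_ms[i]) <= window_T / 2) >= min_in_window
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    if (dense[i]) {
      j <- i
      while (j < n && dense[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_total) { starts <- c(starts, i); ends <- c(ends, j) }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

# Step-by-step discrete-time realisation of the two-state chain at a fixed
# small dt; returns the fraction of time spent in state 1 for one window per
# entry of T_ms (vectorised over windows, not over steps).
ctmc_occupancy_oracle <- function(rates, p1, T_ms, dt = 5e-3) {
  k12 <- rates[1]; k21 <- rates[2]
  f1 <- numeric(length(T_ms))
  for (i in seq_along(T_ms)) {
    steps <- max(1L, round(T_ms[i] / dt))
    s <- if (stats::runif(1) < p1) 1L else 2L
    in1 <- 0L
    for (m in seq_len(steps)) {
      if (s == 1L) {
        in1 <- in1 + 1L
        if (stats::runif(1) < k12 * dt) s <- 2L
      } else {
        if (stats::runif(1) < k21 * dt) s <- 1L
      }
    }
    f1[i] <- in1 / steps
  }
  f1
}

# Monte-Carlo oracle for the PDA expected histogram: per bin simulate the
# exact jump chain, then a binomial photon split. Independent of the
# package's occupancy recursion (and of sim_occupancy).
pda_histogram_oracle <- function(E1, E2, k12, k21, p1, T_ms, N, n_bins,
                                 n_mc, eps1 = E1, eps2 = E2) {
  counts <- numeric(n_bins)
  for (i in seq_len(n_mc)) {
    s <- if (stats::runif(1) < p1) 1L else 2L
    t <- 0; in1 <- 0
    repeat {
      r <- if (s == 1L) k12 else k21
      jump <- if (r > 0) stats::rexp(1, r) else Inf
      dwell <- min(jump, T_ms - t)
      if (s == 1L) in1 <- in1 + dwell
      t <- t + dwell
      if (t >= T_ms) break
      s <- 3L - s
    }
    f <- in1 / T_ms
    ka <- stats::rbinom(1, N, f * eps1 + (1 - f) * eps2)
    b <- min(floor(ka / N * n_bins) + 1L, n_bins)
    counts[b] <- counts[b] + 1
  }
  counts / n_mc
}

# minimal hand-built photon stream
make_stream <- function(times_ms, channel = NULL, micro = NULL, period = 50) {
  n <- length(times_ms)
  structure(list(photons = data.frame(
    macrotime = round(times_ms * 1e6),
    microtime_ns = if (is.null(micro)) rep(1, n) else micro,
    channel = if (is.null(channel)) rep("GG", n) else channel,
    stringsAsFactors = FALSE),
    tick_s = 1e-9, excitation_period_ns = period,
    duration_s = max(times_ms, 1) / 1e3, truth = NULL, corrections = NULL),
    class = "photon_stream")
}

# trapezoidal area of a chromatogram
trapz_area <- function(v, y) sum(diff(v) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# three-atom PDB fixture writers (plain text, hand-assembled records)
write_pdb_fixture <- function(path, lines) writeLines(lines, path)

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, alt = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, element)
}
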