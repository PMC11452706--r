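#' All-photon sliding-window burst search
#'
#' Identifies single-molecule bursts as maximal runs of photons in which every
#' photon has at least `min_in_window` photons (all channels, itself included)
#' within a centred window of `window_T` ms, keeping only runs with at least
#' `min_total` photons. The defaults (15 photons in 0.5 ms, 60 photons total)
#' are conventional values for diffusion-based multiparameter detection.
#'
#' @param stream A `photon_stream`.
#' @param window_T Window width (ms), `> 0`.
#' @param min_in_window Minimum photons inside the window, `>= 1`.
#' @param min_total Minimum photons per burst, `>= 1`.
#' @return Data frame with one row per burst: `start`, `end` (photon indices,
#'   inclusive) and `n_photons`. Empty streams give zero rows.
#' @export
find_bursts <- function(stream, window_T = 0.5, min_in_window = 15,
                        min_total = 60) {
  stopifnot(inherits(stream, "photon_stream"))
  if (window_T <= 0) stop("'window_T' must be > 0")
  if (min_in_window < 1 || min_total < 1) stop("thresholds must be >= 1")
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_photons = integer(0))
  t <- macrotime_ms(stream)
  np <- length(t)
  if (np == 0L) return(empty)
  half <- window_T / 2
  # photons in [t - half, t + half]; findInterval counts <= boundary
  hi <- findInterval(t + half, t)
  lo <- findInterval(t - half, t, left.open = TRUE)
  dense <- (hi - lo) >= min_in_window
  if (!any(dense)) return(empty)
  r <- rle(dense)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_total
  data.frame(start = starts[keep], end = ends[keep],
             n_photons = r$lengths[keep])
}

#' Maximum-likelihood donor lifetime from burst microtimes
#'
#' Fits a single-exponential decay truncated to the donor excitation window
#' by maximum likelihood. The truncated-exponential MLE solves
#' `mean(x) = tau - W / (exp(W/tau) - 1)`; when the window is much longer
#' than the lifetime this reduces to the sample mean. No instrument response
#' function is modelled.
#'
#' @param microtimes Donor (GG) photon microtimes in ns.
#' @param window Length of the donor excitation window in ns (half the
#'   pulsed-interleaved excitation period).
#' @param min_photons Minimum photons required; below it the lifetime is
#'   unavailable (`NA`).
#' @return Lifetime estimate in ns, or `NA_real_` when unavailable.
#' @export
estimate_donor_lifetime <- function(microtimes, window, min_photons = 20) {
  microtimes <- microtimes[is.finite(microtimes)]
  if (length(microtimes) < min_photons) return(NA_real_)
  m <- mean(microtimes)
  # mean of a truncated exponential is < W/2; at W/2 the decay is flat
  if (m >= window / 2 * (1 - 1e-9)) return(NA_real_)
  g <- function(tau) tau - window / (exp(window / tau) - 1) - m
  # g is increasing in tau; bracket the root
  lo <- m / 2
  hi <- max(window, 10 * m)
  while (g(hi) < 0 && hi < 1e8) hi <- hi * 10
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

#' Per-burst corrected FRET observables from a photon stream
#'
#' Runs the burst search, accumulates per-channel counts for each burst,
#' applies background subtraction and the accurate FRET corrections
#' ([correct_and_score()]), and estimates the donor lifetime in the presence
#' of acceptor from the GG microtimes.
#'
#' @param stream A `photon_stream`.
#' @param corr A [correction_set()].
#' @param window_T,min_in_window,min_total Burst-search parameters, see
#'   [find_bursts()].
#' @param lifetime_min_photons Minimum GG photons for a lifetime estimate.
#' @return Data frame of class `burst_metrics`, one row per burst: raw
#'   channel counts `GG`, `GR`, `RR`, background-subtracted signals, `E`,
#'   `S`, `tauDA` (ns), `duration` (ms), `n_photons` and `flag`.
#' @export
analyze_bursts <- function(stream, corr = correction_set(),
                           window_T = 0.5, min_in_window = 15, min_total = 60,
                           lifetime_min_photons = 20) {
  spans <- find_bursts(stream, window_T, min_in_window, min_total)
  t <- macrotime_ms(stream)
  ch <- stream$photons$channel
  W <- stream$excitation_period_ns / 2
  n <- nrow(spans)
  GG <- GR <- RR <- integer(n)
  dur <- tauDA <- numeric(n)
  for (i in seq_len(n)) {
    idx <- spans$start[i]:spans$end[i]
    cc <- ch[idx]
    GG[i] <- sum(cc == "GG"); GR[i] <- sum(cc == "GR"); RR[i] <- sum(cc == "RR")
    dur[i] <- max(t[spans$end[i]] - t[spans$start[i]], 1e-6)
    tauDA[i] <- estimate_donor_lifetime(
      stream$photons$microtime_ns[idx][cc == "GG"], W, lifetime_min_photons)
  }
  sc <- correct_and_score(data.frame(GG = GG, GR = GR, RR = RR), dur, corr)
  out <- cbind(data.frame(start = spans$start, end = spans$end,
                          GG = GG, GR = GR, RR = RR),
               sc,
               data.frame(tauDA = tauDA, duration = dur,
                          n_photons = spans$n_photons))
  class(out) <- c("burst_metrics", "data.frame")
  out
}

#' Burst histograms with stoichiometry filtering
#'
#' Builds the standard presentation histograms from per-burst metrics: the 1D
#' FRET efficiency histogram and the 2D E-versus-S and E-versus-tau_D(A)
#' histograms. A stoichiometry window (default 0.3-0.7) removes donor-only
#' (S near 1) and acceptor-only (S near 0) species before the FRET
#' histograms; bursts flagged `undefined` are always dropped.
#'
#' @param bursts A `burst_metrics` data frame.
#' @param e_breaks Breaks for the efficiency axis.
#' @param s_breaks Breaks for the stoichiometry axis.
#' @param tau_breaks Breaks for the lifetime axis (ns).
#' @param s_window Stoichiometry filter `c(min, max)`; `NULL` disables it.
#' @return List of class `burst_histograms` with elements `E` (counts,
#'   midpoints), `ES` (matrix), `Etau` (matrix), and `n_retained`.
#' @export
build_histograms <- function(bursts,
                             e_breaks = seq(-0.2, 1.2, by = 0.025),
                             s_breaks = seq(0, 1, by = 0.025),
                             tau_breaks = seq(0, 6, by = 0.1),
                             s_window = c(0.3, 0.7)) {
  if (nrow(bursts) == 0L) {
    warning("no bursts; returning empty histograms")
    return(structure(list(E = list(counts = integer(length(e_breaks) - 1L),
                                   mids = head_mids(e_breaks)),
                          ES = NULL, Etau = NULL, n_retained = 0L),
                     class = "burst_histograms"))
  }
  ok <- bursts$flag != "undefined" & is.finite(bursts$E) & is.finite(bursts$S)
  b <- bursts[ok, , drop = FALSE]
  # E-S histogram is built before the stoichiometry filter (it is the
  # diagnostic used to choose the window)
  ES <- hist2(b$E, b$S, e_breaks, s_breaks)
  if (!is.null(s_window))
    b <- b[b$S >= s_window[1] & b$S <= s_window[2], , drop = FALSE]
  Ecut <- pmin(pmax(b$E, min(e_breaks)), max(e_breaks))
  Eh <- graphics::hist(Ecut, breaks = e_breaks, plot = FALSE)
  bt <- b[is.finite(b$tauDA), , drop = FALSE]
  Etau <- hist2(pmin(pmax(bt$tauDA, min(tau_breaks)), max(tau_breaks)),
                pmin(pmax(bt$E, min(e_breaks)), max(e_breaks)),
                tau_breaks, e_breaks)
  structure(list(E = list(counts = Eh$counts, mids = Eh$mids),
                 ES = ES, Etau = Etau, n_retained = nrow(b)),
            class = "burst_histograms")
}

head_mids <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2

hist2 <- function(x, y, xb, yb) {
  ix <- cut(x, xb, include.lowest = TRUE, labels = FALSE)
  iy <- cut(y, yb, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(ix) & !is.na(iy)
  tab <- table(factor(ix[keep], levels = seq_len(length(xb) - 1L)),
               factor(iy[keep], levels = seq_len(length(yb) - 1L)))
  m <- unclass(tab)
  dimnames(m) <- list(sprintf("%.4g", head_mids(xb)), sprintf("%.4g", head_mids(yb)))
  m
}
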