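#' Configuration for the synthetic burst simulator
#'
#' Describes the measurement emulated by [simulate_photon_stream()]: diffusing
#' dual-labelled dimers traverse the confocal volume and emit bursts of
#' photons while interconverting between FRET states. Burst durations are
#' exponential with mean `burst_duration_mean`; inter-burst gaps are
#' exponential with ten times that mean, so bursts remain separable from the
#' background. The paper-level instrument distortions are applied in the
#' forward direction from `truth_corrections`: crosstalk reassigns detected
#' donor photons to the red channel with probability `beta/(1+beta)`, direct
#' acceptor excitation adds a Poisson stream into GR with rate
#' `alpha * acceptor_photon_rate`, and `gamma` is realised as an unequal
#' red/green detection efficiency. The exact correction set that the accurate
#' FRET formula must use to invert the distortions is stored with the stream.
#'
#' @param n_bursts Number of bursts to generate.
#' @param burst_duration_mean Mean burst duration (ms).
#' @param photon_rate Donor-excitation event rate during a burst
#'   (photons/ms, before detection losses).
#' @param acceptor_photon_rate Detected acceptor-excitation (RR) rate during
#'   a burst (photons/ms).
#' @param background_rates Named vector `c(GG=, GR=, RR=)`, photons/ms,
#'   uniform over the whole acquisition.
#' @param tauD0 Donor-only lifetime (ns).
#' @param acceptor_lifetime Acceptor fluorescence lifetime (ns); acceptor
#'   microtimes are single-exponential with this constant (no IRF anywhere).
#' @param truth_corrections A [correction_set()] applied forward.
#' @param donor_only_fraction,acceptor_only_fraction Proportions of singly
#'   labelled species; their sum must be `<= 1`.
#' @param excitation_period Pulsed-interleaved excitation period (ns); the
#'   donor window is the first half, the acceptor window the second.
#' @param seed Integer seed; a fixed seed makes the stream bit-reproducible.
#' @return Object of class `sim_burst_config`.
#' @export
sim_burst_config <- function(n_bursts = 500,
                             burst_duration_mean = 2,
                             photon_rate = 60,
                             acceptor_photon_rate = 30,
                             background_rates = c(GG = 1, GR = 1, RR = 1),
                             tauD0 = 3.8,
                             acceptor_lifetime = 3.5,
                             truth_corrections = correction_set(),
                             donor_only_fraction = 0,
                             acceptor_only_fraction = 0,
                             excitation_period = 50,
                             seed = 1L) {
  if (photon_rate <= 0) stop("invalid config: 'photon_rate' must be > 0")
  if (excitation_period <= 0) stop("invalid config: 'excitation_period' must be > 0")
  if (n_bursts < 1 || burst_duration_mean <= 0 || acceptor_photon_rate < 0)
    stop("invalid config: counts, durations and rates must be positive")
  bg <- background_rates[c("GG", "GR", "RR")]
  if (any(is.na(bg)) || any(bg < 0)) stop("invalid config: background rates")
  if (donor_only_fraction < 0 || acceptor_only_fraction < 0 ||
      donor_only_fraction + acceptor_only_fraction > 1)
    stop("invalid config: species fractions must be nonnegative and sum to <= 1")
  stopifnot(inherits(truth_corrections, "correction_set"))
  structure(list(n_bursts = as.integer(n_bursts),
                 burst_duration_mean = burst_duration_mean,
                 photon_rate = photon_rate,
                 acceptor_photon_rate = acceptor_photon_rate,
                 background_rates = bg,
                 tauD0 = tauD0,
                 acceptor_lifetime = acceptor_lifetime,
                 truth_corrections = truth_corrections,
                 donor_only_fraction = donor_only_fraction,
                 acceptor_only_fraction = acceptor_only_fraction,
                 excitation_period = excitation_period,
                 seed = as.integer(seed)),
            class = "sim_burst_config")
}

# Exponential with mean tau truncated to [0, W).
rexp_trunc <- function(n, tau, W) {
  if (n == 0L) return(numeric(0))
  -tau * log(1 - stats::runif(n) * (1 - exp(-W / tau)))
}

#' Simulate a time-tagged photon stream of single-molecule FRET bursts
#'
#' Generates a pulsed-interleaved-excitation photon stream: bursts separated
#' by background-only gaps, each burst carrying a hidden continuous-time
#' Markov state path drawn from `model`. Donor-excitation photons split
#' between donor (GG) and acceptor (GR) channels according to the current
#' state's FRET efficiency, distorted forward by the truth corrections;
#' acceptor-excitation photons fill RR. Donor microtimes are exponential with
#' the current state's donor lifetime, acceptor microtimes with the acceptor
#' lifetime, both truncated to the respective half of the excitation period.
#'
#' The per-burst ground truth (species label, state-1 occupancy fraction,
#' transition count, window) is stored in the `truth` element so downstream
#' stages can be tested against it.
#'
#' @param model A [two_state_model()].
#' @param cfg A [sim_burst_config()].
#' @return Object of class `photon_stream`: list with elements `photons`
#'   (data frame `macrotime` in clock ticks, `microtime_ns`, `channel` in
#'   GG/GR/RR), `tick_s` (tick resolution, 1 ns), `excitation_period_ns`,
#'   `duration_s`, `truth` (per-burst data frame), and `corrections` (the
#'   exact [correction_set()] that inverts the applied distortions).
#' @export
simulate_photon_stream <- function(model, cfg = sim_burst_config()) {
  stopifnot(inherits(model, "ctmc_model"), inherits(cfg, "sim_burst_config"))
  set.seed(cfg$seed)
  corr <- cfg$truth_corrections
  ct <- corr$beta / (1 + corr$beta)        # crosstalk fraction of detected donor photons
  gG <- 1
  gR <- corr$gamma * gG * (1 - ct)
  sc <- max(1, gG, gR)                     # keep detection probabilities <= 1
  gG <- gG / sc; gR <- gR / sc

  W <- cfg$excitation_period / 2           # donor / acceptor PIE window (ns)
  taus <- model$taus
  Es <- model$E

  n <- cfg$n_bursts
  durations <- stats::rexp(n, 1 / cfg$burst_duration_mean)
  gaps <- stats::rexp(n, 1 / (10 * cfg$burst_duration_mean))
  starts <- cumsum(gaps + c(0, durations[-n]))
  total_ms <- starts[n] + durations[n] + 10 * cfg$burst_duration_mean

  u <- stats::runif(n)
  species <- ifelse(u < cfg$donor_only_fraction, "donor_only",
             ifelse(u < cfg$donor_only_fraction + cfg$acceptor_only_fraction,
                    "acceptor_only", "dual"))

  ph_t <- vector("list", n); ph_mt <- vector("list", n); ph_ch <- vector("list", n)
  f1 <- rep(NA_real_, n); ntrans <- rep(NA_integer_, n); nphot <- integer(n)

  for (b in seq_len(n)) {
    dur <- durations[b]
    t0 <- starts[b]
    tt <- numeric(0); mt <- numeric(0); chn <- character(0)
    has_donor <- species[b] != "acceptor_only"
    has_acceptor <- species[b] != "donor_only"

    if (has_donor) {
      if (species[b] == "dual") {
        path <- sample_ctmc_path(model, dur)
        f1[b] <- path_occupancy(path, dur)
        ntrans[b] <- length(path$times) - 1L
      } else {
        path <- list(times = 0, states = 1L)   # donor-only: E = 0 regardless of state
      }
      n_em <- stats::rpois(1, cfg$photon_rate * dur)
      if (n_em > 0) {
        te <- sort(stats::runif(n_em, 0, dur))
        st <- path$states[findInterval(te, path$times)]
        Eph <- if (species[b] == "dual") Es[st] else 0
        is_acc <- stats::runif(n_em) < Eph
        # acceptor (FRET) emission: detect with gR in GR
        acc_det <- is_acc & stats::runif(n_em) < gR
        # donor emission: detect with gG, then crosstalk to GR with ct
        don_det <- !is_acc & stats::runif(n_em) < gG
        xtalk <- don_det & stats::runif(n_em) < ct
        keep <- acc_det | don_det
        if (any(keep)) {
          te_k <- te[keep]; st_k <- st[keep]
          ch_k <- ifelse(acc_det[keep], "GR", ifelse(xtalk[keep], "GR", "GG"))
          mt_k <- numeric(sum(keep))
          ia <- acc_det[keep]
          mt_k[ia] <- rexp_trunc(sum(ia), cfg$acceptor_lifetime, W)
          # donor emission decays with the current state's donor lifetime
          # (donor-only species decay with tauD0)
          tl <- if (species[b] == "dual") taus else rep(cfg$tauD0, length(taus))
          for (s in seq_along(tl)) {
            id <- !ia & st_k == s
            if (any(id)) mt_k[id] <- rexp_trunc(sum(id), tl[s], W)
          }
          tt <- c(tt, t0 + te_k); mt <- c(mt, mt_k); chn <- c(chn, ch_k)
        }
      }
    }
    if (has_acceptor) {
      n_rr <- stats::rpois(1, cfg$acceptor_photon_rate * dur)
      if (n_rr > 0) {
        tt <- c(tt, t0 + stats::runif(n_rr, 0, dur))
        mt <- c(mt, W + rexp_trunc(n_rr, cfg$acceptor_lifetime, W))
        chn <- c(chn, rep("RR", n_rr))
      }
      n_de <- stats::rpois(1, corr$alpha * cfg$acceptor_photon_rate * dur)
      if (n_de > 0) {
        tt <- c(tt, t0 + stats::runif(n_de, 0, dur))
        mt <- c(mt, rexp_trunc(n_de, cfg$acceptor_lifetime, W))
        chn <- c(chn, rep("GR", n_de))
      }
    }
    nphot[b] <- length(tt)
    ph_t[[b]] <- tt; ph_mt[[b]] <- mt; ph_ch[[b]] <- chn
  }

  t_all <- unlist(ph_t); mt_all <- unlist(ph_mt); ch_all <- unlist(ph_ch)

  # uniform background over the whole acquisition, per channel
  bg <- cfg$background_rates
  for (chan in c("GG", "GR", "RR")) {
    nb <- stats::rpois(1, bg[[chan]] * total_ms)
    if (nb > 0) {
      t_all <- c(t_all, stats::runif(nb, 0, total_ms))
      off <- if (chan == "RR") W else 0
      mt_all <- c(mt_all, off + stats::runif(nb, 0, W))
      ch_all <- c(ch_all, rep(chan, nb))
    }
  }

  ord <- order(t_all)
  photons <- data.frame(macrotime = round(t_all[ord] * 1e6),  # 1 ns ticks
                        microtime_ns = mt_all[ord],
                        channel = ch_all[ord],
                        stringsAsFactors = FALSE)
  truth <- data.frame(burst = seq_len(n), t_start_ms = starts,
                      duration_ms = durations, species = species,
                      f1 = f1, n_transitions = ntrans, n_photons = nphot,
                      stringsAsFactors = FALSE)
  # the exact correction set that inverts the applied distortions, including
  # the background rates the generator used
  corr_out <- correction_set(alpha = corr$alpha, beta = corr$beta,
                             gamma = corr$gamma, background_rates = bg)
  structure(list(photons = photons, tick_s = 1e-9,
                 excitation_period_ns = cfg$excitation_period,
                 duration_s = total_ms / 1e3,
                 truth = truth, corrections = corr_out),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf("photon stream: %d photons over %.3f s (tick %.3g s)\n",
              nrow(x$photons), x$duration_s, x$tick_s))
  cat("channels:", paste(names(table(x$photons$channel)),
                         table(x$photons$channel), collapse = "  "), "\n")
  if (!is.null(x$truth))
    cat("ground truth available for", nrow(x$truth), "bursts\n")
  invisible(x)
}

# Macrotimes in ms for internal use.
macrotime_ms <- function(stream) stream$photons$macrotime * stream$tick_s * 1e3

#' Write / read a photon stream as a CSV photon list
#'
#' The interchange format is a plain CSV with columns `macrotime` (clock
#' ticks), `microtime_ns` and `channel` (GG/GR/RR), preceded by comment
#' header lines carrying the tick resolution and excitation period.
#'
#' @param stream A `photon_stream`.
#' @param file Path to write/read.
#' @return `read_photon_csv()` returns a `photon_stream` (without ground
#'   truth); `write_photon_csv()` returns `file` invisibly.
#' @export
write_photon_csv <- function(stream, file) {
  stopifnot(inherits(stream, "photon_stream"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tick_s=%.12g", stream$tick_s),
               sprintf("# excitation_period_ns=%.12g", stream$excitation_period_ns),
               sprintf("# duration_s=%.12g", stream$duration_s)), con)
  utils::write.csv(stream$photons, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_photon_csv
#' @export
read_photon_csv <- function(file) {
  hdr <- readLines(file, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key, default) {
    m <- grep(paste0("^# *", key, "="), hdr, value = TRUE)
    if (length(m)) as.numeric(sub(".*=", "", m[1])) else default
  }
  photons <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("macrotime", "microtime_ns", "channel") %in% names(photons)))
    stop("photon CSV needs columns macrotime, microtime_ns, channel")
  if (is.unsorted(photons$macrotime)) stop("macrotimes must be nondecreasing")
  if (!all(photons$channel %in% c("GG", "GR", "RR")))
    stop("invalid channel tags (expected GG, GR, RR)")
  structure(list(photons = photons,
                 tick_s = getv("tick_s", 1e-9),
                 excitation_period_ns = getv("excitation_period_ns", 50),
                 duration_s = getv("duration_s",
                                   max(photons$macrotime) * getv("tick_s", 1e-9)),
                 truth = NULL, corrections = NULL),
            class = "photon_stream")
}
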