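#' Correction factors for accurate FRET efficiencies
#'
#' The three multiplicative corrections of the accurate-FRET formula together
#' with per-channel background rates:
#' \describe{
#'   \item{alpha}{direct acceptor excitation by the donor laser, applied to the
#'     acceptor-excitation signal `F_RR`;}
#'   \item{beta}{donor emission crosstalk into the red detection channel,
#'     applied to `F_GG`;}
#'   \item{gamma}{ratio of acceptor to donor detection efficiency times quantum
#'     yield, applied to `F_GG` in the denominator.}
#' }
#' Background rates are in photons/ms for the three channel tags GG (donor
#' emission after donor excitation), GR (acceptor emission after donor
#' excitation) and RR (acceptor emission after acceptor excitation).
#'
#' @param alpha Direct-excitation factor, `>= 0`.
#' @param beta Crosstalk factor, `>= 0`.
#' @param gamma Detection-efficiency ratio, `> 0`.
#' @param background_rates Named numeric vector `c(GG=, GR=, RR=)` in
#'   photons/ms.
#' @return An object of class `correction_set`.
#' @export
correction_set <- function(alpha = 0, beta = 0, gamma = 1,
                           background_rates = c(GG = 0, GR = 0, RR = 0)) {
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be >= 0")
  if (gamma <= 0) stop("'gamma' must be > 0")
  bg <- background_rates[c("GG", "GR", "RR")]
  if (any(is.na(bg)) || any(bg < 0))
    stop("'background_rates' must be a named nonnegative vector with entries GG, GR, RR")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 background_rates = bg),
            class = "correction_set")
}

#' @export
print.correction_set <- function(x, ...) {
  cat(sprintf("correction set: alpha = %.4g, beta = %.4g, gamma = %.4g\n",
              x$alpha, x$beta, x$gamma))
  cat("background (photons/ms): GG =", x$background_rates[["GG"]],
      " GR =", x$background_rates[["GR"]],
      " RR =", x$background_rates[["RR"]], "\n")
  invisible(x)
}

#' Corrected per-burst FRET efficiency and stoichiometry
#'
#' Applies background subtraction and the accurate-FRET correction to raw
#' per-burst channel counts. With background-subtracted signals `F_GG`,
#' `F_GR`, `F_RR`:
#' \deqn{E = (F_GR - alpha F_RR - beta F_GG) /
#'           (F_GR - alpha F_RR - beta F_GG + gamma F_GG)}
#' and the PIE stoichiometry
#' \deqn{S = (gamma F_GG + F_GR - alpha F_RR - beta F_GG) /
#'           (gamma F_GG + F_GR - alpha F_RR - beta F_GG + F_RR).}
#' Photon-starved bursts can give E outside `[0, 1]`; such values are returned
#' as computed and flagged rather than clipped, so that histograms retain
#' their shot-noise wings. A vanishing denominator flags the burst as
#' undefined (E = NA).
#'
#' @param counts Data frame or matrix with columns/elements `GG`, `GR`, `RR`
#'   of raw photon counts (one row per burst), or a single named vector.
#' @param duration Burst duration(s) in ms (recycled), used for background
#'   subtraction.
#' @param corr A [correction_set()].
#' @return A data frame of class `burst_scores` with columns `F_GG`, `F_GR`,
#'   `F_RR`, `E`, `S`, `flag` (one of `"ok"`, `"out_of_range"`,
#'   `"undefined"`).
#' @export
correct_and_score <- function(counts, duration, corr = correction_set()) {
  stopifnot(inherits(corr, "correction_set"))
  if (is.null(dim(counts))) counts <- as.data.frame(as.list(counts))
  counts <- as.data.frame(counts)
  if (!all(c("GG", "GR", "RR") %in% names(counts)))
    stop("'counts' needs columns GG, GR, RR")
  if (any(duration <= 0)) stop("'duration' must be > 0 (ms)")
  bg <- corr$background_rates
  F_GG <- counts$GG - bg[["GG"]] * duration
  F_GR <- counts$GR - bg[["GR"]] * duration
  F_RR <- counts$RR - bg[["RR"]] * duration
  num <- F_GR - corr$alpha * F_RR - corr$beta * F_GG
  denE <- num + corr$gamma * F_GG
  denS <- denE + F_RR
  E <- ifelse(abs(denE) < .Machine$double.eps^0.5, NA_real_, num / denE)
  S <- ifelse(abs(denS) < .Machine$double.eps^0.5, NA_real_,
              (corr$gamma * F_GG + num) / denS)
  flag <- rep("ok", length(E))
  flag[!is.na(E) & (E < 0 | E > 1)] <- "out_of_range"
  flag[is.na(E)] <- "undefined"
  out <- data.frame(F_GG = F_GG, F_GR = F_GR, F_RR = F_RR,
                    E = E, S = S, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("burst_scores", "data.frame")
  out
}

#' Apparent acceptor fraction implied by a corrected FRET efficiency
#'
#' Maps a fully corrected efficiency E to the expected uncorrected proximity
#' ratio (acceptor fraction of donor-excitation photons) under a given
#' correction set; this is the success probability of the binomial photon
#' partition used by photon distribution analysis. Inverse of the accurate
#' FRET formula restricted to the donor-excitation channels (direct acceptor
#' excitation and background are not part of this mapping).
#'
#' @param E Corrected FRET efficiency (vectorised).
#' @param corr A [correction_set()].
#' @return Apparent proximity ratio(s) in `[0, 1]`.
#' @export
apparent_ratio <- function(E, corr = correction_set()) {
  stopifnot(inherits(corr, "correction_set"))
  num <- corr$gamma * E + corr$beta * (1 - E)
  num / (num + (1 - E))
}
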