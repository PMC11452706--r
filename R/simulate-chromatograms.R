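#' Generate a synthetic SEC chromatogram time series with known kinetics
#'
#' Emulates elution profiles recorded at successive incubation times while
#' the closed-state population follows first-order kinetics. Each profile is
#' the sum of two Gaussian peaks (open and closed state); the closed-peak
#' area fraction evolves as `f(t) = f_inf * (1 - exp(-k t))` for closing or
#' `f(t) = f_eq + (f0 - f_eq) * exp(-k t)` for opening. The total area is
#' constant across time points before noise; additive Gaussian noise is
#' scaled to the maximum noise-free signal of the series.
#'
#' @param k Rate constant (1/min).
#' @param times Time points (min), nonnegative.
#' @param f_inf Plateau closed fraction (closing direction).
#' @param f0,f_eq Initial and equilibrium closed fractions (opening
#'   direction).
#' @param direction `"closing"` or `"opening"`.
#' @param centers Peak centers `c(open, closed)` in mL; must be distinct.
#' @param sigmas Peak widths `c(open, closed)` in mL.
#' @param total_area Constant total peak area.
#' @param noise_sd Noise standard deviation as a fraction of the maximum
#'   noise-free amplitude in the series (0 for none).
#' @param volume_step Elution-volume grid step (mL).
#' @param condition Condition label attached to every profile.
#' @param seed Integer seed for the noise.
#' @return List of [chromatogram()] objects (class `chromatogram_series`)
#'   with the generating parameters in attribute `truth`.
#' @export
generate_chromatogram_series <- function(k, times,
                                         f_inf = 0.95, f0 = 0.9, f_eq = 0.05,
                                         direction = c("closing", "opening"),
                                         centers = c(10.4, 11.0),
                                         sigmas = c(0.25, 0.25),
                                         total_area = 1,
                                         noise_sd = 0.01,
                                         volume_step = 0.01,
                                         condition = "",
                                         seed = 1L) {
  direction <- match.arg(direction)
  if (centers[1] == centers[2])
    stop("degenerate config: peak centers must be distinct")
  if (any(times < 0)) stop("times must be nonnegative")
  if (any(sigmas <= 0)) stop("sigmas must be > 0")
  set.seed(seed)
  f_t <- closed_fraction_law(times, k, direction, f_inf, f0, f_eq)
  v <- seq(min(centers) - 5 * max(sigmas), max(centers) + 5 * max(sigmas),
           by = volume_step)
  clean <- lapply(f_t, function(f)
    gauss_peak(v, centers[1], sigmas[1], total_area * (1 - f)) +
      gauss_peak(v, centers[2], sigmas[2], total_area * f))
  sd_abs <- noise_sd * max(vapply(clean, max, numeric(1)))
  out <- lapply(seq_along(times), function(i) {
    sig <- clean[[i]] + if (sd_abs > 0) stats::rnorm(length(v), 0, sd_abs) else 0
    chromatogram(v, sig, time_min = times[i], condition = condition)
  })
  attr(out, "truth") <- list(k = k, direction = direction, f = f_t,
                             centers = centers, sigmas = sigmas,
                             total_area = total_area, noise_sd = noise_sd)
  class(out) <- c("chromatogram_series", "list")
  out
}

closed_fraction_law <- function(times, k, direction, f_inf, f0, f_eq) {
  if (direction == "closing") f_inf * (1 - exp(-k * times))
  else f_eq + (f0 - f_eq) * exp(-k * times)
}

#' Write / read a chromatogram series as CSV files plus a manifest
#'
#' One CSV per time point (columns `volume_mL`, `signal`) and a manifest CSV
#' (columns `file`, `time_min`, `condition`).
#'
#' @param series A `chromatogram_series` (or list of [chromatogram()]s).
#' @param dir Output directory (created if needed).
#' @param manifest Path of a manifest CSV to read.
#' @return `write_chromatogram_series()` returns the manifest path;
#'   `read_chromatogram_series()` returns a `chromatogram_series`.
#' @export
write_chromatogram_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("chromatogram_%03d.csv", seq_along(series))
  for (i in seq_along(series)) {
    utils::write.csv(data.frame(volume_mL = series[[i]]$volume_mL,
                                signal = series[[i]]$signal),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  man <- data.frame(file = files,
                    time_min = vapply(series, function(x) x$time_min, numeric(1)),
                    condition = vapply(series, function(x) x$condition, character(1)))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mpath, row.names = FALSE)
  mpath
}

#' @rdname write_chromatogram_series
#' @export
read_chromatogram_series <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  out <- lapply(seq_len(nrow(man)), function(i) {
    d <- utils::read.csv(file.path(dir, man$file[i]))
    chromatogram(d$volume_mL, d$signal, time_min = man$time_min[i],
                 condition = if ("condition" %in% names(man)) man$condition[i] else "")
  })
  class(out) <- c("chromatogram_series", "list")
  out
}

#' Generate a synthetic crosslinking gel densitometry table
#'
#' Band intensities for a dimer/monomer ladder whose crosslinked-dimer
#' fraction follows the first-order closing law, with multiplicative
#' intensity noise.
#'
#' @param k Closing rate (1/min).
#' @param times Time points (min).
#' @param f_inf Plateau crosslinked fraction.
#' @param f0 Crosslinked fraction at time zero (baseline closed state).
#' @param total Total lane intensity.
#' @param noise_sd Relative intensity noise.
#' @param seed Integer seed.
#' @return Data frame with `time_min`, `dimer_intensity`,
#'   `monomer_intensity` and ground-truth attribute `truth`.
#' @export
generate_gel_table <- function(k, times, f_inf = 0.8, f0 = 0,
                               total = 1000, noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  f <- f0 + (f_inf - f0) * (1 - exp(-k * times))
  dimer <- total * f * (1 + stats::rnorm(length(times), 0, noise_sd))
  mono <- total * (1 - f) * (1 + stats::rnorm(length(times), 0, noise_sd))
  out <- data.frame(time_min = times,
                    dimer_intensity = pmax(dimer, 0),
                    monomer_intensity = pmax(mono, 0))
  attr(out, "truth") <- list(k = k, f_inf = f_inf, f0 = f0, f = f)
  out
}
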