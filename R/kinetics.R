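#' Chromatogram container
#'
#' @param volume_mL Strictly increasing elution-volume grid (mL).
#' @param signal Detector signal (arbitrary units), finite.
#' @param time_min Incubation time point (minutes since nucleotide addition).
#' @param condition Free-text condition label.
#' @return Object of class `chromatogram`.
#' @export
chromatogram <- function(volume_mL, signal, time_min = NA_real_,
                         condition = "") {
  if (any(diff(volume_mL) <= 0)) stop("'volume_mL' must be strictly increasing")
  if (any(!is.finite(signal))) stop("'signal' must be finite")
  if (length(volume_mL) != length(signal)) stop("length mismatch")
  structure(list(volume_mL = volume_mL, signal = signal,
                 time_min = time_min, condition = condition),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram: %d points, %.2f-%.2f mL, t = %s min%s\n",
              length(x$volume_mL), min(x$volume_mL), max(x$volume_mL),
              format(x$time_min),
              if (nzchar(x$condition)) paste0(" (", x$condition, ")") else ""))
  invisible(x)
}

gauss_peak <- function(v, center, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-(v - center)^2 / (2 * sigma^2))
}

# deterministic two-peak initialisation from a smoothed profile
init_two_peaks <- function(volume, signal) {
  k <- min(7L, max(3L, (length(signal) %/% 10) * 2 + 1))
  s <- stats::filter(signal, rep(1 / k, k), sides = 2)
  s[is.na(s)] <- signal[is.na(s)]
  s <- as.numeric(s)
  d <- diff(sign(diff(s)))
  pk <- which(d == -2) + 1L
  if (length(pk) == 0L) pk <- which.max(s)
  pk <- pk[order(s[pk], decreasing = TRUE)]
  span <- diff(range(volume))
  if (length(pk) == 1L) {
    c1 <- volume[pk[1]]
    c2 <- c1 + span / 6 * if (c1 < mean(range(volume))) 1 else -1
  } else {
    c1 <- volume[pk[1]]; c2 <- volume[pk[2]]
  }
  # sigma from FWHM of the dominant peak
  half <- s[pk[1]] / 2
  above <- which(s >= half)
  fwhm <- if (length(above) > 1) volume[max(above)] - volume[min(above)] else span / 10
  sig <- max(fwhm / 2.355 / if (length(pk) == 1L) 1 else 2, span / 200)
  list(centers = sort(c(c1, c2)), sigma = sig,
       amp = max(signal) * sig * sqrt(2 * pi))
}

#' Bi-Gaussian deconvolution of an elution profile
#'
#' Fits the chromatogram with a sum of two Gaussian peaks, one per
#' conformational state, by Levenberg-Marquardt least squares. Population
#' fractions come from the analytic component areas. By default the closed
#' (more compact) state is taken to elute later (larger volume); set
#' `closed = "earlier"` to flip the assignment.
#'
#' @param chrom A [chromatogram()] (or anything with `volume_mL` and
#'   `signal`).
#' @param init Optional numeric vector of two initial peak centers (mL);
#'   otherwise initialised from the two largest local maxima of the smoothed
#'   profile.
#' @param closed Which peak is the closed state: `"later"` or `"earlier"`.
#' @return Object of class `bigauss_fit` with peak parameters (centers,
#'   sigmas, areas), `f_closed` (closed area / total area), residual norm
#'   and convergence flag.
#' @export
fit_bigaussian <- function(chrom, init = NULL, closed = c("later", "earlier")) {
  closed <- match.arg(closed)
  v <- chrom$volume_mL; y <- chrom$signal
  if (length(v) < 20) stop("need at least 20 data points")
  ini <- init_two_peaks(v, y)
  centers <- if (!is.null(init)) sort(init) else ini$centers
  par0 <- c(c1 = centers[1], c2 = centers[2],
            s1 = ini$sigma, s2 = ini$sigma,
            a1 = ini$amp / 2, a2 = ini$amp / 2)
  model <- function(p, v) gauss_peak(v, p[1], p[3], p[5]) + gauss_peak(v, p[2], p[4], p[6])
  res <- function(p) y - model(p, v)
  span <- diff(range(v))
  fit <- minpack.lm::nls.lm(par0, fn = res,
                            lower = c(min(v) - span, min(v) - span,
                                      span / 1000, span / 1000, 0, 0),
                            upper = c(max(v) + span, max(v) + span,
                                      span, span, Inf, Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- unname(fit$par)
  # order peaks by center
  if (p[1] > p[2]) p <- p[c(2, 1, 4, 3, 6, 5)]
  areas <- c(p[5], p[6])
  closed_idx <- if (closed == "later") 2L else 1L
  f_closed <- if (sum(areas) > 0) areas[closed_idx] / sum(areas) else NA_real_
  structure(list(centers = c(p[1], p[2]), sigmas = c(p[3], p[4]),
                 areas = areas, closed_peak = closed_idx,
                 f_closed = f_closed,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = fit$info %in% 1:4,
                 time_min = chrom$time_min,
                 volume_mL = v, signal = y,
                 fitted_signal = model(p, v)),
            class = "bigauss_fit")
}

#' @export
print.bigauss_fit <- function(x, ...) {
  st <- rep("open", 2); st[x$closed_peak] <- "closed"
  cat("bi-Gaussian deconvolution\n")
  for (i in 1:2)
    cat(sprintf("  peak %d (%s): center %.3f mL, sigma %.3f mL, area %.4g\n",
                i, st[i], x$centers[i], x$sigmas[i], x$areas[i]))
  cat(sprintf("  closed fraction f = %.4f, residual norm %.3g%s\n",
              x$f_closed, x$residual_norm,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' @export
fitted.bigauss_fit <- function(object, ...) object$fitted_signal

#' @export
residuals.bigauss_fit <- function(object, ...) object$signal - object$fitted_signal

#' Global bi-Gaussian deconvolution of a chromatogram time series
#'
#' Joint fit of several elution profiles with peak centers and widths shared
#' across time points and per-time-point amplitudes free. Sharing the peak
#' shapes stabilises the decomposition at early and late times where one
#' population nearly vanishes.
#'
#' @param series List of [chromatogram()] objects (at least 3).
#' @param init Optional two initial centers (mL).
#' @param closed As in [fit_bigaussian()].
#' @return Object of class `bigauss_series`: shared `centers`/`sigmas`, and a
#'   data frame `fractions` with `time_min` and `f_closed` per profile.
#' @export
fit_bigaussian_series <- function(series, init = NULL,
                                  closed = c("later", "earlier")) {
  closed <- match.arg(closed)
  if (length(series) < 3) stop("need at least 3 time points")
  nt <- length(series)
  # initialise shared shapes from the profile with the strongest bimodality
  inis <- lapply(series, function(ch) init_two_peaks(ch$volume_mL, ch$signal))
  cen_all <- t(vapply(inis, function(i) i$centers, numeric(2)))
  centers <- if (!is.null(init)) sort(init)
             else c(stats::median(cen_all[, 1]), stats::median(cen_all[, 2]))
  sig0 <- stats::median(vapply(inis, function(i) i$sigma, numeric(1)))
  amp0 <- vapply(inis, function(i) i$amp / 2, numeric(1))
  par0 <- c(centers[1], centers[2], sig0, sig0, rep(amp0, each = 2))
  v_all <- lapply(series, function(ch) ch$volume_mL)
  y_all <- lapply(series, function(ch) ch$signal)
  res <- function(p) {
    unlist(lapply(seq_len(nt), function(i) {
      a <- p[4 + 2 * i - 1]; b <- p[4 + 2 * i]
      y_all[[i]] - gauss_peak(v_all[[i]], p[1], p[3], a) -
        gauss_peak(v_all[[i]], p[2], p[4], b)
    }))
  }
  span <- max(vapply(v_all, max, 1)) - min(vapply(v_all, min, 1))
  lower <- c(rep(min(vapply(v_all, min, 1)) - span, 2),
             rep(span / 1000, 2), rep(0, 2 * nt))
  fit <- minpack.lm::nls.lm(par0, fn = res, lower = lower,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  p <- fit$par
  swap <- p[1] > p[2]
  cen <- if (swap) c(p[2], p[1]) else c(p[1], p[2])
  sig <- if (swap) c(p[4], p[3]) else c(p[3], p[4])
  closed_idx <- if (closed == "later") 2L else 1L
  fr <- vapply(seq_len(nt), function(i) {
    a <- p[4 + 2 * i - 1]; b <- p[4 + 2 * i]
    ar <- if (swap) c(b, a) else c(a, b)
    if (sum(ar) > 0) ar[closed_idx] / sum(ar) else NA_real_
  }, numeric(1))
  structure(list(centers = cen, sigmas = sig, closed_peak = closed_idx,
                 fractions = data.frame(
                   time_min = vapply(series, function(ch) ch$time_min, numeric(1)),
                   f_closed = fr),
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = fit$info %in% 1:4),
            class = "bigauss_series")
}

#' @export
print.bigauss_series <- function(x, ...) {
  cat(sprintf("global bi-Gaussian series fit: centers %.3f / %.3f mL, sigmas %.3f / %.3f mL\n",
              x$centers[1], x$centers[2], x$sigmas[1], x$sigmas[2]))
  print(x$fractions, row.names = FALSE)
  invisible(x)
}

new_rate_fit <- function(k, se, f0, f_asym, direction, times, f, fitted,
                         flags = character(0)) {
  structure(list(k = k, se = se, f0 = f0, f_asym = f_asym,
                 direction = direction, times = times, f = f,
                 fitted = fitted, flags = flags),
            class = "rate_fit")
}

#' First-order closing kinetics
#'
#' Fits the closed-population time series with the single-exponential
#' approach to plateau `f(t) = f_inf * (1 - exp(-k t))`, the first-order law
#' behind quoted closing rate constants.
#'
#' @param times Incubation times (min), at least 4 points.
#' @param f Closed fractions in `[0, 1]`.
#' @return Object of class `rate_fit` with `k` (1/min), its standard error,
#'   and `f_asym` (the plateau `f_inf`).
#' @export
fit_closing <- function(times, f) {
  check_rate_input(times, f)
  if (stats::sd(f) < 1e-8) {
    warning("constant fractions: rate unidentifiable")
    return(new_rate_fit(NA_real_, NA_real_, 0, mean(f), "closing",
                        times, f, rep(mean(f), length(f)),
                        flags = "unidentifiable"))
  }
  flags <- character(0)
  if (all(diff(f[order(times)]) <= 0)) {
    warning("fractions decrease with time: closing model mismatch")
    flags <- "model-mismatch"
  }
  k0 <- init_rate(times, f, mode = "closing")
  dat <- data.frame(t = times, f = f)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ finf * (1 - exp(-k * t)), data = dat,
                      start = list(finf = max(max(f), 1e-3), k = k0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new_rate_fit(NA_real_, NA_real_, 0, NA_real_, "closing",
                        times, f, rep(NA_real_, length(f)),
                        flags = c(flags, "fit-failed")))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  new_rate_fit(unname(cf["k"]), se, 0, unname(cf["finf"]), "closing",
               times, f, stats::fitted(fit), flags)
}

#' First-order opening kinetics
#'
#' Fits the loss of the closed population with
#' `f(t) = f_eq + (f0 - f_eq) * exp(-k t)`. The equilibrium level `f_eq` is a
#' free parameter by default (nucleotide exchange can leave a closed
#' fraction); fix it with `fix_feq` (e.g. 0).
#'
#' @param times Incubation times (min), at least 4 points.
#' @param f Closed fractions, overall decreasing.
#' @param fix_feq Optional fixed equilibrium closed fraction.
#' @return Object of class `rate_fit` with `k` (1/min), `f0`, and `f_asym`
#'   (the equilibrium level).
#' @export
fit_opening <- function(times, f, fix_feq = NULL) {
  check_rate_input(times, f)
  if (stats::sd(f) < 1e-8) {
    warning("constant fractions: rate ~ 0 with large uncertainty")
    return(new_rate_fit(0, Inf, mean(f), mean(f), "opening",
                        times, f, rep(mean(f), length(f)),
                        flags = "unidentifiable"))
  }
  flags <- character(0)
  if (all(diff(f[order(times)]) >= 0)) {
    warning("fractions increase with time: opening model mismatch")
    flags <- "model-mismatch"
  }
  k0 <- init_rate(times, f, mode = "opening")
  dat <- data.frame(t = times, f = f)
  fit <- tryCatch({
    if (is.null(fix_feq))
      minpack.lm::nlsLM(f ~ feq + (f0 - feq) * exp(-k * t), data = dat,
                        start = list(feq = max(min(f), 0),
                                     f0 = max(f), k = k0),
                        lower = c(0, 0, 0), upper = c(1, 1, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(f ~ fix_feq + (f0 - fix_feq) * exp(-k * t),
                        data = dat,
                        start = list(f0 = max(f), k = k0),
                        lower = c(0, 0), upper = c(1, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit))
    return(new_rate_fit(NA_real_, NA_real_, NA_real_, NA_real_, "opening",
                        times, f, rep(NA_real_, length(f)),
                        flags = c(flags, "fit-failed")))
  cf <- stats::coef(fit)
  feq <- if (is.null(fix_feq)) unname(cf["feq"]) else fix_feq
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  new_rate_fit(unname(cf["k"]), se, unname(cf["f0"]), feq, "opening",
               times, f, stats::fitted(fit), flags)
}

check_rate_input <- function(times, f) {
  if (length(times) != length(f)) stop("length mismatch")
  if (length(times) < 4) stop("need at least 4 time points")
  if (any(times < 0)) stop("times must be nonnegative")
  if (any(!is.finite(f)) || any(f < -0.1) || any(f > 1.1))
    stop("fractions must be finite and lie in [0, 1] (small noise excursions allowed)")
}

# crude rate guess from the time over which the amplitude moves 63% of its range
init_rate <- function(times, f, mode) {
  o <- order(times)
  t <- times[o]; ff <- f[o]
  target <- if (mode == "closing") min(ff) + 0.63 * (max(ff) - min(ff))
            else max(ff) - 0.63 * (max(ff) - min(ff))
  idx <- if (mode == "closing") which(ff >= target) else which(ff <= target)
  t63 <- if (length(idx)) t[idx[1]] else t[length(t)]
  if (t63 <= 0) t63 <- t[t > 0][1]
  1 / max(t63, .Machine$double.eps)
}

#' @export
print.rate_fit <- function(x, ...) {
  lab <- if (x$direction == "closing") "k_closing" else "k_opening"
  cat(sprintf("first-order %s kinetics: %s = %.4g /min (se %.2g)\n",
              x$direction, lab, x$k, x$se))
  if (x$direction == "closing")
    cat(sprintf("  plateau f_inf = %.4f\n", x$f_asym))
  else
    cat(sprintf("  f0 = %.4f, equilibrium f_eq = %.4f\n", x$f0, x$f_asym))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(k = object$k, f0 = object$f0, f_asym = object$f_asym)
}

#' @export
predict.rate_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  if (object$direction == "closing")
    object$f_asym * (1 - exp(-object$k * times))
  else
    object$f_asym + (object$f0 - object$f_asym) * exp(-object$k * times)
}

#' @export
residuals.rate_fit <- function(object, ...) object$f - object$fitted

#' @export
summary.rate_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual sd: %.3g over %d points\n",
              stats::sd(residuals(object)), length(object$times)))
  invisible(object)
}

#' @export
plot.rate_fit <- function(x, ...) {
  graphics::plot(x$times, x$f, xlab = "time (min)", ylab = "closed fraction",
                 ...)
  tg <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::lines(tg, predict(x, tg), col = "red")
  invisible(x)
}

#' Crosslinked dimer fractions from gel densitometry
#'
#' Converts band-intensity tables from time-resolved crosslinking gels into a
#' dimer-fraction time series: `fraction = dimer / (dimer + monomer)` per
#' lane. Optional molecular-weight weighting divides each intensity by the
#' species mass before forming the ratio. Lanes with zero total intensity
#' are excluded with a warning. The resulting series feeds [fit_closing()].
#'
#' @param tbl Data frame with columns `time_min`, `dimer_intensity`,
#'   `monomer_intensity`.
#' @param mw_weights Optional `c(dimer =, monomer =)` molecular weights.
#' @return Data frame with `time_min` and `fraction`.
#' @export
gel_band_fractions <- function(tbl, mw_weights = NULL) {
  need <- c("time_min", "dimer_intensity", "monomer_intensity")
  if (!all(need %in% names(tbl))) stop("table needs columns ", paste(need, collapse = ", "))
  d <- tbl$dimer_intensity; m <- tbl$monomer_intensity
  if (any(d < 0) || any(m < 0)) stop("intensities must be >= 0")
  if (!is.null(mw_weights)) {
    d <- d / mw_weights[["dimer"]]
    m <- m / mw_weights[["monomer"]]
  }
  tot <- d + m
  zero <- tot <= 0
  if (any(zero)) warning(sum(zero), " all-zero lane(s) excluded")
  data.frame(time_min = tbl$time_min[!zero], fraction = (d / tot)[!zero])
}
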