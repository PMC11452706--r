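#' Configuration for photon distribution analysis
#'
#' @param bin_duration Duration of the fixed time bins cut from bursts (ms).
#' @param count_range Photon-count window `c(min, max)`; bins outside it are
#'   discarded.
#' @param n_bins_E Number of histogram bins over the proximity ratio `[0, 1]`.
#' @param occupancy_grid Number of discretisation points for the fraction of
#'   bin time spent in state 1 (at least 51).
#' @return Object of class `pda_config`.
#' @export
pda_config <- function(bin_duration = 1, count_range = c(20, 120),
                       n_bins_E = 40, occupancy_grid = 101) {
  if (bin_duration <= 0) stop("'bin_duration' must be > 0")
  if (occupancy_grid < 51) stop("'occupancy_grid' must be >= 51")
  if (length(count_range) != 2L || count_range[1] < 1 ||
      count_range[2] < count_range[1])
    stop("'count_range' must be c(min, max) with 1 <= min <= max")
  structure(list(bin_duration = bin_duration,
                 count_range = as.integer(count_range),
                 n_bins_E = as.integer(n_bins_E),
                 occupancy_grid = as.integer(occupancy_grid)),
            class = "pda_config")
}

#' Distribution of the time fraction spent in state 1 within a bin
#'
#' For a stationary two-state Markov interconversion observed over a window
#' of `T` ms, computes the discrete density of `f1`, the fraction of the
#' window spent in state 1. The endpoint point-masses are the exact
#' no-transition probabilities `p1 * exp(-k12 T)` at `f1 = 1` and
#' `p2 * exp(-k21 T)` at `f1 = 0`. The continuous interior is obtained from a
#' discrete-time survival-probability recursion whose step count grows with
#' `max(k12, k21) * T`, aggregated onto the requested grid and normalised so
#' the total mass is exactly 1.
#'
#' @param model A [two_state_model()].
#' @param T Window duration (ms), `> 0`.
#' @param grid Number of grid points over `[0, 1]` (endpoints included).
#' @return List with `f` (grid), `p` (masses summing to 1), and the exact
#'   endpoint masses `mass0`, `mass1`.
#' @export
occupancy_density <- function(model, T, grid = 101) {
  stopifnot(inherits(model, "two_state_model"))
  if (T <= 0) stop("'T' must be > 0")
  grid <- as.integer(grid)
  f <- seq(0, 1, length.out = grid)
  p <- numeric(grid)
  mass1 <- model$p1 * exp(-model$k12 * T)
  mass0 <- model$p2 * exp(-model$k21 * T)
  if (model$k12 + model$k21 <= 0) {
    # frozen mixture: pure point masses
    p[1] <- model$p2; p[grid] <- model$p1
    return(list(f = f, p = p, mass0 = model$p2, mass1 = model$p1))
  }
  kmax <- max(model$k12, model$k21)
  M <- max(grid - 1L, min(6000L, ceiling(30 * kmax * T)))
  dt <- T / M
  a <- exp(-model$k12 * dt)   # per-step survival in state 1
  b <- exp(-model$k21 * dt)
  # v1[j+1], v2[j+1]: prob of being in state 1/2 having spent j steps in 1
  v1 <- v2 <- numeric(M + 1L)
  v1[1] <- model$p1; v2[1] <- model$p2
  for (m in seq_len(M)) {
    v1 <- c(0, v1[-(M + 1L)])          # occupy one step in state 1
    if (m < M) {                        # transitions between steps
      nv1 <- a * v1 + (1 - b) * v2
      v2 <- (1 - a) * v1 + b * v2
      v1 <- nv1
    }
  }
  d <- v1 + v2
  # exact endpoints, interior rescaled to conserve total mass
  interior <- d[2:M]
  target <- 1 - mass0 - mass1
  if (sum(interior) > 0) interior <- interior * (target / sum(interior))
  d[1] <- mass0; d[M + 1L] <- mass1; d[2:M] <- interior
  if (M == grid - 1L) {
    p <- d
  } else {
    idx <- round((0:M) / M * (grid - 1L)) + 1L
    p <- as.vector(rowsum(d, idx, reorder = TRUE))
    # rowsum drops empty grid cells; rebuild full vector
    p_full <- numeric(grid)
    p_full[sort(unique(idx))] <- p
    p <- p_full
  }
  list(f = f, p = p, mass0 = mass0, mass1 = mass1)
}

#' Shot-noise-limited proximity ratio histogram expected under a model
#'
#' Core forward calculation of photon distribution analysis. For each bin
#' photon count `N`, the acceptor count is binomial with success probability
#' equal to the apparent proximity ratio at the bin's state-1 occupancy
#' fraction, mixed over the occupancy distribution ([occupancy_density()]);
#' the final histogram is the mixture over the supplied photon-count
#' distribution. A static species (single efficiency) is the pure shot-noise
#' limit. Corrections enter through [apparent_ratio()].
#'
#' @param model A [two_state_model()] for a dynamic species, or a single
#'   numeric FRET efficiency for a static one.
#' @param corr A [correction_set()].
#' @param count_dist Photon-count distribution over bins: either an integer
#'   vector of observed counts `N` (tabulated internally) or a data frame
#'   with columns `N` and `w`.
#' @param cfg A [pda_config()].
#' @return Probability vector over the `n_bins_E` proximity-ratio bins
#'   (sums to 1).
#' @export
expected_histogram <- function(model, corr = correction_set(),
                               count_dist, cfg = pda_config()) {
  stopifnot(inherits(cfg, "pda_config"))
  cd <- normalize_count_dist(count_dist)
  if (nrow(cd) == 0L) stop("empty photon-count distribution")
  if (is.numeric(model) && length(model) == 1L) {
    eps <- apparent_ratio(model, corr)
    wocc <- 1
  } else {
    stopifnot(inherits(model, "two_state_model"))
    occ <- occupancy_density(model, cfg$bin_duration, cfg$occupancy_grid)
    eps1 <- apparent_ratio(model$E1, corr)
    eps2 <- apparent_ratio(model$E2, corr)
    eps <- occ$f * eps1 + (1 - occ$f) * eps2
    wocc <- occ$p
  }
  nb <- cfg$n_bins_E
  h <- numeric(nb)
  for (r in seq_len(nrow(cd))) {
    N <- cd$N[r]
    k <- 0:N
    pk_mat <- vapply(eps, function(e) stats::dbinom(k, N, e), numeric(N + 1L))
    pk <- as.vector(pk_mat %*% wocc)
    bin <- pmin(floor(k / N * nb) + 1L, nb)
    h <- h + cd$w[r] * tapply_sum(pk, bin, nb)
  }
  h
}

# sum x by integer group 1..nb into a dense vector
tapply_sum <- function(x, g, nb) {
  out <- numeric(nb)
  s <- rowsum(x, g, reorder = TRUE)
  out[as.integer(rownames(s))] <- s
  out
}

# Reduce a photon-count distribution to at most `groups` representative
# counts (weight-preserving, weighted-mean representative per group); keeps
# the histogram model cheap without biasing the shot-noise width noticeably.
compress_count_dist <- function(cd, groups) {
  if (is.null(groups) || nrow(cd) <= groups) return(cd)
  cw <- cumsum(cd$w)
  grp <- pmin(floor(cw * groups / cw[length(cw)] - 1e-12) + 1L, groups)
  N <- as.integer(round(tapply(cd$N * cd$w, grp, sum) / tapply(cd$w, grp, sum)))
  w <- as.vector(tapply(cd$w, grp, sum))
  agg <- rowsum(w, N)           # merged groups may share a representative
  data.frame(N = as.integer(rownames(agg)), w = as.vector(agg))
}

normalize_count_dist <- function(count_dist) {
  if (is.data.frame(count_dist)) {
    cd <- count_dist[, c("N", "w")]
  } else {
    tab <- table(count_dist)
    cd <- data.frame(N = as.integer(names(tab)), w = as.vector(tab))
  }
  cd <- cd[cd$w > 0 & cd$N >= 1, , drop = FALSE]
  cd$w <- cd$w / sum(cd$w)
  cd
}

#' Cut bursts into fixed-duration bins and count photons
#'
#' Standard PDA preprocessing: each burst is cut into consecutive windows
#' of `bin_duration` starting at its first photon; per window the total
#' number of donor-excitation photons (GG + GR) and the acceptor (GR)
#' count are recorded, and windows outside `count_range` are discarded
#' (which also removes sparse trailing partial windows).
#'
#' @param stream A `photon_stream`.
#' @param cfg A [pda_config()].
#' @param bursts Optional burst table from [find_bursts()]; computed with
#'   default parameters when missing.
#' @param ... Passed to [find_bursts()] when `bursts` is `NULL`.
#' @return Data frame with columns `burst`, `bin`, `N`, `N_acc`.
#' @export
bin_photon_stream <- function(stream, cfg = pda_config(), bursts = NULL, ...) {
  stopifnot(inherits(stream, "photon_stream"))
  if (is.null(bursts)) bursts <- find_bursts(stream, ...)
  t <- macrotime_ms(stream)
  ch <- stream$photons$channel
  res <- list(); ri <- 0L
  for (i in seq_len(nrow(bursts))) {
    idx <- bursts$start[i]:bursts$end[i]
    tb <- t[idx]; cb <- ch[idx]
    don <- cb %in% c("GG", "GR")
    tb <- tb[don]; cb <- cb[don]
    if (!length(tb)) next
    t0 <- tb[1]
    # consecutive windows covering the burst; the trailing partial window is
    # kept and left to the photon-count filter
    nb <- ceiling((tb[length(tb)] - t0) / cfg$bin_duration - 1e-9)
    if (nb < 1L) next
    binid <- floor((tb - t0) / cfg$bin_duration) + 1L
    keep <- binid <= nb
    N <- tabulate(binid[keep], nbins = nb)
    N_acc <- tabulate(binid[keep & cb == "GR"], nbins = nb)
    ok <- N >= cfg$count_range[1] & N <= cfg$count_range[2]
    if (any(ok)) {
      ri <- ri + 1L
      res[[ri]] <- data.frame(burst = i, bin = which(ok),
                              N = N[ok], N_acc = N_acc[ok])
    }
  }
  if (!ri) return(data.frame(burst = integer(0), bin = integer(0),
                             N = integer(0), N_acc = integer(0)))
  do.call(rbind, res)
}

#' Simulate PDA time bins directly at the bin level
#'
#' Monte-Carlo generator (and oracle) for binned PDA data: for each bin a
#' state path of the two-state Markov process is simulated over the bin
#' duration by exact jump sampling, the photon count is drawn from the
#' supplied count distribution, and the acceptor count is binomial with the
#' occupancy-mixed apparent ratio. This route is independent of the
#' deterministic occupancy recursion used by [expected_histogram()].
#'
#' @param model A [two_state_model()].
#' @param n_bins Number of bins to simulate.
#' @param corr A [correction_set()].
#' @param cfg A [pda_config()].
#' @param count_dist Count distribution (vector of counts or `N`/`w` data
#'   frame); defaults to Poisson(50 photons/ms x bin duration) truncated to
#'   the configured count range.
#' @param seed Integer seed.
#' @return Data frame with columns `N`, `N_acc`, `f1` (ground-truth
#'   occupancy).
#' @export
simulate_pda_bins <- function(model, n_bins, corr = correction_set(),
                              cfg = pda_config(), count_dist = NULL,
                              seed = 1L) {
  stopifnot(inherits(model, "two_state_model"))
  set.seed(seed)
  n <- as.integer(n_bins)
  if (is.null(count_dist)) {
    lam <- 50 * cfg$bin_duration
    N <- stats::rpois(n, lam)
    while (any(bad <- N < cfg$count_range[1] | N > cfg$count_range[2]))
      N[bad] <- stats::rpois(sum(bad), lam)
  } else {
    cd <- normalize_count_dist(count_dist)
    N <- sample(cd$N, n, replace = TRUE, prob = cd$w)
  }
  f1 <- sim_occupancy(model, cfg$bin_duration, n)
  eps <- f1 * apparent_ratio(model$E1, corr) +
    (1 - f1) * apparent_ratio(model$E2, corr)
  N_acc <- stats::rbinom(n, N, eps)
  data.frame(N = N, N_acc = N_acc, f1 = f1)
}

# Vectorised exact CTMC occupancy simulation: fraction of [0, T] in state 1.
sim_occupancy <- function(model, T, n) {
  k <- c(model$k12, model$k21)
  state <- ifelse(stats::runif(n) < model$p1, 1L, 2L)
  rem <- rep(T, n)
  occ <- numeric(n)
  active <- rep(TRUE, n)
  while (any(active)) {
    idx <- which(active)
    r <- k[state[idx]]
    jump <- rep(Inf, length(idx))
    pos <- r > 0
    if (any(pos)) jump[pos] <- stats::rexp(sum(pos), r[pos])
    dwell <- pmin(jump, rem[idx])
    occ[idx] <- occ[idx] + dwell * (state[idx] == 1L)
    rem[idx] <- rem[idx] - dwell
    fin <- jump >= rem[idx] + dwell
    active[idx[fin]] <- FALSE
    flip <- idx[!fin]
    state[flip] <- 3L - state[flip]
  }
  occ / T
}

#' Observed proximity-ratio histogram from binned data
#'
#' @param bins Data frame with `N` and `N_acc` columns.
#' @param cfg A [pda_config()].
#' @return Integer count vector over the `n_bins_E` ratio bins.
#' @export
observed_histogram <- function(bins, cfg = pda_config()) {
  nb <- cfg$n_bins_E
  bin <- pmin(floor(bins$N_acc / bins$N * nb) + 1L, nb)
  tabulate(bin, nbins = nb)
}

#' Fit static + dynamic photon distribution analysis
#'
#' Fits the observed proximity-ratio histogram with a three-component
#' mixture: two quasi-static species at efficiencies `E1` and `E2` and one
#' dynamically interconverting species with rates `k12`, `k21`. Component
#' amplitudes are profiled out at every step by nonnegative least squares;
#' the four shape parameters are optimised by Nelder-Mead on a chi-squared
#' objective over histogrammed ratios. Standard errors come from the local
#' curvature (numerical Hessian) at the optimum. The fit is deterministic
#' given the data and the initial model.
#'
#' @param bins Binned photon table (`N`, `N_acc`), e.g. from
#'   [bin_photon_stream()] or [simulate_pda_bins()].
#' @param init A [two_state_model()] with starting values.
#' @param corr A [correction_set()].
#' @param cfg A [pda_config()].
#' @param min_bins Minimum usable bins required.
#' @param maxit Nelder-Mead iteration cap.
#' @param count_groups Maximum number of representative photon counts the
#'   count distribution is compressed to inside the fit (`NULL` for exact).
#' @return Object of class `pda_fit`.
#' @export
fit_pda <- function(bins, init, corr = correction_set(), cfg = pda_config(),
                    min_bins = 1000, maxit = 600, count_groups = 30) {
  if (nrow(bins) < min_bins)
    stop("need at least ", min_bins, " usable bins (got ", nrow(bins), ")")
  obs <- observed_histogram(bins, cfg)
  cd <- normalize_count_dist(bins$N)
  fit_pda_hist(obs, cd, init, corr, cfg, maxit = maxit,
               count_groups = count_groups)
}

#' Histogram-level PDA fit
#'
#' Lower-level entry point of [fit_pda()] operating directly on an observed
#' ratio histogram and a photon-count distribution (useful for fitting
#' noise-free expected histograms).
#'
#' @param obs Observed (possibly fractional) counts over the ratio bins.
#' @param count_dist Count distribution (`N`/`w` data frame or count vector).
#' @param init,corr,cfg,maxit,count_groups See [fit_pda()].
#' @return Object of class `pda_fit`.
#' @export
fit_pda_hist <- function(obs, count_dist, init, corr = correction_set(),
                         cfg = pda_config(), maxit = 600, count_groups = 30) {
  stopifnot(inherits(init, "two_state_model"))
  cd <- compress_count_dist(normalize_count_dist(count_dist), count_groups)
  Ntot <- sum(obs)
  wls <- 1 / sqrt(pmax(obs, 1))

  components <- function(E1, E2, k12, k21) {
    H1 <- expected_histogram(E1, corr, cd, cfg)
    H2 <- expected_histogram(E2, corr, cd, cfg)
    Hd <- expected_histogram(two_state_model(E1, E2, k12, k21, init$tauD0),
                             corr, cd, cfg)
    cbind(H1, H2, Hd) * Ntot
  }
  amp_fit <- function(A) {
    sol <- pracma::lsqnonneg(A * wls, obs * wls)
    sol$x
  }
  unpack <- function(th) list(E1 = stats::plogis(th[1]), E2 = stats::plogis(th[2]),
                              k12 = exp(th[3]), k21 = exp(th[4]))
  objective <- function(th) {
    p <- unpack(th)
    A <- components(p$E1, p$E2, p$k12, p$k21)
    x <- amp_fit(A)
    fitv <- as.vector(A %*% x)
    sum((obs - fitv)^2 / pmax(obs, 1))
  }
  th0 <- c(stats::qlogis(min(max(init$E1, 1e-4), 1 - 1e-4)),
           stats::qlogis(min(max(init$E2, 1e-4), 1 - 1e-4)),
           log(max(init$k12, 1e-4)), log(max(init$k21, 1e-4)))
  opt <- stats::optim(th0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  p <- unpack(opt$par)
  A <- components(p$E1, p$E2, p$k12, p$k21)
  x <- amp_fit(A)
  fitv <- as.vector(A %*% x)
  chi2 <- sum((obs - fitv)^2 / pmax(obs, 1))
  dof <- max(length(obs) - 7L, 1L)
  amps <- if (sum(x) > 0) x / sum(x) else c(NA_real_, NA_real_, NA_real_)

  se <- rep(NA_real_, 4)
  H <- tryCatch(pracma::hessian(objective, opt$par), error = function(e) NULL)
  if (!is.null(H)) {
    cv <- tryCatch(solve(H / 2), error = function(e) NULL)
    if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) >= 0)) {
      jac <- c(p$E1 * (1 - p$E1), p$E2 * (1 - p$E2), p$k12, p$k21)
      se <- sqrt(diag(cv)) * jac
    }
  }
  warn <- character(0)
  if (opt$convergence != 0) warn <- c(warn, "non-convergence")
  if (abs(p$E1 - p$E2) < 0.05) warn <- c(warn, "near-degenerate states")
  if (length(warn)) warning(paste(warn, collapse = "; "))

  structure(list(model = two_state_model(p$E1, p$E2, p$k12, p$k21, init$tauD0),
                 amplitudes = c(static1 = amps[1], static2 = amps[2],
                                dynamic = amps[3]),
                 chi2 = chi2, chi2_red = chi2 / dof,
                 se = c(E1 = se[1], E2 = se[2], k12 = se[3], k21 = se[4]),
                 convergence = opt$convergence, flags = warn,
                 observed = obs, fitted = fitv, n_total = Ntot,
                 cfg = cfg, corr = corr),
            class = "pda_fit")
}

#' @export
print.pda_fit <- function(x, ...) {
  cat("Photon distribution analysis fit\n")
  cat(sprintf("  E1 = %.4f (se %.4f)   E2 = %.4f (se %.4f)\n",
              x$model$E1, x$se[["E1"]], x$model$E2, x$se[["E2"]]))
  cat(sprintf("  k12 = %.4g /ms (se %.2g)   k21 = %.4g /ms (se %.2g)\n",
              x$model$k12, x$se[["k12"]], x$model$k21, x$se[["k21"]]))
  cat(sprintf("  amplitudes: static1 %.3f, static2 %.3f, dynamic %.3f\n",
              x$amplitudes[1], x$amplitudes[2], x$amplitudes[3]))
  cat(sprintf("  reduced chi2 = %.3f over %d histogram counts\n",
              x$chi2_red, x$n_total))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.pda_fit <- function(object, ...) {
  c(E1 = object$model$E1, E2 = object$model$E2,
    k12 = object$model$k12, k21 = object$model$k21,
    object$amplitudes)
}

#' @export
summary.pda_fit <- function(object, ...) {
  est <- c(E1 = object$model$E1, E2 = object$model$E2,
           k12 = object$model$k12, k21 = object$model$k21)
  out <- data.frame(estimate = est, se = object$se[names(est)])
  cat("PDA parameter estimates (rates in 1/ms):\n")
  print(out)
  cat(sprintf("reduced chi2: %.3f\n", object$chi2_red))
  invisible(out)
}

#' @export
plot.pda_fit <- function(x, ...) {
  nb <- x$cfg$n_bins_E
  mids <- (seq_len(nb) - 0.5) / nb
  graphics::plot(mids, x$observed, type = "h", lwd = 3, col = "grey60",
                 xlab = "proximity ratio", ylab = "bins", ...)
  graphics::lines(mids, x$fitted, col = "red", lwd = 2)
  invisible(x)
}
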