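#' Two-state interconversion model
#'
#' Continuous-time Markov model of a molecule switching between two FRET
#' states, the object fitted by dynamic photon distribution analysis. State
#' lifetimes follow from the static FRET line: `tau_i = tauD0 * (1 - E_i)`.
#' Equilibrium occupancies are `p1 = k21 / (k12 + k21)` and `p2 = 1 - p1`
#' (for `k12 = k21 = 0` the occupancy defaults to `p1` given explicitly,
#' otherwise 0.5).
#'
#' @param E1,E2 FRET efficiencies of states 1 and 2, in `[0, 1]`.
#' @param k12 Rate of 1 to 2 transitions (per ms), `>= 0`.
#' @param k21 Rate of 2 to 1 transitions (per ms), `>= 0`.
#' @param tauD0 Donor-only lifetime (ns) used to derive state lifetimes.
#' @param p1 Equilibrium occupancy of state 1 when both rates are zero (a
#'   static mixture); ignored otherwise.
#' @return Object of class `two_state_model` with fields `E1`, `E2`, `k12`,
#'   `k21`, `p1`, `p2`, `tau1`, `tau2`, `tauD0`.
#' @examples
#' m <- two_state_model(E1 = 0.2, E2 = 0.9, k12 = 0.5, k21 = 0.5)
#' m$p1  # 0.5
#' @export
two_state_model <- function(E1, E2, k12 = 0, k21 = 0, tauD0 = 3.8, p1 = NULL) {
  if (E1 < 0 || E1 > 1 || E2 < 0 || E2 > 1) stop("efficiencies must lie in [0, 1]")
  if (k12 < 0 || k21 < 0) stop("rates must be >= 0")
  if (tauD0 <= 0) stop("'tauD0' must be > 0")
  if (k12 + k21 > 0) {
    p1 <- k21 / (k12 + k21)
  } else if (is.null(p1)) {
    p1 <- 0.5
  } else if (p1 < 0 || p1 > 1) stop("'p1' must lie in [0, 1]")
  structure(list(E1 = E1, E2 = E2, k12 = k12, k21 = k21,
                 p1 = p1, p2 = 1 - p1,
                 tau1 = tauD0 * (1 - E1), tau2 = tauD0 * (1 - E2),
                 tauD0 = tauD0,
                 # generic CTMC view used by the photon generator
                 E = c(E1, E2), taus = tauD0 * (1 - c(E1, E2)),
                 p = c(p1, 1 - p1),
                 Q = matrix(c(-k12, k12, k21, -k21), 2, 2, byrow = TRUE)),
            class = c("two_state_model", "ctmc_model"))
}

#' Multi-state interconversion model
#'
#' General continuous-time Markov chain over an arbitrary number of FRET
#' states, used by the photon-stream generator to emulate richer ensembles
#' (e.g. a three-state open / closed / compact mixture). Fitting remains
#' two-state; this model is a simulation device.
#'
#' @param E Vector of FRET efficiencies, one per state.
#' @param Q Square rate matrix (1/ms): off-diagonal `Q[i, j]` is the i to j
#'   transition rate; diagonals are ignored and recomputed as negative row
#'   sums. Occupancies are the stationary distribution of `Q`.
#' @param tauD0 Donor-only lifetime (ns).
#' @return Object of class `multi_state_model` (a `ctmc_model`).
#' @examples
#' # open / closed / compact ensemble with slow excursions to the compact state
#' Q <- rbind(c(0, 0.5, 0.02), c(0.5, 0, 0.05), c(0.1, 0.2, 0))
#' m3 <- multi_state_model(E = c(0.05, 0.2, 0.95), Q = Q)
#' @export
multi_state_model <- function(E, Q, tauD0 = 3.8) {
  n <- length(E)
  if (any(E < 0 | E > 1)) stop("efficiencies must lie in [0, 1]")
  if (!is.matrix(Q) || nrow(Q) != n || ncol(Q) != n)
    stop("'Q' must be an n x n rate matrix matching length(E)")
  if (any(Q[row(Q) != col(Q)] < 0)) stop("off-diagonal rates must be >= 0")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # stationary distribution: null vector of t(Q)
  ev <- eigen(t(Q))
  i <- which.min(abs(ev$values))
  if (abs(ev$values[i]) > 1e-8) stop("rate matrix has no stationary distribution")
  p <- abs(Re(ev$vectors[, i])); p <- p / sum(p)
  structure(list(E = E, Q = Q, p = p, taus = tauD0 * (1 - E), tauD0 = tauD0),
            class = c("multi_state_model", "ctmc_model"))
}

#' @export
print.multi_state_model <- function(x, ...) {
  cat("Multi-state interconversion model (", length(x$E), " states)\n", sep = "")
  for (i in seq_along(x$E))
    cat(sprintf("  state %d: E = %.3f, tau = %.3f ns, occupancy %.3f\n",
                i, x$E[i], x$taus[i], x$p[i]))
  invisible(x)
}

#' @export
print.two_state_model <- function(x, ...) {
  cat("Two-state interconversion model\n")
  cat(sprintf("  state 1: E = %.3f, tau_D(A) = %.3f ns, occupancy %.3f\n",
              x$E1, x$tau1, x$p1))
  cat(sprintf("  state 2: E = %.3f, tau_D(A) = %.3f ns, occupancy %.3f\n",
              x$E2, x$tau2, x$p2))
  cat(sprintf("  rates: k12 = %.4g /ms, k21 = %.4g /ms\n", x$k12, x$k21))
  invisible(x)
}

# Sample one CTMC path over [0, T_ms] for any ctmc_model. Returns
# list(times, states) where states[i] holds on [times[i], times[i+1]);
# times[1] == 0.
sample_ctmc_path <- function(model, T_ms, init = NULL) {
  n <- length(model$E)
  s <- if (is.null(init)) {
    sample.int(n, 1L, prob = model$p)
  } else as.integer(init)
  times <- 0
  states <- s
  t <- 0
  repeat {
    r <- -model$Q[s, s]
    if (r <= 0) break
    t <- t + stats::rexp(1, r)
    if (t >= T_ms) break
    s <- if (n == 2L) 3L - s else
      sample.int(n, 1L, prob = pmax(model$Q[s, ], 0))
    times <- c(times, t)
    states <- c(states, s)
  }
  list(times = times, states = states)
}

# Fraction of [0, T_ms] spent in state 1 for a path from sample_ctmc_path().
path_occupancy <- function(path, T_ms) {
  bounds <- c(path$times, T_ms)
  dwell <- diff(bounds)
  sum(dwell[path$states == 1L]) / T_ms
}
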