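#' Photophysical constants of a FRET dye pair
#'
#' Bundles the Forster radius and the donor-only fluorescence lifetime, the two
#' constants needed to convert between FRET efficiency, inter-dye distance and
#' donor lifetime. The defaults correspond to the Atto532/Atto643 pair used
#' throughout the package (`R0 = 59` angstrom) with a donor-only lifetime of
#' 3.8 ns.
#'
#' @param R0 Forster radius in angstrom (distance at which E = 0.5).
#' @param tauD0 Donor fluorescence lifetime in the absence of acceptor (ns).
#' @return An object of class `fret_constants`.
#' @examples
#' fc <- fret_constants()
#' efficiency_to_distance(0.5, fc$R0)
#' @export
fret_constants <- function(R0 = 59, tauD0 = 3.8) {
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    stop("'R0' must be a single positive number (angstrom)")
  if (!is.numeric(tauD0) || length(tauD0) != 1L || !is.finite(tauD0) || tauD0 <= 0)
    stop("'tauD0' must be a single positive number (ns)")
  structure(list(R0 = R0, tauD0 = tauD0), class = "fret_constants")
}

#' @export
print.fret_constants <- function(x, ...) {
  cat("FRET constants: R0 =", x$R0, "A, tau_D(0) =", x$tauD0, "ns\n")
  invisible(x)
}

#' Convert FRET efficiency to inter-dye distance
#'
#' Inverts the Forster relation `E = 1 / (1 + (R/R0)^6)`, giving
#' `R = R0 * ((1 - E)/E)^(1/6)`. The boundary values `E = 0` and `E = 1` map to
#' `Inf` and `0` respectively (returned as such, not as errors).
#'
#' @param E FRET efficiency (vectorised), in `[0, 1]`.
#' @param R0 Forster radius (angstrom).
#' @return Distance(s) in angstrom.
#' @seealso [distance_to_efficiency()]
#' @export
efficiency_to_distance <- function(E, R0 = 59) {
  if (any(!is.finite(E) | E < 0 | E > 1))
    stop("'E' must lie in [0, 1]")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' Convert inter-dye distance to FRET efficiency
#'
#' @param R Distance(s) in angstrom, `R >= 0`.
#' @param R0 Forster radius (angstrom).
#' @return FRET efficiency `E = 1 / (1 + (R/R0)^6)`.
#' @seealso [efficiency_to_distance()]
#' @export
distance_to_efficiency <- function(R, R0 = 59) {
  if (any(!is.finite(R) | R < 0))
    stop("'R' must be finite and nonnegative")
  1 / (1 + (R / R0)^6)
}

#' Static FRET line
#'
#' Expected relation between the corrected FRET efficiency and the donor
#' lifetime in the presence of acceptor for a conformationally static species:
#' `E(tau) = 1 - tau / tau_D(0)`. Plotted on E versus tau_D(A) histograms,
#' static populations fall on this line; values are returned unclipped.
#'
#' @param tau Donor lifetime grid (ns).
#' @param constants A [fret_constants()] object.
#' @return FRET efficiencies along `tau`.
#' @export
static_fret_line <- function(tau, constants = fret_constants()) {
  stopifnot(inherits(constants, "fret_constants"))
  1 - tau / constants$tauD0
}

#' Dynamic FRET line for two-state interconversion
#'
#' For a molecule switching between two states (donor lifetimes `tau1`, `tau2`)
#' within the duration of a burst, the burst-averaged FRET efficiency is
#' species-weighted while the apparent donor lifetime is photon-weighted. The
#' resulting locus on the E versus tau_D(A) plane is the curve
#' `E(tau) = 1 - tau1 * tau2 / (tau_D(0) * (tau1 + tau2 - tau))`,
#' which passes exactly through the two static endpoints `(tau_i, 1 - tau_i /
#' tau_D(0))` and lies above the static line strictly between them. Dynamic
#' populations therefore deviate to the right of the static FRET line.
#'
#' @param tau Photon-weighted average donor lifetime grid (ns); must lie in
#'   `(0, tau1 + tau2)` to avoid the pole at `tau1 + tau2`.
#' @param tau1,tau2 Donor lifetimes of the two interconverting states (ns).
#' @param constants A [fret_constants()] object; `tau1`, `tau2` must be below
#'   `tauD0`.
#' @return FRET efficiencies along `tau`.
#' @export
dynamic_fret_line <- function(tau, tau1, tau2, constants = fret_constants()) {
  stopifnot(inherits(constants, "fret_constants"))
  if (tau1 <= 0 || tau2 <= 0 || tau1 >= constants$tauD0 || tau2 >= constants$tauD0)
    stop("'tau1' and 'tau2' must lie in (0, tauD0)")
  if (any(tau >= tau1 + tau2))
    stop("'tau' must stay below the pole at tau1 + tau2")
  1 - tau1 * tau2 / (constants$tauD0 * (tau1 + tau2 - tau))
}
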