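---
title: "Models and methods behind fretcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretcycle)
```

`fretcycle` quantifies the nucleotide-driven open/closed cycling of dimeric
chaperones such as Hsp90 from two complementary experimental windows: bulk
population kinetics (size-exclusion chromatography and crosslinking gels)
and diffusion-based single-molecule FRET with multiparameter detection and
pulsed interleaved excitation (MFD-PIE). This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-data layer does and does not emulate.

## Corrected FRET efficiencies and stoichiometry

Per burst, the three detection channels are GG (donor emission after donor
excitation), GR (acceptor emission after donor excitation) and RR (acceptor
emission after acceptor excitation). After subtracting per-channel
background (rate x burst duration), the accurate FRET efficiency is

$$E=\frac{F_{GR}-\alpha F_{RR}-\beta F_{GG}}
        {F_{GR}-\alpha F_{RR}-\beta F_{GG}+\gamma F_{GG}},$$

with $\alpha$ the direct-excitation factor, $\beta$ the donor crosstalk
factor and $\gamma$ the acceptor/donor detection-efficiency and quantum
yield ratio. The PIE stoichiometry uses the same corrected numerator with
$F_{RR}$ in the denominator; the default stoichiometry window 0.3–0.7
removes donor-only ($S \approx 1$) and acceptor-only ($S \approx 0$)
molecules. The correction factors are configuration inputs, not estimated
from the data: the synthetic generator knows them exactly, and for measured
data they come from the instrument calibration. Efficiencies outside
$[0,1]$ (photon-starved bursts) are flagged but never clipped, so histogram
shot-noise wings are preserved.

Distances follow from the Förster relation $E=1/(1+(R/R_0)^6)$ with
$R_0 = 59$ Å for the Atto532/Atto643 pair; at this radius an efficiency of
0.075 (rounding to 0.08) corresponds to 89.6 Å.

## FRET lines

On the efficiency versus donor-lifetime plane, a static species satisfies
$E = 1-\tau_{D(A)}/\tau_{D(0)}$. For a molecule switching between two
states during a burst the efficiency is species-averaged while the lifetime
is photon-averaged, which yields the dynamic FRET line

$$E(\tau)=1-\frac{\tau_1\tau_2}{\tau_{D(0)}\,(\tau_1+\tau_2-\tau)}.$$

It passes exactly through the two static endpoints and lies strictly above
the static line between them — the classic rightward deviation diagnostic
of sub-millisecond dynamics. Renderings of this relation in the literature
are sometimes typographically mangled into expressions that are not even
dimensionless; the form above is the standard one, fixed unambiguously by
the endpoint behaviour. An optional polynomial linker-dynamics correction
to the static line is deliberately not applied by default because its
coefficients are instrument-specific.

Donor lifetimes are estimated per burst by the maximum-likelihood solution
of a single-exponential decay truncated to the donor excitation window
(`mean(x) = tau - W/(exp(W/tau)-1)` solved for `tau`); no instrument
response function is modelled, matching the synthetic data which has none.
Burst-wise lifetime estimates on streams with background carry a small
upward bias from uniform background microtimes, visible only at high
background-to-signal ratios.

## Dynamic photon distribution analysis

PDA asks whether histogram width beyond shot noise reflects distinct states
or millisecond interconversion. Bursts are cut into fixed 1 ms bins
(20–120 photons kept); per bin with $N$ donor-excitation photons the
acceptor count is binomial with success probability equal to the apparent
proximity ratio. For a two-state Markov model the success probability mixes
over $f_1$, the fraction of bin time in state 1:

- the distribution of $f_1$ has exact point masses
  $p_1 e^{-k_{12}T}$ at $f_1{=}1$ and $p_2 e^{-k_{21}T}$ at $f_1{=}0$
  (no-transition probabilities);
- the continuous interior is computed by a discrete-time
  survival-probability recursion whose step count grows with
  $\max(k_{12},k_{21})\,T$ (capped at 3000), aggregated onto an occupancy
  grid of 101 points and renormalised so total mass is exactly one. A
  Monte-Carlo jump-chain simulator, written independently, is the
  correctness arbiter in the tests.

The fitted model is a three-component mixture — quasi-static species at
$E_1$ and $E_2$ plus a dynamically interconverting component with rates
$k_{12}, k_{21}$. Amplitudes are profiled out at every objective evaluation
by nonnegative least squares; the four shape parameters are optimised by
Nelder-Mead on a chi-squared over histogrammed proximity ratios
(fitting happens in uncorrected ratio space with corrections applied inside
the model, as in standard PDA practice). Standard errors come from the
numerical Hessian at the optimum. Two numerical conveniences matter: the
photon-count distribution is compressed to at most 30 weighted
representative counts inside the optimiser (weight-preserving; the
histogram model is insensitive at this granularity), and near-degenerate
state pairs ($|E_1-E_2|<0.05$) trigger an identifiability warning. When
the dynamic component's interconversion is slow, its endpoint mass is
partially collinear with the static amplitudes; rates are then identified
by the interior occupancy shape, which is why parameter-recovery accuracy
is quoted at the reference model (median relative rate error below 15%
across 20 seeded replicates of 30,000 bins).

## Accessible-volume dye model

Structure-based distance predictions use the grid accessible-volume (AV)
model: all positions a dye can reach on its flexible linker without steric
clash. A cubic grid (0.9 Å default spacing) is centred on the attachment
atom; Dijkstra's algorithm over a 7x7x7 neighbourhood (collinear duplicate
offsets removed, intermediate cells checked so multi-cell steps cannot hop
through thin obstacles) computes geodesic path lengths. A point is allowed
iff its geodesic distance is at most the linker length (21 Å), every path
vertex clears all atom surfaces by half the linker width (4.5/2 Å), and the
endpoint clears them by the dye radius. The attachment residue's own atoms
are not obstacles. The three-radii model unions the AVs of the three dye
radii — donor (5.5, 4.5, 1.5) Å, acceptor (7.15, 4.5, 1.5) Å — weighting
each point by the number of component AVs containing it.

Pair statistics are Monte-Carlo over weighted point pairs: the mean
inter-dye distance $\langle R_{DA}\rangle$, the mean-position distance
$R_{mp}$, the AV-averaged efficiency $\langle E\rangle$ and its
efficiency-equivalent distance $R_{\langle E\rangle}$. Because which of
these statistics a reported "expected distance" denotes is often left
unstated, the package reports all of them. Label sites are selected as
`chain:resnum:atom`; for cysteine-labelled sites the SG atom is the natural
choice, with CB the fallback when the deposited structure carries the
wild-type residue.

Validation relies on analytic toy geometries rather than reference
software: a lone attachment atom (AV volume within 5% of the sphere
$\tfrac43\pi L^3$; the 7x7x7 chamfer metric under-estimates it by about
2.5%), a planar wall (hemisphere centroid at $3L/8$), and a spherical
cavity (buried-site detection). The wall validation deliberately uses a
thin, dense wall (0.3 Å atom radius, 0.75 Å spacing, wall plane 0.75 Å
below the attachment) with a narrow linker width, because with
protein-scale clearances the blocked slab above the wall shifts the
centroid more than 1 Å away from the ideal-hemisphere value and the
analytic reference would no longer apply.

## Open/closed population kinetics

SEC elution profiles are deconvolved as the sum of two Gaussians, one per
conformational state ("bi-Gaussian" is read as a two-component sum, since
its purpose is to split open and closed fractions; an asymmetric
single-peak reading would not yield fractions). Fractions come from the
analytic component areas $A\sigma\sqrt{2\pi}$. Initialisation is
deterministic: peak centers from the two largest local maxima of a
smoothed profile, widths from FWHM/2.355. Time series are fitted globally
with shared centers and widths and free per-time amplitudes, which keeps
the decomposition identifiable when one population nearly vanishes at
early or late times. The closed (compact) state elutes later by default;
the assignment is a flag (`closed = "earlier"`) rather than hard-coded.

Closing follows $f(t)=f_\infty(1-e^{-kt})$ (first-order approach to
plateau, the only model consistent with a single quoted rate constant) with
$f(0)=0$; opening follows $f(t)=f_{eq}+(f_0-f_{eq})e^{-kt}$ with a free
equilibrium level, because nucleotide exchange can leave a closed fraction
(ADP) — `fix_feq = 0` recovers the complete-reopening special case.
Crosslinking gels reduce to the same kinetics layer through
`gel_band_fractions()` (dimer/(dimer+monomer) per lane, optional
molecular-weight weighting off by default, since band intensity is already
approximately mass-proportional for a dimer of identical protomers).

## The synthetic-data layer

The generator is first-class, tested code, and defines the study
conditions for every self-contained check:

- **Photon streams.** Bursts with exponential durations (mean 2 ms,
  emulating diffusion-limited transits) separated by exponential gaps ten
  times longer; donor-excitation events at 60 photons/ms and RR events at
  30 photons/ms during a burst; background 1 photon/ms per channel; hidden
  two-state Markov paths; forward distortions constructed so that the
  accurate-FRET formula inverts them exactly in expectation (crosstalk as
  Bernoulli reassignment with probability $\beta/(1+\beta)$, direct
  excitation as a Poisson GR stream at $\alpha$ times the RR rate,
  $\gamma$ as unequal detection efficiencies). Microtimes are single
  exponentials truncated to the PIE half-period — no IRF, no triplet
  blinking, no diffusion through a 3D point-spread function, no
  multi-molecule coincidence. Burst rates and background are not taken
  from any particular instrument; they were chosen once for testability
  (bursts well above background, enough photons per burst for lifetime
  estimates).
- **Chromatograms.** Two-Gaussian mixtures (open 10.4 mL, closed 11.0 mL,
  both $\sigma = 0.25$ mL on a 0.01 mL grid) whose closed-area fraction
  follows the first-order law; additive Gaussian noise at 1% of the
  series' maximum amplitude; total area constant before noise.
- **Gel tables and toy structures** as described above.

Passing tests on these data demonstrate correctness of the estimators
under the stated models, not robustness to the full messiness of measured
data (detector afterpulsing, photobleaching, column tailing, gel
saturation).

## Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed and is
bit-reproducible given it. The standard checks use 300–500 simulated
bursts, 20,000–30,000 PDA bins per fit with 20 replicate fits for the
recovery statistics, seven-point kinetic series with 1% noise, and AV
grids of roughly $10^5$ cells — sizes chosen so the complete validation
suite runs in minutes on a single core while keeping Monte-Carlo error
well below the tolerances being asserted.

## Interfaces and scope

Photon lists interchange as plain CSV (`macrotime` ticks, `microtime_ns`,
`channel`) with tick resolution and excitation period in comment headers;
chromatogram series as one CSV per time point plus a manifest. The
pipeline layer (`run_pipeline()` on a YAML `run_config`, plus
`write_report()`) is the package's entry point for scripted use; the
exported functions themselves are the interface, and no shell executable
is installed. Three-state simulation is available through the generator's
model object only; PDA fitting is intentionally two-state, and a Gaussian
distance-distribution broadening within a state is out of scope.
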