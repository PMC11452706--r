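# fretcycle

Quantitative analysis of nucleotide-driven conformational cycling in
dimeric chaperones (Hsp90-type systems), combining two experimental
windows:

- **Single-molecule FRET (MFD-PIE).** Burst search on time-tagged photon
  streams, fully corrected per-burst FRET efficiencies
  `E = (F_GR − αF_RR − βF_GG) / (F_GR − αF_RR − βF_GG + γF_GG)` and PIE
  stoichiometries, donor-lifetime estimation, static/dynamic FRET-line
  diagnostics, and static + dynamic photon distribution analysis (PDA)
  that fits state efficiencies and millisecond interconversion rates
  (`k12`, `k21`) from shot-noise-limited proximity-ratio histograms.
- **Bulk population kinetics.** Bi-Gaussian deconvolution of SEC elution
  profiles into open/closed fractions (optionally as a global series fit
  with shared peak shapes), first-order closing
  `f(t) = f∞(1 − e^{−kt})` and opening `f(t) = f_eq + (f0 − f_eq)e^{−kt}`
  rate fits, and crosslinking-gel dimer fractions feeding the same
  kinetics layer.

A grid-based accessible-volume (AV) module predicts inter-dye distances
from structures (three-radii dye model, geodesic flood fill with steric
clearance), and distances convert to efficiencies through the Förster
relation `E = 1/(1 + (R/R₀)⁶)` with `R₀ = 59 Å` for Atto532/Atto643. A
seeded synthetic-data layer generates photon streams, chromatogram series,
gel tables and toy structures with known ground truth, so the entire
pipeline is testable end to end.

## Worked example

Simulate a dynamically interconverting dimer, analyse its bursts, and fit
the interconversion by PDA:

```r
library(fretcycle)

model <- two_state_model(E1 = 0.2, E2 = 0.9, k12 = 0.5, k21 = 0.5) # rates in 1/ms
stream <- simulate_photon_stream(model, sim_burst_config(n_bursts = 500, seed = 7))
bursts <- analyze_bursts(stream, stream$corrections)
bins   <- simulate_pda_bins(model, 3e4, seed = 7)
fit    <- fit_pda(bins, two_state_model(0.25, 0.85, 0.8, 0.3))
fit
#> Photon distribution analysis fit
#>   E1 = 0.1998 (se 0.0008)   E2 = 0.9000 (se 0.0006)
#>   k12 = 0.4994 /ms (se 0.0099)   k21 = 0.5098 /ms (se 0.053)
#>   amplitudes: static1 0.000, static2 0.007, dynamic 0.993
#>   reduced chi2 = 1.275 over 30000 histogram counts
```

The fit recovers the generating efficiencies (0.2/0.9) and both 0.5 ms⁻¹
rates within two percent; the mixture is dominated by the dynamic
component, as simulated.

Closing kinetics from a chromatogram time series:

```r
sec <- generate_chromatogram_series(k = 1.03, f_inf = 0.9,
                                    times = c(0, 0.25, 0.5, 1, 2, 3, 5),
                                    noise_sd = 0.01, seed = 201)
series_fit <- fit_bigaussian_series(sec)
fit_closing(series_fit$fractions$time_min, series_fit$fractions$f_closed)
#> first-order closing kinetics: k_closing = 1.03 /min (se 0.0037)
#>   plateau f_inf = 0.9008
```

The recovered `k_closing` matches the generating rate 1.03 min⁻¹ within
its standard error — the ten-fold species difference between fast- and
slow-closing homologues is resolved the same way by fitting each series.

AV-based distance prediction on a structure (label sites as
`chain:resnum:atom`):

```r
s  <- read_structure("structure.pdb")
d  <- compute_av3(s, "A:61:SG", av_params(dye_radii = c(5.5, 4.5, 1.5)))
a  <- compute_av3(s, "B:61:SG", av_params(dye_radii = c(7.15, 4.5, 1.5)))
av_pair_stats(d, a, R0 = 59)   # mean R_DA, Rmp, <E>, R(<E>)
```

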