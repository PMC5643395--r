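---
title: "Methods: FRET-based nucleosome stability analysis and trajectory geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FRET-based nucleosome stability analysis and trajectory geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucfret)
```

This vignette documents the models behind `nucfret`, the parameter
choices that matter, what the synthetic generators do and do not
emulate, and the numerical decisions a maintainer should know about.

## The observables

The proximity ratio `P = I_A / (I_A + I_D)` is the fraction of
(corrected) acceptor-channel signal under donor excitation. It is a
monotone proxy for the FRET efficiency `E = 1 / (1 + (R/R0)^6)`; the
two are linked through the detection factor
`gamma = (eta_A * phi_A) / (eta_D * phi_D)` by
`P = gamma E / (gamma E + 1 - E)`. P, not E, is the package's primary
observable: it needs no gamma calibration, and all downstream
statistics (histograms, mixture fractions, titration midpoints) are
invariant to the monotone P–E mapping. `gamma` therefore defaults
to 1, and the E/R conversions are provided for interpretation only.

### Intensity corrections

Raw well intensities are corrected in a fixed composition: backgrounds
are subtracted per channel first, donor crosstalk (`alpha` times the
background-subtracted donor signal) and direct acceptor excitation
(`delta` times the background-subtracted acceptor-excitation signal)
are then removed from the acceptor channel. `alpha` and `delta` are
instrument properties with no universal values; they are configuration
inputs, estimated from donor-only / acceptor-only / buffer control
wells by `estimate_corrections()` when a plate provides them.
Corrected intensities are deliberately **not clamped at zero**:
negative values are legitimate noise outcomes, and the P histogram
range of [-0.1, 1.1) is chosen precisely so they stay visible instead
of piling up at the boundary.

## Burst analysis

Bursts are maximal clusters of the merged donor+acceptor photon
sequence in which every consecutive gap is strictly less than 120 µs;
clusters of at least 50 photons are kept. Two conventions had to be
fixed because "mutual separation" underdetermines them: gaps are
evaluated on the merged channel sequence (a burst is one molecule's
transit, which emits into both channels), and the gap comparison is
strict, so a gap of exactly 120 µs splits. Per-burst background
correction subtracts the expected background counts, i.e. the channel
background rate times the burst duration, before the crosstalk term;
the per-burst P is then `N_A_corr / (N_A_corr + N_D_corr)`. Each burst
contributes exactly one P value to the histogram regardless of its
size — size-weighting would change the subpopulation fractions from
"fraction of molecules" to "fraction of photons", which is not the
quantity of interest. Bursts with P outside [0, 1] (possible after
correction) are retained; excluding them would bias the LF and HF
tails asymmetrically.

## Mixture decomposition

The P histogram (frequencies at bin centres) is fitted by least
squares with `f(x) = sum_i a_i N(x; mu_i, sigma_i) * bw`, three
components, using a bounded Levenberg–Marquardt optimiser. Component
**areas**, not amplitudes, define the fractions: two peaks of equal
height but different width contain different numbers of molecules.
Fitting the binned curve rather than a per-burst likelihood mirrors
how such histograms are analysed in practice and makes the fractions
exactly invariant under count rescaling (a property the tests
enforce).

Numerical choices:

* Initialisation at means (0.12, 0.39, 0.64) — the canonical LF/MF/HF
  positions; sigmas at 0.05, the shot-noise width of a ~100-photon
  burst at mid-range P.
* Bounds: means within the histogram range [-0.1, 1.1]; sigmas in
  [0.01, 0.3] (narrower than a bin is meaningless, wider than 0.3
  would swallow the whole range); areas non-negative.
* Components are relabelled LF/MF/HF by ascending fitted mean, making
  the labelling invariant to initialisation order.
* A fitted mean pair closer than 0.02 (one bin) sets a `degenerate`
  flag; a component with < 1e-3 of the total area is reported as is
  but flagged, and a two-component re-fit is attached as a robustness
  check (`refit2`) — never silently substituted.

`hf_fraction()` returns `area_HF / (area_MF + area_HF)`: the share of
partially disassembled nucleosomes among those still assembled enough
to FRET, with the LF (open/free-DNA) state excluded by construction.

## Salt titration

The normalised series is fitted with the 4-parameter logistic
`P(x) = P0 + (Pinf - P0) / (1 + exp((c_half - x)/b))`. Normalisation
divides by the mean P of all points at <= 100 mM NaCl — the stable
low-salt plateau — so different constructs and labeling schemes are
comparable; the operation is idempotent and cannot move `c_half`,
which the tests verify by rescaling invariance. With `P0 > Pinf` and
`b > 0` the curve decreases; the midpoint identity
`P(c_half) = (P0 + Pinf)/2` holds for either sign convention of `b`,
and `c_half` is flagged `extrapolated` when it falls outside the
fitted concentration span.

Weighting is `1/sd^2` when replicate SDs are available (the default),
with an automatic unweighted fall-back when the weighted optimisation
fails — replicate SDs estimated from three measurements are noisy, and
a near-zero SD can make the weighted problem ill-conditioned. Both
modes are exposed (`weighted =`). Two standard errors are reported:
the single-fit covariance SE, and — in `run_titration()` — the SEM of
`c_half` over independent replicate fits, which is the convention used
when replicate series are available.

Start values are taken from the data (plateaus from the series
extremes, `c_half` from the point nearest the half-decay level,
`b` = one tenth of the concentration span); with 13 points spanning
the transition the optimiser converges in a handful of iterations.

## Trajectory geometry

Operators take a lightweight `trajectory` (atoms + frames in nm);
multi-model PDB is read natively via bio3d.

* **H-bond occupancy**: fraction of frames in an analysis window in
  which a donor-residue/acceptor-residue pair has at least one
  qualifying bond. The geometric criterion — donor–acceptor heavy
  distance <= 0.35 nm and H–donor–acceptor angle <= 30° — is the
  GROMACS-style convention; both cutoffs are arguments. Hydrogens are
  attached to a donor by same-residue membership plus covalent
  proximity (< 0.12 nm) evaluated per frame, so no bond table is
  required. The default window of 20–150 ns skips the equilibration
  phase of a 150-ns production run; window endpoints are inclusive
  and frames are weighted uniformly.
* **Contacts**: heavy-atom pairs strictly closer than 0.35 nm,
  hydrogens excluded automatically, self-pairs of overlapping
  selections excluded with a warning. `contact_probability()` reduces
  this per neighbour residue and is computed per chain, i.e. per
  histone copy.
* **DNA-arm segment distances**: base pairs are counted 1-based
  inward from each DNA end; bp i pairs residue i (5'→3') of strand 1
  with residue N+1−i of strand 2. The default segments 1–5, 6–10,
  11–15, 16–20 bp are each paired with the mirror segment counted
  from the opposite end, and the per-frame distance is between
  mass-weighted centres of mass. All atoms enter the COM by default
  (`heavy_only` switches to heavy atoms); with full 5-bp segments the
  hydrogen contribution shifts the COM negligibly, but the choice is
  explicit because it is not standardised.
* **Running average**: trailing mean over the half-open window
  `(t - 200 ps, t]`, output time base unchanged. Trailing (not
  centred) so the smoothed trace is causal and comparable across
  segment series with identical time bases.
* No periodic-boundary minimum-image correction is applied:
  trajectories are assumed whole/unwrapped, which holds for a
  solute-centred nucleosome trajectory. All operators reduce to
  internal distances and angles and are therefore exactly invariant
  under rigid motions, a property the tests check with random
  rotations.

## Synthetic generators: what they emulate

`simulate_photon_stream()` reproduces the statistics that matter for
validating the burst pipeline: a categorical species draw per burst,
burst sizes uniform on [50, 150] photons, binomial (shot-noise)
channel partitioning at the species' true P — optionally convolved
with a truncated-normal "extra width" (default 0) — exponential
intra-burst gaps (mean 10 µs) and exponential inter-burst gaps (mean
10 ms), plus optional Poisson background. The two-decade separation
between gap scales reflects the real separation between intra-burst
photon rates and the diffusion-limited burst rate; generation is
refused when the intra-burst mean is not below the burst-search gap.
Deliberately **not** modelled: dye photophysics (blinking, bleaching),
diffusion-path-dependent burst-intensity profiles, detector afterpulsing
and polarisation. Passing recovery tests therefore demonstrates the
correctness of the analysis chain, not robustness to photophysical
artefacts in real data. One consequence of the honest gap model is
that ~1% of bursts merge or get clipped in detection; recovery
tolerances absorb this, and it is a feature, not a bug — real streams
do the same.

`simulate_titration()` is exact: logistic mean plus i.i.d. Gaussian
replicate noise. Defaults (noise SD 0.02, 3 replicates, 13
concentrations from 5 to 1200 mM) match a typical triplicate
microplate titration. `toy_*_trajectory()` builders construct
geometries whose occupancies, contact counts and COM distances are
known in closed form.

All generators are seed-reproducible: the same seed yields an
identical stream, series or trajectory.

## Problem sizes and validation scope

The test suite validates titration recovery over 200 simulated series
per truth set (noiseless recovery to < 0.1 mM; mean noisy recovery
within 10 mM), the full spFRET chain on 30,000 bursts (component means
within 0.01, equal weights within 0.03), burst search against an
independent reference clusterer on 50 random streams of up to 10^4
photons, and the trajectory operators against brute-force oracles and
constructed geometries on toy systems of up to a few hundred atoms.
These sizes were chosen to make sampling error comfortably smaller
than the tolerances while keeping the suite quick to run.

## Known limitations

* The mixture model is fixed at three components; no model selection
  over component counts is attempted, and strongly overlapping
  components (separation below ~2 sigma) are not resolvable from
  binned data at realistic burst counts.
* Sigmas are fitted independently per salt condition; sharing widths
  across conditions could stabilise sparse histograms but is not
  implemented.
* `c_half` standard errors from a single weighted fit assume
  well-estimated weights; with triplicate SDs the replicate-SEM route
  of `run_titration()` is the more defensible uncertainty.
* The H-bond criterion is geometric only; energetic or
  orbital-orientation definitions would classify marginal bonds
  differently.
* Salt titrations are treated as equilibrium measurements; hysteresis
  and disassembly kinetics are out of scope, as is extracting
  thermodynamic quantities from `c_half`.
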