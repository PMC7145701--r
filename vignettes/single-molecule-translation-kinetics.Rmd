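---
title: "Single-molecule kinetics of cap-dependent translation: models, simulator and design choices"
author: "nascentTrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule translation kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentTrack)
```

# The assay and its observables

The package models a surface-tethered translation assay: 3′-biotinylated
reporter mRNAs carrying an N-terminal 3xFLAG tag are immobilized in a TIRF
flow channel, translation extract with Cy3-labeled anti-FLAG is delivered,
and every antibody binding to a nascent tag produces an instantaneous
fluorescence increase on that molecule's trajectory; antibody departure at
peptide release produces an instantaneous decrease. Reagent delivery
itself raises the diffusing-antibody baseline over a few seconds; the
completion of that rise defines time zero of the translation reaction for
every molecule in the field of view.

Two quantities summarize each trajectory:

* the **first arrival time** `t1`, from time zero to the first binding.
  Biochemically `t1 = t1_I + t1_tag`: the first-round initiation time plus
  the time to translate the tag and the exit-tunnel-protected stretch.
  Since initiation and elongation are separate molecular processes,
  `<t1> = <t1_I> + <t1_tag>`, so the mean initiation time is recovered by
  subtracting `(tagAa + tunnelAa) / rate` (`meanInitiationTime()`).
* the **dwell time** `Δt` of each binding, from epitope recognition to
  release at termination; on monosome events it measures the decoding
  time of the coding region downstream of the exposed tag, and
  `elongationRate()` converts its mean into aa/s.

# The generative model

`simulateTimeline()` draws, per mRNA:

1. **First-round initiation** from a shifted log-normal
   `x0 + exp(N(mu, sigma^2))`. This is a descriptive, not mechanistic,
   law: it is the functional form that first-arrival histograms of this
   assay follow, so simulating from it makes the fitting problem
   self-consistent. Defaults (`x0 = 120` s, `mu = log(240)`,
   `sigma = 0.8`) put the earliest initiations near 2 min, the mode near
   5–6 min and a tail beyond 30 min — the asymmetric, minutes-scale,
   highly asynchronous shape the assay reveals.
2. **Re-initiation** (polysomes) with exponential waiting times of mean
   `reinitMean`, blocked until the preceding ribosome has translated
   `clearanceAa` codons (default 35). How long a recruited small subunit
   sequesters the 5′ end is poorly understood; a simple clearance rule is
   the minimal testable assumption, and it is configuration, not claim.
   The default is monosome-only (`reinitMean = Inf`) because dwell
   analysis uses monosome events; field presets enable re-initiation.
3. **Epitope exposure** after `tagExposureAa / elongationRate` seconds
   (default 57 aa: the 22-aa 3xFLAG tag plus a 35-aa tunnel-protected
   stretch; the tunnel range 30–40 aa is carried as a sensitivity band in
   `meanInitiationTime()`, costing under 5 s at ~2.5 aa/s).
4. **Antibody recognition** delays from a two-exponential mixture
   (defaults `tauFast = 3.9` s, `tauSlow = 38` s, fast fraction 13/14).
   The fast component is binding to fully exposed tags; the slow
   component lumps chains that must elongate further before the tag is
   accessible. Both are sampled as exponentials; a delay that would
   outlast the ribosome's own release is discarded as unobservable.
5. **Release** at `nCodons / elongationRate` after initiation (574
   codons, 2.5 aa/s by default): elongation is deterministic in the
   simulator. Per-codon stochasticity is deliberately not modeled — the
   observed dwell dispersion in real data is therefore *not* reproduced
   by the generator, and log-normal dwell-fit validation draws dwells
   directly from the log-normal sampler instead
   (`rLogNormalByMean()`).
6. **Translation-irrelevant loss** (antibody dissociation from an intact
   nascent chain plus photobleaching) as a single exponential clock per
   bound antibody; only the sum of the two processes is measurable, so
   they are lumped. The default rate `-ln(0.9)/1800` s⁻¹ calibrates to
   10% spot loss over 30 min of stalled translation.

`synthesizeTrace()` adds the measurement model: a linear baseline rise of
`deadTime = 3.5` s (reagent exchange takes 3–4 s) starting at
`deliveryStart`, one additive step per bound antibody with amplitude
drawn uniformly from 2–7 dyes (the antibody's labeling ratio; no
blinking, which these antibodies do not show at seconds-scale
acquisition), and Gaussian noise. `simulateField()` adds nonspecific
surface binding as a homogeneous Poisson process (never released, hence
linearly accumulating), and `renderMovie()` turns traces into TIRF-like
image stacks: symmetric 2D Gaussian spots (peak = step amplitude,
integral = `amplitude * 2π σ²`), constant background, optional rigid
drift, Gaussian or Poisson pixel noise.

Every dataset regenerates bit-identically from `(params, seed)`: each
molecule owns a private seeded stream, so molecule *i* is identical
whatever the field size.

# Imaging pipeline

The paper-level description of movie processing is three sentences (drift
and background correction, intensity-based detection, sub-pixel 2D
Gaussian fitting), so the pipeline here is assembled from standard,
individually testable pieces:

* `estimateDrift()` — Fourier cross-correlation of each frame against a
  frame-averaged reference, sub-pixel via log-parabolic interpolation of
  the correlation peak (exact for Gaussian-shaped peaks). Three
  robustness guards matter in this assay, where early frames precede any
  binding: frames whose normalized correlation falls below `minQuality`
  or whose displacement exceeds `maxShift` (spurious constellation
  matches when few spots are present) are interpolated from neighbors,
  the path is median-smoothed (drift is slow and smooth; a running
  median passes a linear drift unchanged), and a second pass correlates
  against a drift-compensated average. On simulated movies at SNR 10
  this recovers a 0.02 px/frame drift slope within a few percent and
  leaves < 0.05 px residual after `correctDrift()` (bilinear
  resampling).
* `subtractBackground()` — per-frame median filter with radius
  `10 × psfSigma` (EBImage); residuals stay signed so photometry is
  unbiased, clipping is for display only.
* `detectSpots()` — local maxima above `thresholdSigma` (default 5)
  times the robust (MAD) noise sd, with non-maximum suppression within
  `2 × psfSigma`.
* `localizeSpot()` — Levenberg–Marquardt fit of a symmetric 2D Gaussian
  plus offset on a `±3 psfSigma` window; fits are failed (not silently
  kept) when the window is edge-clipped, the fit diverges, the center
  leaves the window, or sigma falls outside `[0.5, 3] × psfSigma`.
* `extractTraces()` — fixed-aperture photometry at the tethered-mRNA map
  positions rather than per-frame re-detection, because first-arrival
  analysis needs the intensity at a position *before* anything binds
  there. The aperture sum is rescaled to PSF peak-amplitude units by the
  enclosed-energy factor `2π σ² (1 − e^(−r²/2σ²))`. Molecules within
  `3 × psfSigma` of the border or with overlapping apertures are flagged
  and excluded by default.

# Event analysis

`detectTimeZero()` finds the strongest sustained rise early in the trace,
takes the plateau as the median of a short window after it, and sets `t0`
at the 90% crossing; a field uses the median over traces since exchange
is simultaneous. Traces already at plateau (no detectable delivery) are
an error, and an up-step *before* delivery marks the whole trace invalid
(surface junk), not just the event.

`detectSteps()` segments the baseline-subtracted signal into
piecewise-constant levels by penalized binary segmentation (penalty
`3 log(n) σ²` per change point, with σ the MAD-of-differences noise
estimate), then iteratively merges boundaries whose level change is
below `minAmplitudeSigma × σ` (default 5σ). A change-point formulation
rather than a fixed threshold is essential because step heights vary
4-fold with the 2–7 dye labeling. Two true events landing in the same
frame merge into one step — an intrinsic resolution limit of
frame-quantized counting that the tests document.

Dwell pairing matches each up event to the next down event of compatible
amplitude (within 50% relative tolerance); unpaired ups at the movie end
are censored; a dwell is `monosome` only if no second antibody is bound
at any moment during it, and only uncensored monosome dwells enter the
elongation fit. Censored first arrivals are excluded from histogram
fitting but reported with the censoring fraction, matching the
observed-arrival-histogram convention of the distribution fits.

`computeSNBR()` uses the final 10% of the acquisition as the plateau
window (the plateau window is otherwise unspecified) and rescales the
nonspecific channel by the immobilized-mRNA density ratio of the control
experiment (2.3-fold in the reference design). `survivalCurve()` is a
Kaplan–Meier estimate (via the survival package) with right-censoring at
the movie end.

# Fitting

* `fitDoubleExponential()` — primary mode is MLE on raw delays
  (statistically efficient); a binned least-squares mode mirrors
  histogram fitting of `y = A1/τ1 e^(−t/τ1) + A2/τ2 e^(−t/τ2)`. The two
  agree within combined errors on large samples (a test asserts this).
  Degenerate fits (`τ2/τ1 < 1.5` or boundary mixture weight) are
  flagged, not hidden.
* `fitShiftedLogNormal()` — least squares on histogram counts, because
  the model's `y0 + amplitude` form is a histogram model: the additive
  floor `y0` absorbs nonspecific binding exactly as the assay adds it.
  Binning is Freedman–Diaconis unless breaks are given (no bin width is
  canonical). `x0` is constrained to `[0, min(sample))`. The derived
  mean `x0 + e^(μ+σ²/2)` and mode `x0 + e^(μ−σ²)` get bootstrap errors;
  a quadrature test checks the closed-form mean against the numerical
  first moment to 0.1%.
* `fitLognormalDwell()` — closed-form log-normal MLE; the reported mean
  and its bootstrap error convert to an elongation rate.
* All bootstraps are nonparametric resamples of trajectories (not of
  bins), 200 replicates by default, seeded; the peak/mean uncertainties
  of paired-construct comparisons (e.g. ±hairpin) are obtained as
  bootstrap differences, since no closed form exists for the mode's
  error.

`asynchronyProfile()` divides the observed first arrivals into
consecutive windows one mean elongation time wide (14 by default)
starting at the earliest arrival: molecules in window *k* lead window
*k+1* by a full synthesis round on average, which is how the assay
quantifies translational asynchrony between mRNAs.

# Numerical and scale choices

Problem sizes in the test-suite property checks are the package's own
choices, selected so each oracle has adequate power while the full suite
runs in a couple of minutes: 10⁵ draws for closed-form moment checks,
n = 1500–2000 for Kolmogorov–Smirnov and survival-band checks at
α = 0.01, 500 seeds for the flat-trace false-positive rate, 5×10⁴
samples for MLE-vs-binned agreement, 100 bootstrap-coverage replicates
for the dwell fitter and 40 for the mixture fitter, and 64×64-px,
~600-frame movies for the end-to-end recovery checks (≥ 90% of ≥ 5σ
events, ≤ 5% spurious).

Other deliberate numerics: recognition time constants of exactly zero
are honored as point masses (used by degenerate-configuration tests);
`sigma = 0` collapses the initiation law to a point mass; the
change-point penalty multiplier (3) errs toward missing sub-threshold
changes rather than fragmenting levels, since the amplitude filter
deletes small boundaries anyway; drift-path smoothing uses a running
median (window 9 frames) to stay outlier-robust without biasing linear
drift; TIFF export scales linearly to unsigned 16-bit with the scaling
recorded in a JSON sidecar.

# What passing tests do and do not show

The simulator reproduces the statistical structure the analysis assumes:
shifted log-normal first arrivals spanning minutes, seconds-scale
double-exponential recognition, log-normal-fit-compatible dwell
summaries, linear nonspecific accumulation, ~10%/30 min
translation-irrelevant loss, multi-dye step amplitudes, and a
seconds-scale baseline rise. It does not emulate several features of
real recordings: EMCCD gain-register noise, fluorophore blinking,
per-codon elongation stochasticity (dwell dispersion), sequence-specific
pausing, or mechanistic 43S scanning. Green tests therefore certify
that the estimators recover the parameters of data generated under the
stated assumptions — they cannot certify those assumptions for any
particular extract or optical setup.

# Known limitations

* First-arrival fitting excludes censored molecules rather than using a
  censoring-aware likelihood; with long acquisitions the censored
  fraction is small, but short windows will bias the tail.
* Step calling assumes piecewise-constant intensity; slow focus drift
  within a dwell can split levels.
* Simultaneous events within one frame merge (counting, not pairing, is
  affected).
* The 5′-end clearance rule for re-initiation is an assumption exposed
  as configuration; inferences about inter-initiation kinetics inherit
  it.
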