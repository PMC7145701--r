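# nascentTrack

Single-molecule fluorescence analysis of eukaryotic cap-dependent
translation kinetics.

## The problem

Initiation is the rate-limiting, most heavily regulated step of
cap-dependent translation, yet classical bulk reporter assays only see the
convolved output of initiation, elongation and termination. An in vitro
single-molecule TIRF assay resolves individual initiation events: reporter
mRNAs carrying an N-terminal 3xFLAG tag are tethered by their 3′ ends to a
passivated surface, translation extract supplemented with Cy3-labeled
anti-FLAG is flowed in, and each antibody binding to a nascent tag appears
as an instantaneous fluorescence step on one mRNA; antibody departure at
peptide release appears as a step down.

Two per-molecule observables carry the kinetics:

- **first arrival time** `t1` — lag from completion of reagent exchange to
  the first antibody binding; `t1 = t1_I + t1_tag`, the first-round
  initiation time plus the time to translate the tag and the ~30–40
  tunnel-protected residues;
- **dwell time** `Δt` — duration of one antibody binding, a proxy for the
  total decoding time, giving the peptide chain elongation rate
  `nCodons / Δt`.

`nascentTrack` implements the full computational side of this assay for
R users: a ground-truth stochastic simulator of the experiment, the
imaging pipeline that turns TIRF movies into per-molecule traces, the
change-point event analysis that turns traces into kinetic observables,
and the distribution fits that turn observables into rate estimates.

## Models

- **Antibody recognition** of pre-exposed epitopes follows a
  double-exponential mixture
  `f(t) = A1/τ1 e^(−t/τ1) + A2/τ2 e^(−t/τ2)` (fast phase: tags already
  outside the exit tunnel; slow phase: tags requiring further elongation),
  fitted by maximum likelihood (or binned least squares) with bootstrap
  standard errors.
- **First arrivals** follow a shifted (3-parameter) log-normal with an
  additive floor for nonspecific binding:
  `y = y0 + A / (√(2π)·σ·(x−x0)) · exp(−(ln(x−x0)−μ)² / 2σ²)` for
  `x > x0`, fitted to histogram counts; the derived mean
  `x0 + exp(μ+σ²/2)` and mode `x0 + exp(μ−σ²)` are the comparison
  statistics between constructs (e.g. with and without a 5′ UTR hairpin).
- **Monosome dwell times** follow a log-normal; its mean converts to an
  elongation rate.
- Per-field quality metrics: binding-count time courses, the
  specific/nonspecific binding ratio (SNBR) at plateau, Kaplan–Meier
  survival of bound spots against translation-irrelevant loss, and the
  translational asynchrony profile (fractions of molecules initiating
  within consecutive windows of one mean elongation time).

## Worked example

```r
library(nascentTrack)
report <- runPipeline(list(seed = 8L, nMrna = 300L, nBoot = 100L))
```

which simulates 300 mRNAs under default (yeast-extract-like) conditions,
detects reagent-exchange time zero, calls binding/dissociation steps,
and fits both distributions. The printed summaries:

```
traces: 300  first arrivals: 299  censored fraction: 0.003
t1 fit: x0 = 123.1 s, mu = 5.58 , sigma = 0.68
   mean t1 = 456.5 +/- 39.4 s, peak = 291.4 +/- 17.5 s
dwell mean: 199.3 +/- 0.9 s; elongation 2.9 aa/s
asynchrony: 44%, 31%, 14% ; remainder 0%
```

Reading this: the fitted shift `x0 ≈ 123 s` recovers the generating
earliest-initiation lag (120 s); the mean first arrival of ~7.6 min vs. a
~3.3 min decoding time means early-starting mRNAs complete more than one
full round of synthesis before late starters begin — the asynchrony line
quantifies that (44% of molecules initiate in the first
mean-elongation-time window, 31% in the second, ...). The dwell fit
returns the simulator's exact binding-to-release time (199 s =
(574−57)/2.5 − mean recognition delay), and the derived rate is
`574 codons / 199 s ≈ 2.9 aa/s`.

Movie-level processing (`renderMovie`, `correctDrift`,
`subtractBackground`, `detectSpots`, `localizeSpot`, `extractTraces`) and
preset experiment archetypes (`generateFixtures`) are documented in the
vignette, and `inst/scripts/run_pipeline.R` wraps `runPipeline()` for
shell use.

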