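---
title: "Methods: internal-calibrator nanopore QC of cfDNA samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: internal-calibrator nanopore QC of cfDNA samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoporeQC)
```

## The assay and its model

Sequencing workflows need to know, before library preparation, how much
cell-free DNA (cfDNA) a plasma extract contains and how badly it is
contaminated by high-molecular-weight (HMW) genomic DNA released from lysed
leukocytes. A solid-state nanopore (a pulled glass nanopipette, tip diameter
roughly 6–19 nm, filled with a high-salt measurement buffer) counts
individual DNA molecules label-free: each translocation transiently blocks
the open-pore ionic current, and the blockage amplitude separates short
cfDNA-like fragments (~150 bp), a 1 kbp calibrator, and ~10 kbp HMW gDNA
into distinct populations.

The quantitative core rests on one physical assumption: **diffusion-limited
capture**, under which the event rate of each species is proportional to its
molar concentration and independent of fragment length. Spiking a 1 kbp
internal marker at a known concentration $C_M$ then turns measured event
frequencies into concentrations:

$$C_T = C_M \frac{f_T}{f_M}, \qquad
  \%\mathrm{cfDNA} = 100\,\frac{f_T}{f_T + f_{gDNA}},$$

where $f_T$, $f_M$ and $f_{gDNA}$ are the per-species event frequencies
(events/s). Frequencies are always computed over the *effective* duration —
recording time minus intervals during which the pore was clogged — so that
timed clogging rescales all counts equally and cancels from both metrics.
`estimateConcentration()` is therefore exactly invariant to any global
rescaling of the three frequencies, which is tested as a property.

## Pipeline stages and their parameters

**Pore geometry** (`conductanceFromGeometry()`, `diameterFromConductance()`).
The pore is a truncated cone with tip diameter $d_{tip}$ (nm) and half-cone
angle $\theta$ (degrees), in an electrolyte of conductivity $\sigma$ (S/m):
$G = [R_{cone} + R_{access}]^{-1}$ with
$R_{cone} = 4L/(\sigma \pi d_{tip} d_{base})$ and
$R_{access} = 1/(\sigma d_{tip})$. This is the standard glass-nanopipette
model; it is monotone in $d_{tip}$, so diameters are recovered from measured
open-pore conductances by a bracketed root search on
$[0.1\,\mathrm{nm}, 10\,\mu\mathrm{m}]$ (round-trip accurate to $10^{-6}$ nm).
The package deliberately ships **no default buffer conductivity**: $\sigma$
for the user's buffer must be supplied in the configuration, because treating
an invented value as ground truth would silently bias every diameter
estimate. Relative blockade depths shrink as the pore widens; the simulator
rescales species amplitudes by `amplitudeScale()` $= (d_{ref}/d_{tip})^2$
(cross-sectional exclusion; the exponent is a configuration knob). Both the
amplitude mean **and its standard deviation** are scaled, since the observed
shrinkage affects whole blockage distributions, not just their centres —
this keeps species separability pore-size invariant, which is what the
pore-robustness experiments show.

**Trace simulation** (`simulateEvents()`, `renderTrace()`). Species arrive as
independent homogeneous Poisson processes with rate
$\lambda_i = k \cdot c_i$; the capture-rate constant defaults to
$k = 0.02\ \mathrm{events\,s^{-1}\,pM^{-1}}$ so a 30-min recording of a
100 pM species yields ~3600 events — enough for stable mixture fits at desk
scale. Amplitudes are Normal (truncated at zero) and dwells log-normal; the
default three-species panel (`defaultSpeciesPanel()`: 60/160/380 pA means at
the 10 nm reference pore) is a **synthetic fixture** chosen for clear
histogram separability — no measured amplitudes, dwell statistics or event
rates are claimed, and every recovery test is defined against the injected
truth rather than against unpublished magnitudes. Continuous traces are
rendered at 100 kHz sampling with a low-pass at 5 kHz by default (the
patch-clamp acquisition regime): rectangular pulses are subtracted from the
open-pore level, convolved with a Gaussian FIR kernel whose −3 dB point sits
at the cutoff, and i.i.d. Gaussian noise (default 6 pA) is added. The
Gaussian kernel is used rather than a Butterworth design because its step
response is monotone, like the Bessel filters used in patch-clamp
amplifiers; a 4-pole Butterworth overshoots a long pulse's depth by ~11%,
which would corrupt amplitude truth. Clogs are simulated as marked intervals
that capture no events and render as a deep depressed plateau.

**Event detection** (`estimateBaseline()`, `detectEvents()`, `flagClogs()`).
The baseline is a two-pass running median (default window 501 samples):
candidate event samples (3 MAD-sigma below the first pass) are interpolated
away before the second pass, and the noise level is 1.4826 × the MAD of
event-free residuals. Because a running median tracks any depressed plateau
longer than half its window, sub-baseline runs at least one window long —
judged against a first-difference noise scale, which plateaus cannot
inflate — are masked *before* the first pass; this keeps the baseline on
the open-pore level across arbitrarily long clogs while leaving ordinary
events to the two-pass logic. Detection uses a hysteresis threshold: open at
`kSigma` (default 5) noise-sigmas below baseline, close on return above
1 sigma; the amplitude is baseline minus the minimum current in the event,
which is robust for short filter-attenuated pulses. Events shorter than
`minDwell` (default 100 µs, ≈ two filter-limited rise times at 5 kHz) are
discarded; excursions longer than `maxBlockDuration` (default 1 s, orders of
magnitude above any plausible dwell) are reclassified as clogs and excluded
from the effective duration. All of these are configuration knobs: the
original extraction script for this kind of data is unpublished, so the
detector is the standard resistive-pulse design, validated against oracle
traces rather than against any particular script.

**Mixture fitting** (`fitMixture()`, `selectComponents()`,
`labelComponents()`). A 1-D Gaussian mixture is fitted to the *raw* (never
binned) amplitude sample by EM with 10 k-means++-seeded restarts,
convergence at a log-likelihood gain below $10^{-6}$, and an sd floor of
$10^{-3}$ pA (collapsed restarts are discarded; histograms are for display
only, Freedman–Diaconis binning). Per-species counts are **soft counts** —
sums of posterior responsibilities, i.e. the area under each fitted Gaussian
in event units — which degrade gracefully under component overlap, unlike
hard assignment. The component count is chosen by BIC
($-2\ell + (3K-1)\ln n$, ties to smaller $K$) over $K = 1..4$, because real
plasma samples can lack the gDNA population entirely; for mock samples with
three known species the order can be fixed at 3 via `fixK`. Labels follow
amplitude order (target < marker < gDNA) at $K = 3$; at $K < 3$ a marker
amplitude hint identifies the calibrator and absent roles get zero soft
count (a plasma sample with no gDNA component reports %cfDNA = 100); at
$K > 3$ the three largest components take the roles and the rest are flagged
unassigned. Fits are bit-for-bit reproducible given (data, $K$, seed). An
independent mixture implementation (mclust) is used in the test suite as a
cross-check of means and weights; it plays no role in the pipeline itself.

**Quantification** (`estimateConcentration()`, `estimatePercentTarget()`,
`molarToMassConcentration()`, `backCalculatePlasma()`). Besides the two QC
metrics, measured pM values convert to plasma-equivalent ng/mL via
$c \times \mathrm{bp} \times 650\ \mathrm{g\,mol^{-1}bp^{-1}} \times 10^{-6}$
and the sample-preparation chain (default: 40× dilution into the measurement
buffer, 55 µL eluate from 1 mL plasma, 100% assumed extraction recovery —
all overridable). With these defaults 10–200 pM of 150 bp fragments maps to
roughly 2–40 ng/mL of plasma cfDNA.

**Uncertainty grid** (`chunkEvents()`, `assembleReplicates()`, `cvGrid()`).
Per-pore recordings are cut into 5-min chunks (half-open intervals; a
boundary event belongs to the later chunk). For each combination of pooled
pores (1–4) and acquisition time (5–30 min) — 24 combinations — replicates
are **disjoint consecutive chunk blocks** (n = 3 by default), mimicking
independent physical measurements; a seeded shuffle mode exists for
sensitivity checks, and a bootstrap would correlate replicates, so it is not
the default. Each replicate runs the full mixture + quantification pipeline
and the cell reports $\mathrm{CV} = 100\,\sigma/\mu$ for both metrics. CV
decreases along both axes on average because the estimator variance shrinks
roughly as $1/\sqrt{N}$ in the pooled event count. (One caveat surfaced
rather than resolved: prose summaries of such experiments sometimes state
the pore-count trend in opposite directions; this package follows the
event-count argument — more pooled data, lower CV.)

## What the simulations do and do not show

The simulator reproduces the *statistical* structure of the experiments:
Poisson arrivals proportional to concentration, pore-size amplitude scaling,
filter attenuation, clogging data loss. It does **not** model folded or
partial translocations, 1/f noise, electrode drift, pore-to-pore amplitude
idiosyncrasies beyond diameter scaling, or inter-molecular interactions.
Passing recovery tests therefore demonstrates that the pipeline is an
unbiased, low-variance estimator *under the stated capture model* — not that
any particular physical device satisfies that model. The simulated CV values
(a few percent at 30 min) are accordingly lower bounds: real measurements
add pore-fabrication and sample-handling variability on top of counting
statistics, so simulated CVs sit well inside experimentally reported bounds
(< 15% across pore sizes, < 10% when pooling four pores at 30 min).

## Numerical choices and degenerate inputs

Desk-scale problem sizes: 30-min event streams (~10⁴ events) for recovery
checks, 90-min stores for the 24-cell grid, n = 3 replicates — all generated
in seconds at event level; continuous traces are rendered only for short
detector tests. EM caps at 150 iterations per restart (the separable
fixtures converge far earlier; the cap bounds the flat-likelihood case when
$K$ exceeds the true order). A constant trace yields a machine-epsilon noise
floor and a `degenerate` flag instead of an error; an all-clogged recording
has zero effective duration and frequency computation refuses it explicitly;
a missing marker component raises an error pointing at the hint mechanism
rather than returning a division by zero. Event-table, trace and
configuration files are plain delimited text/YAML and round-trip losslessly.
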