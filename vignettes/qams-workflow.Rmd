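---
title: "Single-marker multi-component quantification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker multi-component quantification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamskit)
```

## The problem and the model

Quality control of herbal preparations routinely requires quantifying
half a dozen marker compounds per batch. Quantifying each against its own
reference standard (the external-standard, ES, route) is accurate but
expensive: some standards are costly or hard to source. The single-marker
strategy (QAMS, *quantitative analysis of multi-components by single
marker*) buys all analytes with one standard. One cheap, stable compound
— here gallic acid — is calibrated conventionally; every other analyte
$k$ is tied to it through a **relative correction factor**

$$ f_{s/k} \;=\; \frac{W_k\,A_s}{W_s\,A_k}, $$

where $A_s, W_s$ are the internal reference's peak area and concentration
and $A_k, W_k$ the analyte's, all measured in the same standard
injection. In a sample run, the analyte's concentration follows from the
reference's measured concentration $C_s$ and the two sample areas:

$$ C_k \;=\; f_{s/k}\; C_s\; \frac{A'_k}{A'_s}. $$

Because $f_{s/k}$ is a ratio of areas from one injection, any factor
common to both areas — injection volume, detector gain, flow-driven
dilution — cancels. That is the method's central assumption and its main
robustness argument, and it is what `multipoint_rcf()` exploits: the RCF
is measured at several injection volumes (3, 5, 10, 15, 20 µL by
default) and summarised by its mean and relative standard deviation; a
small RSD across volumes is direct evidence that the cancellation holds.

With only one standard on hand, the analyte peaks cannot be identified
by spiking. The **relative retention time** $Rt_R = t_{Rk}/t_{Rs}$
localizes them instead: it is invariant under a common rescaling of the
time axis, which is the dominant drift mode when flow rate or instrument
change. `compare_localization_methods()` quantifies this against the
alternative (absolute retention-time differences, invariant under
additive shifts only); under the simulated mixed-drift conditions the
ratio method wins for every analyte.

Accuracy is audited by running both routes on the same batches and
reporting the signed relative error $RE = (ES - QAMS)/ES \times 100$,
with the convention that the internal reference itself — quantified by ES
on its own curve — carries no RE value.

## What the simulator emulates, and what it does not

`simulate_chromatogram()` generates one detector channel as

$$ y(t) = b\,t + \varepsilon(t) + \sum_k A_k\, h_k(t), $$

with linear baseline drift $b$, i.i.d. Gaussian noise
$\varepsilon \sim N(0, \sigma_n^2)$ per sample, and one exponentially
modified Gaussian (EMG) per analyte. The EMG is the standard empirical
shape for tailed liquid-chromatography peaks and collapses to a pure
Gaussian at `tau = 0`. Two implementation details matter:

* the EMG is evaluated in log space so small tail constants do not
  overflow, and
* the peak is shifted so that its *mode* (not the EMG location
  parameter) sits at the configured retention time; the apex invariant
  therefore holds for tailed peaks too.

Each peak's true area is `concentration x injection_volume x
response_factor`, which makes the generator exactly linear in
concentration and volume — the two properties the RCF algebra relies on
— and gives every downstream stage a known ground truth. Each
`(seed, channel)` pair has its own random stream, so channels are
reproducible independently and a negative control that omits analytes
consumes the identical stream as the full run (omitting nothing
reproduces it bit for bit).

The simulator deliberately does **not** model: retention mechanics of
the gradient program (retention times are configuration inputs), detector
saturation, peak fronting beyond the EMG tail, correlated (1/f) detector
noise, matrix interferents, or injection-to-injection volume
imprecision. Consequently, replicate RSDs on large synthetic peaks are
much smaller than a real autosampler would give; the validation battery
exercises the statistics, not the full error budget of a wet-lab assay.
Passing tests demonstrate the correctness of the computations and their
behaviour under the stated noise model — not instrument performance.

## Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `sampling_rate` | 5 Hz | ~35 samples across the narrowest half-height width; trapezoid error far below the 0.1% area tolerance |
| `noise_sd` | 0.2 response units | puts the lowest standards of the dilution series at S/N ≈ 20–30 and the computed LODs at the same order (0.004–0.02 µg/mL) as the 0.01–0.11 µg/mL band of the shipped calibration table |
| `baseline_drift` | 0.02 units/min | visible but small relative to peaks; exercises the baseline estimator |
| `retention_jitter_sd` | 0.01 min | run-to-run apex scatter well inside the matching tolerance |
| `rtr_tolerance` | 5% relative | an order of magnitude above the observed relative-retention scatter (< 0.3% RSD in the robustness grid), with margin for drift |
| `min_snr` (detection) | 10 | the quantification-limit criterion; below it an apex is indistinguishable from a baseline excursion, and a spurious noise apex adjacent to a real peak truncates its tail at their shared valley |
| validation thresholds | 2.0% RSD; recovery 95–105%; robustness 2.27% | derived from the achieved values of the reference study the shipped tables summarise; they are reporting thresholds, not prescriptive acceptance limits |

Analyte defaults: the six-compound panel monitors matrine, oxymatrine
and catechin at 210 nm, gallic acid at 225 nm, rutin at 256 nm and
ferulic acid at 320 nm, with stock concentrations matching the shipped
dilution scheme. Retention times are free parameters chosen to give
well-separated peaks in that elution order within a 53-min run. Response
factors default to the shipped calibration slopes divided by the 5 µL
injection volume, so a simulated calibration recovers those slopes. Note
that the shipped RCF table (an independent measurement series) implies
slightly different response *ratios* than the calibration slopes do; the
two tables are internally inconsistent and both are kept exactly as
printed. Simulation-based checks are therefore property-based
(self-RCF ≡ 1, scale invariance, closed-loop identity, ES/QAMS
agreement) rather than attempts to reproduce the printed RCF values from
simulated chromatograms; the printed RCF summaries are instead
recomputed directly from the shipped per-injection values, which they
match exactly at two decimals.

## Numerical choices

**Baseline and noise.** The baseline is a 2-min running median — robust
to peaks much narrower than the window, able to follow slow drift.
Noise is the standard deviation of the corrected signal over a declared
peak-free window (first 0.5 min by default).

**Peak bounds and integration.** Apexes are local maxima of the lightly
smoothed corrected signal above `min_snr` × noise; shoulder maxima not
separated from a taller neighbour by a valley of at least three noise
s.d. are merged into it. Bounds extend to the enclosing baseline
crossing, at least ± 3 half-widths (≈ ±7σ for a Gaussian, < 0.002% area
loss), and never past a valley shared with an overlapping neighbour.
Integration is trapezoidal on the baseline-corrected trace minus the
chord between the bound levels, each bound level taken as a median over
a 0.1-min window so the chord is not anchored on single noisy samples;
areas are reported in response·seconds. A negative area (possible on
pure noise) is clipped to zero and flagged, and zero-area artifacts are
dropped before peak assignment.

**System suitability.** Plates use the half-height formula
$N = 5.54\,(t_R/W_{1/2})^2$ and resolution uses base widths
$1.699\,W_{1/2}$ — both the common pharmacopoeial Gaussian conventions;
the underlying reference states no formula variant, so the choice is
recorded here as an assumption.

**Calibration.** Unweighted ordinary least squares of area on
concentration; `r` is the Pearson correlation (the reference table's
column is treated as `r` despite its heading naming the coefficient of
determination — its printed values, e.g. 0.9998, are correlation-sized).
LOD and LOQ come from the S/N = 3 and 10 criteria via the noise s.d. and
the height-per-concentration of the lowest standard, so LOQ/LOD = 10/3
identically. Predictions outside the fitted range are flagged with a
warning but returned: the shipped content table itself contains such
values, and several stock/range pairings in the shipped tables are
mutually inconsistent (only the matrine pair is self-consistent, and it
anchors all numeric checks).

**Localization.** Greedy best-first matching of observed to expected
relative retention, each peak used at most once, ties broken to the
earlier-eluting peak; unmatched targets are reported absent rather than
raising an error, which is exactly the desired behaviour on negative
controls.

**Statistics.** All RSDs use the sample (n−1) standard deviation —
this convention reproduces the shipped RCF table's RSD row at two
decimals. RE uses the (ES − QAMS)/ES sign convention, which reproduces
every printed RE cell including signs. Values are carried at full
precision internally and rounded only for reporting.

## The robustness grid

`run_pipeline()` probes RCF reproducibility over four condition axes
(two instruments, three columns, three flow rates, three column
temperatures). A condition change is modelled as a joint rescaling of
all peak areas (s.d. 1%, the injection/flow/detector part that the RCF
ratio cancels) times a four-fold smaller analyte-specific selectivity
residual (the part it cannot cancel), plus a per-condition time-axis
scale and offset. Under this model the maximum RCF RSD stays well under
the 2.27% reporting threshold while absolute retention times move by
up to ±25% on the flow axis — which is what makes the localization
comparison decisive in favour of relative retention.

## Problem sizes

The test suite and the acceptance script run the study at its stated
design: a 53-min run sampled at 5 Hz, six calibration levels, five
injection volumes, five batches, six replicates per validation stage and
an 11-condition robustness grid; the full pipeline completes in well
under two minutes on one CPU. Unit tests use a three-analyte short-run
panel where the full geometry is not needed.

## Known limitations

* The stability stage defaults to no degradation (the replicate noise
  model only); a linear loss rate can be configured but no kinetic model
  is fitted.
* Overlapping peaks are split at the shared valley, not deconvolved;
  severely fused peaks will bias both areas.
* LOD/LOQ derive from the lowest standard's height-per-concentration;
  with a strongly nonlinear detector at trace level they would be
  optimistic.
* The RCF is wavelength-specific and assumed transferable only at the
  analyte's assigned channel; cross-wavelength transfer is out of scope.
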