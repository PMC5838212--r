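---
title: "Methods: EV miRNA cargo enrichment, seed-site targeting, and MEA activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EV miRNA cargo enrichment, seed-site targeting, and MEA activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evcargo)
```

# Scope

`evcargo` implements the computational core of a common experimental design
in glia-neuron signalling: astrocytes are stimulated (ATP, IL-1b, TNFa),
the extracellular vesicles (EVs) they release are profiled for miRNA cargo
on a hybridization counting platform, candidate miRNAs are validated by
qRT-PCR and tied to target mRNAs through 3'-UTR seed sites, and the
functional consequence for neurons is read out as spike and burst activity
on multielectrode arrays (MEAs). Every stage consumes data a wet lab would
produce; because such studies rarely deposit raw data, each stage also has
a synthetic generator with known ground truth, and the test suite runs the
pipeline end to end against that truth.

# miRNA cargo enrichment

## Normalization model

Raw probe counts are modeled as `mu_ij = m_i * f_j`, where `m_i` is the
abundance of miRNA `i` and `f_j` a per-sample technical factor (input
amount, hybridization efficiency). Two corrections are applied in order:

1. **Spike-in normalization** (`spikein_normalize()`): the positive-control
   spike-in probes measure `f_j` directly, so each sample is rescaled by
   `g / s_j`, with `s_j` the sample's positive-control sum and `g` the
   geometric mean of all `s_j`. The geometric mean is the natural center
   for multiplicative factors; an arithmetic-mean variant would weight
   high-input samples more. After scaling, all positive-control sums are
   equal (to `g`) by construction.
2. **Quantile normalization** (`quantile_normalize()`): all samples are
   forced onto the common distribution whose rank-`r` value is the mean of
   the samples' rank-`r` values. Ties within a sample receive the mean of
   the reference values at the tied ranks, which makes the result
   deterministic and independent of input order. Note a subtlety: with
   ties present, tie-averaging necessarily replaces distinct reference
   values by their mean, so the "identical sorted multiset" property holds
   exactly only for tie-free (continuous) columns; the column *total* is
   preserved exactly in all cases, and the tests assert each invariant on
   the data class where it holds.

Control probes measure technique, not cargo, so only endogenous probes
enter quantile normalization, fold changes, and clustering; control rows
are carried through at their spike-in-normalized values.

## Enrichment rule

Fold change per miRNA and stimulus condition is the ratio of mean
normalized counts (condition over baseline, replicates averaged). A
pseudocount of 0.5 enters numerator and denominator only when the baseline
mean is exactly zero, leaving all other ratios untouched. A miRNA is
called *enriched* at fold change >= 1.5, inclusive at the boundary. The
threshold, the baseline label, and the pseudocount are arguments, not
constants.

Detection of "expressed" miRNAs (`detect_mirnas()`) is deliberately
simple: above the within-sample negative-control mean plus 2 SD in at
least one sample. Counting platforms do not fix this rule; multiplier and
sample count are exposed and recorded in the result's attributes.

## Clustering

`cluster_heatmap()` reproduces the standard display: log2 of per-condition
median normalized counts (median across replicates; a single replicate is
its own median), pseudocount 1 before the log, Euclidean distance,
complete linkage. Distance and linkage are arguments because heatmap
conventions differ between labs; the defaults match the common R heatmap
tooling.

## qRT-PCR validation

`ddct_relative_expression()` implements relative quantification:
`dCt = Ct(target) - Ct(housekeeping)` averaged within group,
`ddCt = dCt(treated) - dCt(calibrator)`, relative expression `2^-ddCt`.
The simulator plants a fold change by shifting the treated target Ct by
`-log2(fc)`, so at zero noise the closed form returns the planted value
exactly — this is the oracle the tests assert against.

# Synthetic count design and its calibration

The generator (`simulate_counts()`) draws endogenous counts from a
negative binomial with variance `mu + phi * mu^2`; `phi = 0` degenerates
to the exact means, which gives the test suite a noise-free identity case.
Positive controls are a fixed six-step ladder scaled only by the
per-sample factor; negative controls sit at a low fixed mean (10 counts).

The reference design (`default_cargo_design()`) fixes the study
conditions: 131 endogenous miRNAs, conditions `ADEV-CR` (constitutive
release, the baseline) plus three stimuli, and 7 / 10 / 15 miRNAs planted
as enriched at fold changes 2.5-4 with dispersion 0.05 and spike-in
factors in [0.7, 1.3]. Baseline abundances are log-normal
(`meanlog = log 200`, `sdlog = 1.2`), spanning roughly two orders of
magnitude as hybridization panels do.

Two choices came out of an explicit design analysis and deserve emphasis:

* **Planted miRNAs are drawn from the 5th-85th expression percentile.**
  Quantile normalization maps values through ranks; a fold change planted
  in the top-ranked probe cannot raise its rank, so rank-based
  normalization erases it entirely. This is a real property of quantile
  normalization, not an artifact of the simulator, and it is the reason
  enrichment of the very highest-expressed species is invisible to this
  normalization scheme.
* **Replicate counts were set by power analysis.** Quantile normalization
  under a one-directional shift (only enriched probes, only in stimulated
  samples) compresses a true fold change of 2.0 to roughly 1.75 when 20 of
  131 probes shift at once. With NB dispersion 0.05 the per-sample CV is
  about 22%, so exact recovery of the full planted set against a 1.5-fold
  cutoff needs the standard error of the mean ratio to be small: the
  recovery study uses 48 replicates per condition (20 planted miRNAs split
  7/6/7 across the three stimulus conditions, which matches the multi-
  condition structure of real designs and keeps the per-condition
  distortion small), and the reference design uses 12 replicates, which
  its larger planted fold changes (>= 2.5) tolerate comfortably. These
  numbers describe what the synthetic study needs for near-certain exact
  recovery; a wet-lab NanoString experiment with one pooled sample per
  condition cannot distinguish fold changes this close to the cutoff, and
  passing tests here should not be read as evidence that it could.

What the generator does **not** model: probe-specific hybridization
chemistry, ligation bias, cartridge lane effects, or correlated miRNA
abundances. Passing recovery tests therefore demonstrates correctness of
the normalization and calling arithmetic under overdispersed counting
noise, not robustness to platform-specific artifacts.

# Seed-site scanning

Canonical site types follow the standard taxonomy. With the UTR written
5'->3' and the miRNA pairing antiparallel (miRNA position 1 opposite the
3'-most site position):

| type    | UTR match                                   | length |
|---------|---------------------------------------------|--------|
| 6mer    | reverse complement of miRNA nt 2-7          | 6      |
| 7mer-A1 | 6mer + `A` at the 3' end                    | 7      |
| 7mer-m8 | reverse complement of miRNA nt 2-8          | 7      |
| 8mer    | 7mer-m8 + `A` at the 3' end                 | 8      |

A match whose interval is contained in a longer-type match at the same
locus is subsumed ("longest type wins"). Scanning is exact string matching
on the sense strand; U and T are interchangeable, IUPAC ambiguity codes
are rejected rather than wildcard-matched. Mature miRNA sequences are
inputs, never embedded constants. Conservation scoring is out of scope:
no alignments are defined as inputs.

`disrupt_site()` models the two-nucleotide mutants used in luciferase
reporter assays: it substitutes (by deterministic transversion,
`A<->C` / `G<->T`) positions chosen from the center of the 6mer core
outward, then verifies by re-scanning that no site of any type survives
overlapping the original interval, trying alternative position sets and
the second transversion alphabet in a fixed order should a substitution
accidentally create a shifted site. Every site type contains the 6mer
core, so any core mutation breaks all types at that register; the rescan
guards against new sites appearing in a shifted register. Sequence length
is always preserved and exactly `n_mut` characters change.

`simulate_utr()` plants exact site strings into a random background and
then *screens* the background: any accidental site for a planted miRNA is
patched by a transversion outside the planted intervals, iterating until
a clean scan. The planted truth is therefore exhaustive, which is what
makes "scan finds exactly the planted sites" a valid assertion.

# MEA activity

## Filtering

A second-order Butterworth filter with 200 Hz cutoff is applied before
detection. The direction is high-pass: spike energy lives around
0.3-3 kHz, and removing the sub-200 Hz band strips drift and field
potentials while leaving spike waveforms nearly untouched (a 200 Hz
*low-pass* would remove the spikes themselves; the low-pass option exists
behind `filter_spec(type = "low")` for completeness). Filtering is
zero-phase (forward-backward) by default so spike timing is preserved;
this squares the magnitude response, which the tests account for. The
single-pass response is verified against the analytic second-order
high-pass curve `(f/fc)^2 / sqrt(1 + (f/fc)^4)` at `f/fc` from 0.1 to 10.

## Spike detection

The noise SD is estimated robustly as `median(|x|) / 0.6745` (the Gaussian
quantile estimator), because the plain SD is inflated by the spikes it is
supposed to threshold; the plain estimator remains available and the
choice is recorded in the spike train. Spikes are absolute-value threshold
crossings at `k = 5` SDs (polarity configurable), timestamped at the first
suprathreshold sample, with a 1 ms dead time so one biphasic waveform is
counted once. The dead time is a detector property, not a biological
refractory claim.

At `k = 5` on pure Gaussian noise the expected false-positive rate at
these trace lengths is well under 2 events per minute, and the simulated
10-SD spikes are recovered with recall and precision above 0.95 at
+/-0.5 ms — both asserted in the acceptance tests.

## Bursts, QC, rates

Bursts are maximal runs of at least 4 spikes whose consecutive inter-spike
intervals are all <= 100 ms. The implementation (run-length encoding over
the ISI sequence) is checked against an exhaustive oracle that enumerates
candidate subintervals directly. Electrodes enter analysis only with
baseline noise < 50 uV (interpreted as the SD-like noise estimate;
a peak-to-peak criterion would use a different limit) and spontaneous
activity >= 0.1 spikes/s — the activity floor is a package default, since
"shows spontaneous activity" is qualitative.

Spike rate is spikes/s, burst rate bursts/min. Post-treatment activity is
expressed as percent of the pre-treatment (baseline) rate per electrode;
electrodes with a zero baseline rate are flagged and excluded from
normalized statistics rather than silently dropped. The pre/post
comparison is a standard two-sided paired t test on per-electrode rate
differences, implemented in closed form so the zero-variance edge cases
(identical rates: t = 0, p = 1; constant nonzero shift: degenerate,
flagged) are reported rather than raised as errors.

The trace simulator plants a biphasic 1 ms waveform (amplitude expressed
in units of the noise SD) at Poisson background times plus burst clusters
of 4-8 spikes with 20-50 ms intra-burst intervals; background spikes
colliding with another spike within the detector dead time are dropped
from the truth so recall is well-defined. It does not model electrode
drift, waveform diversity across units, or overlapping spikes — so the
detection tests certify the thresholding logic, not spike sorting.

# Group statistics

`one_way_anova()` and `tukey_hsd()` wrap the standard R fits
(`lm`/`anova`, `aov`/`TukeyHSD`) behind a tidy interface with explicit
precondition checks (>= 2 groups, >= 2 units each) and a degeneracy flag
for zero within-group variance. Unbalanced designs get the Tukey-Kramer
harmonic-mean adjustment, which is what `TukeyHSD` computes. No normality
pre-tests are run; the layer mirrors the conventional ANOVA + Tukey
analysis exactly. The tests verify the sums-of-squares identity against a
closed-form oracle, the `t^2 = F` identity for two groups, and the
reduction of two-group Tukey to the pooled t test.

# Problem sizes and reproducibility

All simulations are seeded; a single master seed fans out to per-stage
seeds through a counter so stages can be reproduced independently
(`run_demo()` writes its resolved configuration and a byte-stable JSON
report). Default problem sizes — 131 probes with up to 192 samples for the
recovery study, 60 s of 25 kHz trace per detection check, 1000 random
trains for the burst oracle, 200 random 2 kb UTRs for the scan oracle —
were chosen so the full suite exercises every claim in minutes on a single
core while keeping Monte Carlo margins wide.

# Known limitations

* Fold-change calling is a ratio rule, not a count model; no variance
  shrinkage, no testing against dispersion. This mirrors the analysis the
  package implements rather than best differential-expression practice.
* Quantile normalization assumes most features unchanged; under strong
  asymmetric cargo changes it biases fold changes toward 1 (quantified
  above) and erases changes at the extreme top rank.
* The seed scanner is match-based only: no pairing thermodynamics, no
  3'-supplementary pairing, no repression prediction.
* The MEA layer detects threshold crossings; it does not sort units, and
  the connectivity/synchrony of networks is out of scope.
* Trace input is long-format CSV (plus in-memory objects); binary
  acquisition formats are expected to be exported upstream.
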