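# evcargo

Astrocytes respond to inflammatory and purinergic stimulation (IL-1b,
TNFa, ATP) by releasing extracellular vesicles (EVs) whose microRNA cargo
differs from constitutively released EVs — and that cargo can silence
neuronal transcripts and dampen network activity. `evcargo` implements the
complete computational side of such a study as a tested, reusable R
pipeline, for analysts working with hybridization-based miRNA counting
(NanoString-style), qRT-PCR validation, 3'-UTR target-site analysis, and
multielectrode-array (MEA) electrophysiology.

Four analysis layers, each with a synthetic generator providing known
ground truth:

1. **miRNA cargo enrichment** — positive-control spike-in scaling (each
   sample scaled by `geomean(s) / s_j` of its positive-control sum),
   quantile normalization with a deterministic tie rule, fold change
   `FC_i = mean(condition_i) / mean(baseline_i)`, and enrichment calling
   at `FC >= 1.5` (inclusive). Plus detection against negative-control
   background (mean + 2 SD), log2-median hierarchical clustering for
   heatmaps, and `2^-ddCt` relative quantification for qRT-PCR.
2. **Seed-site scanning** — canonical 6mer / 7mer-A1 / 7mer-m8 / 8mer
   sites (exact reverse-complement matches to miRNA nt 2-7/2-8, with the
   A1 adenosine for A1 types; longest type subsumes), and two-nucleotide
   site disruption that provably abolishes the site on rescan, as used in
   luciferase reporter mutants.
3. **MEA activity** — second-order 200 Hz high-pass Butterworth filtering
   (zero-phase by default), robust noise estimation `median(|x|)/0.6745`,
   spike detection at 5 noise SDs with a 1 ms dead time, burst clustering
   (>= 4 spikes, consecutive inter-spike intervals <= 100 ms), electrode
   QC (< 50 uV noise, spontaneous activity), 0.2 s raster binning,
   percent-of-baseline rate normalization, and paired pre/post t tests.
4. **Group statistics** — one-way ANOVA with Tukey HSD post hoc
   comparisons (Tukey-Kramer for unbalanced groups) over per-unit
   measurements such as dendrite morphometrics.

## Worked example

Simulate the reference study design (131 miRNAs, baseline `ADEV-CR` plus
three stimulus conditions, 7/10/15 miRNAs planted as enriched), then run
normalization and enrichment calling:

```r
library(evcargo)

design <- default_cargo_design(seed = 1)
sim <- simulate_counts(design$n_mirnas, design$conditions, design$truth)
sim$matrix
#> mirna_counts: 145 probes (131 endogenous, 6 pos ctrl, 8 neg ctrl) x 48 samples [raw]
#> conditions: ADEV-CR, ADEV-ATP, ADEV-IL1b, ADEV-TNFa

norm <- quantile_normalize(spikein_normalize(sim$matrix))
enr <- call_enriched(fold_change(norm, design$baseline), threshold = 1.5)
head(enr, 5)
#>     mirna condition fold_change
#> 1 miR-086  ADEV-ATP    3.662164
#> 2 miR-080  ADEV-ATP    3.612227
#> 3 miR-050  ADEV-ATP    2.905352
#> 4 miR-025  ADEV-ATP    2.683707
#> 5 miR-053  ADEV-ATP    2.676578

vapply(enriched_sets(enr), length, integer(1))
#>  ADEV-ATP ADEV-IL1b ADEV-TNFa
#>         7        10        15
```

The called sets equal the planted sets exactly: 7, 10, and 15 enriched
miRNAs, each with its estimated fold change versus constitutive release
(estimates sit slightly below the planted 2.5-4 because rank-based
quantile normalization compresses one-sided changes; see the methods
vignette).

The MEA layer, on a simulated 60 s recording:

```r
tr <- trace_sim_truth(duration = 60, n_electrodes = 1, seed = 99)
rec <- filter_trace(simulate_recording(60, 1, tr)[[1]])
train <- detect_spikes(rec, k = 5)
bursts <- detect_bursts(train)
#> detected 195 spikes (194 planted), 9 bursts (10 planted)
```

Spike recovery is essentially exact (one extra event is a noise
crossing); two planted bursts bridged by a background spike merge into
one maximal run, which is the defined behaviour of the inter-spike
interval rule.

`run_demo(seed, out_dir)` chains every stage — counts, UTR scan and
disruption, MEA pre/post comparison, ddCt, ANOVA — writes all outputs
with sidecar ground-truth JSON and a resolved `config.yaml`, and returns
a report whose `status` is `"PASS"` when every stage recovered its
planted truth. A thin wrapper lives in `inst/scripts/run_demo.R`.

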