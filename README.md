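# histurnover

Histone PTM relative abundance and turnover from metabolic-labeling mass
spectrometry.

## The problem

Histone post-translational modifications (PTMs) shape chromatin
accessibility, but measuring which chromatin state a PTM — or a
*combination* of PTMs — lives in normally requires an antibody per mark.
If cells are instead grown briefly in medium spiked with a
stable-isotope-labeled amino acid (SILAC-style, e.g. ~5× heavy arginine),
histones synthesized after the spike are heavy, and for every histone
proteoform the **heavy fraction**

```
f = heavy / (light + heavy)
```

of its extracted-ion-chromatogram (XIC) signal measures the nucleosome
turnover of the chromatin carrying that proteoform: high on actively
transcribed, accessible chromatin; low on silenced heterochromatin.
Because the label sits on the sequence rather than the modification, the
readout works for any PTM or PTM combination the mass spectrometer can
resolve.

`histurnover` is for proteomics/epigenetics analysts who have per-analyte
XIC tables (bottom-up DIA or middle-down precursor traces) and want the
full downstream chain, plus seeded synthetic data with known ground truth
to validate it end to end.

## What it computes

* **Mass chemistry** — propionyl derivatization rules (free/me1 lysines +
  N-terminus), monoisotopic proteoform masses, m/z, isotope-label deltas
  (R10 = 10.0083 Da), near-isobaric classification (ac 42.0106 vs me3
  42.0470 Da), and the intact-tail methyl-equivalent m/z ladder.
* **Labeling stoichiometry** — the unlabeled-vs-labeled amino-acid budget
  of a labeling culture, and the replication-dilution expectation
  `1 − 2^(−cycles)`.
* **Bottom-up quantification** — per-proteoform relative abundance within
  its backbone family (total area of all modified forms = 100%) and heavy
  fraction; positional isomers (K9ac vs K14ac) resolved by averaging
  per-fragment-ion ratios from DIA fragment tables.
* **Middle-down quantification** — intact H3 1–50 tails at 8+, extracted
  at 10 ppm over 0–15 methyl equivalents: per-state heavy fractions and
  the abundance distribution over equivalents.
* **Statistics** — Welch (heteroscedastic) two-tailed t-tests with strict
  star thresholds, Pearson correlations, day-to-day correlation,
  abundance-vs-labeling fold-change scatter with a dynamic-range ratio,
  and a replicate-precision (CV) contrast.
* **Genomic overlap metrics** — BED3/BED6 in/out; percent of peaks with a
  ≥ 1 bp intersection, percent of peak bp covered by reads, reads/100 bp,
  TSS −3 kb/+2 kb promoter windows.
* **Synthetic data** — seeded generators for co-eluting Gaussian
  light/heavy XIC pairs, whole runs with ground truth, isobaric fragment
  mixtures, middle-down ladders, and interval sets with a controlled
  overlap fraction.

## Worked example

```r
library(histurnover)

## 1. Is the labeling medium right?
media_stoichiometry(media_params())
#> Labeling stoichiometry
#>   unlabeled in proteome :     70 ug
#>   unlabeled in medium   :    200 ug
#>   total unlabeled       :    270 ug
#>   heavy label added     :   1.06 mg (1.06 mg/mL)
#>   heavy/light molar     :   5.01x
```

With ~70 µg of unlabeled arginine locked in the harvested proteome and
200 µg in the medium (270 µg total) against ~1 mg of heavy arginine, the
medium holds a ~5× molar excess of label, and `expected_new_fraction(1)`
(= 0.5) says an ideal culture reaches 50% labeling after one cell cycle.

```r
## 2. Simulate a study and quantify it
pan   <- default_panel()                      # 23 H3/H4 proteoforms
cfg   <- sim_config(seed = 1)                 # 3 days x 3 replicates
run   <- simulate_run(default_truth(panel = pan), cfg, pan)
quant <- quantify_run(run, pan, cfg)

wt <- quant[quant$condition == "WT" & quant$day == 2, ]
aggregate(heavy_fraction ~ proteoform_id, wt, mean)   # day-2 labeling
#>    proteoform_id heavy_fraction heavy_pct
#>   H3_27_40_K27ac      0.6678321      66.8
#>  H3_27_40_K36me2      0.5853380      58.5
#>     H3_9_17_K9ac      0.4868325      48.7
#>     H3_3_8_K4me3      0.4364925      43.6
#>  H3_27_40_K27me3      0.2314694      23.1
```

The recovered day-2 heavy fractions of the five reference marks sit within
noise of their ground-truth values (66.5/58.2/48.4/43.6/23.5%): active
acetyl marks label fast, the repressive K27me3 slowly.

```r
## 3. Statistics
welch_t(wt$heavy_fraction[wt$proteoform_id == "H3_9_17_K9ac"],
        wt$heavy_fraction[wt$proteoform_id == "H3_9_17_K9me3"])
#> Welch t = 143.6, df = 3.92, p = 1.924e-08 ***

day_correlation(quant, 1, 2, condition = "WT")
#> [1] 0.9961992

fc <- fc_scatter(quant[quant$condition == "WT", ],
                 quant[quant$condition == "TRT", ])
attr(fc, "dynamic_range_ratio")
#> [1] 31.98008
```

K9ac labels significantly faster than K9me3; labeling is highly consistent
across days (r ≈ 0.997); and the abundance fold-change axis spans ~32× the
dynamic range of the labeling axis — the preset's constructed contrast,
recovered.

```r
## 4. Genomic validation metrics on BED input
sim <- simulate_intervals(1e4, n_a = 200, n_b = 100, target = 0.62, seed = 9)
peak_intersect_fraction(sim$a, sim$b)   # 62 (% of peaks with >= 1 bp overlap)
bp_coverage_fraction(sim$a, sim$reads)  # % of peak bp covered by reads
```

A thin command-line front end is installed at
`inst/cli/histurnover.R` (`run`, `simulate`, `quant-bu`, `quant-md`,
`stats`, `overlap`, `stoich` subcommands); `run_pipeline()` is the same
entry point as a function, driven by a YAML config, writing TSV tables
tagged with a config hash and a JSON run manifest.

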