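---
title: "Quantifying histone PTM abundance and turnover from metabolic-labeling MS: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone PTM abundance and turnover from metabolic-labeling MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histurnover)
```

## The measurement

Nucleosomes are evicted and replaced faster on transcriptionally active
chromatin than on silenced heterochromatin. If cells are grown in a medium
spiked with a stable-isotope-labeled amino acid (SILAC-style), histones
synthesized after the spike carry the heavy label, so the fraction of heavy
signal in a histone peptide's MS signal is a proxy for the turnover
("swapping rate") of the nucleosomes carrying that peptide. Because the
*sequence* is labeled rather than the modification, the same peptide
backbone observed in different modified forms (proteoforms) reports the
chromatin state associated with each modification — including combinatorial
marks that no antibody can isolate.

`histurnover` implements the analytical core of that assay:

* **Mass chemistry** of propionyl-derivatized histone peptides: free and
  monomethylated lysines (plus the peptide N-terminus) gain a propionyl
  group (C3H4O, 56.0262 Da); acetylated and di/trimethylated lysines are
  blocked. Acetyl (C2H2O, 42.0106 Da) and trimethyl (C3H6, 42.0470 Da) are
  near-isobaric at 36.4 mDa, the resolution-defining pair of the field.
* **Labeling stoichiometry**: a budget of unlabeled vs labeled amino acid
  in the culture, and the replication-dilution expectation
  `1 - 2^(-cycles)` (50% after one cycle).
* **Bottom-up quantification**: relative abundance of each proteoform
  within its backbone family (total XIC area of all forms = 100%) and the
  heavy fraction `heavy / (light + heavy)`; positional isomers (e.g. K9ac
  vs K14ac) resolved by averaging per-fragment-ion ratios from DIA data.
* **Middle-down quantification**: intact H3 1–50 tails binned by methyl
  equivalents (+14.0157 Da steps) at charge 8+, extracted at 10 ppm and
  quantified at the precursor level.
* **Statistics**: two-tailed heteroscedastic (Welch) t-tests with strict
  star thresholds (0.05 / 0.005 / 0.0005), Pearson correlations,
  abundance-vs-labeling fold-change comparison, and replicate-precision
  contrast.
* **Genomic validation metrics** on user-supplied BED intervals: percent
  of peaks with a ≥ 1 bp intersection, percent of peak base pairs covered
  by reads, reads per 100 bp, TSS −3 kb/+2 kb promoter windows.

## Mass-chemistry conventions

All masses are monoisotopic; the proton mass is fixed at 1.007276 Da.
A methyl equivalent is carried internally at its exact value 14.015650 Da
(the commonly printed "14.01" is a truncation). The R10 arginine label is
6×(¹³C−¹²C) + 4×(¹⁵N−¹⁴N) = 10.0083 Da; at charge 2+ a labeled peptide sits
~5 m/z above its light partner. The heavy histidine used for intact-tail
work has no universally fixed isotopologue; the shipped default is ¹³C₆
(6.0201 Da), it is configurable, and the delta actually used is always
echoed in the run manifest so downstream numbers are interpretable.

One labeled residue per bottom-up analyte is assumed (ArgC-like peptides
end in a single arginine). The intact H3 tail carries a single histidine
(H39), which is what makes heavy histidine a clean two-state label there.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every recovery claim is made.

* **Chromatographic model**: Gaussian peaks, 12 s FWHM, sampled every 2 s
  (typical nanoLC histone peptide peaks). Light and heavy traces co-elute
  exactly — the labels are non-deuterated.
* **Noise model**: additive Gaussian noise on intensities, truncated at
  zero, with `sigma = apex/SNR` defined per trace. Defining SNR against
  each trace's own apex makes the small positive bias introduced by
  truncation approximately multiplicative, so it cancels in
  `heavy/(light+heavy)`; this is also why the heavy-fraction estimator is
  unbiased at the grid ends (a zero-signal channel carries no noise).
  Default SNR is 50, a realistic figure for the abundant histone peptides;
  recovery stress tests run at SNR 20. A 10% log-normal per-analyte
  signal variation is applied jointly to the light/heavy pair of an
  analyte: it perturbs relative abundances (as injection/ionization
  variability does) but cancels in the heavy fraction, which is the
  mechanistic reason labeling incorporation is the more precise replicate
  measurement — the property the replicate-precision contrast detects.
* **Ground-truth preset** (~20 H3/H4 proteoforms, 3 days × 3 replicates ×
  2 conditions): day-2 heavy fractions encode the orderings the assay is
  expected to reproduce (acetyl > trimethyl at the same residue,
  K9me1 > K9me2 > K9me3, the bivalent K27me3K36me2 tracking its repressive
  mark) and the five reference marks carry 0.665/0.582/0.484/0.436/0.235.
  Time courses follow `f(d) = 1 − (1 − f₂)^(d/2)`, monotone in day.
  The second condition perturbs day-2 abundances of two proteoforms by
  2^±8 and heavy fractions of two *different* proteoforms by 2^±0.25 — a
  constructed 32× dynamic-range contrast between the two fold-change axes,
  on orthogonal proteoform sets so their correlation is ~0 by design.
* **Interval generator**: the genome is partitioned into equal slots; a
  chosen number of query intervals are placed inside subject intervals
  (guaranteed ≥ 1 bp overlap) and the rest in private slots (guaranteed
  disjoint), so the realized overlap fraction equals the target to within
  rounding.

What the generator does **not** emulate: isotope envelopes, retention-time
drift between runs, chimeric/interfering signals, peak-shape asymmetry,
missing values from identification failures, and real inter-replicate
biological variation beyond the noise models above. Passing recovery tests
therefore demonstrate the correctness of the computational chain under the
stated signal model, not robustness to every pathology of real LC-MS data.

## Quantification choices

* "Intensity" in the heavy-fraction definition is read as **integrated XIC
  area** (consistent with the total-area definition of relative ratios);
  an apex-height mode exists behind `apex_mode = TRUE`.
* The integration window is ±3 peak widths around the apex of the stronger
  trace of the pair, shared by light and heavy (co-elution assumed).
* Isomer resolution uses the **arithmetic** (unweighted) mean of
  per-fragment shares `a/(a+b)` across distinguishing fragment pairs,
  applied independently to the light and heavy precursor windows so each
  isomer keeps its own heavy fraction; with one distinguishing pair it
  reduces to that pair's ratio. Only pairwise resolution is supported:
  isomer groups of three or more members are flagged `unresolved_isomer`
  (how >2 co-eluting isobaric forms should be apportioned is not defined
  by the averaging rule). Tests compare the estimator against a
  least-squares oracle; at SNR 20 their mean absolute difference is well
  under 0.05.
* Families whose total area falls below `area_floor` are reported missing
  (NA with flag `low_signal`), never as zeros — low-abundance forms (the
  H3K56ac situation) should drop out visibly, not silently bias ratios.
* Undefined signal (light = heavy = 0) raises a classed condition that
  [quantify_run()] converts to a flagged NA record.

For the middle-down ladder, states are binned strictly by total added mass
in 14.0157 Da steps (a pure-methyl ladder); acetyl-containing
states (42.0106 ≠ 3 × 14.0157 exactly) can be modeled as separate entries
by building a custom ladder, and the 15-equivalent cap is an argument.
Ladder windows are checked for overlap at the requested ppm at
construction; at 10 ppm the 8+ spacing of ~1.752 m/z leaves two orders of
magnitude of headroom, and the whole 0–15 ladder (light and heavy) sits
inside the 665–710 acquisition window.

## Statistical choices

* No multiple-testing correction is applied by default (raw two-tailed p
  with stars is the convention being reproduced); `p.adjust` can of course
  be applied downstream.
* Fold changes of fractions use the fractions directly (not logit),
  matching the scatter axes being emulated; zero means are floored at a
  small epsilon and flagged.
* The dynamic-range ratio is the span (max − min) of abundance log2 fold
  changes over the span of labeling log2 fold changes, with per-day fold
  changes averaged across days to use all 9 measurements per condition.
  The span of a noisy ensemble is extreme-value statistics, so single-run
  values scatter a few percent around the constructed 32×; the property
  test asserts the mean over a 10-seed ensemble within 5%, and the fixed
  default seed reproduces 32 within 5% deterministically.
* The replicate-precision contrast compares per-proteoform CVs of the two
  metrics with a **paired** t-test across proteoforms (a "paired Welch
  test" is a contradiction in terms — pairing collapses the comparison to
  one sample, where the Welch correction has no meaning).
* Degenerate inputs are handled explicitly: identical samples give
  t = 0, p = 1, `ns`; zero-variance constant differences in the paired
  test give the same; zero variance otherwise is an error.

## Genomic overlap conventions

Coordinates are 0-based half-open (BED) at the interfaces and converted to
`GRanges` internally. Overlap requires ≥ 1 shared bp — adjacency is not
overlap. Strand is ignored for all overlap metrics and used only to orient
promoter windows (+: [pos−3000, pos+2000); −: [pos−2000, pos+3000),
clipped at 0). Chromosome filtering (e.g. chrM/chrX/chrY) is available at
read time and off by default. Reads are counted as the intervals supplied
— whether they represent fragments or individual mates is the caller's
choice and is not second-guessed. All metrics are checked for exact
equality against per-base-pair brute-force oracles on small genomes
(≤ 10 kb, 200 seeded instances).

## Problem sizes used by the test suite

The shipped preset is deliberately desk-scale: 23 proteoforms × 3 days ×
3 replicates × 2 conditions (~30k signal rows per run), 100-seed recovery
grids, 200-instance interval oracles, 10-seed fold-change ensembles. These
sizes give sub-percent Monte-Carlo error on every asserted quantity while
keeping the full suite under a few minutes. The published headline numbers
that derive from the deposited EL4 datasets (peak counts, genome-wide
correlations, per-mark labeling percentages) are encoded as ground-truth
*inputs* where they parameterize the preset, not as quantities the package
claims to re-derive from raw data.

## Known limitations

* No peak picking, retention-time alignment, or identification: inputs are
  already-extracted XIC tables keyed by analyte.
* Pairwise-only isomer resolution (flagged otherwise).
* Kinetic rate-constant fitting of turnover curves is out of scope; the
  package reports labeling fractions, not rates.
* The ETD fragment content of middle-down runs is ignored by design (only
  precursor intensities are quantified), so PTM localization on intact
  tails is not attempted.
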