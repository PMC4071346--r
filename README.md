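# histoneLFQ

Label-free quantification of histone post-translational modifications
(PTMs) from centroided LC-MS feature maps, for paired tumour/normal tissue
cohorts.

Histone marks such as H3 K27 acetylation are quantified label-free: modified
peptides identified by MS/MS are *tagged* in each sample's 2-D (m/z ×
retention time) map using their predicted coordinates and theoretical
isotopic envelopes, in two passes — a wide-tolerance pass with strict
envelope fits, then LOESS m/z and RT calibration, then a narrowed-tolerance
pass with relaxed fits. Peptide abundances (heights of the most prominent
envelope peaks, median-normalized per sample) are aggregated into site-level
**modification intensities**: for each (histone, site, modification type),
the single-modified peptides covering the site are rescaled to a common
level and their median taken per sample. Differences between tumour (T) and
matched normal (N) samples are tested with a **sign-flip resampling paired-t
test** on log intensities,

&nbsp;&nbsp;&nbsp;&nbsp;*t* = mean(*d*) / (sd(*d*)/√*n*),&nbsp;
*d*ᵢ = log Tᵢ − log Nᵢ,

with the null built from all 2ⁿ sign assignments of the *d*ᵢ (exhaustive for
n = 12 pairs; Monte-Carlo beyond 2¹⁶), and the fold change reported as the
ratio of group means over complete pairs. Upstream, identifications are
filtered by target-decoy q-values (accept at q ≤ 0.01), PTM sites are
localized with a binomial phosphoRS-style score, and known chemical
artifacts (C-terminal methyl-K, methyl-K in acidic context, C-terminal
deamidated R) are rejected.

Because no raw data is deposited for the study design this implements,
correctness is demonstrated on a seeded synthetic cohort generator with
complete ground truth: 12 T/N pairs over the four human core histones, fold
changes 1.67 / 1.54 / 1.24 / 0.83 injected at H3 K27me3, H3 K27ac,
H2B S64ph and H3 K79ac among ≥20 null sites, 20% intensity CV, ≤3 ppm m/z
drift, ≤1.5 min RT drift, 10% missing features.

## Worked example

The `analysis/` scripts run the full chain on the default synthetic cohort
(`01_simulate.R` → `04_differential.R`, plus `05_simulation_study.R` for the
repeated-seed operating characteristics). The same chain in code:

```r
library(histoneLFQ)
res <- analyze_cohort(cohort_config(seed = 1))
subset(res$differential$table, significant,
       select = c(histone, site, mod, fc, p_value))
```

```
 histone site           mod        fc    p_value
      H3  K27    Acetyl (K) 1.4110827 0.00781250
      H3  K79    Acetyl (K) 0.6495103 0.00781250
      H3  K27 Trimethyl (K) 1.3383991 0.04248047
```

Three of the four injected sites are recovered in this single cohort (the
1.24-fold H2B S64ph effect is below the power of a 12-pair design at 20%
CV); each `fc` is the estimated tumour/normal ratio for the site and
`p_value` the exhaustive sign-flip p over 4,096 sign assignments. Across 50
seeded cohorts the median estimated fold changes are within a few percent of
the injected 1.67 / 1.54 / 1.24 / 0.83 and the two large effects are
detected with power ≥ 0.98.

The bundled immunohistochemistry worked example:

```r
li <- h3k27ac_labelling_index()
labelling_index_summary(li$crc, li$normal)
```

returns mean labelling indices of **69.01%** (tumour) versus **52.66%**
(normal) over the 10 matched pairs, with a paired resampling p of 0.0215.

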