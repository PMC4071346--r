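---
title: "Label-free quantification of histone PTMs: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification of histone PTMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneLFQ)
```

# Scope

histoneLFQ implements an identification-directed label-free quantification
(LFQ) chain for histone post-translational modifications (PTMs) measured by
LC-MS on paired tumour/normal cohorts: peptide chemistry and isotopic
envelope prediction, in-silico digestion, confidence filtering of
identifications (target-decoy q-values, binomial site localization, artifact
rules, protein grouping), two-pass feature extraction with LOESS m/z and
retention-time calibration, median normalization, site-level modification
intensities, and a sign-flip resampling paired-t test. Because no public raw
data accompanies the study design this package addresses, validation rests
on a seeded synthetic cohort generator with complete ground truth; this
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

# The measurement model

## Peptide chemistry

Monoisotopic masses are computed from elemental compositions using NIST
atomic masses. The modification registry carries the standard histone search
set — fixed carbamidomethyl-C plus variable Acetyl (K), Methyl/Dimethyl/
Trimethyl (K), Methyl/Dimethyl (R), Deamidated (R), Phospho (S/T) and
Oxidation (M) — each defined by an added/removed formula, so that every
delta mass is recomputable:

```{r registry}
reg <- default_modifications()
sapply(reg, function(m) round(m$delta_mass, 6))
```

Deamidated (R) is modelled as +O −NH on arginine (+0.984016 Da), the
citrullination mass; the two terms are used interchangeably in histone work.
Carbamidomethylation is applied unconditionally to cysteines, as in a fixed
Mascot-style search; this can be disabled per peptide
(`modified_peptide(..., apply_fixed = FALSE)`).

Isotopic envelopes are predicted by iterated convolution of per-element
natural isotope distributions on the nucleon-offset grid (the
aggregated-isotope approximation — fine isotope structure is out of scope),
normalized to the most abundant peak and truncated at a relative-abundance
floor of 1e-3. The floor keeps envelopes of sub-5-kDa peptides at six peaks
or fewer, which is what centroided feature data resolves in practice.
Observed-versus-theoretical envelope agreement is scored by the cosine of
the two intensity vectors after index alignment and zero-padding. The
original feature-extraction software does not document its envelope
distance; cosine is this package's choice and any score in [0, 1] with scale
invariance could be substituted in `match_pass()`.

## Digestion and identification

`digest()` implements tryptic cleavage (C-terminal to K/R, blocked by a
following proline) with configurable missed cleavages, and semitryptic
digestion as all prefixes/suffixes of tryptic peptides retaining one tryptic
terminus. Defaults: 2 missed cleavages, peptide length 5–35 (typical search
defaults), at most 4 variable modifications per peptide.

Target-decoy q-values follow the standard construction: PSMs ranked by
score, FDR(t) = #decoys / max(1, #targets) at or above t, q-values as the
running minimum from the least significant rank, decoys assigned q = 1, ties
sharing the worst rank. The estimator omits the +1 decoy-count correction;
`compute_qvalues(plus_one = TRUE)` gives the conservative variant.
Acceptance is at q ≤ 0.01.

Site localization adapts the binomial scoring idea of phosphoRS: each
positional isomer is scored by the binomial tail probability of its matched
b/y ion count given a uniform per-peak chance-match probability
p = (#peaks × 2 × tolerance)/span, and isomer probabilities are normalized
inverse tail p-values. This deliberately simplifies the published algorithm
(no depth-dependent peak extraction), since only the scoring core is needed
to resolve synthetic isomers; the fragment tolerance default is 0.02 Da.
Manual spectrum inspection is replaced by a configurable best-site
probability threshold (0.75).

Artifact rules reject (a) mono/di/tri-methyl-K on the peptide C-terminus,
(b) methyl-K co-occurring with D or E anywhere in the peptide (both are
signatures of chemical methyl esterification), and (c) deamidated R on the
C-terminus (tryptic cleavage after a deamidated arginine is highly
unlikely). The acidic-context rule is applied to lysine methylation only,
not methyl-R, which matches the stated origin of the artifact.

## Two-pass feature extraction

Predicted coordinates (m/z from mass and charge, reference retention times)
are matched against each sample's centroided map in two passes:

1. **Pass 1** — wide windows (defaults 10 ppm, 3 min) with a strict envelope
   cosine minimum (0.95); each (peptide, charge) takes at most one feature,
   ties broken by the smallest normalized distance
   √((Δm/z/tol)² + (ΔRT/tol)²).
2. **Calibration** — LOESS fits of ppm deviation against m/z and minute
   deviation against RT (span 0.4, tricube weights, robustifying
   iterations), subtracted from the map. The smoother is locally *quadratic*:
   a locally linear fit leaves several percent of curvature bias on smooth
   quadratic/cubic drifts at any usable span, and the calibration
   requirement here is sub-2% residual.
3. **Pass 2** — narrowed windows with a relaxed envelope minimum (0.80).
   The narrowed tolerance is adaptive per sample: max(floor, 3 × MAD of the
   calibrated pass-1 residuals), floors 2 ppm / 0.3 min, capped at the
   pass-1 tolerance. Pass-1 matches not re-found in pass 2 are retained.

Abundance per charge state is the most prominent envelope peak's intensity
(centroid maps); for profile neighborhoods `fit_peak_height()` fits a 2-D
elliptical Gaussian with flat baseline and returns its height. Peptide
abundance sums matched charge states by default (`sum_charges = FALSE`
selects the most intense charge instead — the original software's behavior
on this point is unstated, so both are implemented). Abundances are divided
by the per-sample median of detected peptides; missing values stay missing,
with no imputation.

## Site intensities and statistics

The site-level quantity ("modification intensity") for a (histone, site,
modification type) uses only single-modified peptides covering the site.
Each contributing peptide p is rescaled by L/r_p, where r_p is the median of
its detected abundances and L the median of the r_p; the per-sample
intensity is the median of the rescaled abundances. Note the common level L
is arbitrary (it shifts if one peptide's overall scale changes); every
downstream quantity is a ratio, so the choice cancels.

Differential testing uses the sign-flip resampling paired-t: t on the paired
differences of log intensities, null by flipping difference signs —
exhaustively over all 2^n assignments when 2^n ≤ 65,536 (n = 12 pairs gives
4,096, so the study design is always exhaustive), Monte-Carlo with 10,000
draws and +1 smoothing otherwise. The log scale matches the multiplicative
fold changes being estimated; a raw-scale option is retained
(`log_scale = FALSE`). Fold change is the ratio of group means over complete
pairs (mean-of-ratios is available; which aggregation the original analysis
used is unstated). Sites detected in fewer than `min_pairs = 6` of 12 pairs
are reported as unquantifiable rather than tested — the original
reliability rule is unstated, and half the cohort is this package's
definition. No multiple-testing correction gates the primary output
(mirroring raw p ≤ 0.05 reporting); a Benjamini–Hochberg column is emitted
alongside. The Wilcoxon signed-rank test (for externally quantified paired
band or staining intensities) wraps the exact distribution for n ≤ 20 and
the continuity-corrected normal approximation above.

# The synthetic cohort generator

`generate_cohort()` emulates 12 tumour/normal pairs over a panel of
single-modified core-histone peptides (H3, H4, H2A, H2B; mature-protein
numbering without the initiator methionine, so "H3 K27" means residue 27 of
the mature chain):

* four differential sites with multiplicative tumour/normal fold changes —
  H3 K27me3 × 1.67, H3 K27ac × 1.54, H2B S64ph × 1.24, H3 K79ac × 0.83 —
  H3 K27 covered by two peptides (with and without a missed cleavage) so the
  rescale-and-median aggregation is exercised;
* ~27 null modified sites as background;
* the unmodified tryptic peptidome of the four histones (≈90 peptides).
  This matters: the per-sample normalization median is taken over *all*
  detected peptides, and with only a handful of peptides a few injected fold
  changes shift the median itself, biasing every estimate. Real maps are
  dominated by unmodified peptides, and so is the generator's.

Per peptide: a log-normal base abundance (sdlog 1 around 1e6); tumour
multiplication by the site fold change; per-sample multiplicative log-normal
noise with CV 20% (mean 1 on the raw scale). Per sample: a smooth random
cubic m/z drift scaled to ≤3 ppm (inside a 5 ppm search tolerance) and a
smooth random cubic RT drift ≤1.5 min over a 100-min gradient axis —
amplitudes are this package's choices, as no drift magnitudes are published.
Each (peptide, charge 1–3) becomes one envelope feature (charge weights
0.2/0.5/0.3), each envelope peak perturbed by 5% log-normal noise (so the
strict/relaxed envelope thresholds are non-trivial), and features drop out
independently at 10%. Reference retention times are uniform on the gradient.
A PSM table (targets ~N(35, 5), decoys ~N(12, 5)) feeds the q-value stage.

What the generator does *not* emulate — and hence what passing tests cannot
certify on real data: chimeric and profile-mode spectra, co-eluting
interference beyond the panel, charge-state-dependent ionization efficiency
changes between samples, intensity-dependent missingness (dropout here is
uniform), retention-time nonlinearity beyond low-order smooth drift, and
search-engine score behavior (PSM scores are synthetic stand-ins for an
external engine).

# Numerical choices and degenerate inputs

* Exhaustive sign-flip enumeration uses the sign-flip-invariant identity
  Σd² to get every resampled t from a single matrix product; a resample with
  zero variance and nonzero mean counts as |t| = ∞ (always rejected against),
  and all-zero differences define t = 0, p = 1.
* LOESS calibration falls back to a global median offset (with a warning)
  below max(6, span·n) points, short-circuits on near-constant deviations
  (the robustness reweighting degenerates when MAD = 0), and clamps
  predictions to the fitted coordinate range.
* Envelope truncation guarantees at least one peak; cosine similarity
  errors on all-zero vectors rather than returning 0/0.
* `two_pass_extract` on a map with no pass-1 matches warns
  "calibration not fitted" and returns an empty tag set.
* Q-value ties share the worst rank (via run-length groups), so equal scores
  get equal q-values regardless of input order.

# Problem sizes

The repeated-seed studies in the test suite and acceptance script use 50
cohorts for fold-change recovery/power and 100 all-null cohorts for type-I
calibration, with the 12-pair, ~120-peptide, 3-charge default cohort
(≈7,900 features per cohort). These sizes put the Monte-Carlo error of the
reported medians near 1.5% and of the rejection rate near 0.4%, which is
small against the 5% recovery tolerance being checked.

# Known limitations

* Identification-directed only: no de novo feature detection or
  cross-sample alignment by clustering.
* The localization score uses a uniform per-peak match probability; real
  spectra have intensity-structured noise.
* Centroid abundance is a peak height, not an integrated volume; the 2-D
  Gaussian fit applies only when a local profile neighborhood is supplied.
* Site labels assume the mature-protein convention; proteins whose
  initiator methionine is retained would need a coordinate offset.
* mzML/mzIdentML ingestion is not implemented; `read_feature_map()`
  documents the TSV surface where an adapter would plug in.
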