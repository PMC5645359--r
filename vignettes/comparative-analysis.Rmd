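---
title: "Comparing HGSC tumors with and without tubal precursors: methods and design"
author: "hgscompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing HGSC tumors with and without tubal precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgscompare)
```

## The scientific question

High-grade serous carcinoma (HGSC) of the ovary, fallopian tube and
peritoneum is believed to arise, at least in part, from serous tubal
intra-epithelial carcinoma (STIC), a precursor lesion in the distal
fallopian tube. If tumors found *with* a STIC and tumors found *without*
one were molecularly distinct, that would argue for heterogeneous sites of
origin; if they are indistinguishable, a common (tubal) origin is the more
parsimonious reading. The question is therefore answered by a battery of
*negative-result-oriented* comparisons — expression, miRNA and copy-number
class comparisons between the two groups under multiplicity control — plus
a positive identification step: which normal tissue (fallopian tube,
ovarian surface epithelium, or peritoneum) do the tumors resemble most?

This package implements that battery as testable components:

1. **Class comparison** (`compare_groups`, `count_significant`): per-gene
   two-sample t tests with Benjamini–Hochberg (BH) control at FDR 10%.
2. **Subtype assignment** (`build_prototypes`, `assign_subtype`,
   `assign_cohort`): the nearest-prototype expression-subtype classifier
   with a correlation floor of 0.2 and a 1.5× ambiguity-rejection ratio.
3. **Tissue of origin** (`derive_tissue_signature`, `match_tissue`,
   `summarize_origin`): one-vs-rest marker signatures from normal pools,
   Spearman matching, and an exact binomial confidence interval on the
   fraction of tumors matching fallopian tube better than ovary.
4. **Copy number** (`call_regions`, `fraction_genome_altered`,
   `region_frequency_test`): region-level calls from segmented log2 ratios
   and per-region Fisher frequency comparison between groups.
5. **Power by simulation** (`simulate_power`, `analytic_power_oracle`):
   the design calculation that makes the negative results interpretable.
6. **Synthetic cohorts** (`generate_*`): generators that emulate the
   statistical structure all of the above assumes, so every stage can be
   exercised and calibrated without access to patient data.

## Statistical primitives

The shared primitives are implemented in the package rather than delegated,
because their exact conventions matter to the downstream contracts, and each
is verified in the test suite against an independent oracle (brute-force
enumeration, closed forms, or the corresponding base-R routine):

* `bh_adjust` is the standard BH *step-up* procedure
  (`q_i = min_{p_(j) >= p_i} m p_(j) / j`, capped at 1). Reports sometimes
  label the procedure "step down"; the step-up form is what controls the
  FDR and what is implemented here.
* `clopper_pearson_ci` is the exact binomial interval from beta quantiles;
  with 75 successes in 85 trials it gives (0.794, 0.942), i.e. 88%
  (79–94%) at whole-percent rounding.
* `fisher_exact` is the Freeman–Halton exact test by full enumeration of
  tables with the observed margins. There is deliberately *no* asymptotic
  fallback: tables beyond the enumeration cap (total 500 by default) raise
  an error, because every table this pipeline produces is small and
  exactness is what makes the region tests auditable.
* `two_sample_t` defaults to the Welch variant; the pooled variant is a
  flag. At the near-balanced group sizes used here the two are nearly
  identical. A feature constant across all samples is reported as
  `t = 0, p = 1` rather than dropped, so feature counts are preserved.
* `spearman_rho` is the Pearson correlation of average ranks, hence
  invariant under strictly monotone transforms — the property that makes
  tissue matching robust to monotone distortions of expression scale.

## Normalization

`size_factors` implements median-of-ratios normalization: the factor for a
sample is the median, over genes with no zero count in any sample, of the
ratio of that sample's count to the gene's geometric mean; factors are then
rescaled to geometric mean 1. Note that the formula is scale-equivariant in
the *relative* sense: multiplying one sample's counts by `c` multiplies its
factor by `c` relative to every other sample's (the per-gene geometric
means absorb `c^(1/n)`). `log_normalize` applies
`log2(count / factor + 1)`; the pseudocount of 1 keeps zeros at zero and is
the simplest zero-preserving choice. miRNA matrices are normalized by
total-count scaling in the pipeline, a deliberately simple stand-in for
panel-specific normalization, which is out of scope here.

`select_most_variable` ranks genes by log-scale variance with a
lexicographic tie-break, so selections are deterministic and nested in `k`.
The number of "most variable" genes behind unsupervised clustering plots is
not a principled constant; defaults of 1500 (mRNA) and 200 (miRNA) are used
and always recorded in output metadata. `ward_cluster` delegates to
`stats::hclust` with Ward's variance-minimizing update (`ward.D2`);
with the correlation distance `1 - r` this is Ward linkage on a
non-Euclidean dissimilarity, accepted here as in common practice.

## The subtype classifier

`build_prototypes` averages log-normalized expression per gene over each
subtype's reference samples, restricted to a signature gene set (nominally
the published 100-gene HGSC subtype signature, supplied as a gene-list
file — the signature is data, not code). Classification correlates
*gene-centered* profiles: the per-gene mean over all reference samples is
stored in the model and subtracted from both prototypes and query profiles.
Without centering, shared abundance structure (housekeeping-scale
differences between genes) dominates every correlation and pushes all of
them toward 1, which would defeat both the 0.2 floor and the 1.5× ratio;
with centering, correlations concentrate near 0 for structureless profiles
and the rule behaves as intended. Pearson correlation is the default, as is
conventional for centroid classifiers; Spearman is selectable.

The decision rule (`apply_assignment_rule`) is: candidates are subtypes
with correlation strictly greater than the floor; no candidate means
UNASSIGNED; a single candidate is assigned; among several, the maximum is
assigned only when it strictly exceeds, and is at least 1.5 times, the
runner-up. An exact tie at the top is always ambiguous — for positive
correlations the ratio test already fails on ties, and the explicit check
extends the same behavior below zero.

## The tissue-of-origin barcode

`derive_tissue_signature` runs a one-vs-rest Welch t test per tissue on the
normal pools, ranks genes by ascending p (ties by descending |mean
difference|, then gene id — the ranking rule is recorded in the signature
metadata so alternatives are comparable), keeps the top 50 per tissue, and
unions the three lists. Each tumor is then Spearman-correlated with each
tissue's mean profile over the combined set; the pairwise fallopian-tube
versus ovary winner is recorded separately because the headline proportion
is defined on that pairwise comparison. The mean-profile ("prototype")
matching is the default deterministic reading; correlating against each
individual pool and averaging the correlations is available via
`aggregate = "correlate_then_average"`. Mean correlations are reported over
the combined signature set. Argmax ties are broken by the fixed priority
FT > OV > PER with a warning; ties have measure zero on continuous data but
the behavior must be deterministic.

`summarize_origin` reports the proportion of tumors with
`rho_FT > rho_OV` together with its exact Clopper–Pearson interval — the
construction that yields 88% (79–94%) for 75 of 85 tumors.

## Copy-number comparison

Segmented profiles (SEG files, read as 1-based inclusive and handled
internally as 0-based half-open) are summarized per region as the
length-weighted mean log2 ratio and thresholded: `+2` at log2 ≥ 1
(2+ fold amplification), `−2` at log2 ≤ −1 (a purity-naive proxy for
homozygous deletion, configurable), `±1` at ±0.3 for single-copy events.
`fraction_genome_altered` is the fraction of covered genome meeting the
deep-event cuts. Region discovery itself (GISTIC-style) is treated as an
external input: the testable claim is the *between-group frequency
comparison* on given regions, which `region_frequency_test` performs as a
per-region 2×2 Fisher exact test (altered/not × group) with BH adjustment
across regions. The test behind published "not over-represented" statements
is rarely named; per-region Fisher + BH is this package's explicit,
documented choice. Regions altered in no sample carry no information and
are flagged with p = 1.

## Power by simulation

`simulate_power` draws independent unit-variance Gaussian genes — the
implicit model of a t-test power study; correlation structure is
deliberately out of scope — shifts a subset in one group, and counts BH
discoveries. The default grid is effect sizes 0.75–1.5 s.d., 40–50 samples
per group, 50 true effects among 20,000 genes, FDR 0.10: the design
conditions of a two-arm molecular study at this accrual. Sensitivity is
averaged per replicate and then over replicates, with the Monte-Carlo
standard error taken from replicate variation. `analytic_power_oracle` is
the independent check: the large-`m` BH threshold converges to the fixed
point of `alpha = fdr * R(alpha) / m` with
`R(alpha) = n_de * power(alpha) + (m − n_de) * alpha`, where `power` comes
from the noncentral t distribution with `2n − 2` degrees of freedom and
noncentrality `effect * sqrt(n/2)`. At effect 1.5 s.d. and 48 per group the
fixed point gives sensitivity 0.9997 — "virtually all" — while at 0.75 s.d.
detection is partial (≈ 0.36 at n = 48), which is exactly why the design
argument targets moderate-to-large differences.

## What the synthetic cohorts emulate — and what they do not

`generate_tumor_expression` draws counts negative-binomially around
per-sample log-normal means: a per-gene baseline log2 mean field
(mean 6.5, s.d. 1.5), tumor-to-tumor biological variation (log2 s.d. 0.5,
the dominant variance component, as in bulk tumor cohorts), log-normal
library-size factors (log s.d. 0.3, so size-factor normalization is
exercised non-trivially), and NB dispersion 0.05 for the count draw.
Putting most of the variance in the Gaussian log-scale component keeps the
per-gene t statistics calibrated into the extreme tail — the property the
global-null contract ("zero BH discoveries in most null cohorts, raw
p < 0.01 in ≈1% of genes") depends on, and one that a pure NB draw with all
variance in the dispersion term does not deliver at 4–5 s.d. tail depths.

Four latent subtypes are injected by shifting disjoint 100-gene blocks
(the scale of the published subtype signature) by `subtype_sep` within-group
standard deviations; group labels are independent of expression when
`n_de_genes = 0`. Effects are injected as additive shifts on the log2 mean
in units of the *predicted* within-group s.d. of log2-normalized
expression (delta-method on the NB plus the biological variance); the
realized standardized shift matches the nominal one within 10% on average.

`generate_normal_pools` gives the three tissues disjoint marker sets with
the strong asymmetry observed between tissue programs — 4000
fallopian-tube markers against 300 each for ovarian surface and peritoneum
— plus a shared "mesothelial" log2 component (s.d. 0.3) in OV and PER that
is absent from FT, which reproduces the observed clustering of the two
mesothelial-lineage tissues away from tubal epithelium. Marker shifts
default to 6 within-tissue s.d. for FT and OV and 9 for PER: peritoneum is
modeled as the most divergent of the three from Müllerian-type epithelium,
which yields the observed behavior that peritoneum is the poorest match
for nearly every tumor. The number of pools per tissue (3) is a config
default, not a claim about any particular study. `generate_mirna_counts`
places ≥80% of features below a mean count of 10 and concentrates any true
effects in the low-abundance half, emulating panels in which the
group-differential miRNAs sit in the poorly-expressed tail.

The generators do **not** simulate reads, probe intensities, batch
structure (the motivating analysis found none worth correcting), gene–gene
correlation beyond the subtype blocks, or purity/ploidy effects on copy
number. Passing tests therefore demonstrate that the *procedures* are
correct and calibrated under the stated model — not that real tumor data
satisfy that model.

## Numerical and interface conventions

* All thresholds are strict (`p < 0.01`, `q < 0.10`, correlation `> 0.2`),
  matching the usual reporting wording.
* Every generator takes an explicit seed (default 17) and is
  bit-reproducible; the pipeline derives stage seeds by fixed offsets and
  records the seed in its run log and summary.
* Degenerate inputs have documented conventions rather than silent
  behavior: constant features get `p = 1`; constant profiles raise
  undefined-correlation errors; never-altered regions get `p = 1` with a
  flag; zero-variance-in-both-groups with unequal means gives a signed
  infinite statistic with `p = 0`.
* Test-suite problem sizes: the global-null contract runs 20 cohorts of
  95 × 20,000; the power grid runs 20 replicates per cell (200 is the
  documentation-grade setting); property suites use 1,000 random cases.

## Known limitations

Plain t tests stand in for moderated (empirical-Bayes) statistics; with
~90 samples the difference is small, and the power analysis itself assumes
plain t tests, so the package's calibration claims are internally
consistent. Real-data headline counts (e.g. how many genes pass `p < 0.01`
in a particular cohort) are data-bound quantities that the synthetic
cohorts emulate only in distribution. The deep-deletion log2 threshold is
purity-naive and should be adjusted for impure samples.
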