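---
title: "Candidate-SNP association and paired tumor-normal LOH analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-SNP association and paired tumor-normal LOH analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohassoc)
```

## The scientific setting

`lohassoc` implements the statistical core of a common cancer-genetics
study design: a replication panel of candidate susceptibility SNPs is
genotyped with hard calls (e.g. mass-spectrometry genotyping) in a
case cohort and compared against population controls, and the same
markers are then genotyped in the tumors of the cases to ask whether
heterozygous sites preferentially lose one allele during neoplastic
progression (loss of heterozygosity, LOH, with allele-specific
imbalance). The package ships a synthetic-data generator with the same
statistical structure, so the entire workflow is testable without
access to restricted patient genotypes.

The default study conditions are a 19-SNP colorectal-cancer candidate
panel typed in 705 cases and 1802 population controls, with paired
tumor and adjacent-normal tissue for every case; `default_panel()`
carries the per-marker control and case minor-allele frequencies
(control MAFs 0.072-0.497), the implied per-allele odds ratios, and
per-marker LOH rates (2-36% of informative heterozygotes) and
retention biases (50-100% major-genotype shift) as generative
parameters.

## Genotype model and encoding

Genotypes are allele-B dosages: the number of copies (0/1/2) of the
panel's `allele_b`, with `NA` for a no-call. A single integer per call
supports both allele-based tests (counts of alleles) and
genotype-based tests (counts of the three genotype classes). Panel
alleles are used exactly as given: the package performs no strand
flipping and no resolution of strand-ambiguous (A/T, C/G) markers --
harmonising strands across files is the caller's responsibility.
Missing calls are handled per SNP by complete-case analysis, so the
effective sample size varies across markers, as it does in real
hard-call assay data.

## Case-control association

For each marker the package computes:

* **Allelic test.** The minor allele is defined by control frequency
  (ties resolve to `allele_b`). The 2x2 allele table (cases/controls x
  minor/major) is tested with the 1-df Pearson chi-square without
  continuity correction; at these sample sizes (thousands of alleles)
  the correction would only bias the test conservative. Tables with a
  zero margin (monomorphic markers) return p = 1 with a `degenerate`
  flag rather than an error, so batch runs never abort.
* **Genotypic test.** The 2x3 genotype table is tested with the Pearson
  chi-square; genotype classes absent from both cohorts are dropped and
  the degrees of freedom reduced.
* **Hardy-Weinberg equilibrium.** Control genotype counts are tested
  against p², 2pq, q² at the observed allele frequency by 1-df
  goodness-of-fit chi-square. An exact test (enumeration of
  heterozygote counts conditional on the minor-allele count) is
  available via `hwe_test(..., method = "exact")` for low-MAF markers
  where the chi-square approximation is poor.
* **Odds ratio.** The allelic odds ratio with a Wald 95% interval,
  applying the Haldane-Anscombe +0.5 correction when any cell is zero.
  With `orient_risk = TRUE` (the default) ratios below 1 are
  reciprocated, so the reported OR always refers to the case-enriched
  allele -- the convention used in published replication tables, where
  every printed OR is at least 1. Under log-additive coding this 2x2
  allelic OR coincides with the coefficient an unconditional logistic
  regression without covariates would estimate, which is why published
  ORs are reconstructible from printed MAF pairs via `or_from_maf()`.

### Multiple-testing adjustment

Two adjustments are provided. `bonferroni_adjust()` takes an explicit
family size (19 for the full candidate panel). `permutation_adjust()`
implements Westfall-Young max-T step-down: case/control labels are
permuted, all per-SNP allelic chi-squares recomputed, and each ordered
observed statistic compared with the permutation distribution of the
maximum over the markers still in its step-down set, with monotonicity
enforcement. The add-one correction bounds every adjusted p below by
1/(n_perm + 1), and the reported value is never below the raw
asymptotic p. Max-T respects the correlation among markers, which is
why permutation-adjusted values in replication studies sit between the
raw and Bonferroni p-values. The permutation stream is a deterministic
function of the seed.

### Power

`power_allele_test()` evaluates the design claim that 705 cases and
1802 controls give >80% power for an allele-frequency difference of
0.05 at alpha = 0.05. The analytic route is the standard two-proportion
normal approximation on 2n alleles per group; the simulation route
draws allele counts under Hardy-Weinberg sampling and counts allelic
chi-square rejections. The two agree within 0.03 at 2000 replicates,
and both exceed 0.8 for control MAFs from 0.1 to 0.45.

## Stratification diagnostics

`pca_genotypes()` runs the standard genotype PCA used to check that
cases and public controls come from one population: per-SNP
mean-imputation of missing dosages, centering and unit-variance
scaling (the common choice for stratification checks on small unlinked
panels; the study design uses 44 unlinked markers), eigen-decomposition,
and a deterministic sign convention (largest-magnitude loading
positive). `inflation_lambda()` is the genomic-control factor: the
median observed 1-df chi-square over its null median 0.4549364, with
the denominator fixed by definition. A caution from the package's own
calibration work: with only ~44 statistics the *median* is noisy
(single-panel lambda ranges roughly 0.35-1.7 under the null), so lambda
from a small unlinked panel should be read as a coarse diagnostic, not
a precise estimate.

## LOH and allele-specific imbalance

Only patients whose adjacent-normal genotype is heterozygous are
informative: allele loss is undetectable on a homozygous background.
`informative_pairs()` keeps heterozygous-normal pairs with a
non-missing tumor call; a missing tumor call is dropped, never counted
as LOH. `call_loh()` then classifies tumor calls: dosage 0 (homozygous
`allele_a`) and dosage 2 (homozygous `allele_b`) are LOH events with
the respective allele retained; dosage 1 is a retained heterozygote.

Derived quantities follow printed-table conventions: `loh_percent()`
is LOH events over informative pairs, and `major_shift_percent()` is
the larger homozygous class over all LOH events, both rounded half
away from zero to integer percentages. `risk_retention()` reports the
fraction of LOH tumors retaining the panel-designated risk allele.

Calling LOH from hard genotype transitions (het -> hom) is
deliberately conservative: it cannot distinguish deletion LOH from
copy-neutral LOH, and contamination by normal cells can restore a
heterozygous call, biasing detection toward strong copy-number loss.
The retention test is where a design choice was genuinely open. The
default is the exact two-sided binomial test of the homozygous-A vs
homozygous-B split against 0.5, the sharpest within-SNP question
("is one allele preferentially retained?"). A `pooled_fisher` mode
tests a marker's split against the split pooled over the other panel
markers with Fisher's exact test, asking instead whether the marker
deviates from the panel-wide retention pattern; published per-SNP
exact-test p-values from this design are not always reconstructible
from the printed homozygote counts under either construction, so both
are exposed and documented rather than guessed between. Retention
p-values are Bonferroni-adjusted at the panel family size (19 by
default).

## The synthetic-data generator

`sim_config()` bundles the generative parameters; the defaults are the
study conditions above. The generator emulates:

* control genotypes under HWE at each marker's control MAF;
* case genotypes under a per-allele (log-additive) odds model:
  odds(case frequency) = OR_b x odds(control frequency), HWE within
  cases -- matching the allelic OR the association stage estimates;
* paired tumors: each germline heterozygote suffers LOH with the
  per-SNP `loh_rate`; the retained allele is `allele_a` with
  probability `retention_bias`; the resulting *call* is homozygous
  with probability 2 x purity - 1 (at purity 0.5, normal-cell
  contamination always restores the het call; at purity 1, calls are
  faithful) -- the simplest monotone miscall model consistent with
  conservative hard-call genotyping of tissue that is at least 50%
  tumor cells. Germline homozygotes are copied unchanged;
* LD-proxy pairs at a target r² via the two-SNP haplotype distribution,
  with feasibility bounds checked and reported;
* per-genotype no-calls at `no_call_rate` (default 0.02, a typical
  hard-call assay level; real per-SNP call rates for such panels are
  usually unpublished).

It does **not** emulate intensity-level cluster calling, genotyping
batch effects, somatic copy-number landscapes, haplotype-scale LD
beyond marker pairs, or related individuals. Passing tests therefore
demonstrate correctness of the statistics and calibration under the
stated sampling model, not robustness to assay artifacts in real data.

All generators are deterministic under a fixed seed and restore the
caller's RNG state.

## Numerical conventions and degenerate inputs

* Percentages round half away from zero (`12.5% -> 13%`), matching
  printed tables; ORs render to 3 decimals and p-values to 4
  significant digits in output TSVs.
* Monomorphic or zero-margin tables return p = 1 with a flag;
  undefined ratios (double-zero diagonal) and undefined percentages
  (no informative pairs, no LOH events) return `NA`, and batch drivers
  propagate the `NA` without aborting.
* The genomic-control denominator and the PCA sign convention are
  fixed, not configurable, so outputs are bit-reproducible.
* Adjusted p-values are never reported below the raw p-value.

## Problem sizes used by the test suite

The suite checks calibration at sizes chosen to keep each property
informative yet quick: type-I error over 5000 simulated allele tables,
familywise error of the max-T adjustment over 200 replicates of a
19-SNP null panel (199 permutations each), OR parameter recovery over
500 single-marker cohorts at 705/1802, end-to-end coverage of
generative OR / LOH rate / retention bias over 100 replicates at full
study scale, and LOH parameter recovery at 5000 informative pairs.

## Limitations

* No covariate-adjusted regression, imputation, meta-analysis, or
  genome-wide scalability work: the design targets candidate panels of
  tens of markers.
* No strand or allele-frequency harmonisation against external
  references.
* LOH calling is genotype-only; it neither estimates tumor purity from
  data nor separates deletion from copy-neutral LOH.
* VCF support is minimal (diallelic records, GT field only), intended
  for interchange rather than as a general-purpose VCF reader.
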