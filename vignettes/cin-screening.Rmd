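---
title: "Screening for chromosomal instability in plasma cfDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for chromosomal instability in plasma cfDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinscreen)
```

## The problem

Solid tumors — liver cancer prominently among them — are chromosomally
unstable: whole arms and large segments of the genome are gained or lost
early in tumorigenesis. Tumors shed DNA into the blood, so the copy-number
footprint of these events is present, heavily diluted, in the plasma
cell-free DNA (cfDNA) of a patient. Low-pass whole-genome sequencing of
a plasma sample (around ten million read pairs) is enough to read that
footprint out: a gained arm contributes proportionally more fragments, a
lost arm fewer, and the deviation scales with the fraction of plasma DNA
that is tumor-derived.

`cinscreen` implements the complete screening pipeline: per-bin read
counting, Z-score normalization against a panel of healthy controls,
circular binary segmentation, scoring against a fixed panel of 29
recurrently altered liver-cancer segments, a positive/negative screening
call, and cohort-level evaluation, plus a simulator that generates
cfDNA-like data with known copy-number truth.

## Coordinate frame

Everything is computed on a fixed tiling of the hg19 autosomes into 200 kb
bins (`make_bin_grid(hg19_build())`, 14 415 bins). Coordinates are 0-based
and half-open throughout. A bin belongs to a genomic interval when its
midpoint falls inside the interval; with this rule two non-overlapping
segments can never claim the same bin, even when segment boundaries are
not bin-aligned. Sex chromosomes are optional and excluded from screening
by default: a mixed-sex control panel would turn chrX/chrY coverage into
sex-linked artifacts.

## Coverage and normalization

For one sample, each passing read (mapping quality at least 30, duplicates
excluded, proper pairs, first mate only so a fragment counts once) is
assigned to the bin containing its leftmost mapped position. The working
unit is *relative coverage* — bin count divided by total usable reads —
so sequencing-depth differences between samples and controls cancel
exactly; z-scores are invariant under uniform depth scaling of the counts.

A reference panel is built from healthy-control profiles: per-bin mean
and sample (n−1) standard deviation of relative coverage. The per-bin
statistic for a test sample is then

$$ z_b = \frac{\mathrm{cov}_b - \mu_b^{\mathrm{controls}}}{\sigma_b^{\mathrm{controls}}}. $$

Bins whose control standard deviation is zero, or whose control mean is
below 10% of the genome-wide median bin mean, are masked: these are
centromeric/telomeric dropouts that would otherwise produce infinite or
wildly unstable z-scores. Masked bins are excluded from every downstream
statistic, never interpolated. Controls define the panel once and are
serialized with a validating header; a sample is never normalized against
a panel containing itself.

GC-bias correction (lowess trend of count versus GC, divide and rescale)
is implemented but **off by default**; the default workflow normalizes raw
relative coverage only, and the control panel absorbs shared GC structure.

## Segmentation

Per-chromosome z vectors are segmented by circular binary segmentation
(CBS), implemented from scratch with the exhaustive arc scan in C++.
The statistic for a candidate split is the pooled two-sample t between a
circular arc \((i, j]\) and its complement, with both parts at least
`min_width = 2` bins. Cut position `n` coincides with cut position 0 on
the circle, so the scan enumerates each two-cut partition exactly once;
ties break to the lexicographically smallest `(i, j)` — determinism over
elegance. Significance is assessed by full-vector permutation:

$$ p = \frac{1 + \#\{\max|t^\ast| \ge |t_{\mathrm{obs}}|\}}{B + 1}, $$

and a split is accepted when `p < alpha` with `alpha = 0.05`. Accepted
arcs contribute at most two breakpoints (one when a cut lies at the
vector boundary), and parts are segmented recursively. Adjacent segments
with identical post-hoc means are merged, so degenerate splits can never
survive into the output. No smoothing, outlier shrinking, or
undo-splits pruning is applied; those are extension points deliberately
left out.

The default permutation count is `n_perm = 10000` with the seed recorded
in the result. An optional sequential early stop abandons a permutation
run as soon as enough exceedances have accumulated that the split can no
longer reach `alpha`; accept/reject decisions are provably unchanged, only
the reported p-value of clearly non-significant splits becomes a
sequential estimate. Heavier simulation-based tests and the acceptance
script use 199–499 permutations — at those sizes the p-value resolution
(≈ 0.002–0.005) is still far below `alpha`, and split decisions on the
strong signals being tested are unambiguous.

Per-sample segment tables report `logP`, the log10 permutation p of the
split that created each segment (0 for an unsplit chromosome), floored at
`log10(1/(n_perm+1))` — the resolution limit of a permutation test. The
packaged discovery panel carries `logP` values down to −100; values of
that magnitude are cohort-level statistics and are stored as provenance
metadata, not quantities the per-sample test can reproduce.

## Panel scoring and the screening call

Screening uses a fixed panel of 29 segments (arm-level gains and losses
plus focal TERT and CCND1 amplifications) rather than per-sample CBS
output: this is the validation-phase procedure, in which every new sample
is examined at the same 29 loci. CBS-derived segments can be screened
instead for discovery-phase emulation.

For a panel segment covering \(n\) unmasked bins, the segment mean
\(\bar z\) is the mean bin z, and the screened statistic is the Stouffer
aggregation

$$ Z_{\mathrm{seg}} = \bar z \cdot \sqrt{n}, $$

which is standard normal under the null whatever the segment length. This
is the package's documented convention for the screened statistic: a
single cutoff (2.702) is applied to *segments* whose typical segment means
are far below it, so the segment mean itself cannot be what is
thresholded; scaling by \(\sqrt{n}\) is the canonical choice that makes
one cutoff apply to segments of every size. A segment is called altered
when \(|Z_{\mathrm{seg}}| \ge 2.702\) (inclusive, two-sided `absolute`
mode, the default); `matched` mode instead requires the sign to agree
with the panel direction (gains up, losses down). A segment whose bins
are all masked is reported as explicitly uncallable, never silently zero.

A sample screens **positive** when at least one panel segment is altered,
**negative** when none is. The per-segment two-sided null call rate at
2.702 is \(2(1-\Phi(2.702)) \approx 0.69\%\); compounded over 29
independent segments this yields roughly an 18% family-wise null
positivity bound, which is why the empirical control specificity of the
published design (97–98%) depends on the panel bins being correlated and
the control panel being well matched — a limitation to keep in mind when
transferring the cutoff to new cohorts. The cutoff value 2.702 itself is
the ROC-optimized operating point of the original discovery cohort and is
a tunable parameter (`cutoff=`) everywhere it appears.

Longitudinal tracking (`track_longitudinal()`) orders per-sample panel
scores in time and reports each segment's Z trajectory with per-timepoint
calls, supporting relapse monitoring after surgery; nothing is
interpolated between timepoints.

## Cohort evaluation

`confusion_rates()` reports sensitivity and specificity with their exact
integer ratios. `roc_auc()` sweeps cutoffs over the observed per-sample
statistic (by convention the maximum absolute panel-segment Z,
configurable) and computes the trapezoid AUC, which equals the
Mann-Whitney pairwise-concordance probability — an identity the test
suite verifies on every generated cohort. `optimal_cutoff()` maximizes
Youden's J with ties resolved toward the smaller (more sensitive) cutoff.
Associations between screening positivity and clinical covariates use the
exact Fisher test with the conditional-MLE odds ratio and exact 95%
confidence interval (`fisher_exact_2x2()`, delegating to
`stats::fisher.test`, whose p-value the suite cross-checks against full
hypergeometric enumeration); no multiple-testing correction is applied
across covariates, matching the original analysis. Missing covariate
values are tabulated separately and excluded from tests, never imputed.
`combine_tests()` implements the OR-combination by which the cfDNA screen
adds sensitivity on top of a serum marker such as AFP.

## The simulator

The simulator is the package's source of ground truth. Expected bin
weights follow the standard diploid-admixture model: a region at tumor
copy number \(c\) in a sample with tumor fraction \(f\) has weight
proportional to \(1 + f\,(c/2 - 1)\), times an optional baseline
(mappability-like structure) and GC bias, normalized to sum to 1. Counts
are negative-binomial with mean `depth × weight` and dispersion 50 by
default (variance \(\mu + \mu^2/50\)): real cfDNA bins are overdispersed
relative to Poisson, and dispersion 50 at 200 kb bins and 10 M fragments
gives coverage noise of a realistic size (bin CV ≈ 0.14 at genome scale).
Setting `dispersion = Inf` draws exact multinomial counts for oracle
arithmetic. Cohort simulation assigns controls tumor fraction 0 and draws
case events independently per panel segment with the published
per-segment frequencies by default, tumor fractions uniform on
[0.05, 0.3]; overlapping drawn events resolve by menu precedence (earlier
rows win — irrelevant for the default panel, whose segments are disjoint).

What the simulator does **not** emulate: fragment-length and end-motif
structure, GC waves unless requested, mappability holes, subclonal
heterogeneity, and germline CNVs. Tests passing on simulated data
therefore demonstrate the statistical machinery (calibration, recovery,
monotonicity), not performance on real plasma libraries, which
additionally depends on wet-lab factors the model leaves out.

## Numerical choices and problem sizes

* Degenerate pooled variances in the CBS t statistic are floored at
  1e-24 so a perfect noiseless step yields a very large finite statistic
  rather than NaN; mean differences at rounding-noise scale (below 1e-9
  relative) are treated as ties, so constant vectors report t = 0 and "no
  split".
* The category labels for altered-segment counts are ">=3", "2", "1",
  "0", and the positivity rule is count ≥ 1; these are used both by the
  screening call and by the published-table arithmetic helpers.
* Two published segments on chr10 leave a deliberate 200 kb gap
  (pericentromeric gain ends at 38.4 Mb, the q-arm loss starts at
  38.6 Mb); the panel preserves the printed coordinates, and the
  midpoint rule keeps the intervening bin out of both segments. The
  printed `logP` floor of −100 is stored as −100.
* Simulation-based checks are sized to run comfortably on one CPU: CBS
  oracle equivalence on vectors up to length 40, permutation calibration
  on 500 null chromosomes of 60 bins at 499 permutations,
  leave-one-out calibration with 24 controls on a 300-bin genome,
  null segment call rate over 10 000 draws, and parameter-recovery
  cohorts of 30 controls + 20 cases on a chr1+chr8 grid at 10 M
  fragments. Each was chosen as the smallest size at which the Monte
  Carlo error is well below the tolerance being asserted.

## Known limitations

* The screened statistic (Stouffer Z with one genome-wide cutoff) is one
  defensible reading of the published method, which does not print the
  exact scaling between bin values and the 2.702 cutoff; `matched` mode
  and CBS-based screening are provided as alternatives.
* The discovery-phase count of altered segments per sample could be
  panel-based or CBS-derived; both modes exist, panel-based is the
  default.
* The per-sample `logP` is bounded by the permutation count and is not
  comparable to the cohort-level `logP` column shipped with the panel.
* One published follow-up table row (2 + 1 + 7 positives of 29) is
  inconsistent with the accompanying text (9 of 29, 31.0%); the
  arithmetic helpers treat the ratio text as canonical, and the
  discrepancy is preserved rather than resolved.
* Tumor-fraction quantification, clonality inference, liftover to other
  genome builds, and multivariable logistic modeling of covariates are
  out of scope.
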