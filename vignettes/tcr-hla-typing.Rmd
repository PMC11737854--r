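---
title: "Methods: HLA-associated TCR discovery and repertoire-based HLA typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA-associated TCR discovery and repertoire-based HLA typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrhla)
```

## The model

T cell receptor (TCR) repertoires are shaped by thymic selection on the
host's HLA molecules and by HLA-restricted antigen responses, so public
clonotypes — receptor sequences recurring across unrelated donors — can be
statistically tied to specific HLA alleles, and those ties can be inverted
to *type* a donor from repertoire data alone. `tcrhla` implements that
cycle in four stages, all operating on presence/absence of clonotypes: clone
abundances are deliberately ignored, because publicness and association are
donor-level (carrier/non-carrier) notions.

**Clonotype identity.** A clonotype is `(chain, CDR3 amino-acid sequence,
V-gene family)`. V calls are normalized to family level (`TRBV19-01*01` →
`TRBV19`), a single convention used everywhere so that sharing counts are
well-defined; nonproductive CDR3s (stop `*`, frameshift `_`, characters
outside the 20-letter alphabet) are filtered on read. HLA alleles are kept
at 4-digit (protein-level) resolution; higher-resolution codes are
truncated and 2-digit codes rejected, since allele groups and protein
alleles would otherwise be conflated in the 2×2 tables.

**Association discovery.** For each public clonotype (shared by at least 3
donors, counted across the full merged cohort — the natural reading when
several cohorts are pooled) and each allele carried by at least
`min_carriers` donors (default 5, avoiding vacuous tables), the donor 2×2
table of clonotype presence × allele carriage is tested with a two-tailed
Fisher exact test. The two-sided p-value uses the point-probability
definition — the total hypergeometric probability of all tables with the
observed margins whose point probability does not exceed the observed one —
because "two-tailed Fisher" admits several conventions and this is the one
`stats::fisher.test` implements, which we use as an independent cross-check.
Our implementation sums `dhyper` over the support directly so that scans of
10^5–10^6 tables stay fast. Multiplicity is controlled with
Benjamini–Hochberg at `q = 0.01`, applied jointly over every
(clonotype, allele) test in the run — the conservative choice among
per-allele, per-chain, or joint universes. Alpha-chain tests include only
donors whose alpha chain was sequenced; a declared sequencing flag
overrides inference from content, since alpha sequencing can legitimately
yield no public clonotypes. Both enriched and depleted associations are
recorded, but only enriched ones feed the classifier by default: its
features are presence indicators, and presence of a depleted clonotype is
weak, asymmetric evidence.

**Per-allele classifier.** The probability that a donor carries allele *a*
is the logistic

$$p_a = \frac{1}{1 + e^{-\sum_i w_{ai} x_i - v_a y - b}},$$

with `x_i` the presence indicator of associated clonotype *i*, `y` the
alpha-sequenced indicator, and `v_a` a learned weight that absorbs the
systematic difference between donors with and without alpha data. An
intercept `b` is included by default — without it an all-zero feature
vector is forced to p = 0.5, which is wrong for any allele rarer than 50% —
and an intercept-free mode (`intercept = FALSE`) gives the literal form
above. `v_a` is penalized like every other weight; nothing distinguishes it
in the likelihood. Donors are split 70/30, stratified by allele status so
both portions contain positives (an unstratified split can leave a rare
allele unrepresented); the split depends only on `split_seed`. The model is
fitted by penalized maximum likelihood (`glmnet`) over a geometric grid of
20 inverse-penalty strengths C from 10^-3 to 10^3, mapped to
`lambda = 1/(n_train · C)`; the C minimizing cross-entropy on the 30%
portion is selected, ties resolved toward the stronger penalty (the sparser
model). We run `glmnet` at a tight convergence threshold (1e-10) so the
reported active sets reflect the optimization, not loose stopping. The
decision threshold defaults to 0.5 on the probability scale; ROC and
precision–recall reporting are threshold-free.

**Matching variants.** Exact matching requires the identical clonotype
triple. Fuzzy matching (`fuzzy1`) additionally accepts a repertoire
clonotype with the same chain, V family and CDR3 length at Hamming distance
≤ 1 — the same neighbourhood that defines similarity-network edges, which
keeps "one mismatch" well-defined (no alignment, no length changes). Fuzzy
matching is a strict superset of exact matching, asserted as an invariant.
The weight-free count classifier simply counts matches and thresholds the
count; since the logistic is strictly monotone in the linear score, ranking
donors by count is identical to ranking by an equal-weight logistic score,
which is also asserted rather than assumed.

**Evaluation.** Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
(TP+TN)/total, precision TP/(TP+FP); any zero-denominator metric is
reported as a flagged `NA`, never silently 0, so cross-allele averages stay
honest. ROC-AUC uses the rank/U-statistic formulation with half-credit for
ties — exact under ties, and equal to trapezoidal integration on tie-free
data. Average precision is the step-function sum over recall increments.
Cross-allele summaries report Pearson correlations of per-allele precision
with association count and with allele prevalence.

**Iterative typing.** Untyped donors are partitioned (seeded permutation,
consecutive chunks) into subgroups of 100. Each round: impute the subgroup's
allele status with the current model; append it with frozen labels (imputed
labels are never revised — re-typing earlier subgroups is off by default);
re-mine associations for the allele ranked by raw p-value under a budget of
`ceil(ratio × n_donors)`, where the associations-per-donor ratio is fixed
at its initial-cohort value; re-fit with a fresh 70/30 split. The budget
rule deliberately *replaces* the fixed 1% FDR threshold during iteration:
it caps the error amplification that imputation noise would otherwise feed
back into discovery, and records admitted above the original BH cutoff are
allowed in. Records with raw p = 1 (no evidence) are never admitted, and
the budget is applied from the first iteration. Rounding is `ceil`, so a
growing cohort can never shrink the admissible list. The recursion is
independent across alleles.

## The synthetic-cohort generator

`sim_config()`/`simulate_cohort()` define the study conditions for every
test: donors draw each allele independently at its population frequency
(no linkage — the analysis itself treats alleles independently, and
haplotype structure is out of scope), subject to at most two alleles per
class-I locus (excess positives are pruned at random under the run seed);
background clonotypes are present i.i.d. with probability
`background_sharing` (default 0.1), providing the exchangeable null for FDR
calibration; planted clonotypes are present with probability `p_pos` in
carriers of their allele and `p_neg` otherwise; alpha-chain clonotypes
appear only in the `alpha_fraction` of donors with alpha data. CDR3s are
random strings of length 8–20 (mode near 14–15, matching typical CDR3
length distributions), starting with C and ending with F, so length- and
mismatch-sensitive machinery is exercised realistically. Everything is
reproducible from one integer seed.

What the generator does *not* emulate: V(D)J generation probabilities and
convergent recombination (background sharing is uniform rather than
sequence-dependent), clone sizes, allele linkage disequilibrium, and
cohort batch effects. Passing tests therefore demonstrate that the
statistics behave as designed under their own assumptions — calibrated FDR,
recoverable planted signal, improving iteration — not that real cohorts
meet those assumptions.

## Numerical choices and degenerate inputs

- Fisher p-values: tables at most as probable as the observed one are
  summed with a 1+1e-7 relative tolerance (as in `stats::fisher.test`);
  degenerate margins return p = 1; the sum is capped at 1 against
  floating-point overshoot.
- Association output is ordered by (p_adj, p_raw, allele, chain, V family,
  CDR3) so results are byte-reproducible.
- Donors with duplicated ids keep the first sample encountered; empty
  repertoires are allowed (with a warning on read) and score at the
  baseline `logistic(v·y + b)`.
- Alleles with zero carriers are skipped, not tested; cohorts with fewer
  than two donors refuse to run discovery.
- The L1 active set is reported per grid point. Its size is typically
  nonincreasing in penalty strength, but the lasso path may exchange a
  variable between adjacent grid points when features are correlated; the
  tests assert the strict form only where it holds by construction and the
  trend elsewhere.
- Mann–Whitney tests use the exact distribution for small tie-free samples
  and the normal approximation otherwise; fully tied comparisons return
  p = 1 with an explicit tie flag.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to give stable estimates in
minutes: FDR calibration on 200 replicate null cohorts of 100 donors × 500
public clonotypes × 4 alleles; AUC anchors on cohorts of 200–400 donors
(the null anchor averaged over 20 seeds); parameter recovery at 500 donors,
allele frequency 0.3, 20 planted clonotypes (p_pos 0.6, p_neg 0.05) over 10
seeds; the iterative procedure with 150 typed, 1000 untyped and 200
evaluation donors over 20 seeds. The oracle sweeps cover all 2×2 tables
with total ≤ 60 against exhaustive hypergeometric enumeration, BH against a
hand-written step-up reference, ROC-AUC against all-pairs counting, and
Mann–Whitney against exact permutation enumeration for groups of ≤ 8.

## Known limitations

- Predictions are per-allele and unconstrained: nothing enforces at most
  two called alleles per locus across a donor's predictions (a
  post-processing step a user may add).
- Discovery power for rare alleles is limited by `min_carriers` and cohort
  size; the iterative procedure inherits whatever bias the initial
  classifier has, mitigated but not eliminated by the association budget.
- Fuzzy (one-mismatch) matching applies to classification features only;
  publicness and association testing always use exact clonotype identity.
- The epitope annotation step joins on exact CDR3 + V family against a
  user-supplied reference; no reference data ships with the package.
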