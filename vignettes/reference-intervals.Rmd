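---
title: "Establishing pediatric reference intervals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Establishing pediatric reference intervals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphri)
```

## The problem

Lymphocyte subsets change dramatically through childhood: T, B and NK
compartments expand after birth, peak in infancy, and drift toward adult
proportions through adolescence. Interpreting a child's immunophenotyping
panel therefore requires age-matched reference intervals (RIs) — the
central 95% range of each analyte in a healthy reference population —
rather than a single all-ages range. `lymphri` implements the standard
consensus workflow for establishing and verifying such intervals from a
tidy per-subject cohort table, together with a synthetic cohort generator
so the entire pipeline can be exercised and tested without patient data.

The analyte panel is the usual 16-measure immunophenotyping set:
percentages (of total lymphocytes) for T (CD3+), helper T (CD3+CD4+),
cytotoxic T (CD3+CD8+), double-negative T (CD3+CD4-CD8-), B (CD3-CD19+),
NK (CD3-CD56+) and NKT-like (CD3+CD56+) cells; absolute counts
(cells/µl, single-platform bead counting) for those seven plus total
lymphocytes; and the CD4+/CD8+ ratio. All percentages are treated
uniformly as percentages of total lymphocytes (the convention for the
DNT row is not universal across sources; this package records the
assumption rather than guessing per analyte).

## The workflow

`establish_ri()` executes the stages in their canonical order.

**1. Normality screening.** Each analyte is screened with the
skewness/kurtosis z-test: the bias-adjusted sample skewness $G_1$ and
excess kurtosis $G_2$ are divided by their exact small-sample standard
errors,

$$SE_{skew} = \sqrt{\frac{6n(n-1)}{(n-2)(n+1)(n+3)}}, \qquad
  SE_{kurt} = 2\,SE_{skew}\sqrt{\frac{n^2-1}{(n-3)(n+5)}},$$

and the sample is called normal iff both $|z|$ ratios are below 1.96.
Two deliberate readings are baked in: kurtosis is *excess* kurtosis
(criterion centred at 0), and the decision is the conventional one —
normal when the statistics are *small* relative to their errors. For a
standard normal sample this joint criterion accepts ≈ 90% of the time
(two 5% tests), which the test suite checks by simulation.

**2. Box-Cox transformation.** Analytes failing the screen are
transformed with $y = ((x+s)^\lambda - 1)/\lambda$ ($\ln(x+s)$ at
$\lambda = 0$). $\lambda$ maximises the profile log-likelihood over a
grid on $[-3, 3]$ in steps of 0.05 with ties broken toward 0, refined by
golden-section search; an effectively zero optimum snaps to exactly 0
for interpretability. The shift $s$ is 0 unless the data contain
non-positive values (rare subsets can have zero counts in small
children), in which case $s = |\min x| + \tfrac12 \min\{x : x > 0\}$.
The transform is strictly monotone, so ranks — and hence nonparametric
percentiles — are preserved; the transformed scale is used only for the
normality decision, the Tukey fences and the parametric partition
statistics, never for the reported intervals.

**3. Outlier elimination.** Tukey fences
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ are computed per
analyte within each age-by-sex cell, on the transformed scale when the
analyte needed transformation. Values strictly outside the fences are
removed; values exactly on a fence are kept. The default is a single
pass with per-analyte removal (a subject flagged for one analyte remains
in the others); whole-subject removal and iterated passes are config
options. Every removal lands in a ledger with the violated fence mapped
back to the raw scale.

A consequence worth stating plainly: Tukey fences on continuous data are
not conservative. Even a perfectly clean Gaussian sample has ≈ 0.7% of
points beyond the fences in expectation, and heavy-tailed (strongly
right-skewed) analytes lose up to ~1% of their *genuine* upper tail per
cell. Downstream, that truncation biases the estimated 97.5th percentile
of the widest analytes (log-scale upper spread near 1) downward by up to
~20–25%, while medians are essentially unaffected. This is a property of
the prescribed workflow itself, visible in the test suite's parameter
recovery checks, and it is why a removal ledger is never empty on
realistic skewed cohorts.

**4. Partitioning.** Whether a candidate split (sex first, then adjacent
age bins) deserves separate intervals is decided by two gates: the
omnibus test (one-way ANOVA on the analysis scale by default;
Kruskal–Wallis on raw values as the nonparametric option) must reject at
$\alpha = 0.05$, *and* the Harris–Boyd statistic

$$z = \frac{|\bar x_1 - \bar x_2|}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}$$

must exceed the sample-size-scaled critical value
$z^* = 3\sqrt{(n_1+n_2)/240}$. The $z^*$ scaling is the guideline's
guard against splitting on statistically significant but clinically
negligible differences in large cohorts. $z^*$ is always computed from
the group sizes actually under test. No multiple-testing correction is
applied across analytes (deliberately, matching field practice for this
workflow); the run report exposes every p-value so users can judge.

Age merging is per analyte: all adjacent pairs of current bins are
tested, the mergeable pair with the largest p-value merges first,
statistics are recomputed, and the loop stops when every adjacent pair
splits. Only adjacent bins merge and order is preserved, so final groups
are contiguous unions of the initial five bins — deterministic given the
data. The default bins, in completed months, are 0–1 (neonatal), 2–12
(infancy), 13–47 (early childhood), 48–83 (preschool) and 84–227 (school
age); classification is by completed months with days converted at the
mean month length (floor(days/30.44)).

**5. Interval estimation.** Reference intervals are nonparametric on the
original measurement scale: the 2.5th, 50th and 97.5th percentiles at
rank $r = p(n+1)$ with linear interpolation between order statistics,
clamped to $[1, n]$. The same rank rule is used for the Tukey quartiles,
so one quantile definition governs the whole package. A group needs
$n \ge 39$ for the 2.5th rank to reach the first order statistic; below
the guideline minimum of 120 the estimate is produced with a warning.
The interpolation rule itself is a documented assumption — published
endpoint values cannot identify which interpolation their software used.

**6. Verification.** An established interval is checked against an
independent cohort (protocol: 40 subjects per age group) by counting
values strictly outside it. The default pass rule is *at most* 5%
outside, i.e. 40 samples tolerate 2 outside (95% within passes); the
strict fewer-than-5% reading is selectable. The ≤ 5% default follows the
operational behaviour of published verification tables, which count
exactly-95%-within cells as passes. Endpoint ties count as inside,
consistent with the strict-exceedance convention of the outlier stage.

## The synthetic cohort generator

The generator exists because pediatric reference cohorts are essentially
never deposited; it emulates the *published summaries* of one, not raw
data. Each analyte × age-group cell is modelled as a two-piece (split)
lognormal: log-scale half-normal spreads $\sigma_{low}$ and
$\sigma_{high}$ below and above the median, each side drawn with
probability ½. Given a printed triplet (median, 2.5th, 97.5th), the fit

$$\mu = \ln m, \quad
  \sigma_{low} = \frac{\ln m - \ln p_{2.5}}{z_{0.975}}, \quad
  \sigma_{high} = \frac{\ln p_{97.5} - \ln m}{z_{0.975}}$$

reproduces all three printed quantiles exactly while keeping draws
strictly positive and right-skewed. No claim is made about unprinted
moments or tail shape beyond the 95% band.

Defaults are the study conditions: group sizes 187/154/197/155/120
(total 813), male:female 476:337 with **no sex effect** (the generator
draws analytes independently of sex, mirroring the finding that sexes
merge), ages uniform over each bin's completed months (no within-bin age
distribution is published), analytes drawn independently per cell from
the packaged 16 × 5 parameter table. Optional contamination multiplies a
recorded fraction of values by a gross scale factor (default 10×).
Randomness is fully reproducible: each (analyte, bin) pair gets its own
substream seed derived by hashing the names with the root seed, so
adding or removing an analyte never perturbs the others.

What the generator does *not* emulate — and therefore what green tests
do not establish about real data: compositional coherence (CD4 + CD8 +
DNT percentages are not constrained to the T total; counts are not
percentage × lymphocyte count, though a coherence mode could derive
them), within-subject correlation between analytes, age trends *within*
a bin, assay noise, and any sex effect. Age groups that the source
merged share identical parameters, so the generator cannot produce data
that would justify splitting them — merge tests under the null are
informative, split tests only for groups the source itself separated.

## Numerical and design choices

* **Quantile rule** — rank $p(n+1)$, linear interpolation, clamped;
  shared between RI percentiles and Tukey quartiles. Cross-checked
  against an independent brute-force implementation on random vectors.
* **Box-Cox search** — grid step 0.05 on $[-3,3]$, golden-section
  refinement (tolerance $10^{-6}$), ties toward 0; the $\lambda = 0$
  branch takes over below $|\lambda| < 10^{-8}$, and the transform at
  $\lambda = \pm 10^{-6}$ agrees with the log branch to $10^{-4}$
  relative error.
* **Degenerate inputs** — zero-variance vectors error out of the
  normality screen, the transform and the omnibus test; groups below
  size 4 are skipped (with a warning) by the fence stage; final groups
  below size 39 yield an unavailable cell rather than aborting the run.
* **Merge traversal** — largest-p-first among mergeable adjacent pairs,
  recomputed after each merge. Any fixed traversal is defensible; this
  one is deterministic and does not depend on bin labelling.
* **Sex before age** — the sex decision is taken on the full cohort per
  analyte; only if it splits is age merging done within each sex.
* **Display precision** — 2 decimals for percentages and ratios, whole
  numbers for counts, matching the mixed precision of published tables.

## Problem sizes used in the test suite

Simulation-backed properties run at the sizes a desk check supports:
coverage of the n = 813 nonparametric interval is averaged over 200
seeds with 100,000 fresh evaluation draws each; pipeline parameter
recovery averages 50 full establishment runs on default-size cohorts;
null merging behaviour uses 100 seeds; the omnibus type-I error uses
1,000 replicates. The full suite completes in a couple of minutes on a
single core.

## Known limitations

* The Tukey-truncation bias described above: extreme percentiles of
  very heavy-tailed analytes are systematically compressed relative to
  the uncensored population. If faithful extreme percentiles of such
  analytes matter more than outlier protection, run with the filter's
  findings reviewed from the ledger rather than blindly accepted.
* Discrete age bins only; no continuous-age centile modelling
  (GAMLSS-style curves are out of scope by design).
* No confidence intervals on RI endpoints by default (published tables
  report none); the nonparametric endpoints at n ≈ 120–200 are
  themselves noisy, with relative standard errors scaling with the
  log-scale spread.
* Verification with 40 subjects per group has limited power: a
  correctly calibrated interval passes a given cell with probability
  ≈ 0.68 under the ≤ 5% rule (binomial(40, 0.05) ≤ 2), so occasional
  cell failures on perfectly matched populations are expected and a
  full multi-analyte table will rarely be all-green.

## A minimal run

```{r example, eval = FALSE}
spec <- cohort_spec()                  # study-condition defaults
cohort <- generate_cohort(spec, seed = 1)
run <- establish_ri(cohort)
print(run)                             # normality, outliers, merges, RIs

fresh <- generate_cohort(cohort_spec(sizes = rep(40L, 5)), seed = 2)
groups <- split(as.data.frame(fresh), age_to_group(fresh$age_value, fresh$age_unit))
verify_run(run, groups)
```
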