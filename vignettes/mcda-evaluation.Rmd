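---
title: "Entropy-weighted MCDA evaluation of indicator panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted MCDA evaluation of indicator panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdaeval)
```

## The problem

Public-health surveillance often produces a small rectangular panel: a
handful of indicators (mortality, coverage rates, service uptake) observed
over a run of years, with the question "is the system getting better, and
which years were best?". The indicators disagree in units, direction
(mortality should fall, coverage should rise), and pace of change, so no
single column answers the question. `mcdaeval` implements an integrated
multi-criteria decision analysis (MCDA) pipeline for exactly this setting:
the alternatives are years, the criteria are indicators, and the output is
a set of mutually checking rankings.

The bundled example, `china_mch()`, is a 15-year (2004--2018) by
6-indicator maternal health panel: maternal mortality per 100,000 (`X1`, a
cost indicator) plus five coverage percentages (`X2`--`X6`, benefit
indicators).

## The pipeline

### Entropy weights

Indicator weights are objective, driven only by dispersion. Each raw
column is min-max normalized with its direction flag
($a = (x - \min)/(\max - \min)$ for benefit, $(\max - x)/(\max - \min)$
for cost), converted to column proportions $p_{ij} = a_{ij}/\sum_i a_{ij}$,
and scored by normalized Shannon entropy
$e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}$ with the convention
$0\ln 0 = 0$ (the min-max step guarantees at least one exact zero per
column, so the convention is always exercised). Weights are normalized
redundancies, $W_j = (1 - e_j)/\sum_k (1 - e_k)$: a dispersed indicator
discriminates between years and earns weight; a flat one does not.

Two conventions are deliberate:

* **Entropy sees raw columns, not co-trended ones.** Min-max with the
  direction flag already makes the entropy stage direction-consistent, and
  this is the only reading that reproduces the reference computation for
  the bundled panel ($e_1 = 0.9285$). Co-trending (next section) matters
  only for TOPSIS geometry.
* **Constant columns** make the min-max ratio 0/0. They carry no
  information, so they receive $e = 1$, $d = 0$, $W = 0$ and the other
  weights renormalize; an all-constant panel is an error.

### Weighted TOPSIS

TOPSIS ranks each year by relative closeness to the best attainable
profile. Cost columns are first co-trended so that larger is better;
every column is divided by its Euclidean norm
($a_{ij} = x_{ij}/\sqrt{\sum_i x_{ij}^2}$) and multiplied by its weight.
The ideal solution $A^+$ collects the column maxima, the anti-ideal $A^-$
the minima, and each row is scored by
$C_i = D_i^-/(D_i^+ + D_i^-)$ with $D_i^\pm$ the Euclidean distances to
$A^\pm$; $C_i = 1$ means the year coincides with the ideal profile.

**Why reciprocal co-trend by default.** Two co-trend conventions exist:
difference ($\mathrm{ref} - x$) and reciprocal ($1/x$). For a mortality
column spanning 18--49 against a reference of 100,000, the difference
form produces a column that is constant to five significant figures, so
after vector normalization the cost indicator effectively drops out of
the TOPSIS geometry. The reciprocal form keeps the column informative and
is the only convention consistent with the reference ideal vectors for
the bundled panel ($A^+_1 = 0.0417$, $A^-_1 = 0.0158$). Both are
implemented (`cotrend` argument); reciprocal is the default for cost
indicators, and it requires strictly positive values.

**Degenerate cases.** If a row ties both $A^+$ and $A^-$ (all
alternatives identical) the closeness ratio is 0/0; it is defined as 0.5
with a warning. Exact ties in $C_i$ are ranked by first occurrence
(chronological order), which makes reports deterministic; the bundled
panel has no such ties.

### Weighted rank-sum ratio (WRSR)

The rank-based counterweight to TOPSIS: each column is replaced by
within-column midranks (best value gets rank $n$; benefit columns ranked
ascending, cost columns descending; exact ties share the mean of their
positional ranks, producing the half-integer ranks visible in the bundled
panel), and each year is scored
$\mathrm{WRSR}_i = \frac{1}{n}\sum_j W_j R_{ij}$. Being rank-based it is
invariant under any strictly monotone transform of a raw column and
insensitive to outliers, at the cost of discarding spacing information.
Useful identities hold for any weights summing to 1: every rank column
sums to $n(n+1)/2$ and the mean WRSR is $(n+1)/(2n)$; the tests use both
as invariants. The classical follow-up step that fits WRSR to a normal
quantile scale and grades alternatives into bins is out of scope: the
evaluation here uses the WRSR ordering directly.

### Fuzzy combination

TOPSIS uses full metric information; WRSR uses only order. The fuzzy
stage hedges between them with convex combinations
$W_1 C_i + W_2 \mathrm{WRSR}_i$ under several weight ratios (defaults
0.1:0.9, 0.5:0.5, 0.9:0.1, with $W_1$ on the closeness coefficient),
ranks each scheme, and reports the modal rank across schemes per year.
When the three schemes produce three different ranks there is no mode;
the balanced 0.5:0.5 scheme's rank is then used. This tie rule is a
design choice the method statement leaves open; it coincides with the
median for three schemes and reproduces the reference behaviour on the
bundled panel's no-mode row. The extreme ratios (1,0) and (0,1) recover
the pure TOPSIS and pure WRSR rankings exactly, which the tests assert.

### Concordance

Method agreement is quantified by Spearman rank correlation between the
TOPSIS, WRSR, and balanced-combination rankings. Without ties the
classical shortcut $\rho = 1 - 6\sum d^2 / (n(n^2-1))$ is exact and is
used; with ties it is not, and the product-moment correlation of midranks
is used instead (the two routes are cross-checked against `stats::cor` in
the tests). The p-value uses the t-approximation with $n-2$ degrees of
freedom; it is reported, not validated, since only a threshold is ever
published for such analyses.

### Sensitivity to weights

Entropy weights are data-driven, so the stability of the ranking under
weight perturbation is the natural robustness check. The unitary
variation rate $\beta_k$ is defined so that the *final, renormalized*
perturbed weight satisfies $W'_k = \beta_k W_k$; the raw multiplier
achieving this is $\gamma_k = (\beta_k - \beta_k W_k)/(1 - \beta_k W_k)$,
valid while $\beta_k W_k < 1$ (the perturbed weight must stay below 1 —
the method statement leaves $\beta$ unbounded, but this bound is implied
by the denominator and is enforced). After renormalization the
unperturbed weights keep their pairwise ratios. The default grid is the
14-value scheme 0.01--4.5 with $\beta = 1$ as the unchanged baseline;
`sensitivity_sweep()` recomputes the full TOPSIS closeness under every
perturbed weight vector and `rank_crossings()` reports which pairs of
years swap order between consecutive grid points, with the bracketing
$\beta$ interval. Crossing *locations* are reported but not treated as
reference values, since published statements about them derive from
reading curves off a figure.

## Synthetic panels: what they emulate and what a green test means

`generate_panel()` produces panels with the structure the pipeline
assumes: ordered alternatives, per-indicator linear trends (cost
indicators improving downward, benefit upward) plus independent Gaussian
noise, and occasional exact ties copied from the previous alternative.
Defaults mirror the bundled panel's scale: 15 alternatives, one cost
indicator starting near 48 falling by 2 per step, five benefit
indicators in the 76--90 range rising by 0.5--1.2 per step, noise scales
of 0.3--0.5 (well below the per-step trend, as in the real data), and a
5% tie probability matching the handful of exact ties the real panel
contains. Gaussian noise on cost columns is redrawn when it would cross
zero, keeping the reciprocal co-trend applicable.

The generator does *not* emulate autocorrelated measurement error,
cross-indicator correlation, or policy shocks; a green order-recovery
test therefore establishes that the pipeline respects dominance and
recovers a monotone signal, not that it is robust to structured noise.
The zero-noise configuration gives a parameter-free oracle: with monotone
trends and no ties, every stage must rank alternatives in generation
order for any positive weights.

## Numerical choices

* All internal computation is full precision; rounding (half-even, 4
  decimals by default) happens only in report emission, and every report
  CSV has a `_full` companion.
* Weight vectors are validated to sum to 1 within 1e-8 on input; computed
  weights sum to 1 within 1e-12 (asserted in tests).
* Exact-tie handling is midrank in WRSR and Spearman, first-occurrence in
  score rankings (a deterministic tiebreak for a case the real data never
  exercises).
* The sidecar metadata format is JSON (not YAML): it needs no additional
  dependency and round-trips reliably.

## Known limitations

* Reproduction of the reference computation for the bundled panel is
  exact for the weight table, the midrank/WRSR table, the ideal vectors,
  the $D^+$ column, all published rank orders, and 13 of 14 perturbed
  weight rows — but the published $D^-$ column (and everything downstream
  of its $C_i$: some combined scores, two of three correlation values,
  one comprehensive rank) is internally inconsistent with its own ideal
  vectors: its largest $D^-$ exceeds $\lVert A^+ - A^-\rVert$, the
  maximum attainable distance to $A^-$ for any row inside the data's
  bounding box, which no computation from the stated equations can
  produce. The acceptance tests assert the published values anyway and
  are left red there by design, documenting the discrepancy rather than
  tuning around it. One published perturbed-weight row (labelled
  $\beta = 0.5$) similarly matches the $\beta = 0.4$ computation instead
  of its label.
* The pipeline evaluates one panel at a time; there is no uncertainty
  propagation (bootstrap/Bayesian) on the weights beyond the $\beta$
  sweep, and no subjective-weighting alternative (AHP, Delphi) — the
  entropy weighting is the point.

## A worked run

```{r example}
panel <- china_mch("raw")
ew <- entropy_weights(panel)
round(ew$weights, 4)

ts <- topsis(panel, ew$weights)
rs <- wrsr(panel, ew$weights)
head(data.frame(C = round(ts$closeness, 4), topsis_rank = ts$ranks,
                WRSR = round(rs$wrsr, 4), wrsr_rank = rs$ranks), 4)

fz <- fuzzy_evaluate(ts$closeness, rs$wrsr)
fz$comprehensive_rank

concordance_table(ts$ranks, rs$ranks, fz$scheme_ranks[, 2])

sw <- sensitivity_sweep(panel, ew$weights, k = 6)
nrow(rank_crossings(sw))  # indicator 6 never disturbs the ranking
```
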