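# mcdaeval

Integrated multi-criteria decision analysis (MCDA) for small rectangular
indicator panels — the "years × health indicators" tables produced by
statistical yearbooks and surveillance programmes, where the question is
*which years were best, and is the trend real under different ranking
philosophies?*

The package is aimed at biostatisticians and health-services researchers
evaluating a system over time with a handful of conflicting indicators
(mortality should fall, coverage rates should rise). It chains five
mutually checking stages:

1. **Entropy weights** — objective indicator weights
   `W_j = (1 − e_j) / Σ(1 − e_k)`, where
   `e_j = −(1/ln n) Σ_i p_ij ln p_ij` is the normalized Shannon entropy of
   the min-max-normalized column: dispersed indicators discriminate and
   earn weight.
2. **Weighted TOPSIS** — score each year by relative closeness
   `C_i = D_i⁻ / (D_i⁺ + D_i⁻)` to the ideal (`A⁺`, columnwise best) and
   anti-ideal (`A⁻`) profiles in the weighted, vector-normalized decision
   matrix; cost indicators are reciprocal co-trended (`1/x`) by default.
3. **Weighted rank-sum ratio (WRSR)** — the rank-based counterpart
   `WRSR_i = (1/n) Σ_j W_j R_ij` on within-column midranks (exact ties get
   half-integer ranks), robust to outliers.
4. **Fuzzy combination** — convex combinations `W₁·C + W₂·WRSR` under
   ratio schemes 0.1:0.9, 0.5:0.5, 0.9:0.1, summarized by the modal rank
   across schemes (balanced scheme breaks no-mode cases).
5. **Concordance & sensitivity** — Spearman ρ between the method rankings,
   and a weight-perturbation sweep: the unitary variation rate β rescales
   one final weight (`W′_k = β·W_k`) via
   `γ = (β − βW_k)/(1 − βW_k)` with renormalization, recomputing the
   TOPSIS ranking on a 14-value β grid and reporting rank crossings.

A seeded synthetic panel generator (`generate_panel()`) emulates the
assumed structure (monotone trends + noise + occasional exact ties) so
every stage is testable without the bundled data.

## Worked example

```r
library(mcdaeval)
panel <- china_mch("raw")        # 15 years x 6 maternal-health indicators
ew <- entropy_weights(panel)
round(ew$weights, 4)
#>     X1     X2     X3     X4     X5     X6
#> 0.1154 0.1986 0.2180 0.1935 0.1935 0.0809
```

The system management rate (`X3`) is the most dispersed indicator and
carries the largest weight; the hospital delivery rate (`X6`), nearly
saturated over the period, carries the least.

```r
ts <- topsis(panel, ew$weights)
rs <- wrsr(panel, ew$weights)
tail(data.frame(C = round(ts$closeness, 4), topsis_rank = ts$ranks,
                WRSR = round(rs$wrsr, 4), wrsr_rank = rs$ranks), 4)
#>           C topsis_rank   WRSR wrsr_rank
#> 2015 0.8733           4 0.8746         2
#> 2016 0.8863           3 0.9608         1
#> 2017 0.8943           2 0.8668         3
#> 2018 0.9168           1 0.7897         4
```

TOPSIS (metric) says care improved monotonically through 2018; WRSR
(ordinal) puts 2016 first because 2018's registration-rate dip costs it
whole ranks. The fuzzy stage adjudicates:

```r
fz <- fuzzy_evaluate(ts$closeness, rs$wrsr)
fz$comprehensive_rank
#> 2004 2005 2006 2007 2008 2009 2010 2011 2012 2013 2014 2015 2016 2017 2018
#>   15   14   13   12   11   10    9    8    7    6    5    3    1    3    4

concordance_table(ts$ranks, rs$ranks, fz$scheme_ranks[, 2])
#>              pair       rho sum_d2            p
#> 1  TOPSIS vs WRSR 0.9642857     20 7.072303e-09
#> 2 TOPSIS vs fuzzy 0.9750000     14 7.143706e-10
#> 3   WRSR vs fuzzy 0.9928571      4 2.168121e-13
```

All three rankings agree strongly (ρ ≥ 0.96): maternal health care
improved essentially year by year, with 2015–2018 at the top and
2004–2006 at the bottom. Stability under weight perturbation:

```r
sw <- sensitivity_sweep(panel, ew$weights, k = 6)
nrow(rank_crossings(sw))   # 0 — the ranking never reacts to X6's weight
```

File-based workflows use `read_panel()` + a JSON schema sidecar, and
`run_evaluate()` / `run_sensitivity()` write the full table bundle (CSV +
JSON summary); `inst/cli/mcdaeval.R` exposes `evaluate`, `sensitivity`,
and `synth` subcommands.

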