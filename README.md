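# tmecoexpr

Pan-cancer T-cell co-expression ranking and immune-checkpoint target
complementarity.

## What it does, and for whom

Checkpoint-blockade immunotherapy (anti-PD-1, anti-CTLA-4) helps only a
minority of patients, and a natural place to look for complementary targets
is the set of genes consistently expressed by tumor-infiltrating T cells.
`tmecoexpr` is for computational immuno-oncologists who want that search as
a tested, reproducible pipeline rather than a notebook:

* **Co-expression ranking.** Within each cancer-type cohort, every gene is
  correlated (pairwise-complete Pearson) with the pan T-cell marker *CD3E*;
  genes are ranked by the median correlation across cancer types, with
  support for cohort exclusion (e.g. thymoma, where tumors of the thymus
  distort T-cell composition) and minimum-sample masking.
* **Complementarity scoring.** With ρ<sub>TC</sub>, ρ<sub>TP</sub>,
  ρ<sub>TA</sub> the correlations of a target gene with *CD3E*, *PDCD1* and
  *CTLA4* in one cancer type, each gene receives the PD-1 complementarity
  score |ρ<sub>TC</sub>|(|ρ<sub>TC</sub>| − |ρ<sub>TP</sub>|), or jointly
  |ρ<sub>TC</sub>| min{|ρ<sub>TC</sub>| − |ρ<sub>TP</sub>|,
  |ρ<sub>TC</sub>| − |ρ<sub>TA</sub>|}, per type; per-type scores are
  medianed across types and ranked. High scores mean "tracks T-cell
  abundance, not the existing checkpoint targets".
* **Preranked gene-set enrichment.** A from-scratch weighted running-sum
  enrichment statistic on the median-correlation ranking, with a
  gene-permutation null, normalized enrichment scores (NES), nominal
  p-values and FDR q-values.
* **Responder analysis.** Per response group, *PDCD1* is regressed on
  *CD3E* (TPM); groups are compared by Pearson r, R², and a two-sided
  Mann–Whitney U test on squared residuals, with an outlier-exclusion
  rerun.
* **Ground-truth simulation.** A two-factor linear-Gaussian expression
  simulator with closed-form planted correlations
  (λ/√(λ² + κ² + σ²) against the marker) so every stage is testable against
  known truth; defaults emulate a 31-cancer-type, ≈9,600-tumor collection.

File formats: tab-separated expression matrices (genes × samples, `NA`
missing cells), GMT gene-set collections, RNK preranked lists, and a
responder cohort TSV — all with strict, validating parsers.

## Worked example

```r
library(tmecoexpr)

out <- tempfile("tme_run_")
cfg <- pipeline_config(out, seed = 1)   # default study-shaped simulation
res <- run_full_pipeline(cfg, quiet = TRUE)

print(res$ranked, n = 6)
#> ranked gene table: 103 genes (marker correlation medians)
#>    gene median_r rank
#> 1  CD3E    1.000    1
#> 2   CD2    0.955    2
#> 3 TC001    0.938    3
#> 4 TC002    0.919    4
#> 5 TC003    0.910    5
#> 6 TC004    0.891    6
#> ... 97 more rows
```

The marker trivially tops its own ranking; the planted `CD2`-like gene is
recovered at its designed median correlation of 0.955, and the remaining
T-cell-axis genes follow in loading order.

```r
print(res$complementarity$pdcd1, n = 5)
#> pdcd1 complementarity: 103 genes, 31 cancer types
#>    gene median_score score_rank median_rho_tc rho_tc_rank
#> 1  CD3E        0.185          1         1.000           1
#> 2   CD2        0.171          2         0.955           2
#> 3 TC001        0.166          3         0.938           3
#> 4 TC002        0.159          4         0.919           4
#> 5 TC003        0.155          5         0.910           5
#> ... 98 more rows

print(res$enrichment, n = 3)
#> preranked enrichment: 11 gene sets (NES descending)
#>              name size    es  nes        p     q degenerate
#> 1 TOP_COEXPRESSED   20 1.000 1.61 0.000999 0.000      FALSE
#> 2       RANDOM_04   20 0.656 1.05 0.267000 0.841      FALSE
#> 3       RANDOM_08   20 0.644 1.04 0.340000 0.841      FALSE
#> ... 8 more rows
```

Genes loaded only on the T-cell axis out-score the checkpoint stand-ins
(whose scores are dragged down by their own PD-1-axis loading), and the set
built from the top of the ranking is the only significantly enriched one —
the random sets sit at NES ≈ 1 with large q.

```r
print(res$responders$rerun)
#> == full cohort ==
#> CD3E-PDCD1 coupling by response group
#>   responders    (n = 14): r = 1.000, R^2 = 1.000
#>   nonresponders (n = 12): r = 0.703, R^2 = 0.494
#>   squared residuals: U = 18.0, two-sided p = 0.0007545 (normal-approximation)
#>   responders have smaller squared residuals
#> == excluding P14 ==
#> CD3E-PDCD1 coupling by response group
#>   responders    (n = 13): r = 0.996, R^2 = 0.993
#>   nonresponders (n = 12): r = 0.703, R^2 = 0.494
#>   squared residuals: U = 14.0, two-sided p = 0.0005525 (normal-approximation)
#>   responders have smaller squared residuals
```

Responders show far tighter *CD3E*–*PDCD1* coupling than non-responders
(R² ≈ 1.0 versus ≈ 0.49, squared residuals significantly smaller), and the
contrast survives removal of the planted very-high-expression outlier
(sample `P14`) — the signature expected when response to anti-PD-1 therapy
tracks consistent PD-1 expression on infiltrating T cells.

## Documentation

The methods vignette (`vignettes/tme-coexpression.Rmd`) describes the
factor model behind the simulator, every tunable parameter and default,
the numerical conventions (tie-breaking, missing-cell policy, permutation
null, FDR monotonization), and what the test suite does and does not
establish about real tumor data.
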