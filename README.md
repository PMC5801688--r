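# phiscan

Non-parametric discovery and held-out validation of genomic markers of
in vitro drug response.

## The problem

Large pharmacogenomic screens test panels of drugs against hundreds of
molecularly profiled cancer cell lines, summarising each drug–cell pair by
its half-maximal inhibitory concentration (stored here as logIC50, the
log10 of IC50 in µM, so a value of 1 means 10 µM and differences read as
orders of magnitude on the molar scale). The scientific question, asked
for thousands of drug–gene pairs at once, is whether a mutation in gene
*j* discriminates cell lines by their sensitivity to drug *i*. Parametric
tests (ANOVA/MANOVA) answer it under normality and equal-variance
assumptions that real drug-response distributions — skewed, contaminated
with outliers, heteroscedastic — routinely violate, which both misses real
markers and flags spurious ones.

## The method

phiscan poses each drug–gene association as a binary classification
problem:

1. **Mutation-dependent threshold.** With `medMT` and `medWT` the median
   logIC50 of the mutant and wild-type cell lines,
   `thres = (medMT + medWT)/2`. If `medMT < medWT` the mutation marks
   *sensitivity* (observed positives are cells with `logIC50 < thres`),
   otherwise *resistance* (positives are cells with `logIC50 ≥ thres`).
   Medians make the boundary robust to outliers and skew; the midpoint
   makes it independent of group sizes.
2. **Discrimination.** Mutation status is the prediction, threshold side
   the observation; the 2×2 table (TP/FN/FP/TN) is summarised by the φ
   coefficient — identical to the Matthews correlation coefficient,
   `φ = (TP·TN − FP·FN) / √((TP+FN)(FN+TN)(TN+FP)(FP+TP))`.
3. **Significance.** Pearson's χ² statistic (no continuity correction)
   obeys the exact identity `χ² = n·φ²` and is referred to the df = 1
   upper tail; Benjamini–Hochberg step-up control at FDR q = 20% selects
   significant associations. The identity also yields the minimal
   significant φ at sample size n, `φ_min = √(χ²_crit/n)` — about 0.15 at
   n = 300 and 0.12 at n = 450 for the critical p-value 0.00940155.
4. **Consensus (optional).** Calls can be intersected with an external
   per-association p-value set (e.g. released MANOVA results), BH-adjusted
   over the same pairs.
5. **Held-out validation.** On a newer release's cell lines never used in
   discovery, each marker predicts sensitivity (mutants on the marker's
   training direction side) against an absolute drug-level threshold: the
   median of *all* training logIC50s for the drug. Test performance is the
   MCC of that table; MCC > 0 beats random classification.

## Worked example

```r
library(phiscan)

spec <- synthetic_spec(n_cells = 300, n_drugs = 3, n_features = 25,
                       prevalence = 0.25, baseline_mean = c(-0.5, 0.5, 1),
                       noise_sd = 0.5,
                       planted = data.frame(drug = c("drug01", "drug02"),
                                            feature = c("gene01", "gene02"),
                                            delta = c(-2, 1.5)),
                       seed = 20)
train <- simulate_panel(spec)
fit <- marker_scan(train$response, train$mutation, q = 0.2)
summary(fit)
#> 75 associations scored, 2 significant at FDR q = 0.2 (critical p = 3.02208e-27)
#> ...
#> Strongest associations:
#>    drug feature   n prevalence   direction    phi    chi2         p significant
#>  drug01  gene01 208     0.2692 sensitivity 0.9150 174.151 9.176e-40        TRUE
#>  drug02  gene02 202     0.2376  resistance 0.7607 116.898 3.022e-27        TRUE
#>  drug03  gene22 223     0.3049 sensitivity 0.1767   6.965 8.313e-03       FALSE
```

Both planted effects — a 2-log-unit sensitising shift on drug01:gene01 and
a 1.5-log-unit resistance shift on drug02:gene02 — are recovered with the
correct direction (φ = 0.92 and 0.76; `chi2` is exactly `n * phi^2`), and
nothing else survives BH control. Validating on a second simulated release
of 200 new cell lines:

```r
val <- validate_markers(fit, test_response, test_mutation)
val$results[, c("drug", "feature", "n_train", "phi", "p", "n_test", "mcc_test")]
#>     drug feature n_train   phi        p n_test mcc_test
#> 1 drug01  gene01     208 0.915 9.18e-40    142    0.721
#> 2 drug02  gene02     202 0.761 3.02e-27    141    0.516
```

Both markers beat random classification (MCC > 0) on cell lines never seen
during discovery. `plot(fit, drug = "drug01", feature = "gene01")` draws
the association's response scatter with group medians and the threshold;
`plot(fit)` shows φ against −log10 p across all associations.

Real panel files in the documented CSV dialect (cell lines × drug-response
and `x::y` mutation-descriptor columns) are read with `read_gdsc_panel()`,
which converts natural-log IC50 files to log10 at ingest. A shell pipeline
(`simulate` / `discover` / `validate` subcommands, YAML config) is
installed at `inst/cli/phiscan`.

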