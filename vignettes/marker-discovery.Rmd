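---
title: "Discovering and validating drug-response markers with phiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating drug-response markers with phiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phiscan)
```

## The model

For one drug–gene association we observe pairs $(y_k, x_k)$,
$k = 1,\dots,n$: $y_k$ the logIC50 (log10 µM) of cell line $k$ for the
drug, $x_k \in \{0,1\}$ its mutation status for the gene. Writing
$\mathrm{medMT}$ and $\mathrm{medWT}$ for the group medians, the
association-specific threshold is

$$\mathrm{thres} = \frac{\mathrm{medMT} + \mathrm{medWT}}{2}.$$

If $\mathrm{medMT} < \mathrm{medWT}$ the mutation marks **sensitivity**
and observed positives are cells with $y < \mathrm{thres}$; otherwise it
marks **resistance** and positives are cells with $y \ge \mathrm{thres}$.
Cross-classifying mutation status (the prediction) against threshold side
(the observation) gives a 2×2 table whose φ coefficient — the Matthews
correlation coefficient — measures discrimination, and whose Pearson χ²
statistic, computed without continuity correction, satisfies the exact
algebraic identity

$$\chi^2 = n\,\varphi^2,$$

referred to the upper tail of $\chi^2_1$. Benjamini–Hochberg step-up
control at FDR level $q$ over all scored associations yields the marker
calls, and inverting the identity gives the minimal significant φ at
sample size $n$: $\varphi_{\min} = \sqrt{\chi^2_{\mathrm{crit}}/n}$, i.e.
significance thresholds that tighten as $1/\sqrt{n}$.

The only distributional input is the group median, so the procedure is
insensitive to the skew, outliers and unequal variances that plague
parametric tests on drug-response data. The trade-off is binarisation:
every misclassified cell line counts the same however far it lies from
the threshold.

Validation is a separate, *inter*-association classification problem on
cell lines that were not available at discovery time: the drug-level
sensitivity threshold is the median of **all** training logIC50s for the
drug (absolute sensitivity, deliberately different from the
mutation-dependent discovery threshold), mutants are predicted on the
marker's frozen training direction, and performance is the MCC on the
held-out table. MCC > 0 is the "beats random classification" criterion.

## Tunable parameters

* `q` (default **0.20**): the BH FDR level. The default matches the
  conventional 20% level of large pharmacogenomic screens; at this level
  roughly one call in five is expected to be false, which is why held-out
  validation is part of the pipeline rather than an afterthought.
* `scale` (`"log10"`/`"ln"`, ingest only): raw screen exports often store
  natural-log IC50 in µM; conversion to log10 happens exactly once, at
  read time, so that shifts are orders of magnitude on the molar scale.
  `to_log10()` is deliberately non-idempotent and tested as such, to
  guard against double conversion.
* `strict` (default `FALSE`): significance is `p ≤ critical` (standard
  step-up); a strict `<` variant is provided because published analyses
  sometimes print the strict inequality. At double precision the choice
  is immaterial except for exact ties at the critical value.
* Generator parameters: see below.

## Conventions and numerical choices

* **Ties at the threshold** follow the defining inequalities verbatim:
  strict `<` on the sensitive side, `≥` on the resistant side, both at
  discovery and at validation. No jitter is applied; with continuous
  responses exact ties occur with probability zero, and with discrete
  fixtures the rule is what the tests pin down.
* **Equal medians** (`medMT = medWT`) fall to the resistance branch and
  are flagged `degenerate`; such associations are still reported, but the
  guarantee φ ≥ 0 no longer holds for them.
* **Even-sized groups** use the standard midpoint-of-central-order-
  statistics median.
* **No continuity correction**: a Yates-corrected χ² would break the
  χ² = n·φ² identity that links discrimination and significance.
* **Extreme p-values** are computed with the χ²₁ survival function
  directly (`lower.tail = FALSE`), not as `1 − CDF`, so associations as
  strong as φ = 0.65 at n = 284 (p ≈ 6.4·10⁻²⁸) remain representable
  down to ~10⁻³⁰⁰.
* **Unscorable pairs** (no mutant or no wild-type cell among the drug's
  tested cells, or fewer than two usable cells) are skipped and logged,
  never imputed; BH is applied once, over the scored associations only,
  so the multiple-testing universe is explicit in the output.
* **Validation degeneracies** are kept distinct: a marker with *no mutant
  test cell* yields no prediction and is recorded non-evaluable
  (`mcc_test = NA`), while a test table with a zero marginal for any
  other reason scores `mcc_test = 0` ("no better than random") with a
  degenerate flag. Fractions of markers beating random are computed over
  evaluable markers only.
* **Result files** write doubles with 17 significant digits so that
  `read_results()` reproduces them bit-for-bit.

## The mutation-descriptor dialect

Screen exports encode per-gene calls as `x::y` strings — `x` a coding
variant token, `y` a copy-number token. The published description of the
format is verbal, not a grammar, so this package fixes a canonical
dialect: `x ∈ {wt, na, <variant>}`; `y ∈ {0<cn<8, cn=K, na}`. A feature
is **mutated** if a variant is present (`x ∉ {wt, na}`) or the copy
number leaves the wild-type range (`cn = 0`, deletion, or `cn ≥ 8`,
amplification — the range is open on both sides); **wild-type** if no
variant is present *and* the copy number is inside the range; otherwise
**missing** (e.g. `na::na`). Unrecognised token shapes degrade to missing
with a logged warning rather than a hard error, so real-world files with
dialect drift still load; a malformed separator, by contrast, is a format
error naming the offending column. Gene fusions (e.g. `BCR_ABL`) and
microsatellite-instability status enter as ordinary binary features once
parsed. Duplicate drug columns (re-screened compounds) keep the most
broadly tested instance, ties broken by first occurrence.

## The synthetic-data generator

`synthetic_spec()` / `simulate_panel()` emulate the shape of a real
screen release so that every stage is testable without external data:

* **n_cells = 300** by default: large screens concentrate around ~300
  cell lines per drug (with a second group near 450).
* **missing_fraction = 0.3**: real releases measure roughly 55–80% of
  all drug–cell pairs; 70% filled sits in that band.
* **prevalence** log-uniform on [0.02, 0.5] per feature: cancer-gene
  alterations range from rare point mutations to common ones, and a
  log-uniform draw covers that spectrum without favouring either end.
* **baseline_mean** per drug uniform on [−1, 2] log10 µM and
  **noise_sd = 1**: typical potency centres and across-cell-line spread.
  A drug's baseline is a drug property: when simulating a training and a
  test release of the *same* screen, pass the same `baseline_mean` vector
  to both specs, otherwise the drug-median validation threshold is
  meaningless by construction.
* **noise families**: `gaussian`; `skewed`, a variance-standardised
  centred log-normal (σ = 0.75, skewness ≈ 2.9); `contaminated`, a
  gaussian with 5% of draws inflated 5-fold — the three pathologies the
  method is designed to tolerate. Parameters are spec fields with these
  defaults, since the pathologies are only ever described qualitatively
  for real data.
* **planted effects** shift the mutant group additively on the log10
  scale (negative = sensitising), the same scale the thresholds operate
  on; the truth table is returned and written alongside the panel.
* **Reproducibility**: `simulate_panel()` seeds R's default
  Mersenne-Twister generator from `spec$seed`, so output is
  bit-reproducible for a fixed seed and package version, and written
  panels round-trip exactly through the CSV dialect.

What the generator does **not** emulate: tissue-of-origin structure and
its confounding, correlated mutations (features are independent),
measurement error shared across releases, dose–response curve fitting
artefacts, and genuine biological effect-size distributions. Passing
tests on synthetic panels therefore demonstrate the statistical machinery
under controlled conditions, not performance on any particular real
screen.

## Null calibration: a known limitation

The threshold is estimated from the same responses it then classifies.
Under a global null this adapts the boundary toward whatever accidental
separation the group medians show — at least half of each group always
lies on "its" side of the midpoint — so the χ² statistic is
stochastically larger than a χ²₁ draw and the test is mildly
anti-conservative in finite samples. The package's acceptance script
measures this directly on null panels at n = 300 (the KS distance of the
p-values from uniform, and the realized panel-level false-discovery
proportion under BH at q = 0.2, which comes out above the nominal level).
The distortion shrinks as n grows, since both group medians converge to
the common population median; users analysing small panels should treat
borderline calls with corresponding caution, and the held-out validation
stage exists precisely to catch them. We chose not to "repair" this with
a continuity correction or permutation calibration: the former breaks the
χ² = n·φ² identity the method is built on, and the latter changes the
procedure being studied.

A second, unrelated caveat: reproducing published marker *counts* from a
released screen also depends on that screen's exact association universe
(which pairs entered multiple testing), which released p-value tables do
not fully determine; the package applies standard BH step-up over the
pairs it can score and reports the critical value it used.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on simulated
panels chosen to exercise the method at realistic scale while staying
quick on one CPU: identity and BH oracle checks on 10⁴ random tables and
~3·10³ grid vectors; null calibration on 50 replicates of a 300 × 1000
panel; planted-marker recovery over 100 replicates of a 300-cell panel
(Δ = 2 log units, sd 0.5, prevalence 0.3) validated on 150 new cells;
and a 5-replicate, 6-drug × 80-feature comparison of consensus, χ²-only
and external-only call sets in which the "external" test is a
rank-distorted copy of the scan's own evidence plus a 3% sprinkling of
spurious strong calls — a deliberately simple stand-in for an independent
parametric test that preserves most true signal while adding false calls.
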