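# oralscore

Semi-quantitative immunohistochemistry (IHC) scoring of oral squamous
lesions for pathologists and biostatisticians working on oral cancer
diagnostics.

Low-grade oral malignancies — above all oral verrucous carcinoma (OVC) —
are notoriously hard to call on small pre-treatment biopsies, because the
decisive feature (stromal invasion) is often not captured in the sample.
`oralscore` implements a four-biomarker scoring system that grades three
biological traits of malignancy from routine IHC staining patterns:

| Trait | Marker(s) | Patterns | Pattern score |
|---|---|---|---|
| Differentiation | CK13 | A / B / C | 0 / 1 / 2 |
| Differentiation | CK17 | A / B / C | 0 / 1 / 2 |
| Proliferation | Ki-67 | A / B / C | 0 / 3 / 3 |
| Invasion | Ln5γ2 (laminin-5 γ2) | A1, A2 / B / C / D | 0 / 4 / 4 / 4 |

The **total score** of a specimen is the sum of its four pattern scores,

```
S = s(CK13) + s(CK17) + s(Ki-67) + s(Ln5γ2),   S ∈ [0, 11],
```

and a specimen with `S ≥ 9` is classified at **immediate risk** of oral
squamous malignancy. Because Ln5γ2 carries weight 4 and Ki-67 weight 3,
`S ≥ 9` requires all three traits to be abnormal at once; an
Ln5γ2-negative specimen can reach at most 7, so a biopsy with `S ≥ 5` but
no Ln5γ2 positivity is flagged for re-sampling instead (the invasion
front may simply have been missed).

Around this core the package provides:

* cohort summaries: pattern prevalence, total-score histograms,
  proportion at/above a cutoff, Pearson χ² comparisons of pattern
  proportions between diagnosis groups, and data-driven cutoff selection;
* two-observer reliability: per-marker Cohen's κ on pattern calls and
  binary benign/malignant agreement at the cutoff;
* paired tumor-vs-normal log-expression tests for the genes matching the
  IHC panel (KRT13, KRT17, MKI67, LAMC2);
* a synthetic-data layer: deterministic fixture cohorts reconstructing
  the published discovery (33 OVC + 21 OSCC) and validation (34 biopsy)
  cohorts, plus seeded generators for pattern cohorts, rater pairs and
  paired expression tables;
* CSV/TSV readers and writers, a JSON-reporting pipeline, and a thin
  command-line wrapper (`inst/cli/oralscore.R`).

## Worked example

Score three biopsies and reproduce the cohort-level statistics:

```r
library(oralscore)

biopsy <- specimen_table(
  specimen_id = c("bx_101", "bx_102", "bx_103"),
  group = "biopsy",
  ck13 = c("C", "B", "A"), ck17 = c("C", "A", "A"),
  ki67 = c("B", "C", "A"), ln5g2 = c("D", "B", "A1")
)
score_specimens(biopsy)
#>  specimen_id score_ck13 score_ck17 score_ki67 score_ln5g2 total_score      risk_tier
#>       bx_101          2          2          3           4          11 IMMEDIATE_RISK
#>       bx_102          1          0          3           4           8  INDETERMINATE
#>       bx_103          0          0          0           0           0            LOW
```

`bx_101` carries all three malignant traits (total 11 ≥ 9): immediate
risk. `bx_102` is Ln5γ2-positive but differentiation is near-normal
(total 8): indeterminate. `bx_103` is pattern-normal throughout.

The deterministic discovery fixture reproduces the published cohort
statistics:

```r
fx <- build_discovery_fixture()          # 33 OVC + 21 OSCC
sc <- score_specimens(fx)
proportion_at_or_above(sc, 9)
#> $count    52
#> $n        54
#> $fraction 0.962963
#> $percent  96

ovc  <- pattern_prevalence(fx, "LN5G2", group = "OVC")
oscc <- pattern_prevalence(fx, "LN5G2", group = "OSCC")
compare_pattern_proportions(ovc, oscc, "D")
#> Pearson chi-square on 2x2 table
#>       pattern
#> cohort in out
#>   OVC   5  28
#>   OSCC 12   9
#> X-squared = 10.49, df = 1, p = 0.0012

select_cutoff(score_histogram(sc))       # largest cutoff keeping >= 95%
#> [1] 9
```

52 of the 54 malignancies (96%) score at or above 9; the diffuse-Ln5γ2
comparison between OSCC (12/21) and OVC (5/33) gives p = 0.0012; and the
formalized cutoff rule recovers 9.

## Command line

```sh
Rscript inst/cli/oralscore.R score --input specimens.csv --out scored.csv
Rscript inst/cli/oralscore.R summarize --input specimens.csv --compare OVC,OSCC --out report/
Rscript inst/cli/oralscore.R fixtures --out fixtures/
```

Subcommands: `score`, `summarize`, `compare-patterns`, `kappa`,
`expr-test`, `simulate`, `fixtures`; each supports `--help`.

## Caveats

The fixture cohorts reconstruct published *marginal* counts and
documented total-score facts; per-specimen call combinations were never
published and are canonical synthetic choices (see the provenance notes
attached to each fixture and the methods vignette). The published
inter-observer κ values cannot be recomputed — the raw two-observer calls
are unavailable — so the agreement module is validated by its defining
properties instead. Pattern calls are made by a pathologist; the package
does no image analysis.
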