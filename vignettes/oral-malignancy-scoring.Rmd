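---
title: "Methods: a four-biomarker IHC scoring system for oral squamous lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-biomarker IHC scoring system for oral squamous lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralscore)
```

## The diagnostic problem

Invasion through the basement membrane is the defining feature of
squamous malignancy, but small pre-treatment biopsies frequently miss
the invasion front — especially in oral verrucous carcinoma (OVC), a
low-grade verruco-papillary malignancy that is often under-called as a
benign or reactive lesion. The scoring system implemented here grades
three surrogate biological traits from routine immunohistochemistry so
that a biopsy can be ranked by its similarity to established oral
squamous malignancy even when invasion itself is not captured:

* **differentiation** — CK13 is progressively lost and CK17
  progressively gained in malignant squamous epithelium;
* **proliferation** — Ki-67 localization shifts from the 1st parabasal
  layer (normal) to predominant basal or diffuse basal + parabasal
  staining;
* **invasion** — cytoplasmic laminin-5 γ2 (Ln5γ2) in tumor cells at the
  tumor–stroma interface marks active invasion.

## The model

Each marker's staining pattern is a nominal category called by a
pathologist. The pattern-score table weights the categories by the
biological importance of the trait they represent:

```{r}
pattern_score_table()
```

Invasion (Ln5γ2 positivity, any of patterns B/C/D) scores 4 — more than
the maximal differentiation evidence of a single keratin (2); oncogenic
proliferation (Ki-67 B or C) scores 3 — more than 2. The total score is
the plain sum over the four markers, so the scale is 0–11 and the bands
are interpretable: a total of 9 or more is attainable only when all
three traits are simultaneously abnormal (Ln5γ2 4 + Ki-67 3 + at least
2 combined keratin points). This is an exhaustive fact over the
3×3×3×5 = 135 admissible pattern combinations, checked in the test
suite: every Ln5γ2-negative combination totals ≤ 7.

Two Ln5γ2-negative observations — no staining at all (A1) and staining
confined to an intact basement membrane (A2) — are biologically distinct
and are kept as distinct labels; they share score 0, and cohort
statistics may collapse them.

### Risk tiers

The published rule names only the `≥ 9` band (immediate risk) and the
Ln5γ2-negative `≥ 5` alert. The tier rule is therefore a configurable
policy object (`risk_policy()`):

* `IMMEDIATE_RISK` — total ≥ cutoff (default 9);
* `ALERT_RESAMPLE` — Ln5γ2-negative, total ≥ alert threshold (default
  5): typical abnormal differentiation/proliferation with no invasion
  marker may mean the biopsy missed the invasion front; re-sample or
  follow closely;
* `INDETERMINATE` — Ln5γ2-positive with total 5–8: our own name for a
  band the source rule leaves unnamed (invasion marker present but the
  other traits too normal for the high-risk band);
* `LOW` — everything else.

Missing marker calls are an error by default; `missing = "lower_bound"`
scores absent markers 0 and flags the specimen, because a real biopsy
can fail a stain — the total is then a lower bound and the tier is the
most conservative one consistent with the observed calls.

## Cohort statistics

* **Prevalence and display.** Per-marker pattern counts with integer
  percents rounded half away from zero (15/33 displays as 45), the
  convention of the source tables; full precision is kept internally.
* **Pattern comparisons.** Each published comparison collapses one
  marker to "target pattern(s) vs all others" and tests the 2×2 table
  with the Pearson χ² (df = 1, **no** continuity correction — this is
  what reproduces p = 0.0012 for diffuse Ln5γ2, 5/33 OVC vs 12/21 OSCC,
  and p = 0.18 for CK17 pattern C, 26/33 vs 13/21, from the printed
  counts). A Yates flag exists but defaults off; an uncollapsed r×2 test
  is provided for completeness. The implementation delegates to
  `stats::chisq.test`; the test suite checks it against an independent
  Σ(O−E)²/E evaluation on 1,000 random tables.
* **Cutoff selection.** The source chose 9 by inspection of the
  malignant-cohort score distribution. `select_cutoff()` formalizes
  this as *the largest cutoff retaining at least `min_coverage` of the
  malignant cohort*, default 0.95: on the discovery fixture (52/54 at
  ≥ 9, fewer at ≥ 10) this yields 9. The default is part of the method's
  definition, not a tuned value.

One printed p-value (0.06 for the Ki-67 comparison, 22/33 vs 6/21)
cannot be reproduced by any standard 2×2 test on the printed counts
(Pearson ≈ 0.006, Yates ≈ 0.014); it is presumably a typographical slip
in the source and is not used as a reference value anywhere in this
package.

## Agreement

Inter-observer reliability uses unweighted (nominal) Cohen's κ per
marker, computed over the marker's full admissible label set so unused
labels keep the cross-table shape stable; A1/A2 are distinct categories
by default (`collapse_a` merges them; `on = "score"` computes κ on
pattern scores instead of labels — whether the source computed κ on
labels or scores is unstated, and labels are the stricter choice).
Binary diagnostic agreement is the fraction of specimens on which both
observers land on the same side of the cutoff; disagreements confined to
score-equivalent labels (Ki-67 B vs C, Ln5γ2 B/C/D) provably cannot
lower it.

The published κ values (0.83–0.87) and the 100% binary agreement cannot
be recomputed because the two observers' raw calls were never published;
the module is instead validated by defining properties: perfect
agreement ⇒ κ = 1, independent simulated raters at n = 10,000 give
|κ| < 0.05, equality with a brute-force evaluation of the κ formula on
random cross-tables, and the score-equivalence property above.

## Paired expression comparison

The genes encoding the four markers (KRT13, KRT17, MKI67, LAMC2) are
compared between matched tumor and adjacent normal epithelium by a
paired t-test on log-transformed expression. Choices:

* **log base 2** (the customary expression scale; the base only rescales
  the effect estimate — t and p are base-invariant, which is tested);
* **paired**, because samples are matched per patient (a Welch unpaired
  test would discard the pairing); the source does not state pairedness
  explicitly, but the samples are explicitly matched pairs;
* **no pseudocount by default** — a zero value is an error unless a
  pseudocount is supplied deliberately;
* zero-variance differences (an exactly constant fold change) make the
  t statistic infinite: the result is flagged `zero_variance` and
  reports p = 0 by convention (p = 1 and direction `"flat"` when the
  difference is identically zero).

The source figure reports these comparisons only graphically, so this
stage is validated by simulation recovery: panels generated with
KRT13 fold change 0.5 and the others 2.0 at n = 40 pairs recover the
correct directions at p < 0.05, and null panels keep the empirical
type-I error within 3 points of the nominal 5% over 2,000 replicates.

## The synthetic-data layer

Two kinds of synthetic data with different provenance, both documented
on the objects themselves:

* **Deterministic fixtures** reconstruct the printed cohorts.
  `build_discovery_fixture()` reproduces every per-marker marginal count
  of the 33 OVC + 21 OSCC discovery cohort exactly, and hand-solves the
  joint call assignment to honor the documented total-score facts:
  exactly 52/54 specimens at ≥ 9, the two sub-9 specimens being OVC —
  the single Ln5γ2-negative specimen and one CK13-B/CK17-A specimen with
  focal Ln5γ2 positivity (total 8; any Ln5γ2-positive CK13-B/CK17-A
  assignment is equivalent and one is chosen canonically). Every OSCC is
  automatically ≥ 9 (Ln5γ2 4 + Ki-67 3 + CK13/CK17 ≥ 1 each). The
  remaining calls are paired positionally, which induces arbitrary
  joint structure: *only the marginals and the documented constraints
  are reconstructed facts.* The validation fixture pins only the 31/34
  split (sub-9 totals 5/7/8, above-cutoff totals 9/10/11 in a 4/17/10
  split are canonical choices); the printed per-column histogram digits
  of the source table are run together ambiguously and are deliberately
  not pinned. The benign/malignant fixture realizes the 11-below /
  11-at-or-above split with the stated subgroup sizes; the unenumerated
  eleventh benign specimen is labeled `benign_unspecified`.
* **Seeded generators** emulate the statistical structure the analysis
  assumes. `generate_pattern_cohort()` draws markers *independently*
  per specimen from per-marker multinomials (defaults: the empirical
  discovery-cohort frequencies) — real markers are correlated through
  lesion severity, so generated cohorts match marginal prevalence but
  not joint structure, and passing tests on them demonstrates correct
  statistics, not biological realism. `generate_rater_pairs()` flips
  each call with a configurable probability to a uniformly chosen
  different label (real observer confusions are adjacent-category,
  not uniform). `generate_expression_pairs()` draws normal expression
  log-normally (baseline 2^7 ≈ 128 units, log2 SD 1.5 — a typical
  microarray-intensity spread) and multiplies by the gene's fold change
  and log-normal noise (default SD 0.25 log2 units, giving n = 40
  panels comfortable power at twofold changes, matching the source's
  sample size). All randomness flows through an explicit seed argument;
  fixtures are seed-free and byte-identical across runs.

## Numerical and design notes

* Percent display rounds half away from zero; p-values print to 2
  significant figures; full precision is retained in all objects.
* χ² on a 2×2 with any zero margin is undefined and raises a
  degenerate-table error rather than returning NaN.
* κ with degenerate marginals (expected agreement 1) is defined as 1
  when observed agreement is also 1 (both raters constant and
  identical) and is an error otherwise.
* Pattern labels are case-insensitive on input and canonicalized to
  upper case; files are UTF-8; column names are fixed
  (`ck13`,`ck17`,`ki67`,`ln5g2`) to avoid per-lab naming drift.
* Problem sizes used by the test suite: exhaustive checks over the 135
  pattern combinations; 1,000 random tables for the χ² oracle; n =
  10,000 for the independent-rater κ and generator goodness-of-fit
  checks; 2,000 replicates of n = 40 panels for type-I control — sizes
  chosen so each property is measured with comfortable margin while the
  suite stays quick.

## Limitations

* Pattern calls are inputs made by a human; no slide-image analysis, no
  H&E morphology logic, and no rule for lesions whose staining straddles
  two categories (calls are taken as given).
* The fixtures' per-specimen call combinations are synthetic; any
  statistic that depends on the joint distribution beyond the documented
  constraints (e.g. correlations between markers) is not a
  reconstructed fact.
* No survival or outcome modeling, no ROC/logistic cutoff optimization
  — the cutoff rule is coverage-based by design.
* Certain non-malignant conditions (wound healing, lichen planus,
  bullous lesions) can express individual markers abnormally; the score
  supplements, and never replaces, routine H&E assessment.
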