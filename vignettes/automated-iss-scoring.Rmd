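---
title: "Automated Injury Severity Scores from ICD-10-GM codes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Injury Severity Scores from ICD-10-GM codes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icd2iss)
```

## The problem

The Injury Severity Score (ISS) is the standard anatomic measure of overall
trauma severity. Each injury receives an Abbreviated Injury Scale (AIS)
severity from 1 (minor) to 6 (maximal, currently untreatable), each injury
belongs to one of six body regions (head/neck, face, thorax, abdomen
including pelvic contents, extremities including the pelvic girdle,
external), and the ISS is the sum of squares of the highest AIS in the three
most severely injured regions:

$$\mathrm{ISS} = a_{(1)}^2 + a_{(2)}^2 + a_{(3)}^2, \qquad
  a_{(1)} \ge a_{(2)} \ge a_{(3)}$$

where \(a_{(k)}\) are the ordered per-region maxima. The score ranges 0-75
and an ISS of 16 or more conventionally defines severe polytrauma.

Manual AIS coding is accurate but slow and requires trained coders. Hospitals
in Germany and Switzerland, however, routinely hold every discharge diagnosis
as an ICD-10-GM code. Published automated crosswalks (the ICDPIC family)
translate ICD-10-**CM** codes into AIS/ISS, but the German modification
differs from the US clinical modification in both format and subcategory
semantics, so those tools cannot be applied directly. This package closes
that gap: it rewrites ICD-10-GM codes into canonical ICD-10-CM form through
pluggable correction tables, maps the result to AIS severities and body
regions through a GEM-style lookup, computes the ISS, and ships the complete
statistical protocol for validating automatic against manual scores.

## Code-format model

ICD-10-GM codes carry at most six significant characters (category `S22`,
subclass digits after the dot) and may attach secondary "detail" codes
marked with `!` (for example the `S06.7-!` family grading unconsciousness
after intracranial injury). ICD-10-CM codes extend the category with up to
three characters, an *information* character whose meaning depends on the
subcategory (laterality, duration of unconsciousness, ...) and an
*encounter* character (`A` initial, `D` subsequent, `S` sequela). Counting
the dot, the canonical CM rendering has eight characters, e.g. `S06.5X0A`;
the `X` is the official placeholder used to pad short subclassifications so
that the information and encounter characters always occupy the same
positions. All internal comparisons use the dotless significant characters -
the dot is presentation only - and lower-case input is normalised to
upper-case. Codes that have fewer characters than the canonical form are
legal inputs; `normalize_cm()` completes them and is idempotent.

Because the encounter character never influences severity it is set from a
single configurable default, `"A"`: trauma-room admissions are initial
encounters.

## The conversion pipeline

`convert_cohort()` runs three table-driven steps per patient:

1. **Recode rules** (`recode_rules.tsv`): dotless GM prefix to CM stem
   substitutions externalising the manual review of subcategory differences.
   The shipped fixture carries the canonical example - GM `S22.03` (fracture
   of the *fifth/sixth* thoracic vertebra) becomes CM `S22.05`, because CM's
   own `S22.03` means the *third* thoracic vertebra. Matching is
   longest-prefix on dotless codes, so a rule also covers GM codes more
   specific than its pattern, with the unmatched tail preserved; uniqueness
   of patterns makes ties impossible. A site's full review table is a
   drop-in replacement.
2. **Detail-code collection**: `!`-codes are removed from the injury list
   and mapped to interpretation tags through `detail_interpretations.tsv`
   (e.g. `S06.74!` to `loc_gt24h_no_return`); unrecognised detail codes
   become `"unknown"` annotations rather than errors.
3. **Seventh-character policies** (`seventh_char_policies.tsv`): per CM
   subcategory, the information character to emit. Conditional rows keyed
   on an annotation tag are consulted before the unconditional fallback, so
   a subdural haematoma accompanied by "unconscious more than 24 h without
   return" is emitted as `S06.5X6A` instead of `S06.5X0A`. Stems with no
   policy row fall back to the placeholder `X` with a warning - unreviewed
   stems must not abort a run. Codes outside the injury chapter S00-T88 are
   format-padded, tagged `unmapped_chapter` and warned about, again rather
   than aborting mixed discharge exports; they subsequently miss the AIS
   table and are reported as unmapped.

## AIS lookup and ISS

`load_ais_table()` reads rows of (CM prefix, candidate severity set, body
region). Real GEM-era crosswalks run ICD-10-CM through ICD-9-CM, where one
modern code can land on several legacy codes with different AIS values; this
package collapses the two steps into one prefix table whose rows may carry
several candidate severities, and the GEMmax/GEMmin mode picks the highest
or lowest candidate - the same observable choice the two-step mapping
offers. Lookup is longest-prefix, so rows keyed on a full code (e.g.
`S065X6`) override subcategory stems (`S065`).

Scoring conventions, all configurable or flagged:

* **AIS 6 cap**: any region at AIS 6 sets ISS = 75 outright (standard ISS
  convention; `cap_on_ais6 = FALSE` lets the 6 enter the sum of squares
  instead). The flag `ais6_cap` records when the cap fired.
* **Unknown severity**: severity 9 is the ICDPIC-style "unknown" sentinel.
  It never enters a per-region maximum or a GEM min/max over a mixed
  candidate set - ordering a sentinel is meaningless - and instead raises
  `unknown_severity_present`.
* **Contributing regions**: regions are ranked by severity with the region
  index as tie-break, so the reported up-to-three contributing regions are
  the lexicographically smallest subset achieving the score. The ISS value
  itself is tie-free because only values are summed.
* ISS analysis groups: 1 = 0-8, 2 = 9-15, 3 = 16-24, 4 = 25-40, 5 = 41-49,
  6 = 50-75, a partition of 0-75.

```{r}
ais <- load_ais_table(icd2iss_fixture("ais_table.tsv"))
score_cohort(convert_cohort(
  data.frame(patient_id = "p", icd_code = c("S06.5", "S06.74!"))), ais)
```

## The validation protocol

Given paired manual/automatic scores (sign convention: difference =
automatic - manual), `compare_report()` assembles:

* **Paired TOST** (`paired_tost()`): two one-sided one-sample t-tests of
  the mean difference against the equivalence bounds, default -3/+3 ISS
  points; the TOST p-value is the larger of the two and the
  \((1-2\alpha)\) = 90% confidence interval on the mean is reported.
  Zero-variance differences yield a degenerate, flagged result whose
  verdict is the mean's position inside the open bounds.
* **Wilcoxon signed-rank NHST** (`nhst_wilcoxon()`): two-sided, zeros
  dropped; exact null for 25 or fewer tie-free non-zero differences, normal
  approximation with continuity correction otherwise (ties force the
  approximation, as in `stats::wilcox.test`).
* **Dual-criterion verdict**: equivalent iff the TOST is significant *and*
  the NHST is not. The pairing of a parametric TOST with a nonparametric
  NHST is deliberate - it reproduces the protocol this package validates
  against - and both p-values are always reported separately.
* **Weighted Cohen's kappa** (`weighted_kappa()`): on the 6x6 group
  cross-tabulation, \(\kappa_w = (P_o - P_e)/(1 - P_e)\) with linear
  weights \(w_{ij} = 1 - |i-j|/(k-1)\) by default; interpretation bands
  poor (<= 0.20), fair, moderate, good, excellent at 0.20/0.40/0.60/0.80.
  Linear weighting is the default because it reproduces the published
  agreement value (0.47) on the embedded reference cross-tabulation;
  quadratic weights (which give 0.60 there) remain selectable.
* **Bonferroni correction** across the family of 7 equivalence tests
  (6 groups + overall). Verdicts use the raw p-values, mirroring the
  published decision rule; adjusted columns are reported alongside.
* **Per-region AIS analysis** when the twelve `manual_ais_*`/`auto_ais_*`
  columns are present: the same kappa and TOST machinery per body region
  on the 0-6 ordinal scale.

`tost_sample_size()` returns the smallest n whose paired-TOST power at a
true mean difference of zero reaches the target (default 80% at alpha 5%),
iterating the noncentral-t power expression

$$1 - \beta(n) = t_{\nu,\,\delta_U}(-t_{1-\alpha,\nu}) -
                 t_{\nu,\,\delta_L}(t_{1-\alpha,\nu}),\qquad
  \delta_{L,U} = \frac{0 - \{low, high\}}{\sigma/\sqrt{n}}$$

with \(\nu = n - 1\). The test suite brackets this formula against a
Monte-Carlo oracle. Note one intrinsic subtlety: for small \(\sigma\)
relative to the bounds the discrete power curve is coarse (at
\(\sigma = 3\), the smallest sufficient n jumps from 79% to 85% power
between consecutive n), so power self-consistency checks in this package
use \(\sigma = 7.73\) - a realistic disagreement SD for ISS scoring, where
one extra pair moves power by under one percentage point and the achieved
power at the returned n (59) is 80.7%.

## The synthetic cohort generator

No patient-level data ships with the package; `generate_cohort()` and
`generate_paired_scores()` make every layer testable.

* **What it emulates**: the ISS-group composition of a 640-patient trauma
  cohort (default group weights (219, 122, 155, 114, 13, 17)/640), sparse
  multi-region injury patterns (each region injured independently with
  probability 0.35), and group-appropriate severities (a per-group tilted
  proposal over AIS 1-5, exactness enforced by rejection sampling on the
  resulting ISS group). Codes are drawn from a curated ~30-code catalogue
  spanning all regions and severities 1-5, including the subdural
  haematoma + detail-code pair that exercises the conditional policy path.
  Extra same-region codes of lower severity emulate multiply-coded
  injuries without altering the per-region maxima, so ground truth is
  preserved by construction.
* **The disagreement model** for paired scores: the automatic score equals
  the manual one with probability `p_exact = 0.296` and is otherwise
  shifted by a rounded zero-mean normal with `shift_sd = 24`, clamped to
  [0, 75]. The two values were calibrated once by simulation so that the
  linear weighted kappa of the resulting cross-tabulation lands near the
  published 0.47 at n = 640, then frozen; they are deliberately *not*
  refit per run.
* **What it does not emulate**: real ICD coding behaviour (code
  frequencies, comorbidity patterns, miscoding), AIS severities above 5,
  region correlations, or any per-patient structure of real disagreement
  (which is driven by information genuinely missing from ICD codes, not by
  symmetric noise). Passing the recovery tests therefore demonstrates that
  the *pipeline machinery* is lossless on singleton-severity tables - it
  says nothing about the clinical accuracy of any particular crosswalk
  table, which is exactly the question a site must answer with its own
  validation data and the `compare` protocol.

## Numerical choices and problem sizes

* All randomness flows through explicit seeds (`generator_config(seed =)`,
  the CLI `--seed` flag); identical seeds give byte-identical outputs.
* The ISS implementation is verified against a sort-free subset-enumeration
  oracle over all \(6^6 = 46{,}656\) region profiles; weighted kappa
  against an explicit double-sum oracle on 1000 random 6x6 tables; the
  recode engine against a brute-force prefix/tail matcher; ground-truth
  recovery on 1000 synthetic patients; and the sample-size routine against
  a 10,000-replicate Monte-Carlo power estimate. These sizes keep the
  default suite under a minute while exhausting the discrete domains that
  can be exhausted.
* Degenerate inputs are defined, not crashed on: empty rule tables mean
  pure format padding; an empty AIS table means every lookup misses;
  patients with no mappable code are flagged `no_mappable_injury` with an
  unset ISS; an all-mass-in-one-cell kappa table is an explicit
  undefined-kappa error.

## Known limitations

* The shipped fixture tables cover the documented worked examples and the
  generator catalogue only; they are a demonstration corpus, not a
  clinical crosswalk. Production use requires dropping in a full review
  table and AIS mapping (the file formats are the interface).
* Syntactic validation only: codes are checked for shape and chapter, not
  against the official GM/CM catalogues, which are not redistributable.
* The sample-size routine targets the paired t-based TOST; if the
  equivalence decision were made with a nonparametric TOST its power would
  differ slightly.
* No New ISS (NISS), no AIS-2005 vs AIS-2015 dictionary translation, no
  mortality prediction.
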