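# icd2iss

Automated Injury Severity Scores from German ICD-10 (ICD-10-GM) trauma
diagnosis codes, with the full statistical protocol for validating
automatic against manual scoring.

## Who this is for

Trauma registries, quality-assurance teams and researchers in countries
using the German modification of ICD-10 hold every discharge diagnosis as
an ICD-10-GM code, but the established automated AIS/ISS crosswalks
(the ICDPIC family) only understand ICD-10-CM. `icd2iss` bridges that gap
with a transparent, table-driven pipeline:

```
GM codes --convert--> canonical CM codes --score--> AIS per region + ISS
                                             |
paired manual scores ----------------- compare: TOST + Wilcoxon + kappa
```

## The science in brief

* **ISS**: with `a_(1) >= a_(2) >= a_(3)` the ordered per-region maxima of
  the AIS over the six body regions (head/neck, face, thorax, abdomen,
  extremities, external),
  `ISS = a_(1)^2 + a_(2)^2 + a_(3)^2`, range 0-75; any region at AIS 6
  sets ISS = 75 by convention (configurable); ISS >= 16 defines severe
  polytrauma.
* **Conversion**: ICD-10-GM (<= 6 significant characters, optional `!`
  detail codes) is rewritten into eight-character ICD-10-CM
  (`S06.5X0A`-style) via longest-prefix recode rules, detail-code
  interpretation tags and per-subcategory seventh-character policies, all
  plain TSV tables.
* **AIS lookup**: GEM-style longest-prefix table mapping CM prefixes to
  candidate severity sets and regions; `gemmax`/`gemmin` picks the
  higher/lower candidate.
* **Validation**: paired TOST with bounds -3/+3 ISS points (p_TOST = max
  of the two one-sided t p-values, 90% CI), two-sided Wilcoxon
  signed-rank NHST, the dual criterion (equivalent iff TOST significant
  and NHST not), linearly weighted Cohen's kappa
  `kappa_w = (Po - Pe)/(1 - Pe)`, `w_ij = 1 - |i-j|/(k-1)`, on the 6x6
  ISS-group cross-tabulation, Bonferroni correction over the 7-test
  family, and a noncentral-t TOST sample-size routine.

## Worked example

```r
library(icd2iss)
ais  <- load_ais_table(icd2iss_fixture("ais_table.tsv"))
demo <- read.csv(icd2iss_fixture("demo_cohort.csv"))
conv <- convert_cohort(demo)
conv$conversions
#>   patient_id gm_code  cm_code                rules_fired
#> 1        P01   S06.5 S06.5X6A policy:loc_gt24h_no_return
#> 2        P01  S22.03 S22.05XA               recode:S2203
#> 3        P02   S06.5 S06.5X0A
#> 4        P02   S02.2 S02.2XXA
#> 5        P03   S52.5 S52.5XXA
#> 6        P03   S20.2 S20.2XXA
```

Patient P01 carries a subdural haematoma (`S06.5`) plus the detail code
`S06.74!` (unconscious > 24 h without return), so the conditional policy
emits `S06.5X6A`; the vertebral fracture `S22.03` is recoded to the CM
subcategory `S22.05` before padding. Scoring:

```r
score_cohort(conv, ais, mode = "gemmax")
#>   patient_id ais_head_neck ais_face ais_thorax ais_abdomen ais_extremities
#> 1        P01             5        0          2           0               0
#> 2        P02             4        1          0           0               0
#> 3        P03             0        0          1           0               2
#>   ais_external iss iss_group flags
#> 1            0  29         4
#> 2            0  17         3
#> 3            0   5         1
```

P01's ISS is 5^2 + 2^2 = 29 (group 4, severe polytrauma); P02's plain SDH
maps to AIS 4, giving 4^2 + 1^2 = 17. Agreement statistics on the embedded
640-patient reference cross-tabulation:

```r
weighted_kappa(reference_crosstab(), "linear")
#> Weighted kappa (linear weights): 0.470 ('moderate' agreement), n = 640

n <- tost_sample_size(sd = 7.73)   # bounds -3/+3, alpha 0.05, power 0.8
as.integer(n)                      # 59  (achieved power 0.807)
```

## Command line

An installed copy exposes `exec/icd2iss` with four subcommands; every
output file gets a `.manifest.json` with input checksums, seed and version.

```sh
icd2iss simulate --n 1000 --seed 7 --out cohort.csv --truth truth.csv
icd2iss convert  --in cohort.csv --out cm.csv
icd2iss score    --in cm.csv --ais ais_table.tsv --mode gemmax --out scored.csv
icd2iss compare  --in pairs.csv --alpha 0.05 --bounds -3,3 --out report.json
```

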