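# pnigars

Deterministic rule engines for two structured CT reporting systems for
pulmonary nodules — **PNI-GARS** (Pulmonary Node Imaging-Grading And
Reporting System, grades 0 < I < II < IIIa < IIIb < IIIc < IV) and **ACR
Lung-RADS 2022** (categories 1 < 2 < 3 < 4A < 4B, plus the 4X modifier) —
together with the diagnostic-accuracy machinery to compare them against
surgical pathology, and synthetic-cohort generation for benchmarking.

It is written for radiologists and biostatisticians who want the two
systems' rules as executable, auditable code: every classification returns
the ordered list of rules that fired, both screens dichotomize into
negative/positive (Lung-RADS 1–2 vs 3–4; PNI-GARS 0–II vs III–IV), and a
classified cohort tabulates into per-stratum confusion tables with

* sensitivity Se = TP/(TP+FN),
* specificity Sp = TN/(FP+TN),
* agreement rate AR = (TP+TN)/n,

each with a Wald 95% interval p ± z·√(p(1−p)/n), z = 1.959964. Paired
screens are compared with McNemar's test on the discordant pairs (exact
binomial below 25 discordant pairs, χ² = (b−c)²/(b+c) otherwise);
agreement rates with a 2×2 test selected by sample size n and the minimum
expected frequency T: Fisher's exact probability method if n < 40 or
T < 1, Yates-corrected χ² if n ≥ 40 and 1 < T < 5, plain Pearson χ²
otherwise.

## Worked example

```r
library(pnigars)

# An 11.0 mm solid nodule with central calcification and a fat component
hamartoma <- nodule_record("case1", "SN", 11.0,
                           benign_features = c("pure_calcification", "fat"))
classify_lungrads(hamartoma)$category
#> [1] "1"
classify_pnigars(hamartoma)$grade
#> [1] "0"

# A 9.0 mm part-solid nodule, 4.0 mm solid component, unchanged 16 months
psn <- nodule_record("case2", "PSN", 9.0, solid_component_diameter = 4.0,
                     stability_months = 16, course = "unchanged")
classify_lungrads(psn)$category   # baseline 3, stable >= 6 months -> 2
#> [1] "2"
classify_pnigars(psn)$grade       # sub-solid stability needs 5 years
#> [1] "IIIa"
```

Both engines agree the hamartoma is definitely benign (lowest rung of each
scale); the part-solid nodule is a negative screen under Lung-RADS after
its stability downgrade but remains a positive screen (grade IIIa) under
PNI-GARS, whose sub-solid downgrade requires five stable years.

Cohort level — reconstruct the built-in 7,781-nodule benchmark cohort,
classify it with both engines and compare:

```r
cohort <- classify_cohort(reconstruct_table3_cohort())
compare_systems(cohort)
#> Diagnostic accuracy by stratum and system
#>  stratum    system   TP   FN  FP  TN  Se%   Sp%  AR%
#>       SN Lung-RADS 1839   12 757 410 99.4  35.1 74.5
#>       SN  PNI-GARS 1848    3 569 598 99.8  51.2 81.1
#>      PSN Lung-RADS 1578   26  99   6 98.4   5.7 92.7
#>      PSN  PNI-GARS 1602    2  91  14 99.9  13.3 94.6
#>      GGN Lung-RADS    0 2488   0 566  0.0 100.0 18.5
#>      GGN  PNI-GARS 2401   87 262 304 96.5  53.7 88.6
#>      all Lung-RADS 3417 2526 856 982 57.5  53.4 56.5
#>      all  PNI-GARS 5851   92 922 916 98.5  49.8 87.0
#> ...
```

The rows show the classical screening trade-off: Lung-RADS classifies all
ground-glass nodules under 30 mm as category 2, so on a surgical GGN
stratum its sensitivity is 0 and its specificity 100%, while the
sign-driven PNI-GARS grades recover 96.5% sensitivity at 53.7%
specificity.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pnigars-cli.R reconstruct --output cohort.csv
Rscript inst/cli/pnigars-cli.R classify --input cohort.csv --output classified.csv
Rscript inst/cli/pnigars-cli.R compare --input cohort.csv --out-dir report/
```

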