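# adrmine

Association rule mining for spontaneous adverse-drug-reaction (ADR)
reports, for pharmacovigilance analysts working with JADER-style relational
databases (DEMO / DRUG / REAC CSV tables). Instead of screening one
drug–one event pairs, `adrmine` treats each case report as a market-basket
transaction and mines which reactions co-occur within a drug-class cohort,
and which reaction/age profiles predict patient gender.

For a rule X → Y over `t` case transactions, with `a` cases reporting both
sides, `b` only X, `c` only Y and `d` neither:

    support    = a / t
    confidence = a / (a + b)
    lift       = confidence / ((a + c) / t)
    conviction = (1 − supp(Y)) / (1 − confidence)        [NA when confidence = 1]

Rules are found by a from-scratch level-wise apriori (prefix-join candidate
generation, downward-closure pruning, tid-list counting), default
thresholds support ≥ 0.001 and confidence ≥ 0.8, then ranked by descending
support. The package also ships a synthetic JADER-like generator with
planted associations of closed-form strength, so the whole pipeline is
testable end to end without any database download.

## Worked example

```r
library(adrmine)

# synthetic antidepressant cohort with known planted associations
g <- generate_jader(default_generator_spec(n_cases = 5000, seed = 42),
                    out_dir = "synth")
demo  <- read_jader_table(g$paths["demo"], "DEMO")
reac  <- read_jader_table(g$paths["reac"], "REAC")
drug  <- read_jader_table(g$paths["drug"], "DRUG")
cases <- assemble_cases(demo, reac, drug)
ssri  <- filter_cohort(cases, drug_class_config("SSRI",
           c("パロキセチン", "セルトラリン", "フルボキサミン", "エスシタロプラム")))
run_adr_analysis(ssri, class_name = "SSRI")
```

```
ADR-ADR analysis, cohort 'SSRI': 5 reported rule(s)
Cohort: 3658 case(s), 3028 adverse reactions ( per-case deduplicated terms )
  female    2099 case(s),  1776 ADR(s)
  male      1453 case(s),  1169 ADR(s)
  unknown    106 case(s),    83 ADR(s)
                                            X
         Aspartate aminotransferase increased
           Alanine aminotransferase increased
     International normalised ratio increased
                             Drug interaction
 Alanine aminotransferase increased, Insomnia
                                        Y Support Confidence Lift Conviction
       Alanine aminotransferase increased  0.0172       0.94 49.8       16.4
     Aspartate aminotransferase increased  0.0172       0.91 49.8       11.3
                         Drug interaction  0.0087       1.00 91.4         NA
 International normalised ratio increased  0.0087       0.80 91.5        5.0
     Aspartate aminotransferase increased  0.0016       1.00 54.6         NA
```

The two planted pairs surface as the top rules: the transaminase pair
(planted conditional 0.95) and the INR → drug-interaction pair, whose
planted conditional of 1 yields confidence 1.00 and conviction `NA` — the
conviction denominator is zero for an exceptionless rule. Lift ≈ 50 means
the consequent is ~50× more frequent among antecedent cases than overall.
`run_demo_analysis()` does the same with a gender consequent, and
`write_report()` writes the ranked table plus a full-precision companion
CSV carrying each rule's contingency cells.

Rule statistics are also computable directly from a contingency table:

```r
rule_stats(contingency_table(26, 2, 4, 4345))
#> support 0.0059, confidence 0.9286, lift 135.4786, conviction 13.9040
```

A thin CLI over the same functions lives at `inst/scripts/adrmine.R`
(subcommands `run` and `synth`).

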