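---
title: "Disproportionality analysis of IL-17 inhibitors and inflammatory bowel disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of IL-17 inhibitors and inflammatory bowel disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(il17pv)
```

## The problem

Spontaneous adverse-event databases such as the FDA Adverse Event
Reporting System (FAERS) collect unsolicited reports of suspected drug
reactions. They have no denominator of exposed patients, so absolute
risks cannot be estimated; what can be estimated is *disproportionality*
— whether a particular event is reported more often for a target drug
than for everything else in the database. `il17pv` implements this
analysis for the association between the IL-17 inhibitors secukinumab
(Cosentyx), ixekizumab (Taltz) and brodalumab (Siliq) and the onset or
exacerbation of inflammatory bowel disease (IBD) and colitis, together
with a descriptive summarizer for the published case-report literature
on the same question and a synthetic-report generator for validating the
whole pipeline.

## The statistic

For a target drug and a target event set, reports are cross-classified
into the 2×2 table

|            | target event | other events |
|------------|--------------|--------------|
| target drug (primary suspect) | a | b |
| all other reports             | c | d |

and the reporting odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
\mathrm{CI}_{95\%} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right),$$

the Woolf (log-scale) interval. A drug–event pair is flagged as a
*signal* when the lower CI bound exceeds 1 **and** at least three cases
were reported. If any cell is zero, both the estimate and the interval
are reported as `NA`; no Haldane–Anscombe 0.5 correction is applied,
matching the `NA` convention of the published tables this package
reproduces. The critical value 1.96 (two-sided 95%) is fixed and no
multiple-testing adjustment is made, again matching standard
pharmacovigilance practice for this design.

## Counting convention

Counts are **event-level**: each *distinct* preferred term (PT) on a
report contributes one tally, so a report carrying both "Crohn's
disease" and "Colitis ulcerative" contributes twice to the IBD group
total. This convention is forced by the arithmetic of the published
tables, whose group totals are exactly the sums of the per-PT counts
(233 + 196 + 182 = 611 for the secukinumab IBD column). The alternative
— case-level counting, one tally per report per group — would give group
totals smaller than the per-PT sums whenever PTs co-occur. Both tallies
are legitimate; this package produces event-level tables via
`run_disproportionality()` and case-level classifications via
`characteristics_table()`, and does not force them to agree (the
published case count of 388 primary-suspect cases and the event tallies
of 611 + 160 + 3 IBD events are likewise not mutually derivable).

The comparator for each drug is the full deduplicated database minus the
exposed reports, *including* reports of the other IL-17 inhibitors —
the conventional full-database comparator.

PT matching is case-insensitive exact string equality after whitespace
trimming: "Colitis ulcerative" is not "Colitis", and no MedDRA hierarchy
traversal is performed. The colitis event group ships with the eleven
PTs of the published colitis table. (The accompanying prose claims
twelve colitis PTs; the twelfth is not identifiable from the published
table, so the tabulated eleven are used.)

## Ingestion and deduplication

`read_quarter_files()` reads the five '$'-delimited FAERS-style tables
(demographics, drugs, reactions, outcomes, indications) joined on the
report key. Reports without any reaction PT are dropped (with a logged
count): they carry no analyzable event. Reports with unparseable age,
sex or country are **kept** with unknown values — the published
characteristics table has large Unknown strata, and dropping such
reports would bias the counts. The analysis window (2015Q1–2022Q3 by
default) is applied at file/quarter granularity, because quarterly
extracts define membership by file of origin rather than by any
in-record date.

FAERS publishes every revision of a case. `deduplicate()` keeps, per
case identifier, the report with the highest case version, breaking ties
by later quarter and then by the lexicographically largest report
identifier. The rule is idempotent and logged.

Drug-name matching (`match_drug()`) is case-insensitive substring
matching of dictionary patterns against the trimmed verbatim name, so
"COSENTYX 150MG" matches the `cosentyx` pattern. Exact-token matching
would miss dose- and salt-decorated names, which are the norm in
spontaneous reports. The shipped dictionary holds the three actives with
their generic and US brand names; regional brand names can be added via
`drug_dictionary()`.

## Display conventions

Displayed percentages and odds ratios are rounded half-up
(`round_half_up()`); internal values keep full precision. One published
proportion (611/44,688 printed as 1.36%) is evidently truncated rather
than rounded (the half-up value is 1.37), so `proportion_of_reports()`
exposes the rounding mode as an argument — `"halfup"` by default,
`"truncate"` where a printed value requires it. The package reports the
convention it used rather than silently picking one.

## The case-series summarizer

`summarize_cases()` mirrors the descriptive tables of a case-series
study: every variable is summarized over its own non-missing
denominator (the per-variable "n =" convention), so cases missing a
field are excluded from that variable only. Set-valued variables
(symptoms, imaging, endoscopy and histology findings) use the number of
cases *reporting* the variable as denominator, so their percentages need
not sum to 100.

Bin boundaries for onset and relief times are ambiguous in the published
tables ("1–3" and "3–6" share the value 3). This package adopts
half-open `[lower, upper)` intervals everywhere: 3.0 months falls in
"3–6", 24 months in ">24", and ">4 w" is implemented as `[4, Inf)`.

The packaged 34-case table (`il17_case_fixture()`) is **synthetic**:
individual patient rows are not published, so a table was constructed
whose every per-variable marginal matches the published counts exactly
(34 cases, 27 secukinumab / 7 ixekizumab, diarrhea in 30 of 33
symptomatic cases, median onset 2.9 months with range 0.47–48, …). It
validates the summarization pipeline; its joint structure across columns
is arbitrary and must not be interpreted. Two published inconsistencies
are reproduced rather than repaired: "chronic inflammation 11 (39.3%)"
is printed with a percentage that corresponds to a different denominator
(11/25 = 44.0%, which is what this package prints for the same count),
and the published median time to remission (4 weeks) is not attainable
under the published relief-bin counts (3 / 7 / 5 of 15 forces the 8th
sorted value below 4); the fixture satisfies the bin counts.

## The synthetic generator

`generate_reports()` draws seeded synthetic report collections: one
primary-suspect drug per report from configured marginals (remaining
probability mass split over a pool of background drugs), independent
per-PT event occurrence at background probability $p_0$, and planted
drug–event associations on the **odds scale**,
$\mathrm{odds}(p_1) = \theta \cdot \mathrm{odds}(p_0)$, so the planted
$\theta$ is exactly the ROR estimand. Reports drawing no event receive a
filler PT ("Drug ineffective") so that every report survives ingestion.
Duplicate case versions can be injected to exercise deduplication, and
collections are written in the same '$'-delimited dialect the reader
consumes, making byte-identical regeneration from a seed and full
write–read round trips testable. `expected_contingency()` gives the
closed-form expected 2×2 cells under this model as an analytic oracle.

The generator deliberately does **not** mimic real FAERS marginal
distributions, PT-coding noise, correlated comorbidities within a
report, or reporting trends over time — events are independent across
PTs, and exposure is defined solely by the primary-suspect drug (other
roles are drawn as noise and never planted). Passing recovery tests
therefore shows that the pipeline estimates what it claims to estimate
under the stated model, not that real FAERS data meet that model.
Demographic missingness defaults (68% missing age, 23.9% unknown sex,
16% missing country) mirror the strata of the published characteristics
table.

## Validation studies and problem sizes

Two simulation suites validate the estimator end to end:

* **Parameter recovery.** 500 replicates per planted
  $\theta \in \{1, 1.5, 2.13, 2.79\}$ (the latter two being the
  published secukinumab and ixekizumab headline RORs) at 20,000 reports
  per replicate in memory, and 500 replicates per published headline ROR
  at 50,000 reports per replicate through the full file-based pipeline
  (exposed marginal 0.2, background event probability 0.01). The mean of
  the log-estimates must fall within 3 Monte-Carlo standard errors of
  $\log\theta$, and empirical 95% CI coverage within ±3% of nominal.
  500 replicates makes the ±3% coverage band at least three binomial
  standard errors wide, so the assertion has negligible false-alarm
  probability.
* **Type-I control.** Under $\theta = 1$ everywhere, the signal-flag
  rate across drug×PT pairs over 200 replicates must not exceed the
  nominal one-sided 2.5% plus Monte-Carlo slack (the ≥3-case gate makes
  the rule conservative, so observed rates sit below nominal).

With one planted event PT plus the filler term, the ROR estimand equals
the planted $\theta$ exactly; with several event PTs the filler
probability differs slightly between exposed and unexposed reports and
the estimand is only approximately $\theta$, which is why recovery runs
use the single-PT configuration.

## Known limitations

* Disproportionality is a hypothesis-generating screen: RORs quantify
  reporting imbalance, not incidence or causal risk.
* The published FAERS-wide RORs are computed from ~31 quarters of raw
  FAERS data, which this package does not redistribute; the shipped
  reference tables carry the published per-PT counts, totals and RORs
  as inputs for arithmetic checks and for planting effect sizes.
* Only the exact-PT event sets are supported — no MedDRA hierarchy, no
  standardized MedDRA queries.
* No PRR, Bayesian (IC/BCPNN) or empirical-Bayes (EBGM/MGPS) estimators;
  the ROR with the lower-bound rule is the implemented screen.
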