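---
title: "Era-aware harmonization of child dental registry data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Era-aware harmonization of child dental registry data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scorkit)
```

## The problem

The Danish child odontology registry has recorded one row per dental
examination since 1972, but under three successive registration regimes —
1972–1987, 1988–1999, and 2000 to the present — whose codings for
gingivitis, periodontitis and caries are not directly comparable. A cohort
analysis spanning the registry therefore needs (i) aggregate variables that
mean the same thing in every era, (ii) a defensible cleaning procedure for
duplicates, faulty rows and repeated within-year visits, and (iii) a way to
validate both without access to the registry itself, which is restricted.
`scorkit` implements all three, keyed throughout on the three *criteria
eras* (`ERA1`, `ERA2`, `ERA3`). The registry's historical division into
three *datasets* (1972–1987, 1988–1994, 1995–) does not coincide with the
criteria changes; since every aggregate rule is stated per criteria era,
the dataset of origin is treated as optional metadata only and no logic is
keyed on it.

## The harmonized aggregate variables

**Gingivitis.** ERA1 graded four index teeth (temporary dentition: 52, 55,
82, 85; permanent: 12, 16, 42, 46) on a 0–3 scale; the gingivitis index is
their sum, 0–12. From 1988 twelve permanent index teeth (11, 12, 21, 22,
31, 32, 41, 42, 16, 26, 36, 46) are scored, and the gingivitis level is
the number of teeth carrying the positive code (code 2, bleeding on
probing, in ERA2; code 1 — the only remaining gingivitis registration — in
ERA3), again 0–12. The harmonized flag is *positive at 9 or more* in ERA1
and *6 or more of 12* from 1988 on. The ERA1 cut-off of 9 is not
arbitrary: over four grades capped at 3, a total of 9 is the least value
that forces at least one severely inflamed (grade-3) tooth, since
4 × 2 = 8. The package verifies this by exhaustive enumeration of all
4⁴ grade tuples.

**Periodontitis.** ERA1 carries only a record-level pathological-pockets
flag (`X` if any registration tooth qualified); since the registration was
non-mandatory, any registration is read as indicating significant disease,
so the flag itself is the classification. ERA2 counts registration teeth
with code 5 (pockets > 4 mm *with* attachment loss); code 4 (pockets
> 4 mm without attachment loss) never enters the aggregate and is exposed
only as the diagnostic `pocket_code4_count`. ERA3 sums twelve per-tooth
indicators. From 1988 on the flag is positive at 6 or more of 12.

**Caries.** Severity is the number of tooth surfaces carrying a caries
registration, counted per dentition: `dmf_s` over the temporary teeth
(FDI quadrants 5–8) and `DMF_S` over the permanent teeth (quadrants 1–4),
with `dmf_total` their sum. The default `"international"` variant counts
codes 1, 2, 4 and 6 in every era, matching the internationally used DMF
definition. The registry's own pre-computed temporary-dentition variables
additionally count code 5 from 1988 on; the `"scor_provided"` variant
reproduces that behaviour so both definitions can be compared. The two
variants agree exactly whenever no code-5 surfaces are present (a tested
invariant). Surface codes are treated as opaque labels with these counting
rules; no clinical semantics beyond them are assumed.

**Blank registrations.** For ERA1 periodontitis and all post-1988
registrations, an entirely blank form is indistinguishable from a healthy
dentition. Aggregates score blanks as 0 / flag `FALSE` — preserving the
estimates the aggregate definitions imply — but every harmonized row
carries `gingivitis_all_blank` and `periodontitis_all_blank` indicators so
analysts can stratify on, or sensitivity-test, this ambiguity. The
missing-registration-tooth code `X` is likewise scored 0 wherever it
appears; it marks a tooth, not a disease state.

## Cleaning

The pipeline applies three stages in a fixed order, mirroring how such
registries are prepared for analysis; the order matters for the per-rule
counts and is therefore part of the contract:

1. **Exact duplicates** (equal on every field) reduce to their first
   occurrence. Near-duplicates — same person and date, different codes —
   are deliberately both kept here and left to stage 3.
2. **Faulty rows**: visits dated after the person's death, and visits at
   exact ages outside the open interval 0 < age < 19 years (the ages that
   qualify for care). Exact age is days divided by 365.25. A row failing
   both rules counts under the death rule. Rows whose person identifier
   does not resolve are routed to a `rejected` element and reported —
   never silently dropped — and enter the conservation identity as
   `n_rejected`.
3. **One entry per integer age** (0…18) per person: the earliest-dated
   visit at each integer age is kept; a same-date tie keeps the first row
   in stable input order.

Integer age defaults to *half-down rounding* (`ceiling(age − 0.5)`): it is
deterministic, and exact half-years round toward the lower age rather than
inflating a child past an age boundary. Conventional epidemiology often
uses completed years, so `rounding = "floor"` is available everywhere an
integer age is computed. With half-down rounding, exact ages in
(18.5, 19) — eligible, but rounding to 19 — are clamped into the age-18
bucket so the output invariant (distinct integer ages 0–18, at most 19
rows per person) always holds.

The `cleaning_report` records every count and enforces row conservation at
construction. Because the registry literature is ambiguous about whether
its reported per-individual entry maximum refers to data before or after
the age restriction, the report carries both maxima.

## The synthetic-registry generator

Real registry exports are access-restricted, so the generator is the
package's test bed: it emulates the registry's structure faithfully enough
that every downstream stage can be validated against planted ground truth.

* **Visit regimes.** Annual visits before calendar year 1993; from 1993 a
  needs-based regime with mandatory recall ages 5, 7, 12 and 15. The
  needs-based probability rises by a configurable bonus when the child has
  any latent disease that age, which makes visit frequency genuinely
  needs-based and gives the disease-state visit-mean summaries something
  real to detect. No visit is emitted before 1972, the registry's start.
* **Latent disease.** Per person and age, each of gingivitis,
  periodontitis and caries follows a prevalence curve over (age, calendar
  year), with a persistence parameter (default 0.7) carrying the previous
  age's state forward; with a constant curve the marginal prevalence is
  unchanged by persistence, which is what the parameter-recovery checks
  rely on. The default curves are order-of-magnitude placeholders with
  plausible shapes — rising with age, caries declining secularly to about
  half its 1972 level by 2021 — because the registry's published
  trajectories exist only as figures, not tables. Any analysis needing
  calibrated prevalence must supply its own curves.
* **Coding.** A latently positive, detected visit is coded at or above
  the era's aggregate threshold (ERA1: four grades totalling ≥ 9,
  including a grade-3 tooth; ERA2/ERA3: ≥ 6 of 12 positive teeth), a
  negative visit strictly below it. Which of the twelve teeth are positive
  is a random rotation — only the count enters any aggregate. With
  `detection = 1` harmonization therefore recovers the latent flags
  exactly, a property-tested round trip; lower detection models
  underreporting. An optional reporting-shock multiplier perturbs
  registration probabilities for two calendar years after each criteria
  change (1988–89, 2000–01), a crude model of the calibration spikes such
  transitions can produce; it is off by default.
* **Demographics.** The male fraction defaults to 0.512, matching the sex
  ratio reported for the registry population. Dentition is simplified:
  ages below 6 use temporary teeth only, 6–12 mixed (caries surfaces split
  between dentitions in an age-sliding ratio), above 12 permanent only.
  Eruption timing tables are out of scope.
* **Faults.** Exact duplicates are appended and sampled rows are mutated
  into the two faulty classes (a death date set the day before the
  person's last visit; a visit moved to age ≥ 19 or exactly 0), at most
  one age fault per person, with ground truth recorded in a disjoint
  `fault_ledger`. Default rates (1% duplicates, 0.2% death faults, 0.3%
  age faults) are of the order such registries exhibit while keeping test
  cohorts informative. Age-mutated rows are re-emitted all-blank under the
  era of their new date so per-era files remain dialect-valid.

What passing tests on this generator do **not** show: that the default
prevalence levels, visit probabilities or fault rates match the real
registry; that real forms lack systematic coding idiosyncrasies (e.g.
transcription errors, municipality-specific practice); or that the blank
versus healthy ambiguity is ignorable. They do show that the
harmonization, cleaning and summary code compute exactly what their
definitions state, on data of the right shape.

## Cohort summaries

Entry statistics use the sample standard deviation (n − 1) and report an
`NA` SD for single-individual groups. Period coverage partitions ages into
0–6, 7–11, 12–14 and 15–18 and counts distinct periods with at least one
entry per individual. Prevalence tables report positives per 1000
individuals with a visit in the stratum (calendar year × sex, or × the
index ages 5, 9, 15 chosen to reflect the temporary, mixed and permanent
dentition); the denominator is individuals with a visit, not visits, a
choice the registry literature leaves open. Caries positivity defaults to
`dmf_total ≥ 1` — the conventional caries-experience definition — and is a
parameter. Visit-year distributions can be attributed by visit year or by
administrative report year; the report year disappears from the registry
in 2000, so the visit year serves as its proxy from then on, and both axes
always total the same number of records. Disease-state visit means group
gingivitis and periodontitis as ever/never flagged (with a per-calendar-
year alternative, since the grouping basis for such plots is usually
underspecified) and caries by the per-individual maximum of `dmf_total` in
the intervals 0–4, 5–9 and ≥ 10, the grouping used by the Danish health
authorities. The external population-denominator comparison takes a
user-supplied births-plus-naturalizations table; nothing is downloaded.

## Numerical and degenerate-input choices

* ERA1 missing-index-tooth substitution takes the nearest present tooth in
  the same quadrant; an equidistant tie goes to the lower position number
  (the historical instruction is silent); an empty quadrant yields the
  unscorable sentinel `NA`. No substitution is applied from 1988 on.
* Code alphabets are closed: any symbol outside an era's alphabet is a
  parse or contract error, never coerced.
* FDI ↔ Haderup tooth-notation conversion is a verified bijection on all
  52 valid codes (32 permanent, 20 primary).
* `era_of` is total and monotone for years ≥ 1972 and rejects earlier
  dates.
* Empty strata are omitted from prevalence tables; zero denominators give
  an undefined (`NA`) percentage; a missing denominator year is an error
  naming the year.

## Validation problem sizes

The bundled checks run the ledger-exactness test on a 500-person cohort
with all three fault classes injected, and the parameter-recovery check on
5,000 individuals per era with a planted age-15 gingivitis prevalence of
0.30, perfect detection, and an always-visit schedule, requiring the
harmonized estimate within three binomial standard errors (≈ ±0.019).
These sizes give the recovery check high power while keeping the whole
suite fast enough to run routinely.

## Known limitations

The generator does not model tooth eruption, caries progression biology,
within-municipality correlation, or the pre-1988 school-year reporting
calendar beyond a simple month rule for the report year. The harmonized
flags inherit the thresholds' clinical judgement; the package computes
them, it does not re-derive their clinical validity. Headline counts
published for the real registry (millions of individuals and entries)
concern restricted data and are deliberately not reproduction targets.
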