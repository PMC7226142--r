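---
title: "Case/non-case disproportionality screening of cardiovascular events under CML tyrosine-kinase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality screening of cardiovascular events under CML tyrosine-kinase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design

Spontaneous-report databases such as FAERS accumulate millions of
suspected adverse-event reports. They have no denominators — nobody knows
how many patients took a drug — so absolute risks cannot be estimated.
What *can* be estimated is disproportionality: whether a given event is
reported relatively more often with one drug than with comparable drugs.
This package implements the cross-sectional case/non-case design for that
question, specialised to the cardiovascular safety of the five BCR-ABL
tyrosine-kinase inhibitors (TKIs) licensed in Europe for chronic myeloid
leukemia — imatinib, dasatinib, bosutinib, nilotinib, ponatinib — against
all other antineoplastic (ATC `L01`) drugs as the comparator class.

Within the retained set of serious anticancer reports, *cases* of a
cardiovascular query are reports carrying at least one MedDRA preferred
term from the query's narrow-scope SMQ term list; *all* other retained
reports are non-cases for that query, including reports matching other
cardiovascular queries. Eight queries are screened: cardiac failure,
cardiomyopathy, hypertension, pulmonary hypertension, ischaemic heart
disease, torsade de pointes/QT prolongation, cardiac arrhythmias, and
embolic and thrombotic events. Narrow scope trades sensitivity for
positive predictive value, which is the accepted choice for signal
confirmation on coded data.

The statistic is the reporting odds ratio. With `a`/`b` the exposed
cases/non-cases and `c`/`d` the comparator cases/non-cases,

\[ \mathrm{ROR} = \frac{a\,d}{b\,c}, \qquad
   \mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96\,
   \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big) \]

(the Woolf interval). The adjusted ROR comes from a maximum-likelihood
logistic regression of the case indicator on exposure, age class and sex
over the same report set; the exposure coefficient's exponential is the
aROR, with a Wald interval. A pair is only analysed when it has at least
3 exposed cases, and a *signal of disproportionate reporting* (SDR) is an
eligible pair whose adjusted lower 95% bound exceeds 1 — the standard
criterion consistent with calling an association "significant" in this
design.

## Pipeline decisions

**Report assembly.** FAERS tables are line-oriented (a line per drug or
per reaction); `assemble_reports()` groups them under the report
identifier. Ages arrive in assorted units (`YR`, `MON`, `DEC`, ...) and
are normalised to years; unconvertible units become missing. Age is
analysed in the four classes ≤25, 26–50, 51–75, ≥76 plus an explicit
`unknown` level, with the printed bin labels read as inclusive bounds.
A report is *serious* exactly when it carries at least one outcome code.

**Why age classes, not continuous age.** Roughly 30% of reports carry no
age at all. A continuous-age model would either drop them — discarding
the bulk of the data — or need an imputation model the data cannot
support. Categorical age with an explicit `unknown` level keeps every
report in the regression; the same is done for sex. The synthetic
generator plants its confounding on the same categorical scale, so the
planted conditional odds ratio is exactly the estimand of the adjusted
model.

**Deduplication** is two-step: first only the latest follow-up version of
each case is kept; then reports identical on the five-field key (sorted
event-term set, earliest event onset date, age, sex, country) are
collapsed to one representative. The representative is the
lexicographically smallest report id — an arbitrary but deterministic
tie-break. Missing key fields compare equal only to missing. Whether the
original design keyed on the full event list or a single event is not
decidable from the description; the sorted-set reading is implemented
because it is the stricter (more conservative) duplicate definition.

**Aberrant reports** are those whose recorded therapy start postdates the
event. The rule here requires full-precision dates on both sides and
strict inequality, and removes a report only when *every* dated suspect
drug starts after the earliest dated onset: partial or missing dates are
insufficient evidence, so those reports are retained.

**Drug names** in FAERS are free text. Normalisation tries an exact
match on the case-folded, punctuation-stripped token, then retries after
removing dose/formulation suffixes, and optionally rescues misspellings
at Levenshtein distance exactly 1 — only for tokens of at least 6
characters and only when the rescue is unique across the archive.
The rescue is off by default because short vocabularies make false
merges likely. Combination products are split on `+`/`;` and flags are
unioned over components. Exposure flags deliberately cover *all* drug
roles (suspect, concomitant, interacting), matching the study design's
inclusion sentence.

**Comparator construction.** For a single TKI, the comparator is every
anticancer report not containing that TKI — reports with *other* TKIs
included, mirroring the drug-by-drug design. The TKI-class analysis
excludes all five. A report exposed to both the index TKI and another
anticancer drug counts once, in the index margin.

**Time-to-onset** is event onset minus therapy start in whole days,
using the earliest qualifying (dated, term-matching) onset and the
drug's earliest dated start. Records lacking day precision on either
side are flagged non-informative rather than dropped. Summaries cap
latencies at 365 days and *retain* the capped values: the repeated upper
quartile of 365 in long-latency pairs is the signature of truncation,
not exclusion. Quantiles interpolate linearly between order statistics
(R type 7); the choice is documented because no convention was given.

## Numerical choices

* Woolf intervals use the conventional 1.96 half-width on the log scale;
  no continuity correction is applied. A zero in `b`, `c` or `d` yields
  a "not computed" status instead of a corrected estimate — the ≥3-case
  rule already removes the worst sparsity, and corrected estimates would
  silently change the estimand.
* The adjusted model is fitted on the collapsed
  exposure × age class × sex strata as a binomial-counts GLM. The
  likelihood is identical to the report-level Bernoulli fit, so the MLE
  and Wald interval are identical, at a small fraction of the cost.
* Non-convergence, rank deficiency, or implausible magnitudes
  (|log aROR| or its SE above 15) are reported as diagnostics; no
  estimate is emitted in those states.
* Percentages in descriptive tables round half-up to one decimal —
  the convention of clinical baseline tables — while machine-readable
  outputs keep full precision.

## The synthetic generator

Real FAERS extracts are tens of millions of rows and MedDRA term lists
are licensed, so the package ships a generator
(`generate_faers()`, configured by `scenario_config()`) that emulates the
*structure* of the data and the *assumptions* of the analysis with known
ground truth:

* Reported age class and sex are drawn from configurable marginals;
  exposure (which anticancer drug is the primary suspect) follows a
  logistic model in those covariates; each query's case status follows a
  logistic model in the same covariates plus `log(OR)` for the assigned
  drug. Because confounding acts on the *reported* categorical
  covariates, the planted OR is exactly the conditional odds ratio the
  adjusted analysis estimates — parameter recovery is a sharp test, not
  an approximation.
* Data dirt is injected with bookkeeping: nonserious reports (no outcome
  lines), follow-up clones (same case, higher version), duplicate clones
  (fresh case id, identical five-field key), aberrant reports (therapy
  start displaced after the onset), missing and month-precision dates,
  and drug names emitted as brand/generic/misspelled/dose-suffixed
  variants. Misspellings are single-character deletions or substitutions,
  i.e. guaranteed Levenshtein distance 1; the bundled menus keep all
  names ≥7 characters and pairwise distance ≥3 so the rescue is always
  unique.
* So that "injected duplicates = removed duplicates" holds *exactly*,
  base reports are nudged into having unique five-field keys (onset-day
  shifts, age jitter within class, or a fresh dated onset for reports
  with no other entropy). This is a property of the test harness design,
  not of real data, where true chance collisions exist and deduplication
  is genuinely lossy.
* `paper_margin_preset()` returns a scenario whose *expected* margins
  reproduce the published screen at reduced scale: TKI share of
  anticancer reports (~3.4%), within-TKI drug mix, per-drug
  cardiovascular case probabilities (hence nilotinib's ~59% share of TKI
  cases), the query mix, and the age/sex/reporter/country/year marginals
  of TKI cases. Its per-pair odds ratios are derived from the published
  per-drug case probabilities against the comparator baseline — e.g. the
  implied nilotinib × torsade de pointes/QT prolongation OR is ≈11.6.
  Funnel dirt rates approximate the published exclusion proportions.

What the generator does *not* emulate: free-text narratives, reporting
heterogeneity over time, correlated multi-drug regimens, masking bias
between competing events, country-specific coding habits, and the true
(unknown) duplicate process. Passing tests therefore demonstrate that
the estimators recover what the structural model plants and that the
bookkeeping stages are exact — not that the pipeline's clinical output
on real FAERS would match any published number.

## Problem sizes used by the test-suite

The packaged checks run at sizes chosen to make their statistical
assertions sharp while staying desk-scale: oracle equivalence on 1,000
random 2×2 tables; parameter recovery on 100 replicates of 50,000
reports with a planted conditional OR of 12 under age/sex confounding
(interval coverage ≥90%); a null screen of 40 pairs at n = 50,000 (SDR
rate ≤10%); funnel exactness on dirty corpora of a few thousand reports;
and the preset margins on one corpus of 100,000 base reports. The
published adjusted RORs and time-to-onset medians themselves are *not*
reproducible at these scales — they require the full multi-million
report corpus — and are covered by the parameter-recovery properties
instead.

## Known limitations

* The screen applies no multiplicity correction across the 48 pairs, by
  design parity with the underlying method; SDR counts on null data
  reflect the per-pair one-sided 2.5% level.
* Masking bias (one strongly reported event suppressing another drug's
  apparent disproportionality) is discussed in the pharmacovigilance
  literature but not quantified here.
* Study-window selection is done by choosing which quarterly files are
  ingested; the package does not filter on report dates internally.
* The drug archive is user-supplied in real use; the residual of name
  mapping (historically ~10%) needs manual curation, for which
  `mapping_coverage()` exports the top unresolved tokens.
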