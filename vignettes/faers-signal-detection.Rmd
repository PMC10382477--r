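---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event databases such as FAERS have no denominator: we
observe reports, not prescriptions. Disproportionality analysis sidesteps
the missing denominator by asking whether a drug–event pair is reported
*more often than expected* relative to the rest of the database. The
reference frame is a 2×2 table over all deduplicated reports:

|                | target event | other events |
|----------------|--------------|--------------|
| target drug    | a            | b            |
| other drugs    | c            | d            |

`faersignal` implements this workflow for the motivating use case of
SSRI-associated rhabdomyolysis, but every component is parameterised by a
drug dictionary and an event term, so any drug-class × preferred-term
question over FAERS-style files can be run unchanged.

## Screening model

Four sequential steps turn raw quarterly files into the table margins:

1. **Deduplication.** A case (CASEID) may be revised across quarters under
   new PRIMARYIDs. We keep, per CASEID, the row with the latest FDA_DT,
   breaking exact ties by the highest PRIMARYID. Rows with missing or
   partial FDA_DT are treated as older than any dated row — a revision
   carrying a receipt date supersedes one without. After this step CASEID
   and PRIMARYID are in bijection, so downstream set operations use
   PRIMARYID; intersecting on CASEID would give identical cohorts.
2. **Sole-primary-suspect screening.** Only drug rows with role code PS
   enter assignment; SS/C/I rows are ignored (except by the co-medication
   exclusion). A case with PS rows matching two *distinct* dictionary
   drugs is removed entirely rather than double-counted — such reports
   cannot attribute the event to one drug.
3. **Event extraction.** A case carries the event when any REAC row equals
   the target preferred term, case-insensitively after trimming. Preferred
   terms are plain strings; no MedDRA hierarchy is consulted.
4. **Intersection** of the per-drug exposure sets with the event set.

Drug-name matching deserves a note. FAERS verbatim names carry dose, salt
and formulation text, so a synonym is matched as a whole word inside the
normalized (upper-cased, punctuation-stripped) verbatim: `PROZAC 20MG
CAPSULE` matches fluoxetine. Containment is at word boundaries rather than
raw substrings because generic names nest ("citalopram" occurs inside
"escitalopram"); raw containment would make every escitalopram report
ambiguous. A verbatim that genuinely matches two canonical drugs raises an
ambiguity error in single lookups and counts as multiple suspects during
screening. No fuzzy matching is attempted — misspelled names are missed,
as they are in any exact-dictionary analysis.

## The four statistics

All four are computed from the same table, with
`s = sqrt(1/a + 1/b + 1/c + 1/d)`:

* `ROR = (a/b)/(c/d)` with `exp(ln ROR ± 1.96 s)` as the 95% interval.
* `PRR = (a/(a+b))/(c/(c+d))`, accompanied by Pearson's χ² *without*
  Yates continuity correction.
* `IC = log2(a N / ((a+c)(a+b)))`, the information component — the base-2
  log of observed over expected counts — with the multiplicative lower
  bound `IC025 = IC · exp(−1.96 s)`.
* `EBGM = a N / ((a+c)(a+b))`, the same observed/expected ratio on the
  natural scale, with `EBGM05 = EBGM · exp(−1.64 s)`.

Two deliberate divergences from the eponymous literature methods, kept
because they are what published SSRI–rhabdomyolysis tables computed this
way actually contain: the IC bound is a normal-approximation construction,
not the BCPNN posterior quantile, and EBGM carries no empirical-Bayes
(MGPS) shrinkage — it is the raw relative reporting ratio, so
`IC = log2(EBGM)` identically, a property the test suite asserts. Users
needing shrinkage estimates for very small counts should treat EBGM05 here
as anti-conservative near a ≈ 0 and conservative nowhere.

A signal is declared only when all four criteria hold (CI low > 1 with
N ≥ 2; PRR ≥ 2 with χ² ≥ 4 and N ≥ 3; IC025 ≥ 0; EBGM05 > 2). The
conjunction rule trades sensitivity for specificity, which suits a
hypothesis-strengthening analysis.

### Numerical choices

Cells are held as doubles throughout — `b·c` at FAERS scale overflows
32-bit integers. Zero cells are *not* continuity-corrected: `a = 0` yields
a zero estimate with undefined intervals, a zero in `b`, `c` or `d` yields
infinite/undefined values, and undefined statistics fail their criterion.
The report-count thresholds in the criteria already guard the tiny-count
regime. Display rounding is half-up to 2 decimals, matching publication
convention; full precision is retained in every returned data frame.

## Descriptive analyses

Time-to-onset is `EVENT_DT − START_DT` in days, where the therapy row is
linked through `DSG_DRUG_SEQ` to a PS row of the case's assigned drug;
with several linkable rows the earliest fully dated start is used. Partial
dates never contribute: a year-only date is an "inaccurate date" and the
case is excluded and counted, as are negative durations (input errors) and
cases without a linkable therapy row — the three reasons partition the
non-evaluable set. Quartiles use linear interpolation (R's default type 7);
other quartile conventions shift the reported quartiles by a day or two on
small cohorts.

Outcome codes are counted with set semantics per case (a case reported
with death and hospitalization contributes to both, so proportions may sum
past 1); congenital anomaly (CA) is folded into other-serious (OT). Age
bands are `<18`, `18–65`, `>65` with 65 *inclusive* in the middle band —
the boundary assignment is a convention this package fixes explicitly.
Ages are normalized to years from the AGE_COD unit (YR, DEC, MON, WK, DY,
HR) and flagged unknown outside [0, 130]. Reporting country prefers the
occurrence country over the reporter country, giving a single country per
case.

## The synthetic generator

Real FAERS cannot ship with a package, so validation runs on corpora from
`synth_config()`/`generate_faers()`, which emit the exact file dialect plus
a ground-truth ledger (per-drug sole-PS sets, event sets, multi-PS and
statin-co-exposed cases, true onset days) that screening must recover
*exactly* — set equality, not statistical agreement.

Defaults encode the study conditions of the motivating analysis: SSRI
exposure probabilities reconstructed from the screened margins (per-drug
sole-PS counts implied by each drug's case count and observed/expected
ratio over 16,011,277 reports), rhabdomyolysis at its marginal reporting
rate (33,574/16,011,277 ≈ 0.21%), per-drug signal multipliers equal to the
observed reporting-rate ratios (1.82–11.37), 20% duplicate-version chains,
1% multi-PS injection, statin co-medication at 5.1% of exposed cases
(7,780/151,660), and missingness near the published descriptive table
(15.4% age, 9.7% sex, 55% event dates). Onset times are log-normal with
median 21.5 days and σ_log = 2.5, reproducing the heavy right tail of
onset distributions; the generator does not reproduce the pronounced
same-day reporting spike seen in real onset data, nor misspelled drug
names, realistic country mixes, or MedDRA coding drift. Passing tests therefore
demonstrate correctness of the *pipeline mechanics and estimators*, not
fidelity of any synthetic corpus to FAERS itself.

Generation is a pure function of the config (the caller's RNG state is
saved and restored), and PRIMARYIDs are allocated as `CASEID × 100 +
version` so duplicate chains are structurally visible.

Validation problem sizes, chosen to exercise the asymptotics while staying
desk-scale: ground-truth recovery on five 50,000-case corpora with
duplication 0.2 and multi-PS 0.01; estimator recovery on twenty 200,000-case
corpora per injected ratio λ ∈ {1, 2, 5} (median recovered ROR within 10%
of λ; the λ = 1 null must not signal in ≥95% of seeds). For the recovery
study the target drug is given a 5% exposure share and the event an 0.8%
baseline rate so the drug–event cell is well populated (≈80·λ cases);
duplication and multi-PS injection are switched off there since they are
validated exactly elsewhere.

## Sensitivity analysis

The statin exclusion removes co-medicated cases (any role) from the
*exposure arm only*: the event margin and total N keep their original
values. Whether published comparator cells were also statin-filtered is
generally not reported; this reconstruction is the one that matches
published class-level RORs, and it answers the cleaner question "does the
signal persist among SSRI cases without statin co-exposure?". The funnel
JSON records the removed count.

## Known limitations

* Exact-dictionary matching misses misspellings; no RxNorm/ATC mapping.
* Cross-CASEID duplicates (the same event submitted by different
  reporters under different CASEIDs) are undetectable by the CASEID rule
  and remain in the data.
* No shrinkage, masking adjustment, or stratified analyses; estimates for
  very small `a` should be read alongside their N criteria.
* Reporting databases cannot yield incidence: every statistic here is a
  reporting ratio, not a risk.
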