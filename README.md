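# faersignal

Disproportionality signal detection for FAERS spontaneous adverse-event
reports, built around the question of whether selective serotonin reuptake
inhibitors (SSRIs) carry a reporting signal for rhabdomyolysis — a
potentially fatal breakdown of skeletal muscle best known as a statin
adverse effect.

The package is for pharmacovigilance analysts working with the FDA Adverse
Event Reporting System (FAERS) quarterly ASCII releases. It covers the full
desk workflow:

* **Parsing** the '$'-delimited DEMO / DRUG / REAC / THER / OUTC quarterly
  file dialect, with skip-and-count handling of malformed rows and hard
  errors only for missing mandatory columns or legacy ISR-era layouts.
* **Deduplication** of case versions: for each CASEID keep the report with
  the most recent FDA_DT, breaking ties by the highest PRIMARYID.
* **Screening**: assign each case to a target drug when that drug is the
  sole Primary Suspect (PS) matching a synonym dictionary (cases with two
  or more distinct target drugs as PS are excluded); extract event cases by
  exact MedDRA preferred term; intersect.
* **Disproportionality statistics** on the resulting 2×2 table
  (a = drug & event, b = drug & other events, c = other drugs & event,
  d = neither; N = a+b+c+d):

  | Algorithm | Estimate | Criterion |
  |---|---|---|
  | ROR | (a/b)/(c/d), CI = exp(ln ROR ± 1.96·s) | CI low > 1, N ≥ 2 |
  | PRR | (a/(a+b))/(c/(c+d)), Pearson χ² (no Yates) | PRR ≥ 2, χ² ≥ 4, N ≥ 3 |
  | IC | log₂(aN/((a+c)(a+b))), IC025 = IC·exp(−1.96·s) | IC025 ≥ 0 |
  | EBGM | aN/((a+c)(a+b)), EBGM05 = EBGM·exp(−1.64·s) | EBGM05 > 2 |

  with s = √(1/a + 1/b + 1/c + 1/d). A signal is declared only when all
  four criteria hold simultaneously.
* **Sensitivity analysis** excluding cases co-medicated with statins, and
  **descriptive analyses**: time-to-onset (THER.START_DT → DEMO.EVENT_DT,
  with input-error exclusions), serious-outcome proportions, and
  demographic tables.
* A **deterministic synthetic-corpus generator** with exact ground truth
  (duplicate chains, multi-PS cases, statin co-exposure, log-normal onset
  times), so every pipeline stage is testable without downloading the
  multi-gigabyte FAERS archives.

## Worked example

Reproduce a published-style class-level row straight from four screening
margins — 889 rhabdomyolysis cases with an SSRI as the sole primary
suspect, 151,660 sole-PS SSRI reports, 33,574 rhabdomyolysis reports, and
16,011,277 deduplicated reports:

```r
library(faersignal)
row <- run_margins_only(889, 151660, 33574, 16011277, label = "SSRIs")
row[, c("ror_display", "prr_display", "ic_display", "ebgm_display", "signal")]
#>         ror_display    prr_display  ic_display ebgm_display signal
#> 1 2.86 (2.67, 3.05) 2.84 (1037.16) 1.48 (1.39)  2.80 (2.64)   TRUE
```

Read as: the odds of a rhabdomyolysis report among SSRI-suspect reports are
2.86 times those among all other reports (95% CI 2.67–3.05); the reporting
proportion ratio is 2.84 with χ² = 1037.16; the observed count is
2^1.48 ≈ 2.80 times the expected count (lower bounds 1.39 bits and 2.64);
all four criteria are met, so the drug–event pair signals.

An end-to-end run on a synthetic corpus:

```r
gen <- generate_faers(synth_config(n_cases = 50000, seed = 1), dir = "corpus")
run <- run_analysis("corpus", comed_dict = statin_dictionary(), out_dir = "out")
run$signals[, c("label", "n_reports", "ror", "signal")]
head(run$funnel)
```

which writes `signal_table.csv`, the statin-excluded sensitivity table,
demographic / time-to-onset / outcome CSVs, and a screening-funnel JSON
under `out/`.

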