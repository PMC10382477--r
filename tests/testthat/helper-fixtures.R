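# Fixture builders shared across the suite. Everything is constructed in
# code; no binary data.

empty_tab <- function(cols) {
  out <- lapply(cols, function(x) character(0))
  names(out) <- cols
  out$primaryid <- numeric(0)
  data.table::as.data.table(out)
}

empty_corpus <- function() {
  faers_corpus(
    demo = empty_tab(c("primaryid", "caseid", "fda_dt", "event_dt", "age",
                       "age_cod", "sex", "occp_cod", "reporter_country",
                       "occr_country")),
    drug = empty_tab(c("primaryid", "drug_seq", "role_cod", "drugname")),
    reac = empty_tab(c("primaryid", "pt")),
    ther = empty_tab(c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")),
    outc = empty_tab(c("primaryid", "outc_cod"))
  )
}

demo_row <- function(primaryid, caseid, fda_dt = "20200301",
                     event_dt = "", age = "", age_cod = "", sex = "",
                     occp_cod = "", country = "US") {
  data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
             event_dt = event_dt, age = age, age_cod = age_cod, sex = sex,
             occp_cod = occp_cod, reporter_country = country,
             occr_country = country, stringsAsFactors = FALSE)
}

drug_row <- function(primaryid, drugname, role_cod = "PS", drug_seq = 1L) {
  data.frame(primaryid = primaryid, drug_seq = drug_seq,
             role_cod = role_cod, drugname = drugname,
             stringsAsFactors = FALSE)
}

reac_row <- function(primaryid, pt) {
  data.frame(primaryid = primaryid, pt = pt, stringsAsFactors = FALSE)
}

ther_row <- function(primaryid, start_dt, dsg_drug_seq = 1L, end_dt = "") {
  data.frame(primaryid = primaryid, dsg_drug_seq = dsg_drug_seq,
             start_dt = start_dt, end_dt = end_dt, stringsAsFactors = FALSE)
}

outc_row <- function(primaryid, outc_cod) {
  data.frame(primaryid = primaryid, outc_cod = outc_cod,
             stringsAsFactors = FALSE)
}

make_corpus <- function(demo, drug = NULL, reac = NULL, ther = NULL,
                        outc = NULL) {
  e <- empty_corpus()
  faers_corpus(
    demo = do.call(rbind, c(list(e$demo[0]), demo)),
    drug = if (is.null(drug)) e$drug else do.call(rbind, drug),
    reac = if (is.null(reac)) e$reac else do.call(rbind, reac),
    ther = if (is.null(ther)) e$ther else do.call(rbind, ther),
    outc = if (is.null(outc)) e$outc else do.call(rbind, outc)
  )
}

# Hand-written 12-case corpus covering every screening rule; the expected
# cohort is enumerated in comments and asserted in tests.
#  case 1: PS sertraline, rhabdo                    -> sertraline + event
#  case 2: PS sertraline + C atorvastatin, rhabdo   -> sertraline + event,
#                                                      removed by statin excl.
#  case 3: PS sertraline + PS fluoxetine, rhabdo    -> multi-PS excluded
#  case 4: PS fluoxetine (as PROZAC 20MG), nausea   -> fluoxetine, no event
#  case 5: PS ibuprofen, rhabdo                     -> event only
#  case 6: SS sertraline, rhabdo                    -> event only (not PS)
#  case 7: PS paroxetine, rhabdo twice              -> paroxetine + event once
#  case 8: duplicate chain: v1 then v2 (later FDA_DT) PS citalopram, rhabdo
#                                                   -> citalopram + event (v2)
#  case 9: PS fluvoxamine, myoglobinuria            -> fluvoxamine, no event
#  case 10: PS escitalopram, rhabdo                 -> escitalopram + event
#  case 11: C sertraline only, nausea               -> nothing
#  case 12: PS sertraline, rhabdo, FDA_DT tie chain (max PRIMARYID wins)
hand_fixture_corpus <- function() {
  make_corpus(
    demo = list(
      demo_row(101, 1), demo_row(201, 2), demo_row(301, 3),
      demo_row(401, 4), demo_row(501, 5), demo_row(601, 6),
      demo_row(701, 7),
      demo_row(801, 8, fda_dt = "20200101"),
      demo_row(802, 8, fda_dt = "20210101"),
      demo_row(901, 9), demo_row(1001, 10), demo_row(1101, 11),
      demo_row(1201, 12, fda_dt = "20200601"),
      demo_row(1203, 12, fda_dt = "20200601")
    ),
    drug = list(
      drug_row(101, "SERTRALINE"),
      drug_row(201, "SERTRALINE"), drug_row(201, "ATORVASTATIN", "C", 2L),
      drug_row(301, "SERTRALINE"), drug_row(301, "FLUOXETINE", "PS", 2L),
      drug_row(401, "PROZAC 20MG"),
      drug_row(501, "IBUPROFEN"),
      drug_row(601, "SERTRALINE", "SS"),
      drug_row(701, "PAROXETINE"),
      drug_row(801, "CITALOPRAM"), drug_row(802, "CITALOPRAM"),
      drug_row(901, "FLUVOXAMINE"),
      drug_row(1001, "ESCITALOPRAM"),
      drug_row(1101, "SERTRALINE", "C"),
      drug_row(1201, "SERTRALINE"), drug_row(1203, "SERTRALINE")
    ),
    reac = list(
      reac_row(101, "Rhabdomyolysis"), reac_row(201, "Rhabdomyolysis"),
      reac_row(301, "Rhabdomyolysis"), reac_row(401, "Nausea"),
      reac_row(501, "Rhabdomyolysis"), reac_row(601, "Rhabdomyolysis"),
      reac_row(701, "Rhabdomyolysis"), reac_row(701, "Rhabdomyolysis"),
      reac_row(801, "Rhabdomyolysis"), reac_row(802, "Rhabdomyolysis"),
      reac_row(901, "Myoglobinuria"), reac_row(1001, "Rhabdomyolysis"),
      reac_row(1101, "Nausea"),
      reac_row(1201, "Rhabdomyolysis"), reac_row(1203, "Rhabdomyolysis")
    )
  )
}

# 5 evaluable cases with onset {0, 10, 21, 100, 400} days plus three
# excluded ones: a negative duration, a year-month START_DT, and a case
# with no linkable therapy row.
tto_fixture <- function() {
  starts <- c("20200101", "20200101", "20200101", "20200101", "20200101",
              "20200102", "202001")
  events <- c("20200101", "20200111", "20200122", "20200410", "20210204",
              "20200101", "20200301")
  demo <- lapply(1:8, function(i) {
    demo_row(i * 100 + 1, i, event_dt = if (i <= 7) events[i] else "20200301")
  })
  drug <- lapply(1:8, function(i) drug_row(i * 100 + 1, "SERTRALINE"))
  reac <- lapply(1:8, function(i) reac_row(i * 100 + 1, "Rhabdomyolysis"))
  ther <- lapply(1:7, function(i) ther_row(i * 100 + 1, starts[i]))
  make_corpus(demo = demo, drug = drug, reac = reac, ther = ther)
}

# Expected cohort for hand_fixture_corpus(), enumerated by hand
hand_fixture_expected <- function() {
  list(
    n_total = 12,
    drug_event = list(
      fluoxetine = numeric(0), citalopram = 802, escitalopram = 1001,
      paroxetine = 701, sertraline = c(101, 201, 1203),
      fluvoxamine = numeric(0)
    ),
    # event extraction is independent of drug screening, so the multi-PS
    # case 301 still counts toward the event margin
    event_cases = c(101, 201, 301, 501, 601, 701, 802, 1001, 1203),
    multi_ps_excluded = 1,
    statin_removed = 201
  )
}
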