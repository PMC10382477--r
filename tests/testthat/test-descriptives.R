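test_that("onset durations, quartiles and one-year fraction match hand values", {
  corpus <- tto_fixture()
  co <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis")
  tto <- time_to_onset(co, corpus)

  expect_equal(tto$overall$n_evaluable, 5)
  expect_setequal(unname(tto$durations), c(0, 10, 21, 100, 400))
  expect_equal(tto$overall$median, 21)
  expect_equal(tto$overall$q1, 10)
  expect_equal(tto$overall$q3, 100)
  expect_equal(tto$overall$within_one_year_fraction, 0.8)

  # same-day onset is a valid zero-day duration, not an exclusion
  expect_true(0 %in% tto$durations)
  # exclusion reasons partition the non-evaluable cohort cases
  expect_equal(unname(tto$exclusions["negative_duration"]), 1)
  expect_equal(unname(tto$exclusions["partial_or_missing_date"]), 1)
  expect_equal(unname(tto$exclusions["no_therapy_row"]), 1)
  expect_equal(sum(tto$exclusions) + tto$overall$n_evaluable,
               length(co$drug_event_cases$sertraline))
})

test_that("empty evaluable sets yield flagged-undefined summaries", {
  corpus <- make_corpus(
    demo = list(demo_row(101, 1, event_dt = "")),
    drug = list(drug_row(101, "SERTRALINE")),
    reac = list(reac_row(101, "Rhabdomyolysis")))
  co <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis")
  tto <- time_to_onset(co, corpus)
  expect_equal(tto$overall$n_evaluable, 0)
  expect_true(is.na(tto$overall$median))
})

test_that("outcome counts use set semantics per code and fold CA into OT", {
  # 8 cases; hand-assigned codes
  demo <- lapply(1:8, function(i) demo_row(i * 10 + 1, i))
  drug <- lapply(1:8, function(i) drug_row(i * 10 + 1, "SERTRALINE"))
  reac <- lapply(1:8, function(i) reac_row(i * 10 + 1, "Rhabdomyolysis"))
  outc <- list(
    outc_row(11, "DE"), outc_row(11, "HO"),   # case 1: DE + HO
    outc_row(21, "HO"), outc_row(21, "HO"),   # case 2: HO (repeated row)
    outc_row(31, "LT"),                        # case 3
    outc_row(41, "CA"),                        # case 4: folds into OT
    outc_row(51, "OT"),                        # case 5
    outc_row(61, "DS"), outc_row(61, "DE"),   # case 6
    outc_row(71, "HO")                         # case 7; case 8 none
  )
  corpus <- make_corpus(demo = demo, drug = drug, reac = reac, outc = outc)
  co <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis")
  os <- outcome_summary(co, corpus)
  got <- stats::setNames(os$overall$n, os$overall$outcome)
  expect_equal(got[c("DE", "LT", "HO", "DS", "RI", "OT")],
               c(DE = 2, LT = 1, HO = 3, DS = 1, RI = 0, OT = 2))
  expect_equal(os$overall$proportion, unname(got) / 8)
  # multi-code cases may push the proportion total past 1
  expect_true(all(os$overall$proportion >= 0 & os$overall$proportion <= 1))
})

test_that("empty cohorts give all-zero outcome counts", {
  corpus <- empty_corpus()
  co <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis")
  os <- outcome_summary(co, corpus)
  expect_true(all(os$overall$n == 0))
})

test_that("age bands, sex and medians match hand enumeration", {
  ages <- c("5", "17", "18", "40", "65", "66", "80", "", "25", "64")
  sexes <- c("F", "F", "M", "M", "F", "M", "", "F", "UNK", "M")
  demo <- lapply(1:10, function(i) {
    demo_row(i * 10 + 1, i, age = ages[i],
             age_cod = ifelse(nzchar(ages[i]), "YR", ""), sex = sexes[i])
  })
  drug <- lapply(1:10, function(i) drug_row(i * 10 + 1, "SERTRALINE"))
  reac <- lapply(1:10, function(i) reac_row(i * 10 + 1, "Rhabdomyolysis"))
  corpus <- make_corpus(demo = demo, drug = drug, reac = reac)
  co <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis")
  dm <- demographics_table(co)

  blk <- dm$pooled
  bands <- stats::setNames(blk$age_bands$n, blk$age_bands$band)
  # age 65.0 falls in the middle band (inclusive upper bound)
  expect_equal(bands, c("<18" = 2, "18-65" = 5, ">65" = 2, unknown = 1))
  expect_equal(sum(blk$age_bands$n), blk$n)
  expect_equal(blk$age$median, 40)
  sex <- stats::setNames(blk$sex$n, blk$sex$sex)
  expect_equal(sex, c(F = 4, M = 4, unknown = 2))
  expect_equal(sum(blk$sex$n), blk$n)
})

test_that("an all-unknown-age cohort lands entirely in the unknown band", {
  demo <- lapply(1:3, function(i) demo_row(i * 10 + 1, i))
  drug <- lapply(1:3, function(i) drug_row(i * 10 + 1, "SERTRALINE"))
  reac <- lapply(1:3, function(i) reac_row(i * 10 + 1, "Rhabdomyolysis"))
  corpus <- make_corpus(demo = demo, drug = drug, reac = reac)
  co <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis")
  blk <- demographics_table(co)$pooled
  expect_equal(blk$age_bands$pct[blk$age_bands$band == "unknown"], 100)
})

test_that("age unit codes normalize into years with range guard", {
  yrs <- faersignal:::normalize_age_years(
    c("40", "6", "52", "730", "4", "26298", "3"),
    c("YR", "MON", "WK", "DY", "DEC", "HR", "CENTURY"))
  expect_equal(yrs[1], 40)
  expect_equal(yrs[2], 0.5)
  expect_equal(yrs[3], 52 / 52.18)
  expect_equal(yrs[4], 730 / 365.25)
  expect_equal(yrs[5], 40)
  expect_equal(yrs[6], 3, tolerance = 1e-6)
  expect_true(is.na(yrs[7]))
  expect_true(is.na(faersignal:::normalize_age_years("150", "YR")))
})
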