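test_that("deduplication keeps the latest FDA_DT, then the highest PRIMARYID", {
  demo <- rbind(demo_row(71, 7, "20200101"), demo_row(72, 7, "20210101"))
  expect_equal(deduplicate_cases(demo)$demo$primaryid, 72)

  demo <- rbind(demo_row(71, 7, "20210101"), demo_row(73, 7, "20210101"))
  expect_equal(deduplicate_cases(demo)$demo$primaryid, 73)

  # missing FDA_DT sorts before any dated row
  demo <- rbind(demo_row(99, 7, ""), demo_row(71, 7, "19990101"))
  expect_equal(deduplicate_cases(demo)$demo$primaryid, 71)

  # unparseable CASEID rows dropped and counted
  demo <- rbind(demo_row(71, 7), demo_row(72, "x"))
  dd <- deduplicate_cases(demo)
  expect_equal(dd$n_dropped_invalid, 1)
  expect_equal(dd$n_unique, 1)
})

test_that("deduplication is idempotent and order-independent", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 200
    demo <- do.call(rbind, lapply(seq_len(n), function(i) {
      demo_row(i * 10 + sample(1:3, 1), sample(1:80, 1),
               sample(c("20200101", "20200601", "20210101", ""), 1))
    }))
    once <- deduplicate_cases(demo)$demo
    twice <- deduplicate_cases(once)$demo
    expect_equal(twice, once)
    shuffled <- demo[sample(nrow(demo)), ]
    expect_equal(deduplicate_cases(shuffled)$demo, once)
  }
})

test_that("sole-PS assignment follows the role and multi-suspect rules", {
  dict <- ssri_dictionary()
  drug <- rbind(
    drug_row(1, "SERTRALINE"), drug_row(1, "ATORVASTATIN", "C", 2L),
    drug_row(2, "SERTRALINE"), drug_row(2, "FLUOXETINE", "PS", 2L),
    drug_row(3, "ZOLOFT 50MG"),
    drug_row(4, "SERTRALINE", "SS")
  )
  scr <- screen_primary_suspect(drug, dict, keep_ids = 1:4)
  expect_equal(scr$cases$sertraline, c(1, 3))
  expect_equal(scr$n_excluded_multi, 1)
  expect_true(all(lengths(scr$cases[setdiff(names(dict), "sertraline")]) == 0))
})

test_that("per-drug assignments are pairwise disjoint after multi-PS exclusion", {
  cfg <- synth_config(n_cases = 4000, multi_ps_rate = 0.05, seed = 9)
  gen <- generate_faers(cfg)
  co <- build_cohort(gen$corpus, ssri_dictionary(), "Rhabdomyolysis")
  all_ids <- unlist(co$drug_cases, use.names = FALSE)
  expect_equal(anyDuplicated(all_ids), 0)
  # sum over drugs equals the count of sole-target-PS cases in truth
  expect_equal(length(all_ids),
               length(unlist(gen$truth$drug_cases, use.names = FALSE)))
})

test_that("event extraction is exact-PT, case-insensitive, set-valued", {
  reac <- rbind(reac_row(1, "Rhabdomyolysis"), reac_row(1, "Nausea"),
                reac_row(2, "RHABDOMYOLYSIS "), reac_row(2, "RHABDOMYOLYSIS"),
                reac_row(3, "Myoglobinuria"))
  got <- extract_event_cases(reac, "rhabdomyolysis", keep_ids = 1:3)
  expect_equal(got, c(1, 2))
})

test_that("co-medication exclusion is monotone and partitions its input", {
  drug <- rbind(drug_row(1, "SERTRALINE"),
                drug_row(2, "SERTRALINE"), drug_row(2, "SIMVASTATIN", "C", 2L),
                drug_row(3, "SERTRALINE"), drug_row(3, "LIPITOR", "SS", 2L))
  exc <- exclude_comedicated(1:3, drug, statin_dictionary())
  expect_equal(exc$retained, 1)
  expect_equal(exc$removed, c(2, 3))
  expect_true(all(exc$retained %in% 1:3))
  expect_equal(length(exc$retained) + exc$n_removed, 3)
})

test_that("an empty corpus yields an all-empty cohort with N = 0", {
  co <- build_cohort(empty_corpus(), ssri_dictionary(), "Rhabdomyolysis")
  expect_equal(co$n_total, 0)
  expect_true(all(lengths(co$drug_cases) == 0))
  expect_equal(length(co$event_cases), 0)
})

test_that("the 12-case hand fixture screens to its enumerated cohort", {
  corpus <- hand_fixture_corpus()
  exp <- hand_fixture_expected()

  co <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis")
  expect_equal(co$n_total, exp$n_total)
  expect_setequal(co$event_cases, exp$event_cases)
  for (d in names(exp$drug_event)) {
    expect_equal(sort(co$drug_event_cases[[d]]), sort(exp$drug_event[[d]]),
                 info = d)
  }
  expect_equal(co$funnel$cases_multi_ps_excluded, exp$multi_ps_excluded)

  # statin sensitivity removes exactly case 201 from the sertraline arm
  co2 <- build_cohort(corpus, ssri_dictionary(), "Rhabdomyolysis",
                      comed_dict = statin_dictionary())
  expect_setequal(co2$drug_event_cases$sertraline,
                  setdiff(exp$drug_event$sertraline, exp$statin_removed))
  expect_equal(co2$funnel$cases_comed_removed, 1)
})

test_that("the cohort is invariant to quarter-file load order", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_cases = 2000, seed = 21)
  gen <- generate_faers(cfg, dir = dir)
  bundles <- lapply(gen$paths, read_faers_quarter)
  fwd <- build_cohort(bind_corpora(bundles), ssri_dictionary(),
                      "Rhabdomyolysis")
  rev <- build_cohort(bind_corpora(rev(bundles)), ssri_dictionary(),
                      "Rhabdomyolysis")
  expect_equal(fwd$drug_event_cases, rev$drug_event_cases)
  expect_equal(fwd$event_cases, rev$event_cases)
  expect_equal(fwd$n_total, rev$n_total)
})
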