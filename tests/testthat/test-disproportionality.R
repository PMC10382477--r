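paper_table <- function() contingency_from_counts(889, 151660, 33574, 16011277)

test_that("contingency cells derive from margins, inconsistent margins error", {
  t <- paper_table()
  expect_equal(t$b, 150771)
  expect_equal(t$c, 32685)
  expect_equal(t$d, 15826932)

  t0 <- contingency_from_counts(0, 0, 5, 10)
  expect_equal(unlist(t0[c("a", "b", "c", "d")]),
               c(a = 0, b = 0, c = 5, d = 5))

  expect_error(contingency_from_counts(6, 5, 10, 100), "drug_total")
  expect_error(contingency_from_counts(2, 5, 1, 100), "event_total")
  expect_error(contingency_from_counts(1, 90, 90, 100), "exceeds N")
})

test_that("ROR matches hand arithmetic and the independence value", {
  r <- compute_ror(contingency_from_counts(10, 30, 40, 300))
  expect_equal(r$ror, 4.0)  # (10/20)/(30/240)
  ind <- compute_ror(contingency_from_counts(10, 110, 20, 220))
  expect_equal(ind$ror, 1.0)
  expect_lt(ind$ci_low, 1)
  expect_gt(ind$ci_high, 1)
})

test_that("PRR matches hand arithmetic; chi-squared is 0 at independence", {
  p <- compute_prr(contingency_from_counts(10, 30, 40, 300))
  expect_equal(p$prr, 3.0)  # (10/30)/(30/270)
  ind <- compute_prr(contingency_from_counts(10, 110, 20, 220))
  expect_equal(ind$prr, 1.0)
  expect_equal(ind$chi2, 0.0)
})

test_that("IC and EBGM are the same ratio on two scales", {
  t <- contingency_from_counts(10, 30, 40, 300)
  expect_equal(compute_ic(t)$ic, log2(2.5))  # 10*300/(40*30)
  expect_equal(compute_ebgm(t)$ebgm, 2.5)
  set.seed(31)
  for (i in 1:25) {
    a <- sample(1:200, 1); b <- sample(1:5000, 1)
    c <- sample(1:2000, 1); d <- sample(1000:100000, 1)
    t <- contingency_from_counts(a, a + b, a + c, a + b + c + d)
    expect_equal(compute_ic(t)$ic, log2(compute_ebgm(t)$ebgm))
  }
})

test_that("chi-squared agrees with the expected-counts oracle to 1e-9", {
  set.seed(17)
  for (i in 1:30) {
    a <- sample(1:500, 1); b <- sample(1:10000, 1)
    c <- sample(1:5000, 1); d <- sample(1:500000, 1)
    t <- contingency_from_counts(a, a + b, a + c, a + b + c + d)
    got <- compute_prr(t)$chi2
    oracle <- suppressWarnings(stats::chisq.test(
      matrix(c(a, c, b, d), 2, 2), correct = FALSE))$statistic
    expect_equal(got, unname(oracle), tolerance = 1e-9)
  }
})

test_that("all four statistics increase strictly in a with b, c, d fixed", {
  b <- 500; c <- 300; d <- 100000
  vals <- lapply(1:60, function(a) {
    t <- contingency_from_counts(a, a + b, a + c, a + b + c + d)
    c(ror = compute_ror(t)$ror, prr = compute_prr(t)$prr,
      ic = compute_ic(t)$ic, ebgm = compute_ebgm(t)$ebgm)
  })
  m <- do.call(rbind, vals)
  for (col in colnames(m)) {
    expect_true(all(diff(m[, col]) > 0), info = col)
  }
})

test_that("zero cells flag statistics undefined rather than correcting them", {
  t <- contingency_from_counts(0, 10, 5, 1000)
  expect_equal(compute_ror(t)$ror, 0)
  expect_true(is.na(compute_ror(t)$ci_low))
  expect_true(is.na(compute_ic(t)$ic))
  expect_true(is.na(compute_ebgm(t)$ebgm05))
  row <- signal_from_margins(0, 10, 5, 1000)
  expect_false(row$signal)

  t2 <- contingency_from_counts(5, 5, 8, 1000)  # b = 0
  expect_true(!is.finite(compute_ror(t2)$ror))
})

test_that("signal criteria reproduce published qualitative verdicts", {
  # pooled class row: all four algorithms pass
  f <- evaluate_signal(ror_ci_low = 2.67, prr = 2.84, chi2 = 1037.16,
                       ic025 = 1.39, ebgm05 = 2.64, n = 889)
  expect_true(f$signal)

  # paroxetine row: exactly the PRR and EBGM criteria fail
  f <- evaluate_signal(ror_ci_low = 1.55, prr = 1.82, chi2 = 53.82,
                       ic025 = 0.73, ebgm05 = 1.59, n = 145)
  expect_true(f$ror_pass)
  expect_false(f$prr_pass)
  expect_true(f$bcpnn_pass)
  expect_false(f$ebgm_pass)
  expect_false(f$signal)

  # a single report never signals, whatever its ratios
  f <- evaluate_signal(ror_ci_low = 50, prr = 100, chi2 = 500,
                       ic025 = 3, ebgm05 = 80, n = 1)
  expect_false(f$signal)
})

test_that("cohort scans equal direct per-drug computation and pool additively", {
  cfg <- synth_config(n_cases = 8000, seed = 13)
  gen <- generate_faers(cfg)
  co <- build_cohort(gen$corpus, ssri_dictionary(), "Rhabdomyolysis")
  sc <- scan_cohort(co, class_label = "SSRIs")

  ev <- length(co$event_cases)
  for (d in names(co$drug_cases)) {
    direct <- signal_from_margins(length(co$drug_event_cases[[d]]),
                                  length(co$drug_cases[[d]]),
                                  ev, co$n_total, label = d)
    row <- sc[sc$label == d, ]
    rownames(row) <- NULL
    expect_equal(row, direct)
  }
  # disjoint drug sets: class-level a is the sum of per-drug a
  expect_equal(sc$a[sc$label == "SSRIs"],
               sum(sc$a[sc$label != "SSRIs"]))
})
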