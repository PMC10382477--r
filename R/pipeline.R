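#' Run the full signal-detection pipeline
#'
#' Loads FAERS quarterly bundles, deduplicates, screens the target
#' drug--event cohort, computes the four disproportionality statistics per
#' drug set, optionally repeats the scan after co-medication exclusion
#' (sensitivity analysis), and writes the descriptive summaries. All
#' outputs are plain CSV/JSON; the analysis path is deterministic (no
#' randomness outside the synthetic generator).
#'
#' @param input either a [faers_corpus] or a directory containing quarterly
#'   files (`DEMO*.txt`, `DRUG*.txt`, ...; all quarters found are pooled).
#' @param target_dict target [drug_dictionary()] (default the bundled
#'   SSRIs).
#' @param event_term target MedDRA preferred term (default
#'   `"Rhabdomyolysis"`).
#' @param comed_dict optional co-medication dictionary; when supplied a
#'   second, co-medication-excluded signal table is produced.
#' @param out_dir optional output directory; when given, writes
#'   `signal_table.csv`, `signal_table_comed_excluded.csv` (if configured),
#'   `demographics.csv`, `time_to_onset.csv`, `outcomes.csv` and
#'   `funnel.json`.
#' @param class_label label for the pooled drug-class row.
#' @return list of class `faers_run`: `cohort`, `signals`,
#'   `signals_comed_excluded` (or `NULL`), `tto`, `outcomes`,
#'   `demographics`, `funnel`.
#' @export
run_analysis <- function(input, target_dict = ssri_dictionary(),
                         event_term = "Rhabdomyolysis", comed_dict = NULL,
                         out_dir = NULL, class_label = "pooled") {
  corpus <- if (inherits(input, "faers_corpus")) {
    input
  } else {
    load_faers_dir(input)
  }
  cohort <- build_cohort(corpus, target_dict, event_term)
  signals <- scan_cohort(cohort, class_label = class_label)

  funnel <- cohort$funnel
  signals_sens <- NULL
  if (!is.null(comed_dict)) {
    cohort_sens <- build_cohort(corpus, target_dict, event_term,
                                comed_dict = comed_dict)
    signals_sens <- scan_cohort(cohort_sens, class_label = class_label)
    funnel$cases_comed_removed <- cohort_sens$funnel$cases_comed_removed
  } else {
    funnel$cases_comed_removed <- NULL
  }

  tto <- time_to_onset(cohort, corpus)
  outc <- outcome_summary(cohort, corpus)
  demo <- demographics_table(cohort)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signal_table(signals, file.path(out_dir, "signal_table.csv"))
    if (!is.null(signals_sens)) {
      write_signal_table(
        signals_sens, file.path(out_dir, "signal_table_comed_excluded.csv"))
    }
    utils::write.csv(tto$per_drug, file.path(out_dir, "time_to_onset.csv"),
                     row.names = FALSE)
    utils::write.csv(outc$per_drug, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(.demographics_long(demo),
                     file.path(out_dir, "demographics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(funnel, file.path(out_dir, "funnel.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(cohort = cohort, signals = signals,
                 signals_comed_excluded = signals_sens, tto = tto,
                 outcomes = outc, demographics = demo,
                 funnel = funnel),
            class = "faers_run")
}

#' @export
print.faers_run <- function(x, ...) {
  cat("<faers_run>", x$cohort$event_term, "\n")
  cols <- c("label", "n_reports", "ror", "ror_ci_low", "ror_ci_high",
            "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05", "signal")
  s <- x$signals[, cols]
  num <- vapply(s, is.numeric, logical(1)) & names(s) != "n_reports"
  s[num] <- lapply(s[num], round_half_up, 2)
  print(s, row.names = FALSE)
  invisible(x)
}

# long-format demographics for CSV output; empty sections (e.g. countries of
# a drug with no cases) contribute no rows
.demographics_long <- function(demo) {
  section <- function(set, name, level, n, value) {
    if (!length(level)) return(NULL)
    data.frame(drug_set = set, section = name, level = level, n = n,
               value = value)
  }
  rows <- lapply(names(demo), function(set) {
    blk <- demo[[set]]
    rbind(
      section(set, "age", "median_q1_q3", blk$age$n_known,
              sprintf("%.2f [%.2f, %.2f]", blk$age$median, blk$age$q1,
                      blk$age$q3)),
      section(set, "age_band", blk$age_bands$band, blk$age_bands$n,
              sprintf("%.2f", blk$age_bands$pct)),
      section(set, "sex", blk$sex$sex, blk$sex$n,
              sprintf("%.2f", blk$sex$pct)),
      section(set, "reporter", blk$reporter$class, blk$reporter$n,
              sprintf("%.2f", blk$reporter$pct)),
      section(set, "country", blk$countries$country, blk$countries$n,
              sprintf("%.2f", blk$countries$pct))
    )
  })
  do.call(rbind, rows)
}

# Discover and pool all quarters in a directory (DEMO*.txt etc.)
load_faers_dir <- function(dir) {
  demos <- sort(list.files(dir, pattern = "^DEMO.*\\.txt$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(demos)) stop("no DEMO*.txt files found under: ", dir)
  corpora <- lapply(demos, function(demo_path) {
    paths <- vapply(c("demo", "drug", "reac", "ther", "outc"), function(tbl) {
      p <- sub("(?i)DEMO", toupper(tbl), demo_path, perl = TRUE)
      if (!file.exists(p)) {
        stop(sprintf("missing %s file for quarter bundle: %s",
                     toupper(tbl), p))
      }
      p
    }, character(1))
    read_faers_quarter(paths)
  })
  bind_corpora(corpora)
}

#' One signal row straight from published margins
#'
#' Reproduces a published disproportionality table row from four numbers,
#' with the 2-decimal display strings alongside the full-precision values.
#'
#' @inheritParams signal_from_margins
#' @return one-row data.frame: the [signal_from_margins()] columns plus
#'   `ror_display`, `prr_display`, `ic_display`, `ebgm_display`.
#' @examples
#' run_margins_only(889, 151660, 33574, 16011277, label = "SSRIs")
#' @export
run_margins_only <- function(a, drug_total, event_total, n, label = "drug") {
  res <- signal_from_margins(a, drug_total, event_total, n, label = label)
  r2 <- format_signal_number
  res$ror_display <- sprintf("%s (%s, %s)", r2(res$ror), r2(res$ror_ci_low),
                             r2(res$ror_ci_high))
  res$prr_display <- sprintf("%s (%s)", r2(res$prr), r2(res$chi2))
  res$ic_display <- sprintf("%s (%s)", r2(res$ic), r2(res$ic025))
  res$ebgm_display <- sprintf("%s (%s)", r2(res$ebgm), r2(res$ebgm05))
  res
}
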