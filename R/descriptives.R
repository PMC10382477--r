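# AGE_COD unit conversions to years (FAERS conventions); unknown codes give
# an unknown age. DEC = decades, HR = hours.
.age_unit_to_years <- c(YR = 1, MON = 1 / 12, WK = 1 / 52.18, DY = 1 / 365.25,
                        DEC = 10, HR = 1 / 8766)

# Age in years from raw AGE/AGE_COD; NA when missing, unparseable, an
# unknown unit, or outside the plausible [0, 130] range.
normalize_age_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(as.character(age_cod)))
  unit[is.na(unit) | !nzchar(unit)] <- "YR"
  mult <- .age_unit_to_years[unit]
  yrs <- v * mult
  yrs[!is.finite(yrs) | yrs < 0 | yrs > 130] <- NA_real_
  unname(yrs)
}

# Reporter occupation codes -> the three Table-style classes
.reporter_class <- function(occp_cod) {
  x <- toupper(trimws(as.character(occp_cod)))
  out <- rep("unknown", length(x))
  out[x %in% c("MD", "PH", "OT", "HP", "RN")] <- "health-professional"
  out[x %in% c("CN", "LW")] <- "consumer/lawyer"
  out
}

#' Time-to-onset analysis for a screened cohort
#'
#' Onset time is the number of days from the therapy start (`START_DT` of
#' the THER row linked via `DSG_DRUG_SEQ` to a PS-role row of the case's
#' assigned target drug) to the adverse-event date (`EVENT_DT` in DEMO).
#' Cases are excluded, with a counted reason, when either date is missing
#' or partial (a year-only date cannot anchor a duration), when the event
#' precedes the therapy start (input error), or when no therapy row links
#' to the assigned drug. When several therapy rows link, the earliest full
#' `START_DT` is used. Quartiles use linear interpolation (type 7).
#'
#' @param cohort a [build_cohort()] result.
#' @param corpus the [faers_corpus] the cohort was screened from.
#' @return list of class `tto_summary`: `overall` (data.frame with
#'   `n_evaluable`, `median`, `q1`, `q3`, `within_one_year_fraction`),
#'   `per_drug` (same columns per drug), `durations` (named numeric vector
#'   per evaluable PRIMARYID), and `exclusions` (counts by reason:
#'   `no_therapy_row`, `partial_or_missing_date`, `negative_duration`).
#' @export
time_to_onset <- function(cohort, corpus) {
  stopifnot(inherits(cohort, "screened_cohort"),
            inherits(corpus, "faers_corpus"))
  assign_tbl <- .cohort_assignments(cohort)
  drug <- data.table::as.data.table(corpus$drug)
  ther <- data.table::as.data.table(corpus$ther)
  demo <- data.table::as.data.table(cohort$demo)

  excl <- c(no_therapy_row = 0L, partial_or_missing_date = 0L,
            negative_duration = 0L)
  durations <- numeric(0)
  dur_drug <- character(0)

  if (nrow(assign_tbl)) {
    # PS rows of the assigned drug for each cohort case
    ps <- drug[role_cod == "PS" & primaryid %in% assign_tbl$primaryid]
    if (nrow(ps)) {
      verb <- unique(ps$drugname)
      # which verbatim names canonicalize to which assigned drug
      lut <- data.table::data.table(
        drugname = rep(verb, lengths(m <- match_drug_all(
          verb, attr(assign_tbl, "dict")))),
        canonical = unlist(m, use.names = FALSE))
      ps <- merge(ps, lut, by = "drugname", allow.cartesian = TRUE)
      ps <- merge(ps, assign_tbl, by = "primaryid")
      ps <- ps[canonical == drug_assigned]
    }
    for (i in seq_len(nrow(assign_tbl))) {
      pid <- assign_tbl$primaryid[[i]]
      seqs <- ps[primaryid == pid, drug_seq]
      th <- ther[primaryid == pid & dsg_drug_seq %in% seqs]
      if (!nrow(th)) {
        excl[["no_therapy_row"]] <- excl[["no_therapy_row"]] + 1L
        next
      }
      starts <- parse_faers_date(th$start_dt)
      full <- starts$precision == "day"
      ev_raw <- demo[primaryid == pid, event_dt][1]
      ev <- parse_faers_date(ev_raw)
      if (!any(full) || ev$precision != "day") {
        excl[["partial_or_missing_date"]] <-
          excl[["partial_or_missing_date"]] + 1L
        next
      }
      start <- min(starts$date[full])
      dur <- as.numeric(ev$date - start)
      if (dur < 0) {
        excl[["negative_duration"]] <- excl[["negative_duration"]] + 1L
        next
      }
      durations <- c(durations, stats::setNames(dur, pid))
      dur_drug <- c(dur_drug, assign_tbl$drug_assigned[[i]])
    }
  }

  summarize <- function(d) {
    if (!length(d)) {
      return(data.frame(n_evaluable = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, within_one_year_fraction = NA_real_))
    }
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n_evaluable = length(d), median = q[2], q1 = q[1], q3 = q[3],
               within_one_year_fraction = mean(d <= 365))
  }
  per_drug <- do.call(rbind, lapply(names(cohort$drug_event_cases),
    function(dn) {
      row <- summarize(durations[dur_drug == dn])
      cbind(drug = dn, row)
    }))
  structure(list(overall = summarize(durations), per_drug = per_drug,
                 durations = durations, exclusions = excl),
            class = "tto_summary")
}

# cohort cases as a table primaryid -> assigned drug (drug_event cases only),
# with the target dictionary carried along for THER linkage
.cohort_assignments <- function(cohort) {
  pieces <- lapply(names(cohort$drug_event_cases), function(d) {
    ids <- cohort$drug_event_cases[[d]]
    if (!length(ids)) return(NULL)
    data.table::data.table(primaryid = ids, drug_assigned = d)
  })
  out <- data.table::rbindlist(pieces)
  if (!nrow(out)) {
    out <- data.table::data.table(primaryid = numeric(0),
                                  drug_assigned = character(0))
  }
  dict <- cohort$target_dict %||% ssri_dictionary()
  attr(out, "dict") <- dict
  out
}

#' Serious-outcome summary for a screened cohort
#'
#' Counts distinct cases per outcome code over the cohort's drug--event
#' cases. Codes are not mutually exclusive (a case reported as both death
#' and hospitalization contributes to both), so proportions may sum past 1.
#' The rare congenital-anomaly code `CA` is folded into `OT`.
#'
#' @param cohort a [build_cohort()] result.
#' @param corpus the [faers_corpus] it came from.
#' @return list of class `outcome_summary`: `overall` data.frame with
#'   `outcome`, `n`, `proportion` (over the cohort size), `per_drug`
#'   (same, by drug), and `n_cases`.
#' @export
outcome_summary <- function(cohort, corpus) {
  stopifnot(inherits(cohort, "screened_cohort"))
  codes <- c("DE", "LT", "HO", "DS", "RI", "OT")
  assign_tbl <- .cohort_assignments(cohort)
  outc <- data.table::as.data.table(corpus$outc)
  outc <- outc[primaryid %in% assign_tbl$primaryid]
  outc[, outc_cod := toupper(trimws(outc_cod))]
  outc[outc_cod == "CA", outc_cod := "OT"]
  outc <- unique(outc[outc_cod %in% codes, .(primaryid, outc_cod)])

  n_cases <- nrow(assign_tbl)
  count_codes <- function(ids) {
    sub <- outc[primaryid %in% ids]
    n <- vapply(codes, function(k) sum(sub$outc_cod == k), integer(1))
    data.frame(outcome = codes, n = unname(n),
               proportion = if (length(ids)) unname(n) / length(ids)
                            else rep(NA_real_, length(codes)))
  }
  per_drug <- do.call(rbind, lapply(names(cohort$drug_event_cases),
    function(dn) cbind(drug = dn,
                       count_codes(cohort$drug_event_cases[[dn]]))))
  structure(list(overall = count_codes(assign_tbl$primaryid),
                 per_drug = per_drug, n_cases = n_cases),
            class = "outcome_summary")
}

#' Demographic and administrative summary of a screened cohort
#'
#' Per drug and pooled: median age with quartiles; age-band counts
#' (`<18`, `18-65` with 65 inclusive, `>65`, unknown); sex counts; reporter
#' class counts; and the top reporting countries. Country is taken from
#' `OCCR_COUNTRY` when present, else `REPORTER_COUNTRY`. Percentages are
#' over the drug set's case count.
#'
#' @param cohort a [build_cohort()] result.
#' @param top_k how many countries to list (default 6).
#' @return list of class `demographics_summary` with one element per drug
#'   set (pooled first): each a list with `n`, `age` (median/q1/q3),
#'   `age_bands`, `sex`, `reporter`, `countries` data.frames.
#' @export
demographics_table <- function(cohort, top_k = 6) {
  stopifnot(inherits(cohort, "screened_cohort"))
  demo <- data.table::as.data.table(cohort$demo)
  sets <- c(list(pooled = unique(unlist(cohort$drug_event_cases,
                                        use.names = FALSE))),
            cohort$drug_event_cases)
  lapply(sets, function(ids) .demo_block(demo[primaryid %in% ids], top_k)) |>
    structure(class = "demographics_summary")
}

.demo_block <- function(d, top_k) {
  n <- nrow(d)
  age <- normalize_age_years(d$age, d$age_cod)
  band <- cut(age, breaks = c(-Inf, 18, 65, Inf), right = FALSE,
              labels = c("<18", "18-65", ">65"))
  # 65.0 belongs to the middle band (inclusive upper bound)
  band[!is.na(age) & age == 65] <- "18-65"
  band <- as.character(band)
  band[is.na(band)] <- "unknown"
  band_counts <- table(factor(band, levels = c("<18", "18-65", ">65",
                                               "unknown")))

  sex <- toupper(trimws(as.character(d$sex)))
  sex[!sex %in% c("F", "M")] <- "unknown"
  sex_counts <- table(factor(sex, levels = c("F", "M", "unknown")))

  rep_counts <- table(factor(.reporter_class(d$occp_cod),
                             levels = c("health-professional",
                                        "consumer/lawyer", "unknown")))

  country <- trimws(as.character(d$occr_country))
  fallback <- trimws(as.character(d$reporter_country))
  use_fb <- is.na(country) | !nzchar(country)
  country[use_fb] <- fallback[use_fb]
  country[is.na(country) | !nzchar(country)] <- "unknown"
  ctab <- sort(table(country), decreasing = TRUE)
  ctab <- utils::head(ctab, top_k)
  ctab_names <- if (length(ctab)) names(ctab) else character(0)

  pct <- function(x) if (n > 0) 100 * as.numeric(x) / n else NA_real_
  qs <- if (any(!is.na(age))) {
    stats::quantile(age, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  list(
    n = n,
    age = data.frame(median = qs[2], q1 = qs[1], q3 = qs[3],
                     n_known = sum(!is.na(age))),
    age_bands = data.frame(band = names(band_counts),
                           n = as.integer(band_counts),
                           pct = pct(band_counts)),
    sex = data.frame(sex = names(sex_counts), n = as.integer(sex_counts),
                     pct = pct(sex_counts)),
    reporter = data.frame(class = names(rep_counts),
                          n = as.integer(rep_counts), pct = pct(rep_counts)),
    countries = data.frame(country = ctab_names, n = as.integer(ctab),
                           pct = if (length(ctab)) pct(ctab) else numeric(0))
  )
}
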