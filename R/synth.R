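#' Default drug catalog for the synthetic corpus
#'
#' The six SSRIs with per-report exposure probabilities reconstructed from
#' the screened FAERS margins (each drug's sole-PS report count implied by
#' its case count and observed/expected ratio, over 16,011,277 reports),
#' plus a set of background drugs carrying the remaining probability mass.
#'
#' @return data.frame with columns `name`, `prob`, `is_target`.
#' @export
default_drug_catalog <- function() {
  ssri <- data.frame(
    name = c("sertraline", "fluoxetine", "paroxetine", "escitalopram",
             "citalopram", "fluvoxamine"),
    prob = c(2.948e-3, 1.403e-3, 2.373e-3, 1.206e-3, 1.472e-3, 7.33e-5),
    is_target = TRUE
  )
  bg_names <- c("metformin", "ibuprofen", "amoxicillin", "omeprazole",
                "lisinopril", "aspirin", "prednisone", "gabapentin")
  bg <- data.frame(name = bg_names,
                   prob = rep((1 - sum(ssri$prob)) / length(bg_names),
                              length(bg_names)),
                   is_target = FALSE)
  rbind(ssri, bg)
}

#' Default event catalog for the synthetic corpus
#'
#' Baseline per-report probabilities. Rhabdomyolysis is set to its marginal
#' FAERS reporting rate (33,574 / 16,011,277); the remaining preferred
#' terms are common filler reactions.
#'
#' @return named numeric vector: preferred term -> baseline probability.
#' @export
default_event_catalog <- function() {
  c("Rhabdomyolysis" = 33574 / 16011277,
    "Nausea" = 0.10, "Headache" = 0.08, "Dizziness" = 0.06,
    "Fatigue" = 0.05, "Drug ineffective" = 0.12)
}

#' Default drug--event signal multipliers
#'
#' Relative reporting-rate ratios for each SSRI against rhabdomyolysis, set
#' to the observed/expected ratios of the screened FAERS analysis (the
#' per-drug EBGM values), so the generator's default corpus carries the
#' same signal structure the analysis is built to detect.
#'
#' @return data.frame with columns `drug`, `event`, `lambda`.
#' @export
default_signal_multipliers <- function() {
  data.frame(
    drug = c("sertraline", "fluoxetine", "paroxetine", "escitalopram",
             "citalopram", "fluvoxamine"),
    event = "Rhabdomyolysis",
    lambda = c(2.91, 3.46, 1.82, 3.36, 2.61, 11.37)
  )
}

#' Configuration for the synthetic FAERS generator
#'
#' All probabilities are per case unless noted. Defaults emulate the
#' screened FAERS study conditions: SSRI exposure and rhabdomyolysis
#' reporting rates at their observed marginal frequencies, duplication at
#' 20% of cases, statin co-medication at 5.1% of SSRI-exposed cases
#' (7,780 / 151,660), age/sex/event-date missingness near the published
#' descriptive table, and a log-normal onset model with median 21.5 days.
#'
#' @param n_cases number of unique cases.
#' @param quarters quarter labels over which FDA receipt dates are spread.
#' @param drug_catalog data.frame(`name`, `prob`, `is_target`); `prob` must
#'   sum to 1 (one primary-suspect drug per case).
#' @param event_catalog named baseline event probabilities `p_e`.
#' @param signal_multipliers data.frame(`drug`, `event`, `lambda`): the
#'   drug--event reporting-rate ratio; event probability for a case with
#'   primary drug `d` is `min(1, p_e * lambda(d, e))`, with `lambda = 1`
#'   where unlisted.
#' @param dup_rate probability a case is re-emitted as a later-FDA_DT
#'   duplicate version (same CASEID, new PRIMARYID).
#' @param multi_ps_rate probability a target-drug case carries a second
#'   distinct target drug in the PS role (these are ground-truth excluded).
#' @param comed_rate named vector of statin co-medication probabilities by
#'   drug name; the `.default` element covers unlisted drugs.
#' @param missing_age_rate,missing_sex_rate,missing_event_dt_rate
#'   missingness probabilities for the respective DEMO fields.
#' @param partial_date_rate probability a therapy START_DT is emitted as a
#'   year-month partial (excluded from onset analysis by design).
#' @param date_error_rate probability START_DT and EVENT_DT are swapped,
#'   producing the negative-duration input errors seen in real files.
#' @param onset_meanlog,onset_sdlog log-normal onset-time parameters (days).
#' @param outcome_probs named per-case probabilities of each outcome code.
#' @param seed integer RNG seed; generation is a pure function of the
#'   config.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_cases = 50000,
                         quarters = c("2021q1", "2021q2", "2021q3", "2021q4"),
                         drug_catalog = default_drug_catalog(),
                         event_catalog = default_event_catalog(),
                         signal_multipliers = default_signal_multipliers(),
                         dup_rate = 0.2,
                         multi_ps_rate = 0.01,
                         comed_rate = c(.default = 0.051),
                         missing_age_rate = 0.154,
                         missing_sex_rate = 0.097,
                         missing_event_dt_rate = 0.55,
                         partial_date_rate = 0.05,
                         date_error_rate = 0.02,
                         onset_meanlog = log(21.5),
                         onset_sdlog = 2.5,
                         outcome_probs = c(HO = 0.745, LT = 0.228,
                                           DE = 0.138, DS = 0.03, RI = 0.01,
                                           OT = 0.30, CA = 0.005),
                         seed = 1L) {
  cfg <- list(n_cases = n_cases, quarters = quarters,
              drug_catalog = drug_catalog, event_catalog = event_catalog,
              signal_multipliers = signal_multipliers, dup_rate = dup_rate,
              multi_ps_rate = multi_ps_rate, comed_rate = comed_rate,
              missing_age_rate = missing_age_rate,
              missing_sex_rate = missing_sex_rate,
              missing_event_dt_rate = missing_event_dt_rate,
              partial_date_rate = partial_date_rate,
              date_error_rate = date_error_rate,
              onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
              outcome_probs = outcome_probs, seed = as.integer(seed))
  rates <- c(dup_rate, multi_ps_rate, comed_rate, missing_age_rate,
             missing_sex_rate, missing_event_dt_rate, partial_date_rate,
             date_error_rate, outcome_probs, event_catalog)
  if (any(rates < 0 | rates > 1)) {
    stop("all rate/probability parameters must lie in [0, 1]")
  }
  if (n_cases < 1) stop("n_cases must be >= 1")
  if (abs(sum(drug_catalog$prob) - 1) > 1e-8) {
    stop("drug_catalog$prob must sum to 1")
  }
  if (any(signal_multipliers$lambda < 0)) stop("lambda must be >= 0")
  if (!length(quarters) ||
      !all(grepl("^20[0-9]{2}q[1-4]$", quarters))) {
    stop("quarters must be labels of the form 'YYYYqQ'")
  }
  structure(cfg, class = "synth_config")
}

# statin rows use these verbatims (a subset of statin_dictionary())
.synth_statins <- c("ATORVASTATIN", "SIMVASTATIN CALCIUM", "CRESTOR",
                    "PRAVASTATIN")

#' Generate a synthetic FAERS corpus with ground truth
#'
#' Emits a FAERS-like corpus (and optionally the '$'-delimited quarterly
#' files) whose screening-relevant structure is known exactly: one
#' primary-suspect drug per case, events sampled at
#' `min(1, p_e * lambda(drug, e))`, CASEID duplicate chains with later
#' FDA receipt dates, multi-target-PS cases destined for exclusion, statin
#' co-medication rows, and a log-normal onset process tying START_DT to
#' EVENT_DT. Identical configs produce identical corpora and ground truth.
#'
#' @param config a [synth_config()].
#' @param dir optional directory; when given, quarterly files
#'   (`DEMOyyQq.txt`, ...) are written there with [write_faers_quarter()]
#'   per quarter.
#' @return list with `corpus` (a [faers_corpus]), `truth` (see Details),
#'   and `paths` (per-quarter file paths, when `dir` was given).
#'
#' @details `truth` is a list: `n_unique` (unique case count);
#'   `final_primaryid` (the PRIMARYID surviving deduplication, per case);
#'   `drug_cases` (per target drug, the surviving PRIMARYIDs whose sole PS
#'   target is that drug); `event_cases` (per event term);
#'   `drug_event_cases`; `multi_ps_cases` (ground-truth excluded);
#'   `statin_cases`; `onset_days` (true sampled onset per case).
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_cases
  cat_df <- config$drug_catalog
  targets <- cat_df$name[cat_df$is_target]
  caseid <- seq_len(n)

  ## primary-suspect drug per case
  drug_idx <- sample.int(nrow(cat_df), n, replace = TRUE, prob = cat_df$prob)
  ps_drug <- cat_df$name[drug_idx]
  is_target_case <- cat_df$is_target[drug_idx]

  ## multi-target-PS injection (needs >= 2 targets)
  multi <- rbinom(n, 1, config$multi_ps_rate) == 1 & is_target_case &
    length(targets) >= 2
  second_drug <- rep(NA_character_, n)
  if (any(multi)) {
    second_drug[multi] <- vapply(ps_drug[multi], function(d) {
      sample(setdiff(targets, d), 1)
    }, character(1))
  }

  ## events: per term, probability p_e * lambda(drug, e), capped at 1
  ev_names <- names(config$event_catalog)
  sm <- config$signal_multipliers
  event_hits <- vector("list", length(ev_names))
  names(event_hits) <- ev_names
  for (e in ev_names) {
    lam <- rep(1, n)
    rows <- sm[sm$event == e, , drop = FALSE]
    if (nrow(rows)) {
      lam_map <- stats::setNames(rows$lambda, rows$drug)
      hit <- ps_drug %in% names(lam_map)
      lam[hit] <- lam_map[ps_drug[hit]]
    }
    p <- pmin(1, config$event_catalog[[e]] * lam)
    event_hits[[e]] <- rbinom(n, 1, p) == 1
  }
  any_event <- Reduce(`|`, event_hits)
  filler <- !any_event  # guarantee REAC is never empty

  ## statin co-medication
  cr <- config$comed_rate
  base_rate <- if (".default" %in% names(cr)) cr[[".default"]] else 0
  rate <- rep(base_rate, n)
  for (d in setdiff(names(cr), ".default")) rate[ps_drug == d] <- cr[[d]]
  statin <- rbinom(n, 1, rate) == 1
  statin_name <- rep(NA_character_, n)
  if (any(statin)) {
    statin_name[statin] <- sample(.synth_statins, sum(statin), replace = TRUE)
  }

  ## dates: FDA receipt uniform over the configured quarters; event precedes
  ## receipt by a short reporting lag; therapy start = event - onset
  q_starts <- as.Date(vapply(config$quarters, function(q) {
    y <- substr(q, 1, 4); qq <- as.integer(substr(q, 6, 6))
    sprintf("%s-%02d-01", y, (qq - 1) * 3 + 1)
  }, character(1)))
  qi <- sample.int(length(q_starts), n, replace = TRUE)
  fda_date <- q_starts[qi] + sample.int(89, n, replace = TRUE) - 1L
  quarter_of <- config$quarters[qi]
  onset <- round(rlnorm(n, config$onset_meanlog, config$onset_sdlog))
  lag <- rpois(n, 20)
  event_date <- fda_date - lag
  start_date <- event_date - onset
  swap <- rbinom(n, 1, config$date_error_rate) == 1 & onset > 0
  tmp <- start_date[swap]
  start_date[swap] <- event_date[swap]
  event_date[swap] <- tmp

  fmt <- function(d) format(d, "%Y%m%d")
  event_dt <- fmt(event_date)
  event_dt[rbinom(n, 1, config$missing_event_dt_rate) == 1] <- ""
  start_dt <- fmt(start_date)
  part <- rbinom(n, 1, config$partial_date_rate) == 1
  start_dt[part] <- substr(start_dt[part], 1, 6)

  ## demographics
  age <- as.character(pmax(1, pmin(100, round(rnorm(n, 39, 20)))))
  age[rbinom(n, 1, config$missing_age_rate) == 1] <- ""
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.515, 0.485))
  sex[rbinom(n, 1, config$missing_sex_rate) == 1] <- ""
  occp <- sample(c("MD", "PH", "OT", "CN", "LW", ""), n, replace = TRUE,
                 prob = c(0.45, 0.12, 0.2, 0.12, 0.01, 0.10))
  country <- sample(c("US", "FR", "GB", "IT", "JP", "DE", "CA"), n,
                    replace = TRUE,
                    prob = c(0.30, 0.12, 0.11, 0.09, 0.09, 0.15, 0.14))

  ## duplicate chains: version 1 always; version 2 (same CASEID, higher
  ## PRIMARYID, strictly later FDA_DT) for a dup_rate share of cases
  dup <- rbinom(n, 1, config$dup_rate) == 1
  pid1 <- caseid * 100 + 1
  pid2 <- caseid * 100 + 2
  final_pid <- ifelse(dup, pid2, pid1)

  ## verbatim rendering for the PS drug: canonical, brand, or suffixed form
  dict <- ssri_dictionary()
  render <- function(drugs) {
    out <- toupper(drugs)
    has_syn <- drugs %in% names(dict)
    pick_brand <- has_syn & runif(length(drugs)) < 0.3
    if (any(pick_brand)) {
      out[pick_brand] <- vapply(drugs[pick_brand], function(d) {
        syn <- setdiff(dict[[d]], normalize_drug_name(d))
        if (length(syn)) sample(syn, 1) else toupper(d)
      }, character(1))
    }
    sfx <- sample(c("", " 10MG", " 20MG TABLET", " HCL"), length(drugs),
                  replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15))
    paste0(out, sfx)
  }
  ps_verbatim <- render(ps_drug)
  second_verbatim <- rep(NA_character_, n)
  if (any(multi)) second_verbatim[multi] <- render(second_drug[multi])

  ## assemble per-version tables, then duplicate the dup share
  demo1 <- data.table::data.table(
    primaryid = pid1, caseid = as.numeric(caseid), fda_dt = fmt(fda_date),
    event_dt = event_dt, age = age, age_cod = ifelse(nzchar(age), "YR", ""),
    sex = sex, occp_cod = occp, reporter_country = country,
    occr_country = country)

  drug_rows <- list(
    data.table::data.table(primaryid = pid1, drug_seq = 1L, role_cod = "PS",
                           drugname = ps_verbatim),
    data.table::data.table(primaryid = pid1[multi], drug_seq = 2L,
                           role_cod = "PS",
                           drugname = second_verbatim[multi]),
    data.table::data.table(primaryid = pid1[statin], drug_seq = 3L,
                           role_cod = "C",
                           drugname = statin_name[statin]))
  ## background concomitants
  n_con <- rpois(n, 0.4)
  if (any(n_con > 0)) {
    con_pid <- rep(pid1, n_con)
    bg <- cat_df$name[!cat_df$is_target]
    drug_rows[[4]] <- data.table::data.table(
      primaryid = con_pid,
      drug_seq = 3L + unlist(lapply(n_con[n_con > 0], seq_len)),
      role_cod = "C",
      drugname = toupper(sample(bg, length(con_pid), replace = TRUE)))
  }
  drug1 <- data.table::rbindlist(drug_rows)

  reac_rows <- lapply(ev_names, function(e) {
    data.table::data.table(primaryid = pid1[event_hits[[e]]], pt = e)
  })
  reac_rows[[length(reac_rows) + 1L]] <- data.table::data.table(
    primaryid = pid1[filler], pt = "Drug ineffective")
  reac1 <- unique(data.table::rbindlist(reac_rows))

  ther1 <- data.table::data.table(primaryid = pid1, dsg_drug_seq = 1L,
                                  start_dt = start_dt, end_dt = "")

  outc_rows <- lapply(names(config$outcome_probs), function(k) {
    hit <- rbinom(n, 1, config$outcome_probs[[k]]) == 1
    data.table::data.table(primaryid = pid1[hit], outc_cod = k)
  })
  outc1 <- data.table::rbindlist(outc_rows)

  ## duplicate versions: identical content, new PRIMARYID, later FDA_DT
  redo_pid <- function(dt) {
    out <- dt[primaryid %in% pid1[dup]]
    out[, primaryid := primaryid + 1]
    out
  }
  demo2 <- demo1[dup]
  demo2[, primaryid := pid2[dup]]
  demo2[, fda_dt := fmt(fda_date[dup] + sample.int(300, sum(dup),
                                                   replace = TRUE) + 30L)]
  demo <- data.table::rbindlist(list(demo1, demo2))
  drug_all <- data.table::rbindlist(list(drug1, redo_pid(drug1)))
  reac_all <- data.table::rbindlist(list(reac1, redo_pid(reac1)))
  ther_all <- data.table::rbindlist(list(ther1, redo_pid(ther1)))
  outc_all <- data.table::rbindlist(list(outc1, redo_pid(outc1)))

  corpus <- faers_corpus(demo, drug_all, reac_all, ther_all, outc_all,
                         quarters = config$quarters)

  ## ground truth on surviving PRIMARYIDs
  sole_target <- is_target_case & !multi
  drug_cases <- lapply(stats::setNames(targets, targets), function(d) {
    sort(final_pid[sole_target & ps_drug == d])
  })
  event_cases <- lapply(stats::setNames(ev_names, ev_names), function(e) {
    sort(final_pid[event_hits[[e]]])
  })
  truth <- list(
    n_unique = n,
    final_primaryid = stats::setNames(final_pid, caseid),
    drug_cases = drug_cases,
    event_cases = event_cases,
    drug_event_cases = lapply(stats::setNames(targets, targets), function(d) {
      intersect(drug_cases[[d]], event_cases[["Rhabdomyolysis"]] %||%
                  numeric(0))
    }),
    multi_ps_cases = sort(final_pid[multi]),
    statin_cases = sort(final_pid[statin]),
    onset_days = stats::setNames(onset, final_pid)
  )

  paths <- NULL
  if (!is.null(dir)) {
    paths <- list()
    for (q in unique(quarter_of)) {
      sel <- demo$caseid %in% caseid[quarter_of == q]
      pids <- demo$primaryid[sel]
      sub <- faers_corpus(
        demo[sel], drug_all[primaryid %in% pids],
        reac_all[primaryid %in% pids], ther_all[primaryid %in% pids],
        outc_all[primaryid %in% pids], quarters = q)
      paths[[q]] <- write_faers_quarter(sub, dir, quarter = q)
    }
  }

  list(corpus = corpus, truth = truth, paths = paths)
}

#' Published screening margins for the SSRI--rhabdomyolysis analysis
#'
#' The screened FAERS margins as published: pooled SSRI class with full
#' margins (a = 889 SSRI-PS rhabdomyolysis cases out of 151,660 sole-PS
#' SSRI reports, 33,574 rhabdomyolysis reports, N = 16,011,277 deduplicated
#' reports), and the per-drug drug--event counts. Per-drug exposure totals
#' were not published, so `drug_total` is `NA` for individual drugs; the
#' class row supports a complete statistics check with no corpus.
#'
#' @return data.frame with columns `label`, `a`, `drug_total`,
#'   `event_total`, `n`.
#' @export
paper_margins_fixture <- function() {
  data.frame(
    label = c("SSRIs", "sertraline", "fluoxetine", "paroxetine",
              "escitalopram", "citalopram", "fluvoxamine"),
    a = c(889, 288, 163, 145, 136, 129, 28),
    drug_total = c(151660, NA, NA, NA, NA, NA, NA),
    event_total = 33574,
    n = 16011277
  )
}
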