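#' Deduplicate FAERS case reports
#'
#' A FAERS case (CASEID) accumulates versions (PRIMARYID) across quarters.
#' Following FDA guidance, the most recent FDA_DT wins for each CASEID;
#' when CASEID and FDA_DT tie, the highest PRIMARYID wins. Rows with a
#' missing or partial FDA_DT order before any fully dated row.
#'
#' @param demo DEMO data.frame/data.table with `primaryid`, `caseid`,
#'   `fda_dt` columns (raw strings for `fda_dt`).
#' @return list with `demo` (the surviving rows, one per CASEID), `n_input`,
#'   `n_unique`, and `n_dropped_invalid` (rows with unparseable CASEID).
#' @export
deduplicate_cases <- function(demo) {
  demo <- data.table::as.data.table(demo)
  n_input <- nrow(demo)
  cid <- suppressWarnings(as.numeric(demo$caseid))
  invalid <- is.na(cid)
  demo <- demo[!invalid]
  if (nrow(demo)) {
    key <- faers_date_key(demo$fda_dt)
    ord <- order(demo$caseid, key, demo$primaryid, na.last = FALSE)
    demo <- demo[ord]
    last_of_case <- !duplicated(demo$caseid, fromLast = TRUE)
    demo <- demo[last_of_case]
  }
  list(demo = demo,
       n_input = n_input,
       n_unique = nrow(demo),
       n_dropped_invalid = sum(invalid))
}

#' Assign cases to target drugs by sole primary-suspect role
#'
#' A deduplicated case is assigned to canonical drug `d` when at least one
#' PS-role drug row on the case matches `d` in the dictionary and no PS-role
#' row matches a different dictionary drug. Cases carrying two or more
#' distinct dictionary drugs in the PS role are excluded entirely and
#' counted. SS/C/I rows play no part in assignment.
#'
#' @param drug DRUG table (`primaryid`, `role_cod`, `drugname`).
#' @param dict target [drug_dictionary()].
#' @param keep_ids numeric vector of surviving (deduplicated) PRIMARYIDs.
#' @return list with `cases` (named list: canonical drug -> sorted PRIMARYID
#'   vector, pairwise disjoint) and `n_excluded_multi` (cases dropped for
#'   multiple distinct PS dictionary drugs).
#' @export
screen_primary_suspect <- function(drug, dict, keep_ids) {
  drug <- data.table::as.data.table(drug)
  ps <- drug[role_cod == "PS" & primaryid %in% keep_ids,
             .(primaryid, drugname)]
  empty <- stats::setNames(
    rep(list(numeric(0)), length(names(dict))), names(dict))
  if (!nrow(ps)) {
    return(list(cases = empty, n_excluded_multi = 0L))
  }
  verb <- unique(ps$drugname)
  matches <- match_drug_all(verb, dict)
  lut <- data.table::data.table(
    drugname = rep(verb, lengths(matches)),
    canonical = unlist(matches, use.names = FALSE)
  )
  hit <- merge(ps, lut, by = "drugname", allow.cartesian = TRUE)
  if (!nrow(hit)) {
    return(list(cases = empty, n_excluded_multi = 0L))
  }
  per_case <- hit[, .(n_match = data.table::uniqueN(canonical),
                      canonical = canonical[[1]]), by = primaryid]
  n_multi <- sum(per_case$n_match > 1L)
  sole <- per_case[n_match == 1L]
  cases <- split(sole$primaryid, factor(sole$canonical, levels = names(dict)))
  cases <- lapply(cases, function(v) sort(unname(v)))
  list(cases = cases, n_excluded_multi = n_multi)
}

#' Extract cases reporting a given MedDRA preferred term
#'
#' @param reac REAC table (`primaryid`, `pt`).
#' @param preferred_term target preferred term; compared case-insensitively
#'   after trimming.
#' @param keep_ids surviving (deduplicated) PRIMARYIDs.
#' @return sorted numeric vector of PRIMARYIDs with at least one matching
#'   reaction row (set semantics: repeated rows count once).
#' @export
extract_event_cases <- function(reac, preferred_term, keep_ids) {
  stopifnot(nzchar(trimws(preferred_term)))
  reac <- data.table::as.data.table(reac)
  target <- toupper(trimws(preferred_term))
  hit <- reac[toupper(trimws(pt)) == target & primaryid %in% keep_ids,
              primaryid]
  sort(unique(hit))
}

#' Remove cases co-medicated with drugs from a dictionary
#'
#' Any drug row on the case, whatever its role code, that matches the
#' co-medication dictionary removes the case (used for the statin
#' sensitivity analysis).
#'
#' @param case_ids PRIMARYIDs to filter.
#' @param drug DRUG table.
#' @param comed_dict co-medication [drug_dictionary()].
#' @return list with `retained` (sorted PRIMARYID vector), `removed`
#'   (sorted PRIMARYID vector), `n_removed`.
#' @export
exclude_comedicated <- function(case_ids, drug, comed_dict) {
  drug <- data.table::as.data.table(drug)
  rows <- drug[primaryid %in% case_ids]
  removed <- numeric(0)
  if (nrow(rows)) {
    verb <- unique(rows$drugname)
    matched_verb <- verb[lengths(match_drug_all(verb, comed_dict)) > 0L]
    removed <- sort(unique(rows[drugname %in% matched_verb, primaryid]))
  }
  retained <- sort(setdiff(case_ids, removed))
  list(retained = retained, removed = removed, n_removed = length(removed))
}

#' Build a screened drug--event cohort
#'
#' Composes the four screening steps: deduplication, sole-PS drug
#' assignment, event extraction by preferred term, and the per-drug
#' intersection of the two case sets. The intersection is taken on
#' PRIMARYID; after deduplication PRIMARYID and CASEID are in bijection, so
#' this is equivalent to intersecting CASEIDs.
#'
#' @param corpus a [faers_corpus].
#' @param target_dict [drug_dictionary()] of target drugs.
#' @param event_term MedDRA preferred term of the target event.
#' @param comed_dict optional co-medication [drug_dictionary()]; when given,
#'   co-medicated cases are removed from the per-drug exposure sets before
#'   intersection (sensitivity analysis).
#' @return A `screened_cohort`: list with `event_term`, `n_total`
#'   (deduplicated report count), `drug_cases`, `event_cases`,
#'   `drug_event_cases`, `demo` (deduplicated DEMO rows), and a `funnel` of
#'   counts at every screening step.
#' @export
build_cohort <- function(corpus, target_dict, event_term,
                         comed_dict = NULL) {
  stopifnot(inherits(corpus, "faers_corpus"))
  dd <- deduplicate_cases(corpus$demo)
  keep <- dd$demo$primaryid

  scr <- screen_primary_suspect(corpus$drug, target_dict, keep)
  drug_cases <- scr$cases

  n_comed_removed <- NA_integer_
  if (!is.null(comed_dict)) {
    exposed <- sort(unique(unlist(drug_cases, use.names = FALSE)))
    exc <- exclude_comedicated(exposed, corpus$drug, comed_dict)
    n_comed_removed <- exc$n_removed
    drug_cases <- lapply(drug_cases, function(v) setdiff(v, exc$removed))
  }

  event_cases <- extract_event_cases(corpus$reac, event_term, keep)
  drug_event_cases <- lapply(drug_cases, function(v) intersect(v, event_cases))

  structure(list(
    event_term = event_term,
    target_dict = target_dict,
    n_total = dd$n_unique,
    drug_cases = drug_cases,
    event_cases = event_cases,
    drug_event_cases = drug_event_cases,
    demo = dd$demo,
    funnel = list(
      reports_raw = dd$n_input,
      reports_deduplicated = dd$n_unique,
      cases_multi_ps_excluded = scr$n_excluded_multi,
      cases_target_ps = length(unique(unlist(drug_cases, use.names = FALSE))),
      cases_comed_removed = n_comed_removed,
      cases_event = length(event_cases),
      cases_drug_event = length(unique(unlist(drug_event_cases,
                                              use.names = FALSE)))
    )
  ), class = "screened_cohort")
}

#' @export
print.screened_cohort <- function(x, ...) {
  cat("<screened_cohort> event:", x$event_term, "\n")
  cat("  deduplicated reports:", x$n_total, "\n")
  for (d in names(x$drug_event_cases)) {
    cat(sprintf("  %-14s exposure %6d  with event %4d\n", d,
                length(x$drug_cases[[d]]), length(x$drug_event_cases[[d]])))
  }
  invisible(x)
}
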