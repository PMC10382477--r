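# FAERS quarterly ASCII dialect: '$'-delimited, header row, no quoting.
# Column roster per table: canonical name -> acceptable header aliases
# (case-insensitive). Post-2014 headers use SEX, the 2012Q4-2014Q2 files
# GNDR_COD; both map to `sex`. Legacy ISR-era files (pre-2012Q4) keyed on
# ISR instead of PRIMARYID are rejected outright.
.faers_schema <- list(
  demo = list(
    required = c(primaryid = "primaryid", caseid = "caseid", fda_dt = "fda_dt"),
    optional = c(event_dt = "event_dt", age = "age", age_cod = "age_cod",
                 sex = "sex", sex = "gndr_cod", occp_cod = "occp_cod",
                 reporter_country = "reporter_country",
                 occr_country = "occr_country")
  ),
  drug = list(
    required = c(primaryid = "primaryid"),
    optional = c(drug_seq = "drug_seq", role_cod = "role_cod",
                 drugname = "drugname")
  ),
  reac = list(
    required = c(primaryid = "primaryid"),
    optional = c(pt = "pt")
  ),
  ther = list(
    required = c(primaryid = "primaryid"),
    optional = c(dsg_drug_seq = "dsg_drug_seq", start_dt = "start_dt",
                 end_dt = "end_dt")
  ),
  outc = list(
    required = c(primaryid = "primaryid"),
    optional = c(outc_cod = "outc_cod")
  )
)

.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

# Read one '$'-delimited table. Rows whose field count differs from the
# header (embedded '$' in free text splits the row) are skipped and counted,
# as are rows with an unparseable PRIMARYID. Returns list(data, n_skipped).
read_faers_table <- function(path, table) {
  schema <- .faers_schema[[table]]
  if (!file.exists(path)) {
    stop(sprintf("FAERS %s file not found: %s", toupper(table), path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop(sprintf("empty FAERS file (no header row): %s", path))
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  if ("isr" %in% header && !"primaryid" %in% header) {
    stop(sprintf(
      "legacy ISR-format file not supported (pre-2012Q4 layout): %s", path))
  }
  for (col in unique(names(schema$required))) {
    aliases <- schema$required[names(schema$required) == col]
    if (!any(aliases %in% header)) {
      stop(sprintf("mandatory column '%s' missing in %s file: %s",
                   toupper(aliases[[1]]), toupper(table), path))
    }
  }

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "$", fixed = TRUE)
  # trailing empty field is dropped by strsplit; tolerate one-short rows that
  # end in '$' by padding, otherwise require the exact header width
  nf <- lengths(fields)
  short_ok <- nf == length(header) - 1L & endsWith(body, "$")
  fields[short_ok] <- lapply(fields[short_ok], function(f) c(f, ""))
  nf[short_ok] <- length(header)
  good <- nf == length(header)
  n_skipped <- sum(!good)
  fields <- fields[good]

  mat <- if (length(fields)) {
    matrix(unlist(fields, use.names = FALSE), ncol = length(header),
           byrow = TRUE)
  } else {
    matrix(character(0), ncol = length(header))
  }
  dt <- data.table::as.data.table(mat)
  data.table::setnames(dt, header)

  # map aliases onto canonical names, keep only schema columns
  wanted <- c(schema$required, schema$optional)
  out <- data.table::data.table(.dummy = seq_len(nrow(dt)))
  for (i in seq_along(wanted)) {
    canon <- names(wanted)[[i]]
    alias <- wanted[[i]]
    if (canon %in% names(out)) next
    if (alias %in% names(dt)) {
      out[[canon]] <- trimws(dt[[alias]])
    }
  }
  # any alias for the same canonical name
  for (canon in setdiff(unique(names(wanted)), names(out))) {
    out[[canon]] <- NA_character_
  }
  out[, .dummy := NULL]

  pid <- suppressWarnings(as.numeric(out$primaryid))
  bad_pid <- is.na(pid)
  n_skipped <- n_skipped + sum(bad_pid)
  out <- out[!bad_pid]
  out[, primaryid := pid[!bad_pid]]

  if (table == "demo") {
    cid <- suppressWarnings(as.numeric(out$caseid))
    bad <- is.na(cid)
    n_skipped <- n_skipped + sum(bad)
    out <- out[!bad]
    out[, caseid := cid[!bad]]
  }
  if (table == "drug") {
    out[, drug_seq := suppressWarnings(as.integer(drug_seq))]
    bad_role <- !out$role_cod %in% .role_codes
    n_skipped <- n_skipped + sum(bad_role)
    out <- out[!bad_role]
  }
  if (table == "ther") {
    out[, dsg_drug_seq := suppressWarnings(as.integer(dsg_drug_seq))]
  }
  if (table == "reac") {
    bad_pt <- is.na(out$pt) | !nzchar(out$pt)
    n_skipped <- n_skipped + sum(bad_pt)
    out <- out[!bad_pt]
  }
  list(data = out, n_skipped = n_skipped)
}

#' Read one FAERS quarterly file bundle
#'
#' Parses the five analysis tables of a FAERS quarter (DEMO, DRUG, REAC,
#' THER, OUTC) from their '$'-delimited ASCII files into a `faers_corpus`.
#' Malformed rows (wrong field count, unparseable PRIMARYID, invalid role
#' code, empty preferred term) are skipped and counted, never fatal; a
#' missing mandatory column (PRIMARYID; CASEID and FDA_DT in DEMO) or a
#' legacy ISR-era layout is a hard error.
#'
#' @param paths named character vector or list with elements `demo`, `drug`,
#'   `reac`, `ther`, `outc` (names matched case-insensitively) giving file
#'   paths.
#' @param quarter quarter label, e.g. `"2022q4"`. Defaults to a label
#'   inferred from the DEMO file name (`DEMO22Q4.txt` -> `"2022q4"`).
#' @return A [faers_corpus] holding the five tables plus a log of row counts
#'   read, skipped, and dropped for referential-integrity violations.
#' @seealso [bind_corpora()] to pool quarters, [deduplicate_cases()]
#' @export
read_faers_quarter <- function(paths, quarter = NULL) {
  names(paths) <- tolower(names(paths))
  missing_tbl <- setdiff(names(.faers_schema), names(paths))
  if (length(missing_tbl)) {
    stop("missing path(s) for table(s): ", paste(missing_tbl, collapse = ", "))
  }
  if (is.null(quarter)) {
    m <- regmatches(basename(paths[["demo"]]),
                    regexpr("[0-9]{2}[Qq][1-4]", basename(paths[["demo"]])))
    quarter <- if (length(m)) {
      sprintf("20%sq%s", substr(m, 1, 2), substr(m, 4, 4))
    } else {
      "unknown"
    }
  }
  parsed <- lapply(names(.faers_schema), function(tbl) {
    read_faers_table(paths[[tbl]], tbl)
  })
  names(parsed) <- names(.faers_schema)
  skipped <- vapply(parsed, `[[`, numeric(1), "n_skipped")
  faers_corpus(
    demo = parsed$demo$data, drug = parsed$drug$data, reac = parsed$reac$data,
    ther = parsed$ther$data, outc = parsed$outc$data,
    quarters = quarter, skipped = skipped
  )
}

#' Construct a FAERS corpus from in-memory tables
#'
#' Container for one or more quarters of FAERS data. Non-DEMO rows whose
#' PRIMARYID does not refer to any DEMO row in the corpus are counted and
#' dropped (orphan rows); this is logged, never fatal.
#'
#' @param demo,drug,reac,ther,outc data.frames with the canonical lower-case
#'   FAERS columns (see [read_faers_quarter()]).
#' @param quarters character vector of quarter labels covered.
#' @param skipped named numeric vector of skipped-row counts per table.
#' @return An object of class `faers_corpus`: a list with the five tables
#'   (as data.tables) and a `log` list of row/skip/orphan counts.
#' @export
faers_corpus <- function(demo, drug, reac, ther, outc,
                         quarters = "unknown",
                         skipped = c(demo = 0, drug = 0, reac = 0,
                                     ther = 0, outc = 0)) {
  tabs <- list(demo = data.table::as.data.table(demo),
               drug = data.table::as.data.table(drug),
               reac = data.table::as.data.table(reac),
               ther = data.table::as.data.table(ther),
               outc = data.table::as.data.table(outc))
  known <- unique(tabs$demo$primaryid)
  orphans <- c(demo = 0)
  for (tbl in c("drug", "reac", "ther", "outc")) {
    is_orphan <- !tabs[[tbl]]$primaryid %in% known
    orphans[[tbl]] <- sum(is_orphan)
    tabs[[tbl]] <- tabs[[tbl]][!is_orphan]
  }
  structure(
    c(tabs, list(
      quarters = quarters,
      log = list(
        rows = vapply(tabs, nrow, integer(1)),
        skipped = skipped,
        orphans = orphans
      )
    )),
    class = "faers_corpus"
  )
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat("<faers_corpus> quarters:", paste(x$quarters, collapse = ", "), "\n")
  for (tbl in c("demo", "drug", "reac", "ther", "outc")) {
    cat(sprintf("  %-4s %8d rows (%d skipped, %d orphaned)\n",
                toupper(tbl), nrow(x[[tbl]]),
                x$log$skipped[[tbl]] %||% 0, x$log$orphans[[tbl]] %||% 0))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Pool several quarterly corpora into one
#'
#' @param ... `faers_corpus` objects (or a single list of them).
#' @return One `faers_corpus` covering all quarters, with summed logs and
#'   referential integrity re-checked across the pooled DEMO table.
#' @export
bind_corpora <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "faers_corpus")) xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, logical(1), "faers_corpus")))
  skipped <- Reduce(`+`, lapply(xs, function(x) x$log$skipped))
  faers_corpus(
    demo = data.table::rbindlist(lapply(xs, `[[`, "demo"), fill = TRUE),
    drug = data.table::rbindlist(lapply(xs, `[[`, "drug"), fill = TRUE),
    reac = data.table::rbindlist(lapply(xs, `[[`, "reac"), fill = TRUE),
    ther = data.table::rbindlist(lapply(xs, `[[`, "ther"), fill = TRUE),
    outc = data.table::rbindlist(lapply(xs, `[[`, "outc"), fill = TRUE),
    quarters = unlist(lapply(xs, `[[`, "quarters")),
    skipped = skipped
  )
}

#' Write a signal table to CSV
#'
#' One row per drug set with the full-precision statistics, the per-algorithm
#' criterion flags, the overall signal verdict, and 2-decimal display columns
#' in the conventional "ROR (CI low, CI high)" style of published
#' disproportionality tables.
#'
#' @param results data.frame of signal results as returned by
#'   [scan_cohort()] or [signal_from_margins()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- data.table::as.data.table(results)
  r2 <- function(x) format_signal_number(x)
  if (nrow(out)) {
    out[, `:=`(
      ror_display  = sprintf("%s (%s, %s)", r2(ror), r2(ror_ci_low),
                             r2(ror_ci_high)),
      prr_display  = sprintf("%s (%s)", r2(prr), r2(chi2)),
      ic_display   = sprintf("%s (%s)", r2(ic), r2(ic025)),
      ebgm_display = sprintf("%s (%s)", r2(ebgm), r2(ebgm05))
    )]
  } else {
    out[, `:=`(ror_display = character(0), prr_display = character(0),
               ic_display = character(0), ebgm_display = character(0))]
  }
  data.table::fwrite(out, path)
  invisible(path)
}

# 2-decimal half-up display rendering; NA/Inf rendered as-is
format_signal_number <- function(x) {
  ifelse(is.finite(x), sprintf("%.2f", round_half_up(x, 2)), as.character(x))
}

# Write a corpus back to '$'-delimited quarterly files (upper-case FAERS
# headers); returns the per-table paths.
write_faers_quarter <- function(corpus, dir, quarter = corpus$quarters[[1]]) {
  stopifnot(inherits(corpus, "faers_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- sub("^20([0-9]{2})q([1-4])$", "\\1Q\\2", quarter)
  paths <- c()
  for (tbl in c("demo", "drug", "reac", "ther", "outc")) {
    dt <- data.table::copy(corpus[[tbl]])
    for (col in names(dt)) {
      v <- as.character(dt[[col]])
      v[is.na(v)] <- ""
      # numeric ids render without scientific notation
      if (col %in% c("primaryid", "caseid")) {
        v <- format(corpus[[tbl]][[col]], scientific = FALSE, trim = TRUE)
      }
      data.table::set(dt, j = col, value = v)
    }
    data.table::setnames(dt, toupper(names(dt)))
    path <- file.path(dir, sprintf("%s%s.txt", toupper(tbl), tag))
    data.table::fwrite(dt, path, sep = "$", quote = FALSE)
    paths[[tbl]] <- path
  }
  paths
}

# Half-up decimal rounding (printed tables use half-up, not banker's)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
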