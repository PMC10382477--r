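#' Build a 2x2 contingency table from screening margins
#'
#' Standard disproportionality layout: `a` target drug & target event, `b`
#' target drug & other events, `c` other drugs & target event, `d` other
#' drugs & other events, with `N = a + b + c + d` the deduplicated report
#' count.
#'
#' @param a reports with the target drug and the target event.
#' @param drug_total all reports with the target drug (`a + b`).
#' @param event_total all reports with the target event (`a + c`).
#' @param n total deduplicated reports `N`.
#' @return object of class `contingency_2x2`: list with `a`, `b`, `c`, `d`,
#'   `n`.
#' @examples
#' contingency_from_counts(889, 151660, 33574, 16011277)
#' @export
contingency_from_counts <- function(a, drug_total, event_total, n) {
  stopifnot(length(a) == 1, length(drug_total) == 1,
            length(event_total) == 1, length(n) == 1)
  # doubles throughout: cell products overflow 32-bit integers at FAERS scale
  a <- as.numeric(a); drug_total <- as.numeric(drug_total)
  event_total <- as.numeric(event_total); n <- as.numeric(n)
  b <- drug_total - a
  c <- event_total - a
  d <- n - drug_total - c
  if (a < 0) stop("cell a is negative")
  if (b < 0) stop("inconsistent margins: a exceeds drug_total (cell b < 0)")
  if (c < 0) stop("inconsistent margins: a exceeds event_total (cell c < 0)")
  if (d < 0) stop("inconsistent margins: drug_total + event_total - a exceeds N (cell d < 0)")
  if (n <= 0) stop("total report count N must be positive")
  structure(list(a = a, b = b, c = c, d = d, n = n),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

# shared standard error of the log ratio; Inf when any cell is 0
.log_se <- function(t) {
  with(t, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a/b)/(c/d)`; `CI = exp(ln ROR +/- 1.96 s)` with
#' `s = sqrt(1/a + 1/b + 1/c + 1/d)`. With `a = 0` the point estimate is 0
#' and the interval undefined (`NA`); a zero in `b`, `c` or `d` yields an
#' infinite/undefined estimate. No continuity correction is applied: the
#' signal criteria's report-count thresholds already exclude tiny counts,
#' and silent 0.5-corrections would change published values.
#'
#' @param t a [contingency_from_counts()] table.
#' @return named list: `ror`, `ci_low`, `ci_high`.
#' @export
compute_ror <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  ror <- with(t, (a * d) / (b * c))
  if (!is.finite(ror) || t$a == 0) {
    return(list(ror = if (t$a == 0 && t$b > 0) 0 else ror,
                ci_low = NA_real_, ci_high = NA_real_))
  }
  s <- .log_se(t)
  list(ror = ror,
       ci_low = ror * exp(-1.96 * s),
       ci_high = ror * exp(1.96 * s))
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`; the chi-squared statistic is Pearson's
#' without Yates continuity correction,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @inheritParams compute_ror
#' @return named list: `prr`, `chi2`.
#' @export
compute_prr <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  prr <- with(t, (a / (a + b)) / (c / (c + d)))
  chi2 <- with(t, n * (a * d - b * c)^2 /
                    ((a + b) * (c + d) * (a + c) * (b + d)))
  list(prr = prr, chi2 = chi2)
}

#' Information component with its lower bound
#'
#' `IC = log2( a N / ((a+c)(a+b)) )`, the base-2 log of the observed over
#' expected reporting count (BCPNN family). The lower bound is the
#' multiplicative normal-approximation construction
#' `IC025 = IC * exp(-1.96 s)`, not the BCPNN posterior quantile; see the
#' package vignette for the distinction. `a = 0` gives undefined (`NA`)
#' values.
#'
#' @inheritParams compute_ror
#' @return named list: `ic`, `ic025` (bits).
#' @export
compute_ic <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$a == 0) return(list(ic = NA_real_, ic025 = NA_real_))
  ic <- with(t, log2(a * n / ((a + c) * (a + b))))
  s <- .log_se(t)
  list(ic = ic, ic025 = ic * exp(-1.96 * s))
}

#' Observed-over-expected reporting ratio (EBGM form) with lower bound
#'
#' `EBGM = a N / ((a+c)(a+b))` -- the relative reporting ratio, without
#' empirical-Bayes shrinkage (see vignette) -- and
#' `EBGM05 = exp(ln EBGM - 1.64 s)`, a one-sided lower bound.
#' Note `IC = log2(EBGM)` identically.
#'
#' @inheritParams compute_ror
#' @return named list: `ebgm`, `ebgm05`.
#' @export
compute_ebgm <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$a == 0) return(list(ebgm = 0, ebgm05 = NA_real_))
  ebgm <- with(t, a * n / ((a + c) * (a + b)))
  s <- .log_se(t)
  list(ebgm = ebgm, ebgm05 = ebgm * exp(-1.64 * s))
}

#' Apply the four signal criteria
#'
#' Criteria: ROR -- lower 95% CI bound > 1 and N >= 2; PRR -- PRR >= 2,
#' chi-squared >= 4 and N >= 3; BCPNN -- IC025 >= 0; EBGM -- EBGM05 > 2.
#' A safety signal is declared only when all four algorithms meet their
#' criteria simultaneously. Undefined (`NA`) statistics fail their
#' criterion.
#'
#' @param ror_ci_low lower 95% CI bound of the ROR.
#' @param prr,chi2 PRR point estimate and Pearson chi-squared.
#' @param ic025 lower bound of the information component.
#' @param ebgm05 lower one-sided bound of EBGM.
#' @param n number of target drug--event reports (cell `a`).
#' @return named logical list: `ror_pass`, `prr_pass`, `bcpnn_pass`,
#'   `ebgm_pass`, `signal`.
#' @export
evaluate_signal <- function(ror_ci_low, prr, chi2, ic025, ebgm05, n) {
  ok <- function(x) !is.na(x) & is.finite(x)
  ror_pass   <- ok(ror_ci_low) && ror_ci_low > 1 && n >= 2
  prr_pass   <- ok(prr) && ok(chi2) && prr >= 2 && chi2 >= 4 && n >= 3
  bcpnn_pass <- ok(ic025) && ic025 >= 0
  ebgm_pass  <- ok(ebgm05) && ebgm05 > 2
  list(ror_pass = ror_pass, prr_pass = prr_pass, bcpnn_pass = bcpnn_pass,
       ebgm_pass = ebgm_pass,
       signal = ror_pass && prr_pass && bcpnn_pass && ebgm_pass)
}

#' All four disproportionality statistics from a 2x2 table or raw margins
#'
#' Convenience wrapper producing one result row with every statistic, its
#' interval bound(s), the per-algorithm criterion flags, and the overall
#' signal verdict, so a published table row can be checked from four
#' numbers with no corpus.
#'
#' @param a,drug_total,event_total,n screening margins (see
#'   [contingency_from_counts()]); alternatively pass a ready
#'   `contingency_2x2` as `table`.
#' @param label drug-set label for the output row.
#' @param table optional prebuilt `contingency_2x2` (overrides the margins).
#' @return one-row data.frame with columns `label`, `n_reports`, `a:d`,
#'   `ror`, `ror_ci_low`, `ror_ci_high`, `prr`, `chi2`, `ic`, `ic025`,
#'   `ebgm`, `ebgm05`, the four `*_pass` flags and `signal`.
#' @examples
#' signal_from_margins(889, 151660, 33574, 16011277, label = "SSRIs")
#' @export
signal_from_margins <- function(a, drug_total, event_total, n,
                                label = "drug", table = NULL) {
  t <- if (is.null(table)) {
    contingency_from_counts(a, drug_total, event_total, n)
  } else {
    table
  }
  r <- compute_ror(t)
  p <- compute_prr(t)
  i <- compute_ic(t)
  e <- compute_ebgm(t)
  f <- evaluate_signal(r$ci_low, p$prr, p$chi2, i$ic025, e$ebgm05, t$a)
  data.frame(
    label = label, n_reports = t$a,
    a = t$a, b = t$b, c = t$c, d = t$d,
    ror = r$ror, ror_ci_low = r$ci_low, ror_ci_high = r$ci_high,
    prr = p$prr, chi2 = p$chi2,
    ic = i$ic, ic025 = i$ic025,
    ebgm = e$ebgm, ebgm05 = e$ebgm05,
    ror_pass = f$ror_pass, prr_pass = f$prr_pass,
    bcpnn_pass = f$bcpnn_pass, ebgm_pass = f$ebgm_pass,
    signal = f$signal,
    stringsAsFactors = FALSE
  )
}

#' Scan a screened cohort for signals
#'
#' Computes one signal row for the pooled drug class (union of all target
#' drugs) and one per individual drug, each against the same deduplicated
#' total `N` and the same event margin.
#'
#' @param cohort a [build_cohort()] result.
#' @param class_label label for the pooled row (default `"pooled"`).
#' @return data.frame with one row per drug set; see
#'   [signal_from_margins()] for columns.
#' @export
scan_cohort <- function(cohort, class_label = "pooled") {
  stopifnot(inherits(cohort, "screened_cohort"))
  event_total <- length(cohort$event_cases)
  pooled_drug <- unique(unlist(cohort$drug_cases, use.names = FALSE))
  pooled_de <- unique(unlist(cohort$drug_event_cases, use.names = FALSE))
  rows <- list(signal_from_margins(
    length(pooled_de), length(pooled_drug), event_total, cohort$n_total,
    label = class_label))
  for (d in names(cohort$drug_cases)) {
    rows[[d]] <- signal_from_margins(
      length(cohort$drug_event_cases[[d]]),
      length(cohort$drug_cases[[d]]),
      event_total, cohort$n_total, label = d)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
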