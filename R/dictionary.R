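#' Drug synonym dictionaries
#'
#' A drug dictionary maps canonical (generic) drug names to sets of synonyms
#' (generic + brand names). Matching is case-insensitive on a normalized form
#' (upper-cased, trimmed, punctuation and repeated whitespace collapsed), and
#' a synonym contained as a substring of a verbatim DRUGNAME counts as a hit,
#' because FAERS verbatim names carry dose, salt and formulation suffixes
#' ("PROZAC 20MG CAPSULE"). Synonym sets of distinct canonical drugs must be
#' disjoint.
#'
#' @param synonyms named list: canonical name -> character vector of synonyms
#'   (the canonical name itself is always included as a synonym).
#' @return An object of class `drug_dictionary`.
#' @examples
#' d <- drug_dictionary(list(fluoxetine = c("Prozac", "Sarafem")))
#' canonicalize_drug("PROZAC 20MG", d)
#' @export
drug_dictionary <- function(synonyms) {
  stopifnot(is.list(synonyms), length(names(synonyms)) == length(synonyms))
  norm <- lapply(seq_along(synonyms), function(i) {
    unique(normalize_drug_name(c(names(synonyms)[[i]], synonyms[[i]])))
  })
  names(norm) <- names(synonyms)
  all_syn <- unlist(norm, use.names = FALSE)
  dup <- unique(all_syn[duplicated(all_syn)])
  if (length(dup)) {
    stop("synonym(s) shared by multiple canonical drugs: ",
         paste(dup, collapse = ", "))
  }
  structure(norm, class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("<drug_dictionary>", length(x), "canonical drugs,",
      length(unlist(x)), "synonyms\n")
  invisible(x)
}

# Upper-case, trim, strip punctuation to spaces, collapse whitespace
normalize_drug_name <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Bundled SSRI dictionary
#'
#' The six SSRIs with their major U.S./EU brand names.
#' @return a [drug_dictionary()]
#' @export
ssri_dictionary <- function() {
  drug_dictionary(list(
    fluoxetine   = c("Prozac", "Sarafem", "Selfemra", "Rapiflux"),
    citalopram   = c("Celexa", "Cipramil"),
    escitalopram = c("Lexapro", "Cipralex"),
    paroxetine   = c("Paxil", "Pexeva", "Seroxat", "Brisdelle"),
    sertraline   = c("Zoloft", "Lustral"),
    fluvoxamine  = c("Luvox", "Faverin", "Fevarin")
  ))
}

#' Bundled statin dictionary
#'
#' HMG-CoA reductase inhibitors, used for the co-medication sensitivity
#' analysis (statins are the best-established rhabdomyolysis precipitant).
#' @return a [drug_dictionary()]
#' @export
statin_dictionary <- function() {
  drug_dictionary(list(
    atorvastatin = c("Lipitor"),
    simvastatin  = c("Zocor"),
    rosuvastatin = c("Crestor"),
    pravastatin  = c("Pravachol"),
    lovastatin   = c("Mevacor", "Altoprev"),
    fluvastatin  = c("Lescol"),
    pitavastatin = c("Livalo", "Zypitamag")
  ))
}

#' Read a drug dictionary from a synonym file
#'
#' One line per synonym, `CANONICAL<TAB>SYNONYM`; `#` starts a comment;
#' blank lines ignored.
#'
#' @param path path to the synonym file.
#' @return a [drug_dictionary()]
#' @export
read_drug_dictionary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop(sprintf("malformed dictionary line(s) in %s (need CANONICAL<TAB>SYNONYM): %s",
                 path, paste(head(lines[bad], 3), collapse = "; ")))
  }
  canon <- vapply(parts, `[[`, character(1), 1L)
  syn <- vapply(parts, `[[`, character(1), 2L)
  drug_dictionary(split(syn, factor(canon, levels = unique(canon))))
}

#' Canonicalize a verbatim drug name against a dictionary
#'
#' @param verbatim character vector of verbatim DRUGNAME strings.
#' @param dict a [drug_dictionary()].
#' @return character vector: the canonical name, or `NA` where no synonym
#'   matches. A verbatim that matches synonyms of two distinct canonical
#'   drugs is an ambiguous match and raises an error.
#' @export
canonicalize_drug <- function(verbatim, dict) {
  m <- match_drug_all(verbatim, dict)
  n <- vapply(m, length, integer(1))
  if (any(n > 1L)) {
    i <- which(n > 1L)[[1]]
    stop(sprintf("ambiguous drug name '%s' matches: %s",
                 verbatim[[i]], paste(m[[i]], collapse = ", ")))
  }
  out <- rep(NA_character_, length(verbatim))
  out[n == 1L] <- unlist(m[n == 1L], use.names = FALSE)
  out
}

# All canonical drugs whose synonyms occur within each verbatim; returns a
# list of character vectors (possibly length > 1: the screening layer treats
# a multi-drug verbatim as multiple suspect drugs). Containment is at word
# boundaries on the normalized form: dose/salt suffixes still match
# ("PROZAC 20MG"), but CITALOPRAM does not fire inside ESCITALOPRAM.
match_drug_all <- function(verbatim, dict) {
  stopifnot(inherits(dict, "drug_dictionary"))
  nv <- normalize_drug_name(verbatim)
  hits <- vector("list", length(nv))
  for (i in seq_along(hits)) hits[[i]] <- character(0)
  for (canon in names(dict)) {
    hit <- rep(FALSE, length(nv))
    for (syn in dict[[canon]]) {
      hit <- hit | grepl(paste0("\\b", syn, "\\b"), nv)
    }
    idx <- which(hit)
    for (i in idx) hits[[i]] <- c(hits[[i]], canon)
  }
  hits
}
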