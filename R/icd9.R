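# ICD-9 code handling: lexical validation, normalization, prefix
# classification, and the configurable rule sets that drive the case finder.

#' Normalize an ICD-9 code for prefix matching
#'
#' Strips the decimal point and upper-cases the code, so that claims extracts
#' with and without dots ("338.29" vs "33829") match identically.
#'
#' @param code character vector of ICD-9 codes.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd9(c("338.29", "v70.0", "E9501"))
#' @export
normalize_icd9 <- function(code) {
  toupper(gsub(".", "", as.character(code), fixed = TRUE))
}

# Lexical pattern after normalization: 3-digit rubric plus up to two digits,
# or V-codes (2 digits + up to 2) or E-codes (3 digits + up to 1).
icd9_lexical_ok <- function(code) {
  norm <- normalize_icd9(code)
  grepl("^([0-9]{3}[0-9]{0,2}|V[0-9]{2}[0-9]{0,2}|E[0-9]{3}[0-9]?)$", norm)
}

#' Validate ICD-9 codes lexically
#'
#' @param code character vector.
#' @return invisibly, `code`; errors on the first lexically invalid entry.
#' @export
assert_icd9 <- function(code) {
  bad <- which(!icd9_lexical_ok(code))
  if (length(bad) > 0) {
    abort(sprintf("invalid ICD-9 code at position %d: '%s'",
                  bad[1], code[bad[1]]))
  }
  invisible(code)
}

# TRUE where any configured prefix is a (normalized) prefix of any other,
# used to enforce pairwise disjointness between rule sets.
.prefix_overlap <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(FALSE)
  a <- normalize_icd9(a); b <- normalize_icd9(b)
  any(vapply(a, function(x) {
    any(startsWith(b, x) | startsWith(x, b))
  }, logical(1)))
}

#' Build the ICD-9 classification rule set
#'
#' The rule set has four parts: `highly_likely_prefixes` (a single claim with
#' such a code qualifies a person-year; default the 338 chronic-pain family),
#' `likely_codes` (two claims on dates >= 30 days apart qualify),
#' `excluded_codes` (migraine, other headache, facial pain — person-years with
#' only these are excluded), and `cancer_pain_prefixes` (338.3x, carved out of
#' the 338 family by longest-prefix precedence and likewise excluding).
#'
#' The default `likely_codes` list is a documented synthetic stand-in
#' (common dorsopathy, arthropathy, myalgia and neuralgia codes); the
#' validated code list of the source phenotyping algorithm is proprietary to
#' that publication, so substitute your own list for production use.
#'
#' @param highly_likely_prefixes character vector of code prefixes.
#' @param likely_codes character vector of codes or prefixes.
#' @param excluded_codes character vector of prefixes (headache/facial pain).
#' @param cancer_pain_prefixes character vector of prefixes within 338.
#' @return an object of class `code_config`.
#' @examples
#' cfg <- code_config()
#' match_icd9(c("338.29", "338.3", "724.2", "346.90", "460"), cfg)
#' @export
code_config <- function(highly_likely_prefixes = "338",
                        likely_codes = c(
                          "307.80", "307.89", "353", "354", "355",
                          "714.0", "715", "719.4", "720", "721", "722",
                          "723", "724", "729.1", "729.2"
                        ),
                        excluded_codes = c("339", "346", "350.1", "350.2",
                                           "784.0"),
                        cancer_pain_prefixes = "338.3") {
  all_prefixes <- c(highly_likely_prefixes, likely_codes, excluded_codes,
                    cancer_pain_prefixes)
  # rule entries are *prefixes*: may be shorter than a full code
  ok <- grepl("^([0-9]{1,5}|V[0-9]{0,4}|E[0-9]{0,4})$",
              normalize_icd9(all_prefixes))
  if (!all(ok)) {
    abort(sprintf("code_config: invalid ICD-9 prefix '%s'",
                  all_prefixes[!ok][1]))
  }
  # pairwise disjointness after prefix expansion; the cancer-pain carve-out
  # from the highly-likely family is the one sanctioned overlap.
  pairs <- list(
    c("likely_codes", "excluded_codes"),
    c("likely_codes", "highly_likely_prefixes"),
    c("likely_codes", "cancer_pain_prefixes"),
    c("excluded_codes", "highly_likely_prefixes"),
    c("excluded_codes", "cancer_pain_prefixes")
  )
  sets <- list(highly_likely_prefixes = highly_likely_prefixes,
               likely_codes = likely_codes,
               excluded_codes = excluded_codes,
               cancer_pain_prefixes = cancer_pain_prefixes)
  for (p in pairs) {
    if (.prefix_overlap(sets[[p[1]]], sets[[p[2]]])) {
      abort(sprintf("code_config: sets '%s' and '%s' overlap after prefix expansion",
                    p[1], p[2]))
    }
  }
  ok <- vapply(normalize_icd9(cancer_pain_prefixes), function(x) {
    any(startsWith(x, normalize_icd9(highly_likely_prefixes)))
  }, logical(1))
  if (length(cancer_pain_prefixes) > 0 && !all(ok)) {
    abort("code_config: cancer_pain_prefixes must fall within the highly-likely lexical range")
  }
  structure(sets, class = "code_config")
}

#' @export
print.code_config <- function(x, ...) {
  cat("<code_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Build the opioid drug identifier list
#'
#' Default is a synthetic stand-in of generic opioid molecule names;
#' replace with the drug identifiers (names or NDCs) used in your extract.
#' Matching is case-insensitive on the exact identifier.
#'
#' @param drug_ids character vector of drug identifiers.
#' @return an object of class `opioid_list`.
#' @export
opioid_list <- function(drug_ids = c(
                          "BUPRENORPHINE", "BUTORPHANOL", "CODEINE",
                          "FENTANYL", "HYDROCODONE", "HYDROMORPHONE",
                          "LEVORPHANOL", "MEPERIDINE", "METHADONE",
                          "MORPHINE", "OXYCODONE", "OXYMORPHONE",
                          "PENTAZOCINE", "PROPOXYPHENE", "TAPENTADOL",
                          "TRAMADOL")) {
  if (length(drug_ids) == 0) {
    abort("opioid_list: drug_ids must be non-empty when the opioid criterion is enabled")
  }
  structure(list(drug_ids = toupper(drug_ids)), class = "opioid_list")
}

is_opioid <- function(drug_id, opioids) {
  toupper(drug_id) %in% opioids$drug_ids
}

#' Classify an ICD-9 code against the rule set
#'
#' Longest-prefix wins: a code matching both a general and a more specific
#' configured prefix takes the classification of the more specific one, which
#' is how 338.3x (cancer pain) is carved out of the 338 family.
#'
#' @param code character vector of lexically valid ICD-9 codes.
#' @param config a [code_config()].
#' @return character vector over `{"highly_likely", "likely",
#'   "excluded_headache", "cancer_pain", "none"}`.
#' @export
match_icd9 <- function(code, config = code_config()) {
  assert_icd9(code)
  norm <- normalize_icd9(code)
  classes <- c(highly_likely_prefixes = "highly_likely",
               likely_codes = "likely",
               excluded_codes = "excluded_headache",
               cancer_pain_prefixes = "cancer_pain")
  out <- rep("none", length(norm))
  best <- integer(length(norm))
  for (set_name in names(classes)) {
    prefixes <- normalize_icd9(config[[set_name]])
    for (p in prefixes) {
      hit <- startsWith(norm, p) & nchar(p) > best
      if (any(hit)) {
        out[hit] <- classes[[set_name]]
        best[hit] <- nchar(p)
      }
    }
  }
  out
}

#' Read a case-finder configuration file
#'
#' Reads a YAML or JSON file with any of the keys `code_config` (with the
#' four rule-set fields), `opioid_list` (vector of drug ids), and `policy`
#' (fields of [finder_policy()]); absent keys fall back to package defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return list with elements `code_config`, `opioids`, `policy`.
#' @export
read_finder_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cc <- do.call(code_config, as.list(raw$code_config %||% list()))
  ol <- if (is.null(raw$opioid_list)) opioid_list() else
    opioid_list(unlist(raw$opioid_list))
  pol <- do.call(finder_policy, as.list(raw$policy %||% list()))
  list(code_config = cc, opioids = ol, policy = pol)
}
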