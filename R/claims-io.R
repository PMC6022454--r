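# Tabular readers/writers and record validation shared by all stages.
#
# In-memory representations (all tibbles):
#   medical:  person_id, service_date (Date), icd9_codes (list of chr), payer_type
#   pharmacy: person_id, fill_date (Date), drug_id, days_supply (int), payer_type
#   person:   person_id, sex, birth_year (int), county
#   census:   county, sex, age_band, population, median_income, pct_poverty,
#             pct_bachelors
# On disk the medical icd9_codes column is semicolon-joined; dates are ISO-8601.

.schemas <- list(
  medical = c("person_id", "service_date", "icd9_codes", "payer_type"),
  pharmacy = c("person_id", "fill_date", "drug_id", "days_supply", "payer_type"),
  person = c("person_id", "sex", "birth_year", "county"),
  census = c("county", "sex", "age_band", "population", "median_income",
             "pct_poverty", "pct_bachelors")
)

.payer_levels <- c("public", "private")
.sex_levels <- c("female", "male")

.fail_row <- function(schema, row, field, msg) {
  abort(sprintf("%s record invalid at row %d, field '%s': %s",
                schema, row, field, msg))
}

.first_bad <- function(bad) if (any(bad)) which(bad)[1] else 0L

#' Validate a claims record collection
#'
#' Checks the type invariants of one of the four record schemas: required
#' columns, parseable ISO dates, lexically valid ICD-9 codes, positive
#' days' supply, recognised payer/sex levels, non-negative populations, and
#' person-id uniqueness for the person schema. Errors name the first
#' offending row and field.
#'
#' @param records a data frame.
#' @param schema one of `"medical"`, `"pharmacy"`, `"person"`, `"census"`.
#' @return the validated records as a tibble (invisibly usable in pipes).
#' @export
validate_claims <- function(records, schema = c("medical", "pharmacy",
                                                "person", "census")) {
  schema <- match.arg(schema)
  records <- as_tibble(records)
  missing <- setdiff(.schemas[[schema]], names(records))
  if (length(missing) > 0) {
    abort(sprintf("%s records missing column(s): %s",
                  schema, paste(missing, collapse = ", ")))
  }
  n <- nrow(records)
  if (n == 0) return(records)

  check_date <- function(col) {
    x <- records[[col]]
    if (!inherits(x, "Date")) {
      parsed <- as.Date(as.character(x), format = "%Y-%m-%d")
      i <- .first_bad(is.na(parsed) & !is.na(x))
      if (i > 0 || anyNA(parsed)) {
        i <- max(i, .first_bad(is.na(parsed)))
        .fail_row(schema, i, col, sprintf("not an ISO-8601 date: '%s'", x[i]))
      }
      records[[col]] <<- parsed
    } else if (anyNA(x)) {
      .fail_row(schema, .first_bad(is.na(x)), col, "missing date")
    }
  }
  check_levels <- function(col, levels) {
    i <- .first_bad(!(records[[col]] %in% levels))
    if (i > 0) {
      .fail_row(schema, i, col,
                sprintf("'%s' not one of {%s}", records[[col]][i],
                        paste(levels, collapse = ", ")))
    }
  }

  if (schema == "medical") {
    check_date("service_date")
    check_levels("payer_type", .payer_levels)
    codes <- records$icd9_codes
    if (!is.list(codes)) {
      codes <- strsplit(as.character(codes), ";", fixed = TRUE)
      records$icd9_codes <- codes
    }
    lens <- lengths(codes)
    flat <- unlist(codes, use.names = FALSE)
    row_of <- rep(seq_len(n), lens)
    nonblank <- tapply(nzchar(flat), factor(row_of, levels = seq_len(n)),
                       any, default = FALSE)
    i <- .first_bad(lens == 0 | !as.logical(nonblank))
    if (i > 0) .fail_row(schema, i, "icd9_codes", "empty code list")
    bad <- !icd9_lexical_ok(flat)
    if (any(bad)) {
      j <- which(bad)[1]
      .fail_row(schema, row_of[j], "icd9_codes",
                sprintf("invalid ICD-9 code '%s'", flat[j]))
    }
  } else if (schema == "pharmacy") {
    check_date("fill_date")
    check_levels("payer_type", .payer_levels)
    ds <- suppressWarnings(as.integer(records$days_supply))
    i <- .first_bad(is.na(ds) | ds < 1)
    if (i > 0) {
      .fail_row(schema, i, "days_supply",
                sprintf("must be a positive integer, got '%s'",
                        records$days_supply[i]))
    }
    records$days_supply <- ds
    i <- .first_bad(is.na(records$drug_id) | !nzchar(records$drug_id))
    if (i > 0) .fail_row(schema, i, "drug_id", "empty drug identifier")
  } else if (schema == "person") {
    check_levels("sex", .sex_levels)
    by <- suppressWarnings(as.integer(records$birth_year))
    i <- .first_bad(is.na(by) | by < 1850 | by > 2100)
    if (i > 0) {
      .fail_row(schema, i, "birth_year",
                sprintf("implausible birth year '%s'", records$birth_year[i]))
    }
    records$birth_year <- by
    if (anyDuplicated(records$person_id)) {
      i <- which(duplicated(records$person_id))[1]
      .fail_row(schema, i, "person_id",
                sprintf("duplicate person_id '%s'", records$person_id[i]))
    }
  } else if (schema == "census") {
    check_levels("sex", .sex_levels)
    pop <- suppressWarnings(as.numeric(records$population))
    i <- .first_bad(is.na(pop) | pop < 0)
    if (i > 0) .fail_row(schema, i, "population", "must be a count >= 0")
    records$population <- pop
    if (anyDuplicated(records[c("county", "sex", "age_band")])) {
      i <- which(duplicated(records[c("county", "sex", "age_band")]))[1]
      .fail_row(schema, i, "county", "duplicate stratum")
    }
    for (col in c("median_income", "pct_poverty", "pct_bachelors")) {
      v <- suppressWarnings(as.numeric(records[[col]]))
      i <- .first_bad(is.na(v))
      if (i > 0) .fail_row(schema, i, col, "missing covariate")
      records[[col]] <- v
    }
  }
  i <- .first_bad(if ("person_id" %in% names(records))
    is.na(records$person_id) | !nzchar(records$person_id) else FALSE)
  if (i > 0) .fail_row(schema, i, "person_id", "empty person id")
  records
}

#' Read a claims table
#'
#' Reads a comma-delimited text file (header row, ISO-8601 dates; the
#' medical `icd9_codes` column semicolon-joined) or, when the path ends in
#' `.parquet` and the arrow package is installed, a Parquet file with the
#' same schema. All records are validated against the schema invariants.
#'
#' @param path file path.
#' @param schema one of `"medical"`, `"pharmacy"`, `"person"`, `"census"`.
#' @return validated tibble of records.
#' @export
read_claims <- function(path, schema = c("medical", "pharmacy", "person",
                                         "census")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    rlang::check_installed("arrow")
    arrow::read_parquet(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  out <- validate_claims(raw, schema)
  message(sprintf("read %d %s record(s) from %s", nrow(out), schema, path))
  out
}

#' Write a claims table
#'
#' Inverse of [read_claims()]: emits comma-delimited text (or Parquet for a
#' `.parquet` path) that round-trips through [read_claims()] without loss.
#' An empty collection yields a header-only file.
#'
#' @param records validated records (see [validate_claims()]).
#' @param path output file path.
#' @param schema record schema.
#' @return invisibly, `path`.
#' @export
write_claims <- function(records, path, schema = c("medical", "pharmacy",
                                                   "person", "census")) {
  schema <- match.arg(schema)
  records <- validate_claims(records, schema)
  if (schema == "medical" && is.list(records$icd9_codes)) {
    records$icd9_codes <- vapply(records$icd9_codes, paste,
                                 character(1), collapse = ";")
  }
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    rlang::check_installed("arrow")
    arrow::write_parquet(records, path)
  } else {
    readr::write_csv(records, path, progress = FALSE)
  }
  invisible(path)
}
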