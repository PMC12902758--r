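#' @importFrom data.table data.table as.data.table setDT setorder setorderv
#'   copy fread fwrite rbindlist setnames set setattr := .N .I .SD
#' @importFrom stats rpois rlnorm runif sd setNames
#' @importFrom utils head
#' @importFrom pracma lsqnonneg
NULL

# data.table NSE column names
utils::globalVariables(c(
  ".", "person_id", "visit_id", "visit_kind", "start_date", "end_date",
  "drug_code", "ingredient_code", "atc5", "atc2", "year_of_birth", "gender",
  "admit_date", "discharge_date", "followup_end", "n_visits", "source_visit_ids",
  "entry_date", "episode_id", "ostart", "oend", "date", "n_ingredients",
  "max_count", "max_date", "category", "dist", "combo_key", "n_patients",
  "age", "stratum", "rank", "concept_id", "concept_code", "vocabulary",
  "atc_level", "ancestor_id", "descendant_id", "..keep", "row_id",
  "episode_count", "total_observed_days", "stay_days", "i.date",
  "i.n_ingredients", "x.admit_date", "level", "keep", "k", "V1"
))

#' Table schemas for the flat-file CDM dialect
#'
#' Columns and semantic types for the minimal OMOP-CDM-shaped tables the
#' pipeline consumes: `person`, `visit_occurrence`, `drug_exposure`, the
#' drug-code `dictionary`, and the optional `concept` / `concept_ancestor`
#' vocabulary tables. Dates are ISO-8601 calendar dates with no time
#' component; all interval logic downstream is day-granular.
#'
#' @format A named list; each element has `$required` (column names that must
#'   be present), `$dates` (columns parsed as dates), `$mandatory_dates`
#'   (date columns that must parse for a row to be kept), and `$optional`
#'   (columns that may be absent from the file).
#' @export
cdm_schemas <- list(
  person = list(
    required = c("person_id", "year_of_birth", "gender"),
    dates = character(), mandatory_dates = character(), optional = character()
  ),
  visit_occurrence = list(
    required = c("person_id", "visit_id", "visit_kind", "start_date", "end_date"),
    dates = c("start_date", "end_date"),
    mandatory_dates = c("start_date", "end_date"), optional = character()
  ),
  drug_exposure = list(
    required = c("person_id", "drug_code", "start_date"),
    dates = c("start_date", "end_date"),
    mandatory_dates = "start_date", optional = c("end_date", "visit_id")
  ),
  dictionary = list(
    required = c("drug_code", "ingredient_code", "atc5"),
    dates = character(), mandatory_dates = character(), optional = character()
  ),
  concept = list(
    required = c("concept_id", "concept_code", "vocabulary", "atc_level"),
    dates = character(), mandatory_dates = character(), optional = character()
  ),
  concept_ancestor = list(
    required = c("ancestor_id", "descendant_id"),
    dates = character(), mandatory_dates = character(), optional = character()
  )
)

#' Read a CDM-shaped table from a delimited text file
#'
#' Reads a comma- or tab-delimited file with a header row, checks that the
#' schema's required columns are present, coerces date columns from ISO-8601,
#' and drops rows whose mandatory dates fail to parse. Row order is
#' preserved. A load report (`rows_in`, `rows_kept`, `rows_dropped`) is
#' attached as the `"load_report"` attribute; `rows_in == rows_kept +
#' rows_dropped` always holds.
#'
#' @param path Path to the file.
#' @param table Schema name, one of `names(cdm_schemas)`.
#' @return A `data.table` with schema columns typed; identifier columns are
#'   character, dates are `Date`.
#' @export
read_cdm_table <- function(path, table = names(cdm_schemas)) {
  table <- match.arg(table)
  schema <- cdm_schemas[[table]]
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, sep = "auto", colClasses = "character",
              header = TRUE, na.strings = c("", "NA"))
  if (nrow(dt) == 0L && ncol(dt) == 0L) {
    warning("empty file: ", path)
    dt <- empty_cdm_table(table)
    setattr(dt, "load_report", list(rows_in = 0L, rows_kept = 0L, rows_dropped = 0L))
    return(dt)
  }
  missing_cols <- setdiff(schema$required, names(dt))
  if (length(missing_cols)) {
    stop("table '", table, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rows_in <- nrow(dt)
  for (dc in intersect(schema$dates, names(dt))) {
    set(dt, j = dc, value = suppressWarnings(as.Date(dt[[dc]], format = "%Y-%m-%d")))
  }
  keep <- rep(TRUE, nrow(dt))
  for (dc in intersect(schema$mandatory_dates, names(dt))) {
    raw_missing <- is.na(dt[[dc]])
    # a row is dropped only when the raw field was non-missing but unparseable,
    # or the mandatory date is absent outright
    keep <- keep & !raw_missing
  }
  dropped <- sum(!keep)
  if (dropped > 0L) {
    warning("dropped ", dropped, " row(s) of '", table,
            "' with missing or unparseable mandatory dates")
    dt <- dt[keep]
  }
  if ("year_of_birth" %in% names(dt)) {
    set(dt, j = "year_of_birth", value = as.integer(dt[["year_of_birth"]]))
  }
  setattr(dt, "load_report",
          list(rows_in = rows_in, rows_kept = nrow(dt), rows_dropped = dropped))
  dt[]
}

#' Write a CDM-shaped table to a delimited text file
#'
#' Writes with a header row, ISO-8601 dates, and empty fields for missing
#' optional values, such that `read_cdm_table()` reproduces the records
#' field-for-field.
#'
#' @param records A `data.table` or data.frame conforming to a schema in
#'   [cdm_schemas].
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_cdm_table <- function(records, path, sep = ",") {
  records <- as.data.table(records)
  fwrite(records, path, sep = sep, na = "", quote = "auto", dateTimeAs = "ISO")
  invisible(path)
}

empty_cdm_table <- function(table) {
  schema <- cdm_schemas[[table]]
  cols <- unique(c(schema$required, schema$optional))
  dt <- setDT(lapply(setNames(cols, cols), function(cn) {
    if (cn %in% schema$dates) as.Date(character()) else character()
  }))
  if ("year_of_birth" %in% cols) set(dt, j = "year_of_birth", value = integer())
  dt
}

#' Read a full CDM bundle from a directory
#'
#' Expects `person.csv`, `visit_occurrence.csv`, `drug_exposure.csv`, and
#' optionally `dictionary.csv`, `concept.csv`, `concept_ancestor.csv`.
#'
#' @param dir Directory containing the files.
#' @return A named list of `data.table`s (absent optional tables are `NULL`).
#' @export
read_bundle <- function(dir) {
  req <- c("person", "visit_occurrence", "drug_exposure")
  opt <- c("dictionary", "concept", "concept_ancestor")
  out <- list()
  for (tb in c(req, opt)) {
    p <- file.path(dir, paste0(tb, ".csv"))
    if (file.exists(p)) {
      out[[tb]] <- read_cdm_table(p, tb)
    } else if (tb %in% req) {
      stop("bundle at '", dir, "' is missing ", tb, ".csv")
    } else {
      out[tb] <- list(NULL)
    }
  }
  out
}

#' Write a CDM bundle to a directory
#'
#' @param bundle Named list of tables as returned by [generate_cohort()] or
#'   [read_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in names(bundle)) {
    if (!is.null(bundle[[tb]]) && tb %in% names(cdm_schemas)) {
      write_cdm_table(bundle[[tb]], file.path(dir, paste0(tb, ".csv")))
    }
  }
  invisible(dir)
}
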