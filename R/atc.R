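# WHO ATC codes are hierarchical strings: level 1 = anatomical main group
# (1 char, e.g. "J"), level 2 = therapeutic subgroup (3 chars, "J01"),
# level 3 = pharmacological subgroup (4 chars), level 4 = chemical subgroup
# (5 chars), level 5 = chemical substance (7 chars, "J01CA04").

.atc_len <- c(1L, 3L, 4L, 5L, 7L)
.atc_re <- c(
  "^[A-Z]$",
  "^[A-Z][0-9]{2}$",
  "^[A-Z][0-9]{2}[A-Z]$",
  "^[A-Z][0-9]{2}[A-Z]{2}$",
  "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
)

#' Validate ATC codes at a given hierarchy level
#'
#' A code is valid at level `k` when its length and alphanumeric pattern
#' match the WHO ATC structure for that level (1 -> 1 char, 2 -> 3, 3 -> 4,
#' 4 -> 5, 5 -> 7).
#'
#' @param code Character vector of candidate codes.
#' @param level Integer 1-5.
#' @return Logical vector.
#' @export
is_valid_atc <- function(code, level = 5L) {
  stopifnot(length(level) == 1L, level %in% 1:5)
  !is.na(code) & grepl(.atc_re[level], code)
}

#' Truncate an ATC code to a coarser hierarchy level
#'
#' Takes the prefix of the length defined for `target_level`; truncating a
#' code to its own level is the identity, and truncation composes along the
#' hierarchy (`atc_truncate(atc_truncate(x, 4), 2) == atc_truncate(x, 2)`).
#'
#' @param code Character vector of ATC codes (at level >= `target_level`).
#' @param target_level Integer 1-5.
#' @return Character vector of truncated codes.
#' @export
atc_truncate <- function(code, target_level) {
  if (length(target_level) != 1L || is.na(target_level) ||
      !(target_level %in% 1:5)) {
    stop("target_level must be a single integer between 1 and 5")
  }
  len <- .atc_len[target_level]
  if (any(!is.na(code) & nchar(code) < len)) {
    stop("some codes are shorter than the level-", target_level, " prefix")
  }
  substr(code, 1L, len)
}

#' Load a drug-code dictionary mapping products to ingredients and ATC codes
#'
#' The dictionary emulates a national product-code file (one row per product
#' x ingredient): columns `drug_code`, `ingredient_code`, `atc5`. Rows with
#' a blank ingredient code or blank ATC code contribute nothing, so products
#' whose rows are all blank remain unmapped — mirroring the exclusion of
#' products lacking both codes. Rows whose `atc5` is present but not a valid
#' level-5 ATC string are rejected with a counted warning. Products with
#' multiple rows are fixed-dose combinations and yield multi-ingredient
#' entries.
#'
#' @param x Path to a delimited file, or a data.frame with those columns.
#' @return An `atc_map`: a `data.table` with columns `drug_code`,
#'   `ingredient_code`, `atc5`, with attributes `provenance = "dictionary"`
#'   and `n_rejected` (malformed rows dropped).
#' @export
load_dictionary <- function(x) {
  dict <- if (is.character(x)) read_cdm_table(x, "dictionary") else as.data.table(x)
  stopifnot(all(c("drug_code", "ingredient_code", "atc5") %in% names(dict)))
  dict <- dict[, .(drug_code = as.character(drug_code),
                   ingredient_code = as.character(ingredient_code),
                   atc5 = as.character(atc5))]
  blank <- function(v) is.na(v) | v == ""
  dict <- dict[!blank(ingredient_code) & !blank(atc5)]
  bad <- !is_valid_atc(dict$atc5, 5L)
  n_rejected <- sum(bad)
  if (n_rejected > 0L) {
    warning("rejected ", n_rejected, " dictionary row(s) with malformed ATC codes")
    dict <- dict[!bad]
  }
  dict <- unique(dict)
  setorder(dict, drug_code, ingredient_code, atc5)
  setattr(dict, "provenance", "dictionary")
  setattr(dict, "n_rejected", n_rejected)
  dict[]
}

#' Derive a drug-to-ATC map from CDM vocabulary tables
#'
#' Reproduces the vocabulary-based mapping strategy: a drug code maps to a
#' level-5 ATC code exactly when the concept_ancestor table links that drug
#' (descendant) to a concept flagged in the concept table as ATC level 5.
#' Because this path carries no ingredient codes, the ingredient code
#' defaults to the ATC level-5 code itself.
#'
#' @param concept `data.table` with `concept_id`, `concept_code`,
#'   `vocabulary`, `atc_level` ("" or NA for non-ATC concepts).
#' @param concept_ancestor `data.table` with `ancestor_id`, `descendant_id`.
#' @return An `atc_map` with `provenance = "vocabulary"`.
#' @export
derive_from_vocabulary <- function(concept, concept_ancestor) {
  concept <- as.data.table(concept)
  concept_ancestor <- as.data.table(concept_ancestor)
  concept[, concept_id := as.character(concept_id)]
  concept_ancestor[, `:=`(ancestor_id = as.character(ancestor_id),
                          descendant_id = as.character(descendant_id))]
  known <- concept$concept_id
  orphan <- !(concept_ancestor$ancestor_id %in% known) |
    !(concept_ancestor$descendant_id %in% known)
  if (any(orphan)) {
    warning("ignored ", sum(orphan),
            " concept_ancestor pair(s) referencing unknown concepts")
    concept_ancestor <- concept_ancestor[!orphan]
  }
  atc5_concepts <- concept[vocabulary == "ATC" &
                             suppressWarnings(as.integer(atc_level)) == 5L &
                             is_valid_atc(concept_code, 5L),
                           .(ancestor_id = concept_id, atc5 = concept_code)]
  map <- concept_ancestor[atc5_concepts, on = "ancestor_id", nomatch = NULL][
    , .(drug_code = descendant_id, ingredient_code = atc5, atc5)]
  map <- unique(map)
  setorder(map, drug_code, ingredient_code, atc5)
  setattr(map, "provenance", "vocabulary")
  setattr(map, "n_rejected", 0L)
  map[]
}

#' Annotate drug exposures with ingredient and ATC codes
#'
#' Each exposure of a mapped drug expands to one annotated exposure per
#' (ingredient, ATC level-5) pair, with the level-2 therapeutic subgroup
#' precomputed; exposures of unmapped drugs are excluded. The mapping report
#' counts distinct input drug codes, with `n_mapped + n_unmapped ==
#' n_input_codes`.
#'
#' @param exposures `data.table` of drug exposures (`person_id`,
#'   `drug_code`, `start_date`, optional `end_date`). Absent end dates are
#'   treated as one-day exposures.
#' @param atc_map An `atc_map` from [load_dictionary()] or
#'   [derive_from_vocabulary()].
#' @return A list: `exposures` (annotated `data.table` with added
#'   `ingredient_code`, `atc5`, `atc2`) and `report` (named list
#'   `n_input_codes`, `n_mapped`, `n_unmapped`, `unmapped`).
#' @export
map_exposures <- function(exposures, atc_map) {
  exposures <- copy(as.data.table(exposures))
  if (!"end_date" %in% names(exposures)) exposures[, end_date := as.Date(NA)]
  exposures[is.na(end_date), end_date := start_date]
  input_codes <- unique(as.character(exposures$drug_code))
  mapped_codes <- unique(atc_map$drug_code)
  unmapped <- sort(setdiff(input_codes, mapped_codes))
  ann <- atc_map[exposures, on = "drug_code", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(ann)) ann[, atc2 := atc_truncate(atc5, 2L)]
  else ann[, atc2 := character()]
  report <- list(
    n_input_codes = length(input_codes),
    n_mapped = length(input_codes) - length(unmapped),
    n_unmapped = length(unmapped),
    unmapped = unmapped
  )
  list(exposures = ann[], report = report)
}

#' Drop exposures belonging to excluded ATC second-level classes
#'
#' By default removes B05 (blood substitutes and perfusion solutions), the
#' class conventionally excluded from inpatient prescribing-pattern analyses
#' as near-universal and clinically uninformative for interaction risk.
#'
#' @param mapped Annotated exposures from [map_exposures()].
#' @param excluded Character vector of ATC level-2 codes; `character(0)` is
#'   the identity.
#' @return Filtered `data.table`.
#' @export
exclude_atc2 <- function(mapped, excluded = "B05") {
  mapped <- as.data.table(mapped)
  if (!length(excluded)) return(mapped)
  mapped[!(atc2 %in% excluded)]
}
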