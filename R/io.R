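#' Default ICD-10 cause map
#'
#' Maps ICD-10 underlying-cause codes to the analysis cause list. Stomach
#' cancer comprises the range C16-C16.9 plus the singleton codes D00.2
#' (carcinoma in situ of stomach), D13.1 (benign neoplasm of stomach) and
#' D37.1 (neoplasm of uncertain behaviour of stomach). Garbage codes --
#' underlying causes that are intermediate, implausible, or insufficiently
#' specific and must be redistributed before modelling -- default to the
#' ill-defined mortality stems (R96, R98, R99) and unspecified-site cancer
#' (C76, C80); the list is configurable.
#'
#' @param garbage_stems,garbage_codes Character vectors of 3-character code
#'   stems / exact codes treated as garbage.
#' @return A cause map: named list of rules, one per cause, each with
#'   `stems` and `codes`.
#' @export
default_cause_map <- function(garbage_stems = c("R96", "R98", "R99", "C76", "C80"),
                              garbage_codes = character()) {
  list(
    stomach_cancer = list(stems = "C16",
                          codes = c("D00.2", "D13.1", "D37.1")),
    garbage = list(stems = garbage_stems, codes = garbage_codes)
  )
}

#' Map ICD-10 codes to analysis causes
#'
#' @param code Character vector of ICD-10 codes (letter, two digits,
#'   optional one-digit decimal, e.g. `"C16.3"`).
#' @param cause_map A cause map as produced by [default_cause_map()].
#'   Causes are matched in list order; unmatched well-formed codes map to
#'   `"other"`.
#' @return Character vector of cause labels.
#' @export
#' @examples
#' map_icd_code(c("C16.3", "D13.1", "C17", "R99"))
map_icd_code <- function(code, cause_map = default_cause_map()) {
  code <- as.character(code)
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9])?$", code)
  if (!all(ok))
    stop("malformed ICD-10 code(s): ", paste(unique(code[!ok]), collapse = ", "))
  stem <- substr(code, 1L, 3L)
  out <- rep("other", length(code))
  for (cz in rev(names(cause_map))) {
    rule <- cause_map[[cz]]
    hit <- stem %in% (rule$stems %||% character()) |
      code %in% (rule$codes %||% character())
    out[hit] <- cz
  }
  out
}

#' Read a stratified count table from delimited text
#'
#' Expects UTF-8 comma-separated text with a header naming the index
#' columns (`county`, `race`, `sex`, `age`, `year`, and for deaths
#' `cause`) and a `value` column. The table is validated against the
#' schema; for deaths, missing grid cells are inserted as explicit zeros.
#'
#' @param path File path.
#' @param schema A [strata_schema()].
#' @param kind `"deaths"` or `"population"`.
#' @param allow_fractional Permit non-integer death counts.
#' @return A validated `data.table`; see [count_table()].
#' @export
read_count_table <- function(path, schema, kind = c("deaths", "population"),
                             allow_fractional = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = ",", header = TRUE)
  for (col in intersect(c("county", "race", "sex", "age", "cause"), names(dt)))
    dt[, (col) := as.character(get(col))]
  count_table(dt, schema, kind = kind, allow_fractional = allow_fractional)
}

#' Write a stratified count table
#'
#' @param x A count table (`data.table`).
#' @param path Output file path.
#' @export
write_count_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = ",")
  invisible(path)
}

#' Write a summary table to delimited text
#'
#' One row per stratum or comparison with `mean`, `lower`, `upper`,
#' `significant` and `masked` columns. Masked rows are emitted with empty
#' value fields. Values round-trip at full double precision.
#'
#' @param table A summary table as produced by [summarise_draws()] or
#'   [disparity()].
#' @param path Output file path.
#' @export
write_summary_table <- function(table, path) {
  dt <- copy(as.data.table(table))
  if (!"masked" %in% names(dt)) dt[, masked := FALSE]
  for (col in intersect(c("mean", "lower", "upper"), names(dt)))
    dt[masked == TRUE, (col) := NA_real_]
  ok <- tryCatch({
    fwrite(dt, path, sep = ",", na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write summary table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a summary table written by [write_summary_table()]
#'
#' @param path File path.
#' @return A `data.table`; masked rows have `NA` value fields and
#'   `masked = TRUE`.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = ",", header = TRUE, na.strings = "")
  for (col in intersect(c("significant", "masked"), names(dt)))
    dt[, (col) := as.logical(get(col))]
  if ("year" %in% names(dt)) dt[, year := as.integer(year)]
  set_strata_order(dt)
  dt[]
}

#' Read a pipeline configuration file
#'
#' A YAML file whose keys override entries of
#' [default_scenario_config()]; unspecified keys keep their defaults.
#'
#' @param path Path to a YAML config file.
#' @return A complete config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- modifyList(default_scenario_config(), user)
  cfg
}
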