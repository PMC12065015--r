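# Per-case table interface: one row per neoplasm case with an identifier,
# an entity label, optional group/sex labels and a raw karyotype.

.check_case_cols <- function(cases) {
  need <- c("case_id", "entity", "karyotype")
  miss <- setdiff(need, names(cases))
  if (length(miss)) {
    rlang::abort(paste0(
      "case table is missing required column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  invisible(cases)
}

#' Read a per-case table from TSV or CSV
#'
#' Expects at least the columns `case_id`, `entity` and `karyotype`;
#' `group` and `sex` are optional. The delimiter is taken from the file
#' extension (`.csv` = comma, anything else = tab) unless given.
#'
#' @param path Path to a UTF-8 delimited text file.
#' @param delim Field delimiter; `NULL` (default) infers from the extension.
#' @return A tibble of case records.
#' @export
read_cases <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  cases <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  .check_case_cols(cases)
  cases
}

#' Parse the karyotypes of a case table
#'
#' Runs [parse_karyotype()] over every row and augments the table with the
#' extracted translocation types. Each case contributes a type at most
#' once. Skipped translocation-like terms are collected into a skip report
#' retrievable with [skip_report()].
#'
#' @param cases Data frame with columns `case_id`, `entity`, `karyotype`
#'   (plus optional `group`, `sex`).
#' @param count_nested Passed to [parse_karyotype()].
#' @return The input as a tibble with three new columns:
#'   `translocations` (list column of canonical labels), `trl_labels`
#'   (semicolon-joined text form) and `n_trl`; the skip report is attached
#'   as an attribute.
#' @examples
#' df <- tibble::tibble(
#'   case_id = "c1", entity = "CML",
#'   karyotype = "46,XY,t(9;22)(q34;q11)"
#' )
#' parsed <- parse_cases(df)
#' parsed$trl_labels
#' @export
parse_cases <- function(cases, count_nested = FALSE) {
  .check_case_cols(cases)
  parsed <- purrr::map(cases$karyotype, parse_karyotype,
    count_nested = count_nested
  )
  out <- tibble::as_tibble(cases)
  out$translocations <- purrr::map(parsed, "types")
  out$trl_labels <- purrr::map_chr(out$translocations, paste, collapse = ";")
  out$n_trl <- lengths(out$translocations)

  skips <- purrr::map2(cases$case_id, parsed, function(id, p) {
    if (nrow(p$skipped) == 0L) return(NULL)
    dplyr::mutate(p$skipped, case_id = id, .before = 1L)
  })
  attr(out, "skip_report") <- dplyr::bind_rows(skips)
  if (is.null(attr(out, "skip_report")) ||
      nrow(attr(out, "skip_report")) == 0L) {
    attr(out, "skip_report") <- tibble::tibble(
      case_id = character(0), fragment = character(0), reason = character(0)
    )
  }
  out
}

#' Skip report of a parsed case table
#'
#' @param parsed_cases Result of [parse_cases()].
#' @return Tibble with columns `case_id`, `fragment`, `reason`.
#' @export
skip_report <- function(parsed_cases) {
  rep <- attr(parsed_cases, "skip_report")
  if (is.null(rep)) {
    rlang::abort("no skip report attached; run parse_cases() first")
  }
  rep
}

#' Attach group labels from an entity-to-group mapping
#'
#' Grouping (e.g. pooling FAB subtypes of acute myeloid leukemia, or
#' lumping entities into main tumor groups) is configuration, not code:
#' the mapping is supplied as a two-column data frame or named vector.
#' Entities absent from the map keep their existing `group` (or get `NA`).
#'
#' @param cases Case table.
#' @param map Either a data frame with columns `entity` and `group`, or a
#'   named character vector `c(entity = group, ...)`, or a path readable
#'   by [read_group_map()].
#' @return The case table with a filled `group` column.
#' @export
apply_grouping <- function(cases, map) {
  if (is.character(map) && length(map) == 1L && file.exists(map)) {
    map <- read_group_map(map)
  }
  if (is.character(map) && !is.null(names(map))) {
    map <- tibble::tibble(entity = names(map), group = unname(map))
  }
  if (!is.data.frame(map) || !all(c("entity", "group") %in% names(map))) {
    rlang::abort("group map must have columns entity and group")
  }
  out <- tibble::as_tibble(cases)
  mapped <- unname(map$group)[match(out$entity, map$entity)]
  out$group <- if ("group" %in% names(cases)) {
    dplyr::coalesce(mapped, out$group)
  } else {
    mapped
  }
  out
}

#' Read an entity-to-group mapping file
#'
#' Accepts YAML (`entity: group` pairs) or delimited text with columns
#' `entity` and `group`.
#'
#' @param path File path; format inferred from the extension.
#' @return Tibble with columns `entity` and `group`.
#' @export
read_group_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    lst <- yaml::read_yaml(path)
    tibble::tibble(
      entity = names(lst),
      group = unname(vapply(lst, as.character, character(1)))
    )
  } else {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    readr::read_delim(path,
      delim = delim,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
}
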