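# Frequency spectra over the 253-type universe, one per entity / group /
# stratum. A spectra object is a long tibble (253 rows per label) carrying
# per-label totals as an attribute.

.as_trl_spectra <- function(long, totals) {
  structure(
    long,
    totals = totals,
    class = c("trl_spectra", class(tibble::tibble()))
  )
}

.get_translocation_sets <- function(cases) {
  if ("translocations" %in% names(cases)) {
    return(cases$translocations)
  }
  if ("trl_labels" %in% names(cases)) {
    return(strsplit(ifelse(is.na(cases$trl_labels), "", cases$trl_labels),
      ";",
      fixed = TRUE
    ))
  }
  rlang::abort(
    "case table has no translocations; run parse_cases() first"
  )
}

.one_spectrum <- function(sets, label) {
  labs <- .universe_labels()
  counts <- tabulate(.label_index(unlist(sets)), nbins = 253L)
  total <- sum(counts)
  tibble::tibble(
    label = label,
    index = seq_len(253L),
    type = labs,
    n_abs = counts,
    pct = if (total > 0L) 100 * counts / total else rep(0, 253L)
  )
}

#' Build a translocation frequency spectrum for one cohort
#'
#' Counts each case's deduplicated translocation types into absolute
#' frequencies over all 253 types and converts to percentages of the
#' cohort's translocation total. Percentages are kept at full floating
#' precision; rounding happens only when tables are written.
#'
#' @param cases Parsed case table (see [parse_cases()]), or any data frame
#'   with a `translocations` list column.
#' @param label Name for the cohort (one spectrum is built over all rows).
#' @return A `trl_spectra` tibble: 253 rows with columns `label`, `index`,
#'   `type`, `n_abs`, `pct`; per-label totals (`n_cases`,
#'   `n_translocations`) are attached and retrievable with
#'   [spectrum_totals()] or `glance()`.
#' @export
build_spectrum <- function(cases, label = "cohort") {
  if (nrow(cases) == 0L) rlang::abort("empty case list")
  sets <- .get_translocation_sets(cases)
  long <- .one_spectrum(sets, label)
  totals <- tibble::tibble(
    label = label,
    n_cases = nrow(cases),
    n_translocations = sum(long$n_abs)
  )
  .as_trl_spectra(long, totals)
}

#' Build spectra for every entity, group or stratum
#'
#' Splits the case table by one or more label columns and builds one
#' spectrum per stratum. With `by = c("entity", "sex")` the strata are the
#' sex-specific sub-cohorts of each entity, labelled `"entity/sex"`.
#'
#' @param cases Parsed case table.
#' @param by Character vector of column names to stratify by
#'   (default `"entity"`).
#' @return A `trl_spectra` tibble with 253 rows per stratum.
#' @export
build_spectra <- function(cases, by = "entity") {
  if (nrow(cases) == 0L) rlang::abort("empty case list")
  miss <- setdiff(by, names(cases))
  if (length(miss)) {
    rlang::abort(paste0("stratification column(s) not found: ",
      paste(miss, collapse = ", ")))
  }
  key <- do.call(paste, c(unname(as.list(cases[by])), sep = "/"))
  sets <- .get_translocation_sets(cases)
  pieces <- split(seq_along(key), key)
  longs <- purrr::imap(pieces, function(idx, lab) .one_spectrum(sets[idx], lab))
  totals <- tibble::tibble(
    label = names(pieces),
    n_cases = lengths(pieces),
    n_translocations = purrr::map_int(longs, function(x) sum(x$n_abs))
  )
  .as_trl_spectra(dplyr::bind_rows(longs), totals)
}

#' Per-label case and translocation totals of a spectra object
#'
#' @param spectra A `trl_spectra` object.
#' @return Tibble with columns `label`, `n_cases`, `n_translocations`.
#' @export
spectrum_totals <- function(spectra) {
  tot <- attr(spectra, "totals")
  if (is.null(tot)) rlang::abort("not a trl_spectra object")
  tot
}

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::glance
glance.trl_spectra <- function(x, ...) spectrum_totals(x)

# 253 x n_labels percentage matrix, columns in totals order
.pct_matrix <- function(spectra) {
  tot <- spectrum_totals(spectra)
  wide <- matrix(0, nrow = 253L, ncol = nrow(tot),
    dimnames = list(.universe_labels(), tot$label))
  for (lab in tot$label) {
    sub <- spectra[spectra$label == lab, ]
    wide[sub$index, lab] <- sub$pct
  }
  wide
}

.subset_spectra <- function(spectra, labels) {
  tot <- spectrum_totals(spectra)
  .as_trl_spectra(
    spectra[spectra$label %in% labels, ],
    tot[tot$label %in% labels, ]
  )
}

#' Partition spectra by the cohort-size inclusion filter
#'
#' An entity enters the comparative analysis only when enough material is
#' behind its spectrum: at least `min_cases` cases and at least
#' `min_translocations` observed translocations (both bounds inclusive).
#'
#' @param spectra A `trl_spectra` object.
#' @param min_cases,min_translocations Inclusion thresholds; default 100
#'   each.
#' @return List with `included` and `excluded` `trl_spectra` objects.
#' @export
apply_inclusion_filter <- function(spectra, min_cases = 100,
                                   min_translocations = 100) {
  tot <- spectrum_totals(spectra)
  keep <- tot$n_cases >= min_cases & tot$n_translocations >= min_translocations
  list(
    included = .subset_spectra(spectra, tot$label[keep]),
    excluded = .subset_spectra(spectra, tot$label[!keep])
  )
}

#' Frequency-category summary of each spectrum
#'
#' Bins the 253 per-type percentages of each label into the reporting
#' categories 0%, (0%, 1%), \[1%, 10%\] and (10%, 100%\]. The four counts
#' always sum to 253.
#'
#' @param spectra A `trl_spectra` object; every label must have at least
#'   one observed translocation.
#' @return Tibble with columns `label`, `n_zero`, `n_lt1`, `n_1to10`,
#'   `n_gt10`.
#' @export
frequency_categories <- function(spectra) {
  tot <- spectrum_totals(spectra)
  if (any(tot$n_translocations == 0L)) rlang::abort("no observations")
  spectra |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_zero = sum(.data$pct == 0),
      n_lt1 = sum(.data$pct > 0 & .data$pct < 1),
      n_1to10 = sum(.data$pct >= 1 & .data$pct <= 10),
      n_gt10 = sum(.data$pct > 10),
      .groups = "drop"
    )
}

#' Association between cohort size and translocation yield
#'
#' Squared Pearson correlation between the number of cases and the number
#' of translocations across spectra -- large cohorts should have yielded
#' proportionally more translocations.
#'
#' @param spectra A `trl_spectra` object with at least 3 labels.
#' @return A number in \[0, 1\].
#' @export
cases_vs_translocations_r2 <- function(spectra) {
  tot <- spectrum_totals(spectra)
  if (nrow(tot) < 3L) rlang::abort("need at least 3 spectra")
  r_squared(tot$n_cases, tot$n_translocations)
}

#' Wide type-by-label matrix export of spectra
#'
#' @param spectra A `trl_spectra` object.
#' @param value `"pct"` (default) or `"n_abs"`.
#' @return Tibble with `index`, `type` and one column per label.
#' @export
spectrum_wide <- function(spectra, value = c("pct", "n_abs")) {
  value <- match.arg(value)
  spectra |>
    dplyr::select("index", "type", "label", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "label", values_from = dplyr::all_of(value))
}
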