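# End-to-end pipeline: parse -> spectra -> inclusion filter -> pairwise
# comparison -> summaries, with all artifacts written as TSV plus a JSON
# manifest that records the configuration needed to re-run the analysis.

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full translocation-signature pipeline
#'
#' Executes parse, spectrum building, inclusion filtering, pairwise R^2
#' comparison, cutoff sensitivity and summary reporting over a per-case
#' table, writing every artifact to `output_dir`. Defaults reproduce the
#' reference analysis settings: inclusion at >= 100 cases and >= 100
#' translocations, characteristic-translocation cutoff 10%, sensitivity
#' cutoffs 10/5/2/1%.
#'
#' Written artifacts: `parsed_cases.tsv`, `skip_report.tsv`,
#' `spectrum_totals.tsv`, `spectra_long.tsv`, `spectra_wide_pct.tsv`,
#' `spectra_wide_abs.tsv`, `frequency_categories.tsv`,
#' `characteristic_types.tsv`, `comparisons.tsv`, `r2_matrix.tsv`,
#' `sensitivity.tsv`, `report.md`, `manifest.json`. Percentages are
#' rounded to 2 decimals and R^2 to 3 decimals at write time only.
#'
#' @param input Path to a TSV/CSV case table (see [read_cases()]) or a
#'   data frame of case records.
#' @param output_dir Directory for artifacts (created if absent).
#' @param by Stratification column(s) for spectra; default `"entity"`.
#' @param group_map Optional entity-to-group mapping (see
#'   [apply_grouping()]); applied when provided.
#' @param min_cases,min_translocations Inclusion thresholds (default 100).
#' @param cutoff_pct Characteristic-translocation exclusion cutoff in
#'   percent (default 10).
#' @param sensitivity Cutoffs for the sensitivity analysis
#'   (default `c(10, 5, 2, 1)`).
#' @param count_nested Count `t(...)` nested in derivatives; default
#'   `FALSE`.
#' @param seed Optional integer recorded in the manifest (the pipeline
#'   itself is deterministic; the seed matters when `input` was
#'   simulated).
#' @return Invisibly, an object of class `trl_run` bundling every
#'   intermediate table and the artifact paths.
#' @export
run_pipeline <- function(input, output_dir,
                         by = "entity", group_map = NULL,
                         min_cases = 100, min_translocations = 100,
                         cutoff_pct = 10, sensitivity = c(10, 5, 2, 1),
                         count_nested = FALSE, seed = NULL) {
  input_path <- NULL
  if (is.character(input) && length(input) == 1L) {
    input_path <- input
    input <- read_cases(input)
  }
  if (!is.data.frame(input)) rlang::abort("input must be a path or a data frame")
  if (nrow(input) == 0L) rlang::abort("empty input")

  cases <- if (!"translocations" %in% names(input)) {
    parse_cases(input, count_nested = count_nested)
  } else {
    tibble::as_tibble(input)
  }
  skips <- attr(cases, "skip_report")
  if (is.null(skips)) {
    skips <- tibble::tibble(case_id = character(0), fragment = character(0),
      reason = character(0))
  }
  if (nrow(skips) > 0L) {
    rlang::warn(paste0(nrow(skips), " translocation-like term(s) skipped; ",
      "see skip_report.tsv"))
  }
  if (!is.null(group_map)) cases <- apply_grouping(cases, group_map)

  spectra <- build_spectra(cases, by = by)
  parts <- apply_inclusion_filter(spectra, min_cases, min_translocations)
  included <- parts$included
  n_inc <- nrow(spectrum_totals(included))
  if (n_inc < 2L) rlang::abort("nothing to compare")

  freq_cat <- frequency_categories(included)
  characteristic <- included |>
    dplyr::filter(.data$pct > cutoff_pct) |>
    dplyr::arrange(.data$label, dplyr::desc(.data$pct))
  comparisons <- pairwise_comparisons(included, cutoff_pct)
  strength <- strength_summary(comparisons)
  sens <- purrr::map2(comparisons$label_a, comparisons$label_b,
    function(a, b) {
      dplyr::mutate(
        cutoff_sensitivity(included, a, b, sensitivity),
        label_a = a, label_b = b, .before = 1L
      )
    }) |> dplyr::bind_rows()

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rnd <- function(x, d) round(x, d)
  flat_cases <- dplyr::select(cases, -dplyr::any_of("translocations"))
  paths <- c(
    parsed_cases = .write_tsv(flat_cases, output_dir, "parsed_cases.tsv"),
    skip_report = .write_tsv(skips, output_dir, "skip_report.tsv"),
    spectrum_totals = .write_tsv(spectrum_totals(spectra), output_dir,
      "spectrum_totals.tsv"),
    spectra_long = .write_tsv(
      dplyr::mutate(tibble::as_tibble(included), pct = rnd(.data$pct, 2)),
      output_dir, "spectra_long.tsv"),
    spectra_wide_pct = .write_tsv(
      dplyr::mutate(spectrum_wide(included, "pct"),
        dplyr::across(-c("index", "type"), function(x) rnd(x, 2))),
      output_dir, "spectra_wide_pct.tsv"),
    spectra_wide_abs = .write_tsv(spectrum_wide(included, "n_abs"),
      output_dir, "spectra_wide_abs.tsv"),
    frequency_categories = .write_tsv(freq_cat, output_dir,
      "frequency_categories.tsv"),
    characteristic_types = .write_tsv(
      dplyr::mutate(tibble::as_tibble(characteristic), pct = rnd(.data$pct, 2)),
      output_dir, "characteristic_types.tsv"),
    comparisons = .write_tsv(
      comparisons |>
        dplyr::mutate(
          excluded = purrr::map_chr(.data$excluded, paste, collapse = ";"),
          r2 = rnd(.data$r2, 3)
        ),
      output_dir, "comparisons.tsv"),
    r2_matrix = .write_tsv(r2_matrix(comparisons), output_dir,
      "r2_matrix.tsv"),
    sensitivity = .write_tsv(
      sens |>
        dplyr::mutate(
          excluded = purrr::map_chr(.data$excluded, paste, collapse = ";"),
          r2 = rnd(.data$r2, 3)
        ),
      output_dir, "sensitivity.tsv"),
    strength_summary = .write_tsv(strength, output_dir,
      "strength_summary.tsv")
  )

  run <- structure(
    list(
      cases = cases, skip_report = skips, spectra = spectra,
      included = included, excluded = parts$excluded,
      frequency_categories = freq_cat, characteristic = characteristic,
      comparisons = comparisons, strength = strength, sensitivity = sens,
      paths = paths,
      config = list(
        by = by, min_cases = min_cases,
        min_translocations = min_translocations, cutoff_pct = cutoff_pct,
        sensitivity = sensitivity, count_nested = count_nested, seed = seed
      )
    ),
    class = "trl_run"
  )

  report <- summarize_run(run)
  writeLines(report, file.path(output_dir, "report.md"))
  run$paths <- c(run$paths, report = file.path(output_dir, "report.md"))

  manifest <- list(
    tool = "translosig",
    version = as.character(utils::packageVersion("translosig")),
    config = run$config,
    seed = seed,
    input = list(
      path = input_path,
      n_cases = nrow(cases),
      md5_parsed_cases = unname(tools::md5sum(paths[["parsed_cases"]]))
    ),
    artifacts = as.list(basename(run$paths))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null")
  run$paths <- c(run$paths, manifest = file.path(output_dir, "manifest.json"))
  invisible(run)
}

#' Human-readable report of a pipeline run
#'
#' Renders the run's totals, frequency-category table, characteristic
#' translocations, strength tallies and cutoff-sensitivity summary as a
#' markdown document.
#'
#' @param run A `trl_run` object from [run_pipeline()].
#' @return Character vector of markdown lines (invisibly written to
#'   `report.md` by the pipeline).
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "trl_run"))
  tot <- spectrum_totals(run$included)
  md_tab <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
      function(x) round(x, 3)))
    c(
      paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    )
  }
  char_tab <- run$characteristic |>
    tibble::as_tibble() |>
    dplyr::select("label", "type", "n_abs", "pct")
  spread <- run$sensitivity |>
    dplyr::group_by(.data$label_a, .data$label_b) |>
    dplyr::summarise(
      r2_at_max_cutoff = dplyr::first(.data$r2),
      max_spread = max(.data$r2, na.rm = TRUE) - min(.data$r2, na.rm = TRUE),
      .groups = "drop"
    )
  c(
    "# Translocation signature analysis",
    "",
    paste0("Strata compared: ", nrow(tot), " (of ",
      nrow(spectrum_totals(run$spectra)), " built); inclusion at >= ",
      run$config$min_cases, " cases and >= ", run$config$min_translocations,
      " translocations."),
    paste0("Characteristic-translocation cutoff: > ", run$config$cutoff_pct,
      "% of a stratum's translocations."),
    paste0("Parser skipped ", nrow(run$skip_report),
      " translocation-like term(s)."),
    "",
    "## Cohort totals",
    "",
    md_tab(tot),
    "",
    "## Frequency categories (counts of the 253 types per stratum)",
    "",
    md_tab(run$frequency_categories),
    "",
    "## Characteristic translocations (above cutoff)",
    "",
    if (nrow(char_tab)) md_tab(char_tab) else "(none)",
    "",
    "## Pairwise comparison strength",
    "",
    paste0(nrow(run$comparisons), " pairwise comparisons."),
    "",
    md_tab(run$strength),
    "",
    "## Cutoff sensitivity",
    "",
    paste0("Cutoffs evaluated: ",
      paste(run$config$sensitivity, collapse = ", "), "%."),
    paste0("Largest R^2 spread across cutoffs in any pair: ",
      round(max(spread$max_spread, na.rm = TRUE), 3), "."),
    "",
    md_tab(spread)
  )
}

#' @export
print.trl_run <- function(x, ...) {
  tot <- spectrum_totals(x$included)
  cat("<trl_run>", nrow(x$cases), "cases,", nrow(tot), "strata compared,",
    nrow(x$comparisons), "pairwise comparisons\n")
  cat("  artifacts in:", dirname(x$paths[[1]]), "\n")
  invisible(x)
}
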