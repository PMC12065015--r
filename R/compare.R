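# Pairwise comparison of translocation spectra by coefficient of
# determination (R^2), after excluding characteristic translocations whose
# frequency exceeds the cutoff in either member of the pair.

#' Coefficient of determination between two vectors
#'
#' The squared Pearson product-moment correlation, equivalently the OLS
#' coefficient of determination of either vector regressed on the other.
#' Symmetric in its arguments and blind to the sign of the association.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return A number in \[0, 1\].
#' @examples
#' r_squared(1:4, c(1, 2, 2, 4))
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (length(x) < 3L) rlang::abort("need at least 3 coordinates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("degenerate spectrum")
  }
  stats::cor(x, y)^2
}

#' Strength class of an R-squared value
#'
#' Classification is applied to R^2 rounded to one decimal, so the three
#' printed bins 0.0--0.3, 0.4--0.6 and 0.7--1.0 tile the unit interval
#' without gaps.
#'
#' @param r2 Numeric vector of R^2 values in \[0, 1\] (`NA` allowed).
#' @return Character vector: `"insignificant/very weak"`,
#'   `"weak/moderate"`, `"strong/very strong"` or `NA`.
#' @export
strength_class <- function(r2) {
  r1 <- round(r2, 1)
  dplyr::case_when(
    is.na(r1) ~ NA_character_,
    r1 <= 0.3 ~ "insignificant/very weak",
    r1 <= 0.6 ~ "weak/moderate",
    TRUE ~ "strong/very strong"
  )
}

#' Characteristic translocations of a spectrum pair
#'
#' A type is characteristic for the pair when its percentage frequency
#' strictly exceeds `cutoff_pct` in either spectrum (a type at exactly the
#' cutoff is retained). The union over both members is excluded from both
#' vectors so the retained coordinates stay aligned.
#'
#' @param spectra A `trl_spectra` object.
#' @param label_a,label_b The two labels to compare.
#' @param cutoff_pct Exclusion threshold in percent, in (0, 100\];
#'   default 10.
#' @return Character vector of excluded type labels (possibly empty).
#' @export
exclude_characteristic <- function(spectra, label_a, label_b,
                                   cutoff_pct = 10) {
  stopifnot(cutoff_pct > 0, cutoff_pct <= 100)
  tot <- spectrum_totals(spectra)
  for (lab in c(label_a, label_b)) {
    if (!lab %in% tot$label) rlang::abort(paste0("unknown label: ", lab))
    if (tot$n_translocations[tot$label == lab] == 0L) {
      rlang::abort(paste0("spectrum has no observations: ", lab))
    }
  }
  m <- .pct_matrix(.subset_spectra(spectra, c(label_a, label_b)))
  rownames(m)[m[, label_a] > cutoff_pct | m[, label_b] > cutoff_pct]
}

#' Compare two translocation spectra
#'
#' Excludes the pair's characteristic types (see
#' [exclude_characteristic()]), then computes R^2 between the two
#' percentage vectors over the retained coordinates and assigns a strength
#' class. Percentages are not recomputed after exclusion: R^2 is invariant
#' under positive rescaling of either vector, so renormalizing cannot
#' change the result.
#'
#' @inheritParams exclude_characteristic
#' @return One-row tibble: `label_a`, `label_b`, `cutoff_pct`,
#'   `excluded` (list column of excluded type labels), `n_excluded`,
#'   `n_retained`, `r2`, `strength`.
#' @export
compare_pair <- function(spectra, label_a, label_b, cutoff_pct = 10) {
  excluded <- exclude_characteristic(spectra, label_a, label_b, cutoff_pct)
  keep <- !.universe_labels() %in% excluded
  if (sum(keep) < 3L) rlang::abort("fewer than 3 retained coordinates")
  m <- .pct_matrix(.subset_spectra(spectra, c(label_a, label_b)))
  r2 <- r_squared(m[keep, label_a], m[keep, label_b])
  n_ex <- length(excluded)
  tibble::tibble(
    label_a = label_a,
    label_b = label_b,
    cutoff_pct = cutoff_pct,
    excluded = list(excluded),
    n_excluded = n_ex,
    n_retained = sum(keep),
    r2 = r2,
    strength = strength_class(r2)
  )
}

#' All pairwise spectrum comparisons
#'
#' Compares every unordered pair of labels; n spectra give n(n-1)/2 rows,
#' laid out as the upper triangle of the comparison matrix. A pair whose
#' comparison fails (degenerate retained vector, too few coordinates) is
#' kept as a flagged row with `r2 = NA` and the error message in `note`
#' rather than aborting the matrix.
#'
#' @param spectra A `trl_spectra` object with at least 2 labels.
#' @param cutoff_pct Exclusion threshold in percent; default 10.
#' @return A `trl_comparisons` tibble, one row per unordered pair.
#' @export
pairwise_comparisons <- function(spectra, cutoff_pct = 10) {
  labs <- spectrum_totals(spectra)$label
  if (length(labs) < 2L) rlang::abort("need at least 2 spectra")
  pairs <- utils::combn(labs, 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]
    b <- pairs[2L, j]
    tryCatch(
      dplyr::mutate(compare_pair(spectra, a, b, cutoff_pct),
        note = NA_character_
      ),
      error = function(e) tibble::tibble(
        label_a = a, label_b = b, cutoff_pct = cutoff_pct,
        excluded = list(character(0)), n_excluded = NA_integer_,
        n_retained = NA_integer_, r2 = NA_real_,
        strength = NA_character_, note = conditionMessage(e)
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("trl_comparisons", class(tibble::tibble())))
}

#' Tally comparisons by strength class and reporting thresholds
#'
#' @param comparisons A `trl_comparisons` tibble (or any data frame with
#'   columns `r2` and `strength`).
#' @return Tibble with columns `category`, `n`, `pct` (percent of
#'   computable comparisons, rounded to integer). Categories are the three
#'   strength classes plus the thresholds `R2 <= 0.3` and `R2 < 0.1`; a
#'   `not computable` row appears when flagged cells exist.
#' @export
strength_summary <- function(comparisons) {
  ok <- !is.na(comparisons$r2)
  n_ok <- sum(ok)
  r2 <- comparisons$r2[ok]
  cls <- comparisons$strength[ok]
  cats <- c(
    "insignificant/very weak", "weak/moderate", "strong/very strong"
  )
  n <- c(
    vapply(cats, function(cc) sum(cls == cc), integer(1)),
    `R2 <= 0.3` = sum(r2 <= 0.3),
    `R2 < 0.1` = sum(r2 < 0.1)
  )
  out <- tibble::tibble(
    category = names(n),
    n = as.integer(n),
    pct = as.integer(round(100 * n / max(n_ok, 1L)))
  )
  if (any(!ok)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      category = "not computable", n = sum(!ok), pct = NA_integer_
    ))
  }
  out
}

#' @exportS3Method generics::glance
glance.trl_comparisons <- function(x, ...) {
  ok <- !is.na(x$r2)
  tibble::tibble(
    n_pairs = nrow(x),
    n_computable = sum(ok),
    n_le_0.3 = sum(x$r2[ok] <= 0.3),
    n_lt_0.1 = sum(x$r2[ok] < 0.1),
    pct_le_0.3 = as.integer(round(100 * sum(x$r2[ok] <= 0.3) /
      max(sum(ok), 1L))),
    max_r2 = if (any(ok)) max(x$r2[ok]) else NA_real_
  )
}

#' Sensitivity of a pairwise R-squared to the exclusion cutoff
#'
#' Re-runs [compare_pair()] at progressively stricter cutoffs. The number
#' of retained coordinates is non-increasing as the cutoff decreases; for
#' a robust comparison the R^2 values should change only marginally.
#'
#' @inheritParams exclude_characteristic
#' @param cutoffs Percent cutoffs to evaluate; default `c(10, 5, 2, 1)`.
#' @return Tibble with one row per cutoff: `cutoff_pct`, `n_excluded`,
#'   `n_retained`, `r2`, `strength` (flagged rows carry `NA` and a
#'   `note`).
#' @export
cutoff_sensitivity <- function(spectra, label_a, label_b,
                               cutoffs = c(10, 5, 2, 1)) {
  rows <- purrr::map(cutoffs, function(co) {
    tryCatch(
      dplyr::mutate(compare_pair(spectra, label_a, label_b, co),
        note = NA_character_
      ),
      error = function(e) tibble::tibble(
        label_a = label_a, label_b = label_b, cutoff_pct = co,
        excluded = list(character(0)), n_excluded = NA_integer_,
        n_retained = NA_integer_, r2 = NA_real_,
        strength = NA_character_, note = conditionMessage(e)
      )
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::select(-"label_a", -"label_b") |>
    dplyr::relocate("cutoff_pct")
}

#' Upper-triangular R-squared matrix
#'
#' Lays the pairwise comparisons out as a square table with labels on both
#' margins and R^2 (rounded to `digits`) in the upper triangle.
#'
#' @param comparisons A `trl_comparisons` tibble.
#' @param digits Decimals to print; default 3.
#' @return Tibble; first column `label`, remaining columns one per label.
#' @export
r2_matrix <- function(comparisons, digits = 3) {
  labs <- unique(c(comparisons$label_a, comparisons$label_b))
  m <- matrix(NA_real_, length(labs), length(labs),
    dimnames = list(labs, labs)
  )
  idx <- cbind(
    match(comparisons$label_a, labs),
    match(comparisons$label_b, labs)
  )
  m[idx] <- round(comparisons$r2, digits)
  tibble::as_tibble(m, rownames = "label")
}
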