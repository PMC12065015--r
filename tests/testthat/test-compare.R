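# helpers to build multi-label spectra objects from explicit percentage
# vectors (counts over a fixed total keep pct exact)
spectra_from_counts <- function(...) {
  specs <- list(...)
  longs <- list()
  tots <- list()
  u <- trl_universe()
  for (nm in names(specs)) {
    counts <- integer(253)
    counts[match(names(specs[[nm]]), u$label)] <- specs[[nm]]
    sets <- unlist(
      purrr::map2(u$label, counts, function(lab, k) rep(list(lab), k)),
      recursive = FALSE
    )
    s <- build_spectrum(cases_from_sets(sets, nm), nm)
    longs[[nm]] <- tibble::as_tibble(s)
    tots[[nm]] <- spectrum_totals(s)
  }
  structure(
    dplyr::bind_rows(longs),
    totals = dplyr::bind_rows(tots),
    class = c("trl_spectra", class(tibble::tibble()))
  )
}

test_that("r_squared matches the OLS oracle and is symmetric", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  expect_equal(r_squared(x, y), ols_r2_oracle(x, y), tolerance = 1e-12)
  expect_equal(r_squared(x, y), r_squared(y, x), tolerance = 1e-15)
  expect_equal(r_squared(c(5, 1, 7), c(5, 1, 7)), 1.0)
  expect_equal(r_squared(c(1, 2, 3), c(3, 2, 1)), 1.0)  # sign-blind
})

test_that("r_squared equals brute-force OLS on 100 random pairs", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(3:253, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n) + stats::runif(1, -2, 2) * x
    expect_lt(abs(r_squared(x, y) - ols_r2_oracle(x, y)), 1e-12)
  }
})

test_that("degenerate vectors error rather than returning 0", {
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(r_squared(c(1, 2, 3), c(4, 4, 4)), "degenerate")
  expect_error(r_squared(c(1, 2), c(1, 2)), "at least 3")
  expect_error(r_squared(1:4, 1:5), "equal length")
})

test_that("R-squared is invariant under positive rescaling", {
  set.seed(7)
  for (i in 1:20) {
    x <- stats::runif(50)
    y <- stats::runif(50)
    k <- stats::runif(1, 0.001, 1000)
    expect_lt(abs(r_squared(x, y) - r_squared(k * x, y)), 1e-12)
    expect_lt(abs(r_squared(x, y) - r_squared(x, k * y)), 1e-12)
  }
})

test_that("strength classes follow the one-decimal bins", {
  expect_equal(strength_class(0.0), "insignificant/very weak")
  expect_equal(strength_class(0.3), "insignificant/very weak")
  expect_equal(strength_class(0.34), "insignificant/very weak") # rounds to 0.3
  expect_equal(strength_class(0.4), "weak/moderate")
  expect_equal(strength_class(0.599), "weak/moderate")          # rounds to 0.6
  expect_equal(strength_class(0.66), "strong/very strong")      # rounds to 0.7
  expect_equal(strength_class(1.0), "strong/very strong")
  expect_true(is.na(strength_class(NA_real_)))
})

test_that("characteristic exclusion is strict and pairwise-union", {
  s <- spectra_from_counts(
    CML = c("t(9;22)" = 600, "t(1;2)" = 200, "t(1;3)" = 200),
    other = c("t(8;21)" = 150, "t(1;2)" = 425, "t(1;3)" = 425)
  )
  ex <- exclude_characteristic(s, "CML", "other", 10)
  # union: t(9;22) at 60% in CML; t(8;21) at 15% in other; t(1;2)/t(1;3)
  # exceed 10% in both
  expect_setequal(ex, c("t(9;22)", "t(8;21)", "t(1;2)", "t(1;3)"))

  # uniform spectra: nothing above 10%
  u <- trl_universe()
  flat <- stats::setNames(rep(1L, 253), u$label)
  s2 <- spectra_from_counts(a = flat, b = flat)
  expect_equal(exclude_characteristic(s2, "a", "b", 10), character(0))
})

test_that("a type at exactly 10.0% is retained; just above is excluded", {
  # 100/1000 = exactly 10%; 101/1000 = 10.1%
  s <- spectra_from_counts(
    at = c("t(1;4)" = 100, "t(9;22)" = 900),
    above = c("t(1;5)" = 101, "t(9;22)" = 899)
  )
  ex <- exclude_characteristic(s, "at", "above", 10)
  expect_false("t(1;4)" %in% ex)
  expect_true("t(1;5)" %in% ex)
  expect_true("t(9;22)" %in% ex)
})

test_that("compare_pair of a spectrum with itself gives R2 = 1", {
  m <- make_signature("self", n_cases = 400, seed = 5, concentration = 0.5)
  cases <- sample_cohort(m)$cases
  s <- build_spectra(
    dplyr::bind_rows(
      dplyr::mutate(cases, entity = "a"),
      dplyr::mutate(cases, entity = "b")
    )
  )
  res <- compare_pair(s, "a", "b", cutoff_pct = 100)
  expect_equal(res$r2, 1.0)
  expect_equal(res$strength, "strong/very strong")
  expect_equal(res$n_retained + res$n_excluded, 253L)
})

test_that("compare_pair is symmetric in its arguments", {
  study <- make_study(2, seed = 13, n_cases = 300)
  s <- build_spectra(study_cases(study))
  ab <- compare_pair(s, "E01", "E02")
  ba <- compare_pair(s, "E02", "E01")
  expect_equal(ab$r2, ba$r2)
  expect_setequal(ab$excluded[[1]], ba$excluded[[1]])
  expect_equal(ab$strength, ba$strength)
})

test_that("renormalizing after exclusion cannot change R-squared", {
  study <- make_study(2, seed = 31, n_cases = 500)
  s <- build_spectra(study_cases(study))
  res <- compare_pair(s, "E01", "E02")
  keep <- !trl_universe()$label %in% res$excluded[[1]]
  m <- spectrum_wide(s, "pct")
  x <- m$E01[keep]
  y <- m$E02[keep]
  # renormalize retained percentages to sum to 100 again
  x2 <- 100 * x / sum(x)
  y2 <- 100 * y / sum(y)
  expect_equal(res$r2, r_squared(x2, y2), tolerance = 1e-12)
})

test_that("pairwise matrix has n(n-1)/2 rows and flags bad cells", {
  study <- make_study(5, seed = 17, n_cases = 200)
  s <- build_spectra(study_cases(study))
  cmp <- pairwise_comparisons(s)
  expect_equal(nrow(cmp), 10L)
  expect_true(all(!is.na(cmp$r2)))

  # append a degenerate stratum: a single type -> zero variance retained
  deg <- build_spectrum(cases_from_sets(
    replicate(50, "t(9;22)", simplify = FALSE), "DEG"), "DEG")
  s2 <- structure(
    dplyr::bind_rows(tibble::as_tibble(s), tibble::as_tibble(deg)),
    totals = dplyr::bind_rows(spectrum_totals(s), spectrum_totals(deg)),
    class = class(s)
  )
  cmp2 <- pairwise_comparisons(s2)
  expect_equal(nrow(cmp2), 15L)
  flagged <- cmp2[cmp2$label_a == "DEG" | cmp2$label_b == "DEG", ]
  expect_true(all(is.na(flagged$r2)))
  expect_true(all(!is.na(flagged$note)))
})

test_that("strength summary equals a brute-force recount", {
  study <- make_study(10, shared_pairs = 2, seed = 23, n_cases = 400)
  s <- build_spectra(study_cases(study))
  cmp <- pairwise_comparisons(s)
  expect_equal(nrow(cmp), 45L)
  sm <- strength_summary(cmp)
  expect_equal(
    sm$n[sm$category == "insignificant/very weak"],
    sum(cmp$strength == "insignificant/very weak")
  )
  expect_equal(sm$n[sm$category == "R2 <= 0.3"], sum(cmp$r2 <= 0.3))
  expect_equal(sm$n[sm$category == "R2 < 0.1"], sum(cmp$r2 < 0.1))
  # percentages are integer-rounded fractions of computable comparisons
  expect_equal(
    sm$pct[sm$category == "R2 <= 0.3"],
    as.integer(round(100 * sum(cmp$r2 <= 0.3) / nrow(cmp)))
  )
})

test_that("a 66-of-66 style tally reports 98%", {
  fake <- tibble::tibble(
    r2 = c(rep(0.05, 54), rep(0.25, 11), 0.45),
    strength = strength_class(r2)
  )
  sm <- strength_summary(fake)
  expect_equal(sm$n[sm$category == "R2 <= 0.3"], 65L)
  expect_equal(sm$pct[sm$category == "R2 <= 0.3"], 98L)
  expect_equal(sm$n[sm$category == "R2 < 0.1"], 54L)
})

test_that("cutoff sensitivity is monotone in retained coordinates", {
  study <- make_study(2, shared_pairs = 1, seed = 41, n_cases = 1500,
    spikes = list(E01 = c(type = "t(9;22)", mass = "0.6")))
  s <- build_spectra(study_cases(study))
  sens <- cutoff_sensitivity(s, "E01", "E02")
  expect_equal(sens$cutoff_pct, c(10, 5, 2, 1))
  expect_true(all(diff(sens$n_retained) <= 0))
  expect_true(all(sens$n_retained <= 252L))  # the 60% spike always excluded
})

test_that("with no type above 1% the R2 is identical at all cutoffs", {
  u <- trl_universe()
  set.seed(99)
  ca <- stats::setNames(sample(5:9, 253, replace = TRUE), u$label)
  cb <- stats::setNames(sample(5:9, 253, replace = TRUE), u$label)
  s <- spectra_from_counts(a = ca, b = cb)  # each type ~0.4% of total
  sens <- cutoff_sensitivity(s, "a", "b", cutoffs = c(10, 5, 2, 1))
  expect_equal(length(unique(sens$r2)), 1L)
  expect_true(all(sens$n_excluded == 0L))
})

test_that("the r2 matrix is upper-triangular in label order", {
  study <- make_study(4, seed = 57, n_cases = 300)
  s <- build_spectra(study_cases(study))
  cmp <- pairwise_comparisons(s)
  m <- r2_matrix(cmp)
  expect_equal(m$label, c("E01", "E02", "E03", "E04"))
  expect_true(is.na(m$E01[2]))            # lower triangle empty
  expect_equal(m$E02[1], round(cmp$r2[cmp$label_a == "E01" &
    cmp$label_b == "E02"], 3))
})
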