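# Independent oracles, deliberately kept apart from the package's own
# computation paths.

# Brute-force OLS coefficient of determination: fit y = a + b x by the
# normal equations and compute 1 - SSres/SStot.
ols_r2_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - (a + b * x)
  1 - sum(resid^2) / sum((y - mean(y))^2)
}

# Brute-force enumeration of unordered distinct non-Y chromosome pairs.
pair_enumeration_oracle <- function() {
  chroms <- c(as.character(1:22), "X")
  out <- character(0)
  for (i in seq_along(chroms)) {
    for (j in seq_along(chroms)) {
      if (i < j) {
        out <- c(out, paste(sort(c(chroms[i], chroms[j])), collapse = "|"))
      }
    }
  }
  out
}

# Brute-force frequency binning into the four reporting categories.
bin_oracle <- function(pct) {
  c(
    n_zero = sum(pct == 0),
    n_lt1 = sum(pct > 0 & pct < 1),
    n_1to10 = sum(pct >= 1 & pct <= 10),
    n_gt10 = sum(pct > 10)
  )
}

# Minimal parsed-case tibble from explicit per-case type sets.
cases_from_sets <- function(sets, entity = "E") {
  tibble::tibble(
    case_id = sprintf("%s_%03d", entity, seq_along(sets)),
    entity = entity,
    karyotype = "46,XX",
    translocations = lapply(sets, as.character)
  )
}
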