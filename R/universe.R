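# The 253-type translocation universe over chromosomes {1..22, X}.
# Y never participates in a countable type.

.AUTOSOMES <- as.character(1:22)
.COUNTABLE <- c(.AUTOSOMES, "X")

#' Enumerate the universe of two-way translocation types
#'
#' All unordered pairs of distinct, non-homologous chromosomes drawn from
#' the 22 autosomes plus X give 23 * 22 / 2 = 253 whole-chromosome
#' translocation types. The ordering is fixed and stable: the 231
#' autosome-autosome pairs in lexicographic order, `t(1;2)` through
#' `t(21;22)`, followed by the 22 X-involving pairs `t(X;1)` through
#' `t(X;22)` -- so the universe runs from `t(1;2)` to `t(X;22)`.
#'
#' @return A tibble with 253 rows and columns `index` (1--253), `chrom_a`,
#'   `chrom_b` and the canonical `label` (e.g. `"t(9;22)"`).
#' @examples
#' u <- trl_universe()
#' nrow(u)          # 253
#' u$label[1]       # "t(1;2)"
#' u$label[253]     # "t(X;22)"
#' @export
trl_universe <- function() {
  auto <- t(utils::combn(1:22, 2L))
  chrom_a <- c(as.character(auto[, 1L]), rep("X", 22L))
  chrom_b <- c(as.character(auto[, 2L]), as.character(1:22))
  tibble::tibble(
    index = seq_len(253L),
    chrom_a = chrom_a,
    chrom_b = chrom_b,
    label = paste0("t(", chrom_a, ";", chrom_b, ")")
  )
}

#' Canonical label for a two-way translocation type
#'
#' Writes X first when present (ISCN convention, e.g. `t(X;18)`), otherwise
#' the smaller autosome first (`t(9;22)`). Symmetric in its arguments:
#' `canonical_label(a, b) == canonical_label(b, a)`.
#'
#' @param chrom_a,chrom_b Chromosome identifiers: `"1"`..`"22"` or `"X"`
#'   (case-insensitive; numerics accepted). Vectorized.
#' @return Character vector of canonical labels.
#' @examples
#' canonical_label("18", "X")  # "t(X;18)"
#' canonical_label(22, 9)      # "t(9;22)"
#' @export
canonical_label <- function(chrom_a, chrom_b) {
  a <- toupper(trimws(as.character(chrom_a)))
  b <- toupper(trimws(as.character(chrom_b)))
  if (length(a) != length(b)) {
    rlang::abort("chrom_a and chrom_b must have equal length")
  }
  bad <- !(a %in% c(.COUNTABLE, "Y")) | !(b %in% c(.COUNTABLE, "Y"))
  if (any(bad)) {
    rlang::abort(paste0("unknown chromosome: ", a[bad][1], " / ", b[bad][1]))
  }
  if (any(a == "Y" | b == "Y")) rlang::abort("Y not countable")
  if (any(a == b)) rlang::abort("homologous pair")
  has_x <- a == "X" | b == "X"
  first <- character(length(a))
  second <- character(length(a))
  first[has_x] <- "X"
  second[has_x] <- ifelse(a[has_x] == "X", b[has_x], a[has_x])
  ia <- as.integer(a[!has_x])
  ib <- as.integer(b[!has_x])
  first[!has_x] <- as.character(pmin(ia, ib))
  second[!has_x] <- as.character(pmax(ia, ib))
  paste0("t(", first, ";", second, ")")
}

# Fast lookup: label -> universe index; built once at load time.
.universe_env <- new.env(parent = emptyenv())

.universe_labels <- function() {
  if (is.null(.universe_env$labels)) {
    .universe_env$labels <- trl_universe()$label
  }
  .universe_env$labels
}

.label_index <- function(labels) {
  match(labels, .universe_labels())
}
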