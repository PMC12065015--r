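# ISCN karyotype parsing restricted to what translocation extraction needs:
# clone splitting on "/", term splitting on commas (the implemented subset
# never carries commas inside parentheses -- ISCN bands are ";"-separated),
# recognition of t(...)(...) and of t(...) nested in derivative terms.
# Everything else (+8, -7, inv, del, idem, mar, sex constitution, ...) is
# passed over silently.

.SKIP_REASONS <- c(
  "three_or_more_way", "homologous", "y_involved",
  "unparseable", "nested_in_derivative"
)

# Classify the chromosome list of one t(...) term. Returns a list with
# either `label` (canonical) or `reason` (skip code).
.classify_t <- function(chrom_tokens) {
  toks <- toupper(trimws(chrom_tokens))
  if (length(toks) >= 3L) {
    return(list(reason = "three_or_more_way"))
  }
  if (length(toks) != 2L || any(!toks %in% c(as.character(1:22), "X", "Y"))) {
    # includes "?" in a chromosome position and empty tokens
    return(list(reason = "unparseable"))
  }
  if (toks[1] == toks[2]) {
    return(list(reason = "homologous"))
  }
  if (any(toks == "Y")) {
    return(list(reason = "y_involved"))
  }
  list(label = canonical_label(toks[1], toks[2]))
}

# All "t(" occurrences not embedded in a longer identifier (so "t(" in
# "der(16)t(1;16)" matches, "dup(" and "dic(" do not).
.T_OPEN <- "(?<![A-Za-z])t\\("

#' Extract two-way translocation types from an ISCN-style karyotype
#'
#' Scans every clone of a karyotype string for translocation terms and
#' returns the distinct countable types. Only two-way translocations
#' between non-homologous, non-Y chromosomes are countable; everything
#' else that looks like a translocation is reported as a skipped event
#' with a machine-readable reason:
#'
#' * `three_or_more_way` -- `t(1;2;5)` and longer,
#' * `homologous` -- both partners the same chromosome, e.g. `t(1;1)`,
#' * `y_involved` -- the Y chromosome participates,
#' * `unparseable` -- a chromosome token outside `1..22`, `X`, `Y`
#'   (including `?` in a chromosome position),
#' * `nested_in_derivative` -- a `t(...)` inside `der(...)`/`ider(...)` or
#'   any other compound term (an unbalanced derivative, not a balanced
#'   translocation; see `count_nested`).
#'
#' Band-level parentheticals are parsed past and discarded (aggregation is
#' to whole-chromosome level; `?` inside bands is tolerated). A type is
#' counted at most once per case regardless of repetition across clones.
#' Chromosome letters are matched case-insensitively and whitespace is
#' ignored.
#'
#' @param karyotype A single non-empty ISCN-style string, clones separated
#'   by `/`, abnormality terms by commas.
#' @param count_nested If `TRUE`, `t(...)` terms nested inside derivative
#'   terms are counted like free-standing translocations instead of being
#'   skipped. Default `FALSE`.
#' @return A list with `types` (character vector of canonical labels in
#'   universe order) and `skipped` (tibble with columns `fragment`,
#'   `reason`, one row per rejected `t(` occurrence).
#' @examples
#' parse_karyotype("46,XY,t(9;22)(q34;q11)")$types
#' parse_karyotype("46,XX,der(16)t(1;16)(q11;q11)")$skipped
#' @export
parse_karyotype <- function(karyotype, count_nested = FALSE) {
  if (length(karyotype) != 1L || is.na(karyotype) ||
      !nzchar(trimws(karyotype))) {
    rlang::abort("empty karyotype")
  }
  kt <- gsub("[[:space:]]+", "", karyotype)
  types <- character(0)
  frag <- character(0)
  reason <- character(0)

  for (clone in strsplit(kt, "/", fixed = TRUE)[[1]]) {
    if (!nzchar(clone)) next
    for (term in strsplit(clone, ",", fixed = TRUE)[[1]]) {
      if (!nzchar(term)) next
      hits <- gregexpr(.T_OPEN, term, perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      core <- sub("^\\+", "", term)
      standalone <- grepl(paste0("^", .T_OPEN), core, perl = TRUE)
      for (pos in hits) {
        nested <- !(standalone && pos == regexpr(.T_OPEN, term, perl = TRUE))
        if (nested && !count_nested) {
          frag <- c(frag, term)
          reason <- c(reason, "nested_in_derivative")
          next
        }
        # chromosome list = content of the parenthesis right after this "t("
        close <- regexpr("\\)", substr(term, pos, nchar(term)))
        if (close == -1L) {
          frag <- c(frag, term)
          reason <- c(reason, "unparseable")
          next
        }
        inner <- substr(term, pos + 2L, pos + close - 2L)
        res <- .classify_t(strsplit(inner, ";", fixed = TRUE)[[1]])
        if (is.null(res$label)) {
          frag <- c(frag, term)
          reason <- c(reason, res$reason)
        } else {
          types <- c(types, res$label)
        }
      }
    }
  }

  types <- unique(types)
  types <- types[order(.label_index(types))]
  list(
    types = types,
    skipped = tibble::tibble(fragment = frag, reason = reason)
  )
}
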