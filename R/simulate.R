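# Synthetic cohorts with known translocation-signature structure.
#
# An entity's signature is a probability vector over the 253 types drawn
# from a symmetric Dirichlet; a small concentration (default 0.05) gives
# the sparse, long-tailed spectra seen in real cytogenetic data, where the
# bulk of translocation types sit below 1% frequency. A characteristic
# translocation (e.g. t(9;22) in chronic myeloid leukemia) is emulated by
# assigning a fixed "spike" mass to one type and rescaling the rest.

#' Generative signature model for one synthetic tumor entity
#'
#' Draws a 253-type probability vector from a symmetric
#' Dirichlet(`concentration`), optionally folds in a characteristic-
#' translocation spike, and bundles it with the cohort-level sampling
#' parameters. Per-case translocation counts follow a zero-inflated
#' Poisson: with probability `p_zero` a case carries no translocation,
#' otherwise a Poisson(`lambda`) count. Deterministic given `seed`.
#'
#' @param entity Entity name.
#' @param concentration Dirichlet concentration parameter (> 0); smaller
#'   values give sparser signatures. Default 0.05.
#' @param spike_type Optional canonical type label (e.g. `"t(9;22)"`) to
#'   receive a fixed probability mass.
#' @param spike_mass Probability mass of the spike, in \[0, 1); the
#'   remaining types are rescaled to `1 - spike_mass`.
#' @param n_cases Number of cases to simulate. Default 1000.
#' @param p_zero Zero-inflation probability of the per-case translocation
#'   count. Default 0.3.
#' @param lambda Poisson mean of the per-case translocation count.
#'   Default 1.2.
#' @param sex_ratio Fraction of female cases. Default 0.5.
#' @param seed Integer seed for the signature draw (and, by default, for
#'   cohort sampling).
#' @return An object of class `signature_model`: a list with the fields
#'   above plus `probs`, a named probability vector over the universe.
#' @export
make_signature <- function(entity = "synthetic", concentration = 0.05,
                           spike_type = NULL, spike_mass = 0,
                           n_cases = 1000, p_zero = 0.3, lambda = 1.2,
                           sex_ratio = 0.5, seed = 1) {
  stopifnot(concentration > 0, spike_mass >= 0, spike_mass < 1,
    p_zero >= 0, p_zero <= 1, lambda >= 0)
  labs <- .universe_labels()
  if (!is.null(spike_type) && !spike_type %in% labs) {
    rlang::abort(paste0("spike type not in universe: ", spike_type))
  }
  set.seed(seed)
  g <- stats::rgamma(253L, shape = concentration, rate = 1)
  probs <- g / sum(g)
  if (!is.null(spike_type) && spike_mass > 0) {
    probs[labs == spike_type] <- 0
    probs <- probs / sum(probs) * (1 - spike_mass)
    probs[labs == spike_type] <- spike_mass
  }
  names(probs) <- labs
  structure(
    list(
      entity = entity, probs = probs,
      spike_type = spike_type, spike_mass = spike_mass,
      n_cases = as.integer(n_cases), p_zero = p_zero, lambda = lambda,
      sex_ratio = sex_ratio, seed = as.integer(seed)
    ),
    class = "signature_model"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @exportS3Method generics::tidy
tidy.signature_model <- function(x, ...) {
  tibble::tibble(
    index = seq_len(253L),
    type = names(x$probs),
    prob = unname(x$probs)
  )
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model>", x$entity, "\n")
  cat("  n_cases:", x$n_cases, " p_zero:", x$p_zero,
    " lambda:", x$lambda, " seed:", x$seed, "\n")
  if (!is.null(x$spike_type) && x$spike_mass > 0) {
    cat("  spike:", x$spike_type, "at mass", x$spike_mass, "\n")
  }
  top <- sort(x$probs, decreasing = TRUE)[1:3]
  cat("  top types:", paste(names(top), round(top, 3), collapse = ", "), "\n")
  invisible(x)
}

# Fixed band placeholder; random bands only exercise parser tolerance
# (the pipeline discards band content either way).
.BANDS <- c("p11", "p13", "p15", "q11", "q13", "q21", "q22", "q34", "?")

.render_karyotype <- function(sex, labels, random_bands = FALSE) {
  sexchrom <- if (identical(sex, "F")) "XX" else "XY"
  if (length(labels) == 0L) return(paste0("46,", sexchrom))
  bands <- if (random_bands) {
    paste0("(", sample(.BANDS, length(labels), replace = TRUE), ";",
      sample(.BANDS, length(labels), replace = TRUE), ")")
  } else {
    rep("(q11;q22)", length(labels))
  }
  paste0("46,", sexchrom, ",", paste0(labels, bands, collapse = ","))
}

#' Sample a synthetic cohort from a signature model
#'
#' For each case: draws a sex, a translocation count k from the
#' zero-inflated Poisson, and k distinct types i.i.d. from the signature
#' (collisions are redrawn up to `max_retries`, keeping per-case sets
#' consistent with the parser's once-per-case counting unit), then renders
#' an ISCN-style karyotype string. Every emitted type is tallied in the
#' emission log, so re-parsing the rendered karyotypes must recover the
#' log exactly.
#'
#' @param model A [make_signature()] object.
#' @param seed Sampling seed; defaults to `model$seed`.
#' @param random_bands Render randomized band parentheticals (including
#'   `?`) instead of the fixed `(q11;q22)` placeholder. Default `FALSE`.
#' @param max_retries Bound on collision redraws per case. Default 100.
#' @return An object of class `synthetic_cohort`: list with `cases`
#'   (tibble: `case_id`, `entity`, `sex`, `karyotype`, `translocations`
#'   list column, `n_trl`), `truth` (the model) and `emission_log`
#'   (named integer vector of per-type emitted counts).
#' @export
sample_cohort <- function(model, seed = model$seed, random_bands = FALSE,
                          max_retries = 100) {
  stopifnot(inherits(model, "signature_model"))
  labs <- .universe_labels()
  set.seed(seed)
  n <- model$n_cases
  sex <- ifelse(stats::runif(n) < model$sex_ratio, "F", "M")
  k <- stats::rpois(n, model$lambda)
  k[stats::runif(n) < model$p_zero] <- 0L
  k <- pmin(k, 253L)

  sets <- vector("list", n)
  nz <- which(k > 0L)
  if (length(nz)) {
    draws <- sample.int(253L, sum(k[nz]), replace = TRUE, prob = model$probs)
    pieces <- split(draws, rep(nz, k[nz]))
    for (nm in names(pieces)) {
      i <- as.integer(nm)
      got <- unique(pieces[[nm]])
      tries <- 0L
      while (length(got) < k[i]) {
        tries <- tries + 1L
        if (tries > max_retries) rlang::abort("retry bound exceeded")
        extra <- sample.int(253L, k[i] - length(got), replace = TRUE,
          prob = model$probs)
        got <- unique(c(got, extra))
      }
      sets[[i]] <- sort(got)
    }
  }
  sets[k == 0L] <- list(integer(0))

  label_sets <- purrr::map(sets, function(ix) labs[ix])
  karyotypes <- purrr::map2_chr(sex, label_sets, .render_karyotype,
    random_bands = random_bands)
  emission <- tabulate(unlist(sets), nbins = 253L)
  names(emission) <- labs

  cases <- tibble::tibble(
    case_id = sprintf("%s_%05d", model$entity, seq_len(n)),
    entity = model$entity,
    sex = sex,
    karyotype = karyotypes,
    translocations = label_sets,
    n_trl = lengths(label_sets)
  )
  structure(
    list(cases = cases, truth = model, emission_log = emission),
    class = "synthetic_cohort"
  )
}

#' @exportS3Method generics::glance
glance.synthetic_cohort <- function(x, ...) {
  tibble::tibble(
    entity = x$truth$entity,
    n_cases = nrow(x$cases),
    n_translocations = sum(x$emission_log),
    n_types_seen = sum(x$emission_log > 0L)
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$truth$entity, ":", nrow(x$cases), "cases,",
    sum(x$emission_log), "translocations\n")
  invisible(x)
}

#' Generate a multi-entity synthetic study
#'
#' Builds independent signatures for `n_entities` entities, except that
#' the first `shared_pairs` consecutive entity pairs (entities 1&2, 3&4,
#' ...) reuse one signature -- emulating, e.g., the female/male split of a
#' single disease, where the underlying signature is common but the
#' cohorts are sampled independently. Deterministic given `seed`.
#'
#' @param n_entities Number of entities (>= 2). Entities are named
#'   `"E01"`, `"E02"`, ...
#' @param shared_pairs Number of leading entity pairs sharing a signature
#'   (default 0); requires `2 * shared_pairs <= n_entities`.
#' @param seed Integer master seed; per-entity seeds are derived from it.
#' @param spikes Optional named list `list(E01 = c(type = "t(9;22)",
#'   mass = 0.6))` adding characteristic-translocation spikes to selected
#'   entities.
#' @param ... Further arguments (`n_cases`, `concentration`, `p_zero`,
#'   `lambda`, `sex_ratio`) passed to [make_signature()]; `n_cases` may be
#'   a vector, recycled over entities, to emulate cohorts of unequal size.
#' @return An object of class `trl_study`: a list of `synthetic_cohort`s.
#' @export
make_study <- function(n_entities, shared_pairs = 0, seed = 1,
                       spikes = NULL, ...) {
  if (n_entities < 2L) rlang::abort("need at least 2 entities")
  if (2L * shared_pairs > n_entities) {
    rlang::abort("shared_pairs exceeds available entity pairs")
  }
  names_e <- sprintf("E%02d", seq_len(n_entities))
  # signature index: shared pairs collapse onto one signature each
  sig_of <- seq_len(n_entities)
  if (shared_pairs > 0L) {
    for (p in seq_len(shared_pairs)) sig_of[2L * p] <- 2L * p - 1L
  }
  dots <- list(...)
  if (!is.null(dots$n_cases)) {
    dots$n_cases <- rep_len(dots$n_cases, n_entities)
  }
  cohorts <- purrr::map(seq_len(n_entities), function(i) {
    spike <- spikes[[names_e[i]]]
    args <- dots
    if (!is.null(args$n_cases)) args$n_cases <- args$n_cases[i]
    model <- do.call(make_signature, c(
      list(
        entity = names_e[i],
        spike_type = if (!is.null(spike)) unname(spike["type"]) else NULL,
        spike_mass = if (!is.null(spike)) as.numeric(spike["mass"]) else 0,
        seed = seed + 7L * sig_of[i]
      ),
      args
    ))
    sample_cohort(model, seed = seed + 1000L + i)
  })
  names(cohorts) <- names_e
  structure(cohorts, class = "trl_study")
}

#' Bind the case tables of a study into one tibble
#'
#' @param study A [make_study()] result (or list of cohorts).
#' @return Tibble of all cases across entities.
#' @export
study_cases <- function(study) {
  purrr::map(unclass(study), "cases") |> dplyr::bind_rows()
}
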