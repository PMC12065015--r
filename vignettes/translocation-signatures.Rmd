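---
title: "Comparing chromosomal translocation signatures across tumor entities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing chromosomal translocation signatures across tumor entities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translosig)
library(dplyr)
```

## The question and the method

Reciprocal (two-way) translocations are among the most consequential
chromosome abnormalities in neoplasia. A handful are famous and
tumor-defining — t(9;22) in chronic myeloid leukemia, t(X;18) in synovial
sarcoma — but the overwhelming majority of translocations recorded in
tumor karyotypes are rare or exceedingly rare, and it has long been
debated whether these rare events are biologically meaningful or mere
noise. One way to address that question at the whole-chromosome level is
to ask whether the *distribution* of rare translocations is
entity-specific: if each tumor type carries its own reproducible
"translocation signature", the rare events cannot be random.

`translosig` implements that analysis as a tested, reusable pipeline:

1. **Extraction.** Two-way translocations are parsed out of ISCN-style
   karyotype strings. Translocations involving homologous chromosomes or
   the Y chromosome are excluded, as are three-way and more complex
   events; band-level detail is parsed past and discarded, so aggregation
   is to whole-chromosome resolution. A case contributes each
   translocation type at most once, however many clones repeat it.
2. **Spectrum building.** With 22 autosomes plus X there are
   23 × 22 / 2 = 253 possible translocation types, ordered here from
   t(1;2) to t(X;22). For each entity (or group, or sex stratum) the
   pipeline counts absolute frequencies over all 253 types and converts
   them to percentages of the entity's translocation total. Entities
   enter comparative analysis only with ≥ 100 cases *and* ≥ 100
   translocations (both bounds inclusive).
3. **Comparison.** For each pair of entities, *characteristic*
   translocations — those strictly exceeding 10% of either member's
   translocations — are excluded (union over the pair, dropped from both
   vectors so coordinates stay aligned), and the coefficient of
   determination R² is computed between the two percentage vectors over
   the retained coordinates. R² is binned, after rounding to one
   decimal, as insignificant/very weak (0.0–0.3), weak/moderate
   (0.4–0.6) or strong/very strong (0.7–1.0).
4. **Sensitivity.** The comparison is repeated at progressively stricter
   cutoffs (10, 5, 2, 1%) to check that the exclusion threshold does not
   drive the result.

## What R² means here, and design choices that were genuinely open

R² is defined as the **squared Pearson correlation** of the two retained
percentage vectors. The source analysis reports a symmetric triangle of
"associations" between pairs of spectra, and squared Pearson correlation
is the only symmetric reading of an R² between two variables (it equals
the OLS coefficient of determination of either vector regressed on the
other). The test suite pins this to an independent least-squares oracle.

Two ambiguities had to be resolved:

* **Whose spectrum triggers an exclusion?** A type could be excluded
  using each entity's own spectrum only, or using the union over the
  pair. We exclude the **pairwise union**: characteristic translocations
  are entity properties (t(9;22) is characteristic *of CML*), but
  dropping a coordinate from one vector and not the other would misalign
  the comparison. Both readings leave the same coordinates in both
  vectors only under the union rule.
* **Renormalize after exclusion?** It does not matter, provably: R² is
  invariant under positive rescaling of either vector, so recomputing
  percentages over the retained types cannot change any R². The suite
  asserts this to 1e-12; exported tables carry raw percentages (a
  renormalized column is trivial to add downstream).

Smaller conventions: the strength bins are applied to R² rounded to one
decimal, because the printed bins (0.0–0.3 / 0.4–0.6 / 0.7–1.0) tile the
interval only on one-decimal values; the exclusion rule is strict
("more than 10%"), so a type at exactly 10.0% is retained; frequency
categories are 0%, (0, 1)%, [1, 10]% and (10, 100]%, which partition the
253 types exactly; and a pair whose retained vectors are degenerate
(zero variance) is reported as *not computable*, never as R² = 0 —
absence of evidence is not evidence of no association.

## The parser and its deliberate limits

Only the subset of ISCN needed for translocation extraction is
implemented: clones split on `/`, abnormality terms on commas,
translocation terms `t(a;b)(bands)` recognized wherever they stand.
Everything else (`+8`, `-7`, `inv`, `del`, `idem`, marker chromosomes,
the sex-chromosome constitution) is passed over silently. Every
translocation-like term that is *not* counted appears in a skip report
with a machine-readable reason: `three_or_more_way`, `homologous`,
`y_involved`, `unparseable` (e.g. `?` in a chromosome position — `?`
inside bands is tolerated since bands are discarded) or
`nested_in_derivative`.

The last reason encodes a substantive decision: a `t(...)` inside
`der(...)` or `ider(...)` describes an **unbalanced derivative**
chromosome, not a balanced reciprocal translocation, so it is not
counted by default. Whether the source database counts such events is
not documented; users who want the other convention set
`count_nested = TRUE` and the skip report makes the affected cases
auditable either way. Similarly, whether a translocation should count
once per case or once per clone is unstated upstream; we count **once
per case**, which matches the per-case structure of the input records,
and the deduplication makes `idem` shorthand safe to ignore.

## The synthetic cohort generator

No external database is needed to test any stage: the
`make_signature()` / `sample_cohort()` / `make_study()` generator
produces cohorts with known ground truth.

* An entity's signature is a probability vector over the 253 types drawn
  from a **symmetric Dirichlet** with concentration 0.05. At this
  concentration well over 80% of types fall below 1% probability,
  emulating the long tail of rare translocations that dominates real
  spectra, while a few types carry visible mass like recurrent
  translocations do.
* A characteristic translocation is emulated by a **spike**: a fixed
  probability mass (e.g. 0.6 on t(9;22)) folded into the vector, with
  the remainder rescaled.
* Per-case translocation counts follow a **zero-inflated Poisson**
  (p_zero = 0.3, λ = 1.2), so most cases carry 0–2 translocations —
  loosely matching cytogenetic reality; these are configuration values,
  not empirical claims.
* Each case's k types are drawn i.i.d. from the signature and
  **deduplicated within the case** (collisions redrawn, bounded at 100
  retries), keeping the generator consistent with the parser's
  once-per-case counting unit. Karyotypes are rendered as
  `46,XX,t(a;b)(q11;q22),...` with fixed placeholder bands (a
  `random_bands` option exists purely to exercise parser tolerance).
  Re-parsing the rendered strings reproduces the generator's emission
  log exactly — the round trip is asserted on 10 000 cases.

One consequence of within-case deduplication is worth knowing: the
*marginal* observed frequency of a strong spike is attenuated below its
nominal mass, because a case that draws the spike twice keeps it once
and redraws the duplicate. A 0.6-mass spike appears at roughly 42% of
observed translocations under the default per-case count distribution.
The exact, unattenuated property — asserted in the tests — is that among
cases carrying exactly one translocation, the spike's share estimates
its mass directly.

```{r example}
study <- make_study(4, shared_pairs = 1, seed = 5, n_cases = 1200)
spectra <- build_spectra(study_cases(study))
glance(spectra)
pairwise_comparisons(spectra) |>
  select(label_a, label_b, n_excluded, n_retained, r2, strength)
```

Entities E01 and E02 share a signature (sampled independently), the rest
are unrelated; the shared pair stands out by an order of magnitude.

## Problem sizes used in the checks

The test suite and the acceptance script choose cohort sizes to match
what each property needs scientifically:

* Distinguishability (same-signature R² ≥ 0.7 vs independent-signature
  R² ≤ 0.3, 20 seeded replicates) uses cohorts of 3 000 cases, about
  2 500 translocations each — the scale at which the concentrated part
  of a spectrum is well estimated.
* Cutoff sensitivity uses cohorts of 10 000 cases. The sensitivity
  question targets entities large enough that their sub-1% coordinates
  are measured rather than noise (the largest disease groups in real
  cytogenetic databases run to tens of thousands of cases). At much
  smaller cohorts the spread of R² across cutoffs is dominated by
  sampling noise in the rare types — an attenuation artifact, not a
  cutoff bias.
* The acceptance script simulates three comparison blocks of 12, 16 and
  11 cohorts (giving 66 + 120 + 55 = 241 pairwise comparisons) with
  sizes drawn from 400–3 000 cases, and a shared-signature "females vs
  males" pair of 11 000 cases each.

## What passing tests do and do not show

The generator emulates entity-specific multinomial sampling of
translocation types with a long rare tail, characteristic spikes,
unequal cohort sizes and sex labels. It does **not** emulate numerical
abnormalities, co-occurrence structure between aberrations, band-level
breakpoint distributions, clone evolution within cases, or the
correlated ascertainment biases of a literature-curated database. Green
tests therefore demonstrate that the pipeline's machinery is correct —
extraction rules, counting, exclusion, R², binning, determinism — and
that the comparison statistic behaves as designed on data with known
structure. They do not validate biological conclusions about any real
tumor entity; for that the pipeline must be run on real case records.

## Known limitations

* The parser covers the translocation-relevant subset of ISCN only; it
  is tolerant but not validating, and complex derivative resolution is
  out of scope by design.
* R² between sparse percentage vectors is driven by the best-measured
  coordinates; comparisons between small cohorts are noisy even when
  both pass the 100/100 inclusion filter.
* No significance testing or multiple-comparison correction is applied
  to the R² matrix, matching the descriptive character of the analysis.
* The ordering of the 253 types (autosome pairs lexicographically, then
  the X pairs) is this package's convention; any consistent ordering
  yields identical statistics.
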