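---
title: "Designing multifunctional vegetative-strip seed mixes from plant traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multifunctional vegetative-strip seed mixes from plant traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmix)
```

## The problem

Sown vegetative strips at arable field margins and along farmland
watercourses are one of the few levers a landowner has to support several
ecosystem services at once: buffering watercourses against sediment,
nitrate and phosphate runoff; feeding pollinators; and sheltering the
natural enemies of crop pests. Which services a strip actually supports is
determined by the plant species in the seed mix, and in practice those
species are chosen by habit and supplier catalogue rather than by any
transparent, repeatable procedure.

`seedmix` implements an evidence-informed, trait-based selection method for
temperate farmland. The premise is that a plant's *functional traits* — the
size of its floral display, the density of its leaf trichomes, its leaf
area, its root system, whether its leaves persist over winter — are what
link a species to the services it can support, while a small set of
*establishment factors* (life history, native status, regional
distribution, competitive strategy, soil suitability, flowering phenology)
determine whether the species will establish and persist in a sown strip at
all. Selection therefore proceeds in three steps, each of which is a
package module:

1. **Gate** (`filter_criteria()`, `filter_candidates()`) — binary
   establishment criteria every candidate must pass.
2. **Score and rank** (`default_rubric()`, `score_table()`,
   `rank_species()`) — ordinal trait rubrics whose totals order the
   candidates by their expected contribution to the target services.
3. **Assemble** (`select_candidates()`, `assemble_mix()`) — a cutoff plus
   explicitly logged expert overrides, growth-form composition, commercial
   availability substitution and flowering-coverage reporting.

## The gate

A species is considered at all only if it is **perennial** (strips along
watercourses should persist 5–10 years without resowing, so annuals are
unsuitable), **native** (to avoid introducing invasive non-natives), and
shows **good regional distribution** (so seed provenance is widely
applicable). Forbs are additionally required to show an indication of
**pollinator support**; grasses are not gated on this. Each criterion is
checked independently and the full verdict list is always reported — a
rejection report never hides a second failure behind the first.

Two design choices here were genuinely open:

* **Missing gate fields exclude conservatively.** A species whose life
  history or status is unrecorded is rejected with an `unknown` verdict,
  distinct from a definite `fail`. The alternative — letting unknowns
  through — would risk recommending species of unknown provenance, which
  defeats the purpose of the gate.
* **Biennials fail the perennial requirement.** Only the stated category
  passes; the method's justification (multi-year persistence without
  resowing) argues against biennials as much as annuals.

## The rubrics

Scoring is driven by *rubrics*: declarative, ordered lists of rules, each
mapping one raw trait value to a non-negative integer. Rubrics are data,
not code — the built-in profile `uk_lowland_2019` encodes the UK lowland
case study, and the soil rule can be re-targeted to a named soil profile
(`most_soils`, `heavy_clay`, `sandy_loam`, or any profile declared as a
`soil_<name>` column in the input table) without touching the engine.

```{r}
show_rubric(default_rubric("forb"))
show_rubric(default_rubric("grass"))
```

Units: floral display and height in mm, leaf area in mm²; associated
floristic diversity (AFD) is the mean number of co-occurring species in
survey quadrats, recorded at one-decimal resolution; CSR codes are Grime's
established strategies (C competitor, S stress-tolerator, R ruderal, plus
intermediates).

Three numerical conventions deserve explanation:

* **Soil weighting.** Soil suitability scores 0 or 5 while every other forb
  trait scores 0 or 1. The heavy weight is deliberate: a strip must
  establish across soil conditions that vary from farm to farm, so
  suitability for the target soil profile dominates the forb ranking. The
  weight is a single configurable multiplier (`soil_weight`), so the
  0-or-5 default can be relaxed.
* **Boundary conventions.** Where a scale is explicit about a boundary
  (`>=10`, `>=25`, `<=750`, `>=2000`, "10.0 or fewer") we follow it. The
  grass leaf-area classes print shared endpoints (15/20/25/30 mm²); we
  resolve them lower-closed (a value equal to an edge takes the higher
  class, so 15 scores 2 and 30 scores 5). The AFD bins are printed
  gap-free at one-decimal resolution (…14.0, 14.1…), which pins every
  boundary: a value equal to an upper edge stays in the lower bin. No
  case-study total depends on a shared-endpoint value, so the convention is
  documented and auditable (`show_rubric()`) rather than inferable from
  data. The full sweep of every rule against an independently coded
  piecewise oracle, including all printed boundaries, is part of the test
  suite.
* **Missing data.** Trait databases are incomplete; unavailable values
  appear as `"?"` in the CSV schema and as `NA` in R. A missing trait
  contributes the rule's **minimum** score (0; the lowest bin, 1, for the
  two graded grass rules) and the trait is flagged on the scorecard. The
  zero-contribution policy is the one consistent with the case-study
  tables: every published total for a species with unavailable data equals
  the sum of its known components alone. Unrecognized category labels, by
  contrast, are errors, never silent zeros — a typo must not quietly
  corrupt a ranking.

Under the default rubrics a forb total lies in [0, 10] and a grass total in
[2, 14] (the two graded grass rules floor at 1 each).

## Ranking, selection and overrides

Totals are ranked within each growth form. The published method does not
say how equal totals are ordered, so the package imposes a deterministic
tie-break — fewer missing traits first (a complete scorecard is more
trustworthy than an equal total achieved with unknowns), then botanical
name — making every ranking a reproducible permutation regardless of input
order.

The final cut in the case study mixes a score cutoff with expert judgement:
one early-flowering, slightly lower-scoring forb was included for its
phenology; two high scorers could not be sourced commercially; one
competitive grass was kept for its pollen value. `select_candidates()`
therefore takes a threshold (`min_total`), an optional `top_n`, and
explicit `include`/`exclude` overrides, and **logs every override with a
reason**. No numeric cutoff is hard-coded: `min_total = 6` reproduces the
case-study forb selection exactly and is shipped in the example
configuration, but it is a reconstruction — the published account
highlights the selected species without stating the threshold — so it
stays in config rather than in code.

## Mix assembly

`assemble_mix()` combines the selections under a forb:grass composition
ratio (default 20:80 by seed weight, the cost-driven standard practice; a
50:50 alternative is a built-in variant). The ratio is metadata on the mix
plus a validation that both growth forms are present — per-species sowing
rates are out of scope.

Commercial availability is handled by substitution: "a similar flowering
period" is operationalized as **month-set overlap** — the replacement is
the available, not-yet-used species from the ranked pool sharing the most
flowering months with the lost species, ties broken by rank; if nothing
overlaps, the highest-ranked available species filling the largest gap in
the remaining seasonal coverage is taken and flagged; an exhausted pool
drops the species with a warning. Every substitution is logged with the
shared months. Unavailable species are processed in rank order so the
outcome does not depend on input order.

Coverage is reported per month over the beneficial-invertebrate activity
season. The season is not fixed numerically by the method, so the package
defaults to **March–October** (a reasonable span for UK bees, hoverflies
and parasitoids) and makes it configurable. Months without a flowering
forb raise explicit warnings on the mix object.

The four built-in configurations (`builtin_mix_configs()`) cover the
case-study variants: general 20:80, general 50:50, heavy clay and sandy
loam. The soil variants differ only in which soil profile the forb
rubric's soil rule targets; the package reproduces them as procedure
(published species lists exist only for the general mix).

## The synthetic generator

`generate_species_table()` emulates a compiled national trait database so
every stage is testable without downloads: schema-valid records, trait
values sampled across the rubric bin domains, a configurable per-trait
missing-data rate, optional planted winners (forbs given maximal trait
values, with all other forbs capped strictly below the maximum) and
planted establishment-gate failures.

Defaults mirror the case study's scale: 20 forbs and 10 grasses against
the case study's 24 and 7, and a 5% missing rate against the roughly 4%
of forb rubric cells unavailable in the case-study table. All species pass
the gate by construction unless a failure is planted, so the generator's
manifest is an exact oracle for the filter as well as for scoring: it
records each species' expected component scores computed from its own
independently written if/else rule tables, which share no code with the
rubric engine. Identical seed and configuration give byte-identical
serialized tables; the generator restores the caller's RNG state.

What the generator does **not** emulate: trait covariances in real floras
(tall competitive grasses, evergreen rosette forbs), taxonomic structure,
or realistic flowering phenologies beyond contiguous spans within
March–October. Passing tests on synthetic tables therefore demonstrate
that the pipeline's logic is correct, not that the rubric's ecology
generalizes — the case-study fixtures are the ground truth for the latter.

## Validation scale and determinism

The test suite validates the engine against the packaged case-study
fixtures (all 24 forb and all 7 grass totals, bit-for-bit), sweeps every
graded rule over ~10,000 grid points per trait domain against an
independent piecewise oracle, checks the sum identity, range bounds and
generator-oracle agreement on 1,000 generated species at a fixed seed, and
confirms planted-winner recovery in 100 seeded runs of 100 species each.
These sizes keep the whole suite under a minute on one CPU while
exercising every boundary the scales print.

All randomness flows through explicit seeds; pipelines re-run from their
written effective configuration reproduce their artifacts byte for byte
(timestamps appear only in logs, never in outputs).

## Known limitations

* The rubric is the fixed output of an evidence synthesis; the package
  applies it but cannot re-derive which traits matter, nor extend it to
  services (drought or flood tolerance) the synthesis did not cover.
* "Good regional distribution" is consumed as a pre-computed boolean; the
  qualitative judgement behind it (atlas hectad maps) is upstream of this
  tool.
* Scores are ordinal and additive: the method deliberately avoids
  multivariate or interaction effects between traits, and the package
  follows it.
* Seed-weight fractions are labels, not sowing-rate calculations.
* Establishment outcomes (whether the designed community actually
  establishes in the field) are outside the package's scope.
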