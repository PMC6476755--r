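# seedmix

Trait-based design of seed mixes for multifunctional farmland vegetative
strips.

Vegetative strips — sown field margins and watercourse buffers — can
support water quality protection, pollinators and crop-pest natural
enemies at the same time, but only if the right plant species are sown.
`seedmix` turns species selection from catalogue habit into a transparent,
repeatable procedure for temperate lowland farmland:

1. **Gate.** Every candidate must be perennial, native and well
   distributed regionally; forbs must additionally show support for
   pollinators. Unknown gate fields exclude conservatively.
2. **Score.** Survivors are scored against declarative ordinal rubrics.
   For a species *s* with traits *x₁…xₖ*, the overall rank is the weighted
   sum of per-trait rubric scores

   *Rₛ = Σₜ wₜ · rₜ(xₜₛ)*

   where each *rₜ* is a published 0/1 rule (forbs: floral display ≥ 10 mm,
   numerous trichomes, leaf area ≥ 25 mm², adventitious root, evergreen
   leaves) or a graded bin scale (grasses: leaf-area class 1–5, Grime CSR
   strategy 0/1, maximum-height class 0–3, associated floristic diversity
   class 1–5), and the forb soil-suitability rule is heavily weighted
   (*w* = 5). Missing trait data (`"?"` in the CSV schema) contributes the
   rule minimum and is flagged, never silently imputed.
3. **Rank and assemble.** Deterministic ranking (ties: fewer missing
   traits, then name), a configurable selection cutoff with logged
   include/exclude overrides, growth-form composition (default 20% forbs /
   80% grasses), substitution of commercially unavailable species by
   flowering-period overlap, and a per-month flowering coverage report
   over the activity season (default March–October).

The packaged case-study fixtures are the UK lowland candidate lists (24
forbs, 7 grasses); scoring them reproduces the published rank totals
exactly. A seeded synthetic-table generator with an independent scoring
oracle makes every stage testable at any scale.

## Worked example

Score, rank and cut the packaged forb list:

```r
library(seedmix)

forbs  <- case_study_fixture("table5_forbs")
cards  <- score_table(forbs, default_rubric("forb"))
ranked <- rank_species(cards)
head(as.data.frame(ranked[, c("rank", "botanical_name", "floral_display",
                              "trichome_density", "leaf_area", "root_system",
                              "leaf_phenology", "soil", "total")]), 7)
```

```
  rank            botanical_name floral_display trichome_density leaf_area
1    1        Trifolium pratense              1                1         1
2    2          Trifolium repens              1                0         1
3    3           Centaurea nigra              1                1         1
4    4      Leucanthemum vulgare              1                0         0
5    5         Stachys sylvatica              1                1         1
6    6 Taraxacum officinale agg.              1                0         1
7    7         Prunella vulgaris              0                1         1
  root_system leaf_phenology soil total
1           0              1    5     9
2           1              1    5     9
3           0              0    5     8
4           1              1    5     8
5           0              0    5     8
6           0              1    5     8
7           0              1    5     8
```

Each component column is one rubric rule (1 point per favourable trait,
0/5 for soil suitability); `total` is their sum, the species' overall
rank score. Red clover (*Trifolium pratense*) tops the list at 9 of 10:
every trait favourable except its tap-root, plus the 5-point soil score.
Selfheal (*Prunella vulgaris*) reaches 8 with a flagged unknown root
system contributing 0.

Assemble the general-purpose mix — score-6 cutoff, the early-flowering
primrose included by override, unavailable species substituted:

```r
grasses <- case_study_fixture("table4_grasses")
rg  <- rank_species(score_table(grasses, default_rubric("grass")))
sel <- select_candidates(ranked, min_total = 6, include = "Primula vulgaris")
mix <- assemble_mix(sel$selected, rg, rbind(forbs, grasses),
                    forb_fraction = 0.2, ranked_forb_pool = ranked,
                    ranked_grass_pool = rg, name = "general_20_80")
mix$substitutions
```

```
# A tibble: 2 × 4
  unavailable       substitute            shared_months note
  <chr>             <chr>                 <chr>         <chr>
1 Prunella vulgaris Hypochaeris radicata  6;7;8;9       flowering-period match
2 Galium verum      Heracleum sphondylium 6;7;8;9       flowering-period match
```

The two forbs that cannot be sourced from seed companies are replaced by
the best-ranked available species sharing their June–September flowering
window; `print(mix)` lists the final 14 forbs and 7 grasses with reasons,
and reports 100% flowering coverage of March–October (primrose covers the
early months).

The same pipeline runs end to end from a YAML config
(`inst/extdata/example_config.yaml`) via `run_pipeline()`, or from the
shell:

```sh
Rscript inst/cli/seedmix.R mix --input species.csv --min-total 6 \
    --include "Primula vulgaris" --out out/
Rscript inst/cli/seedmix.R show-rubric --growth-form grass
Rscript inst/cli/seedmix.R synth --out synthetic.csv --seed 7
```

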