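# Rubric rules and the scoring engine.

test_that("forb binary rules score at their published boundaries", {
  expect_equal(score_floral_display(c(9.9, 10, 12, NA)), c(0, 1, 1, 0))
  expect_error(score_floral_display(-1), "below valid minimum")
  expect_equal(score_trichome_density(c("sparse", "numerous", NA)), c(0, 1, 0))
  expect_error(score_trichome_density("fuzzy"), "unrecognized label")
  expect_equal(score_leaf_area_forb(c(24.9, 25, 30, NA)), c(0, 1, 1, 0))
  expect_equal(score_root_system(c("tap-root", "adventitious", NA)),
               c(0, 1, 0))
  expect_equal(score_leaf_phenology(c("estival", "evergreen", NA)), c(0, 1, 0))
})

test_that("soil suitability is weighted 0-or-5 and re-targetable", {
  rec <- make_record(soil_most_soils = TRUE, soil_sandy_loam = FALSE)
  expect_equal(score_soil(rec, "most_soils"), 5)
  expect_equal(score_soil(rec, "sandy_loam"), 0)
  expect_equal(score_soil(make_record(soil_most_soils = NA), "most_soils"), 0)
  expect_equal(score_soil(rec, "most_soils", weight = 3), 3)
  expect_error(score_soil(rec, "chalk"), "config error.*chalk")
})

test_that("grass binned rules score at their published boundaries", {
  expect_equal(score_leaf_area_class_grass(c(14, 15, 19.9, 20, 22, 25, 29,
                                             30, 35, NA)),
               c(1, 2, 2, 3, 3, 4, 4, 5, 5, 1))
  expect_equal(score_established_strategy(c("C", "SC", "CR", "CSR", "R", "S",
                                            "SR", NA)),
               c(0, 0, 0, 1, 1, 1, 1, 0))
  expect_error(score_established_strategy("X"), "unrecognized label")
  expect_equal(score_height_grass(c(600, 750, 751, 1499, 1500, 1999, 2000,
                                    2500, NA)),
               c(3, 3, 2, 2, 1, 1, 0, 0, 0))
  expect_error(score_height_grass(0), "outside the valid domain")
  expect_equal(score_afd_grass(c(9.5, 10, 10.1, 14, 14.1, 18, 18.1, 22, 22.1,
                                 NA)),
               c(1, 1, 2, 2, 3, 3, 4, 4, 5, 1))
  expect_error(score_afd_grass(-1), "outside the valid domain")
})

test_that("score_species produces components, flags and a summed total", {
  f <- case_study_fixture("table5_forbs")
  tp <- score_species(f[f$botanical_name == "Trifolium pratense", ],
                      default_rubric("forb"))
  expect_equal(unlist(tp[, c("floral_display", "trichome_density",
                             "leaf_area", "root_system", "leaf_phenology",
                             "soil")]),
               c(floral_display = 1, trichome_density = 1, leaf_area = 1,
                 root_system = 0, leaf_phenology = 1, soil = 5))
  expect_equal(tp$total, 9)
  expect_length(tp$missing_traits[[1]], 0)

  g <- case_study_fixture("table4_grasses")
  ac <- score_species(g[g$botanical_name == "Agrostis capillaris", ],
                      default_rubric("grass"))
  expect_equal(unlist(ac[, c("leaf_area_class", "established_strategy",
                             "height", "associated_floristic_diversity")]),
               c(leaf_area_class = 5, established_strategy = 1, height = 3,
                 associated_floristic_diversity = 2))
  expect_equal(ac$total, 11)
})

test_that("missing traits contribute the rule minimum and are flagged", {
  all_na_forb <- make_record(
    floral_display_mm = NA, trichome_density = NA_character_,
    leaf_area_mm2 = NA, root_system = NA_character_,
    leaf_phenology = NA_character_, soil_most_soils = NA)
  card <- score_species(all_na_forb, default_rubric("forb"))
  expect_equal(card$total, 0)
  expect_length(card$missing_traits[[1]], 6)

  all_na_grass <- make_record(
    growth_form = "grass", root_system = NA_character_,
    leaf_area_mm2 = NA, established_strategy = NA_character_,
    max_height_mm = NA, associated_floristic_diversity = NA)
  card <- score_species(all_na_grass, default_rubric("grass"))
  expect_equal(card$total, 2)  # two graded rules floor at their lowest bin
  expect_length(card$missing_traits[[1]], 4)
})

test_that("totals equal the sum of components on fixtures and synthetic data", {
  check_sum <- function(cards) {
    comp_cols <- setdiff(names(cards), c("botanical_name", "growth_form",
                                         "missing_traits", "total"))
    expect_equal(rowSums(as.matrix(cards[, comp_cols])), cards$total,
                 ignore_attr = TRUE)
  }
  check_sum(score_table(case_study_fixture("table5_forbs"),
                        default_rubric("forb")))
  check_sum(score_table(case_study_fixture("table4_grasses"),
                        default_rubric("grass")))
  gen <- generate_species_table(n_forbs = 40, n_grasses = 20,
                                missing_rate = 0.15, seed = 3)
  check_sum(score_table(gen$records[gen$records$growth_form == "forb", ],
                        default_rubric("forb")))
  check_sum(score_table(gen$records[gen$records$growth_form == "grass", ],
                        default_rubric("grass")))
})

test_that("improving a trait never decreases the total", {
  set.seed(21)
  rubric_f <- default_rubric("forb")
  rubric_g <- default_rubric("grass")
  for (i in 1:50) {
    base_floral <- runif(1, 0, 25)
    rec <- make_record(floral_display_mm = base_floral,
                       leaf_area_mm2 = runif(1, 5, 40))
    better <- rec
    better$floral_display_mm <- base_floral + runif(1, 0, 20)
    better$leaf_area_mm2 <- rec$leaf_area_mm2 + runif(1, 0, 20)
    expect_gte(score_species(better, rubric_f)$total,
               score_species(rec, rubric_f)$total)

    h <- runif(1, 200, 2400)
    grec <- make_record(growth_form = "grass", root_system = "adventitious",
                        max_height_mm = h,
                        associated_floristic_diversity = round(runif(1, 4, 25), 1))
    gbetter <- grec
    gbetter$max_height_mm <- runif(1, 100, h)
    gbetter$associated_floristic_diversity <-
      grec$associated_floristic_diversity + round(runif(1, 0, 10), 1)
    expect_gte(score_species(gbetter, rubric_g)$total,
               score_species(grec, rubric_g)$total)
  }
})

test_that("scoring errors identify the species and trait", {
  rec <- make_record("Errans exempli", trichome_density = "woolly")
  expect_error(score_species(rec, default_rubric("forb")),
               "Errans exempli.*trichome_density")
  expect_error(score_species(make_record(growth_form = "grass"),
                             default_rubric("forb")),
               "grass.*rubric targets forb")
})

test_that("show_rubric tabulates every rule with its boundary convention", {
  tf <- show_rubric(default_rubric("forb"))
  expect_equal(nrow(tf), 6)
  tg <- show_rubric(default_rubric("grass"))
  expect_equal(nrow(tg), 4)
  expect_match(tg$scale[tg$trait == "height"], "<=750")
  expect_match(tf$scale[tf$trait == "floral_display"], ">=10")
})
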