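# Seed mix assembly, substitution and flowering coverage.

case_mix_inputs <- function(min_total = 6, include = "Primula vulgaris") {
  forbs <- case_study_fixture("table5_forbs")
  grasses <- case_study_fixture("table4_grasses")
  records <- rbind(forbs, grasses)
  rf <- rank_species(score_table(forbs, default_rubric("forb")))
  rg <- rank_species(score_table(grasses, default_rubric("grass")))
  sel <- select_candidates(rf, min_total = min_total, include = include)
  list(records = records, ranked_forbs = rf, ranked_grasses = rg,
       selected_forbs = sel$selected)
}

test_that("composition fractions label the mix and must be a proper ratio", {
  x <- case_mix_inputs()
  mix <- assemble_mix(x$selected_forbs, x$ranked_grasses, x$records,
                      forb_fraction = 0.2, ranked_forb_pool = x$ranked_forbs,
                      ranked_grass_pool = x$ranked_grasses)
  expect_equal(mix$forb_fraction + mix$grass_fraction, 1)
  alt <- assemble_mix(x$selected_forbs, x$ranked_grasses, x$records,
                      forb_fraction = 0.5, ranked_forb_pool = x$ranked_forbs,
                      ranked_grass_pool = x$ranked_grasses)
  expect_equal(alt$forb_fraction, 0.5)
  expect_equal(alt$species, mix$species)  # ratio is metadata, not selection
  expect_error(assemble_mix(x$selected_forbs, x$ranked_grasses, x$records,
                            forb_fraction = 1), "between 0 and 1")
  expect_error(assemble_mix(x$selected_forbs, x$ranked_grasses[0, ],
                            x$records), "no grasses")
  expect_error(assemble_mix(x$selected_forbs[0, ], x$ranked_grasses,
                            x$records), "no forbs")
})

test_that("unavailable species are substituted by flowering-period overlap", {
  x <- case_mix_inputs()
  sub <- substitute_unavailable(x$selected_forbs, x$ranked_forbs, x$records)
  expect_setequal(sub$substitutions$unavailable,
                  c("Galium verum", "Prunella vulgaris"))
  expect_false(any(is.na(sub$substitutions$substitute)))
  expect_true(all(nzchar(sub$substitutions$shared_months)))
  # substitutes are available, lower-ranked species
  for (i in seq_len(nrow(sub$substitutions))) {
    s <- sub$substitutions[i, ]
    rec <- x$records[x$records$botanical_name == s$substitute, ]
    expect_true(rec$commercially_available)
    lost_rank <- x$ranked_forbs$rank[x$ranked_forbs$botanical_name ==
                                       s$unavailable]
    sub_rank <- x$ranked_forbs$rank[x$ranked_forbs$botanical_name ==
                                      s$substitute]
    expect_gt(sub_rank, lost_rank)
  }
  expect_false(any(c("Galium verum", "Prunella vulgaris") %in%
                     sub$final$botanical_name))
})

test_that("substitution is the identity when everything is available", {
  x <- case_mix_inputs()
  avail <- x$records
  avail$commercially_available <- TRUE
  sub <- substitute_unavailable(x$selected_forbs, x$ranked_forbs, avail)
  expect_equal(nrow(sub$substitutions), 0)
  expect_setequal(sub$final$botanical_name,
                  x$selected_forbs$botanical_name)
})

test_that("an exhausted pool drops the species with a warning", {
  rec <- make_record("Sola species", commercially_available = FALSE)
  card <- score_species(rec, default_rubric("forb"))
  ranked <- rank_species(card)
  expect_warning(sub <- substitute_unavailable(ranked, ranked, rec),
                 "no available substitute")
  expect_equal(nrow(sub$final), 0)
  expect_true(is.na(sub$substitutions$substitute))
})

test_that("coverage is computed per month with warnings for gaps", {
  june_forb <- make_record("Aestas brevis", flowering_months = 6:7)
  grass <- make_record("Gramen unum", growth_form = "grass",
                       root_system = "adventitious")
  records <- rbind(june_forb, grass)
  cards_f <- score_table(june_forb, default_rubric("forb"))
  cards_g <- score_table(grass, default_rubric("grass"))
  mix <- assemble_mix(cards_f, cards_g, records, season = 3:10)
  expect_equal(mix$coverage$covered, c(FALSE, FALSE, FALSE, TRUE, TRUE,
                                       FALSE, FALSE, FALSE))
  expect_length(mix$warnings, 6)
  expect_equal(mix$coverage_fraction, 2 / 8)

  rep_full <- coverage_report(mix, season = 6:7)
  expect_equal(rep_full$fraction_covered, 1)
})

test_that("an early-flowering include covers the early season", {
  x <- case_mix_inputs()
  mix <- assemble_mix(x$selected_forbs, x$ranked_grasses, x$records,
                      ranked_forb_pool = x$ranked_forbs,
                      ranked_grass_pool = x$ranked_grasses)
  cov <- coverage_report(mix)
  expect_equal(cov$fraction_covered, 1)
  march <- cov$months[cov$months$month == 3, ]
  expect_match(march$species, "Primula vulgaris")
  # without the early-flowering override, March-April hinge on fewer species
  sel_no_primula <- case_mix_inputs(include = character(0))
  mix2 <- assemble_mix(sel_no_primula$selected_forbs, x$ranked_grasses,
                       x$records, ranked_forb_pool = x$ranked_forbs,
                       ranked_grass_pool = x$ranked_grasses)
  march2 <- coverage_report(mix2)$months
  expect_false(grepl("Primula", march2$species[march2$month == 3]))
})

test_that("assembly is invariant to input list order and adding forbs never
           shrinks coverage", {
  x <- case_mix_inputs()
  set.seed(4)
  shuffled <- x$selected_forbs[sample(nrow(x$selected_forbs)), ]
  m1 <- assemble_mix(x$selected_forbs, x$ranked_grasses, x$records,
                     ranked_forb_pool = x$ranked_forbs,
                     ranked_grass_pool = x$ranked_grasses)
  m2 <- assemble_mix(shuffled, x$ranked_grasses[sample(7), ], x$records,
                     ranked_forb_pool = x$ranked_forbs,
                     ranked_grass_pool = x$ranked_grasses)
  expect_equal(m1$species, m2$species)
  expect_equal(m1$coverage, m2$coverage)

  # coverage fraction is monotone in the forb set
  fewer <- assemble_mix(x$selected_forbs[1:3, ], x$ranked_grasses, x$records,
                        ranked_forb_pool = x$ranked_forbs,
                        ranked_grass_pool = x$ranked_grasses)
  expect_lte(fewer$coverage_fraction, m1$coverage_fraction)
})

test_that("seed mix JSON export round-trips the key fields", {
  x <- case_mix_inputs()
  mix <- assemble_mix(x$selected_forbs, x$ranked_grasses, x$records,
                      ranked_forb_pool = x$ranked_forbs,
                      ranked_grass_pool = x$ranked_grasses,
                      name = "general_20_80")
  path <- withr::local_tempfile(fileext = ".json")
  seed_mix_to_json(mix, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$name, "general_20_80")
  expect_equal(parsed$forb_fraction, 0.2)
  expect_equal(length(parsed$species),
               nrow(mix$species))
})

test_that("the built-in configurations cover the four case-study variants", {
  cfgs <- builtin_mix_configs()
  expect_setequal(names(cfgs), c("general_20_80", "general_50_50",
                                 "heavy_clay", "sandy_loam"))
  expect_equal(cfgs$general_50_50$mix$forb_fraction, 0.5)
  expect_equal(cfgs$sandy_loam$rubric$soil_profile, "sandy_loam")
})
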