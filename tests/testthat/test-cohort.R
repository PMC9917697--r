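test_that("generation is deterministic and prefix-stable in n", {
  a <- generate_cohort(n_patients = 60, seed = 123)
  b <- generate_cohort(n_patients = 60, seed = 123)
  expect_identical(a, b)
  longer <- generate_cohort(n_patients = 90, seed = 123)
  expect_identical(longer[1:60, ], a)
  other <- generate_cohort(n_patients = 60, seed = 124)
  expect_false(identical(a, other))
})

test_that("an empty cohort and invalid configs are handled explicitly", {
  e <- generate_cohort(n_patients = 0, seed = 1)
  expect_s3_class(e, "data.frame")
  expect_identical(nrow(e), 0L)
  cfg <- default_cohort_config()
  cfg$etiology_mix[1] <- cfg$etiology_mix[1] + 0.1
  expect_error(generate_cohort(cfg, n_patients = 5), "sum to 1")
  cfg2 <- default_cohort_config()
  cfg2$feature_freqs$other$ruptured_chordae <- 1.4
  expect_error(generate_cohort(cfg2, n_patients = 5), "\\[0, 1\\]")
  cfg3 <- default_cohort_config()
  cfg3$n_patients <- -2
  expect_error(generate_cohort(cfg3), "non-negative")
})

test_that("every generated record satisfies the patient invariants", {
  co <- generate_cohort(n_patients = 300, seed = 9)
  expect_identical(nrow(co), 300L)
  for (i in seq_len(nrow(co))) {
    f <- do.call(echo_features,
                 as.list(co[i, c("prolapse_p1", "prolapse_p2", "prolapse_p3",
                                 "prolapse_a1", "prolapse_a2", "prolapse_a3",
                                 "prolapse_anterolateral_commissure",
                                 "prolapse_posteromedial_commissure",
                                 "ruptured_chordae", "leaflet_morphology",
                                 "calc_leaflet", "calc_annulus",
                                 "calc_chordae", "commissure_fusion",
                                 "vegetation_class",
                                 "perforation_cleft_class",
                                 "leaflet_motion")]))
    b <- complexity_score(f)
    expect_identical(co$complexity_score[i], b$total)
    expect_identical(co$stratum[i],
                     as.character(suppressWarnings(assign_stratum(b$total))))
  }
  expect_true(all(co$approach %in% c("repair", "replacement")))
  expect_false(any(co$adverse_event[co$approach == "replacement"]))
  expect_true(all(is.na(co$technique_score[co$approach == "replacement"])))
  expect_true(all(!is.na(co$technique_score[co$approach == "repair"])))
})

test_that("sampled feature frequencies match their configured parameters", {
  cfg <- default_cohort_config()
  co <- generate_cohort(cfg, n_patients = 50000, seed = 2024)
  mix <- table(co$diagnosis)[names(cfg$etiology_mix)]
  expect_equal(as.numeric(mix) / nrow(co), unname(cfg$etiology_mix),
               tolerance = 0.02)
  within_4se <- function(emp, p, m) {
    se <- sqrt(p * (1 - p) / m)
    abs(emp - p) <= 4 * se + 1e-12
  }
  for (et in names(cfg$feature_freqs)) {
    sub <- co[co$diagnosis == et, ]
    m <- nrow(sub)
    ff <- cfg$feature_freqs[[et]]
    for (fl in names(ff$prolapse)) {
      expect_true(within_4se(mean(sub[[fl]]), ff$prolapse[[fl]], m),
                  label = paste(et, fl))
    }
    expect_true(within_4se(mean(sub$ruptured_chordae),
                           ff$ruptured_chordae, m))
    expect_true(within_4se(mean(sub$commissure_fusion),
                           ff$commissure_fusion, m))
    for (site in names(ff$calc)) {
      expect_true(within_4se(mean(sub[[paste0("calc_", site)]]),
                             ff$calc[[site]], m), label = paste(et, site))
    }
    for (lv in names(ff$morphology)) {
      expect_true(within_4se(mean(sub$leaflet_morphology == lv),
                             ff$morphology[[lv]], m), label = paste(et, lv))
    }
    for (lv in names(ff$motion)) {
      expect_true(within_4se(mean(sub$leaflet_motion == lv),
                             ff$motion[[lv]], m), label = paste(et, lv))
    }
    for (lv in names(ff$vegetation)) {
      expect_true(within_4se(mean(sub$vegetation_class == as.integer(lv)),
                             ff$vegetation[[lv]], m), label = paste(et, lv))
    }
    for (lv in names(ff$perforation_cleft)) {
      expect_true(
        within_4se(mean(sub$perforation_cleft_class == as.integer(lv)),
                   ff$perforation_cleft[[lv]], m), label = paste(et, lv))
    }
  }
  # atrial regurgitation concentrates in low-score profiles
  amr <- co$diagnosis == "atrial_mitral_regurgitation"
  expect_gt(sum(amr), 0)
  expect_true(mean(co$stratum[amr] == "simple") > 0.9)
})

test_that("cohort config files merge over the calibrated defaults", {
  path <- system.file("extdata", "example_cohort_config.yaml",
                      package = "mvscore")
  cfg <- load_cohort_config(path)
  expect_identical(cfg$n_patients, 500L)
  expect_equal(unname(cfg$etiology_mix[["rheumatic_heart_disease"]]), 0.45)
  expect_equal(
    unname(cfg$feature_freqs$rheumatic_heart_disease$calc[["chordae"]]),
    0.9)
  # untouched groups keep their defaults
  expect_identical(cfg$feature_freqs$barlows_syndrome,
                   default_cohort_config()$feature_freqs$barlows_syndrome)
  expect_identical(cfg$outcome_link, default_cohort_config()$outcome_link)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("cohort_size: 10", bad)
  expect_error(load_cohort_config(bad), "unknown cohort config key")
  # weight files load from the shipped defaults too
  w <- load_weights(system.file("extdata", "default_weights.yaml",
                                package = "mvscore"))
  expect_identical(w[names(w) != "pooled_lesion_variant"],
                   default_weights()[names(w) != "pooled_lesion_variant"])
})

test_that("replacement probability rises monotonically with the score", {
  co <- generate_cohort(n_patients = 8000, seed = 31)
  p_hi <- mean(co$approach[co$complexity_score >= 9] == "replacement")
  p_lo <- mean(co$approach[co$complexity_score <= 4] == "replacement")
  expect_gt(p_hi - p_lo, 0.2)
})

test_that("cohort summary equals a brute-force recount", {
  co <- generate_cohort(n_patients = 50, seed = 77)
  s <- cohort_summary(co)
  for (st in c("simple", "intermediate", "complex")) {
    expect_identical(s$stratum_counts$n[s$stratum_counts$stratum == st],
                     sum(co$stratum == st))
  }
  expect_equal(s$stratum_counts$pct,
               round(100 * s$stratum_counts$n / 50, 1))
  for (et in unique(co$diagnosis)) {
    for (st in c("simple", "intermediate", "complex")) {
      expect_identical(as.integer(s$etiology_by_stratum[et, st]),
                       sum(co$diagnosis == et & co$stratum == st))
    }
  }
  for (ap in c("repair", "replacement")) {
    for (st in c("simple", "intermediate", "complex")) {
      expect_identical(as.integer(s$approach_by_stratum[ap, st]),
                       sum(co$approach == ap & co$stratum == st))
    }
  }
})

test_that("summary percentages handle the boundary cases", {
  one <- cohort_summary(data.frame(stratum = "intermediate"))
  expect_equal(
    one$stratum_counts$pct[one$stratum_counts$stratum == "intermediate"],
    100.0)
  expect_error(cohort_summary(data.frame(stratum = character(0))),
               "empty cohort")
})
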