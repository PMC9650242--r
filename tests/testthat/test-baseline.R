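pipeline_flags <- function(store, day_range = c(-1L, 1L)) {
  run_pipeline(store, day_range = day_range)$sepsis
}

test_that("each baseline criterion fires independently", {
  # 1: admission-form flag
  adm <- adm_row("b1")
  store <- mini_store(adm, listitems = list_row("b1", "Sepsis at admission"))
  expect_true(baseline_sepsis_at_admission(store, "b1", pipeline_flags(store)))

  # 2: severe-infection admission diagnosis (case-insensitive)
  store <- mini_store(adm, listitems = list_row("b1", "Admission diagnosis",
                                                value = "Cholangitis"))
  expect_true(baseline_sepsis_at_admission(store, "b1", pipeline_flags(store)))
  store <- mini_store(adm, listitems = list_row("b1", "Admission diagnosis",
                                                value = "elective cardiac surgery"))
  expect_false(baseline_sepsis_at_admission(store, "b1", pipeline_flags(store)))

  # 4: antibiotics and culture drawn within 6 h of admission
  store <- mini_store(adm,
                      drugitems = drug_row("b1", "Ceftriaxone", day = 0,
                                           offset = 2 * 3600000),
                      listitems = list_row("b1", "Blood culture",
                                           offset = 5 * 3600000))
  expect_true(baseline_sepsis_at_admission(store, "b1", pipeline_flags(store)))
  # culture outside the window does not count
  store <- mini_store(adm,
                      drugitems = drug_row("b1", "Ceftriaxone", day = 0,
                                           offset = 2 * 3600000),
                      listitems = list_row("b1", "Blood culture",
                                           offset = 8 * 3600000))
  expect_false(baseline_sepsis_at_admission(store, "b1", pipeline_flags(store)))

  # no flags, clean diagnosis, no antibiotics
  store <- mini_store(adm)
  expect_false(baseline_sepsis_at_admission(store, "b1", pipeline_flags(store)))
})

test_that("criterion 3 reuses the pipeline's prophylaxis classification", {
  # urgent surgical admission, antibiotics at day 0, not prophylactic
  adm <- adm_row("s1", urgency = TRUE, surgical = TRUE)
  store <- mini_store(adm, drugitems = drug_row("s1", "Ceftriaxone", day = 0,
                                                offset = 10 * 3600000))
  expect_true(baseline_sepsis_at_admission(store, "s1", pipeline_flags(store)))

  # elective surgical admission: the same administration is perioperative
  # prophylaxis, so the criterion does not fire
  adm2 <- adm_row("s2", urgency = FALSE, surgical = TRUE)
  store2 <- mini_store(adm2, drugitems = drug_row("s2", "Cefazolin", day = 0,
                                                  offset = 10 * 3600000))
  expect_false(baseline_sepsis_at_admission(store2, "s2", pipeline_flags(store2)))
})

test_that("sepsis3_at_admission looks only at the windows adjacent to admission", {
  flags <- tibble::tibble(
    admissionid = rep("x", 3), day = c(-1L, 0L, 3L),
    sepsis_episode = c(TRUE, FALSE, FALSE))
  expect_true(sepsis3_at_admission(flags, "x"))
  flags$sepsis_episode <- c(FALSE, FALSE, TRUE)
  expect_false(sepsis3_at_admission(flags, "x"))
  flags$sepsis_episode <- FALSE
  expect_false(sepsis3_at_admission(flags, "x"))
})

test_that("confusion matrix counts, sensitivity and degenerate cases", {
  pairs <- tibble::tibble(sepsis3 = c(TRUE, TRUE, FALSE),
                          baseline = c(TRUE, FALSE, FALSE))
  cm <- confusion_matrix(pairs)
  expect_equal(unlist(cm$matrix), c(tt = 1, tf = 1, ft = 0, ff = 1))
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$n, 3)

  # permutation invariance
  set.seed(9)
  cm2 <- confusion_matrix(pairs[sample(3), ])
  expect_equal(cm2$matrix, cm$matrix)

  all_ff <- tibble::tibble(sepsis3 = rep(FALSE, 4), baseline = FALSE)
  expect_true(is.nan(confusion_matrix(all_ff)$sensitivity))
  expect_error(confusion_matrix(pairs[0, ]), "empty")
})

test_that("matched and anti-matched synthetic cohorts hit the extremes", {
  dir <- withr::local_tempdir()
  spec <- random_scenario(60, seed = 314, baseline_mode = "matched")
  gen <- generate_cohort(spec, file.path(dir, "m"))
  store <- read_tables(gen$paths)
  flags <- run_pipeline(store, day_range = spec$day_range)$sepsis
  cmp <- compare_definitions(store, flags)
  expect_equal(cmp$n, 60)
  expect_gt(cmp$matrix$tt, 0)  # the cohort does contain sepsis admissions
  expect_equal(cmp$sensitivity, 1)
  expect_equal(cmp$specificity, 1)

  spec_a <- random_scenario(60, seed = 314, baseline_mode = "anti")
  gen_a <- generate_cohort(spec_a, file.path(dir, "a"))
  store_a <- read_tables(gen_a$paths)
  flags_a <- run_pipeline(store_a, day_range = spec_a$day_range)$sepsis
  cmp_a <- compare_definitions(store_a, flags_a)
  expect_equal(cmp_a$sensitivity, 0)

  # counts equal an independent per-admission recount
  recount <- table(factor(paste(cmp$pairs$sepsis3, cmp$pairs$baseline),
                          levels = c("TRUE TRUE", "TRUE FALSE",
                                     "FALSE TRUE", "FALSE FALSE")))
  expect_equal(unname(unlist(cm <- cmp$matrix)), as.vector(recount))
})
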