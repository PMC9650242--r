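range25 <- c(-2L, 5L)

test_that("the acute SOFA-rise rule checks the three pairwise differences", {
  expect_true(delta_rule(c("-2" = 0, "-1" = 1, "0" = 6), -1L, c(-2L, 0L)))
  expect_false(delta_rule(c("0" = 5, "1" = 5, "2" = 5), 1L, c(0L, 2L)))
  expect_true(delta_rule(c("0" = 0, "1" = 2), 1L, c(0L, 1L)))  # no d+1 window
  # days in range but unscored count as zero
  expect_true(delta_rule(c("0" = 3), 0L, c(-1L, 0L)))
  # comparisons outside the range are skipped
  expect_false(delta_rule(c("0" = 3), 0L, c(0L, 0L)))
})

test_that("the delta rule agrees with brute force on integer triples", {
  set.seed(23)
  grid <- expand.grid(a = 0:24, b = 0:24, c = 0:24)
  pick <- grid[sample(nrow(grid), 800), ]
  for (i in seq_len(nrow(pick))) {
    S <- c("-1" = pick$a[i], "0" = pick$b[i], "1" = pick$c[i])
    expect_identical(delta_rule(S, 0L, c(-1L, 1L)),
                     oracle_delta(pick$a[i], pick$b[i], pick$c[i]))
  }
})

make_flag_store <- function(...) {
  mini_store(...)
}

test_that("sepsis needs escalation, no prophylaxis and an acute SOFA rise", {
  # urgent admission: escalation at day 0 with a 0 -> 4 rise => sepsis
  adm <- adm_row("u1", urgency = TRUE, surgical = FALSE)
  num <- dplyr::bind_rows(
    num_row("u1", "Platelets", 250, day = -1),
    num_row("u1", "Platelets", 40, day = 0),    # coag 3
    num_row("u1", "ABP mean", 60, day = 0),     # cardio 1
    num_row("u1", "GCS total", 15, day = 0),
    num_row("u1", "Creatinine", 80, day = 0))
  drg <- drug_row("u1", "Ceftriaxone", day = 0)
  store <- make_flag_store(adm, numericitems = num, drugitems = drg)
  out <- run_pipeline(store, day_range = c(-1L, 1L))
  d0 <- out$sepsis[out$sepsis$day == 0L, ]
  expect_true(d0$escalation)
  expect_false(d0$prophylaxis)
  expect_true(d0$infection)
  expect_true(d0$sepsis_episode)
})

test_that("elective-surgery antibiotics suppress sepsis for two windows only", {
  adm <- adm_row("e1", urgency = FALSE, surgical = TRUE)
  num <- dplyr::bind_rows(
    num_row("e1", "Platelets", 250, day = -1),
    num_row("e1", "Platelets", 40, day = 0),   # 0 -> 3 rise at day 0
    num_row("e1", "ABP mean", 60, day = 0),
    num_row("e1", "GCS total", 14, day = 0),
    num_row("e1", "Creatinine", 80, day = 0),
    num_row("e1", "Platelets", 35, day = 2),   # plateau then new rise day 3
    num_row("e1", "Platelets", 15, day = 3),   # coag 4
    num_row("e1", "ABP mean", 55, day = 3),
    num_row("e1", "GCS total", 9, day = 3),
    num_row("e1", "Creatinine", 200, day = 3))
  drg <- dplyr::bind_rows(
    drug_row("e1", "Cefazolin", day = 0),
    drug_row("e1", "Meropenem", day = 3))
  store <- make_flag_store(adm, numericitems = num, drugitems = drg)
  out <- run_pipeline(store, day_range = c(-1L, 3L))
  s <- out$sepsis
  # day 0: escalation with a qualifying rise, but perioperative => prophylactic
  expect_true(s$escalation[s$day == 0L])
  expect_true(s$prophylaxis[s$day == 0L])
  expect_false(s$infection[s$day == 0L])
  expect_false(s$sepsis_episode[s$day == 0L])
  # day 3: a later escalation may still be sepsis
  expect_true(s$sepsis_episode[s$day == 3L])
})

test_that("post-admission windows with >= 3 missing components are discarded", {
  adm <- adm_row("m1", urgency = TRUE, surgical = FALSE)
  num <- dplyr::bind_rows(
    num_row("m1", "Platelets", 250, day = -1),
    num_row("m1", "Platelets", 40, day = 0),   # coag 3; 4 components missing
    num_row("m1", "ABP mean", 60, day = 0))
  drg <- drug_row("m1", "Ceftriaxone", day = 0)
  store <- make_flag_store(adm, numericitems = num, drugitems = drg)
  out <- run_pipeline(store, day_range = c(-1L, 1L))
  d0 <- out$sepsis[out$sepsis$day == 0L, ]
  expect_true(d0$infection)
  expect_true(d0$indeterminate)
  expect_false(d0$sepsis_episode)

  # the same escalation and rise in a PRE-admission window is not discarded:
  # absent pre-admission components are assumed zero, not unknown
  adm2 <- adm_row("m2", urgency = TRUE, surgical = FALSE)
  num2 <- dplyr::bind_rows(
    num_row("m2", "Platelets", 40, day = -1),
    num_row("m2", "Platelets", 30, day = 0),
    num_row("m2", "ABP mean", 60, day = 0),
    num_row("m2", "GCS total", 15, day = 0),
    num_row("m2", "Creatinine", 300, day = 0))
  drg2 <- drug_row("m2", "Ceftriaxone", day = -1)
  store2 <- make_flag_store(adm2, numericitems = num2, drugitems = drg2)
  out2 <- run_pipeline(store2, day_range = c(-1L, 1L))
  dm1 <- out2$sepsis[out2$sepsis$day == -1L, ]
  expect_equal(dm1$n_missing, 5L)
  expect_true(dm1$sepsis_episode)
})

test_that("septic shock is the vasopressor + lactate subset of sepsis", {
  adm <- adm_row("k1", urgency = TRUE, surgical = FALSE)
  base_num <- dplyr::bind_rows(
    num_row("k1", "Platelets", 250, day = -1),
    num_row("k1", "Platelets", 40, day = 0),
    num_row("k1", "GCS total", 15, day = 0),
    num_row("k1", "Creatinine", 80, day = 0))
  drg <- dplyr::bind_rows(drug_row("k1", "Ceftriaxone", day = 0),
                          drug_row("k1", "Noradrenaline", day = 0, dose = 0.3))
  run_case <- function(extra_num) {
    store <- make_flag_store(adm, numericitems = dplyr::bind_rows(base_num, extra_num),
                             drugitems = drg)
    run_pipeline(store, day_range = c(-1L, 1L))$sepsis
  }
  with_lact <- run_case(num_row("k1", "Lactate", 3.1, day = 0))
  d0 <- with_lact[with_lact$day == 0L, ]
  expect_true(d0$sepsis_episode)
  expect_equal(d0$cardiovascular, 4L)
  expect_true(d0$septic_shock)

  low_lact <- run_case(num_row("k1", "Lactate", 1.2, day = 0))
  expect_false(low_lact$septic_shock[low_lact$day == 0L])

  no_lact <- run_case(NULL)
  expect_false(no_lact$septic_shock[no_lact$day == 0L])
})

test_that("the pipeline is deterministic and respects the logical chain", {
  spec <- random_scenario(40, seed = 909)
  dir <- withr::local_tempdir()
  gen <- generate_cohort(spec, file.path(dir, "g"))
  store <- read_tables(gen$paths)
  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  run_pipeline(store, day_range = spec$day_range, out_dir = out1)
  run_pipeline(store, day_range = spec$day_range, out_dir = out2)
  expect_identical(readLines(file.path(out1, "sofa.csv")),
                   readLines(file.path(out2, "sofa.csv")))
  expect_identical(readLines(file.path(out1, "sepsis.csv")),
                   readLines(file.path(out2, "sepsis.csv")))

  s <- run_pipeline(store, day_range = spec$day_range)$sepsis
  expect_true(all(!s$septic_shock | s$sepsis_episode))
  expect_true(all(!s$sepsis_episode | s$infection))
  expect_true(all(!s$infection | (!is.na(s$escalation) & s$escalation &
                                    !s$prophylaxis)))
})

test_that("an empty cohort yields header-only outputs", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec(tibble::tibble(admissionid = character(0),
                                       patientid = character(0),
                                       urgency = logical(0),
                                       surgical = logical(0),
                                       location = character(0)))
  gen <- generate_cohort(spec, file.path(dir, "g"))
  store <- read_tables(gen$paths)
  out <- run_pipeline(store, day_range = c(-1L, 1L),
                      out_dir = file.path(dir, "o"))
  expect_equal(nrow(out$sofa), 0)
  expect_equal(nrow(out$sepsis), 0)
  expect_length(readLines(file.path(dir, "o", "sofa.csv")), 1)
  expect_length(readLines(file.path(dir, "o", "sepsis.csv")), 1)
})
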