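test_that("window assignment uses half-open 24h intervals with floor semantics", {
  expect_identical(assign_window(0), 0L)
  expect_identical(assign_window(86399999), 0L)
  expect_identical(assign_window(86400000), 1L)
  expect_identical(assign_window(-1), -1L)
  expect_identical(assign_window(-86400000), -1L)
  expect_identical(assign_window(-86400001), -2L)

  # monotone and partitioning: window boundaries are exact, order preserved
  set.seed(11)
  t <- sort(round(runif(500, -5e8, 5e8)))
  w <- assign_window(t)
  expect_true(all(diff(w) >= 0))
  expect_true(all(t >= w * 86400000 & t < (w + 1) * 86400000))
})

test_that("read_tables builds a validated store and drops unmapped items", {
  adm <- dplyr::bind_rows(adm_row("a1"), adm_row("a2"), adm_row("a3"),
                          adm_row("a4"))
  store <- mini_store(adm)
  expect_s3_class(store, "icu_store")
  expect_equal(nrow(store$admissions), 4)
  expect_equal(nrow(store$events), 0)
  expect_true(all(store$admissions$first_admission))

  # a mapped numeric item lands as a concept event in the right window
  store <- mini_store(adm, numericitems = num_row("a1", "Platelets", 90, day = 1))
  expect_equal(store$events$concept, "platelets")
  expect_equal(store$events$day, 1L)

  # unmapped drug name: row dropped, warning carries the count
  expect_warning(
    store <- mini_store(adm, drugitems = drug_row("a1", "NotADrug")),
    "dropped 1 row")
  expect_equal(nrow(store$events), 0)
  expect_equal(sum(store$dropped$n), 1)
})

test_that("read_tables rejects broken inputs with named errors", {
  adm <- adm_row("a1")
  dir <- withr::local_tempdir()
  paths <- list(admissions = write_table(adm, dir, "admissions"))

  # event referencing an unknown admission
  paths$numericitems <- write_table(num_row("ghost", "Platelets", 90), dir,
                                    "numericitems")
  expect_error(read_tables(paths), "referential-integrity.*ghost")

  # missing required column names table and column
  bad <- dplyr::select(num_row("a1", "Platelets", 90), -"measuredat")
  paths$numericitems <- write_table(bad, dir, "numericitems")
  expect_error(read_tables(paths), "numericitems.*measuredat")

  # unparseable timestamp names the row
  ugly <- num_row("a1", "Platelets", 90)
  ugly$measuredat <- "not-a-time"
  paths$numericitems <- write_table(ugly, dir, "numericitems")
  expect_error(read_tables(paths), "unparseable timestamp.*row 1")
})

test_that("output writers serialise the fixed schemas and round-trip exactly", {
  dir <- withr::local_tempdir()
  scores <- tibble::tibble(
    admissionid = c("7", "7"), day = c(-1L, 0L),
    respiration = c(NA, 3L), coagulation = c(0L, 0L), liver = c(NA, NA),
    cardiovascular = c(NA, 1L), cns = c(NA, 0L), renal = c(0L, 0L),
    total = c(0L, 4L), n_missing = c(4L, 1L))
  p <- file.path(dir, "sofa.csv")
  write_sofa_table(scores, p)
  lines <- readLines(p)
  expect_equal(lines[1], paste("admissionid,time,sofa_respiration_score",
                               "sofa_coagulation_score,sofa_liver_score",
                               "sofa_cardiovascular_score,sofa_cns_score",
                               "sofa_renal_score,sofa_total_score", sep = ","))
  expect_equal(lines[2], "7,-1,NaN,0,NaN,NaN,NaN,0,0")
  back <- read_sofa_table(p)
  expect_equal(back$respiration, c(NA, 3))
  expect_equal(back$total, c(0, 4))

  flags <- tibble::tibble(
    admissionid = "7", day = c(-1L, 0L), total = c(0L, 4L),
    escalation = c(TRUE, NA), prophylaxis = c(TRUE, FALSE),
    infection = FALSE, sepsis_episode = FALSE, septic_shock = FALSE)
  p2 <- file.path(dir, "sepsis.csv")
  write_sepsis_table(flags, p2)
  lines2 <- readLines(p2)
  expect_equal(lines2[2], "7,-1,0,True,True,False,False,False")
  expect_equal(lines2[3], "7,0,4,NaN,False,False,False,False")
  back2 <- read_sepsis_table(p2)
  expect_equal(back2$escalation, c(TRUE, NA))
  expect_equal(back2$prophylaxis, c(TRUE, FALSE))

  # empty inputs give header-only files
  write_sofa_table(scores[0, ], file.path(dir, "empty_sofa.csv"))
  write_sepsis_table(flags[0, ], file.path(dir, "empty_sepsis.csv"))
  expect_length(readLines(file.path(dir, "empty_sofa.csv")), 1)
  expect_length(readLines(file.path(dir, "empty_sepsis.csv")), 1)
})

test_that("output size grows with admissions x days, not raw event count", {
  adm <- dplyr::bind_rows(adm_row("a1"), adm_row("a2"))
  # many repeated measurements in one window collapse to one output row
  num <- dplyr::bind_rows(lapply(1:200, function(i) {
    num_row("a1", "Platelets", 100 + i, day = 0, offset = i * 1000)
  }))
  store <- mini_store(adm, numericitems = num)
  sofa <- daily_sofa(store, day_range = c(-1L, 1L))
  expect_equal(nrow(sofa), 2)  # one observed window + day-0 row for a2
})
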