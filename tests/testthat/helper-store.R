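# Build a small icu_store from in-code tables, via the CSV reader itself.

write_table <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  readr::write_csv(df, path, progress = FALSE)
  path
}

adm_row <- function(admissionid, patientid = paste0("p", admissionid),
                    admittedat = 0, urgency = TRUE, surgical = FALSE,
                    location = "ICU") {
  tibble::tibble(admissionid = as.character(admissionid),
                 patientid = patientid, admittedat = admittedat,
                 urgency = urgency, surgical = surgical, location = location)
}

num_row <- function(admissionid, item, value, day = 0, offset = 3600000) {
  tibble::tibble(admissionid = as.character(admissionid), item = item,
                 value = value, unit = "",
                 measuredat = day * 86400000 + offset)
}

drug_row <- function(admissionid, item, day = 0, route = "IV", dose = 1000,
                     offset = 3600000) {
  tibble::tibble(admissionid = as.character(admissionid), item = item,
                 dose = dose, doseunit = "", route = route,
                 start = day * 86400000 + offset)
}

list_row <- function(admissionid, item, value = "True", day = 0,
                     offset = 3600000) {
  tibble::tibble(admissionid = as.character(admissionid), item = item,
                 value = value, measuredat = day * 86400000 + offset)
}

mini_store <- function(admissions, numericitems = NULL, drugitems = NULL,
                       listitems = NULL, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(admissions = write_table(admissions, dir, "admissions"))
  if (!is.null(numericitems)) {
    paths$numericitems <- write_table(numericitems, dir, "numericitems")
  }
  if (!is.null(drugitems)) {
    paths$drugitems <- write_table(drugitems, dir, "drugitems")
  }
  if (!is.null(listitems)) {
    paths$listitems <- write_table(listitems, dir, "listitems")
  }
  read_tables(paths)
}

# antibiotic event tibble in store-event shape (for module-level tests)
abx_events <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(admissionid = r[["admissionid"]] %||% "a1",
                   concept = "antibiotic", name = r[["name"]],
                   value = 1000, text = NA_character_,
                   route = r[["route"]] %||% "IV",
                   measuredat = as.numeric(r[["day"]]) * 86400000 + 1,
                   day = as.integer(r[["day"]]))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
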