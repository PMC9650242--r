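MS_PER_DAY <- 86400000

#' Assign a timestamp to its 24-hour window
#'
#' Windows ("days") are half-open intervals `[d*24h, (d+1)*24h)` in
#' milliseconds relative to admission, indexed by a signed integer `d`; day 0
#' starts at the admission instant and negative days cover the pre-admission
#' period. The mapping is floor division, so it is total, deterministic and
#' monotone.
#'
#' @param measured_at Numeric vector of timestamps in milliseconds relative to
#'   admission (may be negative).
#' @return Integer vector of day indices.
#' @examples
#' assign_window(c(0, 86399999, 86400000, -1))
#' @export
assign_window <- function(measured_at) {
  as.integer(floor(measured_at / MS_PER_DAY))
}

sofa_concepts <- function() {
  c("pao2", "fio2", "platelets", "bilirubin", "map", "gcs", "creatinine",
    "urine_output", "ventilated", "dopamine_dose", "norepinephrine_dose",
    "epinephrine_dose", "dobutamine_dose")
}

check_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in table '", table, "': missing column(s) ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  }
}

parse_ms <- function(x, table, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad)) {
    stop("table '", table, "': unparseable timestamp in column '", col,
         "' at row ", bad[1], " (value '", x[bad[1]], "')", call. = FALSE)
  }
  out
}

parse_flag <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes", "y")
}

normalise_route <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("other", length(x))
  out[grepl("^iv$|intraven", x)] <- "IV"
  out[grepl("^po$|^or|oraal|oral", x)] <- "oral"
  out[is.na(x) | x == ""] <- "n/a"
  out
}

read_raw_csv <- function(path, table) {
  if (!file.exists(path)) {
    stop("table '", table, "': file not found: ", path, call. = FALSE)
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

map_items <- function(df, section, table) {
  known <- names(section)
  hit <- df$item %in% known
  dropped <- df$item[!hit]
  df <- df[hit, , drop = FALSE]
  entry <- section[df$item]
  df$concept <- unname(vapply(entry, function(e) e$concept, character(1)))
  df$name <- unname(vapply(entry, function(e) if (is.null(e$name)) NA_character_ else e$name,
                           character(1)))
  df$factor <- unname(vapply(entry, function(e) if (is.null(e$factor)) 1 else as.numeric(e$factor),
                             numeric(1)))
  list(mapped = df, dropped = dropped)
}

#' Read the input tables into a validated event store
#'
#' Reads long-format CSV tables (admissions plus any of drugitems,
#' numericitems, listitems), translates raw item labels to clinical concepts
#' through the concept map, assigns every event to its 24-hour window, and
#' validates referential integrity. Rows whose item label is absent from the
#' concept map are dropped with a warning reporting the count per table.
#'
#' Expected columns: `admissions` needs `admissionid, patientid, admittedat,
#' urgency, surgical, location` (optional `admissioncount`, 1 = first
#' admission); `numericitems` needs `admissionid, item, value, unit,
#' measuredat`; `drugitems` needs `admissionid, item, dose, doseunit, route,
#' start`; `listitems` needs `admissionid, item, value, measuredat`. All
#' timestamps are integer milliseconds relative to admission.
#'
#' @param paths Named list/vector of file paths; `admissions` is required.
#' @param concept_map A concept map from [load_concept_map()].
#' @return An object of class `icu_store`: a list with tibbles `admissions`
#'   (one row per admission, logical `urgency`/`surgical`/`first_admission`)
#'   and `events` (columns `admissionid, concept, name, value, text, route,
#'   measuredat, day`), plus a `dropped` tibble of unmapped item counts.
#' @export
read_tables <- function(paths, concept_map = default_concept_map()) {
  paths <- as.list(paths)
  if (is.null(paths$admissions)) {
    stop("paths must include an 'admissions' table", call. = FALSE)
  }

  adm <- read_raw_csv(paths$admissions, "admissions")
  check_cols(adm, c("admissionid", "patientid", "admittedat", "urgency",
                    "surgical", "location"), "admissions")
  admissions <- tibble::tibble(
    admissionid = adm$admissionid,
    patientid = adm$patientid,
    admittedat = parse_ms(adm$admittedat, "admissions", "admittedat"),
    urgency = parse_flag(adm$urgency),
    surgical = parse_flag(adm$surgical),
    location = adm$location)
  if (anyDuplicated(admissions$admissionid)) {
    stop("admissions: duplicated admissionid", call. = FALSE)
  }
  if ("admissioncount" %in% names(adm)) {
    admissions$first_admission <- suppressWarnings(as.integer(adm$admissioncount)) == 1L
  } else {
    admissions <- admissions |>
      dplyr::group_by(.data$patientid) |>
      dplyr::mutate(first_admission = dplyr::row_number(
        order(.data$admittedat, .data$admissionid)) == 1L) |>
      dplyr::ungroup()
  }

  empty_events <- tibble::tibble(
    admissionid = character(0), concept = character(0), name = character(0),
    value = numeric(0), text = character(0), route = character(0),
    measuredat = numeric(0))
  events <- list()
  dropped <- list()

  if (!is.null(paths$numericitems)) {
    num <- read_raw_csv(paths$numericitems, "numericitems")
    check_cols(num, c("admissionid", "item", "value", "unit", "measuredat"),
               "numericitems")
    m <- map_items(num, concept_map$numericitems, "numericitems")
    dropped$numericitems <- m$dropped
    d <- m$mapped
    events$numeric <- tibble::tibble(
      admissionid = d$admissionid,
      concept = d$concept,
      name = NA_character_,
      value = suppressWarnings(as.numeric(d$value)) * d$factor,
      text = NA_character_,
      route = "n/a",
      measuredat = parse_ms(d$measuredat, "numericitems", "measuredat"))
  }

  if (!is.null(paths$drugitems)) {
    drg <- read_raw_csv(paths$drugitems, "drugitems")
    check_cols(drg, c("admissionid", "item", "dose", "doseunit", "route", "start"),
               "drugitems")
    m <- map_items(drg, concept_map$drugitems, "drugitems")
    dropped$drugitems <- m$dropped
    d <- m$mapped
    events$drug <- tibble::tibble(
      admissionid = d$admissionid,
      concept = d$concept,
      name = tolower(d$name),
      value = suppressWarnings(as.numeric(d$dose)) * d$factor,
      text = NA_character_,
      route = normalise_route(d$route),
      measuredat = parse_ms(d$start, "drugitems", "start"))
  }

  if (!is.null(paths$listitems)) {
    lst <- read_raw_csv(paths$listitems, "listitems")
    check_cols(lst, c("admissionid", "item", "value", "measuredat"), "listitems")
    m <- map_items(lst, concept_map$listitems, "listitems")
    dropped$listitems <- m$dropped
    d <- m$mapped
    events$list <- tibble::tibble(
      admissionid = d$admissionid,
      concept = d$concept,
      name = NA_character_,
      value = as.numeric(parse_flag(d$value)),
      text = as.character(d$value),
      route = "n/a",
      measuredat = parse_ms(d$measuredat, "listitems", "measuredat"))
  }

  events <- if (length(events)) dplyr::bind_rows(events) else empty_events
  unknown <- setdiff(unique(events$admissionid), admissions$admissionid)
  if (length(unknown)) {
    stop("referential-integrity error: event admissionid(s) not in admissions: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  events$day <- assign_window(events$measuredat)

  dropped_tbl <- if (length(dropped)) {
    dplyr::bind_rows(lapply(names(dropped), function(tab) {
      if (!length(dropped[[tab]])) return(NULL)
      tibble::as_tibble(table(item = dropped[[tab]])) |>
        dplyr::mutate(table = tab, .before = 1)
    }))
  } else {
    tibble::tibble(table = character(0), item = character(0), n = integer(0))
  }
  if (!is.null(dropped_tbl) && nrow(dropped_tbl)) {
    warning("dropped ", sum(dropped_tbl$n), " row(s) with item(s) absent from ",
            "the concept map (", paste(unique(dropped_tbl$table), collapse = ", "),
            ")", call. = FALSE)
  } else {
    dropped_tbl <- tibble::tibble(table = character(0), item = character(0),
                                  n = integer(0))
  }

  structure(list(admissions = admissions, events = events, dropped = dropped_tbl),
            class = "icu_store")
}

#' @export
print.icu_store <- function(x, ...) {
  cat("<icu_store> ", nrow(x$admissions), " admissions, ",
      nrow(x$events), " mapped events", sep = "")
  if (nrow(x$dropped)) cat(", ", sum(x$dropped$n), " dropped rows", sep = "")
  cat("\n")
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NaN", format(x, trim = TRUE, scientific = FALSE))
}

fmt_bool <- function(x) {
  ifelse(is.na(x), "NaN", ifelse(x, "True", "False"))
}

#' Write the daily SOFA score table
#'
#' Serialises per-window SOFA scores to CSV with the fixed column set
#' `admissionid, time, sofa_respiration_score, sofa_coagulation_score,
#' sofa_liver_score, sofa_cardiovascular_score, sofa_cns_score,
#' sofa_renal_score, sofa_total_score`. Missing components are written as
#' literal `NaN`; rows are sorted by (admissionid, time).
#'
#' @param scores A tibble from [daily_sofa()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sofa_table <- function(scores, path) {
  scores <- dplyr::arrange(scores, .data$admissionid, .data$day)
  header <- paste(c("admissionid", "time", "sofa_respiration_score",
                    "sofa_coagulation_score", "sofa_liver_score",
                    "sofa_cardiovascular_score", "sofa_cns_score",
                    "sofa_renal_score", "sofa_total_score"), collapse = ",")
  rows <- if (nrow(scores)) {
    paste(scores$admissionid, scores$day,
          fmt_num(scores$respiration), fmt_num(scores$coagulation),
          fmt_num(scores$liver), fmt_num(scores$cardiovascular),
          fmt_num(scores$cns), fmt_num(scores$renal), fmt_num(scores$total),
          sep = ",")
  } else {
    character(0)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write the per-window sepsis table
#'
#' Serialises per-window sepsis flags to CSV with the fixed column set
#' `admissionid, time, sofa_total_score, antibiotic_escalation, prophylaxis,
#' infection, sepsis_episode, septic_shock`. Booleans are written as
#' `True`/`False`; an undefined escalation (window with no antibiotic
#' administrations) is written as `NaN`.
#'
#' @param flags A tibble from [detect_sepsis()] / [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sepsis_table <- function(flags, path) {
  flags <- dplyr::arrange(flags, .data$admissionid, .data$day)
  header <- paste(c("admissionid", "time", "sofa_total_score",
                    "antibiotic_escalation", "prophylaxis", "infection",
                    "sepsis_episode", "septic_shock"), collapse = ",")
  rows <- if (nrow(flags)) {
    paste(flags$admissionid, flags$day, fmt_num(flags$total),
          fmt_bool(flags$escalation), fmt_bool(flags$prophylaxis),
          fmt_bool(flags$infection), fmt_bool(flags$sepsis_episode),
          fmt_bool(flags$septic_shock), sep = ",")
  } else {
    character(0)
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

read_output_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

as_num_nan <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x == "NaN"] <- NA_real_
  out
}

as_bool_nan <- function(x) {
  out <- rep(NA, length(x))
  out[x == "True"] <- TRUE
  out[x == "False"] <- FALSE
  out
}

#' Read back a written SOFA table
#'
#' Inverse of [write_sofa_table()]: `NaN` cells become `NA`.
#' @param path File written by [write_sofa_table()].
#' @return A tibble with the same columns as [daily_sofa()] output (without
#'   `n_missing`).
#' @export
read_sofa_table <- function(path) {
  d <- read_output_csv(path)
  tibble::tibble(
    admissionid = d$admissionid,
    day = as.integer(d$time),
    respiration = as_num_nan(d$sofa_respiration_score),
    coagulation = as_num_nan(d$sofa_coagulation_score),
    liver = as_num_nan(d$sofa_liver_score),
    cardiovascular = as_num_nan(d$sofa_cardiovascular_score),
    cns = as_num_nan(d$sofa_cns_score),
    renal = as_num_nan(d$sofa_renal_score),
    total = as_num_nan(d$sofa_total_score))
}

#' Read back a written sepsis table
#'
#' Inverse of [write_sepsis_table()]: `NaN` cells become `NA`.
#' @param path File written by [write_sepsis_table()].
#' @return A tibble of per-window flags.
#' @export
read_sepsis_table <- function(path) {
  d <- read_output_csv(path)
  tibble::tibble(
    admissionid = d$admissionid,
    day = as.integer(d$time),
    total = as_num_nan(d$sofa_total_score),
    escalation = as_bool_nan(d$antibiotic_escalation),
    prophylaxis = as_bool_nan(d$prophylaxis),
    infection = as_bool_nan(d$infection),
    sepsis_episode = as_bool_nan(d$sepsis_episode),
    septic_shock = as_bool_nan(d$septic_shock))
}
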