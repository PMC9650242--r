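# SOFA component scoring. Each scorer is vectorised over windows; NA in means
# the driving measurements are absent, NA out means the component is missing
# for that window.

score_respiration_vec <- function(ratio, ventilated, th) {
  cut <- th$respiration$cutoffs
  s <- rowSums(outer(ratio, cut, "<"))
  vfrom <- th$respiration$ventilation_required_from
  cap <- !is.na(s) & s >= vfrom & !ventilated
  s[cap] <- vfrom - 1
  as.integer(s)
}

score_coagulation_vec <- function(platelets, th) {
  as.integer(rowSums(outer(platelets, th$coagulation$cutoffs, "<")))
}

score_liver_vec <- function(bilirubin, th) {
  as.integer(rowSums(outer(bilirubin, th$liver$cutoffs, ">=")))
}

score_cns_vec <- function(gcs, th) {
  # bands from cutoffs [15, 13, 10, 6]: 15 -> 0, 13-14 -> 1, 10-12 -> 2,
  # 6-9 -> 3, <6 -> 4
  as.integer(rowSums(outer(gcs, th$cns$cutoffs, "<")))
}

score_cardiovascular_vec <- function(map, dopamine, norepinephrine, epinephrine,
                                     dobutamine, th) {
  tc <- th$cardiovascular
  n <- length(map)
  any_input <- !is.na(map) | !is.na(dopamine) | !is.na(norepinephrine) |
    !is.na(epinephrine) | !is.na(dobutamine)
  s <- ifelse(any_input, 0L, NA_integer_)
  bump <- function(s, cond, level) {
    ifelse(!is.na(cond) & cond & !is.na(s), pmax(s, level), s)
  }
  s <- bump(s, map < tc$map_cutoff, 1L)
  s <- bump(s, dopamine > 0 & dopamine <= tc$dopamine_low, 2L)
  s <- bump(s, dobutamine > 0, 2L)
  s <- bump(s, dopamine > tc$dopamine_low & dopamine <= tc$dopamine_high, 3L)
  s <- bump(s, norepinephrine > 0 & norepinephrine <= tc$norepinephrine, 3L)
  s <- bump(s, epinephrine > 0 & epinephrine <= tc$epinephrine, 3L)
  s <- bump(s, dopamine > tc$dopamine_high, 4L)
  s <- bump(s, norepinephrine > tc$norepinephrine, 4L)
  s <- bump(s, epinephrine > tc$epinephrine, 4L)
  as.integer(s)
}

score_renal_vec <- function(creatinine, urine, th) {
  tr <- th$renal
  cs <- rowSums(outer(creatinine, tr$creatinine_cutoffs, ">="))
  us <- ifelse(is.na(urine), NA_real_,
               ifelse(urine < tr$urine_score4_below, 4,
                      ifelse(urine < tr$urine_score3_below, 3, 0)))
  s <- pmax(cs, us, na.rm = TRUE)
  s[is.na(creatinine) & is.na(urine)] <- NA
  as.integer(s)
}

#' Score a single SOFA component from worst-in-window aggregates
#'
#' Scores one of the six SOFA components for one window, given the worst
#' values of the concepts it needs. Aggregation direction is part of the SOFA
#' definition: minimum for PaO2, platelets, MAP and GCS; maximum for FiO2,
#' bilirubin, creatinine and vasopressor doses; total for urine output.
#' Respiration scores at or above the configured ventilation requirement
#' (default 3) additionally need ventilatory support in the window and are
#' capped below it otherwise; the cardiovascular score reaches 3-4 whenever a
#' vasopressor dose event meets the dose cut-offs, vasopressor use being
#' inferred from the presence of a dose (given to maintain adequate mean
#' arterial pressure).
#'
#' @param component One of `"respiration"`, `"coagulation"`, `"liver"`,
#'   `"cardiovascular"`, `"cns"`, `"renal"`.
#' @param aggregates Named list of worst-in-window values. Recognised names:
#'   `pao2`, `fio2` (fraction or percent), `ratio` (precomputed PaO2/FiO2,
#'   overrides `pao2`/`fio2`), `ventilated` (logical), `platelets`,
#'   `bilirubin`, `map`, `dopamine`, `norepinephrine`, `epinephrine`,
#'   `dobutamine`, `gcs`, `creatinine`, `urine_output`. Absent or `NA` entries
#'   mean "not measured".
#' @param thresholds Thresholds from [load_sofa_thresholds()].
#' @return Integer score 0-4, or `NA` if every concept the component needs is
#'   absent.
#' @export
score_component <- function(component, aggregates,
                            thresholds = default_sofa_thresholds()) {
  g <- function(nm) {
    v <- aggregates[[nm]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v[1])
  }
  switch(component,
    respiration = {
      ratio <- g("ratio")
      if (is.na(ratio)) {
        pao2 <- g("pao2"); fio2 <- g("fio2")
        if (!is.na(fio2) && fio2 > 1) fio2 <- fio2 / 100
        ratio <- if (is.na(pao2) || is.na(fio2) || fio2 <= 0) NA_real_ else pao2 / fio2
      }
      vent <- isTRUE(as.logical(aggregates$ventilated))
      score_respiration_vec(ratio, vent, thresholds)
    },
    coagulation = score_coagulation_vec(g("platelets"), thresholds),
    liver = score_liver_vec(g("bilirubin"), thresholds),
    cardiovascular = score_cardiovascular_vec(g("map"), g("dopamine"),
                                              g("norepinephrine"),
                                              g("epinephrine"), g("dobutamine"),
                                              thresholds),
    cns = score_cns_vec(g("gcs"), thresholds),
    renal = score_renal_vec(g("creatinine"), g("urine_output"), thresholds),
    stop("unknown SOFA component: ", component, call. = FALSE))
}

#' Worst value of a concept within a window
#'
#' @param events Event tibble (as in an `icu_store`).
#' @param concept Concept name.
#' @param day Window index.
#' @param direction `"min"`, `"max"` or `"sum"` (urine output).
#' @return The extremum (or total) of the concept's values in the window, or
#'   `NA` if there are none.
#' @export
worst_in_window <- function(events, concept, day, direction = c("min", "max", "sum")) {
  direction <- match.arg(direction)
  v <- events$value[events$concept == concept & events$day == day & !is.na(events$value)]
  if (!length(v)) return(NA_real_)
  switch(direction, min = min(v), max = max(v), sum = sum(v))
}

# One row per (admission, day) holding worst-in-window values of every
# SOFA-relevant concept; only windows with >= 1 relevant event appear.
window_aggregates <- function(store, day_range) {
  ev <- store$events |>
    dplyr::filter(.data$day >= day_range[1], .data$day <= day_range[2],
                  .data$concept %in% sofa_concepts(), !is.na(.data$value))
  if (!nrow(ev)) {
    return(tibble::tibble(admissionid = character(0), day = integer(0)))
  }
  dir_min <- c("pao2", "platelets", "map", "gcs")
  dir_max <- c("fio2", "bilirubin", "creatinine", "dopamine_dose",
               "norepinephrine_dose", "epinephrine_dose", "dobutamine_dose",
               "ventilated")
  ev |>
    dplyr::mutate(value = ifelse(.data$concept == "fio2" & .data$value > 1,
                                 .data$value / 100, .data$value)) |>
    dplyr::group_by(.data$admissionid, .data$day, .data$concept) |>
    dplyr::summarise(value = dplyr::case_when(
      .data$concept[1] %in% dir_min ~ min(.data$value),
      .data$concept[1] %in% dir_max ~ max(.data$value),
      TRUE ~ sum(.data$value)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "concept", values_from = "value")
}

ensure_cols <- function(df, cols) {
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA_real_
  df
}

#' Daily SOFA scores for every admission
#'
#' Computes the six SOFA component scores and total for every (admission,
#' 24-hour window) pair within `day_range`. A row is produced for every window
#' holding at least one SOFA-relevant event, plus day 0 for every admission.
#' The total is the sum of the non-missing components (a missing component
#' contributes zero, consistent with assuming absent pre-admission scores are
#' zero); `n_missing` carries the number of missing components so downstream
#' sepsis detection can discard windows with too little information.
#'
#' @param store An `icu_store` from [read_tables()].
#' @param thresholds Thresholds from [load_sofa_thresholds()].
#' @param day_range Integer vector `c(d_min, d_max)` with `d_min <= 0 <= d_max`.
#' @return A tibble with columns `admissionid, day, respiration, coagulation,
#'   liver, cardiovascular, cns, renal, total, n_missing`, sorted by
#'   (admissionid, day).
#' @export
daily_sofa <- function(store, thresholds = default_sofa_thresholds(),
                       day_range = c(-1L, 3L)) {
  stopifnot(length(day_range) == 2, day_range[1] <= 0, day_range[2] >= 0)
  agg <- window_aggregates(store, day_range)
  base <- tibble::tibble(admissionid = store$admissions$admissionid, day = 0L)
  agg <- dplyr::full_join(agg, base, by = c("admissionid", "day"))
  agg <- ensure_cols(agg, c("pao2", "fio2", "platelets", "bilirubin", "map",
                            "gcs", "creatinine", "urine_output", "ventilated",
                            "dopamine_dose", "norepinephrine_dose",
                            "epinephrine_dose", "dobutamine_dose"))
  ratio <- ifelse(is.na(agg$pao2) | is.na(agg$fio2) | agg$fio2 <= 0,
                  NA_real_, agg$pao2 / agg$fio2)
  vent <- !is.na(agg$ventilated) & agg$ventilated > 0
  comp <- tibble::tibble(
    respiration = score_respiration_vec(ratio, vent, thresholds),
    coagulation = score_coagulation_vec(agg$platelets, thresholds),
    liver = score_liver_vec(agg$bilirubin, thresholds),
    cardiovascular = score_cardiovascular_vec(agg$map, agg$dopamine_dose,
                                              agg$norepinephrine_dose,
                                              agg$epinephrine_dose,
                                              agg$dobutamine_dose, thresholds),
    cns = score_cns_vec(agg$gcs, thresholds),
    renal = score_renal_vec(agg$creatinine, agg$urine_output, thresholds))
  m <- as.matrix(comp)
  out <- tibble::tibble(admissionid = agg$admissionid, day = as.integer(agg$day)) |>
    dplyr::bind_cols(comp) |>
    dplyr::mutate(total = as.integer(rowSums(m, na.rm = TRUE)),
                  n_missing = as.integer(rowSums(is.na(m)))) |>
    dplyr::arrange(.data$admissionid, .data$day)
  out
}
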