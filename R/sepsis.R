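# Sepsis-episode and septic-shock detection: the Sepsis-3 rule engine.

#' Acute SOFA rise rule
#'
#' A window `d` satisfies the acute-deterioration part of Sepsis-3 when the
#' total SOFA score rises by at least `min_rise` (default 2) between the
#' previous and current, previous and subsequent, or current and subsequent
#' windows. Days inside the computed range with no recorded score count as
#' zero (absent scores are assumed zero); comparisons involving days outside
#' the range are skipped.
#'
#' @param totals Named numeric vector of total SOFA scores, names being day
#'   indices (e.g. `c("-1" = 0, "0" = 4)`); days in range but absent count 0.
#' @param d Day index to evaluate.
#' @param day_range Integer `c(d_min, d_max)` of the computed range.
#' @param min_rise Minimum rise (default 2).
#' @return `TRUE` or `FALSE`.
#' @export
delta_rule <- function(totals, d, day_range, min_rise = 2) {
  get_total <- function(x) {
    if (x < day_range[1] || x > day_range[2]) return(NA_real_)
    v <- totals[as.character(x)]
    if (is.na(v)) 0 else unname(v)
  }
  prev <- get_total(d - 1)
  cur <- get_total(d)
  nxt <- get_total(d + 1)
  isTRUE(cur - prev >= min_rise) ||
    isTRUE(nxt - prev >= min_rise) ||
    isTRUE(nxt - cur >= min_rise)
}

# elective surgical admission = planned (urgency FALSE) and surgical TRUE
is_elective_surgical <- function(admissions) {
  !admissions$urgency & admissions$surgical
}

#' Detect per-window sepsis episodes
#'
#' Combines daily SOFA totals, antibiotic escalation and prophylaxis rules
#' into the per-window flags. For each window:
#' * `infection`: escalation is `TRUE`, the window is not prophylactic, and
#'   the window is not suppressed by the elective-surgery rule;
#' * `sepsis_episode`: infection together with an acute total-SOFA rise of at
#'   least 2 ([delta_rule()]); post-admission windows (day >= 0) with three or
#'   more missing SOFA components are indeterminate and never flagged
#'   (pre-admission windows are exempt: their absent components are assumed
#'   zero rather than unknown).
#'
#' Prophylaxis: a window whose administrations were all SDD exclusions, or —
#' for admissions after elective surgery (planned and surgical) — the earliest
#' window in day -1/0 containing any antibiotic administration. The
#' elective-surgery suppression also blocks `infection` in the window after
#' the prophylactic one; later windows may still qualify.
#'
#' Rows cover every window in `day_range` with at least one SOFA-relevant
#' event or antibiotic administration, plus day 0 for every admission.
#'
#' @param sofa Output of [daily_sofa()] (must cover the same `day_range`).
#' @param abx Output of the antibiotic flag stage (see [run_pipeline()]), a
#'   tibble `admissionid, day, escalation, sdd_prophylaxis`.
#' @param admissions Admissions tibble from an `icu_store`.
#' @param day_range Integer `c(d_min, d_max)` as used for `sofa`.
#' @return A tibble `admissionid, day, total, escalation, prophylaxis,
#'   infection, sepsis_episode, septic_shock, indeterminate, cardiovascular,
#'   n_missing` (the last three are working columns; [write_sepsis_table()]
#'   serialises only the standard ones). `septic_shock` is initialised `FALSE`
#'   pending [detect_septic_shock()].
#' @export
detect_sepsis <- function(sofa, abx, admissions, day_range = c(-1L, 3L)) {
  if (nrow(sofa) && (min(sofa$day) < day_range[1] || max(sofa$day) > day_range[2])) {
    stop("sofa table has windows outside day_range", call. = FALSE)
  }
  if (nrow(abx) && (min(abx$day) < day_range[1] || max(abx$day) > day_range[2])) {
    stop("antibiotic flags have windows outside day_range", call. = FALSE)
  }

  windows <- dplyr::bind_rows(
    dplyr::select(sofa, "admissionid", "day"),
    dplyr::select(abx, "admissionid", "day")) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$admissionid, .data$day)

  if (!nrow(windows)) {
    return(tibble::tibble(admissionid = character(0), day = integer(0),
                          total = integer(0), escalation = logical(0),
                          prophylaxis = logical(0), infection = logical(0),
                          sepsis_episode = logical(0), septic_shock = logical(0),
                          indeterminate = logical(0),
                          cardiovascular = integer(0), n_missing = integer(0)))
  }

  d <- windows |>
    dplyr::left_join(dplyr::select(sofa, "admissionid", "day", "total",
                                   "n_missing", "cardiovascular"),
                     by = c("admissionid", "day")) |>
    dplyr::left_join(abx, by = c("admissionid", "day")) |>
    dplyr::mutate(
      total = ifelse(is.na(.data$total), 0L, .data$total),
      n_missing = ifelse(is.na(.data$n_missing), 6L, .data$n_missing),
      has_abx = !is.na(.data$sdd_prophylaxis),
      sdd_prophylaxis = !is.na(.data$sdd_prophylaxis) & .data$sdd_prophylaxis)

  elective <- stats::setNames(is_elective_surgical(admissions),
                              admissions$admissionid)

  out <- d |>
    dplyr::group_by(.data$admissionid) |>
    dplyr::group_modify(function(g, key) {
      el <- isTRUE(elective[[as.character(key$admissionid)]])
      peri <- NA_integer_
      if (el) {
        cand <- g$day[g$has_abx & g$day %in% c(-1L, 0L)]
        if (length(cand)) peri <- min(cand)
      }
      prophylaxis <- g$sdd_prophylaxis | (!is.na(peri) & g$day == peri)
      suppressed <- !is.na(peri) & g$day %in% c(peri, peri + 1L)
      totals <- stats::setNames(g$total, g$day)
      delta <- vapply(g$day, function(dd) delta_rule(totals, dd, day_range),
                      logical(1))
      infection <- !is.na(g$escalation) & g$escalation & !prophylaxis & !suppressed
      indeterminate <- g$day >= 0L & g$n_missing >= 3L
      sepsis <- infection & delta & !indeterminate
      tibble::tibble(day = g$day, total = g$total,
                     escalation = g$escalation,
                     prophylaxis = prophylaxis,
                     infection = infection,
                     sepsis_episode = sepsis,
                     septic_shock = FALSE,
                     indeterminate = indeterminate,
                     cardiovascular = g$cardiovascular,
                     n_missing = g$n_missing)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$admissionid, .data$day)
  out
}

#' Flag septic shock
#'
#' Septic shock is the subset of sepsis episodes whose cardiovascular SOFA
#' score is at least the configured minimum (default 3, i.e. vasopressor
#' support) and whose worst (maximum) lactate in the window meets the
#' threshold (default at least 2 mmol/L). A window with no lactate
#' measurement is not flagged.
#'
#' @param flags Output of [detect_sepsis()].
#' @param store The `icu_store` (source of lactate events).
#' @param criteria A [shock_criteria()] object.
#' @return `flags` with `septic_shock` filled in.
#' @export
detect_septic_shock <- function(flags, store, criteria = shock_criteria()) {
  lac_ev <- dplyr::filter(store$events, .data$concept == "lactate",
                          !is.na(.data$value))
  lac <- if (nrow(lac_ev)) {
    lac_ev |>
      dplyr::group_by(.data$admissionid, .data$day) |>
      dplyr::summarise(lactate_max = max(.data$value), .groups = "drop")
  } else {
    tibble::tibble(admissionid = character(0), day = integer(0),
                   lactate_max = numeric(0))
  }
  cmp <- if (criteria$lactate_comparator == ">=") `>=` else `>`
  flags |>
    dplyr::left_join(lac, by = c("admissionid", "day")) |>
    dplyr::mutate(septic_shock = .data$sepsis_episode &
                    !is.na(.data$cardiovascular) &
                    .data$cardiovascular >= criteria$cardiovascular_min_score &
                    !is.na(.data$lactate_max) &
                    cmp(.data$lactate_max, criteria$lactate_threshold)) |>
    dplyr::select(-"lactate_max")
}

#' Run the full phenotyping pipeline
#'
#' Computes daily SOFA scores, antibiotic escalation, and per-window
#' sepsis-episode / septic-shock flags, optionally writing the two output
#' CSVs (`sofa.csv`, `sepsis.csv`). Deterministic given its inputs.
#'
#' @param store An `icu_store` from [read_tables()].
#' @param day_range Integer `c(d_min, d_max)`, `d_min <= 0 <= d_max`.
#' @param thresholds SOFA thresholds ([load_sofa_thresholds()]).
#' @param rank_map Antibiotic rank map ([load_antibiotic_ranks()]).
#' @param criteria Septic-shock criteria ([shock_criteria()]).
#' @param out_dir If non-`NULL`, directory into which `sofa.csv` and
#'   `sepsis.csv` are written.
#' @return A list with tibbles `sofa` and `sepsis` (the sepsis tibble keeps
#'   the working columns `indeterminate`, `cardiovascular`, `n_missing` that
#'   the CSV writer does not serialise).
#' @export
run_pipeline <- function(store, day_range = c(-1L, 3L),
                         thresholds = default_sofa_thresholds(),
                         rank_map = default_antibiotic_ranks(),
                         criteria = shock_criteria(),
                         out_dir = NULL) {
  sofa <- daily_sofa(store, thresholds, day_range)
  abx <- antibiotic_flags(store, rank_map, day_range)
  flags <- detect_sepsis(sofa, abx, store$admissions, day_range)
  flags <- detect_septic_shock(flags, store, criteria)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_sofa_table(sofa, file.path(out_dir, "sofa.csv"))
    write_sepsis_table(flags, file.path(out_dir, "sepsis.csv"))
  }
  list(sofa = sofa, sepsis = flags)
}
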