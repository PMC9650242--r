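# Admission-time ("current") sepsis criteria and their comparison against the
# Sepsis-3 phenotype in the first 24 hours.

#' Baseline admission-sepsis criteria for one admission
#'
#' The pre-existing admission-oriented definition flags sepsis when any of
#' the following holds:
#' 1. sepsis at admission flagged on the admission form;
#' 2. the admission diagnosis is on the severe-infection list;
#' 3. non-prophylactic antibiotic use after surgery (surgical admission with
#'    an antibiotic administration in the admission window that the pipeline
#'    did not classify as prophylactic);
#' 4. antibiotics given and cultures drawn within the configured window
#'    (default 6 h) after admission.
#'
#' @param store An `icu_store`.
#' @param admission_id Admission identifier.
#' @param sepsis_flags Output of [detect_sepsis()] / [run_pipeline()]; source
#'   of the prophylaxis classification for criterion 3.
#' @param config A [baseline_config()].
#' @return `TRUE` or `FALSE`.
#' @export
baseline_sepsis_at_admission <- function(store, admission_id, sepsis_flags,
                                         config = baseline_config()) {
  ev <- store$events[store$events$admissionid == admission_id, , drop = FALSE]
  arow <- store$admissions[store$admissions$admissionid == admission_id, ]
  if (!nrow(arow)) stop("unknown admission_id: ", admission_id, call. = FALSE)

  flagged <- any(ev$concept == "admission_sepsis_flag" & ev$value == 1)

  diag <- tolower(ev$text[ev$concept == "admission_diagnosis"])
  severe <- any(diag %in% config$severe_infection_diagnoses)

  post_surgery <- FALSE
  if (config$post_surgery_rule && isTRUE(arow$surgical)) {
    f <- sepsis_flags[sepsis_flags$admissionid == admission_id &
                        sepsis_flags$day == 0L, , drop = FALSE]
    abx_day0 <- any(ev$concept == "antibiotic" & ev$day == 0L)
    post_surgery <- abx_day0 && nrow(f) > 0 && !any(f$prophylaxis)
  }

  win <- config$culture_window_hours * 3600 * 1000
  abx_early <- any(ev$concept == "antibiotic" & ev$measuredat >= 0 &
                     ev$measuredat < win)
  culture_early <- any(ev$concept == "culture_drawn" & ev$measuredat >= 0 &
                         ev$measuredat < win)

  flagged || severe || post_surgery || (abx_early && culture_early)
}

#' Sepsis-3 label at admission
#'
#' An admission is Sepsis-3-positive at admission when a sepsis episode is
#' flagged in the 24-hour window before or after admission (day -1 or day 0).
#'
#' @param sepsis_flags Per-window flags from [detect_sepsis()] /
#'   [run_pipeline()].
#' @param admission_id Admission identifier.
#' @return `TRUE` or `FALSE`.
#' @export
sepsis3_at_admission <- function(sepsis_flags, admission_id) {
  f <- sepsis_flags[sepsis_flags$admissionid == admission_id &
                      sepsis_flags$day %in% c(-1L, 0L), , drop = FALSE]
  any(f$sepsis_episode)
}

#' Confusion matrix of Sepsis-3 versus the baseline criteria
#'
#' Cross-tabulates per-admission labels with Sepsis-3 as the reference:
#' `tt`/`tf` are Sepsis-3-positive admissions where the baseline is
#' positive/negative, `ft`/`ff` the Sepsis-3-negative ones. Sensitivity is
#' `tt / (tt + tf)` and specificity `ff / (ff + ft)`; either is `NaN` when
#' its denominator is empty, and reported as such.
#'
#' @param pairs A data frame with logical columns `sepsis3` and `baseline`,
#'   one row per admission.
#' @return A list with `matrix` (tibble of the four counts), `n`,
#'   `sensitivity` and `specificity`.
#' @export
confusion_matrix <- function(pairs) {
  if (!nrow(pairs)) stop("confusion_matrix: empty input", call. = FALSE)
  stopifnot(all(c("sepsis3", "baseline") %in% names(pairs)))
  tt <- sum(pairs$sepsis3 & pairs$baseline)
  tf <- sum(pairs$sepsis3 & !pairs$baseline)
  ft <- sum(!pairs$sepsis3 & pairs$baseline)
  ff <- sum(!pairs$sepsis3 & !pairs$baseline)
  list(matrix = tibble::tibble(tt = tt, tf = tf, ft = ft, ff = ff),
       n = nrow(pairs),
       sensitivity = if (tt + tf > 0) tt / (tt + tf) else NaN,
       specificity = if (ff + ft > 0) ff / (ff + ft) else NaN)
}

#' Compare Sepsis-3 against the baseline criteria over a cohort
#'
#' Restricts to unique first admissions, labels each with both definitions,
#' and tabulates the confusion matrix.
#'
#' @param store An `icu_store`.
#' @param sepsis_flags Per-window flags from [run_pipeline()] (must cover
#'   days -1 and 0).
#' @param config A [baseline_config()].
#' @return A list as from [confusion_matrix()], plus the per-admission
#'   `pairs` tibble.
#' @export
compare_definitions <- function(store, sepsis_flags, config = baseline_config()) {
  adm <- store$admissions[store$admissions$first_admission, , drop = FALSE]
  pairs <- tibble::tibble(
    admissionid = adm$admissionid,
    sepsis3 = vapply(adm$admissionid,
                     function(a) sepsis3_at_admission(sepsis_flags, a),
                     logical(1)),
    baseline = vapply(adm$admissionid,
                      function(a) baseline_sepsis_at_admission(store, a,
                                                               sepsis_flags,
                                                               config),
                      logical(1)))
  c(confusion_matrix(pairs), list(pairs = pairs))
}
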