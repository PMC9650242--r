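#' Load a concept map
#'
#' A concept map translates the raw item labels found in the input tables to
#' the clinical concepts the pipeline understands (pao2, platelets, map, ...,
#' antibiotic). It is a YAML file with one section per input table
#' (`numericitems`, `drugitems`, `listitems`), each mapping an item label to a
#' list with at least a `concept` field; antibiotics also carry a canonical
#' `name`, and any numeric item may carry a `factor` multiplier for unit
#' conversion.
#'
#' @param path Path to a YAML concept map. The default map shipped with the
#'   package covers the synthetic vocabulary of [generate_cohort()].
#' @return A named list with elements `numericitems`, `drugitems`,
#'   `listitems`.
#' @export
load_concept_map <- function(path = system.file("extdata", "concept_map.yaml",
                                                package = "sepsis3icu")) {
  cm <- yaml::read_yaml(path)
  for (tab in c("numericitems", "drugitems", "listitems")) {
    if (is.null(cm[[tab]])) cm[[tab]] <- list()
    ok <- vapply(cm[[tab]], function(x) is.list(x) && !is.null(x$concept), logical(1))
    if (!all(ok)) {
      stop("concept map section '", tab, "': every item needs a 'concept' field",
           call. = FALSE)
    }
  }
  cm
}

#' @rdname load_concept_map
#' @export
default_concept_map <- function() load_concept_map()

#' Load SOFA component thresholds
#'
#' Cut-offs for the six SOFA components (respiration, coagulation, liver,
#' cardiovascular, central nervous system, renal). Defaults follow the 1996
#' consensus score in AmsterdamUMCdb units (PaO2/FiO2 in kPa, platelets
#' x10^9/L, bilirubin and creatinine in umol/L, vasopressor doses in
#' ug/kg/min, urine output in mL/day); all cut-offs are configuration, not
#' code, so sites using e.g. mmHg ratios supply their own file.
#'
#' @param path Path to a YAML threshold file.
#' @return A named list with one entry per component.
#' @export
load_sofa_thresholds <- function(path = system.file("extdata", "sofa_thresholds.yaml",
                                                    package = "sepsis3icu")) {
  th <- yaml::read_yaml(path)
  need <- c("respiration", "coagulation", "liver", "cardiovascular", "cns", "renal")
  missing <- setdiff(need, names(th))
  if (length(missing)) {
    stop("threshold file lacks component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (comp in c("respiration", "coagulation", "cns")) {
    co <- th[[comp]]$cutoffs
    if (length(co) != 4 || any(diff(co) >= 0)) {
      stop("'", comp, "' cutoffs must be 4 strictly decreasing values", call. = FALSE)
    }
  }
  for (comp in c("liver")) {
    co <- th[[comp]]$cutoffs
    if (length(co) != 4 || any(diff(co) <= 0)) {
      stop("'", comp, "' cutoffs must be 4 strictly increasing values", call. = FALSE)
    }
  }
  co <- th$renal$creatinine_cutoffs
  if (length(co) != 4 || any(diff(co) <= 0)) {
    stop("renal creatinine cutoffs must be 4 strictly increasing values", call. = FALSE)
  }
  th
}

#' @rdname load_sofa_thresholds
#' @export
default_sofa_thresholds <- function() load_sofa_thresholds()

#' Load an antibiotic rank map
#'
#' Maps canonical antibiotic names to positive integer ranks (higher = broader
#' spectrum), with a synonym table for name normalisation and the selective
#' digestive decontamination (SDD) exclusion (drugs and post-admission window
#' days within which they are disregarded by escalation detection). The
#' shipped ranking is illustrative; the escalation algebra is the method, the
#' ranking is replaceable data.
#'
#' @param path Path to a YAML rank map.
#' @return A list with elements `ranks` (named integer vector), `synonyms`
#'   (named character vector) and `sdd` (list with `drugs`, `days`).
#' @export
load_antibiotic_ranks <- function(path = system.file("extdata", "antibiotic_ranks.yaml",
                                                     package = "sepsis3icu")) {
  rm_ <- yaml::read_yaml(path)
  ranks <- unlist(rm_$ranks)
  if (is.null(ranks) || any(ranks < 1) || any(ranks != round(ranks))) {
    stop("rank map must assign positive integer ranks", call. = FALSE)
  }
  names(ranks) <- tolower(trimws(names(ranks)))
  syn <- unlist(rm_$synonyms)
  if (is.null(syn)) syn <- character(0) else names(syn) <- tolower(trimws(names(syn)))
  bad <- setdiff(unname(syn), names(ranks))
  if (length(bad)) {
    stop("synonym target(s) not in rank map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sdd <- rm_$sdd
  if (is.null(sdd)) sdd <- list(drugs = character(0), days = integer(0))
  sdd$drugs <- tolower(trimws(unlist(sdd$drugs)))
  sdd$days <- as.integer(unlist(sdd$days))
  list(ranks = ranks, synonyms = syn, sdd = sdd)
}

#' @rdname load_antibiotic_ranks
#' @export
default_antibiotic_ranks <- function() load_antibiotic_ranks()

#' Septic shock criteria
#'
#' Septic shock is the subset of sepsis episodes with a cardiovascular SOFA
#' score of at least `cardiovascular_min_score` (i.e. vasopressor support,
#' assumed given to hold mean arterial pressure at or above `map_target`) and
#' a worst-in-window lactate at or above `lactate_threshold`.
#'
#' @param cardiovascular_min_score Minimum cardiovascular SOFA score (default 3).
#' @param lactate_threshold Lactate threshold in mmol/L (default 2).
#' @param lactate_comparator `">="` (default) or `">"`.
#' @param map_target Mean arterial pressure target in mmHg (documentation of
#'   the vasopressor assumption; default 65).
#' @return A list of class `shock_criteria`.
#' @export
shock_criteria <- function(cardiovascular_min_score = 3L,
                           lactate_threshold = 2.0,
                           lactate_comparator = c(">=", ">"),
                           map_target = 65) {
  lactate_comparator <- match.arg(lactate_comparator)
  stopifnot(cardiovascular_min_score > 0, lactate_threshold > 0, map_target > 0)
  structure(
    list(cardiovascular_min_score = as.integer(cardiovascular_min_score),
         lactate_threshold = lactate_threshold,
         lactate_comparator = lactate_comparator,
         map_target = map_target),
    class = "shock_criteria")
}

#' Baseline (admission-time) sepsis criteria configuration
#'
#' Configuration for the pre-existing admission-sepsis definition: a list of
#' admission diagnoses considered severe infections, the window (hours after
#' admission) within which co-occurring antibiotics and drawn cultures count,
#' and a toggle for the non-prophylactic-antibiotics-after-surgery criterion.
#'
#' @param severe_infection_diagnoses Character vector of diagnosis strings
#'   (matched case-insensitively).
#' @param culture_window_hours Hours after admission (default 6).
#' @param post_surgery_rule Logical toggle (default TRUE).
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(severe_infection_diagnoses = c("gastrointestinal perforation",
                                                           "cholangitis",
                                                           "meningitis"),
                            culture_window_hours = 6,
                            post_surgery_rule = TRUE) {
  stopifnot(culture_window_hours > 0)
  structure(
    list(severe_infection_diagnoses = tolower(severe_infection_diagnoses),
         culture_window_hours = culture_window_hours,
         post_surgery_rule = isTRUE(post_surgery_rule)),
    class = "baseline_config")
}
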