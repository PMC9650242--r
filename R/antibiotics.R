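# Antibiotic escalation: the per-window proxy for suspected infection.

#' Normalise an antibiotic name
#'
#' Case-insensitive exact matching plus the rank map's synonym table; no fuzzy
#' matching, so unknown spellings surface in the unknown-drug report instead
#' of being silently guessed.
#'
#' @param name Character vector of drug names.
#' @param rank_map Rank map from [load_antibiotic_ranks()].
#' @return Character vector of canonical names (unknown names pass through
#'   lower-cased).
#' @export
normalise_antibiotic <- function(name, rank_map = default_antibiotic_ranks()) {
  x <- tolower(trimws(name))
  hit <- x %in% names(rank_map$synonyms)
  x[hit] <- unname(rank_map$synonyms[x[hit]])
  x
}

#' Exclude selective-digestive-decontamination prophylaxis
#'
#' Removes administrations of the configured SDD drugs (default: cefotaxime)
#' in the configured post-admission windows (default: days 0-3, i.e. the first
#' four 24-hour periods) from the escalation input. Pre-admission
#' administrations of the same drug are retained. A window whose
#' administrations are all excluded is flagged as prophylactic.
#'
#' @param abx_events Antibiotic event tibble (concept `"antibiotic"`, columns
#'   `admissionid, name, route, day`).
#' @param rank_map Rank map from [load_antibiotic_ranks()].
#' @return A list with `events` (the retained administrations) and
#'   `prophylaxis` (tibble `admissionid, day, sdd_prophylaxis` for windows
#'   that contained only excluded administrations).
#' @export
filter_sdd_prophylaxis <- function(abx_events, rank_map = default_antibiotic_ranks()) {
  nm <- normalise_antibiotic(abx_events$name, rank_map)
  excluded <- nm %in% rank_map$sdd$drugs & abx_events$day %in% rank_map$sdd$days
  kept <- abx_events[!excluded, , drop = FALSE]
  all_excluded <- tibble::tibble(admissionid = abx_events$admissionid,
                                 day = abx_events$day, excluded = excluded) |>
    dplyr::group_by(.data$admissionid, .data$day) |>
    dplyr::summarise(sdd_prophylaxis = all(.data$excluded), .groups = "drop") |>
    dplyr::filter(.data$sdd_prophylaxis)
  list(events = kept, prophylaxis = all_excluded)
}

#' Build per-window antibiotic profiles
#'
#' Summarises each (admission, 24-hour window) with at least one antibiotic
#' administration: the set of distinct agents (deduplicated by normalised
#' name), the maximum rank, the number of distinct agents at that rank, and
#' whether any agent was given intravenously. Administrations of drugs absent
#' from the rank map are skipped and collected into the `unknown` report.
#'
#' @param abx_events Antibiotic event tibble (typically the `events` element
#'   of [filter_sdd_prophylaxis()]).
#' @param rank_map Rank map from [load_antibiotic_ranks()].
#' @return A tibble `admissionid, day, max_rank, n_at_max, any_iv, agents`
#'   (list column of per-agent tibbles), with an `unknown` attribute counting
#'   skipped names.
#' @export
build_day_profiles <- function(abx_events, rank_map = default_antibiotic_ranks()) {
  nm <- normalise_antibiotic(abx_events$name, rank_map)
  known <- nm %in% names(rank_map$ranks)
  unknown <- sort(table(nm[!known]), decreasing = TRUE)
  d <- tibble::tibble(admissionid = abx_events$admissionid[known],
                      day = abx_events$day[known],
                      name = nm[known],
                      rank = unname(rank_map$ranks[nm[known]]),
                      route = abx_events$route[known])
  profiles <- d |>
    dplyr::group_by(.data$admissionid, .data$day, .data$name, .data$rank) |>
    dplyr::summarise(iv = any(.data$route == "IV"), .groups = "drop") |>
    dplyr::group_by(.data$admissionid, .data$day) |>
    dplyr::summarise(
      max_rank = max(.data$rank),
      n_at_max = sum(.data$rank == max(.data$rank)),
      any_iv = any(.data$iv),
      agents = list(dplyr::pick("name", "rank", "iv")),
      .groups = "drop")
  attr(profiles, "unknown") <- unknown
  profiles
}

#' Detect antibiotic escalation between consecutive windows
#'
#' Escalation in window `d` means: at least one agent in `d` was given
#' intravenously, and either the maximum antibiotic rank rose relative to
#' window `d - 1`, or it stayed equal while the number of distinct agents at
#' that rank rose. A previous window with no administrations (including the
#' start of observation) counts as rank "none", so a first intravenous course
#' is an escalation. A window with no administrations has no determination:
#' the result is `NA`.
#'
#' @param profile One-row profile (from [build_day_profiles()]) for window
#'   `d`, or `NULL` if the window had no administrations.
#' @param profile_prev Profile for window `d - 1`, or `NULL` if empty.
#' @return `TRUE`, `FALSE`, or `NA` (undefined: no administrations in `d`).
#' @export
detect_escalation <- function(profile, profile_prev = NULL) {
  if (is.null(profile) || !NROW(profile)) return(NA)
  prev_max <- if (is.null(profile_prev) || !NROW(profile_prev)) 0L else profile_prev$max_rank
  prev_n <- if (is.null(profile_prev) || !NROW(profile_prev)) 0L else profile_prev$n_at_max
  rose <- profile$max_rank > prev_max ||
    (profile$max_rank == prev_max && profile$n_at_max > prev_n)
  isTRUE(profile$any_iv) && rose
}

# Per-window escalation + prophylaxis flags for a whole store, over every
# window that had any antibiotic administration (before SDD filtering).
antibiotic_flags <- function(store, rank_map = default_antibiotic_ranks(),
                             day_range = c(-1L, 3L)) {
  abx <- store$events |>
    dplyr::filter(.data$concept == "antibiotic",
                  .data$day >= day_range[1], .data$day <= day_range[2])
  if (!nrow(abx)) {
    return(tibble::tibble(admissionid = character(0), day = integer(0),
                          escalation = logical(0), sdd_prophylaxis = logical(0)))
  }
  filt <- filter_sdd_prophylaxis(abx, rank_map)
  profiles <- build_day_profiles(filt$events, rank_map)

  # escalation for every raw antibiotic window; previous-day profile looked up
  # in the filtered profiles (empty if none)
  windows <- dplyr::distinct(abx, .data$admissionid, .data$day)
  key <- function(a, d) paste(a, d, sep = "\r")
  pidx <- stats::setNames(seq_len(nrow(profiles)),
                          key(profiles$admissionid, profiles$day))
  esc <- vapply(seq_len(nrow(windows)), function(i) {
    cur <- pidx[key(windows$admissionid[i], windows$day[i])]
    prv <- pidx[key(windows$admissionid[i], windows$day[i] - 1L)]
    detect_escalation(if (is.na(cur)) NULL else profiles[cur, ],
                      if (is.na(prv)) NULL else profiles[prv, ])
  }, logical(1))

  windows |>
    dplyr::mutate(escalation = esc) |>
    dplyr::left_join(filt$prophylaxis, by = c("admissionid", "day")) |>
    dplyr::mutate(sdd_prophylaxis = !is.na(.data$sdd_prophylaxis) &
                    .data$sdd_prophylaxis) |>
    dplyr::arrange(.data$admissionid, .data$day)
}
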