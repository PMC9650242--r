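# Synthetic cohort generator. Emits the four input CSV tables with *planted*
# per-window SOFA component scores and antibiotic schedules, plus a ground
# truth derived from the rules by direct construction at generation time —
# deliberately a second, separate implementation of the escalation/delta
# logic, so that recovery tests are a genuine two-implementation cross-check.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a synthetic scenario specification
#'
#' A scenario fixes, per admission, the planted SOFA component score for each
#' (day, component), the antibiotic schedule (canonical name, day, route),
#' and per-day lactate values. [generate_cohort()] inverts the scoring bands
#' to raw measurements and derives the ground truth.
#'
#' @param admissions Tibble with `admissionid, patientid, urgency, surgical,
#'   location`.
#' @param sofa_plan Tibble with `admissionid, day, component, score` (score
#'   0-4; omit rows for missing components).
#' @param abx_plan Tibble with `admissionid, day, name, route` (canonical
#'   antibiotic names; route `"IV"` or `"oral"`).
#' @param lactate_plan Tibble with `admissionid, day, value` (mmol/L).
#' @param day_range Integer `c(d_min, d_max)`.
#' @param seed Integer seed; identical spec + seed gives byte-identical CSVs.
#' @param margin Fraction of each scoring band's width kept clear of the band
#'   edges when drawing raw values (default 0.05), so recovered scores never
#'   sit on a threshold.
#' @param baseline_mode `"none"`, `"matched"` (admission-form sepsis flag
#'   emitted exactly where the ground truth has a sepsis episode at day -1 or
#'   0) or `"anti"` (flag emitted exactly where it has none).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(admissions, sofa_plan = NULL, abx_plan = NULL,
                          lactate_plan = NULL, day_range = c(-1L, 3L),
                          seed = 1L, margin = 0.05,
                          baseline_mode = c("none", "matched", "anti")) {
  baseline_mode <- match.arg(baseline_mode)
  empty_sofa <- tibble::tibble(admissionid = character(0), day = integer(0),
                               component = character(0), score = integer(0))
  empty_abx <- tibble::tibble(admissionid = character(0), day = integer(0),
                              name = character(0), route = character(0))
  empty_lac <- tibble::tibble(admissionid = character(0), day = integer(0),
                              value = numeric(0))
  if (is.null(sofa_plan)) sofa_plan <- empty_sofa
  if (is.null(abx_plan)) abx_plan <- empty_abx
  if (is.null(lactate_plan)) lactate_plan <- empty_lac
  stopifnot(day_range[1] <= 0, day_range[2] >= 0,
            all(sofa_plan$score >= 0 & sofa_plan$score <= 4))
  structure(list(admissions = admissions, sofa_plan = sofa_plan,
                 abx_plan = abx_plan, lactate_plan = lactate_plan,
                 day_range = as.integer(day_range), seed = as.integer(seed),
                 margin = margin, baseline_mode = baseline_mode),
            class = "scenario_spec")
}

# value intervals per (component, score) band; continuous unless `integer`
band_table <- function(thresholds) {
  rc <- thresholds$respiration$cutoffs
  cc <- thresholds$coagulation$cutoffs
  lc <- thresholds$liver$cutoffs
  kc <- thresholds$renal$creatinine_cutoffs
  list(
    respiration = list(c(rc[1], 80), c(rc[2], rc[1]), c(rc[3], rc[2]),
                       c(rc[4], rc[3]), c(4, rc[4])),
    coagulation = list(c(cc[1], 450), c(cc[2], cc[1]), c(cc[3], cc[2]),
                       c(cc[4], cc[3]), c(5, cc[4])),
    liver = list(c(3, lc[1]), c(lc[1], lc[2]), c(lc[2], lc[3]),
                 c(lc[3], lc[4]), c(lc[4], 420)),
    renal = list(c(45, kc[1]), c(kc[1], kc[2]), c(kc[2], kc[3]),
                 c(kc[3], kc[4]), c(kc[4], 700)))
}

draw_in_band <- function(interval, margin) {
  w <- (interval[2] - interval[1]) * margin
  stats::runif(1, interval[1] + w, interval[2] - w)
}

gcs_for_score <- function(score) {
  pool <- switch(as.character(score), "0" = 15L, "1" = 13:14, "2" = 10:12,
                 "3" = 6:9, "4" = 3:5)
  if (length(pool) == 1) pool else sample(pool, 1)
}

cardio_emission <- function(score, thresholds, margin) {
  tc <- thresholds$cardiovascular
  switch(as.character(score),
    "0" = list(item = "ABP mean", table = "numericitems",
               value = draw_in_band(c(tc$map_cutoff, 110), margin)),
    "1" = list(item = "ABP mean", table = "numericitems",
               value = draw_in_band(c(45, tc$map_cutoff), margin)),
    "2" = list(item = "Dopamine", table = "drugitems",
               value = draw_in_band(c(0.5, tc$dopamine_low), margin)),
    "3" = list(item = "Noradrenaline", table = "drugitems",
               value = draw_in_band(c(0.01, tc$norepinephrine), margin)),
    "4" = list(item = "Noradrenaline", table = "drugitems",
               value = draw_in_band(c(tc$norepinephrine, 1), margin)))
}

# canonical antibiotic name -> raw drugitems label in the default concept map
abx_item_label <- function(name) {
  map <- c("amoxicillin-clavulanate" = "Amoxicillin/clavulanate",
           "piperacillin-tazobactam" = "Piperacillin/tazobactam")
  ifelse(name %in% names(map), unname(map[name]),
         paste0(toupper(substring(name, 1, 1)), substring(name, 2)))
}

rand_offset <- function(n) round(stats::runif(n, 0, MS_PER_DAY - 1))

#' Generate a synthetic cohort on disk
#'
#' Writes `admissions.csv`, `numericitems.csv`, `drugitems.csv` and
#' `listitems.csv` into `dir`, drawing raw measurement values uniformly
#' inside the scoring band of each planted component score (respecting the
#' edge margin), and returns the table paths together with the independently
#' derived ground truth. Deterministic for a given spec and seed.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @param thresholds SOFA thresholds the bands are inverted against.
#' @param rank_map Antibiotic rank map used by the ground-truth derivation.
#' @return A list with `paths` (named vector for [read_tables()]), `truth`
#'   (tibble of expected per-window scores and flags) and `spec`.
#' @export
generate_cohort <- function(spec, dir,
                            thresholds = default_sofa_thresholds(),
                            rank_map = default_antibiotic_ranks()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bands <- band_table(thresholds)
  vfrom <- thresholds$respiration$ventilation_required_from

  truth <- derive_truth(spec, rank_map)

  with_seed(spec$seed, {
    adm <- spec$admissions
    num <- list(); drg <- list(); lst <- list()
    add_num <- function(a, item, value, d) {
      num[[length(num) + 1]] <<- tibble::tibble(
        admissionid = a, item = item, value = signif(value, 6), unit = "",
        measuredat = d * MS_PER_DAY + rand_offset(1))
    }
    add_drug <- function(a, item, dose, route, d) {
      drg[[length(drg) + 1]] <<- tibble::tibble(
        admissionid = a, item = item, dose = signif(dose, 6), doseunit = "",
        route = route, start = d * MS_PER_DAY + rand_offset(1))
    }
    add_list <- function(a, item, value, d) {
      lst[[length(lst) + 1]] <<- tibble::tibble(
        admissionid = a, item = item, value = value,
        measuredat = d * MS_PER_DAY + rand_offset(1))
    }

    sp <- spec$sofa_plan
    for (i in seq_len(nrow(sp))) {
      a <- sp$admissionid[i]; d <- sp$day[i]
      comp <- sp$component[i]; s <- sp$score[i]
      if (comp == "respiration") {
        ratio <- draw_in_band(bands$respiration[[s + 1]], spec$margin)
        fio2 <- 0.5
        add_num(a, "FiO2", fio2, d)
        add_num(a, "PaO2", ratio * fio2, d)
        if (s >= vfrom) add_list(a, "Mechanical ventilation", "True", d)
      } else if (comp == "coagulation") {
        add_num(a, "Platelets", draw_in_band(bands$coagulation[[s + 1]], spec$margin), d)
      } else if (comp == "liver") {
        add_num(a, "Bilirubin (total)", draw_in_band(bands$liver[[s + 1]], spec$margin), d)
      } else if (comp == "renal") {
        add_num(a, "Creatinine", draw_in_band(bands$renal[[s + 1]], spec$margin), d)
      } else if (comp == "cns") {
        add_num(a, "GCS total", gcs_for_score(s), d)
      } else if (comp == "cardiovascular") {
        em <- cardio_emission(s, thresholds, spec$margin)
        if (em$table == "numericitems") add_num(a, em$item, em$value, d)
        else add_drug(a, em$item, em$value, "IV", d)
      } else {
        stop("unknown component in sofa_plan: ", comp, call. = FALSE)
      }
    }

    ap <- spec$abx_plan
    for (i in seq_len(nrow(ap))) {
      add_drug(ap$admissionid[i], abx_item_label(ap$name[i]), 1000,
               ap$route[i], ap$day[i])
    }

    lp <- spec$lactate_plan
    for (i in seq_len(nrow(lp))) {
      add_num(lp$admissionid[i], "Lactate", lp$value[i], lp$day[i])
    }

    if (spec$baseline_mode != "none" && nrow(adm)) {
      at_adm <- truth |>
        dplyr::filter(.data$day %in% c(-1L, 0L)) |>
        dplyr::group_by(.data$admissionid) |>
        dplyr::summarise(sep = any(.data$sepsis_episode), .groups = "drop")
      sep_ids <- at_adm$admissionid[at_adm$sep]
      flag_ids <- if (spec$baseline_mode == "matched") sep_ids
                  else setdiff(adm$admissionid, sep_ids)
      for (a in flag_ids) add_list(a, "Sepsis at admission", "True", 0L)
    }

    paths <- c(admissions = file.path(dir, "admissions.csv"),
               numericitems = file.path(dir, "numericitems.csv"),
               drugitems = file.path(dir, "drugitems.csv"),
               listitems = file.path(dir, "listitems.csv"))
    adm_out <- tibble::tibble(
      admissionid = adm$admissionid, patientid = adm$patientid,
      admittedat = 0, urgency = ifelse(adm$urgency, "True", "False"),
      surgical = ifelse(adm$surgical, "True", "False"), location = adm$location)
    readr::write_csv(adm_out, paths["admissions"], progress = FALSE)
    bind_or_empty <- function(rows, proto) {
      if (length(rows)) dplyr::bind_rows(rows) else proto
    }
    readr::write_csv(bind_or_empty(num, tibble::tibble(
      admissionid = character(0), item = character(0), value = numeric(0),
      unit = character(0), measuredat = numeric(0))),
      paths["numericitems"], progress = FALSE)
    readr::write_csv(bind_or_empty(drg, tibble::tibble(
      admissionid = character(0), item = character(0), dose = numeric(0),
      doseunit = character(0), route = character(0), start = numeric(0))),
      paths["drugitems"], progress = FALSE)
    readr::write_csv(bind_or_empty(lst, tibble::tibble(
      admissionid = character(0), item = character(0), value = character(0),
      measuredat = numeric(0))),
      paths["listitems"], progress = FALSE)

    list(paths = paths, truth = truth, spec = spec)
  })
}

# Ground truth by direct rule application to the plan (independent of the
# pipeline code paths).
derive_truth <- function(spec, rank_map = default_antibiotic_ranks()) {
  dr <- spec$day_range
  comps <- c("respiration", "coagulation", "liver", "cardiovascular", "cns",
             "renal")
  out <- list()
  for (a in spec$admissions$admissionid) {
    sp <- spec$sofa_plan[spec$sofa_plan$admissionid == a, , drop = FALSE]
    ap <- spec$abx_plan[spec$abx_plan$admissionid == a, , drop = FALSE]
    lp <- spec$lactate_plan[spec$lactate_plan$admissionid == a, , drop = FALSE]
    arow <- spec$admissions[spec$admissions$admissionid == a, ]
    elective <- !arow$urgency && arow$surgical

    days <- sort(unique(c(sp$day, ap$day, 0L)))
    days <- days[days >= dr[1] & days <= dr[2]]

    total_of <- function(d) {
      if (d < dr[1] || d > dr[2]) return(NA_real_)
      sum(sp$score[sp$day == d])
    }
    comp_of <- function(d, comp) {
      v <- sp$score[sp$day == d & sp$component == comp]
      if (length(v)) v[1] else NA_integer_
    }

    # SDD exclusion on the schedule
    nm <- normalise_antibiotic(ap$name, rank_map)
    excl <- nm %in% rank_map$sdd$drugs & ap$day %in% rank_map$sdd$days
    kept <- ap[!excl, , drop = FALSE]
    kept_nm <- nm[!excl]

    prof_of <- function(d) {
      idx <- which(kept$day == d)
      if (!length(idx)) return(NULL)
      agents <- unique(tibble::tibble(name = kept_nm[idx],
                                      iv = kept$route[idx] == "IV") |>
                         dplyr::group_by(.data$name) |>
                         dplyr::summarise(iv = any(.data$iv), .groups = "drop"))
      rk <- unname(rank_map$ranks[agents$name])
      list(max_rank = max(rk), n_at_max = sum(rk == max(rk)),
           any_iv = any(agents$iv))
    }

    peri <- NA_integer_
    if (elective) {
      cand <- intersect(unique(ap$day), c(-1L, 0L))
      if (length(cand)) peri <- min(cand)
    }

    rows <- lapply(days, function(d) {
      scores <- vapply(comps, function(cc) comp_of(d, cc), integer(1))
      n_missing <- sum(is.na(scores))
      total <- sum(scores, na.rm = TRUE)
      has_raw <- any(ap$day == d)
      p_cur <- prof_of(d)
      esc <- if (!has_raw || is.null(p_cur)) NA else {
        p_prev <- prof_of(d - 1L)
        pm <- if (is.null(p_prev)) 0 else p_prev$max_rank
        pn <- if (is.null(p_prev)) 0 else p_prev$n_at_max
        p_cur$any_iv && (p_cur$max_rank > pm ||
                           (p_cur$max_rank == pm && p_cur$n_at_max > pn))
      }
      proph <- (has_raw && all(excl[ap$day == d])) ||
        (!is.na(peri) && d == peri)
      suppressed <- !is.na(peri) && d %in% c(peri, peri + 1L)
      infection <- isTRUE(esc) && !proph && !suppressed
      deltas <- c(total_of(d) - total_of(d - 1L),
                  total_of(d + 1L) - total_of(d - 1L),
                  total_of(d + 1L) - total_of(d))
      delta <- any(deltas >= 2, na.rm = TRUE)
      indeterminate <- d >= 0L && n_missing >= 3L
      sepsis <- infection && delta && !indeterminate
      lac <- lp$value[lp$day == d]
      shock <- sepsis && !is.na(scores["cardiovascular"]) &&
        scores["cardiovascular"] >= 3L && length(lac) > 0 && max(lac) >= 2
      tibble::tibble(admissionid = a, day = d,
                     respiration = scores[["respiration"]],
                     coagulation = scores[["coagulation"]],
                     liver = scores[["liver"]],
                     cardiovascular = scores[["cardiovascular"]],
                     cns = scores[["cns"]],
                     renal = scores[["renal"]],
                     total = as.integer(total),
                     n_missing = as.integer(n_missing),
                     escalation = esc, prophylaxis = proph,
                     infection = infection, sepsis_episode = sepsis,
                     septic_shock = shock)
    })
    out[[a]] <- dplyr::bind_rows(rows)
  }
  if (!length(out)) {
    return(tibble::tibble(admissionid = character(0), day = integer(0),
                          respiration = integer(0), coagulation = integer(0),
                          liver = integer(0), cardiovascular = integer(0),
                          cns = integer(0), renal = integer(0),
                          total = integer(0), n_missing = integer(0),
                          escalation = logical(0), prophylaxis = logical(0),
                          infection = logical(0), sepsis_episode = logical(0),
                          septic_shock = logical(0)))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$admissionid, .data$day)
}

#' Worked-example fixture
#'
#' A four-admission scenario (ids 0-3) whose generated tables, run through
#' [run_pipeline()] with the default configuration over days -3..1, reproduce
#' the package's reference example output tables cell for cell: two elective
#' surgical admissions with perioperative prophylactic antibiotics, and two
#' urgent admissions that develop an antibiotic-escalation-plus-SOFA-rise
#' sepsis episode in the pre-admission window.
#'
#' @return A [scenario_spec()] (day range -3..1, fixed seed).
#' @export
tables23_fixture <- function() {
  admissions <- tibble::tibble(
    admissionid = c("0", "1", "2", "3"),
    patientid = c("p0", "p1", "p2", "p3"),
    urgency = c(FALSE, FALSE, TRUE, TRUE),
    surgical = c(TRUE, TRUE, FALSE, FALSE),
    location = "ICU")
  sofa_plan <- dplyr::bind_rows(
    tibble::tribble(
      ~day, ~component, ~score,
      -1L, "coagulation", 0L,
      -1L, "renal", 0L,
      0L, "respiration", 3L,
      0L, "coagulation", 0L,
      0L, "cardiovascular", 1L,
      0L, "cns", 0L,
      0L, "renal", 0L,
      1L, "respiration", 2L,
      1L, "coagulation", 1L,
      1L, "cardiovascular", 2L,
      1L, "renal", 0L) |> dplyr::mutate(admissionid = "0"),
    tibble::tribble(
      ~day, ~component, ~score,
      -1L, "coagulation", 1L,
      -1L, "renal", 0L,
      0L, "respiration", 2L,
      0L, "coagulation", 0L,
      0L, "cardiovascular", 2L,
      0L, "cns", 0L,
      0L, "renal", 0L,
      1L, "cardiovascular", 0L,
      1L, "renal", 0L) |> dplyr::mutate(admissionid = "1"),
    tibble::tribble(
      ~day, ~component, ~score,
      -2L, "coagulation", 0L,
      -2L, "liver", 0L,
      -2L, "renal", 0L,
      -1L, "coagulation", 1L,
      0L, "respiration", 2L,
      0L, "coagulation", 0L,
      0L, "cardiovascular", 4L,
      0L, "cns", 0L,
      0L, "renal", 0L) |> dplyr::mutate(admissionid = "2"),
    tibble::tribble(
      ~day, ~component, ~score,
      -3L, "coagulation", 0L,
      -3L, "renal", 1L,
      0L, "respiration", 2L,
      0L, "coagulation", 0L,
      0L, "cardiovascular", 0L,
      0L, "renal", 1L) |> dplyr::mutate(admissionid = "3")) |>
    dplyr::select("admissionid", "day", "component", "score")
  abx_plan <- tibble::tribble(
    ~admissionid, ~day, ~name, ~route,
    "0", -1L, "cefazolin", "IV",
    "0", 0L, "cefazolin", "IV",
    "1", -1L, "cefazolin", "IV",
    "1", 0L, "cefazolin", "IV",
    "2", -1L, "ceftriaxone", "IV",
    "2", 0L, "ceftriaxone", "IV",
    "3", -1L, "vancomycin", "IV",
    "3", 0L, "vancomycin", "IV")
  scenario_spec(admissions, sofa_plan, abx_plan, day_range = c(-3L, 1L),
                seed = 1203L)
}

#' Random synthetic scenario
#'
#' Draws a cohort of `n` admissions with random elective-surgery status,
#' random per-window component scores and missingness, antibiotic courses
#' (with occasional mid-stay escalations and SDD cefotaxime regimens), and
#' lactate trajectories kept clear of the shock threshold. The emulation is
#' deliberately coarse — independent draws per window, no physiological
#' autocorrelation, no real item vocabulary — because its purpose is rule
#' verification, not realism.
#'
#' @param n Number of admissions.
#' @param seed Integer seed.
#' @param day_range Integer `c(d_min, d_max)` (default -1..3).
#' @param baseline_mode Passed to [scenario_spec()].
#' @return A [scenario_spec()].
#' @export
random_scenario <- function(n, seed, day_range = c(-1L, 3L),
                            baseline_mode = c("none", "matched", "anti")) {
  baseline_mode <- match.arg(baseline_mode)
  comps <- c("respiration", "coagulation", "liver", "cardiovascular", "cns",
             "renal")
  formulary <- names(default_antibiotic_ranks()$ranks)
  ranks <- default_antibiotic_ranks()$ranks
  with_seed(seed, {
    matched <- baseline_mode != "none"
    admissions <- tibble::tibble(
      admissionid = sprintf("S%04d", seq_len(n)),
      patientid = sprintf("P%04d", seq_len(n)),
      urgency = if (matched) rep(TRUE, n) else stats::runif(n) > 0.2,
      surgical = NA,
      location = ifelse(stats::runif(n) < 0.15, "MCU", "ICU"))
    admissions$surgical <- ifelse(!admissions$urgency, TRUE,
                                  !matched & stats::runif(n) < 0.3)
    sofa <- list(); abx <- list(); lac <- list()
    for (i in seq_len(n)) {
      a <- admissions$admissionid[i]
      for (d in seq(day_range[1], day_range[2])) {
        p_present <- if (d < 0) 0.3 else 0.75
        present <- stats::runif(6) < p_present
        if (any(present)) {
          sofa[[length(sofa) + 1]] <- tibble::tibble(
            admissionid = a, day = as.integer(d), component = comps[present],
            score = sample(0:4, sum(present), replace = TRUE,
                           prob = c(0.45, 0.25, 0.15, 0.1, 0.05)))
        }
        if (stats::runif(1) < 0.4) {
          lv <- if (stats::runif(1) < 0.5) stats::runif(1, 0.6, 1.8)
                else stats::runif(1, 2.2, 6)
          lac[[length(lac) + 1]] <- tibble::tibble(
            admissionid = a, day = as.integer(d), value = round(lv, 2))
        }
      }
      if (stats::runif(1) < 0.6) {
        drug <- sample(formulary, 1)
        ds <- sample(seq(day_range[1], day_range[2]), 1)
        len <- sample(1:3, 1)
        route <- if (stats::runif(1) < 0.85) "IV" else "oral"
        for (d in ds:min(ds + len - 1, day_range[2])) {
          abx[[length(abx) + 1]] <- tibble::tibble(
            admissionid = a, day = as.integer(d), name = drug, route = route)
        }
        if (stats::runif(1) < 0.35) {
          broader <- formulary[ranks > ranks[drug]]
          if (length(broader) && ds + 1 <= day_range[2]) {
            drug2 <- sample(broader, 1)
            d2 <- sample(seq(min(ds + 1, day_range[2]), day_range[2]), 1)
            abx[[length(abx) + 1]] <- tibble::tibble(
              admissionid = a, day = as.integer(d2), name = drug2, route = "IV")
          }
        }
      }
      if (stats::runif(1) < 0.3) {
        for (d in intersect(0:3, seq(day_range[1], day_range[2]))) {
          abx[[length(abx) + 1]] <- tibble::tibble(
            admissionid = a, day = as.integer(d), name = "cefotaxime",
            route = "IV")
        }
      }
      if (!admissions$urgency[i] && admissions$surgical[i] &&
            stats::runif(1) < 0.9) {
        abx[[length(abx) + 1]] <- tibble::tibble(
          admissionid = a, day = sample(c(-1L, 0L), 1), name = "cefazolin",
          route = "IV")
      }
    }
    scenario_spec(admissions,
                  if (length(sofa)) dplyr::bind_rows(sofa),
                  if (length(abx)) dplyr::bind_rows(abx),
                  if (length(lac)) dplyr::bind_rows(lac),
                  day_range = day_range, seed = seed + 1L,
                  baseline_mode = baseline_mode)
  })
}
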