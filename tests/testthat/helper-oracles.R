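# Independent oracles: exhaustive band scans and direct-definition checks,
# kept deliberately separate from the package's scoring arithmetic.

oracle_band_ok <- function(component, s, agg) {
  in_iv <- function(x, lo, hi) !is.na(x) && x >= lo && x < hi
  switch(component,
    coagulation = {
      p <- agg$platelets
      if (is.na(p)) return(NA)
      switch(as.character(s),
             "4" = in_iv(p, -Inf, 20), "3" = in_iv(p, 20, 50),
             "2" = in_iv(p, 50, 100), "1" = in_iv(p, 100, 150),
             "0" = in_iv(p, 150, Inf))
    },
    liver = {
      b <- agg$bilirubin
      if (is.na(b)) return(NA)
      switch(as.character(s),
             "4" = in_iv(b, 204, Inf), "3" = in_iv(b, 102, 204),
             "2" = in_iv(b, 33, 102), "1" = in_iv(b, 20, 33),
             "0" = in_iv(b, -Inf, 20))
    },
    cns = {
      g <- agg$gcs
      if (is.na(g)) return(NA)
      switch(as.character(s),
             "4" = in_iv(g, -Inf, 6), "3" = in_iv(g, 6, 10),
             "2" = in_iv(g, 10, 13), "1" = in_iv(g, 13, 15),
             "0" = in_iv(g, 15, Inf))
    },
    respiration = {
      pao2 <- agg$pao2; fio2 <- agg$fio2
      if (is.na(pao2) || is.na(fio2)) return(NA)
      if (fio2 > 1) fio2 <- fio2 / 100
      r <- pao2 / fio2
      vent <- isTRUE(agg$ventilated)
      raw <- if (in_iv(r, -Inf, 13.3)) 4 else if (in_iv(r, 13.3, 26.7)) 3
             else if (in_iv(r, 26.7, 40)) 2 else if (in_iv(r, 40, 53.3)) 1 else 0
      if (raw >= 3 && !vent) raw <- 2
      s == raw
    },
    renal = {
      cr <- agg$creatinine; u <- agg$urine_output
      if (is.na(cr) && is.na(u)) return(NA)
      crs <- if (is.na(cr)) 0 else if (cr >= 440) 4 else if (cr >= 300) 3
             else if (cr >= 171) 2 else if (cr >= 110) 1 else 0
      us <- if (is.na(u)) 0 else if (u < 200) 4 else if (u < 500) 3 else 0
      s == max(crs, us)
    },
    cardiovascular = {
      cand <- integer(0)
      if (!is.na(agg$map)) cand <- c(cand, if (agg$map < 70) 1L else 0L)
      if (!is.na(agg$dopamine) && agg$dopamine > 0) {
        cand <- c(cand, if (agg$dopamine > 15) 4L else if (agg$dopamine > 5) 3L else 2L)
      }
      if (!is.na(agg$dobutamine) && agg$dobutamine > 0) cand <- c(cand, 2L)
      if (!is.na(agg$norepinephrine) && agg$norepinephrine > 0) {
        cand <- c(cand, if (agg$norepinephrine > 0.1) 4L else 3L)
      }
      if (!is.na(agg$epinephrine) && agg$epinephrine > 0) {
        cand <- c(cand, if (agg$epinephrine > 0.1) 4L else 3L)
      }
      if (!length(cand)) return(NA)
      s == max(cand)
    })
}

# scan all bands 0..4, return the (unique) score whose band matches
oracle_sofa_score <- function(component, agg) {
  for (s in 4:0) {
    ok <- oracle_band_ok(component, s, agg)
    if (is.na(ok)) return(NA_integer_)
    if (isTRUE(ok)) return(s)
  }
  NA_integer_
}

# random worst-in-window aggregates for a component (NA = absent)
random_aggregates <- function(component) {
  maybe <- function(v, p = 0.85) if (stats::runif(1) < p) v else NA_real_
  switch(component,
    coagulation = list(platelets = maybe(stats::runif(1, 1, 450))),
    liver = list(bilirubin = maybe(stats::runif(1, 1, 420))),
    cns = list(gcs = maybe(sample(3:15, 1))),
    respiration = list(pao2 = maybe(stats::runif(1, 3, 60)),
                       fio2 = maybe(sample(c(stats::runif(1, 0.21, 1),
                                             stats::runif(1, 21, 100)), 1)),
                       ventilated = stats::runif(1) < 0.5),
    renal = list(creatinine = maybe(stats::runif(1, 30, 700), 0.7),
                 urine_output = maybe(stats::runif(1, 0, 3000), 0.5)),
    cardiovascular = list(map = maybe(stats::runif(1, 30, 120), 0.6),
                          dopamine = maybe(stats::runif(1, 0.1, 25), 0.3),
                          norepinephrine = maybe(stats::runif(1, 0.01, 1), 0.3),
                          epinephrine = maybe(stats::runif(1, 0.01, 1), 0.2),
                          dobutamine = maybe(stats::runif(1, 1, 10), 0.2)))
}

# direct-definition escalation check on raw agent sets
oracle_escalation <- function(cur, prev) {
  if (is.null(cur) || nrow(cur) == 0) return(NA)
  if (!any(cur$iv)) return(FALSE)
  cm <- max(cur$rank)
  cn <- length(unique(cur$name[cur$rank == cm]))
  pm <- 0; pn <- 0
  if (!is.null(prev) && nrow(prev) > 0) {
    pm <- max(prev$rank)
    pn <- length(unique(prev$name[prev$rank == pm]))
  }
  (cm > pm) || (cm == pm && cn > pn)
}

# enumerate all agent-set states over a pool (absent / IV / oral per agent)
enumerate_profile_sets <- function(pool = tibble::tibble(
                                     name = c("a", "b", "c", "d"),
                                     rank = c(1L, 2L, 2L, 3L))) {
  states <- expand.grid(rep(list(0:2), nrow(pool)))
  lapply(seq_len(nrow(states)), function(i) {
    st <- as.integer(states[i, ])
    keep <- st > 0
    if (!any(keep)) return(tibble::tibble(name = character(0),
                                          rank = integer(0), iv = logical(0)))
    tibble::tibble(name = pool$name[keep], rank = pool$rank[keep],
                   iv = st[keep] == 1)
  })
}

oracle_delta <- function(prev, cur, nxt, min_rise = 2) {
  any(c(cur - prev, nxt - prev, nxt - cur) >= min_rise, na.rm = TRUE)
}

# profile tibble (as from build_day_profiles) for a raw agent set
profile_from_agents <- function(agents) {
  if (nrow(agents) == 0) return(NULL)
  ag <- dplyr::summarise(dplyr::group_by(agents, name, rank),
                         iv = any(iv), .groups = "drop")
  tibble::tibble(max_rank = max(ag$rank),
                 n_at_max = sum(ag$rank == max(ag$rank)),
                 any_iv = any(ag$iv))
}
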