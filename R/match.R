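#' Sequential risk-set matching on the time-varying propensity score
#'
#' Processes observed switch events in calendar order (same-day events in
#' seeded-random order). At each event the risk set contains persons who are
#' switch-eligible by the event date, still enrolled, still TDF-only (their
#' own switch, if any, is later), and not yet consumed by an earlier matched
#' set in either role. The switcher and candidates are scored with the
#' extended Cox linear predictor using covariate values current at the event
#' date, and up to `ratio` nearest candidates by absolute score difference
#' (optionally within `caliper`) are selected without replacement;
#' equal-distance ties are broken by a seeded random draw. A person consumed
#' as a control whose own switch comes later is removed from the switcher
#' stream and permanently labeled a nonswitcher; sets with fewer than
#' `ratio` available controls are retained at reduced ratio, and a switcher
#' facing an empty risk set is discarded.
#'
#' @param model a [fit_tvps_model()] object, or a function
#'   `(profiles, comorbidities, ids, date) -> scores` (useful for testing
#'   with hand-assigned scores)
#' @param profiles imputed covariate profiles of the included cohort
#' @param comorbidities comorbidity onsets table
#' @param switch_dates data.frame `person_id`, `switch_date` (NA = never
#'   switched); only included persons are considered
#' @param persons persons table (for enrollment intervals)
#' @param ratio maximum controls per switcher
#' @param caliper maximum |score difference| allowed (default none)
#' @param seed seed for tie-breaking
#' @param study_end switch events after this date are not matched
#' @param log optional pipeline log
#' @return data.frame of class `matched_sets`: one row per
#'   switcher-control pair (`set_id`, `switcher_id`, `switch_date`,
#'   `control_id`, `score_distance`, `control_rank`), with attributes
#'   `reclassified` (ids dropped from the switcher stream) and
#'   `unmatched` (ids discarded for empty risk sets)
#' @export
sequential_match <- function(model, profiles, comorbidities, switch_dates,
                             persons, ratio = 4, caliper = Inf, seed = 1L,
                             study_end = as.Date("2022-06-30"), log = NULL) {
  sd_in <- switch_dates[switch_dates$person_id %in% profiles$person_id, ,
                        drop = FALSE]
  ev <- sd_in[!is.na(sd_in$switch_date) & sd_in$switch_date <= study_end, ,
              drop = FALSE]
  set.seed(sub_seed(seed, 11L))
  ev <- ev[order(ev$switch_date, stats::runif(nrow(ev))), , drop = FALSE]

  dis <- persons$disenrollment_date[match(profiles$person_id,
                                          persons$person_id)]
  sw_all <- sd_in$switch_date[match(profiles$person_id, sd_in$person_id)]
  elig <- profiles$switch_eligible_date

  consumed <- logical(nrow(profiles))
  names(consumed) <- profiles$person_id
  reclassified <- integer(0)
  unmatched <- integer(0)
  out <- list()
  set_id <- 0L
  for (e in seq_len(nrow(ev))) {
    pid <- ev$person_id[e]
    d <- ev$switch_date[e]
    pk <- match(pid, profiles$person_id)
    if (consumed[pk]) {
      reclassified <- c(reclassified, pid)
      log_msg(log, sprintf(
        "match: person %d already consumed as control; treated as nonswitcher", pid))
      next
    }
    risk <- which(!consumed &
                    elig <= d &
                    (is.na(sw_all) | sw_all > d) &
                    (is.na(dis) | dis > d) &
                    profiles$person_id != pid)
    if (!length(risk)) {
      consumed[pk] <- TRUE
      unmatched <- c(unmatched, pid)
      log_msg(log, sprintf("match: empty risk set for switcher %d on %s; discarded",
                           pid, format(d)))
      next
    }
    ids <- c(pid, profiles$person_id[risk])
    sc <- if (is.function(model)) model(profiles, comorbidities, ids, d) else
      tvps_score(model, profiles, comorbidities, ids, d)
    dist <- abs(sc[-1] - sc[1])
    ok <- dist <= caliper
    if (!any(ok)) {
      consumed[pk] <- TRUE
      unmatched <- c(unmatched, pid)
      log_msg(log, sprintf("match: no candidate within caliper for switcher %d", pid))
      next
    }
    ordc <- order(dist, stats::runif(length(dist)))
    ordc <- ordc[ok[ordc]]
    sel <- ordc[seq_len(min(ratio, length(ordc)))]
    set_id <- set_id + 1L
    out[[set_id]] <- data.frame(
      set_id = set_id,
      switcher_id = pid,
      switch_date = d,
      control_id = profiles$person_id[risk][sel],
      score_distance = dist[sel],
      control_rank = seq_along(sel),
      stringsAsFactors = FALSE
    )
    consumed[pk] <- TRUE
    consumed[risk[sel]] <- TRUE
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(set_id = integer(0), switcher_id = integer(0),
               switch_date = as.Date(character(0)), control_id = integer(0),
               score_distance = numeric(0), control_rank = integer(0))
  rownames(res) <- NULL
  log_count(log, "switch_events_observed", nrow(ev))
  log_count(log, "switchers_reclassified_as_controls", length(reclassified))
  log_count(log, "switchers_unmatched_empty_risk_set", length(unmatched))
  log_count(log, "matched_sets", length(unique(res$set_id)))
  log_count(log, "matched_controls", nrow(res))
  structure(res, reclassified = reclassified, unmatched = unmatched,
            class = c("matched_sets", "data.frame"))
}

#' Assign follow-up index dates to a matched cohort
#'
#' Switchers' index date is their switch date. Each matched nonswitcher
#' receives as index date their own switch-eligible date plus the matched
#' switcher's eligibility-to-switch interval (in days), preserving the
#' distribution of eligibility-to-index intervals across arms — the
#' immortal-time-safe assignment. Controls whose assigned index date falls
#' after their disenrollment or the study end are dropped; sets left with no
#' controls are dropped entirely.
#'
#' @param matched output of [sequential_match()]
#' @param profiles covariate profiles (for eligible dates)
#' @param persons persons table
#' @param study_end study end date
#' @param log optional pipeline log
#' @return data.frame `person_id`, `arm`, `set_id`, `eligible_date`,
#'   `index_date`, one row per person
#' @export
assign_index_dates <- function(matched, profiles, persons,
                               study_end = as.Date("2022-06-30"), log = NULL) {
  if (!nrow(matched)) stop("no matched sets to index")
  elig_of <- function(id) profiles$switch_eligible_date[
    match(id, profiles$person_id)]
  dis_of <- function(id) persons$disenrollment_date[
    match(id, persons$person_id)]

  sw <- unique(matched[, c("set_id", "switcher_id", "switch_date")])
  sw$eligible_date <- elig_of(sw$switcher_id)
  sw$interval <- as.numeric(sw$switch_date - sw$eligible_date)
  if (any(sw$interval < 0)) stop("switch date precedes eligibility")

  ctl <- matched
  ctl$eligible_date <- elig_of(ctl$control_id)
  ctl$interval <- sw$interval[match(ctl$set_id, sw$set_id)]
  ctl$index_date <- ctl$eligible_date + ctl$interval
  dis <- dis_of(ctl$control_id)
  drop <- ctl$index_date > study_end |
    (!is.na(dis) & ctl$index_date > dis)
  if (any(drop)) {
    log_msg(log, sprintf(
      "index: dropped %d controls with index date beyond study end/disenrollment",
      sum(drop)))
  }
  ctl <- ctl[!drop, , drop = FALSE]
  keep_sets <- intersect(sw$set_id, ctl$set_id)
  lost <- setdiff(sw$set_id, keep_sets)
  if (length(lost)) {
    log_msg(log, sprintf("index: dropped %d sets left without controls",
                         length(lost)))
  }

  out <- rbind(
    data.frame(person_id = sw$switcher_id[sw$set_id %in% keep_sets],
               arm = "switcher",
               set_id = sw$set_id[sw$set_id %in% keep_sets],
               eligible_date = sw$eligible_date[sw$set_id %in% keep_sets],
               index_date = sw$switch_date[sw$set_id %in% keep_sets],
               stringsAsFactors = FALSE),
    data.frame(person_id = ctl$control_id, arm = "nonswitcher",
               set_id = ctl$set_id, eligible_date = ctl$eligible_date,
               index_date = ctl$index_date, stringsAsFactors = FALSE)
  )
  out <- out[order(out$set_id, out$arm != "switcher", out$person_id), ]
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$person_id))
  log_count(log, "indexed_switchers", sum(out$arm == "switcher"))
  log_count(log, "indexed_nonswitchers", sum(out$arm == "nonswitcher"))
  out
}
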