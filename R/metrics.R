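# A priori recognition metrics on AAE decompositions.
#
# Five metric families, all pure set/count functions of the decomposition:
#  - participation counters Ca(ek|Ai), Ca(ek), CA(ek), CA(aj): in how many
#    actions/activities an event or action takes part;
#  - sharing rates Se(aj|ak), Sa(Ai|Aj), Se(Ai|Aj): asymmetric overlap
#    fractions between event or action sets;
#  - weights W(ek|aj), W(aj|Ai), W(ek|Ai): inverse-size importance of an
#    element within its container;
#  - elementary contributions F(ek|Ai) = Ca(ek|Ai)/sum_i Ca(ek|Ai) and
#    F(aj|Ai) = 1/CA(aj): participation in one activity normalized by
#    participation everywhere;
#  - distinguishabilities De(Ai), Da(Ai): mean elementary contribution of
#    an activity's events / actions; 1 means separable a priori.
#
# Counters are set-membership counts and ignore edge multiplicities even in
# weighted mode; multiplicities only enter the weight family. All averaging
# is done in exact rational arithmetic (see rational.R).

check_activity <- function(x, activity) {
  if (!activity %in% activity_ids(x)) {
    stop("unknown activity id '", activity, "'", call. = FALSE)
  }
  invisible(activity)
}

# per-activity participation counter row for one event label
ca_row <- function(x, event) {
  acts <- activity_ids(x)
  if (inherits(x, "incidence_fixture")) {
    if (event %in% rownames(x$counts)) {
      out <- x$counts[event, ]
    } else {
      out <- stats::setNames(integer(length(acts)), acts)
    }
    return(out)
  }
  vapply(acts, function(Ai) {
    sum(vapply(activity_actions(x, Ai), function(aj) {
      event %in% names(x$actions[[aj]]$events)
    }, logical(1)))
  }, integer(1))
}

#' Participation counter of an event in an activity: Ca(ek|Ai)
#'
#' The number of actions of activity `Ai` whose event set contains the
#' event. Labels absent from the activity (or from the whole model) count
#' zero. Set membership only: edge multiplicities do not raise the count.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param event Event label.
#' @param activity Activity id.
#' @return Non-negative integer.
#' @export
count_actions_with_event_in_activity <- function(x, event, activity) {
  check_activity(x, activity)
  unname(ca_row(x, event)[activity])
}

#' Participation counter of an event over all actions: Ca(ek)
#'
#' The number of actions in the whole model (each shared action counted
#' once) whose event set contains the event.
#'
#' @inheritParams count_actions_with_event_in_activity
#' @return Non-negative integer.
#' @export
count_actions_with_event <- function(x, event) {
  if (inherits(x, "incidence_fixture")) {
    # fixture actions each belong to one activity, so the union action set
    # is the disjoint union of the per-activity sets
    return(unname(sum(ca_row(x, event))))
  }
  sum(vapply(x$actions, function(a) event %in% names(a$events), logical(1)))
}

#' Participation counter of an event over activities: CA(ek)
#'
#' The number of activities whose event set contains the event. An event
#' with CA(ek) = 1 is differentiating; a high CA(ek) means its occurrence
#' says little about which activity is in progress.
#'
#' @inheritParams count_actions_with_event_in_activity
#' @return Non-negative integer.
#' @export
count_activities_with_event <- function(x, event) {
  unname(sum(ca_row(x, event) > 0))
}

#' Participation counter of an action over activities: CA(aj)
#'
#' The number of activities containing the action; 1 for every action when
#' shared actions are disallowed.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param action Action id.
#' @return Positive integer.
#' @export
count_activities_with_action <- function(x, action) {
  if (inherits(x, "incidence_fixture")) {
    if (!action %in% names(x$action_membership)) {
      stop("unknown action id '", action, "'", call. = FALSE)
    }
    return(1L)
  }
  if (!action %in% names(x$actions)) {
    stop("unknown action id '", action, "'", call. = FALSE)
  }
  sum(vapply(x$activities, function(A) action %in% A$actions, logical(1)))
}

#' Event sharing rate between actions: Se(aj|ak)
#'
#' The fraction of `action`'s events also belonging to `other`:
#' |Se(aj) n Se(ak)| / |Se(aj)|. Asymmetric; the self-rate is 1.
#'
#' @param dec An `aae_decomposition` (a fixture does not carry
#'   event-to-action wiring).
#' @param action,other Action ids.
#' @return Number in \[0, 1\].
#' @export
event_sharing_rate_actions <- function(dec, action, other) {
  need_full_decomposition(dec, "Se(aj|ak)")
  ej <- names(action_events(dec, action))
  ek <- names(action_events(dec, other))
  length(intersect(ej, ek)) / length(ej)
}

#' Action sharing rate between activities: Sa(Ai|Aj)
#'
#' The fraction of `activity`'s actions also belonging to `other`. Always
#' 0 off-diagonal when shared actions are disallowed.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param activity,other Activity ids.
#' @return Number in \[0, 1\].
#' @export
action_sharing_rate_activities <- function(x, activity, other) {
  check_activity(x, activity)
  check_activity(x, other)
  if (inherits(x, "incidence_fixture")) {
    aset <- names(x$action_membership)[x$action_membership == activity]
    bset <- names(x$action_membership)[x$action_membership == other]
  } else {
    aset <- activity_actions(x, activity)
    bset <- activity_actions(x, other)
  }
  length(intersect(aset, bset)) / length(aset)
}

#' Event sharing rate between activities: Se(Ai|Aj)
#'
#' The fraction of `activity`'s events also belonging to the union of the
#' `others`' event sets. With a single other activity this is the pairwise
#' rate; with several, the multi-object rate
#' |Se(Ai) n (Se(Aj) u Se(Ak) u ...)| / |Se(Ai)|. An activity sharing all
#' its events with the rest (rate 1) may be unrecognizable; the
#' acceptable level is case-specific (see [analyzer_config()]).
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param activity Activity id.
#' @param others One or more activity ids whose event sets are unioned.
#' @return Number in \[0, 1\].
#' @export
event_sharing_rate_activities <- function(x, activity, others) {
  check_activity(x, activity)
  for (o in others) check_activity(x, o)
  ei <- activity_events(x, activity)
  ej <- unique(unlist(lapply(others, function(o) activity_events(x, o)),
                      use.names = FALSE))
  length(intersect(ei, ej)) / length(ei)
}

#' Weight of an event in an action: W(ek|aj)
#'
#' Inverse-size importance of the event within its action. Unweighted
#' edges give 1/|Se(aj)|; with weighted edges the numerator is the event's
#' multiplicity and the denominator the action's total multiplicity mass.
#'
#' @param dec An `aae_decomposition`.
#' @param event Event label; must belong to the action.
#' @param action Action id.
#' @return Number in (0, 1\].
#' @export
weight_event_in_action <- function(dec, event, action) {
  need_full_decomposition(dec, "W(ek|aj)")
  ev <- action_events(dec, action)
  if (!event %in% names(ev)) {
    stop("event '", event, "' is not in action '", action, "'",
         call. = FALSE)
  }
  unname(ev[event]) / sum(ev)
}

#' Weight of an action in an activity: W(aj|Ai)
#'
#' 1/|Sa(Ai)|: the action's share of its activity's action set.
#'
#' @param dec An `aae_decomposition`.
#' @param action Action id; must belong to the activity.
#' @param activity Activity id.
#' @return Number in (0, 1\].
#' @export
weight_action_in_activity <- function(dec, action, activity) {
  need_full_decomposition(dec, "W(aj|Ai)")
  ajs <- activity_actions(dec, activity)
  if (!action %in% ajs) {
    stop("action '", action, "' is not in activity '", activity, "'",
         call. = FALSE)
  }
  1 / length(ajs)
}

weight_event_in_activity_q <- function(dec, event, activity) {
  ajs <- activity_actions(dec, activity)
  acc <- q_new(0)
  for (aj in ajs) {
    ev <- dec$actions[[aj]]$events
    if (event %in% names(ev)) {
      acc <- q_add(acc, q_new(unname(ev[event]), sum(ev) * length(ajs)))
    }
  }
  acc
}

#' Weight of an event in an activity: W(ek|Ai)
#'
#' The bilinear composition over the activity's actions:
#' sum_aj W(ek|aj) W(aj|Ai), with W(ek|aj) taken as 0 where the event is
#' not in the action. Returns 0 for events outside the activity's event
#' set, the convention used in printed metric tables.
#'
#' @param dec An `aae_decomposition`.
#' @param event Event label.
#' @param activity Activity id.
#' @return Number in \[0, 1\].
#' @export
weight_event_in_activity <- function(dec, event, activity) {
  need_full_decomposition(dec, "W(ek|Ai)")
  check_activity(dec, activity)
  q_value(weight_event_in_activity_q(dec, event, activity))
}

contribution_event_q <- function(x, event, activity) {
  row <- ca_row(x, event)
  tot <- sum(row)
  if (tot == 0) {
    stop("event '", event, "' is unused: no activity has a positive ",
         "participation counter for it", call. = FALSE)
  }
  q_new(unname(row[activity]), tot)
}

#' Elementary contribution of an event to an activity: F(ek|Ai)
#'
#' The event's participation counter in the activity normalized by its
#' total participation across all activities:
#' Ca(ek|Ai) / sum_i Ca(ek|Ai). 1 means the event points only at this
#' activity; values below 1 dilute the activity's distinguishability. By
#' convention 0 for events of other activities; an event used by no
#' activity has no defined contribution and raises an error.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param event Event label used by at least one activity.
#' @param activity Activity id.
#' @return Number in \[0, 1\].
#' @export
contribution_event <- function(x, event, activity) {
  check_activity(x, activity)
  q_value(contribution_event_q(x, event, activity))
}

#' Elementary contribution of an action to an activity: F(aj|Ai)
#'
#' 1/CA(aj): the reciprocal of the number of activities containing the
#' action; 1 for every unshared action.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param action Action id; must belong to the activity.
#' @param activity Activity id.
#' @return Number in (0, 1\].
#' @export
contribution_action <- function(x, action, activity) {
  check_activity(x, activity)
  if (inherits(x, "incidence_fixture")) {
    member <- x$action_membership[action]
    if (is.na(member)) stop("unknown action id '", action, "'", call. = FALSE)
    if (member != activity) {
      stop("action '", action, "' is not in activity '", activity, "'",
           call. = FALSE)
    }
    return(1)
  }
  if (!action %in% activity_actions(x, activity)) {
    stop("action '", action, "' is not in activity '", activity, "'",
         call. = FALSE)
  }
  1 / count_activities_with_action(x, action)
}

distinguishability_events_q <- function(x, activity) {
  evs <- activity_events(x, activity)
  if (length(evs) == 0) {
    stop("activity '", activity, "' has an empty event set", call. = FALSE)
  }
  num <- integer(length(evs)); den <- integer(length(evs))
  for (i in seq_along(evs)) {
    fq <- contribution_event_q(x, evs[i], activity)
    num[i] <- fq$num; den[i] <- fq$den
  }
  q_mean(q_new(num, den))
}

#' Event distinguishability of an activity: De(Ai)
#'
#' The mean elementary contribution over the activity's distinct events,
#' computed in exact rational arithmetic. De(Ai) = 1 exactly when the
#' activity shares no event with any other activity; low values warn that
#' realizations of other activities will look like this one.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param activity Activity id with a non-empty event set.
#' @return Number in \[0, 1\].
#' @export
distinguishability_events <- function(x, activity) {
  check_activity(x, activity)
  q_value(distinguishability_events_q(x, activity))
}

distinguishability_actions_q <- function(x, activity) {
  if (inherits(x, "incidence_fixture")) {
    ajs <- names(x$action_membership)[x$action_membership == activity]
    if (length(ajs) == 0) {
      stop("activity '", activity, "' has no actions", call. = FALSE)
    }
    return(q_new(1))  # fixture actions are unshared by construction
  }
  ajs <- activity_actions(x, activity)
  if (length(ajs) == 0) {
    stop("activity '", activity, "' has no actions", call. = FALSE)
  }
  den <- vapply(ajs, function(aj) count_activities_with_action(x, aj),
                integer(1))
  q_mean(q_new(rep(1L, length(ajs)), den))
}

#' Action distinguishability of an activity: Da(Ai)
#'
#' The mean elementary contribution over the activity's actions; 1 when
#' none of its actions is shared with another activity.
#'
#' @inheritParams distinguishability_events
#' @return Number in \[0, 1\].
#' @export
distinguishability_actions <- function(x, activity) {
  check_activity(x, activity)
  q_value(distinguishability_actions_q(x, activity))
}

#' Check the distinguishability implication De = 1 => Da = 1
#'
#' For every activity with event distinguishability exactly 1, the action
#' distinguishability must also be 1: an activity sharing no events shares
#' no actions. This holds for every valid decomposition, so any witness
#' signals an implementation defect; the checker doubles as a permanent
#' self-test. The converse fails: two single-action activities with
#' overlapping event sets have Da = 1 but De < 1.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @return A list with `holds` (logical) and `witnesses` (tibble of
#'   violating activities with their exact De and Da, empty when `holds`).
#' @export
check_distinguishability_implication <- function(x) {
  acts <- activity_ids(x)
  w_act <- character(); w_de <- numeric(); w_da <- numeric()
  for (Ai in acts) {
    de <- distinguishability_events_q(x, Ai)
    if (q_is_one(de)) {
      da <- distinguishability_actions_q(x, Ai)
      if (!q_is_one(da)) {
        w_act <- c(w_act, Ai)
        w_de <- c(w_de, q_value(de))
        w_da <- c(w_da, q_value(da))
      }
    }
  }
  list(
    holds = length(w_act) == 0,
    witnesses = tibble::tibble(activity = w_act, De = w_de, Da = w_da)
  )
}

#' Assemble the full metric tables
#'
#' Computes every metric the input supports and lays them out as the
#' published tables do: an activity-level table (pairwise Sa and Se, Da,
#' De), an event-level table (per-activity Ca, global Ca and CA,
#' per-activity W and F) and, for a full decomposition, an action-level
#' table (owning activity, CA, W(aj|Ai), F(aj|Ai)) with the pairwise
#' action sharing-rate matrix. On an incidence fixture the weight columns
#' and the action table are absent, since the event-to-action wiring is
#' not part of a fixture.
#'
#' Rows and columns follow declaration order. Values are full-precision;
#' round for display with [round_half_up()] (the print method shows two
#' decimals).
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @return An object of class `aae_metric_tables`: a list with `activity`,
#'   `events`, `actions` (tibbles; `actions` is `NULL` on a fixture) and
#'   `action_sharing` (matrix or `NULL`).
#' @examples
#' tabs <- metric_tables(case_study_fixture())
#' tabs$activity
#' @export
metric_tables <- function(x) {
  acts <- activity_ids(x)
  is_dec <- inherits(x, "aae_decomposition")

  activity <- tibble::tibble(activity = acts)
  for (Aj in acts) {
    activity[[paste0("Sa_", Aj)]] <- unname(vapply(acts, function(Ai) {
      action_sharing_rate_activities(x, Ai, Aj)
    }, numeric(1)))
  }
  for (Aj in acts) {
    activity[[paste0("Se_", Aj)]] <- unname(vapply(acts, function(Ai) {
      event_sharing_rate_activities(x, Ai, Aj)
    }, numeric(1)))
  }
  activity$Da <- unname(vapply(acts, function(Ai)
    distinguishability_actions(x, Ai), numeric(1)))
  activity$De <- unname(vapply(acts, function(Ai)
    distinguishability_events(x, Ai), numeric(1)))

  evs <- used_events(x)
  events <- tibble::tibble(event = evs)
  carows <- matrix(
    vapply(evs, function(ek) ca_row(x, ek), integer(length(acts))),
    nrow = length(acts), dimnames = list(acts, evs)
  )
  for (Ai in acts) events[[paste0("Ca_", Ai)]] <- unname(carows[Ai, ])
  events$Ca <- unname(vapply(evs, function(ek)
    count_actions_with_event(x, ek), integer(1)))
  events$CA <- unname(vapply(evs, function(ek)
    count_activities_with_event(x, ek), integer(1)))
  if (is_dec) {
    for (Ai in acts) {
      events[[paste0("W_", Ai)]] <- unname(vapply(evs, function(ek)
        weight_event_in_activity(x, ek, Ai), numeric(1)))
    }
  }
  for (Ai in acts) {
    events[[paste0("F_", Ai)]] <- unname(vapply(evs, function(ek)
      contribution_event(x, ek, Ai), numeric(1)))
  }

  actions <- NULL
  action_sharing <- NULL
  if (is_dec) {
    ajs <- action_ids(x)
    owner <- vapply(ajs, function(aj) {
      paste(acts[vapply(acts, function(Ai)
        aj %in% activity_actions(x, Ai), logical(1))], collapse = ",")
    }, character(1))
    actions <- tibble::tibble(
      action = ajs,
      activities = owner,
      CA = unname(vapply(ajs, function(aj)
        count_activities_with_action(x, aj), integer(1)))
    )
    # W and F of an action in each owning activity (one row per pair)
    pair_rows <- do.call(rbind, lapply(ajs, function(aj) {
      owners <- acts[vapply(acts, function(Ai)
        aj %in% activity_actions(x, Ai), logical(1))]
      data.frame(
        action = aj, activity = owners,
        W = vapply(owners, function(Ai)
          weight_action_in_activity(x, aj, Ai), numeric(1)),
        F = vapply(owners, function(Ai)
          contribution_action(x, aj, Ai), numeric(1)),
        stringsAsFactors = FALSE
      )
    }))
    actions <- list(summary = actions,
                    in_activity = tibble::as_tibble(pair_rows))
    action_sharing <- matrix(
      0, length(ajs), length(ajs), dimnames = list(ajs, ajs)
    )
    for (aj in ajs) for (ak in ajs) {
      action_sharing[aj, ak] <- event_sharing_rate_actions(x, aj, ak)
    }
  }

  structure(
    list(activity = activity, events = events, actions = actions,
         action_sharing = action_sharing),
    class = "aae_metric_tables"
  )
}

#' @export
print.aae_metric_tables <- function(x, digits = 2, ...) {
  rnd <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.double(col)) round_half_up(col, digits) else col)
    df
  }
  cat("Activity-level metrics:\n")
  print(rnd(x$activity), n = Inf)
  cat("\nEvent-level metrics:\n")
  print(rnd(x$events), n = Inf)
  if (!is.null(x$actions)) {
    cat("\nAction-level metrics:\n")
    print(rnd(x$actions$summary), n = Inf)
  }
  invisible(x)
}

#' Write metric tables to disk
#'
#' @param tables An `aae_metric_tables` object.
#' @param path Output path. For `format = "json"` a single JSON file; for
#'   `format = "tsv"`, `path` is used as a prefix and one
#'   `<path>.<table>.tsv` file is written per table.
#' @param format `"tsv"` or `"json"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_metric_tables <- function(tables, path, format = c("tsv", "json")) {
  stopifnot(inherits(tables, "aae_metric_tables"))
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(activity = tables$activity, events = tables$events)
    if (!is.null(tables$actions)) {
      doc$actions <- tables$actions$summary
      doc$actions_in_activity <- tables$actions$in_activity
      m <- tables$action_sharing
      doc$action_sharing <- list(actions = rownames(m),
                                 Se = unname(split(m, row(m))))
    }
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  written <- character()
  emit <- function(df, suffix) {
    p <- paste0(path, ".", suffix, ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    written <<- c(written, p)
  }
  emit(tables$activity, "activity")
  emit(tables$events, "events")
  if (!is.null(tables$actions)) {
    emit(tables$actions$summary, "actions")
    emit(tables$actions$in_activity, "actions_in_activity")
  }
  invisible(written)
}
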