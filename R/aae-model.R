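# Data model for activities-actions-events (AAE) decompositions.
#
# An AAE decomposition links high-level activities of daily living (cooking,
# personal hygiene, ...) to the raw events emitted by smart-home binary
# sensors, through an intermediate layer of actions. Activities own sets of
# actions; actions own sets of events, optionally with multiplicities when
# the same movement recurs within an action (weighted edges). Every a priori
# metric in this package is a set-theoretic function of this structure.

stop_validation <- function(message, ...) {
  stop(structure(
    class = c("aae_validation_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stop_io <- function(message, ...) {
  stop(structure(
    class = c("aae_io_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Create an action
#'
#' An action is a named step of an activity ("make tea", "have a shower")
#' observed through the sensor events its movements trigger.
#'
#' @param id Unique action identifier.
#' @param events Events of the action: either a character vector of event
#'   labels (each with multiplicity 1) or a named integer vector mapping
#'   event label to multiplicity. Labels conventionally follow
#'   `"Zone|Sensor|Signal|Edge"` (e.g. `"Kitchen|Kettle|Power|1"`), but any
#'   non-empty string is accepted; identity is exact string equality.
#' @param name Display name; defaults to `id`.
#' @return An object of class `aae_action`.
#' @export
aae_action <- function(id, events, name = id) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  if (is.character(events)) {
    mult <- rep(1L, length(events))
    names(mult) <- events
  } else {
    mult <- as.integer(events)
    names(mult) <- names(events)
  }
  if (is.null(names(mult)) || any(!nzchar(names(mult)))) {
    stop("events must be labelled", call. = FALSE)
  }
  if (anyDuplicated(names(mult))) {
    stop("duplicate event labels within action '", id, "'", call. = FALSE)
  }
  structure(list(id = id, name = name, events = mult), class = "aae_action")
}

#' Create an activity
#'
#' @param id Unique activity identifier.
#' @param actions Character vector of action ids composing the activity.
#' @param name Display name; defaults to `id`.
#' @return An object of class `aae_activity`.
#' @export
aae_activity <- function(id, actions, name = id) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  structure(
    list(id = id, name = name, actions = unique(as.character(actions))),
    class = "aae_activity"
  )
}

#' Assemble an AAE decomposition
#'
#' Builds the three-level activities-actions-events structure that all
#' metrics read. By default each action belongs to exactly one activity and
#' all action-event edges carry multiplicity 1; both assumptions can be
#' relaxed with the flags, and every metric is defined for the relaxed
#' forms as well.
#'
#' @param activities List of [aae_activity()] objects.
#' @param actions List of [aae_action()] objects.
#' @param event_universe Optional character vector of all possible event
#'   labels; must be a superset of the events used by the actions. Defaults
#'   to the used events in first-appearance order.
#' @param allow_shared_actions If `FALSE` (default), an action id appearing
#'   in more than one activity is a validation error.
#' @param weighted_edges If `FALSE` (default), any event multiplicity above
#'   1 is a validation error.
#' @param check Validate on construction and abort with the full violation
#'   list if any invariant fails. Set to `FALSE` to build an unvalidated
#'   object (e.g. to inspect its violations with [aae_validate()]).
#' @return An object of class `aae_decomposition`.
#' @seealso [aae_validate()], [read_decomposition()], [metric_tables()]
#' @examples
#' dec <- aae_decomposition(
#'   activities = list(aae_activity("A1", "a1"), aae_activity("A2", "a2")),
#'   actions = list(
#'     aae_action("a1", c("e1", "e2")),
#'     aae_action("a2", c("e2", "e3"))
#'   )
#' )
#' activity_events(dec, "A1")
#' @export
aae_decomposition <- function(activities, actions, event_universe = NULL,
                              allow_shared_actions = FALSE,
                              weighted_edges = FALSE, check = TRUE) {
  if (inherits(activities, "aae_activity")) activities <- list(activities)
  if (inherits(actions, "aae_action")) actions <- list(actions)
  act_ids <- vapply(activities, `[[`, character(1), "id")
  aj_ids <- vapply(actions, `[[`, character(1), "id")
  if (anyDuplicated(act_ids)) {
    stop("duplicate activity ids: ",
         paste(unique(act_ids[duplicated(act_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(aj_ids)) {
    stop("duplicate action ids: ",
         paste(unique(aj_ids[duplicated(aj_ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(activities) <- act_ids
  names(actions) <- aj_ids
  used <- unique(unlist(lapply(actions, function(a) names(a$events)),
                        use.names = FALSE))
  if (is.null(event_universe)) {
    event_universe <- used
  } else {
    event_universe <- unique(as.character(event_universe))
  }
  dec <- structure(
    list(
      activities = activities,
      actions = actions,
      event_universe = event_universe,
      allow_shared_actions = isTRUE(allow_shared_actions),
      weighted_edges = isTRUE(weighted_edges)
    ),
    class = "aae_decomposition"
  )
  if (check) {
    v <- aae_validate(dec)
    if (nrow(v) > 0) {
      stop_validation(paste0(
        "invalid AAE decomposition (", nrow(v), " violation",
        if (nrow(v) > 1) "s" else "", "):\n",
        paste0("  - [", v$invariant, "] ", v$message, collapse = "\n")
      ))
    }
  }
  dec
}

#' Validate an AAE decomposition
#'
#' Checks every structural invariant and returns the violations as data
#' rather than raising: an empty result means the decomposition is valid.
#' Checked invariants: every action referenced by an activity exists; every
#' activity has at least one action and every action at least one event;
#' all multiplicities are positive, and exceed 1 only in weighted-edge
#' mode; all used events belong to the event universe; and, unless shared
#' actions are allowed, each action belongs to exactly one activity.
#'
#' @param dec An `aae_decomposition` (possibly built with `check = FALSE`).
#' @return A tibble with columns `invariant`, `element`, `message`; zero
#'   rows when all invariants hold.
#' @export
aae_validate <- function(dec) {
  stopifnot(inherits(dec, "aae_decomposition"))
  inv <- character(); el <- character(); msg <- character()
  note <- function(invariant, element, message) {
    inv[[length(inv) + 1]] <<- invariant
    el[[length(el) + 1]] <<- element
    msg[[length(msg) + 1]] <<- message
  }
  for (A in dec$activities) {
    if (length(A$actions) == 0) {
      note("nonempty_activity", A$id,
           paste0("activity '", A$id, "' has no actions"))
    }
    missing <- setdiff(A$actions, names(dec$actions))
    for (m in missing) {
      note("action_exists", m,
           paste0("activity '", A$id, "' references undeclared action '",
                  m, "'"))
    }
  }
  for (a in dec$actions) {
    if (length(a$events) == 0) {
      note("nonempty_action", a$id,
           paste0("action '", a$id, "' has no events"))
    }
    if (any(a$events < 1)) {
      note("positive_multiplicity", a$id,
           paste0("action '", a$id, "' has a multiplicity below 1"))
    }
    if (!dec$weighted_edges && any(a$events > 1)) {
      note("unweighted_multiplicity", a$id,
           paste0("action '", a$id,
                  "' has multiplicity > 1 but weighted_edges is FALSE"))
    }
    outside <- setdiff(names(a$events), dec$event_universe)
    for (e in outside) {
      note("event_in_universe", e,
           paste0("event '", e, "' of action '", a$id,
                  "' is outside the event universe"))
    }
  }
  if (!dec$allow_shared_actions) {
    owners <- table(unlist(lapply(dec$activities, `[[`, "actions"),
                           use.names = FALSE))
    for (aj in names(owners)[owners > 1]) {
      note("unshared_actions", aj,
           paste0("action '", aj, "' belongs to ", owners[[aj]],
                  " activities but allow_shared_actions is FALSE"))
    }
  }
  tibble::tibble(invariant = inv, element = el, message = msg)
}

# ---- accessors (the derived sets of the model) -------------------------

#' Activity identifiers, in declaration order
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @return Character vector of activity ids.
#' @export
activity_ids <- function(x) UseMethod("activity_ids")

#' @export
activity_ids.aae_decomposition <- function(x) names(x$activities)

#' Action identifiers, in declaration order
#' @param dec An `aae_decomposition`.
#' @return Character vector of action ids.
#' @export
action_ids <- function(dec) {
  stopifnot(inherits(dec, "aae_decomposition"))
  names(dec$actions)
}

#' Actions of an activity
#'
#' The action set of one activity.
#'
#' @param dec An `aae_decomposition`.
#' @param activity Activity id.
#' @return Character vector of action ids.
#' @export
activity_actions <- function(dec, activity) {
  stopifnot(inherits(dec, "aae_decomposition"))
  A <- dec$activities[[activity]]
  if (is.null(A)) stop("unknown activity id '", activity, "'", call. = FALSE)
  A$actions
}

#' Events of an action
#'
#' The event set of one action, as a named integer vector of multiplicities
#' (all 1 unless weighted edges are enabled).
#'
#' @param dec An `aae_decomposition`.
#' @param action Action id.
#' @return Named integer vector: event label -> multiplicity.
#' @export
action_events <- function(dec, action) {
  stopifnot(inherits(dec, "aae_decomposition"))
  a <- dec$actions[[action]]
  if (is.null(a)) stop("unknown action id '", action, "'", call. = FALSE)
  a$events
}

#' Events of an activity
#'
#' The event set of an activity: the union of the event sets of its
#' actions, in first-appearance order.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param activity Activity id.
#' @return Character vector of event labels.
#' @export
activity_events <- function(x, activity) UseMethod("activity_events")

#' @export
activity_events.aae_decomposition <- function(x, activity) {
  unique(unlist(
    lapply(activity_actions(x, activity),
           function(aj) names(x$actions[[aj]]$events)),
    use.names = FALSE
  ))
}

#' Events used anywhere in the model
#'
#' The union of all activities' event sets (a subset of the event
#' universe; events in the universe but used by no action are possible and
#' simply never score).
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @return Character vector of event labels in declaration order.
#' @export
used_events <- function(x) UseMethod("used_events")

#' @export
used_events.aae_decomposition <- function(x) {
  unique(unlist(lapply(x$actions, function(a) names(a$events)),
                use.names = FALSE))
}

#' @export
print.aae_decomposition <- function(x, ...) {
  cat("<aae_decomposition> ",
      length(x$activities), " activities, ",
      length(x$actions), " actions, ",
      length(used_events(x)), " used events (universe ",
      length(x$event_universe), ")\n", sep = "")
  cat(" flags: allow_shared_actions=", x$allow_shared_actions,
      ", weighted_edges=", x$weighted_edges, "\n", sep = "")
  for (A in x$activities) {
    cat(" ", A$id, " -> {", paste(A$actions, collapse = ", "), "}\n",
        sep = "")
  }
  invisible(x)
}
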