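# Event-by-activity incidence fixtures.
#
# An incidence fixture is the activity-level projection of a decomposition:
# a matrix of per-activity event participation counters Ca(ek|Ai) plus the
# action-to-activity membership map. It is what a published metric table
# lets you reconstruct when the full event-to-action wiring is only shown
# graphically. Activity-level metrics (Ca, CA, F, De, Da, Se/Sa between
# activities) are computable from it; metrics that need to know which
# action an event sits in (action-level sharing rates and all weights) are
# not, and raise a "requires a full decomposition" error.

#' Create an incidence fixture
#'
#' @param counts Integer matrix of participation counters with events as
#'   rows (rownames = event labels) and activities as columns (colnames =
#'   activity ids). `counts[k, i]` is the number of actions of activity `i`
#'   containing event `k`. Every row must have at least one positive entry.
#' @param action_membership Named character vector mapping each action id
#'   to the single activity id owning it.
#' @return An object of class `incidence_fixture`.
#' @export
incidence_fixture <- function(counts, action_membership) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have event-label rownames and activity-id colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("duplicate event labels or activity ids in counts", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts > 0) == 0)) {
    bad <- rownames(counts)[rowSums(counts > 0) == 0]
    stop("events with no positive count in any activity: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(action_membership)) ||
      any(!action_membership %in% colnames(counts))) {
    stop("action_membership must map action ids to known activity ids",
         call. = FALSE)
  }
  structure(
    list(counts = counts,
         action_membership = action_membership),
    class = "incidence_fixture"
  )
}

#' Project a decomposition onto its incidence fixture
#'
#' Computes the event-by-activity participation-counter matrix and the
#' action membership map of a full decomposition. The projection keeps
#' exactly the information the activity-level metrics use, so those
#' metrics agree between a decomposition and its projection.
#'
#' @param dec A valid `aae_decomposition` with unshared actions (a fixture
#'   maps each action to a single owning activity, so shared actions
#'   cannot be projected).
#' @return An `incidence_fixture`.
#' @export
as_incidence_fixture <- function(dec) {
  stopifnot(inherits(dec, "aae_decomposition"))
  owners <- table(unlist(lapply(dec$activities, `[[`, "actions"),
                         use.names = FALSE))
  if (any(owners > 1)) {
    stop("cannot project a decomposition with shared actions onto an ",
         "incidence fixture", call. = FALSE)
  }
  evs <- used_events(dec)
  acts <- activity_ids(dec)
  counts <- matrix(0L, nrow = length(evs), ncol = length(acts),
                   dimnames = list(evs, acts))
  membership <- character()
  for (Ai in acts) {
    for (aj in activity_actions(dec, Ai)) {
      membership[[aj]] <- Ai
      counts[names(action_events(dec, aj)), Ai] <-
        counts[names(action_events(dec, aj)), Ai] + 1L
    }
  }
  incidence_fixture(counts, membership)
}

#' @export
activity_ids.incidence_fixture <- function(x) colnames(x$counts)

#' @export
activity_events.incidence_fixture <- function(x, activity) {
  if (!activity %in% colnames(x$counts)) {
    stop("unknown activity id '", activity, "'", call. = FALSE)
  }
  rownames(x$counts)[x$counts[, activity] > 0]
}

#' @export
used_events.incidence_fixture <- function(x) rownames(x$counts)

#' @export
print.incidence_fixture <- function(x, ...) {
  cat("<incidence_fixture> ", nrow(x$counts), " events x ",
      ncol(x$counts), " activities (",
      paste(colnames(x$counts), collapse = ", "), "), ",
      length(x$action_membership), " actions\n", sep = "")
  invisible(x)
}

# guard used by metrics that need event-to-action wiring
need_full_decomposition <- function(x, what) {
  if (!inherits(x, "aae_decomposition")) {
    stop(what, " requires a full decomposition; an incidence fixture only ",
         "carries activity-level participation counters", call. = FALSE)
  }
  invisible(x)
}
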