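# File formats for AAE decompositions.
#
# JSON is the canonical dialect; a TSV edge list (activity_id, action_id,
# event_label, multiplicity) is an import/export convenience that drops
# display names and universe-only events. Both are UTF-8.

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = "json",
    tsv = "tsv",
    txt = "tsv",
    stop_io(paste0("cannot infer format from extension '.", ext,
                   "'; pass format explicitly"))
  )
}

#' Read an AAE decomposition from a file
#'
#' @param path Path to a JSON or TSV file.
#' @param format `"json"` or `"tsv"`; inferred from the file extension
#'   when omitted.
#' @param allow_shared_actions,weighted_edges Flags applied when reading
#'   the TSV dialect, which cannot carry them itself (`weighted_edges`
#'   defaults to `TRUE` exactly when a multiplicity above 1 occurs). For
#'   JSON the file's own `options` block wins.
#' @return A validated [aae_decomposition()]. Parse failures raise an I/O
#'   error; invariant failures abort with the full violation list.
#'
#' @section JSON dialect:
#' Top-level keys `activities` (list of `{id, name, actions}`), `actions`
#' (list of `{id, name, events: [{label, multiplicity}]}`),
#' `event_universe` (optional list of labels, defaulting to the used
#' events) and `options` (`{allow_shared_actions, weighted_edges}`).
#'
#' @section TSV dialect:
#' Header row required; columns `activity_id`, `action_id`, `event_label`
#' and optional `multiplicity` (default 1). One row per
#' activity-action-event edge.
#' @export
read_decomposition <- function(path, format = NULL,
                               allow_shared_actions = FALSE,
                               weighted_edges = NULL) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  format <- if (is.null(format)) infer_format(path) else
    match.arg(format, c("json", "tsv"))
  if (format == "json") {
    doc <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) stop_io(paste0("malformed JSON in ", path, ": ",
                                         conditionMessage(e)))
    )
    acts <- lapply(doc$activities, function(A) {
      aae_activity(A$id, as.character(unlist(A$actions)),
                   name = A$name %||% A$id)
    })
    ajs <- lapply(doc$actions, function(a) {
      mult <- vapply(a$events, function(e) as.integer(e$multiplicity %||% 1L),
                     integer(1))
      names(mult) <- vapply(a$events, function(e) as.character(e$label),
                            character(1))
      aae_action(a$id, mult, name = a$name %||% a$id)
    })
    universe <- if (!is.null(doc$event_universe))
      as.character(unlist(doc$event_universe)) else NULL
    opts <- doc$options %||% list()
    aae_decomposition(
      acts, ajs, event_universe = universe,
      allow_shared_actions = isTRUE(opts$allow_shared_actions),
      weighted_edges = isTRUE(opts$weighted_edges)
    )
  } else {
    edges <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE,
                        colClasses = "character"),
      error = function(e) stop_io(paste0("malformed TSV in ", path, ": ",
                                         conditionMessage(e)))
    )
    required <- c("activity_id", "action_id", "event_label")
    if (!all(required %in% names(edges))) {
      stop_io(paste0("TSV edge list must have columns ",
                     paste(required, collapse = ", ")))
    }
    edges$multiplicity <- if ("multiplicity" %in% names(edges))
      as.integer(edges$multiplicity) else 1L
    if (is.null(weighted_edges)) weighted_edges <- any(edges$multiplicity > 1)
    act_ids <- unique(edges$activity_id)
    aj_ids <- unique(edges$action_id)
    acts <- lapply(act_ids, function(Ai) {
      aae_activity(Ai, unique(edges$action_id[edges$activity_id == Ai]))
    })
    ajs <- lapply(aj_ids, function(aj) {
      rows <- edges[edges$action_id == aj, , drop = FALSE]
      # an action shared between activities has its edges repeated per owner
      rows <- rows[!duplicated(rows$event_label), , drop = FALSE]
      mult <- rows$multiplicity
      names(mult) <- rows$event_label
      aae_action(aj, mult)
    })
    aae_decomposition(acts, ajs,
                      allow_shared_actions = allow_shared_actions,
                      weighted_edges = weighted_edges)
  }
}

#' Write an AAE decomposition to a file
#'
#' Emits a file that reads back (with [read_decomposition()]) to an equal
#' object. The TSV edge list cannot represent display names or events in
#' the universe that no action uses; JSON preserves everything.
#'
#' @param dec A valid `aae_decomposition`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(dec, path, format = NULL) {
  stopifnot(inherits(dec, "aae_decomposition"))
  format <- if (is.null(format)) infer_format(path) else
    match.arg(format, c("json", "tsv"))
  if (format == "json") {
    doc <- list(
      activities = lapply(unname(dec$activities), function(A) {
        list(id = A$id, name = A$name, actions = as.list(A$actions))
      }),
      actions = lapply(unname(dec$actions), function(a) {
        list(id = a$id, name = a$name,
             events = lapply(seq_along(a$events), function(i) {
               list(label = names(a$events)[i],
                    multiplicity = unname(a$events[i]))
             }))
      }),
      event_universe = as.list(dec$event_universe),
      options = list(allow_shared_actions = dec$allow_shared_actions,
                     weighted_edges = dec$weighted_edges)
    )
    ok <- tryCatch({
      jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_io(paste0("cannot write ", path))
  } else {
    rows <- do.call(rbind, lapply(unname(dec$activities), function(A) {
      do.call(rbind, lapply(A$actions, function(aj) {
        ev <- dec$actions[[aj]]$events
        data.frame(activity_id = A$id, action_id = aj,
                   event_label = names(ev), multiplicity = unname(ev),
                   stringsAsFactors = FALSE)
      }))
    }))
    ok <- tryCatch({
      utils::write.table(rows, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_io(paste0("cannot write ", path))
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
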