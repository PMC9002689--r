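# Top-down diagnostic analysis of an AAE decomposition.
#
# The workflow mirrors how a designer reads the metrics: start from the
# activity-level view (distinguishabilities and sharing rates), flag the
# activities that look hard to separate, then drill down to the elementary
# contributions to find which events or actions are responsible, and
# finally read their participation counters and weights to name the issue.
# The metric families deliberately come with no universal thresholds --
# acceptable levels depend on the number of activities and how events are
# spread -- so every cutoff here is an explicit, per-activity-overridable
# configuration value.

#' Analyzer configuration
#'
#' Thresholds driving the top-down analysis. Defaults are pragmatic
#' starting points, not universal constants: tune them per deployment, or
#' per activity via `overrides`.
#'
#' @param distinguishability_floor Activities with De or Da strictly below
#'   this are flagged (default 0.8).
#' @param sharing_ceiling Activities with a pairwise event- or
#'   action-sharing rate strictly above this are flagged (default 0.5).
#' @param contribution_floor Drill-down reports elements with elementary
#'   contribution strictly below this (default 0.5).
#' @param weight_ceiling Weight above which a shared event is considered
#'   heavy for its activity (default 0.1).
#' @param rounding Decimal places used by the text rendering (default 2).
#' @param overrides Named list: activity id -> list overriding any of the
#'   four thresholds for that activity.
#' @return An object of class `aae_analyzer_config`.
#' @export
analyzer_config <- function(distinguishability_floor = 0.8,
                            sharing_ceiling = 0.5,
                            contribution_floor = 0.5,
                            weight_ceiling = 0.1,
                            rounding = 2,
                            overrides = list()) {
  vals <- c(distinguishability_floor, sharing_ceiling, contribution_floor,
            weight_ceiling)
  if (any(vals < 0 | vals > 1)) {
    stop("all thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(distinguishability_floor = distinguishability_floor,
         sharing_ceiling = sharing_ceiling,
         contribution_floor = contribution_floor,
         weight_ceiling = weight_ceiling,
         rounding = rounding,
         overrides = overrides),
    class = "aae_analyzer_config"
  )
}

#' Read an analyzer configuration from YAML or JSON
#'
#' The file mirrors [analyzer_config()]'s arguments, including an optional
#' `overrides` mapping of activity id to per-activity thresholds.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `aae_analyzer_config`.
#' @export
read_analyzer_config <- function(path) {
  if (!file.exists(path)) stop_io(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = FALSE)
  defaults <- formals(analyzer_config)
  args <- doc[intersect(names(doc), names(defaults))]
  do.call(analyzer_config, args)
}

threshold_for <- function(config, activity, name) {
  ov <- config$overrides[[activity]]
  if (!is.null(ov) && !is.null(ov[[name]])) ov[[name]] else config[[name]]
}

recommendation_text <- c(
  HIGH_PARTICIPATION_HIGH_WEIGHT = paste(
    "event participates in several activities yet sits in a single action",
    "here with a high weight; lower this activity's weight on it by",
    "adding other events"),
  SHARED_HIGH_WEIGHT = paste(
    "event is shared across activities through several actions and is",
    "heavy for this activity; consider more specific instrumentation"),
  SHARED_LOW_WEIGHT = paste(
    "event is shared across activities but carries little weight here;",
    "impact on recognition should be limited"),
  SHARED_EVENT = paste(
    "event participates in several activities (weights unavailable on an",
    "incidence fixture); inspect the full decomposition to judge severity"),
  SHARED_ACTION = paste(
    "action belongs to several activities; its realizations are",
    "inherently ambiguous"),
  LOW_CONTRIBUTION = "element contributes little to this activity"
)

event_code <- function(CA, ca_here, W, weight_ceiling) {
  if (CA >= 2 && is.na(W)) return("SHARED_EVENT")
  if (CA >= 2 && W > weight_ceiling && ca_here == 1) {
    return("HIGH_PARTICIPATION_HIGH_WEIGHT")
  }
  if (CA >= 2 && W > weight_ceiling) return("SHARED_HIGH_WEIGHT")
  if (CA >= 2) return("SHARED_LOW_WEIGHT")
  "LOW_CONTRIBUTION"
}

#' Analyze an AAE decomposition top-down
#'
#' Stage 1 computes the activity-level table (De, Da, pairwise Se and Sa)
#' and flags every activity whose distinguishability falls below its floor
#' or whose sharing rate with some other activity exceeds its ceiling.
#' Stage 2 lists, for each flagged activity, its events (and actions, on a
#' full decomposition) by ascending elementary contribution, ties broken
#' by declaration order. Stage 3 reports, for each listed element below
#' the contribution floor, its participation counters and weights, and
#' attaches a recommendation code naming the pattern (e.g. an event with a
#' high activity-participation counter present in only one action of the
#' activity).
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param config An [analyzer_config()].
#' @return An object of class `aae_analysis`: list with `stage1`
#'   (activity-level tibble), `flags` (tibble of threshold violations),
#'   `drilldown` (per flagged activity, elements by ascending F),
#'   `diagnostics` (stage-3 tibble with recommendation codes) and
#'   `config` (snapshot).
#' @examples
#' rep <- analyze(case_study_fixture())
#' rep$flags
#' @export
analyze <- function(x, config = analyzer_config()) {
  stopifnot(inherits(config, "aae_analyzer_config"))
  tabs <- metric_tables(x)
  acts <- activity_ids(x)
  is_dec <- inherits(x, "aae_decomposition")

  flags <- tibble::tibble(activity = character(), metric = character(),
                          other = character(), value = numeric(),
                          threshold = numeric(), comparison = character(),
                          margin = numeric())
  add_flag <- function(activity, metric, other, value, threshold,
                       comparison) {
    flags <<- rbind(flags, tibble::tibble(
      activity = activity, metric = metric, other = other, value = value,
      threshold = threshold, comparison = comparison,
      margin = abs(value - threshold)
    ))
  }
  for (Ai in acts) {
    floor_i <- threshold_for(config, Ai, "distinguishability_floor")
    ceil_i <- threshold_for(config, Ai, "sharing_ceiling")
    de <- tabs$activity$De[tabs$activity$activity == Ai]
    da <- tabs$activity$Da[tabs$activity$activity == Ai]
    if (de < floor_i) add_flag(Ai, "De", NA_character_, de, floor_i, "<")
    if (da < floor_i) add_flag(Ai, "Da", NA_character_, da, floor_i, "<")
    for (Aj in setdiff(acts, Ai)) {
      se <- event_sharing_rate_activities(x, Ai, Aj)
      sa <- action_sharing_rate_activities(x, Ai, Aj)
      if (se > ceil_i) add_flag(Ai, "Se", Aj, se, ceil_i, ">")
      if (sa > ceil_i) add_flag(Ai, "Sa", Aj, sa, ceil_i, ">")
    }
  }
  flagged <- unique(flags$activity)

  drilldown <- list()
  diag_rows <- list()
  for (Ai in flagged) {
    evs <- activity_events(x, Ai)
    fvals <- vapply(evs, function(ek) contribution_event(x, ek, Ai),
                    numeric(1))
    ev_tab <- tibble::tibble(event = evs, F = unname(fvals))
    ev_tab <- ev_tab[order(ev_tab$F), , drop = FALSE]  # stable: ties keep declaration order
    act_tab <- NULL
    if (is_dec) {
      ajs <- activity_actions(x, Ai)
      af <- vapply(ajs, function(aj) contribution_action(x, aj, Ai),
                   numeric(1))
      act_tab <- tibble::tibble(action = ajs, F = unname(af))
      act_tab <- act_tab[order(act_tab$F), , drop = FALSE]
    }
    drilldown[[Ai]] <- list(events = ev_tab, actions = act_tab)

    cfloor <- threshold_for(config, Ai, "contribution_floor")
    wceil <- threshold_for(config, Ai, "weight_ceiling")
    low <- ev_tab[ev_tab$F < cfloor, , drop = FALSE]
    for (ek in low$event) {
      row <- ca_row(x, ek)
      W <- if (is_dec) weight_event_in_activity(x, ek, Ai) else NA_real_
      code <- event_code(count_activities_with_event(x, ek),
                         unname(row[Ai]), W, wceil)
      diag_rows[[length(diag_rows) + 1]] <- tibble::tibble(
        activity = Ai, element = ek, kind = "event",
        F = low$F[low$event == ek],
        CA = count_activities_with_event(x, ek),
        Ca = paste(paste0(names(row), "=", row), collapse = ";"),
        W = W, code = code,
        suggestion = unname(recommendation_text[code])
      )
    }
    if (is_dec) {
      low_a <- act_tab[act_tab$F < cfloor, , drop = FALSE]
      for (aj in low_a$action) {
        diag_rows[[length(diag_rows) + 1]] <- tibble::tibble(
          activity = Ai, element = aj, kind = "action",
          F = low_a$F[low_a$action == aj],
          CA = count_activities_with_action(x, aj),
          Ca = NA_character_,
          W = weight_action_in_activity(x, aj, Ai),
          code = "SHARED_ACTION",
          suggestion = unname(recommendation_text[["SHARED_ACTION"]])
        )
      }
    }
  }
  diagnostics <- if (length(diag_rows)) do.call(rbind, diag_rows) else
    tibble::tibble(activity = character(), element = character(),
                   kind = character(), F = numeric(), CA = integer(),
                   Ca = character(), W = numeric(), code = character(),
                   suggestion = character())

  structure(
    list(stage1 = tabs$activity, flags = flags, drilldown = drilldown,
         diagnostics = diagnostics, config = config),
    class = "aae_analysis"
  )
}

#' Render an analysis report
#'
#' @param report An `aae_analysis`.
#' @param format `"text"` (human-readable, numbers rounded to the config's
#'   decimal places), `"json"` (machine-parsable; round-trips the report
#'   content through [report_from_json()]) or `"tsv"` (stage-1 table with
#'   flag annotations).
#' @return A single character string.
#' @export
render_report <- function(report, format = c("text", "json", "tsv")) {
  stopifnot(inherits(report, "aae_analysis"))
  format <- match.arg(format)
  d <- report$config$rounding
  if (format == "json") {
    doc <- list(
      stage1 = report$stage1,
      flags = report$flags,
      drilldown = lapply(report$drilldown, function(dd) {
        out <- list(events = dd$events)
        if (!is.null(dd$actions)) out$actions <- dd$actions
        out
      }),
      diagnostics = report$diagnostics,
      config = unclass(report$config)
    )
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE,
                                         null = "null")))
  }
  if (format == "tsv") {
    tab <- report$stage1
    tab[] <- lapply(tab, function(col)
      if (is.double(col)) round_half_up(col, d) else col)
    tab$flagged <- tab$activity %in% report$flags$activity
    tab$reasons <- vapply(tab$activity, function(Ai) {
      f <- report$flags[report$flags$activity == Ai, , drop = FALSE]
      if (nrow(f) == 0) return("")
      paste(paste0(f$metric, ifelse(is.na(f$other), "",
                                    paste0("|", f$other)),
                   f$comparison, f$threshold), collapse = ";")
    }, character(1))
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  # text
  lines <- character()
  put <- function(...) lines <<- c(lines, paste0(...))
  fmt <- function(v) formatC(round_half_up(v, d), format = "f", digits = d)
  put("AAE decomposition analysis")
  put("==========================")
  put("")
  put("Stage 1 - activity-level metrics:")
  tab <- report$stage1
  for (i in seq_len(nrow(tab))) {
    put("  ", tab$activity[i], ": De=", fmt(tab$De[i]),
        " Da=", fmt(tab$Da[i]))
  }
  put("")
  if (nrow(report$flags) == 0) {
    put("No issues: every activity meets its distinguishability floor and ",
        "sharing ceiling.")
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  put("Flagged activities:")
  for (i in seq_len(nrow(report$flags))) {
    f <- report$flags[i, ]
    put("  ", f$activity, ": ", f$metric,
        if (!is.na(f$other)) paste0("(vs ", f$other, ")") else "",
        " = ", fmt(f$value), " ", f$comparison, " ", fmt(f$threshold),
        " (margin ", fmt(f$margin), ")")
  }
  put("")
  put("Stage 2 - elements by ascending elementary contribution:")
  for (Ai in names(report$drilldown)) {
    dd <- report$drilldown[[Ai]]
    put("  ", Ai, " events:")
    for (i in seq_len(nrow(dd$events))) {
      put("    ", dd$events$event[i], "  F=", fmt(dd$events$F[i]))
    }
    if (!is.null(dd$actions)) {
      put("  ", Ai, " actions:")
      for (i in seq_len(nrow(dd$actions))) {
        put("    ", dd$actions$action[i], "  F=", fmt(dd$actions$F[i]))
      }
    }
  }
  put("")
  put("Stage 3 - diagnostics for low-contribution elements:")
  if (nrow(report$diagnostics) == 0) {
    put("  none below the contribution floor")
  }
  for (i in seq_len(nrow(report$diagnostics))) {
    g <- report$diagnostics[i, ]
    put("  [", g$code, "] ", g$kind, " '", g$element, "' in ", g$activity,
        ": F=", fmt(g$F), " CA=", g$CA,
        if (!is.na(g$Ca)) paste0(" Ca{", g$Ca, "}") else "",
        if (!is.na(g$W)) paste0(" W=", fmt(g$W)) else "",
        " -> ", g$suggestion)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Rebuild report content from its JSON rendering
#'
#' Inverse of `render_report(report, "json")` for the report's data
#' content (tables and configuration; the rebuilt object compares equal on
#' every value the rendering carries).
#'
#' @param txt JSON string produced by [render_report()].
#' @return A list with `stage1`, `flags`, `drilldown`, `diagnostics` and
#'   `config`.
#' @export
report_from_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  list(
    stage1 = tibble::as_tibble(doc$stage1),
    flags = tibble::as_tibble(doc$flags),
    drilldown = lapply(doc$drilldown, function(dd) {
      out <- list(events = tibble::as_tibble(dd$events))
      out$actions <- if (!is.null(dd$actions))
        tibble::as_tibble(dd$actions) else NULL
      out
    }),
    diagnostics = tibble::as_tibble(doc$diagnostics),
    config = doc$config
  )
}

#' @export
print.aae_analysis <- function(x, ...) {
  cat(render_report(x, "text"))
  invisible(x)
}
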