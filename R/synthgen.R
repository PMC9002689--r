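# Synthetic decompositions and simulated sensor-event streams.
#
# The generator emulates realistic smart-home decompositions: a handful of
# activities, a few actions each, action event sets drawn from a finite
# sensor-event pool with controllable within- and cross-activity sharing.
# The simulator builds ground-truth-annotated event streams the way an
# experimental training set is assembled: chosen activity realizations
# concatenated in order, with random noise events inserted between stream
# events (a person wandering into the room, an interrupted activity).
# A transparent membership recognizer (mean elementary contribution over a
# sliding window) closes the loop: it lets property tests verify that
# activities predicted separable by the metrics produce no cross-activity
# hits, without committing to any particular learning-based recognizer.

#' Generator parameters
#'
#' Defaults mirror a small instrumented-flat study: 3 activities, 2
#' actions each, action event sets of 6-14 events drawn from a pool of 43
#' sensor events, with moderate sharing.
#'
#' @param n_activities Number of activities.
#' @param actions_per_activity Integer range `c(min, max)` of actions per
#'   activity.
#' @param events_per_action Integer range `c(min, max)` of distinct events
#'   per action.
#' @param event_pool_size Total number of distinct event labels available;
#'   the pool is split into per-activity slices so that disjointness is
#'   guaranteed when `cross_activity_share_prob = 0`.
#' @param cross_activity_share_prob Probability that an event draw reuses
#'   an event already used by another activity.
#' @param within_activity_share_prob Probability that an event draw reuses
#'   an event already used by another action of the same activity.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `aae_gen_params`.
#' @export
gen_params <- function(n_activities = 3,
                       actions_per_activity = c(2, 2),
                       events_per_action = c(6, 14),
                       event_pool_size = 43,
                       cross_activity_share_prob = 0.15,
                       within_activity_share_prob = 0.1,
                       seed = 1L) {
  stopifnot(
    n_activities >= 1,
    length(actions_per_activity) == 2,
    actions_per_activity[1] >= 1,
    actions_per_activity[1] <= actions_per_activity[2],
    length(events_per_action) == 2,
    events_per_action[1] >= 1,
    events_per_action[1] <= events_per_action[2],
    cross_activity_share_prob >= 0, cross_activity_share_prob <= 1,
    within_activity_share_prob >= 0, within_activity_share_prob <= 1,
    cross_activity_share_prob + within_activity_share_prob <= 1
  )
  slice <- floor(event_pool_size / n_activities)
  if (slice < events_per_action[2]) {
    stop("infeasible parameters: the per-activity share of the event pool (",
         slice, ") is smaller than the maximum events per action (",
         events_per_action[2], ")", call. = FALSE)
  }
  structure(
    list(n_activities = n_activities,
         actions_per_activity = as.integer(actions_per_activity),
         events_per_action = as.integer(events_per_action),
         event_pool_size = as.integer(event_pool_size),
         cross_activity_share_prob = cross_activity_share_prob,
         within_activity_share_prob = within_activity_share_prob,
         seed = as.integer(seed)),
    class = "aae_gen_params"
  )
}

sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Generate a random AAE decomposition
#'
#' Each activity owns a private slice of the event pool; each event draw
#' reuses another activity's event with probability
#' `cross_activity_share_prob`, reuses one of this activity's own events
#' with probability `within_activity_share_prob`, and otherwise takes a
#' fresh event from the private slice (unused labels first). With
#' `cross_activity_share_prob = 0` the activities' event sets are
#' pairwise disjoint by construction, so every activity has
#' distinguishability 1.
#'
#' @param params An [gen_params()] object.
#' @return A valid `aae_decomposition` with unshared actions and
#'   unweighted edges.
#' @export
generate_decomposition <- function(params = gen_params()) {
  stopifnot(inherits(params, "aae_gen_params"))
  withr::with_seed(params$seed, {
    pool <- sprintf("e%03d", seq_len(params$event_pool_size))
    n <- params$n_activities
    slice_size <- floor(params$event_pool_size / n)
    slices <- split(pool[seq_len(slice_size * n)],
                    rep(seq_len(n), each = slice_size))
    used_by <- replicate(n, character(), simplify = FALSE)
    activities <- list()
    actions <- list()
    for (i in seq_len(n)) {
      Ai <- sprintf("A%02d", i)
      n_act <- sample1(seq(params$actions_per_activity[1],
                           params$actions_per_activity[2]))
      aj_ids <- sprintf("%s_a%02d", Ai, seq_len(n_act))
      for (aj in aj_ids) {
        m <- sample1(seq(params$events_per_action[1],
                         params$events_per_action[2]))
        chosen <- character()
        for (k in seq_len(m)) {
          u <- stats::runif(1)
          others <- setdiff(unique(unlist(used_by[-i])), chosen)
          own <- setdiff(used_by[[i]], chosen)
          fresh_new <- setdiff(setdiff(slices[[i]], used_by[[i]]), chosen)
          fresh_any <- setdiff(slices[[i]], chosen)
          pick <-
            if (u < params$cross_activity_share_prob &&
                length(others) > 0) {
              sample1(others)
            } else if (u < params$cross_activity_share_prob +
                         params$within_activity_share_prob &&
                       length(own) > 0) {
              sample1(own)
            } else if (length(fresh_new) > 0) {
              sample1(fresh_new)
            } else {
              sample1(fresh_any)
            }
          chosen <- c(chosen, pick)
        }
        actions[[aj]] <- aae_action(aj, chosen)
        used_by[[i]] <- unique(c(used_by[[i]], chosen))
      }
      activities[[Ai]] <- aae_activity(Ai, aj_ids)
    }
    aae_decomposition(unname(activities), unname(actions),
                      event_universe = pool)
  })
}

#' Stream simulation configuration
#'
#' @param schedule Data frame with columns `activity` and `action`: the
#'   ordered activity realizations to concatenate.
#' @param noise_rate Expected number of noise events inserted at each gap
#'   between consecutive realization events (Poisson-distributed;
#'   0 disables noise).
#' @param noise_pool `"all_events"` draws noise uniformly from all used
#'   events; `"other_activity_events"` excludes the events of the activity
#'   being realized, emulating unrelated movements only.
#' @param shuffle_within_action Randomly permute each realization's events
#'   (step inversions, e.g. taking a tea bag before the cup); otherwise
#'   declaration order.
#' @param seed Integer seed.
#' @return An object of class `aae_stream_config`.
#' @export
stream_config <- function(schedule, noise_rate = 0,
                          noise_pool = c("all_events",
                                         "other_activity_events"),
                          shuffle_within_action = FALSE, seed = 1L) {
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("activity", "action") %in% names(schedule)),
            noise_rate >= 0)
  structure(
    list(schedule = schedule[, c("activity", "action")],
         noise_rate = noise_rate,
         noise_pool = match.arg(noise_pool),
         shuffle_within_action = isTRUE(shuffle_within_action),
         seed = as.integer(seed)),
    class = "aae_stream_config"
  )
}

#' Simulate a ground-truth-annotated event stream
#'
#' Realizes the scheduled (activity, action) entries in order: each
#' realization emits the action's events (each repeated its multiplicity),
#' optionally shuffled, and tagged with a realization id. Noise events are
#' then inserted independently at every gap between consecutive stream
#' events, tagged `"NOISE"`. The non-noise event count always equals the
#' scheduled event mass.
#'
#' @param dec A valid `aae_decomposition`.
#' @param config An [stream_config()].
#' @return A tibble of class `aae_event_stream` with columns `index`,
#'   `event`, `truth` (realization tag `"r<k>:<activity>:<action>"` or
#'   `"NOISE"`).
#' @export
simulate_stream <- function(dec, config) {
  stopifnot(inherits(dec, "aae_decomposition"),
            inherits(config, "aae_stream_config"))
  sched <- config$schedule
  for (i in seq_len(nrow(sched))) {
    Ai <- sched$activity[i]; aj <- sched$action[i]
    if (!Ai %in% activity_ids(dec)) {
      stop("schedule references unknown activity '", Ai, "'", call. = FALSE)
    }
    if (!aj %in% activity_actions(dec, Ai)) {
      stop("schedule references action '", aj, "' not in activity '", Ai,
           "'", call. = FALSE)
    }
  }
  all_ev <- used_events(dec)
  withr::with_seed(config$seed, {
    events <- character(); truth <- character(); noise_ok <- list()
    for (i in seq_len(nrow(sched))) {
      Ai <- sched$activity[i]; aj <- sched$action[i]
      ev <- action_events(dec, aj)
      seq_ev <- rep(names(ev), times = ev)
      if (config$shuffle_within_action && length(seq_ev) > 1) {
        seq_ev <- sample(seq_ev)
      }
      tag <- sprintf("r%d:%s:%s", i, Ai, aj)
      pool_i <- if (config$noise_pool == "all_events") all_ev else
        setdiff(all_ev, activity_events(dec, Ai))
      events <- c(events, seq_ev)
      truth <- c(truth, rep(tag, length(seq_ev)))
      noise_ok <- c(noise_ok, rep(list(pool_i), length(seq_ev)))
    }
    if (config$noise_rate > 0 && length(events) > 1) {
      out_ev <- events[1]; out_tr <- truth[1]
      for (k in 2:length(events)) {
        pool_k <- noise_ok[[k]]
        n_noise <- stats::rpois(1, config$noise_rate)
        if (n_noise > 0 && length(pool_k) > 0) {
          picks <- sample(pool_k, n_noise, replace = TRUE)
          out_ev <- c(out_ev, picks)
          out_tr <- c(out_tr, rep("NOISE", n_noise))
        }
        out_ev <- c(out_ev, events[k])
        out_tr <- c(out_tr, truth[k])
      }
      events <- out_ev; truth <- out_tr
    }
    out <- tibble::tibble(index = seq_along(events), event = events,
                          truth = truth)
    class(out) <- c("aae_event_stream", class(out))
    out
  })
}

#' Write an event stream to TSV
#'
#' @param stream An `aae_event_stream`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path) {
  utils::write.table(as.data.frame(stream), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Membership score of an event window against an activity
#'
#' The mean elementary contribution F(ek|Ai) over the window's events,
#' counting 0 for events the activity does not use (or that no activity
#' uses). A window drawn entirely from an activity that shares no events
#' with the others scores 1 against it and 0 against everything else.
#' This is a deliberately transparent stand-in for a learned recognizer,
#' used to validate the metrics' predictions at property level.
#'
#' @param x An `aae_decomposition` or `incidence_fixture`.
#' @param window Non-empty character vector of event labels.
#' @param activity Activity id.
#' @return Number in \[0, 1\].
#' @export
membership_score <- function(x, window, activity) {
  check_activity(x, activity)
  stopifnot(length(window) > 0)
  f <- vapply(window, function(ek) {
    row <- ca_row(x, ek)
    tot <- sum(row)
    if (tot == 0) 0 else unname(row[activity]) / tot
  }, numeric(1))
  mean(f)
}

#' Cross-activity false-positive study
#'
#' For every activity, simulates streams of its realizations (one per
#' action, `n_streams` times, optionally with noise), slides a window of
#' `window_size` events over each stream, scores each window against
#' every activity with [membership_score()], and reports the fraction of
#' windows with a strictly positive score per ordered (truth, scored)
#' activity pair. In noise-free runs, the fraction for a pair with zero
#' event-sharing rate is exactly 0, and positive fractions appear exactly
#' where events are shared -- the predictive link the metrics promise.
#'
#' @param dec A valid `aae_decomposition`.
#' @param n_streams Streams simulated per activity.
#' @param window_size Sliding-window width in events.
#' @param seed Integer seed (per-stream seeds are derived from it).
#' @param noise_rate,noise_pool Passed to [stream_config()].
#' @return A tibble with columns `truth_activity`, `scored_activity`,
#'   `fraction`, `n_windows`.
#' @export
false_positive_study <- function(dec, n_streams = 5, window_size = 5,
                                 seed = 1L, noise_rate = 0,
                                 noise_pool = "all_events") {
  stopifnot(inherits(dec, "aae_decomposition"))
  acts <- activity_ids(dec)
  rows <- list()
  for (ti in seq_along(acts)) {
    Aj <- acts[ti]
    sched <- data.frame(activity = Aj,
                        action = activity_actions(dec, Aj))
    hits <- stats::setNames(numeric(length(acts)), acts)
    total <- 0L
    for (s in seq_len(n_streams)) {
      cfg <- stream_config(sched, noise_rate = noise_rate,
                           noise_pool = noise_pool,
                           shuffle_within_action = TRUE,
                           seed = (seed * 1000L + ti * 100L + s) %% .Machine$integer.max)
      st <- simulate_stream(dec, cfg)
      n <- nrow(st)
      w <- min(window_size, n)
      for (start in seq_len(n - w + 1)) {
        win <- st$event[start:(start + w - 1)]
        total <- total + 1L
        for (Ai in acts) {
          if (membership_score(dec, win, Ai) > 0) hits[Ai] <- hits[Ai] + 1
        }
      }
    }
    for (Ai in acts) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        truth_activity = Aj, scored_activity = Ai,
        fraction = unname(hits[Ai]) / total, n_windows = total
      )
    }
  }
  do.call(rbind, rows)
}
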