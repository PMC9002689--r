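# Hand-enumerated values on the toy decomposition T1
# (A1 = {a1}, a1 = {e1, e2}; A2 = {a2}, a2 = {e2, e3}):

test_that("participation counters match hand enumeration on T1", {
  dec <- toy_t1()
  expect_equal(count_actions_with_event_in_activity(dec, "e2", "A1"), 1L)
  expect_equal(count_actions_with_event_in_activity(dec, "e4", "A1"), 0L)
  expect_equal(count_actions_with_event(dec, "e2"), 2L)
  expect_equal(count_actions_with_event(dec, "e1"), 1L)
  expect_equal(count_actions_with_event(dec, "not-a-label"), 0L)
  expect_equal(count_activities_with_event(dec, "e2"), 2L)
  expect_equal(count_activities_with_event(dec, "e1"), 1L)
  expect_equal(count_activities_with_action(dec, "a1"), 1L)
  expect_error(count_actions_with_event_in_activity(dec, "e1", "A9"),
               "unknown activity")
  expect_error(count_activities_with_action(dec, "a9"), "unknown action")
})

test_that("sharing rates are asymmetric overlap fractions", {
  dec <- toy_t1()
  expect_equal(event_sharing_rate_actions(dec, "a1", "a2"), 1 / 2)
  expect_equal(event_sharing_rate_actions(dec, "a1", "a1"), 1)
  expect_equal(action_sharing_rate_activities(dec, "A1", "A1"), 1)
  expect_equal(action_sharing_rate_activities(dec, "A1", "A2"), 0)
  expect_equal(event_sharing_rate_activities(dec, "A1", "A2"), 1 / 2)
  # disjoint actions share nothing
  dec2 <- aae_decomposition(
    list(aae_activity("A1", c("a1", "a2"))),
    list(aae_action("a1", "e1"), aae_action("a2", "e2"))
  )
  expect_equal(event_sharing_rate_actions(dec2, "a1", "a2"), 0)
})

test_that("shared actions shift Sa, CA(aj), F(aj|Ai) and Da as defined", {
  dec <- shared_action_dec()  # A1 = {a1, a2}, A2 = {a2}
  expect_equal(action_sharing_rate_activities(dec, "A1", "A2"), 1 / 2)
  expect_equal(action_sharing_rate_activities(dec, "A2", "A1"), 1)
  expect_equal(count_activities_with_action(dec, "a2"), 2L)
  expect_equal(contribution_action(dec, "a2", "A1"), 1 / 2)
  expect_equal(contribution_action(dec, "a1", "A1"), 1)
  # activity whose only action is shared with one other activity
  expect_equal(distinguishability_actions(dec, "A2"), 1 / 2)
  expect_equal(distinguishability_actions(dec, "A1"), (1 + 1 / 2) / 2)
})

test_that("the multi-activity sharing rate unions the other event sets", {
  dec <- aae_decomposition(
    list(aae_activity("A1", "a1"), aae_activity("A2", "a2"),
         aae_activity("A3", "a3")),
    list(aae_action("a1", c("e1", "e2", "e3", "e4")),
         aae_action("a2", c("e1", "e9")),
         aae_action("a3", c("e2", "e8")))
  )
  expect_equal(event_sharing_rate_activities(dec, "A1", "A2"), 1 / 4)
  expect_equal(event_sharing_rate_activities(dec, "A1", c("A2", "A3")),
               2 / 4)
})

test_that("weights are inverse-size shares, multiplicity-aware", {
  dec <- toy_t1()
  expect_equal(weight_event_in_action(dec, "e1", "a1"), 1 / 2)
  expect_equal(weight_action_in_activity(dec, "a1", "A1"), 1)
  expect_equal(weight_event_in_activity(dec, "e2", "A1"), 1 / 2)
  expect_equal(weight_event_in_activity(dec, "e3", "A1"), 0)
  expect_error(weight_event_in_action(dec, "e3", "a1"), "not in action")
  expect_error(weight_action_in_activity(dec, "a2", "A1"),
               "not in activity")

  # single-event action carries full weight
  dec1 <- aae_decomposition(list(aae_activity("A1", "a1")),
                            list(aae_action("a1", "e1")))
  expect_equal(weight_event_in_action(dec1, "e1", "a1"), 1)

  # weighted edges: numerator is the multiplicity, denominator the mass
  wdec <- aae_decomposition(
    list(aae_activity("A1", "a1")),
    list(aae_action("a1", c(e1 = 2L, e2 = 1L))),
    weighted_edges = TRUE
  )
  expect_equal(weight_event_in_action(wdec, "e1", "a1"), 2 / 3)
  # counters stay set-based in weighted mode
  expect_equal(count_actions_with_event_in_activity(wdec, "e1", "A1"), 1L)

  # bilinear composition: event in both actions of sizes 2 and 4
  dec2 <- aae_decomposition(
    list(aae_activity("A1", c("a1", "a2"))),
    list(aae_action("a1", c("e1", "e2")),
         aae_action("a2", c("e1", "e3", "e4", "e5")))
  )
  expect_equal(weight_event_in_activity(dec2, "e1", "A1"),
               1 / 2 * 1 / 2 + 1 / 4 * 1 / 2)
})

test_that("elementary contributions and distinguishability on T1", {
  dec <- toy_t1()
  expect_equal(contribution_event(dec, "e1", "A1"), 1)
  expect_equal(contribution_event(dec, "e2", "A1"), 1 / 2)
  expect_equal(contribution_event(dec, "e3", "A1"), 0)
  expect_error(contribution_event(dec, "e9", "A1"), "unused")
  expect_equal(distinguishability_events(dec, "A1"), 3 / 4)
  expect_equal(distinguishability_actions(dec, "A1"), 1)
})

test_that("fixture metrics reproduce the published case-study tables", {
  fx <- case_study_fixture()
  # activity-level table, two-decimal half-up rounding
  expect_equal(round_half_up(event_sharing_rate_activities(fx, "AC", "AHBP")),
               0.56)
  expect_equal(round_half_up(event_sharing_rate_activities(fx, "AHBP", "AC")),
               0.56)
  expect_equal(round_half_up(distinguishability_events(fx, "AC")), 0.69)
  expect_equal(round_half_up(distinguishability_events(fx, "AHBP")), 0.76)
  expect_equal(distinguishability_events(fx, "APH"), 1)
  for (Ai in c("AC", "AHBP", "APH")) {
    expect_equal(distinguishability_actions(fx, Ai), 1)
    for (Aj in setdiff(c("AC", "AHBP", "APH"), Ai)) {
      expect_equal(action_sharing_rate_activities(fx, Ai, Aj), 0)
    }
  }
  # hygiene shares nothing even with both others pooled
  expect_equal(event_sharing_rate_activities(fx, "APH", c("AC", "AHBP")), 0)
  # event-level spot rows
  expect_equal(count_actions_with_event_in_activity(
    fx, "Kitchen|Cupboard_Bottom|Open|0", "AHBP"), 2L)
  expect_equal(count_activities_with_event(fx, "Kitchen|Kettle|Power|1"), 2L)
  expect_equal(count_activities_with_event(fx, "Bathroom|Shower_Door|Open|0"),
               1L)
  expect_equal(round_half_up(contribution_event(
    fx, "Kitchen|Cupboard_Bottom|Open|0", "AHBP")), 0.67)
  expect_equal(contribution_event(fx, "Kitchen|Kettle|Power|1", "AC"), 1 / 2)
  expect_equal(contribution_event(fx, "Bathroom|Door_PIR|Open|0", "APH"), 1)
  # all six actions unshared
  for (aj in names(fx$action_membership)) {
    expect_equal(count_activities_with_action(fx, aj), 1L)
    expect_equal(contribution_action(fx, aj, fx$action_membership[[aj]]), 1)
  }
})

test_that("weights and action-level rates demand a full decomposition", {
  fx <- case_study_fixture()
  expect_error(weight_event_in_activity(fx, "Kitchen|Kettle|Power|1", "AC"),
               "requires a full decomposition")
  expect_error(event_sharing_rate_actions(fx, "make_tea", "make_coffee"),
               "requires a full decomposition")
})

test_that("normalization and conservation hold exactly on random models", {
  for (seed in 1:15) {
    dec <- random_dec(seed)
    acts <- activity_ids(dec)
    for (aj in action_ids(dec)) {
      ev <- names(action_events(dec, aj))
      expect_equal(sum(vapply(ev, function(ek)
        weight_event_in_action(dec, ek, aj), numeric(1))), 1)
    }
    for (Ai in acts) {
      ajs <- activity_actions(dec, Ai)
      expect_equal(sum(vapply(ajs, function(aj)
        weight_action_in_activity(dec, aj, Ai), numeric(1))), 1)
      ev <- activity_events(dec, Ai)
      expect_equal(sum(vapply(ev, function(ek)
        weight_event_in_activity(dec, ek, Ai), numeric(1))), 1)
    }
    for (ek in used_events(dec)) {
      expect_equal(sum(vapply(acts, function(Ai)
        contribution_event(dec, ek, Ai), numeric(1))), 1)
    }
  }
})

test_that("per-activity counters sum to the global action counter", {
  # unshared actions: equality; shared actions: the per-activity sum
  # counts each shared action once per owner, so it can only exceed
  for (seed in 1:10) {
    dec <- random_dec(seed)
    acts <- activity_ids(dec)
    for (ek in used_events(dec)) {
      percount <- sum(vapply(acts, function(Ai)
        count_actions_with_event_in_activity(dec, ek, Ai), integer(1)))
      expect_equal(percount, count_actions_with_event(dec, ek))
    }
  }
  dec <- shared_action_dec()
  for (ek in used_events(dec)) {
    percount <- sum(vapply(activity_ids(dec), function(Ai)
      count_actions_with_event_in_activity(dec, ek, Ai), integer(1)))
    expect_gte(percount, count_actions_with_event(dec, ek))
  }
  # e3/e4 sit in the shared action: counted twice per-activity, once globally
  expect_equal(count_actions_with_event(dec, "e3"), 1L)
  expect_equal(sum(vapply(activity_ids(dec), function(Ai)
    count_actions_with_event_in_activity(dec, "e3", Ai), integer(1))), 2L)
})

test_that("all rates, weights and contributions stay within [0, 1]", {
  for (seed in c(2, 9, 21)) {
    dec <- random_dec(seed, cross = 0.4, within = 0.3)
    tabs <- metric_tables(dec)
    num_cols <- vapply(tabs$events, is.double, logical(1))
    expect_true(all(as.matrix(tabs$events[, num_cols]) >= 0))
    expect_true(all(as.matrix(tabs$events[, num_cols]) <= 1))
    acts_num <- vapply(tabs$activity, is.double, logical(1))
    expect_true(all(as.matrix(tabs$activity[, acts_num]) >= 0))
    expect_true(all(as.matrix(tabs$activity[, acts_num]) <= 1))
    expect_true(all(diag(tabs$action_sharing) == 1))
    for (Ai in activity_ids(dec)) {
      expect_equal(action_sharing_rate_activities(dec, Ai, Ai), 1)
      expect_equal(event_sharing_rate_activities(dec, Ai, Ai), 1)
    }
  }
})

test_that("a decomposition with disjoint activities is fully distinguishable", {
  dec <- generate_decomposition(gen_params(
    n_activities = 4, actions_per_activity = c(1, 2),
    events_per_action = c(2, 4), event_pool_size = 20,
    cross_activity_share_prob = 0, within_activity_share_prob = 0.2,
    seed = 11
  ))
  for (Ai in activity_ids(dec)) {
    expect_equal(distinguishability_events(dec, Ai), 1)
    expect_equal(distinguishability_actions(dec, Ai), 1)
  }
})

test_that("De = 1 implies Da = 1 across random models; converse fails", {
  res <- check_distinguishability_implication(case_study_fixture())
  expect_true(res$holds)
  expect_true(check_distinguishability_implication(toy_t1())$holds)
  for (seed in 1:200) {
    expect_true(check_distinguishability_implication(random_dec(seed, cross = 0.25))$holds)
  }
  # converse counterexample: two single-action activities overlapping in
  # events have Da = 1 but De < 1
  dec <- toy_t1()
  expect_equal(distinguishability_actions(dec, "A1"), 1)
  expect_lt(distinguishability_events(dec, "A1"), 1)
})

test_that("fixture projection preserves every activity-level metric", {
  for (seed in 1:10) {
    dec <- random_dec(seed)
    fx <- as_incidence_fixture(dec)
    acts <- activity_ids(dec)
    expect_equal(activity_ids(fx), acts)
    for (ek in used_events(dec)) {
      for (Ai in acts) {
        expect_equal(
          count_actions_with_event_in_activity(fx, ek, Ai),
          count_actions_with_event_in_activity(dec, ek, Ai)
        )
        expect_equal(contribution_event(fx, ek, Ai),
                     contribution_event(dec, ek, Ai))
      }
      expect_equal(count_activities_with_event(fx, ek),
                   count_activities_with_event(dec, ek))
      expect_equal(count_actions_with_event(fx, ek),
                   count_actions_with_event(dec, ek))
    }
    for (Ai in acts) {
      expect_equal(distinguishability_events(fx, Ai),
                   distinguishability_events(dec, Ai))
      expect_equal(distinguishability_actions(fx, Ai),
                   distinguishability_actions(dec, Ai))
      for (Aj in acts) {
        expect_equal(event_sharing_rate_activities(fx, Ai, Aj),
                     event_sharing_rate_activities(dec, Ai, Aj))
        expect_equal(action_sharing_rate_activities(fx, Ai, Aj),
                     action_sharing_rate_activities(dec, Ai, Aj))
      }
    }
  }
})

test_that("metric tables agree cell-by-cell with the single-metric ops", {
  dec <- toy_t1()
  tabs <- metric_tables(dec)
  expect_equal(tabs$activity$De, c(3 / 4, 3 / 4))
  expect_equal(tabs$activity$Da, c(1, 1))
  expect_equal(tabs$activity$Se_A2, c(1 / 2, 1))
  expect_equal(tabs$activity$Sa_A2, c(0, 1))
  e2 <- tabs$events[tabs$events$event == "e2", ]
  expect_equal(e2$Ca_A1, 1L)
  expect_equal(e2$Ca, 2L)
  expect_equal(e2$CA, 2L)
  expect_equal(e2$W_A1, 1 / 2)
  expect_equal(e2$F_A1, 1 / 2)
  expect_equal(tabs$action_sharing["a1", "a2"], 1 / 2)
  expect_equal(tabs$actions$summary$CA, c(1L, 1L))

  # fixture tables carry no weight columns and no action table
  ftabs <- metric_tables(case_study_fixture())
  expect_false(any(grepl("^W_", names(ftabs$events))))
  expect_null(ftabs$actions)
  expect_equal(round_half_up(ftabs$activity$De), c(0.69, 0.76, 1))
})

test_that("metric tables export to TSV and JSON", {
  tabs <- metric_tables(toy_t1())
  prefix <- withr::local_tempfile()
  paths <- write_metric_tables(tabs, prefix, "tsv")
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(paths[1])
  expect_equal(back$De, c(0.75, 0.75))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_metric_tables(tabs, jpath, "json")
  doc <- jsonlite::fromJSON(jpath)
  expect_equal(doc$activity$De, c(0.75, 0.75))
  expect_equal(doc$events$event, c("e1", "e2", "e3"))
})
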