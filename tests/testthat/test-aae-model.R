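test_that("a valid decomposition has no violations and exposes its sets", {
  dec <- toy_t1()
  expect_equal(nrow(aae_validate(dec)), 0)
  expect_equal(activity_ids(dec), c("A1", "A2"))
  expect_equal(action_ids(dec), c("a1", "a2"))
  expect_equal(activity_actions(dec, "A1"), "a1")
  expect_equal(names(action_events(dec, "a2")), c("e2", "e3"))
  expect_equal(activity_events(dec, "A1"), c("e1", "e2"))
  expect_equal(used_events(dec), c("e1", "e2", "e3"))
  expect_equal(dec$event_universe, c("e1", "e2", "e3"))
})

test_that("validation reports each broken invariant with its element", {
  # action in both activities while sharing is disallowed
  dec <- aae_decomposition(
    activities = list(aae_activity("A1", "a1"), aae_activity("A2", "a1")),
    actions = list(aae_action("a1", "e1")),
    check = FALSE
  )
  v <- aae_validate(dec)
  expect_equal(v$invariant, "unshared_actions")
  expect_equal(v$element, "a1")
  # the same structure is legal in shared mode
  dec$allow_shared_actions <- TRUE
  expect_equal(nrow(aae_validate(dec)), 0)

  # event used but absent from the declared universe
  dec2 <- aae_decomposition(
    activities = list(aae_activity("A1", "a1")),
    actions = list(aae_action("a1", c("e1", "e2"))),
    event_universe = "e1", check = FALSE
  )
  v2 <- aae_validate(dec2)
  expect_true("event_in_universe" %in% v2$invariant)
  expect_true("e2" %in% v2$element)

  # dangling action reference and multiplicity without weighted edges
  dec3 <- aae_decomposition(
    activities = list(aae_activity("A1", c("a1", "ghost"))),
    actions = list(aae_action("a1", c(e1 = 2L))),
    check = FALSE
  )
  v3 <- aae_validate(dec3)
  expect_setequal(v3$invariant, c("action_exists", "unweighted_multiplicity"))
  expect_true("ghost" %in% v3$element)

  # the constructor aborts with the full list when checking
  expect_error(
    aae_decomposition(
      activities = list(aae_activity("A1", "a1"), aae_activity("A2", "a1")),
      actions = list(aae_action("a1", "e1"))
    ),
    class = "aae_validation_error"
  )
})

test_that("activity event sets equal the union over their actions", {
  for (seed in 1:10) {
    dec <- random_dec(seed)
    for (Ai in activity_ids(dec)) {
      manual <- unique(unlist(lapply(
        activity_actions(dec, Ai),
        function(aj) names(action_events(dec, aj))
      ), use.names = FALSE))
      expect_equal(activity_events(dec, Ai), manual)
    }
  }
})

test_that("save then load is the identity, for both formats", {
  dec <- toy_t1()
  for (fmt in c("json", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_decomposition(dec, path)
    expect_identical(read_decomposition(path), dec)
  }
  # weighted multiplicity survives the round trip
  wdec <- aae_decomposition(
    activities = list(aae_activity("A1", "a1")),
    actions = list(aae_action("a1", c(e1 = 2L, e2 = 1L))),
    weighted_edges = TRUE
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_decomposition(wdec, path)
  back <- read_decomposition(path)
  expect_identical(back, wdec)
  expect_equal(action_events(back, "a1")[["e1"]], 2L)

  # property: random decompositions round-trip (JSON carries everything;
  # TSV once the universe is the used-event set)
  for (seed in 1:8) {
    dec <- random_dec(seed)
    pj <- withr::local_tempfile(fileext = ".json")
    write_decomposition(dec, pj)
    expect_identical(read_decomposition(pj), dec)
    dec_min <- aae_decomposition(unname(dec$activities),
                                 unname(dec$actions))
    pt <- withr::local_tempfile(fileext = ".tsv")
    write_decomposition(dec_min, pt)
    expect_identical(read_decomposition(pt), dec_min)
  }
})

test_that("loading malformed or invalid files fails with clear errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_decomposition(bad), class = "aae_io_error")

  # JSON referencing an undeclared action id aborts with the id named
  dangling <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    activities = list(list(id = "A1", actions = list("a1", "missing"))),
    actions = list(list(id = "a1",
                        events = list(list(label = "e1"))))
  ), dangling, auto_unbox = TRUE)
  expect_error(read_decomposition(dangling), "missing",
               class = "aae_validation_error")

  expect_error(read_decomposition("does-not-exist.json"),
               class = "aae_io_error")
})

test_that("the case-study fixture matches its published table", {
  fx <- case_study_fixture()
  expect_equal(dim(fx$counts), c(38, 3))
  expect_equal(colnames(fx$counts), c("AC", "AHBP", "APH"))
  expect_length(fx$action_membership, 6)
  expect_equal(sort(unique(fx$action_membership)), c("AC", "AHBP", "APH"))
  expect_equal(unname(table(fx$action_membership)[c("AC", "AHBP", "APH")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
  # every row participates somewhere
  expect_true(all(rowSums(fx$counts > 0) >= 1))
  # published spot rows
  expect_equal(unname(fx$counts["Kitchen|Cupboard_Bottom|Open|0", ]),
               c(1L, 2L, 0L))
  expect_equal(unname(fx$counts["Bathroom|Door_PIR|Open|0", ]),
               c(0L, 0L, 2L))
  # rows with a positive hygiene count: 10 bathroom rows + the 2 wardrobe
  # rows in the kitchen zone
  expect_equal(sum(fx$counts[, "APH"] > 0), 12)
  # duplicate printed labels kept as distinct suffixed rows
  expect_true(all(c("Bathroom|Sink_waterflow|Flow|1#1",
                    "Bathroom|Sink_waterflow|Flow|1#2",
                    "Kitchen|Coffee_machine|Power|1#1",
                    "Kitchen|Coffee_machine|Power|1#2")
                  %in% rownames(fx$counts)))
})

test_that("the sensor inventory yields 43 available events", {
  inv <- case_study_inventory()
  expect_equal(available_event_count(inv), 43L)
  expect_equal(sum(inv$n_sensors), 20L)
})

test_that("incidence fixtures reject malformed inputs", {
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
              dimnames = list(c("e1", "e2"), c("A1", "A2")))
  expect_error(incidence_fixture(m, c(a1 = "A1")), "no positive count")
  m2 <- matrix(1L, 1, 1, dimnames = list("e1", "A1"))
  expect_error(incidence_fixture(m2, c(a1 = "B9")), "known activity ids")
})
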