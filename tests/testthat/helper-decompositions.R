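# Shared builders for tests.

# Toy decomposition: two single-action activities overlapping in e2.
toy_t1 <- function() {
  aae_decomposition(
    activities = list(aae_activity("A1", "a1"), aae_activity("A2", "a2")),
    actions = list(
      aae_action("a1", c("e1", "e2")),
      aae_action("a2", c("e2", "e3"))
    )
  )
}

# Small random decompositions for property loops: varied sharing, cheap to
# generate and to score.
random_dec <- function(seed, cross = 0.3, within = 0.15) {
  generate_decomposition(gen_params(
    n_activities = 3, actions_per_activity = c(1, 3),
    events_per_action = c(2, 5), event_pool_size = 24,
    cross_activity_share_prob = cross,
    within_activity_share_prob = within, seed = seed
  ))
}

# Decomposition with a shared action (a2 in both activities).
shared_action_dec <- function() {
  aae_decomposition(
    activities = list(
      aae_activity("A1", c("a1", "a2")),
      aae_activity("A2", "a2")
    ),
    actions = list(
      aae_action("a1", c("e1", "e2")),
      aae_action("a2", c("e3", "e4"))
    ),
    allow_shared_actions = TRUE
  )
}
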