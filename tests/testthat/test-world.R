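test_that("the corpus builds, validates and has the printed structure", {
  corpus <- shared_corpus()
  lens <- vapply(corpus$sequences, function(sq) length(sq$actions), integer(1))
  tasks <- vapply(corpus$sequences, `[[`, character(1), "task")
  expect_equal(sum(tasks == "coffee"), 4L)
  expect_equal(sum(tasks == "tea"), 2L)
  expect_true(all(lens[tasks == "coffee"] == 37L))
  expect_true(all(lens[tasks == "tea"] == 20L))
  expect_gte(nrow(corpus$background$inputs), 250L)
  # subtask boundaries fall at the canonical steps
  for (sq in corpus$sequences) {
    want <- if (sq$task == "coffee") c(10L, 21L, 32L) else c(10L, 15L)
    expect_equal(sq$boundaries, want)
  }
})

test_that("every sequence replays through the environment without anomalies", {
  corpus <- shared_corpus()
  for (sq in corpus$sequences) {
    st <- sq$initial_state
    for (i in seq_along(sq$actions)) {
      out <- step_world(st, sq$actions[i])
      expect_false(out$anomaly)
      st <- out$state
    }
    expect_true(st$done)
    expect_true(st$sipped)
  }
})

test_that("each goal subtask contains exactly one crux action", {
  corpus <- shared_corpus()
  for (tmpl in corpus$grammar$templates) {
    expect_equal(sum(seq_along(tmpl$actions) == tmpl$crux), 1L)
  }
  for (sq in corpus$sequences) {
    # one crux per goal segment
    per_goal <- tapply(sq$crux, factor(sq$goals, levels = unique(sq$goals)), sum)
    expect_true(all(per_goal == 1L))
  }
})

test_that("world transitions follow the applicability predicates", {
  st <- world_initial_state("coffee", "packet")
  st <- step_world(st, "fixate_spoon")$state
  out <- step_world(st, "pick_up")
  expect_false(out$anomaly)
  expect_equal(out$state$held, "spoon")
  # picking up while holding is anomalous and leaves the state unchanged
  again <- step_world(out$state, "pick_up")
  expect_true(again$anomaly)
  expect_identical(again$state, out$state)
  expect_error(step_world(st, "levitate"), "unknown action")
  # determinism: identical action sequences give identical trajectories
  replay <- function() {
    s <- world_initial_state("tea", "bowl")
    for (a in c("fixate_teabag", "pick_up", "tear_open", "fixate_cup", "dip"))
      s <- step_world(s, a)$state
    s
  }
  expect_identical(replay(), replay())
})

test_that("the input/output encoding is fixed-width, one-hot and invertible", {
  st <- world_initial_state("coffee", "bowl")
  enc <- encode_io(st, "pick_up")
  expect_length(enc$input, 24L)
  expect_equal(sum(enc$output), 1)
  expect_equal(decode_action(enc$output), "pick_up")
  # empty hand encodes as all zeros in the held slot
  expect_equal(enc$input[13:24], rep(0, 12))
  for (a in action_set()) {
    expect_equal(decode_action(encode_io(st, a)$output), a)
  }
  # the generic sugar fixation resolves to the source actually present
  st_p <- step_world(world_initial_state("tea", "packet"), "fixate_sugar")$state
  st_b <- step_world(world_initial_state("tea", "bowl"), "fixate_sugar")$state
  expect_equal(st_p$fixated, "sugar_packet")
  expect_equal(st_b$fixated, "sugar_bowl")
  expect_false(identical(encode_io(st_p)$input, encode_io(st_b)$input))
})
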