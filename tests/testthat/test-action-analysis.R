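test_that("the classifier labels canonical corruptions correctly", {
  corpus <- shared_corpus()
  tmpl <- corpus$grammar$templates
  sq <- corpus$sequences$coffee_sugar_first_packet$actions
  tq <- corpus$sequences$tea_packet$actions

  intact <- classify_episode(mk_trace(sq, "coffee", "packet"), corpus)
  expect_false(intact$erroneous)
  expect_equal(sum(intact$subtask), 0L)
  expect_equal(intact$independent_actions, 0L)

  no_cream <- classify_episode(mk_trace(c(sq[1:21], sq[33:37]),
                                        "coffee", "packet"), corpus)
  expect_true(no_cream$erroneous)
  expect_equal(no_cream$subtask[["omission"]], 1L)
  expect_equal(sum(no_cream$subtask) - no_cream$subtask[["omission"]], 0L)

  with_cream <- classify_episode(
    mk_trace(c(tq[1:15], tmpl$cream$actions, tq[16:20]), "tea", "packet"),
    corpus)
  expect_true(with_cream$erroneous)
  expect_equal(with_cream$subtask[["intrusion"]], 1L)

  repeated <- classify_episode(
    mk_trace(c(sq[1:21], sq[11:21], sq[22:37]), "coffee", "packet"), corpus)
  expect_equal(repeated$subtask[["perseveration"]], 1L)

  # order variation in coffee is legitimate, not a displacement
  alt <- corpus$sequences$coffee_cream_first_packet$actions
  swapped <- classify_episode(mk_trace(alt, "coffee", "packet"), corpus)
  expect_false(swapped$erroneous)
  expect_equal(sum(swapped$subtask), 0L)
})

test_that("crux and non-crux action errors are separated", {
  corpus <- shared_corpus()
  sq <- corpus$sequences$tea_packet$actions
  # delete the steep crux (the dip at step 5): one crux omission
  lab <- classify_episode(mk_trace(sq[-5], "tea", "packet"), corpus)
  expect_gte(lab$crux_errors, 1L)
  # delete a non-crux action (the initial fixation): no crux errors
  lab2 <- classify_episode(mk_trace(sq[-1], "tea", "packet"), corpus)
  expect_equal(lab2$crux_errors, 0L)
  expect_gte(lab2$non_crux_errors, 1L)
})

test_that("survival curves follow first divergence from the nearest realization", {
  corpus <- shared_corpus()
  sq <- corpus$sequences$coffee_sugar_first_packet$actions
  perfect <- lapply(1:4, function(i) mk_trace(sq, "coffee", "packet"))
  sv <- survival_analysis(perfect, corpus)
  expect_true(all(sv$surviving == 1))
  expect_true(all(diff(sv$surviving[sv$task == "coffee"]) <= 0))
  # an episode corrupted at step 5 fails from step 5 onwards
  broken <- mk_trace(c(sq[1:4], "say_done"), "coffee", "packet")
  sv2 <- survival_analysis(list(broken), corpus)
  expect_equal(sv2$surviving[sv2$step == 4], 1)
  expect_equal(sv2$surviving[sv2$step == 5], 0)
  # order-variant episodes never count as divergent
  alt <- corpus$sequences$coffee_cream_first_bowl$actions
  sv3 <- survival_analysis(list(mk_trace(alt, "coffee", "bowl")), corpus)
  expect_true(all(sv3$surviving == 1))
})

test_that("crux analysis ratios follow hand arithmetic", {
  fake <- structure(list(aggregates = data.frame(
    kind = "sever", severity = 0.05, network = 1L, task = "coffee",
    n_episodes = 10L, n_erroneous = 5L,
    sub_omission = 2, sub_intrusion = 0, sub_perseveration = 0,
    sub_displacement = 0, within_subtask = 1,
    act_omission = 8, act_sequence = 2, act_other = 2,
    crux_errors = 3, non_crux_errors = 9,
    independent_actions = 6, total_actions = 300),
    episodes_per_cell = 10L), class = "error_report")
  ca <- crux_analysis(fake)
  expect_equal(ca$non_crux_to_crux, 3)
  expect_equal(ca$independent_prop, 6 / 300)
})

test_that("the DP classifier agrees with the exhaustive-alignment oracle", {
  corpus <- shared_corpus()
  tmpl <- corpus$grammar$templates
  tq_p <- corpus$sequences$tea_packet$actions   # 20 steps
  tq_b <- corpus$sequences$tea_bowl$actions
  steep <- tmpl$steep$actions
  sugar <- tmpl$sugar_t_packet$actions
  drink <- tmpl$drink$actions

  cases <- list(
    list(a = tq_p, src = "packet"),                        # intact
    list(a = tq_b, src = "bowl"),                          # intact variant
    list(a = c(steep, drink), src = "packet"),             # sugar omitted
    list(a = c(steep, sugar, sugar, drink), src = "packet"),  # perseveration
    list(a = c(steep, drink, sugar), src = "packet"),      # displaced sugar
    list(a = c(steep, tmpl$cream$actions[1:5], sugar, drink), src = "packet"),
    list(a = c(tq_p[1:10], "stir", "stir", tq_p[11:20])[1:22], src = "packet"),
    list(a = c(sugar, drink), src = "packet"),             # steep omitted
    list(a = tq_p[c(1:6, 9:20)], src = "packet"),          # broken steep
    list(a = c(steep, sugar, tmpl$sugar_t_bowl$actions, drink), src = "packet"),
    list(a = rev(tq_p), src = "packet"),                   # garbage order
    list(a = c(drink, steep, sugar), src = "packet"),      # drink displaced
    list(a = tq_p[1:19], src = "packet"),                  # truncated
    list(a = c(tq_p[1:15], "fixate_spoon", tq_p[16:20]), src = "packet"),
    list(a = c(steep, "pour", "pour", drink), src = "packet"),
    list(a = c(tq_b[1:15], "stir", "stir", tq_b[16:20]), src = "bowl"),
    list(a = c(steep, tmpl$grounds$actions[1:8], drink), src = "packet"),
    list(a = c("say_done"), src = "packet"),
    list(a = c(steep, sugar[1:3], drink), src = "packet"),
    list(a = c(steep, sugar, drink[1:4], "say_done"), src = "packet")
  )
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    expect_lte(length(cs$a), 25L)
    got <- classify_episode(mk_trace(cs$a, "tea", cs$src), corpus)$subtask
    want <- brute_force_subtask_labels(cs$a, "tea", corpus)
    expect_equal(got, want, info = paste("case", k))
  }
})
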