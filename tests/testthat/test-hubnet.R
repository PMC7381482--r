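test_that("network initialisation is seed-deterministic with a fixed -2 bias", {
  a <- init_hub(hub_config(), seed = 5L)
  b <- init_hub(hub_config(), seed = 5L)
  expect_identical(a$W_vh, b$W_vh)
  expect_identical(a$W_hh, b$W_hh)
  expect_identical(a$W_hv, b$W_hv)
  expect_equal(a$bias, -2.0)
  expect_error(hub_config(n_hidden = 0L), "positive")
  expect_false(identical(a$W_vh, init_hub(hub_config(), seed = 6L)$W_vh))
})

test_that("settling with all-zero weights gives the closed-form bias response", {
  net <- init_hub(hub_config(), seed = 1L)
  net$W_vh[] <- 0; net$W_hh[] <- 0; net$W_hv[] <- 0
  clamp <- clamp_spec(visual = rep(1, 64))
  tr <- settle(net, clamp)
  # every free unit sits at sigmoid(-2.0) on every cycle
  free_cols <- c(1:40, 105:216)
  expect_equal(unname(tr$visible[, free_cols]),
               matrix(plogis(-2), nrow(tr$visible), length(free_cols)),
               tolerance = 1e-12)
  expect_equal(unname(tr$hidden),
               matrix(plogis(-2), nrow(tr$hidden), ncol(tr$hidden)),
               tolerance = 1e-12)
  # clamped visual values held during the clamped phase
  expect_equal(unname(tr$visible[1:2, 41:104]), matrix(1, 2, 64))
  expect_error(settle(net, clamp, cycles_clamped = -1), "non-negative")
})

test_that("clamped units are never altered during the clamped phase", {
  net <- init_hub(hub_config(), seed = 11L)
  set.seed(42)
  for (rep in 1:5) {
    vals <- sample(0:1, 112, replace = TRUE)
    tr <- settle(net, clamp_spec(verbal = vals), cycles_clamped = 3,
                 cycles_free = 2)
    for (t in 1:3) expect_equal(unname(tr$visible[t, 105:216]), vals)
  }
})

test_that("training reduces the visible error and zero epochs is the identity", {
  ps <- shared_pattern_set("P2-like")
  net <- init_hub(hub_config(), seed = 2L)
  same <- train_hub(net, ps, epochs = 0L)
  expect_identical(same$W_vh, net$W_vh)
  trained <- train_hub(net, ps, epochs = 50L)
  expect_identical(trained$bias, net$bias)
  # summed squared visible error decreases over the first 50 epochs
  expect_lt(trained$loss_trace[50], trained$loss_trace[1])
  expect_true(mean(diff(trained$loss_trace) < 0) > 0.9)
})

test_that("naming readout applies the 0.5 threshold and lowest-index tie-break", {
  net <- init_hub(hub_config(), seed = 1L)
  net$W_vh[] <- 0; net$W_hh[] <- 0; net$W_hv[] <- 0
  # all name activations equal plogis(-2) < 0.5: no response
  expect_true(is.na(name_response(net, rep(1, 64))))
  expect_error(name_response(net, rep(1, 10)), "length")
  # threshold and tie-break on the raw readout rule
  expect_equal(lesionette:::read_name(c(0.4, 0.9, 0.9, 0.1)), 2L)
  expect_true(is.na(lesionette:::read_name(rep(0.5, 40))))
})

test_that("feed-forward variant has no recurrence and learns the auto-association", {
  net <- make_feedforward_variant(hub_config(), seed = 7L)
  expect_null(net$W_hh)
  expect_identical(net$W_vh, make_feedforward_variant(hub_config(), seed = 7L)$W_vh)
  ps <- shared_pattern_set("P2-like")
  mean_err <- function(n) {
    out <- lesionette:::settle_visual_batch(n, ps$units[, 41:104])
    mean(abs(out$visible - ps$units))
  }
  err0 <- mean_err(net)
  trained <- train_hub(net, ps, epochs = 40L)
  expect_lt(tail(trained$loss_trace, 1), trained$loss_trace[1])
  expect_lt(mean_err(trained), err0)
})

test_that("checkpoints round-trip through JSON", {
  net <- init_hub(hub_config(n_hidden = 8L), seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(net, path)
  back <- read_checkpoint(path)
  expect_equal(back$W_vh, net$W_vh)
  expect_equal(back$W_hh, net$W_hh)
  expect_equal(back$bias, net$bias)
  expect_s3_class(back, "hub_net")
})
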