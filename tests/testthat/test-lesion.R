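intact_net <- function() init_hub(hub_config(), seed = 21L)

test_that("severity-zero lesions are exact identities and bounds are enforced", {
  net <- intact_net()
  expect_identical(sever(net, 0, seed = 1L)$W_vh, net$W_vh)
  expect_identical(ablate_units(net, 0, seed = 1L)$W_hh, net$W_hh)
  expect_identical(scale_weights(net, 1)$W_hv, net$W_hv)
  expect_error(sever(net, 1.2, seed = 1L), "\\[0, 1\\]")
  expect_error(perturb_weights(net, 0, seed = 1L), "> 0")
  expect_error(scale_weights(net, 0), "\\(0, 1\\]")
  expect_error(scale_weights(net, 1.5), "\\(0, 1\\]")
  expect_error(activation_noise(-0.1), ">= 0")
})

test_that("full severing zeroes every trainable weight but never the bias", {
  net <- intact_net()
  cut <- sever(net, 1, seed = 2L)
  expect_true(all(cut$W_vh == 0) && all(cut$W_hh == 0) && all(cut$W_hv == 0))
  expect_equal(cut$bias, -2.0)
  # with no drive left, every free unit settles to sigmoid(-2)
  out <- settle(cut, clamp_spec(visual = rep(1, 64)))
  expect_equal(unname(out$final_visible[1:40]), rep(plogis(-2), 40),
               tolerance = 1e-12)
})

test_that("severed fraction matches the Bernoulli model", {
  net <- intact_net()
  n_w <- length(net$W_vh) + length(net$W_hh) + length(net$W_hv)
  q <- 0.25
  cut <- sever(net, q, seed = 33L)
  zeroed <- sum(cut$W_vh == 0) + sum(cut$W_hh == 0) + sum(cut$W_hv == 0)
  # exact binomial 99% interval around q
  bounds <- qbinom(c(0.005, 0.995), n_w, q)
  expect_gte(zeroed, bounds[1])
  expect_lte(zeroed, bounds[2])
})

test_that("weight perturbation is bounded uniform noise with the stated moments", {
  net <- intact_net()
  r <- 0.3
  bent <- perturb_weights(net, r, seed = 4L)
  delta <- c(bent$W_vh - net$W_vh, bent$W_hh - net$W_hh, bent$W_hv - net$W_hv)
  expect_true(all(abs(delta) <= r))
  expect_lt(abs(mean(delta)), 3 * r / sqrt(3 * length(delta)))
  expect_lt(abs(var(delta) - r^2 / 3) / (r^2 / 3), 0.05)
  # r -> 0+ limit leaves the network essentially unchanged
  eps <- perturb_weights(net, 1e-9, seed = 4L)
  expect_lt(max(abs(eps$W_vh - net$W_vh)), 1e-8)
})

test_that("ablation removes exactly the outgoing weights of selected hub units", {
  net <- intact_net()
  gone <- ablate_units(net, 1, seed = 5L)
  expect_true(all(gone$W_hh == 0) && all(gone$W_hv == 0))
  expect_identical(gone$W_vh, net$W_vh)  # incoming weights retained
  # ablating with a given seed equals severing those units' outgoing rows
  p <- 0.3
  ab <- ablate_units(net, p, seed = 6L)
  killed <- which(rowSums(ab$W_hv != 0) == 0)
  manual <- net
  manual$W_hh[killed, ] <- 0
  manual$W_hv[killed, ] <- 0
  expect_identical(ab$W_hh, manual$W_hh)
  expect_identical(ab$W_hv, manual$W_hv)
})

test_that("weight scaling is deterministic, exact and multiplicative", {
  net <- intact_net()
  s <- scale_weights(net, 0.65)
  expect_identical(s$W_vh, net$W_vh * 0.65)
  expect_identical(s$bias, net$bias)
  twice <- scale_weights(scale_weights(net, 0.5), 0.5)
  once <- scale_weights(net, 0.25)
  expect_equal(twice$W_hh, once$W_hh, tolerance = 1e-15)
})

test_that("lesion records replay to bit-identical damaged networks", {
  net <- intact_net()
  for (damaged in list(sever(net, 0.3, seed = 7L),
                       perturb_weights(net, 0.2, seed = 8L),
                       ablate_units(net, 0.4, seed = 9L),
                       scale_weights(net, 0.7))) {
    replayed <- apply_lesion(net, damaged$lesion_record)
    expect_identical(replayed$W_vh, damaged$W_vh)
    expect_identical(replayed$W_hv, damaged$W_hv)
  }
})

test_that("lesion operators apply to sequence networks with bias exemption", {
  net <- tiny_srn()
  cut <- sever(net, 1, seed = 10L)
  expect_true(all(cut$W_ih == 0) && all(cut$W_ch == 0) && all(cut$W_ho == 0))
  expect_identical(cut$b_h, net$b_h)
  expect_identical(cut$b_o, net$b_o)
  # recurrent targeting touches only the context-to-hidden matrix
  rec <- sever(net, 1, seed = 11L, target = "recurrent")
  expect_true(all(rec$W_ch == 0))
  expect_identical(rec$W_ih, net$W_ih)
  ab <- ablate_units(net, 1, seed = 12L)
  expect_true(all(ab$W_ch == 0))
  expect_identical(ab$W_ih, net$W_ih)
})

test_that("activation noise is a per-step context injector, zero-sigma inert", {
  net <- tiny_srn()
  base <- run_episode(net, world_initial_state("coffee", "packet"), seed = 1L)
  zero <- run_episode(net, world_initial_state("coffee", "packet"),
                      noise = activation_noise(0), seed = 1L)
  expect_identical(base$actions, zero$actions)
  a <- run_episode(net, world_initial_state("coffee", "packet"),
                   noise = activation_noise(0.5), seed = 2L)
  b <- run_episode(net, world_initial_state("coffee", "packet"),
                   noise = activation_noise(0.5), seed = 2L)
  expect_identical(a$actions, b$actions)  # reproducible draws
  c <- run_episode(net, world_initial_state("coffee", "packet"),
                   noise = activation_noise(0.5), seed = 3L)
  expect_false(identical(a$hidden, c$hidden))
})
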