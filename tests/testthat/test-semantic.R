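test_that("damage grids reproduce the printed severity ladders", {
  expect_equal(damage_grid("sever")$levels, seq(0.025, 0.50, by = 0.025))
  expect_equal(damage_grid("perturb")$levels, seq(0.05, 1.00, by = 0.05))
  expect_equal(damage_grid("ablate")$levels, seq(0.00, 1.00, by = 0.05))
  expect_equal(damage_grid("scale")$levels, seq(0.75, 0.55, by = -0.01))
  expect_equal(damage_grid("sever")$lesions_per_level, 10L)
  expect_equal(damage_grid("scale")$lesions_per_level, 1L)  # deterministic
})

test_that("grid extremes behave as closed forms dictate", {
  nets <- shared_hub_cohort("P2-like")[1]
  ps <- shared_pattern_set("P2-like")
  grid <- damage_grid("ablate", levels = c(0, 1), lesions_per_level = 2L)
  curve <- run_damage_grid(nets, grid, ps, master_seed = 7L)
  zero <- curve[curve$severity == 0, ]
  expect_true(all(zero$accuracy == 1))     # ceiling network, identity lesion
  one <- curve[curve$severity == 1, ]
  expect_true(all(one$accuracy == 0))      # sigmoid(-2) < 0.5: no responses
})

test_that("area between curves matches hand arithmetic and is antisymmetric", {
  two_level <- data.frame(
    network = 1L, kind = "sever", severity = rep(c(0.1, 0.2), each = 2),
    replicate = 1L, domain = rep(c("artefact", "animal"), 2),
    accuracy = c(1.0, 1.0, 0.8, 0.6))
  ar <- area_between_curves(two_level)
  expect_equal(ar$mean, +0.10)
  expect_true(is.na(ar$ci[1]))             # single network: CI unavailable
  # identical domain curves give area 0 with a CI spanning 0
  same <- do.call(rbind, lapply(1:3, function(n) {
    d <- two_level; d$network <- n
    d$accuracy <- rep(c(0.9, 0.7), each = 2) + n * 1e-3
    d
  }))
  ar0 <- area_between_curves(same)
  expect_equal(ar0$mean, 0)
  expect_lte(ar0$ci[1], 0); expect_gte(ar0$ci[2], 0)
  # swapping the domain labels flips the sign
  flipped <- two_level
  flipped$domain <- ifelse(flipped$domain == "animal", "artefact", "animal")
  expect_equal(area_between_curves(flipped)$mean, -ar$mean)
})

test_that("template-variant study aggregates per-kind areas correctly", {
  # two variants, two severity levels: means equal hand-computed averages
  profile <- build_profile("P2-like")
  out <- template_variants_study(profile, n_variants = 2L, kinds = "sever",
                                 lesions_per_level = 2L, epochs = 5L,
                                 master_seed = 3L)
  expect_equal(out$summary$kind, "sever")
  expect_equal(out$summary$mean_area, mean(out$areas[, "sever"]))
  expect_equal(out$summary$sd_area, sd(out$areas[, "sever"]))
  expect_error(template_variants_study(profile, n_variants = 1L), ">= 2")
})

test_that("attractor summaries degenerate correctly and require both domains", {
  ps <- shared_pattern_set("P2-like")
  net <- init_hub(hub_config(), seed = 1L)
  net$W_vh[] <- 0; net$W_hh[] <- 0; net$W_hv[] <- 0
  att <- attractor_summary(net, ps)   # all items share one hidden state
  expect_equal(att$animal_mean, 0)
  expect_equal(att$artefact_mean, 0)
})

test_that("the mixed-design ANOVA recovers known effects and matches hand sums of squares", {
  # identical groups: both F statistics ~ 0
  flat <- data.frame(network = rep(1:8, each = 2),
                     profile = rep(c("A", "B"), each = 8),
                     domain = rep(c("animal", "artefact"), 8),
                     distance = 5)
  # the same network-by-domain jitter pattern in both groups: group means
  # and per-network domain differences match exactly across profiles, so
  # the profile and interaction effects are identically zero while the
  # error strata keep nonzero variance
  vals <- c(0.011, -0.009, 0.021, 0.004, -0.013, 0.017, 0.002, -0.008)
  flat$distance <- flat$distance + rep(vals, 2)
  an <- attractor_anova(flat)
  expect_lt(an$F[an$effect == "profile"], 1e-10)
  expect_lt(an$F[an$effect == "profile:domain"], 1e-10)
  # injected additive domain effect: domain significant, interaction nil
  set.seed(9)
  eff <- data.frame(network = rep(1:20, each = 2),
                    profile = rep(c("A", "B"), each = 20),
                    domain = rep(c("animal", "artefact"), 20))
  eff$distance <- 4 + 0.5 * (eff$domain == "artefact") + rnorm(40, 0, 0.05)
  an <- attractor_anova(eff)
  expect_lt(an$p[an$effect == "domain"], 1e-6)
  expect_gt(an$p[an$effect == "profile:domain"], 0.01)
  # hand-computed oracle on a balanced 2x2 with per-network pairing
  d <- data.frame(network = rep(1:4, each = 2),
                  profile = rep(c("A", "B"), each = 4),
                  domain = rep(c("animal", "artefact"), 4),
                  distance = c(3, 5, 4, 6, 7, 8, 6, 9))
  an <- attractor_anova(d)
  # between-network stratum: profile effect against network-to-network error
  net_means <- tapply(d$distance, d$network, mean)
  prof_of_net <- c("A", "A", "B", "B")
  ss_prof <- 2 * sum(tapply(net_means, prof_of_net, function(x)
    length(x) * (mean(x) - mean(net_means))^2))
  ss_net_err <- 2 * sum((net_means - ave(net_means, prof_of_net))^2)
  F_prof <- (ss_prof / 1) / (ss_net_err / 2)
  expect_equal(an$F[an$effect == "profile"], F_prof, tolerance = 1e-8)
})

test_that("weight summaries report exact statistics for crafted matrices", {
  fake <- structure(list(W_vh = matrix(c(-1, 0, 2, 3), 2, 2),
                         W_hh = matrix(1, 2, 2),
                         W_hv = matrix(-1, 2, 2),
                         bias = -2, feedforward = FALSE),
                    class = "hub_net")
  ws <- weight_summary(list(fake))
  vh <- ws[ws$matrix == "W_vh", ]
  expect_equal(vh$mean[vh$stat == "min"], -1)
  expect_equal(vh$mean[vh$stat == "max"], 3)
  expect_equal(vh$mean[vh$stat == "mean"], 1)
  expect_equal(vh$mean[vh$stat == "prop_positive"], 0.5)
})

test_that("pattern and name errors are consistent Euclidean distances", {
  net <- shared_hub_cohort("P2-like")[[1]]
  ps <- shared_pattern_set("P2-like")
  pe <- pattern_and_name_error(net, ps)
  expect_true(all(pe$pattern_error >= pe$name_error))
  expect_true(all(pe$pattern_error >= 0))
  # oracle: recompute one domain mean directly from the settled states
  out <- lesionette:::settle_visual_batch(net, ps$units[, 41:104])
  d <- sqrt(rowSums((out$visible - ps$units)^2))
  expect_equal(pe$pattern_error[pe$domain == "animal"],
               mean(d[ps$items$domain == "animal"]))
})

test_that("naming accuracy declines monotonically with stochastic damage severity", {
  for (kind in c("sever", "perturb")) {
    curve <- shared_grid_curve("P2-like", kind)
    m <- stats::aggregate(accuracy ~ severity, data = curve, mean)
    tr <- suppressWarnings(stats::cor.test(m$severity, m$accuracy,
                                           method = "spearman"))
    expect_lt(tr$estimate, 0)
    expect_lt(m$accuracy[nrow(m)], m$accuracy[1])
  }
})
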