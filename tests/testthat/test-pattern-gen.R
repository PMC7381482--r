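test_that("generated pattern sets have the canonical dimensions and labels", {
  ps <- shared_pattern_set("P1-like")
  expect_equal(dim(ps$units), c(48L, 216L))
  expect_true(all(ps$units %in% c(0L, 1L)))
  expect_equal(unname(table(ps$items$category)[unique(ps$items$category)]),
               rep(8L, 6L), ignore_attr = TRUE)
  expect_equal(sum(table(ps$items$category) > 0), 6L)
  expect_equal(unname(table(ps$items$domain)), c(24L, 24L), ignore_attr = TRUE)
  # localist name block: exactly the assigned unit active
  for (i in c(1L, 17L, 48L)) {
    expect_equal(which(ps$units[i, 1:40] == 1L), ps$items$name_unit[i])
  }
})

test_that("generation is bit-identical under the same seed", {
  prof <- build_profile("P2-like")
  a <- generate_patterns(prof, seed = 99L)
  b <- generate_patterns(prof, seed = 99L)
  expect_identical(a$units, b$units)
  expect_identical(a$items, b$items)
  c <- generate_patterns(prof, seed = 100L)
  expect_false(identical(a$units, c$units))
})

test_that("profile expectations hit the calibration targets in closed form", {
  for (id in c("P1-like", "P2-like")) {
    prof <- build_profile(id)
    expect_true(all(abs(feature_expectations(prof) - prof$target_means) < 0.5),
                info = id)
  }
  expect_error(build_profile("P3-like"), "unknown profile")
})

test_that("realized per-category means converge to the closed-form expectations", {
  # law-of-large-numbers check over many generated sets
  for (id in c("P1-like", "P2-like")) {
    prof <- build_profile(id)
    counts <- matrix(0, 200L, 6L)
    for (s in 1:200) {
      ps <- generate_patterns(prof, seed = s)
      counts[s, ] <- tapply(rowSums(ps$units),
                            factor(ps$items$category, levels = prof$categories),
                            mean)
    }
    realized <- colMeans(counts)
    expected <- unname(feature_expectations(prof))
    # Monte-Carlo error of a mean of 1600 item draws per category
    expect_true(all(abs(realized - expected) < 0.35), info = id)
  }
})

test_that("similarity structure is ordered: category > domain > cross-domain", {
  for (id in c("P1-like", "P2-like")) {
    ps <- shared_pattern_set(id)
    ss <- similarity_summary(ps)
    expect_true(isSymmetric(ss$correlation))
    expect_equal(unname(diag(ss$correlation)), rep(1, 48))
    bm <- ss$block_means
    expect_gt(bm["within_category"], bm["within_domain"])
    expect_gt(bm["within_domain"], bm["cross_domain"])
    expect_gt(bm["within_category"] - bm["cross_domain"], 0.2)
    expect_true(bm["cross_domain"] > -0.1 && bm["cross_domain"] < 0.1)
  }
})

test_that("identical items correlate at 1 and zero-variance items are flagged", {
  ps <- shared_pattern_set("P1-like")
  ps$units[2, ] <- ps$units[1, ]
  ss <- similarity_summary(ps)
  expect_equal(ss$correlation[1, 2], 1)
  ps$units[3, ] <- 0L
  ss <- similarity_summary(ps)
  expect_equal(ss$degenerate_items, 3L)
  expect_true(all(is.na(ss$correlation[3, -3])))
})

test_that("boosting domain norms rescales expectations and is a fixed point at the current mean", {
  prof <- build_profile("P2-like")
  boosted <- boost_domain_norms(prof, "animal", 42)
  expected <- feature_expectations(boosted)
  expect_true(all(abs(expected[1:3] - 42) < 1e-6))
  expect_equal(expected[4:6], feature_expectations(prof)[4:6])
  # fixed point: boosting to the current expectation changes nothing
  cur <- unname(feature_expectations(prof)["birds"])
  same <- boost_domain_norms(prof, "animal", cur)
  expect_equal(same$prob[1, ], prof$prob[1, ], tolerance = 1e-8)
  expect_error(boost_domain_norms(prof, "animal", 400), "not achievable")
  # sample-mean check on the boosted profile
  counts <- sapply(1:100, function(s) {
    ps <- generate_patterns(boosted, seed = s)
    mean(rowSums(ps$units[ps$items$domain == "animal", ]))
  })
  expect_lt(abs(mean(counts) - 42), 0.4)
})

test_that("pattern CSV round trip is lossless and malformed files are rejected", {
  ps <- shared_pattern_set("P2-like")
  path <- withr::local_tempfile(fileext = ".csv")
  write_patterns(ps, path)
  back <- read_patterns(path)
  expect_identical(back$units, ps$units)
  expect_equal(back$items$name_unit, ps$items$name_unit)
  expect_equal(back$seed, ps$seed)
  expect_equal(back$profile_id, ps$profile_id)

  df <- utils::read.csv(path)
  utils::write.csv(df[, -ncol(df)], path, row.names = FALSE)  # 215 unit columns
  expect_error(read_patterns(path), "expected 216")
  utils::write.csv(transform(df, u005 = 2L), path, row.names = FALSE)
  expect_error(read_patterns(path), "non-binary")
})
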