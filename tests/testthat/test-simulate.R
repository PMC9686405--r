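test_that("simulation output has the documented shape and is reproducible", {
  m <- pf_model("bifactor", seed = 3)
  s1 <- simulate(m, nsim = 250, seed = 9)
  s2 <- simulate(m, nsim = 250, seed = 9)
  expect_identical(s1$items, s2$items)
  expect_identical(s1$scales, s2$scales)
  expect_equal(nrow(s1$items), 250)
  expect_equal(nrow(s1$scales), 250)
  expect_setequal(names(s1$scales),
                  c(rc_scales(), "EID", "THD", "BXD", "sample", "age", "gender"))
  expect_true(all(unlist(s1$items[, m$item_ids]) %in% 0:1))
  s3 <- simulate(m, nsim = 250, seed = 10)
  expect_false(identical(s1$items, s3$items))
  expect_error(simulate(m, nsim = 1), "at least 2")
})

test_that("scale scores are the keyed row sums of the items", {
  m <- pf_model("bifactor", seed = 5)
  sim <- simulate(m, nsim = 120, seed = 2)
  im <- item_matrix(sim$items[, m$item_ids], m$item_scale_map, m$item_key)
  expect_equal(sim$scales[, rc_scales()], score_scales(im),
               ignore_attr = TRUE)
})

test_that("flipping an item's key flips its column but not the score", {
  m <- pf_model("bifactor", seed = 7)
  sim <- simulate(m, nsim = 150, seed = 4)
  id <- m$item_ids[1]
  im <- item_matrix(sim$items[, m$item_ids], m$item_scale_map, m$item_key)
  flipped_values <- im$values
  flipped_values[, id] <- 1L - flipped_values[, id]
  key2 <- im$key
  names(key2) <- im$item_ids
  key2[id] <- -key2[id]
  im2 <- item_matrix(flipped_values, m$item_scale_map, key2)
  expect_equal(score_scales(im), score_scales(im2))
  expect_false(identical(im$values[, id], im2$values[, id]))
})

test_that("zero context effect leaves the group means equal", {
  m <- pf_model("bifactor", context_effect = 0, seed = 1)
  sim <- simulate(m, nsim = 20000, seed = 6)
  g <- sim$latents$G
  d <- mean(g[sim$scales$sample == 1]) - mean(g[sim$scales$sample == 0])
  expect_lt(abs(d), 3 * sqrt(1 / sum(sim$scales$sample == 1) +
                             1 / sum(sim$scales$sample == 0)))
  # and the default shift separates the groups by ~1 SD of G
  m1 <- pf_model("bifactor", seed = 1)
  sim1 <- simulate(m1, nsim = 20000, seed = 6)
  g1 <- sim1$latents$G
  d1 <- mean(g1[sim1$scales$sample == 1]) - mean(g1[sim1$scales$sample == 0])
  expect_equal(d1, 1, tolerance = 0.05)
  expect_equal(stats::sd(g1), 1, tolerance = 0.02)
})

test_that("empirical composite covariance converges to the implied one", {
  m <- pf_model("bifactor", seed = 2)
  sim <- simulate(m, nsim = 50000, seed = 3)
  emp <- stats::cov(sim$latents[, m$scales])
  expect_lt(max(abs(emp - implied_scale_covariance(m))), 0.02)
})

test_that("without a general factor, cross-spectrum correlations vanish", {
  m <- pf_model("bifactor", general_loading = 0,
                cross_loadings = data.frame(scale = character(0),
                                            spectrum = character(0),
                                            loading = numeric(0)),
                context_effect = 0,
                covariate_effects = c(age = 0, gender = 0), seed = 4)
  sim <- simulate(m, nsim = 30000, seed = 5)
  co <- stats::cor(sim$latents[, m$scales])
  map <- m$spectra_map
  for (a in m$scales) for (b in m$scales) {
    if (a < b && !pfnet:::shares_spectrum(map, a, b)) {
      expect_lt(abs(co[a, b]), 0.03)
    }
  }
})
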