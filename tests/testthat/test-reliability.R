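test_that("reliabilities separate independence from dependence", {
  set.seed(41)
  n <- 5000
  x <- rnorm(n); w <- 0.8 * x + 0.6 * rnorm(n); y <- 0.8 * w + 0.6 * rnorm(n)
  d <- data.frame(x = x, w = w, y = y, u = rnorm(n))
  cfg <- small_config()
  expect_gt(independence_reliability("x", "u", character(0), d, cfg)$reliability,
            0.95)
  expect_gt(independence_reliability("x", "y", "w", d, cfg)$reliability, 0.95)
  expect_lt(independence_reliability("x", "y", character(0), d, cfg)$reliability,
            0.05)
  st <- independence_reliability("x", "y", "w", d, cfg)
  expect_identical(st$source, "bge_averaged")
  # complement: dependence reliability is one minus independence reliability
  expect_equal(st$reliability + (1 - st$reliability), 1)
})

test_that("large conditioning sets fall back to the Bayes-factor test", {
  set.seed(42)
  n <- 2000
  d <- data.frame(matrix(rnorm(n * 6), n, 6))
  names(d) <- letters[1:6]
  cfg <- small_config()
  st <- independence_reliability("a", "b", c("c", "d", "e"), d, cfg)
  expect_identical(st$source, "bic_bayes_factor")
  # matches the stated formula computed by hand from the partial correlation
  P <- solve(cor(d[, c("a", "b", "c", "d", "e")]))
  r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  lam <- -n * log(1 - r^2)
  bf <- exp((log(n) - lam) / 2)
  expect_equal(st$reliability, bf / (1 + bf), tolerance = 1e-12)
  # beyond max_cond_size the statement is skipped
  st2 <- independence_reliability("a", "b", c("c", "d", "e", "f"),
                                  d, bccd_config(max_subset_size = 3,
                                                 max_cond_size = 3))
  expect_identical(st2$source, "skipped")
  expect_true(is.na(st2$reliability))
})

test_that("degenerate conditionals are handled without failure", {
  set.seed(43)
  n <- 500
  a <- rnorm(n); b <- rnorm(n)
  d <- data.frame(a = a, b = b, s = a + b, x = rnorm(n), y = rnorm(n))
  # exact collinearity in the fallback test is flagged, not propagated
  st <- independence_reliability("s", "x", c("a", "b", "y"), d,
                                 bccd_config(max_subset_size = 3))
  expect_identical(st$source, "singular")
  expect_equal(st$reliability, 0)
  # a variable that is constant given z is conditionally independent of
  # anything; the averaged score removes the edge (reliability above the
  # decision threshold, though structures with spurious extra parents keep
  # some posterior mass)
  st2 <- independence_reliability("s", "x", c("a", "b"), d, small_config())
  expect_gt(st2$reliability, 0.5)
})

test_that("argument validation catches misuse", {
  d <- data.frame(a = rnorm(10), b = rnorm(10))
  expect_error(independence_reliability("a", "zz", character(0), d),
               "unknown variable")
  expect_error(independence_reliability("a", "a", character(0), d),
               "disjoint")
  expect_error(independence_reliability("a", "b", "a", d), "disjoint")
})

test_that("chain independence evidence grows with the sample size", {
  rels <- sapply(c(200, 1000, 5000), function(n) {
    mean(sapply(1:10, function(s) {
      set.seed(1000 + s)
      x <- rnorm(n); w <- 0.8 * x + 0.6 * rnorm(n)
      y <- 0.8 * w + 0.6 * rnorm(n)
      independence_reliability("x", "y", "w", data.frame(x, w, y),
                               small_config())$reliability
    }))
  })
  expect_true(all(diff(rels) >= 0))
})
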