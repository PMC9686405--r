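test_that("scale scoring handles keys, extremes and higher-order maps", {
  one <- matrix(1L, 3, 21,
                dimnames = list(NULL, sprintf("S_%02d", 1:21)))
  expect_equal(score_scales(item_matrix(one))$S, rep(21, 3))
  zero <- one * 0L
  expect_equal(score_scales(item_matrix(zero))$S, rep(0, 3))
  # hand-worked 3-person fixture with mixed keys
  sc <- score_scales(toy_items())
  expect_equal(sc$A, c(4, 2, 3))
  expect_equal(sc$B, c(0, 1, 2))
  ho <- score_scales(toy_items(), higher_order_map = list(AB = c("A", "B")))
  expect_equal(ho$AB, sc$A + sc$B)
  expect_error(score_scales(toy_items(), list(X = "nope")), "unknown scale")
  expect_error(item_matrix(matrix(2, 2, 1, dimnames = list(NULL, "A_1"))),
               "0 or 1")
})

test_that("one-factor model df equals the free-parameter difference", {
  expect_identical(efa_model_df(192), 18144L)
  expect_identical(efa_model_df(168), 13860L)
  expect_identical(efa_model_df(3), 0L)
  for (p in 3:300) {
    expect_equal(efa_model_df(p), p * (p + 1) / 2 - 2 * p)
  }
  expect_error(efa_model_df(2), "not testable")
})

test_that("ML EFA recovers an exact one-factor structure", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  R <- tcrossprod(lam); diag(R) <- 1
  dimnames(R) <- list(paste0("i", 1:4), paste0("i", 1:4))
  fit <- one_factor_efa_ml(R, n = 2000, max_iter = 500, tol = 1e-12)
  expect_true(fit$converged)
  expect_equal(unname(fit$loadings), lam, tolerance = 1e-4)
  expect_lt(fit$discrepancy, 1e-8)
  expect_equal(unname(fit$uniquenesses), 1 - lam^2, tolerance = 1e-4)
  # the default 25-iteration cap still lands close
  fit25 <- one_factor_efa_ml(R, n = 2000)
  expect_equal(unname(fit25$loadings), lam, tolerance = 5e-3)
})

test_that("an identity correlation matrix carries no common factor", {
  R <- diag(5)
  dimnames(R) <- list(paste0("i", 1:5), paste0("i", 1:5))
  fit <- one_factor_efa_ml(R, n = 500)
  expect_equal(unname(fit$loadings), rep(0, 5))
  expect_equal(fit$chi_square, 0)
  expect_identical(fit$df, efa_model_df(5))
})

test_that("the chi-square uses the Bartlett correction", {
  set.seed(1)
  X <- matrix(rnorm(600), 100, 6)
  X[, 2] <- X[, 1] * 0.6 + X[, 2]
  R <- cor(X); dimnames(R) <- list(paste0("i", 1:6), paste0("i", 1:6))
  n <- 100; p <- 6
  fit <- one_factor_efa_ml(R, n = n)
  expect_equal(fit$chi_square,
               (n - 1 - (2 * p + 5) / 6 - 2 / 3) * fit$discrepancy)
})

test_that("EFA is invariant to item order and matches factanal", {
  set.seed(21)
  lam <- runif(7, 0.3, 0.8)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  noise <- cor(matrix(rnorm(70 * 7), 70, 7))
  R <- 0.9 * R + 0.1 * noise
  dimnames(R) <- list(paste0("i", 1:7), paste0("i", 1:7))
  fit <- one_factor_efa_ml(R, n = 500, max_iter = 200, tol = 1e-10)
  perm <- sample(7)
  fit_p <- one_factor_efa_ml(R[perm, perm], n = 500, max_iter = 200,
                             tol = 1e-10)
  expect_equal(fit_p$loadings[names(fit$loadings)], fit$loadings,
               tolerance = 1e-6)
  expect_equal(fit_p$discrepancy, fit$discrepancy, tolerance = 1e-8)
  # independent implementation as cross-check
  fa <- stats::factanal(covmat = R, factors = 1, n.obs = 500)
  expect_equal(unname(fit$loadings), unname(as.numeric(fa$loadings)),
               tolerance = 1e-3)
})

test_that("Heywood cases are floored and flagged", {
  # implied lambda_1^2 = .9 * .9 / .3 = 2.7 > 1: a textbook Heywood case
  R <- matrix(c(1, .9, .9, .9, 1, .3, .9, .3, 1), 3, 3)
  dimnames(R) <- list(paste0("i", 1:3), paste0("i", 1:3))
  fit <- one_factor_efa_ml(R, n = 100, max_iter = 100)
  expect_true(fit$heywood)
  expect_true(all(fit$uniquenesses >= 0.005))
})

test_that("proxy selection keeps the k largest absolute loadings", {
  V <- matrix(rbinom(60, 1, 0.5), 20, 3,
              dimnames = list(NULL, c("A_1", "A_2", "B_1")))
  im <- item_matrix(V)
  sol <- structure(list(loadings = c(A_1 = 0.9, A_2 = -0.85, B_1 = 0.5)),
                   class = "efa1")
  px <- select_p_proxy(sol, im, k = 2)
  expect_setequal(px$selected_items, c("A_1", "A_2"))
  expect_identical(px$item_keys[["A_2"]], -1L)
  expect_equal(px$scores, V[, "A_1"] + (1L - V[, "A_2"]))
  # k = pool size keeps everything
  expect_length(select_p_proxy(sol, im, k = 3)$selected_items, 3)
  expect_error(select_p_proxy(sol, im, k = 4), "smaller than k")
  # excluded scale shrinks the pool
  px_b <- select_p_proxy(sol, im, k = 1, excluded_scale = "A")
  expect_identical(px_b$selected_items, "B_1")
})

test_that("proxy selection is invariant to a whole-factor sign flip", {
  set.seed(3)
  V <- matrix(rbinom(200, 1, 0.5), 20, 10,
              dimnames = list(NULL, sprintf("A_%02d", 1:10)))
  im <- item_matrix(V)
  lam <- runif(10, -0.8, 0.8); names(lam) <- colnames(V)
  sol <- structure(list(loadings = lam), class = "efa1")
  sol_neg <- structure(list(loadings = -lam), class = "efa1")
  a <- select_p_proxy(sol, im, k = 4)
  b <- select_p_proxy(sol_neg, im, k = 4)
  expect_identical(a$selected_items, b$selected_items)
  expect_identical(b$item_keys, -a$item_keys)
  expect_equal(b$scores, 4 - a$scores)
})

test_that("Cronbach's alpha matches its closed forms", {
  set.seed(4)
  x <- rnorm(60)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # two uncorrelated equal-variance columns: alpha 0 in expectation; use an
  # exactly orthogonal construction
  a <- rep(c(1, -1), 30); b <- rep(c(1, 1, -1, -1), 15)
  expect_equal(cronbach_alpha(cbind(a, b)), 0)
  expect_error(cronbach_alpha(cbind(a, -a)), "zero variance")
})

test_that("correlation tables flag significance and degenerate columns", {
  x <- c(1, 2, 3, 4, 5)
  tb <- correlation_table(data.frame(x = x, mx = -x, k = rep(1, 5)))
  expect_equal(tb$r[tb$a == "x" & tb$b == "mx"], -1)
  expect_true(is.na(tb$r[tb$b == "k"][1]))
  # hand-worked pair
  y <- c(1, 2, 4, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tb2 <- correlation_table(data.frame(x = x, y = y))
  expect_equal(tb2$r, r_hand)
  expect_identical(tb2$sig, "*")
})

test_that("pooled t from summaries matches hand unit cases", {
  expect_equal(pooled_t_from_summary(1, 1, 5, 1, 1, 5)$t_statistic, 0)
  unit <- pooled_t_from_summary(1, 1, 2, 0, 1, 2)
  expect_equal(unit$t_statistic, 1)
  expect_identical(unit$t_df, 2)
  expect_error(pooled_t_from_summary(1, 0, 5, 0, 1, 5), "sd")
})

test_that("2x2 chi-square matches the brute-force expected counts", {
  tab <- matrix(c(30, 20, 25, 25), 2, 2)
  out <- chisq_2x2(tab, yates = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  E <- outer(rs, cs) / n
  expect_equal(unname(out$expected), unname(E))
  expect_equal(out$chi_square, sum((tab - E)^2 / E))
  expect_equal(out$chi_df, 1)
  # equal row proportions give zero
  expect_equal(chisq_2x2(matrix(c(40, 20, 40, 20), 2, 2),
                         yates = FALSE)$chi_square, 0)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginals")
})
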