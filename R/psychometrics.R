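#' Item response matrix
#'
#' Bundles a person-by-item table of 0/1 responses with the item-to-scale
#' map and the item key directions (+1 keyed true, -1 keyed false). A raw
#' scale score is the keyed sum over the scale's items: the response itself
#' for a positively keyed item, `1 - response` for a negatively keyed one.
#'
#' @param values matrix or data frame of 0/1 responses (columns = items).
#' @param item_scale_map named character vector, item id -> scale name.
#'   Defaults to the part of each column name before the last underscore.
#' @param key named integer vector of +1/-1 key directions (default all +1).
#' @return an object of class `item_matrix`.
#' @export
item_matrix <- function(values, item_scale_map = NULL, key = NULL) {
  X <- as.matrix(values)
  if (is.null(colnames(X))) stop("item columns must be named")
  if (!all(X %in% c(0L, 1L))) stop("item responses must all be 0 or 1")
  storage.mode(X) <- "integer"
  ids <- colnames(X)
  if (is.null(item_scale_map)) {
    item_scale_map <- stats::setNames(sub("_[^_]*$", "", ids), ids)
  }
  if (!all(ids %in% names(item_scale_map))) {
    stop("item_scale_map must cover every item")
  }
  if (is.null(key)) key <- stats::setNames(rep(1L, length(ids)), ids)
  if (!all(ids %in% names(key))) stop("key must cover every item")
  structure(list(values = X, item_ids = ids,
                 item_scale_map = item_scale_map[ids],
                 key = as.integer(key[ids])), class = "item_matrix")
}

#' @export
print.item_matrix <- function(x, ...) {
  cat(sprintf("Item responses: %d persons x %d items over %d scales (%d reverse-keyed)\n",
              nrow(x$values), length(x$item_ids),
              length(unique(x$item_scale_map)), sum(x$key < 0)))
  invisible(x)
}

#' Keyed responses (response if key = +1, 1 - response otherwise)
#' @keywords internal
keyed_values <- function(items) {
  V <- items$values
  neg <- items$key < 0
  if (any(neg)) V[, neg] <- 1L - V[, neg, drop = FALSE]
  V
}

#' Raw scale scores from item responses
#'
#' Sums the keyed responses of each scale's items. When a higher-order map
#' is supplied (named list of constituent scale names), keyed item sums
#' over the constituent scales' items are appended as higher-order
#' composites.
#'
#' @param items an [item_matrix()].
#' @param higher_order_map optional named list of character vectors, e.g.
#'   [default_higher_order_map()].
#' @return data frame of raw sum scores, one column per scale (plus one per
#'   higher-order composite).
#' @examples
#' im <- item_matrix(matrix(c(1, 0, 1, 1), 2, 2,
#'                   dimnames = list(NULL, c("A_1", "A_2"))))
#' score_scales(im)
#' @export
score_scales <- function(items, higher_order_map = NULL) {
  stopifnot(inherits(items, "item_matrix"))
  V <- keyed_values(items)
  map <- items$item_scale_map
  scales <- unique(map)
  out <- sapply(scales, function(s) rowSums(V[, map == s, drop = FALSE]))
  out <- as.data.frame(out)
  names(out) <- scales
  if (!is.null(higher_order_map)) {
    for (h in names(higher_order_map)) {
      member <- higher_order_map[[h]]
      bad <- setdiff(member, scales)
      if (length(bad)) stop("higher-order map references unknown scale: ",
                            paste(bad, collapse = ", "))
      out[[h]] <- rowSums(V[, map %in% member, drop = FALSE])
    }
  }
  out
}

#' Degrees of freedom of the one-factor model
#'
#' For `p` observed variables the single-factor model leaves
#' `p(p+1)/2 - 2p = p(p-3)/2` degrees of freedom.
#'
#' @param p number of items (at least 3; with fewer the model is not
#'   testable).
#' @return integer degrees of freedom.
#' @examples
#' efa_model_df(192)  # 18144
#' efa_model_df(168)  # 13860
#' @export
efa_model_df <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 3) stop("one-factor model is not testable for p < 3")
  as.integer(p * (p - 3) / 2)
}

#' One-factor maximum-likelihood factor analysis
#'
#' Fits the single-factor model `Sigma = lambda lambda' + Psi` to a
#' correlation matrix by conditional maximization: given uniquenesses, the
#' loading vector comes from the leading eigenpair of
#' `Psi^{-1/2} R Psi^{-1/2}`; uniquenesses are then updated to
#' `1 - lambda^2`. Iteration stops when the maximum-likelihood discrepancy
#' changes by less than `tol` or after `max_iter` iterations (the default
#' cap of 25 mirrors common statistical-software practice). The chi-square
#' statistic uses the Bartlett correction
#' `(n - 1 - (2p+5)/6 - 2/3) * F_ML` on `p(p-3)/2` degrees of freedom.
#' Uniquenesses are floored at 0.005 and flagged (Heywood case) rather than
#' allowed to collapse. The loading sign is fixed so their sum is
#' non-negative.
#'
#' @param corr correlation matrix (unit diagonal, positive semi-definite).
#' @param n sample size behind `corr` (must exceed the number of items).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the discrepancy.
#' @return an object of class `efa1` with elements `loadings`,
#'   `uniquenesses`, `discrepancy`, `chi_square`, `df`, `n`, `converged`,
#'   `iterations`, `heywood`.
#' @examples
#' lam <- c(0.8, 0.7, 0.6, 0.5)
#' R <- tcrossprod(lam); diag(R) <- 1
#' fit <- one_factor_efa_ml(R, n = 1000)
#' round(fit$loadings, 3)
#' @export
one_factor_efa_ml <- function(corr, n, max_iter = 25L, tol = 1e-6) {
  R <- as.matrix(corr)
  p <- ncol(R)
  stopifnot(nrow(R) == p, p >= 2)
  if (max(abs(diag(R) - 1)) > 1e-8) stop("corr must have a unit diagonal")
  if (n <= p) stop("sample size must exceed the number of items")

  ldR <- determinant(R, logarithm = TRUE)$modulus[1]
  psi <- rep(0.5, p)
  lam <- rep(0, p)
  heywood <- FALSE
  discrepancy <- function(lam, psi) {
    ip <- 1 / psi
    q <- sum(lam^2 * ip)
    logdet <- sum(log(psi)) + log1p(q)
    u <- lam * ip
    tr <- sum(diag(R) * ip) - c(crossprod(u, R %*% u)) / (1 + q)
    logdet + tr - ldR - p
  }
  Fv <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- 1 / sqrt(psi)
    M <- R * tcrossprod(d)
    e <- eigen(M, symmetric = TRUE)
    theta <- e$values[1]
    lam <- if (theta > 1) sqrt(psi) * e$vectors[, 1] * sqrt(theta - 1)
           else rep(0, p)
    psi_new <- 1 - lam^2
    if (any(psi_new <= 0.005)) heywood <- TRUE
    psi <- pmax(psi_new, 0.005)
    Fnew <- discrepancy(lam, psi)
    if (is.finite(Fv) && abs(Fv - Fnew) < tol) {
      Fv <- Fnew
      converged <- TRUE
      break
    }
    Fv <- Fnew
  }
  if (sum(lam) < 0) lam <- -lam
  # the one-factor model is not identified when no common variance exists
  # (e.g. an identity matrix); prefer the null solution when it fits as well
  F_null <- -ldR
  if (F_null <= Fv + tol) {
    lam <- rep(0, p); psi <- rep(1, p); Fv <- F_null
    converged <- TRUE; heywood <- FALSE
  }
  Fv <- max(Fv, 0)
  names(lam) <- names(psi) <- colnames(R)
  chi <- max((n - 1 - (2 * p + 5) / 6 - 2 / 3) * Fv, 0)
  structure(list(loadings = lam, uniquenesses = psi, discrepancy = Fv,
                 chi_square = chi, df = if (p >= 3) efa_model_df(p) else NA_integer_,
                 n = n, converged = converged, iterations = iter,
                 heywood = heywood), class = "efa1")
}

#' @export
print.efa1 <- function(x, ...) {
  cat(sprintf("One-factor ML solution: %d items, n = %d\n",
              length(x$loadings), x$n))
  cat(sprintf("  chi-square = %.2f on %s df, F = %.5f, %s after %d iterations%s\n",
              x$chi_square, format(x$df), x$discrepancy,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, if (x$heywood) " [Heywood]" else ""))
  invisible(x)
}

#' Extract a p-factor proxy scale from a factor solution
#'
#' Ranks the pool items by absolute loading (descending, ties broken by
#' pool order), keeps the top `k`, reverse-keys items with negative
#' loadings, and scores each person as the keyed sum over the selected
#' items. When `excluded_scale` is given, that scale's items are removed
#' from the pool before ranking (the "p-factor" variant excludes RCd; the
#' "p_factor_rcd" variant excludes nothing).
#'
#' @param solution an [one_factor_efa_ml()] fit whose loadings are named by
#'   item id.
#' @param items the [item_matrix()] holding those items.
#' @param k number of items to keep (default 21, the average scale length).
#' @param excluded_scale optional scale name to drop from the pool.
#' @return an object of class `p_proxy`: `selected_items`, `item_keys`
#'   (+1/-1 relative to the stored responses), `loadings`, `scores`,
#'   `excluded_scale`.
#' @export
select_p_proxy <- function(solution, items, k = 21L, excluded_scale = NULL) {
  stopifnot(inherits(solution, "efa1"), inherits(items, "item_matrix"))
  lam <- solution$loadings
  pool <- names(lam)
  if (!all(pool %in% items$item_ids)) {
    stop("solution contains items absent from the item matrix")
  }
  if (!is.null(excluded_scale)) {
    pool <- pool[items$item_scale_map[pool] != excluded_scale]
  }
  if (length(pool) < k) stop("item pool smaller than k")
  lam <- lam[pool]
  ord <- order(-abs(lam))   # ties: stable, pool order
  sel <- pool[ord[seq_len(k)]]
  keys <- ifelse(lam[sel] >= 0, 1L, -1L)
  V <- items$values[, sel, drop = FALSE]
  neg <- keys < 0
  if (any(neg)) V[, neg] <- 1L - V[, neg, drop = FALSE]
  structure(list(selected_items = sel,
                 item_keys = stats::setNames(as.integer(keys), sel),
                 loadings = lam[sel],
                 scores = rowSums(V),
                 excluded_scale = excluded_scale), class = "p_proxy")
}

#' @export
print.p_proxy <- function(x, ...) {
  org <- table(sub("_[^_]*$", "", x$selected_items))
  cat(sprintf("p-factor proxy: %d items%s, |loadings| %.2f-%.2f\n",
              length(x$selected_items),
              if (is.null(x$excluded_scale)) ""
              else paste0(" (pool excludes ", x$excluded_scale, ")"),
              min(abs(x$loadings)), max(abs(x$loadings))))
  cat("  origin:", paste(sprintf("%s:%d", names(org), org), collapse = " "), "\n")
  invisible(x)
}

#' Run the full proxy construction on an item pool
#'
#' Convenience wrapper: subsets the pool (optionally dropping one scale's
#' items), computes product-moment correlations of the 0/1 responses, fits
#' the one-factor ML model, and extracts the top-`k` proxy. Thomson
#' regression factor scores over the whole pool are returned alongside the
#' keyed sum scores.
#'
#' @inheritParams select_p_proxy
#' @param items an [item_matrix()].
#' @param max_iter,tol passed to [one_factor_efa_ml()].
#' @return a `p_proxy` with extra fields `solution` (the `efa1` fit on the
#'   pool) and `regression_scores`.
#' @export
extract_p_proxy <- function(items, k = 21L, excluded_scale = NULL,
                            max_iter = 25L, tol = 1e-6) {
  stopifnot(inherits(items, "item_matrix"))
  pool <- items$item_ids
  if (!is.null(excluded_scale)) {
    pool <- pool[items$item_scale_map[pool] != excluded_scale]
  }
  X <- items$values[, pool, drop = FALSE]
  R <- stats::cor(X)
  fit <- one_factor_efa_ml(R, n = nrow(X), max_iter = max_iter, tol = tol)
  px <- select_p_proxy(fit, items, k = k, excluded_scale = excluded_scale)
  lam <- fit$loadings
  w <- lam / fit$uniquenesses
  q <- sum(lam * w)
  px$solution <- fit
  px$regression_scores <- as.numeric(scale(X) %*% w / (1 + q))
  px
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of sum)`.
#'
#' @param columns person-by-item table (at least 2 columns and rows).
#' @return numeric alpha.
#' @examples
#' x <- matrix(rnorm(100), 50, 2); cronbach_alpha(cbind(x, x))
#' @export
cronbach_alpha <- function(columns) {
  X <- as.matrix(columns)
  k <- ncol(X)
  stopifnot(k >= 2, nrow(X) >= 2)
  tot <- stats::var(rowSums(X))
  if (tot <= .Machine$double.eps) {
    stop("total score has zero variance; alpha is undefined")
  }
  k / (k - 1) * (1 - sum(apply(X, 2, stats::var)) / tot)
}

#' Pairwise correlation table with significance flags
#'
#' Product-moment correlations among the requested variables with two-sided
#' significance flags at the 0.05 and 0.01 levels. Pairs involving a
#' constant column are reported as missing.
#'
#' @param scores data frame of numeric variables.
#' @param targets variables to correlate (default all).
#' @return data frame with columns `a`, `b`, `r`, `p`, `sig` (`""`, `"*"`,
#'   `"**"`).
#' @export
correlation_table <- function(scores, targets = names(scores)) {
  X <- as.data.frame(scores)[, targets, drop = FALSE]
  n <- nrow(X)
  stopifnot(n >= 3)
  prs <- utils::combn(targets, 2)
  res <- apply(prs, 2, function(pr) {
    x <- X[[pr[1]]]; y <- X[[pr[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    r <- stats::cor(x, y)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r, 2 * stats::pt(-abs(tt), df = n - 2))
  })
  data.frame(a = prs[1, ], b = prs[2, ], r = res[1, ], p = res[2, ],
             sig = ifelse(is.na(res[2, ]), NA_character_,
                          ifelse(res[2, ] < 0.01, "**",
                                 ifelse(res[2, ] < 0.05, "*", ""))),
             stringsAsFactors = FALSE)
}

#' Two-sample pooled-variance t test from summary statistics
#'
#' @param m1,sd1,n1 mean, SD and size of the first sample.
#' @param m2,sd2,n2 mean, SD and size of the second sample.
#' @return list with `t_statistic`, `t_df`, `p_value`.
#' @examples
#' pooled_t_from_summary(49.1, 16.4, 3242, 35.1, 11.9, 2466)
#' @export
pooled_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t_statistic = tval, t_df = df,
       p_value = 2 * stats::pt(-abs(tval), df = df))
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square with optional Yates continuity correction, one degree
#' of freedom. Wraps [stats::chisq.test()].
#'
#' @param counts 2x2 table of non-negative counts with positive marginals.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return list with `chi_square`, `chi_df`, `p_value`, `yates_applied`,
#'   `expected`.
#' @export
chisq_2x2 <- function(counts, yates = TRUE) {
  M <- as.matrix(counts)
  stopifnot(all(dim(M) == c(2, 2)), all(M >= 0))
  if (any(rowSums(M) == 0) || any(colSums(M) == 0)) {
    stop("all marginals of the 2x2 table must be positive")
  }
  ct <- stats::chisq.test(M, correct = yates)
  list(chi_square = unname(ct$statistic), chi_df = unname(ct$parameter),
       p_value = ct$p.value, yates_applied = yates, expected = ct$expected)
}
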