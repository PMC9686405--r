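#' Simulate item responses and scale scores from a generating model
#'
#' Draws the context indicator, age and gender, the general factor G (whose
#' mean is shifted by `context_effect` SD for clinical respondents), the six
#' spectrum factors, the latent scale composites, latent item variables, and
#' dichotomizes the latter at the item thresholds. Raw scale scores are
#' keyed sums of the item responses. The three higher-order variables are
#' simulated as noisy measurements of their spectrum-factor composites: EID
#' of internalizing + detachment, THD of thought disorder, BXD of the two
#' externalizing spectra. The general factor is standardized exactly, so the
#' empirical covariance of the latent composites converges to
#' [implied_scale_covariance()].
#'
#' @param object a [pf_model()].
#' @param nsim number of respondents.
#' @param seed integer seed; the same `(model, nsim, seed)` triple gives
#'   bit-identical output.
#' @param ... unused.
#' @return an object of class `pf_sim`: a list with
#'   \describe{
#'     \item{items}{data frame of 0/1 responses, one column per item, plus
#'       `sample`, `age`, `gender`.}
#'     \item{scales}{data frame of raw scale scores, higher-order scores
#'       `EID`/`THD`/`BXD`, and `sample`, `age`, `gender`.}
#'     \item{latents}{data frame of the latent general factor `G`, spectrum
#'       factors and scale composites.}
#'     \item{truth}{the generating model.}
#'     \item{true_adjacencies}{data frame of scale pairs sharing a spectrum
#'       factor (ground truth for structure-recovery checks).}
#'     \item{roles}{roles of the `scales` columns.}
#'     \item{seed}{the seed used.}
#'   }
#' @examples
#' sim <- simulate(pf_model("bifactor"), nsim = 200, seed = 1)
#' dim(sim$items); names(sim$scales)
#' @export
simulate.pf_model <- function(object, nsim = 5708, seed = 1L, ...) {
  model <- object
  n <- as.integer(nsim)
  if (n < 2) stop("nsim must be at least 2")
  set.seed(as.integer(seed))

  pc <- model$clinical_fraction
  vc <- pc * (1 - pc)
  wa <- model$covariate_effects[["age"]]
  wg <- model$covariate_effects[["gender"]]
  pg <- 0.45
  vg <- pg * (1 - pg)

  ctx <- stats::rbinom(n, 1L, pc)
  age <- stats::rnorm(n, 43, 16.2)
  gender <- stats::rbinom(n, 1L, pg)
  agez <- (age - 43) / 16.2

  # raw shift chosen so that, after standardization of G, the clinical
  # group mean exceeds the normative one by exactly context_effect SD
  D <- model$context_effect
  Draw <- D * sqrt((1 + wa^2 + wg^2 * vg) / (1 - D^2 * vc))
  s <- sqrt(Draw^2 * vc + wa^2 + wg^2 * vg + 1)
  G <- (Draw * (ctx - pc) + wa * agez + wg * (gender - pg) + stats::rnorm(n)) / s

  sps <- spectrum_names()
  if (model$kind == "bifactor") {
    Fm <- matrix(stats::rnorm(n * length(sps)), n, length(sps),
                 dimnames = list(NULL, sps))
  } else {
    gam <- model$hierarchy_loading[sps]
    U <- matrix(stats::rnorm(n * length(sps)), n, length(sps))
    Fm <- sweep(U, 2, sqrt(1 - gam^2), `*`) + outer(G, gam)
    colnames(Fm) <- sps
  }

  # composites: loadings on (G, orthogonal spectrum components); for the
  # hierarchical kind the factor draw above already mixes G into Fm, so
  # composites are built from the model's raw loadings directly
  scales <- model$scales
  S <- matrix(0, n, length(scales), dimnames = list(NULL, scales))
  prim <- model$spectra_map$primary
  ve <- rowSums(composite_loading_matrix(model)^2)  # explained variance
  for (sc in scales) {
    cl <- model$cross_loadings
    cx <- cl[cl$scale == sc, , drop = FALSE]
    if (model$kind == "bifactor") {
      comp <- model$general_loading[[sc]] * G +
        model$specific_loading[[sc]] * Fm[, prim[[sc]]]
    } else {
      comp <- model$scale_loading[[sc]] * Fm[, prim[[sc]]]
    }
    if (nrow(cx)) {
      for (i in seq_len(nrow(cx))) {
        comp <- comp + cx$loading[i] * Fm[, cx$spectrum[i]]
      }
    }
    S[, sc] <- comp + sqrt(1 - ve[[sc]]) * stats::rnorm(n)
  }

  # items: latent y = a * composite + sqrt(1-a^2) * noise, cut at tau
  ids <- model$item_ids
  a <- model$item_loading
  tau <- model$item_threshold
  key <- model$item_key
  imap <- model$item_scale_map
  X <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    y <- a[j] * S[, imap[j]] + sqrt(1 - a[j]^2) * stats::rnorm(n)
    zj <- as.integer(y > tau[j])
    X[, j] <- if (key[j] > 0) zj else 1L - zj
  }

  items <- data.frame(X, check.names = FALSE)
  items$sample <- ctx
  items$age <- age
  items$gender <- gender

  irm <- item_matrix(X, item_scale_map = imap, key = key)
  raw <- score_scales(irm)

  ho <- ho_spectra_map()
  aho <- model$ho_loading
  HO <- sapply(names(ho), function(h) {
    sp <- ho[[h]]
    f <- rowSums(Fm[, sp, drop = FALSE])
    # analytic variance of the spectrum-factor sum (factors are orthogonal
    # in the bifactor kind, correlated gamma_c * gamma_d hierarchically)
    v <- length(sp)
    if (model$kind == "hierarchical" && length(sp) > 1) {
      gam <- model$hierarchy_loading[sp]
      v <- v + 2 * sum(utils::combn(gam, 2, prod))
    }
    aho * f / sqrt(v) + sqrt(1 - aho^2) * stats::rnorm(n)
  })
  colnames(HO) <- names(ho)

  scl <- data.frame(raw, HO, sample = ctx, age = age, gender = gender,
                    check.names = FALSE)

  pairs <- utils::combn(scales, 2)
  shared <- apply(pairs, 2, function(p)
    shares_spectrum(model$spectra_map, p[1], p[2]))
  true_adj <- data.frame(a = pairs[1, shared], b = pairs[2, shared],
                         stringsAsFactors = FALSE)

  structure(list(
    items = items,
    scales = scl,
    latents = data.frame(G = G, Fm, S, check.names = FALSE),
    truth = model,
    true_adjacencies = true_adj,
    roles = infer_roles(names(scl)),
    seed = as.integer(seed)
  ), class = "pf_sim")
}

#' @export
print.pf_sim <- function(x, ...) {
  cat(sprintf("Synthetic sample: %d persons, %d items, %d scale columns (%s)\n",
              nrow(x$items), length(x$truth$item_ids), ncol(x$scales),
              x$truth$kind))
  cat(sprintf("  clinical %d / normative %d, seed %d\n",
              sum(x$items$sample == 1), sum(x$items$sample == 0), x$seed))
  invisible(x)
}
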