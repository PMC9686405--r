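#' Construct a generating model for synthetic scale and item data
#'
#' Builds the ground-truth latent structure from which item responses and
#' scale scores are simulated. Two kinds are supported. In the *bifactor*
#' kind every scale composite loads directly on a general factor G and on
#' its spectrum factor (with the spectrum factors orthogonal to G). In the
#' *hierarchical* kind G acts only through the spectrum factors:
#' `F_c = gamma_c * G + sqrt(1 - gamma_c^2) * u_c`, and scales load on their
#' spectrum factor alone.
#'
#' The defaults emulate a combined clinical/normative administration of a
#' nine-scale dichotomous inventory: 21 true/false items per scale (24 for
#' RCd, so the full pool has 192 items and the pool without RCd has 168),
#' heterogeneous item quality, a clinical/normative context indicator that
#' shifts the mean of G, and small age and gender effects on G. General
#' loadings are highest for demoralization (RCd) and dysfunctional negative
#' emotions (RC7) and lowest for cynicism (RC3), mirroring the ordering of
#' published proxy-scale correlations; per-scale values can be overridden.
#'
#' @param kind `"bifactor"` or `"hierarchical"`.
#' @param general_loading named numeric vector in (0,1), per-scale loading on
#'   G (bifactor kind). Scalar values are recycled.
#' @param specific_loading named numeric vector in (0,1), per-scale loading
#'   on the scale's spectrum factor (bifactor kind).
#' @param hierarchy_loading named numeric vector in (0,1) per spectrum: the
#'   coefficient of G in each spectrum factor (hierarchical kind only).
#' @param scale_loading named numeric vector in (0,1), per-scale loading on
#'   its spectrum factor in the hierarchical kind.
#' @param cross_loadings `NULL`, or a data frame with columns `scale`,
#'   `spectrum`, `loading` giving hypothesized secondary loadings. The
#'   default gives RC3 a secondary loading on the thought-disorder spectrum
#'   (0.20 bifactor, 0.15 hierarchical), emulating its diffuse position.
#' @param spectra_map a `spectra_map` (see [default_spectra_map()]).
#' @param n_items named integer vector of items per scale.
#' @param item_loading range (length 2) or constant per-item loading of the
#'   latent item variable on its scale composite.
#' @param item_threshold range (length 2) of dichotomization thresholds in
#'   SD units, drawn uniformly per item.
#' @param reverse_every every `reverse_every`-th item of a scale is keyed
#'   negatively (`0` disables reverse keying).
#' @param context_effect shift (in SD of G) of the general factor for
#'   clinical relative to normative respondents.
#' @param clinical_fraction expected fraction of clinical respondents.
#' @param covariate_effects length-2 numeric, weights of standardized age
#'   and gender on G.
#' @param ho_loading loading of the simulated higher-order scores on their
#'   spectrum factor composites.
#' @param seed integer seed fixing the item design (thresholds, loadings).
#' @return an object of class `pf_model`.
#' @examples
#' m <- pf_model("bifactor")
#' m
#' round(implied_scale_covariance(m)[1:4, 1:4], 3)
#' @export
pf_model <- function(kind = c("bifactor", "hierarchical"),
                     general_loading = NULL,
                     specific_loading = NULL,
                     hierarchy_loading = 0.80,
                     scale_loading = NULL,
                     cross_loadings = NULL,
                     spectra_map = default_spectra_map(),
                     n_items = NULL,
                     item_loading = c(0.45, 0.85),
                     item_threshold = c(0.2, 1.2),
                     reverse_every = 4L,
                     context_effect = 1.0,
                     clinical_fraction = 2466 / 5708,
                     covariate_effects = c(age = 0.1, gender = 0.1),
                     ho_loading = 0.90,
                     seed = 1L) {
  kind <- match.arg(kind)
  scales <- names(spectra_map$primary)
  stopifnot(setequal(unique(spectra_map$primary), spectrum_names()))

  fill <- function(x, default, who) {
    out <- default
    if (!is.null(x)) {
      if (is.null(names(x)) && length(x) == 1L) {
        out[] <- x
      } else {
        bad <- setdiff(names(x), scales)
        if (length(bad)) stop("unknown scale in ", who, ": ",
                              paste(bad, collapse = ", "))
        out[names(x)] <- x
      }
    }
    out
  }

  lg_default <- c(RCd = 0.88, RC1 = 0.72, RC2 = 0.70, RC3 = 0.50, RC4 = 0.68,
                  RC6 = 0.74, RC7 = 0.82, RC8 = 0.78, RC9 = 0.62)
  ls_default <- c(RCd = 0.30, RC1 = 0.45, RC2 = 0.45, RC3 = 0.50, RC4 = 0.45,
                  RC6 = 0.40, RC7 = 0.36, RC8 = 0.40, RC9 = 0.48)
  # RC3 reduced so that, together with its cross-loading and the factor
  # correlation gamma^2, its communality matches the other scales
  lh_default <- c(RCd = 0.85, RC1 = 0.85, RC2 = 0.85, RC3 = 0.75,
                  RC4 = 0.85, RC6 = 0.85, RC7 = 0.85, RC8 = 0.85,
                  RC9 = 0.85)

  lg <- fill(general_loading, lg_default[scales], "general_loading")
  ls <- fill(specific_loading, ls_default[scales], "specific_loading")
  lh <- fill(scale_loading, lh_default[scales], "scale_loading")
  gam <- stats::setNames(rep_len(hierarchy_loading, length(spectrum_names())),
                         spectrum_names())
  if (!is.null(names(hierarchy_loading))) {
    gam[names(hierarchy_loading)] <- hierarchy_loading
  }

  if (is.null(cross_loadings)) {
    cross_loadings <- data.frame(
      scale = "RC3", spectrum = "thought_disorder",
      loading = if (kind == "bifactor") 0.20 else 0.15,
      stringsAsFactors = FALSE)
  }
  if (nrow(cross_loadings)) {
    stopifnot(all(cross_loadings$scale %in% scales),
              all(cross_loadings$spectrum %in% spectrum_names()))
  }

  ni_default <- stats::setNames(rep(21L, length(scales)), scales)
  ni_default["RCd"] <- 24L
  ni <- fill(n_items, ni_default, "n_items")
  storage.mode(ni) <- "integer"

  chk01 <- function(x, who) {
    if (any(x < 0 | x >= 1)) stop(who, " must lie in [0, 1)")
  }
  chk01(lg, "general_loading"); chk01(ls, "specific_loading")
  chk01(lh, "scale_loading"); chk01(gam, "hierarchy_loading")

  vc <- clinical_fraction * (1 - clinical_fraction)
  if (context_effect^2 * vc >= 1) {
    stop("context_effect too large: the implied group shift cannot reach ",
         context_effect, " SD of a unit-variance general factor")
  }

  # fixed item design, drawn once from the model seed
  rng <- local({
    set.seed(seed)
    ids <- unlist(lapply(scales, function(s)
      sprintf("%s_%02d", s, seq_len(ni[[s]]))))
    imap <- rep(scales, ni[scales])
    ail <- if (length(item_loading) == 2L)
      stats::runif(length(ids), item_loading[1], item_loading[2])
    else rep_len(item_loading, length(ids))
    tau <- stats::runif(length(ids), item_threshold[1], item_threshold[2])
    key <- rep(1L, length(ids))
    if (reverse_every > 0) {
      idx <- unlist(lapply(ni[scales], function(k)
        seq_len(k) %% reverse_every == 0))
      key[idx] <- -1L
    }
    list(ids = ids, imap = imap, a = ail, tau = tau, key = key)
  })

  m <- structure(list(
    kind = kind,
    scales = scales,
    spectra_map = spectra_map,
    general_loading = lg,
    specific_loading = ls,
    scale_loading = lh,
    hierarchy_loading = gam,
    cross_loadings = cross_loadings,
    n_items = ni,
    item_ids = rng$ids,
    item_scale_map = stats::setNames(rng$imap, rng$ids),
    item_loading = stats::setNames(rng$a, rng$ids),
    item_threshold = stats::setNames(rng$tau, rng$ids),
    item_key = stats::setNames(rng$key, rng$ids),
    context_effect = context_effect,
    clinical_fraction = clinical_fraction,
    covariate_effects = covariate_effects,
    ho_loading = ho_loading,
    seed = as.integer(seed)
  ), class = "pf_model")

  # residual variance of each composite must stay positive (explained
  # variance from the orthogonalized loading rows, which accounts for the
  # factor correlations the hierarchical kind induces)
  ve <- rowSums(composite_loading_matrix(m)^2)
  if (any(ve >= 1)) {
    bad <- names(ve)[which.max(ve)]
    stop("loadings for scale ", bad, " imply non-positive residual ",
         "variance (explained variance ", round(max(ve), 3), " >= 1)")
  }
  # positive definiteness of the implied composite covariance
  ev <- eigen(implied_scale_covariance(m), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("implied scale covariance is not positive definite")
  m
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf("Generating model (%s): %d scales, %d spectra, %d items\n",
              x$kind, length(x$scales), length(spectrum_names()),
              length(x$item_ids)))
  lam <- if (x$kind == "bifactor") x$general_loading else x$scale_loading
  cat("  loadings: ",
      paste(sprintf("%s=%.2f", names(lam), lam), collapse = " "), "\n",
      sep = "")
  cat(sprintf("  context shift %.2f SD, clinical fraction %.3f, seed %d\n",
              x$context_effect, x$clinical_fraction, x$seed))
  invisible(x)
}

#' Loading matrix of the scale composites on orthogonal factors
#'
#' Columns: G then the six spectrum-specific (orthogonalized) factors. In
#' the hierarchical kind the spectrum factors are re-expressed as
#' `gamma_c G + sqrt(1-gamma_c^2) u_c`, so a scale's effective G loading is
#' `lambda_c * gamma_c`.
#'
#' @keywords internal
composite_loading_matrix <- function(model) {
  scales <- model$scales
  sps <- spectrum_names()
  L <- matrix(0, length(scales), 1 + length(sps),
              dimnames = list(scales, c("G", sps)))
  prim <- model$spectra_map$primary
  add <- function(L, s, sp, lam) {
    if (model$kind == "bifactor") {
      L[s, sp] <- L[s, sp] + lam
    } else {
      g <- model$hierarchy_loading[[sp]]
      L[s, "G"] <- L[s, "G"] + lam * g
      L[s, sp] <- L[s, sp] + lam * sqrt(1 - g^2)
    }
    L
  }
  for (s in scales) {
    if (model$kind == "bifactor") L[s, "G"] <- model$general_loading[[s]]
    lam <- if (model$kind == "bifactor") model$specific_loading[[s]]
           else model$scale_loading[[s]]
    L <- add(L, s, prim[[s]], lam)
  }
  cl <- model$cross_loadings
  if (!is.null(cl) && nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      L <- add(L, cl$scale[i], cl$spectrum[i], cl$loading[i])
    }
  }
  L
}

#' Implied covariance of the latent scale composites
#'
#' Closed-form covariance of the standardized, pre-dichotomization scale
#' composites under the linear-Gaussian generating model; the diagonal is 1.
#' For two bifactor scales in different spectra the entry is the product of
#' their general loadings; scales sharing a spectrum add the product of the
#' specific loadings.
#'
#' @param model a [pf_model()]
#' @return symmetric positive-definite matrix over the scales.
#' @export
implied_scale_covariance <- function(model) {
  stopifnot(inherits(model, "pf_model"))
  L <- composite_loading_matrix(model)
  S <- tcrossprod(L)
  diag(S) <- 1
  S
}

#' Adjacency matrix of the generating DAG
#'
#' Nodes: context (`sample`, `age`, `gender`), the general factor `G`, the
#' six spectrum factors, and the scale composites. Entry `[i, j] = 1` means
#' an edge i -> j.
#'
#' @keywords internal
model_dag <- function(model) {
  sps <- spectrum_names()
  nodes <- c("sample", "age", "gender", "G", sps, model$scales)
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  A[c("sample", "age", "gender"), "G"] <- 1L
  prim <- model$spectra_map$primary
  if (model$kind == "bifactor") {
    A["G", model$scales] <- 1L
    for (s in model$scales) A[prim[[s]], s] <- 1L
  } else {
    A["G", sps] <- 1L
    for (s in model$scales) A[prim[[s]], s] <- 1L
  }
  cl <- model$cross_loadings
  if (!is.null(cl) && nrow(cl)) {
    for (i in seq_len(nrow(cl))) A[cl$spectrum[i], cl$scale[i]] <- 1L
  }
  A
}
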