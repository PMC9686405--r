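test_that("default models are fully populated and pass their invariants", {
  for (kind in c("bifactor", "hierarchical")) {
    m <- pf_model(kind)
    expect_length(m$scales, 9)
    expect_setequal(unique(m$spectra_map$primary), spectrum_names())
    expect_length(m$item_ids, 192)
    expect_equal(sum(m$item_scale_map != "RCd"), 168)
    S <- implied_scale_covariance(m)
    expect_equal(diag(S), setNames(rep(1, 9), m$scales))
    expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 0)
  }
  # bifactor G touches every scale directly, hierarchical only via spectra
  A_b <- pfnet:::model_dag(pf_model("bifactor"))
  A_h <- pfnet:::model_dag(pf_model("hierarchical"))
  expect_true(all(A_b["G", rc_scales()] == 1))
  expect_true(all(A_h["G", rc_scales()] == 0))
  expect_true(all(A_h["G", spectrum_names()] == 1))
})

test_that("invalid loading sets are rejected with an explanation", {
  expect_error(pf_model("bifactor", general_loading = 0.9,
                        specific_loading = 0.6),
               "non-positive residual variance")
  expect_error(pf_model("bifactor", general_loading = c(BAD = 0.5)),
               "unknown scale")
  expect_error(pf_model("bifactor", context_effect = 3), "context_effect")
})

test_that("implied covariance follows the factor algebra", {
  m <- pf_model("bifactor")
  S <- implied_scale_covariance(m)
  lg <- m$general_loading; ls <- m$specific_loading
  # different spectra, no cross-loadings: product of general loadings
  expect_equal(S["RC1", "RC4"], lg[["RC1"]] * lg[["RC4"]])
  # same spectrum: add product of specific loadings
  expect_equal(S["RC6", "RC8"],
               lg[["RC6"]] * lg[["RC8"]] + ls[["RC6"]] * ls[["RC8"]])
  # hierarchical, different spectra: lambda_j gamma_c * lambda_k gamma_d
  h <- pf_model("hierarchical", cross_loadings = data.frame(
    scale = character(0), spectrum = character(0), loading = numeric(0)))
  Sh <- implied_scale_covariance(h)
  g <- h$hierarchy_loading
  expect_equal(Sh["RC1", "RC4"],
               h$scale_loading[["RC1"]] * g[["somatoform"]] *
               h$scale_loading[["RC4"]] * g[["disinhibited_externalizing"]])
})

test_that("zero general loading decouples the spectra", {
  m <- pf_model("bifactor", general_loading = 0, context_effect = 0,
                covariate_effects = c(age = 0, gender = 0))
  S <- implied_scale_covariance(m)
  map <- m$spectra_map
  for (a in m$scales) for (b in m$scales) {
    if (a < b && !pfnet:::shares_spectrum(map, a, b)) {
      expect_equal(S[a, b], 0)
    }
  }
})

test_that("implied covariance agrees with Wright path tracing for all pairs", {
  for (kind in c("bifactor", "hierarchical")) {
    m <- pf_model(kind, context_effect = 0,
                  covariate_effects = c(age = 0, gender = 0))
    expect_equal(implied_scale_covariance(m), path_tracing_cov(m),
                 tolerance = 1e-12)
  }
})
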