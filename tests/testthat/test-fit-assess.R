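test_that("the baseline chi-square has its closed form", {
  expect_equal(baseline_chisq(diag(4), 200)$chisq, 0)
  expect_identical(baseline_chisq(diag(3), 50)$df, 3)

  r <- stats::uniroot(function(r) (1 - r)^2 * (1 + 2 * r) - 0.5, c(0, 0.9),
                      tol = 1e-12)$root
  R <- matrix(r, 3, 3); diag(R) <- 1
  expect_equal(baseline_chisq(R, 101)$chisq, 100 * log(2), tolerance = 1e-6)

  S_bad <- matrix(1, 3, 3)
  expect_error(baseline_chisq(S_bad, 100), "positive definite")
})

test_that("fit indices match their plug-in formulas and cutoffs", {
  base <- tibble::tibble(chisq = 2000, df = 120, p = 16)
  perfect <- list(chisq = 100, df = 100, n = 500, q = 36)
  fi <- fit_indices(perfect, baseline = base)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)

  f2 <- fit_indices(list(chisq = 200, df = 100, n = 1001, q = 30), baseline = base)
  expect_equal(f2$rmsea, sqrt(100 / 100000), tolerance = 1e-12)
  expect_equal(f2$aic, 200 + 60)
  expect_equal(f2$bic, 200 + 30 * log(1001))

  # the survey's selected-model profile classifies as acceptable throughout
  sel <- fit_indices(list(chisq = 3.47 * 180, df = 180, n = 1504, q = 60),
                     baseline = tibble::tibble(chisq = 18000, df = 210, p = 21))
  expect_true(sel$acceptable_cfi && sel$acceptable_tli)
  expect_false(fit_indices(list(chisq = 900, df = 100, n = 500, q = 10),
                           baseline = base)$acceptable_rmsea)

  expect_error(fit_indices(list(chisq = 1, df = 0, n = 100, q = 10),
                           baseline = base), "df > 0")
})

test_that("RMSEA is monotone in chi-square at fixed df and n", {
  base <- tibble::tibble(chisq = 900, df = 45, p = 10)
  r <- vapply(seq(30, 600, by = 30), function(x2) {
    fit_indices(list(chisq = x2, df = 45, n = 300, q = 10), baseline = base)$rmsea
  }, numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("modification indices approximate the refit chi-square drop", {
  # generating model carries one moderate within-construct error covariance
  # that the fitted model omits
  m <- one_factor_model(4)
  mtrue <- m
  mtrue$paths <- dplyr::bind_rows(mtrue$paths, tibble::tibble(
    source = "x1", target = "x2", kind = "error_covariance",
    fixed = TRUE, value = 0.06))
  ramt <- to_ram(mtrue)
  th <- stats::setNames(c(0.8, 0.7, 0.9, rep(0.4, 4), 1), ramt$free$label)
  Sig <- implied_covariance(ramt, th)

  m_free <- m
  m_free$paths <- dplyr::bind_rows(m_free$paths, tibble::tibble(
    source = "x1", target = "x2", kind = "error_covariance",
    fixed = FALSE, value = NA_real_))

  for (seed in c(2, 5, 8)) {
    set.seed(seed)
    X <- as.data.frame(MASS::mvrnorm(1000, rep(0, 4), Sig))
    names(X) <- paste0("x", 1:4)
    fit <- sem_fit(m, data = X)
    mi <- modification_indices(fit, threshold = 0)
    refit <- sem_fit(m_free, data = X)
    dchi <- fit$chisq - refit$chisq
    row <- mi[mi$term == "x1~~x2", ]
    expect_lt(abs(row$mi - dchi) / dchi, 0.15)
    # freeing the top-MI parameter never increases the chi-square
    expect_gte(fit$chisq - refit$chisq, -1e-8)
    # EPC points at the generating covariance
    expect_equal(row$epc, refit$theta[["x1~~x2"]], tolerance = 0.05)
  }
})

test_that("already-free parameters get MI zero and thresholds filter", {
  truth <- two_factor_truth()
  Sig <- implied_covariance(to_ram(two_factor_model()), truth)
  set.seed(3)
  X <- as.data.frame(MASS::mvrnorm(500, rep(0, 6), Sig))
  names(X) <- colnames(Sig)
  fit <- sem_fit(two_factor_model(), data = X)

  free_cand <- tibble::tibble(label = "f1=~x2", matrix = "A", row = "x2",
                              col = "f1", type = "loading")
  mi <- modification_indices(fit, candidates = free_cand, threshold = 0)
  expect_equal(mi$mi, 0)

  # for a well-specified model, default candidates rarely clear MI > 4
  mi_all <- modification_indices(fit, threshold = 0)
  mi_filtered <- modification_indices(fit)
  expect_true(all(mi_filtered$mi > 4 | mi_filtered$term %in% mi$term))
  expect_lte(nrow(mi_filtered), nrow(mi_all))
})

test_that("model comparison reproduces the survey's selection logic", {
  printed <- tibble::tibble(
    label = c("hypothesized", "significant_only", "plus_error_covariances",
              "plus_exogenous_covariances"),
    aic = c(8261.6, 4289.1, 3501.5, 1667.6),
    bic = c(8856.1, 4687.2, 3968.5, 2102.8),
    cfi = c(0.65, 0.79, 0.83, 0.93),
    tli = c(0.63, 0.77, 0.82, 0.92),
    rmsea = c(0.07, 0.07, 0.06, 0.04)
  )
  cmp <- compare_models(printed)
  expect_identical(attr(cmp, "selection"), "plus_exogenous_covariances")
  expect_false(attr(cmp, "no_candidate_meets_thresholds"))
  expect_identical(sum(cmp$selected), 1L)

  single <- compare_models(printed[1, ])
  expect_true(single$selected)
  expect_true(attr(single, "no_candidate_meets_thresholds"))

  tied <- printed[c(4, 4), ]
  tied$label <- c("first", "second")
  cmp_tie <- compare_models(tied)
  expect_identical(attr(cmp_tie, "selection"), "first")
  expect_true(attr(cmp_tie, "tie"))

  # fitted candidates on different n are refused
  truth <- two_factor_truth()
  Sig <- implied_covariance(to_ram(two_factor_model()), truth)
  f1 <- sem_fit(two_factor_model(), sample_cov = Sig, n = 300)
  f2 <- sem_fit(two_factor_model(), sample_cov = Sig, n = 400)
  expect_error(compare_models(list(a = f1, b = f2)), "sample sizes")
})
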