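test_that("KMO matches its closed forms and the brute-force oracle", {
  R2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(kmo(R2)$overall, 0.5)

  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  expect_equal(kmo(R3)$overall, 0.75 / (0.75 + 1 / 3), tolerance = 1e-12)

  # near-unit equicorrelation: anti-image partials shrink like 1/(p-1), so
  # the overall measure approaches 1 for a wide battery
  R_hi <- matrix(0.999, 20, 20); diag(R_hi) <- 1
  expect_gt(kmo(R_hi)$overall, 0.99)

  set.seed(13)
  X <- matrix(rnorm(250), 50, 5) %*% matrix(rnorm(25), 5, 5)
  R <- cor(X)
  expect_equal(kmo(R)$overall, kmo_brute(R), tolerance = 1e-10)
  expect_true(all(kmo(R)$per_item >= 0 & kmo(R)$per_item <= 1))

  expect_error(kmo(diag(3)), "zero")
})

test_that("Bartlett's sphericity statistic matches the plug-in formula", {
  b0 <- bartlett_sphericity(diag(4), n = 100)
  expect_equal(b0$statistic, 0)
  expect_equal(b0$p.value, 1)
  expect_identical(bartlett_sphericity(diag(3), 50)$df, 3)

  # equicorrelated 3x3 with det(R) = (1-r)^2 (1+2r) = 0.5
  r <- stats::uniroot(function(r) (1 - r)^2 * (1 + 2 * r) - 0.5, c(0, 0.9),
                      tol = 1e-12)$root
  R <- matrix(r, 3, 3); diag(R) <- 1
  b <- bartlett_sphericity(R, n = 101)
  expect_equal(b$statistic, -(100 - 11 / 6) * log(0.5), tolerance = 1e-6)
  expect_error(bartlett_sphericity(diag(3), 2), "n > p")
})

test_that("Mardia's statistics match a brute-force double loop and normal limits", {
  set.seed(5)
  X <- matrix(rnorm(150), 50, 3)
  m <- mardia(X)
  oracle <- mardia_brute(X)
  expect_equal(m$b1p, unname(oracle["b1p"]), tolerance = 1e-10)
  expect_equal(m$b2p, unname(oracle["b2p"]), tolerance = 1e-10)

  z <- matrix(rnorm(5000), ncol = 1)
  mz <- mardia(z)
  expect_lt(abs(mz$b2p - 3), 0.2)   # univariate kurtosis limit
  expect_lt(abs(mz$b1p), 0.05)      # symmetry
})

test_that("Mahalanobis screening is calibrated and centre-safe", {
  set.seed(3)
  X <- MASS::mvrnorm(100000, rep(0, 5), diag(5))
  out <- mahalanobis_outliers(X, alpha = 0.001)
  expect_lt(abs(mean(out$flag) - 0.001), 0.0007)

  # symmetric cloud: the zero row sits exactly at the sample mean
  Y <- X[1:50, ]
  X2 <- rbind(Y, -Y, rep(0, 5))
  o2 <- mahalanobis_outliers(X2)
  expect_lt(o2$distance[nrow(X2)], 1e-20)
  expect_false(o2$flag[nrow(X2)])

  expect_error(mahalanobis_outliers(cbind(1:5, 1:5)), "singular")
})

test_that("Harman's single-factor share behaves at both extremes", {
  set.seed(8)
  base <- rnorm(300)
  collinear <- cbind(base, 2 * base, -base)
  h1 <- harman_single_factor(cor(collinear + 1e-8 * matrix(rnorm(900), 300)))
  expect_gt(h1$share, 0.99)
  expect_true(h1$flagged)

  indep <- matrix(rnorm(300 * 8), 300, 8)
  h0 <- harman_single_factor(indep)
  expect_lt(abs(h0$share - 1 / 8), 0.08)
  expect_false(h0$flagged)

  expect_false(harman_single_factor(diag(5) * 0 + diag(5))$flagged)
  # a 19% share, as the survey reported, is comfortably unflagged
  expect_false(tibble::tibble(share = 0.19, flagged = 0.19 > 0.5)$flagged)
})

test_that("composite reliability, AVE and discriminant validity compute exactly", {
  expect_equal(composite_reliability(c(1, 1, 1), c(0, 0, 0)), 1)
  expect_equal(ave_extracted(c(1, 1, 1)), 1)
  expect_equal(composite_reliability(rep(0.7, 3), rep(0.51, 3)),
               4.41 / (4.41 + 1.53), tolerance = 1e-12)
  expect_equal(ave_extracted(rep(0.7, 3)), 0.49)

  fc <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  dv <- discriminant_validity(c(a = 0.49, b = 0.49), fc)
  expect_true(dv$pass)            # 0.6 < sqrt(0.49) = 0.7
  fc[1, 2] <- fc[2, 1] <- 0.75
  expect_false(discriminant_validity(c(a = 0.49, b = 0.49), fc)$pass)
})

test_that("one-way ICC recovers designed variance ratios", {
  set.seed(21)
  g <- rep(1:50, each = 100)
  flat <- rnorm(5000)
  expect_lt(abs(icc_oneway(flat, g)$icc), 0.05)

  pure <- rep(rnorm(50), each = 100)
  expect_equal(icc_oneway(pure, g)$icc, 1)

  mixed <- rep(rnorm(50, sd = sqrt(0.1)), each = 100) + rnorm(5000, sd = sqrt(0.9))
  r <- icc_oneway(mixed, g)
  expect_lt(abs(r$icc - 0.1), 0.03)
  expect_true(r$recommend_multilevel || r$icc < 0.1)
  expect_error(icc_oneway(1:3, c(1, 2, 3)), "2 groups")
})

test_that("serpentine parceling deals items deterministically and balances loads", {
  nine <- parcel_items(stats::setNames(seq(0.9, 0.5, length.out = 9), paste0("i", 1:9)))
  expect_identical(as.integer(table(nine$assignment$parcel)), c(3L, 3L, 3L))
  six <- parcel_items(stats::setNames(rep(0.7, 6), paste0("i", 1:6)))
  expect_identical(as.integer(table(six$assignment$parcel)), c(2L, 2L, 2L))
  seven <- parcel_items(stats::setNames(seq(0.9, 0.6, length.out = 7), paste0("i", 1:7)))
  expect_identical(sort(as.integer(table(seven$assignment$parcel)), decreasing = TRUE),
                   c(3L, 2L, 2L))

  # equal loadings: assignment follows declared order (stable tie-break)
  eq <- parcel_items(stats::setNames(rep(0.7, 6), paste0("i", 1:6)))
  expect_identical(eq$assignment$parcel, c(1L, 2L, 3L, 3L, 2L, 1L))

  # serpentine balance: parcel loading sums differ by at most one loading
  set.seed(4)
  for (rep in 1:20) {
    k <- sample(6:12, 1)
    lam <- stats::setNames(runif(k, 0.3, 0.95), paste0("i", 1:k))
    pa <- parcel_items(lam, 3)
    sums <- tapply(pa$assignment$loading, pa$assignment$parcel, sum)
    expect_lte(max(sums) - min(sums), max(lam) + 1e-12)
  }

  # parcel scores: with equal parcel sizes the grand mean is preserved exactly
  dat <- tibble::as_tibble(matrix(rpois(45 * 9, 3), 45,
                                  dimnames = list(NULL, paste0("i", 1:9))))
  pa <- parcel_items(stats::setNames(runif(9, 0.4, 0.9), paste0("i", 1:9)),
                     3, data = dat)
  expect_equal(mean(as.matrix(pa$scores)), mean(as.matrix(dat)), tolerance = 1e-12)

  expect_error(parcel_items(c(a = 0.7, b = 0.6), 3), "parcels")
})

test_that("listwise deletion follows the 5% rule", {
  d <- tibble::tibble(a = c(1:24, NA), b = 1:25)
  out <- listwise_delete(d)
  expect_identical(nrow(out), 24L)
  expect_equal(attr(out, "prop_dropped"), 0.04, tolerance = 1e-9)
  d2 <- tibble::tibble(a = c(NA, 2:20), b = 1:20)  # exactly 5%: refused
  expect_error(listwise_delete(d2), "5%")
})

test_that("the full diagnostics battery runs on simulated survey data", {
  sim <- simulate_survey(sim_config(n = 600, seed = 31))
  dg <- run_diagnostics(sim$data)
  expect_true(dg$kmo_overall > 0.5)
  expect_identical(nrow(dg$per_construct), 6L)
  expect_true(all(dg$per_construct$bartlett_p < 0.001))
  expect_false(dg$harman$flagged)
  expect_true(is.numeric(dg$n_outliers))
})
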