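test_that("RAM mapping is consistent with the identification counts", {
  m <- adhd_depression_model("final")
  ram <- to_ram(m)
  expect_identical(nrow(ram$free), count_free_parameters(m)$total)
  expect_true(all(diag(ram$A) == 0))

  # fixed scale loadings carry their value
  expect_equal(ram$A["phq_1", "depression"], 1)

  # unknown variable in a path is refused
  bad <- m
  bad$paths <- dplyr::bind_rows(bad$paths, tibble::tibble(
    source = "ghost", target = "depression", kind = "structural",
    fixed = FALSE, value = NA_real_))
  expect_error(to_ram(bad), "declared")

  # a loop with no excluded variables fails the rank condition and is refused
  toy <- loop_toy_model()
  toy$paths <- dplyr::bind_rows(toy$paths, tibble::tibble(
    source = c("z1", "z2"), target = c("e2", "e1"),
    kind = "structural", fixed = FALSE, value = NA_real_))
  expect_error(to_ram(toy), "not identified")
})

test_that("implied covariance matches hand calculations and the series oracle", {
  # A = 0: the implied covariance is the filtered S
  m <- one_factor_model(2)
  ram <- to_ram(m)
  th <- stats::setNames(c(0.8, 0.2, 0.2, 1), ram$free$label)
  Sigma <- implied_covariance(ram, th)
  expect_equal(Sigma, matrix(c(1.2, 0.8, 0.8, 0.84), 2,
                             dimnames = list(c("x1", "x2"), c("x1", "x2"))),
               tolerance = 1e-12)

  # feedback loop: (I - A)^-1 equals the truncated geometric series
  ram2 <- to_ram(loop_toy_model())
  th2 <- loop_toy_truth(0.5, 0.5)
  filled <- ram_fill(ram2, th2)
  k <- nrow(filled$A)
  E_series <- diag(k)
  P <- diag(k)
  for (i in 1:50) { P <- P %*% filled$A; E_series <- E_series + P }
  obs_idx <- match(ram2$obs, ram2$nodes)
  Sigma_series <- (E_series %*% filled$S %*% t(E_series))[obs_idx, obs_idx]
  expect_equal(unname(implied_covariance(ram2, th2)), unname(Sigma_series),
               tolerance = 1e-9)

  # a loop at the stability boundary makes (I - A) singular and is refused
  expect_error(implied_covariance(ram2, loop_toy_truth(2, 0.5)), "stability")
})

test_that("the ML discrepancy has its closed-form values and invariances", {
  S <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  expect_equal(ml_discrepancy(matrix(2), matrix(1)), log(1) + 2 - log(2) - 1,
               tolerance = 1e-12)

  set.seed(2)
  for (rep in 1:20) {
    A <- matrix(rnorm(16), 4); S1 <- crossprod(A) + diag(4)
    B <- matrix(rnorm(16), 4); S2 <- crossprod(B) + diag(4)
    f <- ml_discrepancy(S1, S2)
    expect_gte(f, -1e-12)
    pi_ <- sample(4)
    expect_equal(f, ml_discrepancy(S1[pi_, pi_], S2[pi_, pi_]), tolerance = 1e-9)
  }
  expect_error(ml_discrepancy(diag(2) * 0, diag(2)), "positive definite")
})

test_that("analytic gradients agree with numerical differentiation", {
  for (build in list(
    function() list(ram = to_ram(two_factor_model()), th = two_factor_truth()),
    function() list(ram = to_ram(loop_toy_model()), th = loop_toy_truth())
  )) {
    b <- build()
    Sig <- implied_covariance(b$ram, b$th)
    ob <- semloop:::objective_factory(b$ram, Sig)
    set.seed(6)
    th <- b$th * runif(length(b$th), 0.8, 1.2)
    expect_equal(ob$gr(th), numDeriv::grad(ob$fn, th), tolerance = 1e-6)
  }
})

test_that("fitting the population covariance returns the truth exactly", {
  m <- two_factor_model()
  truth <- two_factor_truth()
  Sig <- implied_covariance(to_ram(m), truth)
  fit <- sem_fit(m, sample_cov = Sig, n = 1000)
  expect_true(fit$converged)
  expect_lt(fit$F_ml, 1e-8)
  expect_lt(max(abs(fit$theta - truth[names(fit$theta)])), 1e-4)

  # the same holds through a feedback loop
  lt <- loop_toy_truth()
  Sig2 <- implied_covariance(to_ram(loop_toy_model()), lt)
  fit2 <- sem_fit(loop_toy_model(), sample_cov = Sig2, n = 1000)
  expect_lt(max(abs(fit2$theta - lt[names(fit2$theta)])), 1e-3)
  expect_gt(fit2$stability, 0)
})

test_that("the just-identified one-factor model matches its closed form", {
  set.seed(19)
  lam <- c(1, 0.8, 0.65); phi <- 0.9; th_e <- c(0.4, 0.3, 0.5)
  Sig <- tcrossprod(lam) * phi + diag(th_e)
  dimnames(Sig) <- list(paste0("x", 1:3), paste0("x", 1:3))
  fit <- sem_fit(one_factor_model(3), sample_cov = Sig, n = 500)
  expect_identical(fit$df, 0)
  expect_lt(fit$F_ml, 1e-10)
  s <- Sig
  phi_hat <- s["x1", "x2"] * s["x1", "x3"] / s["x2", "x3"]
  expect_equal(fit$theta[["f1~~f1"]], phi_hat, tolerance = 1e-6)
  expect_equal(fit$theta[["f1=~x2"]], s["x2", "x3"] / s["x1", "x3"], tolerance = 1e-6)
  expect_equal(fit$theta[["f1=~x3"]], s["x2", "x3"] / s["x1", "x2"], tolerance = 1e-6)
})

test_that("estimates are invariant to the ordering of observed variables", {
  truth <- two_factor_truth()
  Sig <- implied_covariance(to_ram(two_factor_model()), truth)
  pi_ <- c(4, 1, 6, 2, 3, 5)
  fit_a <- sem_fit(two_factor_model(), sample_cov = Sig, n = 400)
  fit_b <- sem_fit(two_factor_model(), sample_cov = Sig[pi_, pi_], n = 400)
  expect_equal(fit_a$theta, fit_b$theta, tolerance = 1e-5)
})

test_that("degenerate data are rejected, Heywood cases flagged not hidden", {
  const <- data.frame(x1 = rep(1, 50), x2 = rep(2, 50), x3 = rep(3, 50))
  expect_error(sem_fit(one_factor_model(3), data = const), "positive definite")

  # a tiny sample with a near-unit correlation drives an error variance
  # negative; the fit reports it rather than silently constraining
  set.seed(33)
  f <- rnorm(60)
  d <- data.frame(x1 = f + rnorm(60, sd = 0.08),
                  x2 = f + rnorm(60, sd = 0.08),
                  x3 = 0.3 * f + rnorm(60, sd = 1.5))
  fit <- sem_fit(one_factor_model(3), data = d)
  fitb <- sem_fit(one_factor_model(3), data = d, bounded = TRUE)
  expect_true(is.logical(fit$heywood))
  expect_true(all(fitb$estimates$estimate[
    fitb$estimates$type == "error_variance"] >= -1e-9))
})

test_that("standard errors track the bootstrap spread", {
  set.seed(44)
  truth <- two_factor_truth()
  Sig <- implied_covariance(to_ram(two_factor_model()), truth)
  X <- MASS::mvrnorm(600, rep(0, 6), Sig)
  colnames(X) <- colnames(Sig)
  fit <- sem_fit(two_factor_model(), data = as.data.frame(X))
  boot <- sem_bootstrap(fit, as.data.frame(X), replicates = 60, seed = 2)
  sds <- apply(boot$boot_draws, 2, sd, na.rm = TRUE)
  ratio <- sds / fit$estimates$se
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("bootstrap intervals are deterministic and bracket the estimates", {
  set.seed(9)
  truth <- two_factor_truth()
  Sig <- implied_covariance(to_ram(two_factor_model()), truth)
  X <- as.data.frame(MASS::mvrnorm(300, rep(0, 6), Sig))
  names(X) <- colnames(Sig)
  fit <- sem_fit(two_factor_model(), data = X)
  b1 <- sem_bootstrap(fit, X, replicates = 50, seed = 5)
  b2 <- sem_bootstrap(fit, X, replicates = 50, seed = 5)
  expect_identical(b1$boot_ci, b2$boot_ci)

  inside <- b1$boot_ci$conf.low <= fit$theta & fit$theta <= b1$boot_ci$conf.high
  expect_gte(mean(inside), 0.99)
})

test_that("stability index reads the endogenous block", {
  expect_equal(stability_index(matrix(0, 2, 2)), 0)
  nil <- matrix(c(0, 0, 0.6, 0), 2)   # single directed path, nilpotent
  expect_equal(stability_index(nil), 0)
  B <- matrix(c(0, -0.14, 0.73, 0), 2,
              dimnames = list(c("dep", "adhd"), c("dep", "adhd")))
  expect_equal(stability_index(B), sqrt(0.73 * 0.14), tolerance = 1e-9)

  fit <- sem_fit(loop_toy_model(),
                 sample_cov = implied_covariance(to_ram(loop_toy_model()),
                                                 loop_toy_truth()), n = 500)
  expect_equal(fit$stability, sqrt(0.3 * 0.25), tolerance = 1e-4)
})

test_that("effect decomposition multiplies chains and survives loops", {
  # pure chain: indirect = product, no direct share
  vars <- tibble::tibble(
    name = c("c", "b", "a", paste0("i", 1:4)),
    role = c("observed_exogenous", "latent_endogenous", "latent_endogenous",
             rep("indicator", 4)),
    scale = NA_integer_,
    measures = c(NA, NA, NA, "b", "b", "a", "a")
  )
  paths <- dplyr::bind_rows(
    tibble::tibble(source = c("b", "b", "a", "a"),
                   target = paste0("i", 1:4), kind = "loading",
                   fixed = c(TRUE, FALSE, TRUE, FALSE), value = c(1, NA, 1, NA)),
    tibble::tibble(source = c("c", "b"), target = c("b", "a"),
                   kind = "structural", fixed = TRUE, value = c(0.5, 0.4))
  )
  ram <- to_ram(sem_model(vars, paths), check_identification = FALSE)
  th <- stats::setNames(rep(0.5, nrow(ram$free)), ram$free$label)
  eff <- effect_decomposition(ram, theta = th, outcomes = c("a", "b"))
  row <- eff[eff$cause == "c" & eff$outcome == "a", ]
  expect_equal(row$indirect, 0.2, tolerance = 1e-12)
  expect_equal(row$direct, 0)

  # feedback loop: total = A (I + total) algebraic identity, exact
  ram2 <- to_ram(loop_toy_model())
  th2 <- loop_toy_truth()
  filled <- semloop::ram_fill(ram2, th2)
  Tfull <- solve(diag(nrow(filled$A)) - filled$A) - diag(nrow(filled$A))
  expect_equal(Tfull, filled$A %*% (diag(nrow(filled$A)) + Tfull), tolerance = 1e-12)
  expect_error(effect_decomposition(ram2, theta = loop_toy_truth(1.3, 0.9)),
               "unstable")
})

test_that("total effects equal the path-enumeration oracle on random DAGs", {
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(4:7, 1)
    A <- matrix(0, k, k)
    for (i in 2:k) for (j in 1:(i - 1)) {
      if (runif(1) < 0.5) A[i, j] <- round(runif(1, -0.8, 0.8), 2)
    }
    total <- solve(diag(k) - A) - diag(k)
    expect_equal(total, path_enumeration_total(A), tolerance = 1e-9)
  }
})
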