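objective_factory <- function(ram, S_sample) {
  p <- nrow(S_sample)
  k <- length(ram$nodes)
  obs_idx <- match(ram$obs, ram$nodes)
  fr <- ram$free
  iA <- which(fr$matrix == "A")
  iS <- which(fr$matrix == "S")
  A_cells <- cbind(fr$row[iA], fr$col[iA])
  S_cells <- cbind(fr$row[iS], fr$col[iS])
  S_diag <- fr$row[iS] == fr$col[iS]
  ld_S <- as.numeric(determinant(S_sample, logarithm = TRUE)$modulus)
  big <- 1e10

  shared <- new.env(parent = emptyenv())

  eval_point <- function(theta) {
    m <- ram_fill(ram, theta)
    IA <- diag(k) - m$A
    E <- tryCatch(solve(IA), error = function(e) NULL)
    if (is.null(E)) return(NULL)
    full <- E %*% m$S %*% t(E)
    Sigma <- full[obs_idx, obs_idx, drop = FALSE]
    cT <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(cT)) return(NULL)
    Sigma_inv <- chol2inv(cT)
    value <- 2 * sum(log(diag(cT))) + sum(Sigma_inv * S_sample) - ld_S - p
    list(m = m, E = E, Sigma = Sigma, Sigma_inv = Sigma_inv, value = value)
  }

  fn <- function(theta) {
    pt <- eval_point(theta)
    shared$last <- list(theta = theta, pt = pt)
    if (is.null(pt) || !is.finite(pt$value)) return(big)
    pt$value
  }

  gr <- function(theta) {
    pt <- if (!is.null(shared$last) && identical(shared$last$theta, theta)) {
      shared$last$pt
    } else {
      eval_point(theta)
    }
    if (is.null(pt)) return(rep(0, length(theta)))
    # dF/dSigma = Sigma^-1 (Sigma - S) Sigma^-1, embedded at observed nodes
    G <- pt$Sigma_inv %*% (pt$Sigma - S_sample) %*% pt$Sigma_inv
    W <- matrix(0, k, k)
    W[obs_idx, obs_idx] <- G
    U <- crossprod(pt$E, W %*% pt$E)        # E' W E
    dA <- 2 * (U %*% pt$m$S %*% t(pt$E))    # dF/dA
    g <- numeric(length(theta))
    if (length(iA)) g[iA] <- dA[A_cells]
    if (length(iS)) {
      gS <- 2 * U[S_cells]
      gS[S_diag] <- gS[S_diag] / 2
      g[iS] <- gS
    }
    g
  }

  list(fn = fn, gr = gr, eval_point = eval_point)
}

start_values <- function(ram, S_sample) {
  fr <- ram$free
  s_var <- diag(S_sample)[match(fr$row, colnames(S_sample))]
  theta <- numeric(nrow(fr))
  theta[fr$type == "loading"] <- 0.7
  theta[fr$type == "structural"] <- 0
  theta[fr$type == "error_variance"] <- 0.5 * s_var[fr$type == "error_variance"]
  theta[fr$type == "exogenous_variance"] <-
    ifelse(is.na(s_var[fr$type == "exogenous_variance"]), 1,
           s_var[fr$type == "exogenous_variance"])
  theta[fr$type == "disturbance_variance"] <- 0.5
  # covariances start at 0
  theta[is.na(theta)] <- 0.5
  names(theta) <- fr$label
  theta
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy [ml_discrepancy()] between the
#' sample covariance and the RAM-implied covariance, by quasi-Newton
#' optimization with an analytic gradient. Ordinal items are treated as
#' continuous, mirroring the survey workflow this package reproduces (with
#' bootstrap inference available for the resulting non-normality).
#' Standard errors come from the inverse Hessian of the discrepancy
#' (observed information). Negative variance estimates (Heywood cases) are
#' reported and flagged, not constrained, unless `bounded = TRUE`.
#'
#' @param model A valid, identified [sem_model()].
#' @param data Data frame holding every observed model variable (items and
#'   covariates); used to compute the sample covariance. Alternatively
#'   supply `sample_cov` and `n`.
#' @param sample_cov Sample covariance matrix with dimnames (used when
#'   `data` is `NULL`).
#' @param n Sample size (required with `sample_cov`).
#' @param start Optional named start vector (defaults: loadings 0.7,
#'   variances from the sample diagonal, structural paths and covariances
#'   0).
#' @param se `"information"` (default) or `"none"` (skip the Hessian, e.g.
#'   inside bootstrap replicates).
#' @param bounded Constrain variances to be nonnegative.
#' @param max_iter,grad_tol Optimizer budget and convergence tolerance on
#'   the gradient max-norm.
#' @return An object of class `semloop_fit`: `estimates` tibble (label,
#'   type, estimate, se), discrepancy `F_ml`, `chisq = (n-1) F_ml`, `df`,
#'   `n`, `p`, `q`, `converged`, `heywood`, `stability`, the sample and
#'   implied covariances, and the underlying RAM structure.
#' @export
sem_fit <- function(model, data = NULL, sample_cov = NULL, n = NULL,
                    start = NULL, se = c("information", "none"),
                    bounded = FALSE, max_iter = 1000, grad_tol = 1e-6) {
  se <- match.arg(se)
  ram <- if (inherits(model, "semloop_ram")) model else to_ram(model)
  if (!is.null(data)) {
    missing <- setdiff(ram$obs, names(data))
    if (length(missing)) {
      abort(paste0("data lack observed model variables: ",
                   paste(missing, collapse = ", ")))
    }
    n <- nrow(data)
    S_sample <- cov(as.matrix(data[, ram$obs, drop = FALSE]))
  } else {
    if (is.null(sample_cov) || is.null(n)) {
      abort("supply `data`, or `sample_cov` together with `n`")
    }
    if (is.null(dimnames(sample_cov))) {
      abort("`sample_cov` needs dimnames naming the observed variables")
    }
    missing <- setdiff(ram$obs, colnames(sample_cov))
    if (length(missing)) {
      abort(paste0("sample_cov lacks observed model variables: ",
                   paste(missing, collapse = ", ")))
    }
    S_sample <- sample_cov[ram$obs, ram$obs]
  }
  p <- nrow(S_sample)
  if (n <= p) abort("sample size must exceed the number of observed variables")
  tryCatch(chol(S_sample), error = function(e) {
    abort("sample covariance matrix is not positive definite (degenerate data)")
  })
  q <- nrow(ram$free)
  df <- p * (p + 1) / 2 - q
  if (df < 0) abort(sprintf("model has negative degrees of freedom (q = %d > %d moments)",
                            q, p * (p + 1) / 2))

  ob <- objective_factory(ram, S_sample)
  theta0 <- start_values(ram, S_sample)
  if (!is.null(start)) {
    idx <- match(names(start), names(theta0))
    theta0[idx[!is.na(idx)]] <- start[!is.na(idx)]
  }
  variance_types <- c("error_variance", "exogenous_variance", "disturbance_variance")
  lower <- rep(-Inf, q)
  if (bounded) {
    lower[ram$free$type %in% variance_types] <- 0
  }
  opt <- nlminb(theta0, ob$fn, gradient = ob$gr, lower = lower,
                control = list(iter.max = max_iter, eval.max = 4 * max_iter,
                               rel.tol = 1e-12, x.tol = 1e-12))
  theta <- opt$par
  F_ml <- opt$objective
  g <- ob$gr(theta)
  grad_norm <- max(abs(g))
  H <- NULL
  # Newton polish: nlminb stops on relative-tolerance grounds slightly short
  # of the gradient contract; near the optimum a damped Newton step closes
  # the gap in one or two iterations
  polish <- 0
  while (is.finite(F_ml) && grad_norm >= grad_tol && polish < 5) {
    H <- numDeriv::jacobian(ob$gr, theta)
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      cand <- pmax(theta - alpha * step, lower)
      f_cand <- ob$fn(cand)
      if (f_cand <= F_ml + 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (f_cand > F_ml + 1e-12) break
    theta <- cand; F_ml <- f_cand
    g <- ob$gr(theta); grad_norm <- max(abs(g))
    polish <- polish + 1
  }
  converged <- is.finite(F_ml) && grad_norm < grad_tol
  est <- ram$free
  est$estimate <- as.numeric(theta)
  est$se <- NA_real_
  vcov_theta <- NULL
  if (se == "information" && is.finite(F_ml)) {
    H <- numDeriv::jacobian(ob$gr, theta)
    H <- (H + t(H)) / 2
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi)) {
      vcov_theta <- (2 / (n - 1)) * Hi
      sevec <- sqrt(pmax(diag(vcov_theta), 0))
      sevec[diag(vcov_theta) < 0] <- NA_real_
      est$se <- sevec
    }
  }
  heywood <- any(est$type %in% variance_types & est$estimate < 0)

  structure(
    list(
      model = ram$model, ram = ram, theta = setNames(theta, ram$free$label),
      estimates = est[, c("label", "type", "estimate", "se")],
      F_ml = F_ml, chisq = (n - 1) * F_ml, df = df, n = n, p = p, q = q,
      converged = converged, grad_norm = grad_norm, iterations = opt$iterations,
      heywood = heywood, vcov = vcov_theta,
      S_sample = S_sample, implied = implied_covariance(ram, theta),
      stability = stability_index(ram_fill(ram, theta)$A, ram$endo)
    ),
    class = "semloop_fit"
  )
}

#' @export
print.semloop_fit <- function(x, ...) {
  cat("<semloop_fit> ", x$p, " observed variables, n = ", x$n, "\n", sep = "")
  cat(sprintf("  F_ML = %.6f, chi-square = %.2f on %d df, q = %d\n",
              x$F_ml, x$chisq, x$df, x$q))
  cat(sprintf("  converged: %s (|grad| = %.2e)%s%s\n",
              x$converged, x$grad_norm,
              if (x$heywood) ", Heywood case flagged" else "",
              if (x$stability > 0) sprintf(", stability index %.3f", x$stability) else ""))
  invisible(x)
}

#' Coefficient tibble for a fitted model
#'
#' @param x A [sem_fit()] result.
#' @param conf.int Add Wald (or, when present, bootstrap percentile)
#'   confidence intervals.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `type`,
#'   `estimate`, `std.error`, `statistic`, `p.value` (and interval bounds
#'   when requested).
#' @export
tidy.semloop_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- tibble::tibble(
    term = x$estimates$label,
    type = x$estimates$type,
    estimate = x$estimates$estimate,
    std.error = x$estimates$se,
    statistic = x$estimates$estimate / x$estimates$se,
    p.value = 2 * pnorm(-abs(x$estimates$estimate / x$estimates$se))
  )
  if (conf.int) {
    if (!is.null(x$boot_ci)) {
      out <- dplyr::left_join(out, x$boot_ci, by = "term")
    } else {
      z <- qnorm(1 - (1 - conf.level) / 2)
      out$conf.low <- out$estimate - z * out$std.error
      out$conf.high <- out$estimate + z * out$std.error
    }
  }
  out
}

#' One-line model summary
#'
#' @param x A [sem_fit()] result.
#' @param ... Unused.
#' @return A one-row tibble: discrepancy, chi-square, df, n, q,
#'   convergence, Heywood flag, stability index.
#' @export
glance.semloop_fit <- function(x, ...) {
  tibble::tibble(
    F_ml = x$F_ml, chisq = x$chisq, df = x$df, n = x$n, p = x$p, q = x$q,
    converged = x$converged, heywood = x$heywood, stability = x$stability
  )
}

#' Bootstrap confidence intervals for a fitted model
#'
#' Resamples subjects with replacement, refits the model (starting from
#' the point estimates), and returns percentile intervals. Replicates that
#' fail to converge or error (e.g. non-positive-definite resampled
#' covariance) are logged and excluded; more than 10% failures raises a
#' warning in the result.
#'
#' @param fit A [sem_fit()] result.
#' @param data The subject-level data the model was fitted to.
#' @param replicates Number of bootstrap resamples (the survey workflow
#'   used 3500; desk-scale analyses use fewer).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param conf.level Confidence level for the percentile intervals.
#' @return The fit with `boot_ci` (tibble `term`, `conf.low`, `conf.high`),
#'   `boot_draws` (replicate-by-parameter matrix) and `boot_failures`
#'   attached.
#' @export
sem_bootstrap <- function(fit, data, replicates = 200, seed = 1,
                          conf.level = 0.95) {
  stopifnot(inherits(fit, "semloop_fit"))
  n <- nrow(data)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * replicates, replace = TRUE), nrow = n)
  draws <- matrix(NA_real_, nrow = replicates, ncol = fit$q,
                  dimnames = list(NULL, fit$ram$free$label))
  failures <- 0L
  for (b in seq_len(replicates)) {
    res <- tryCatch(
      sem_fit(fit$ram, data = data[idx[, b], , drop = FALSE],
              start = fit$theta, se = "none", max_iter = 500),
      error = function(e) NULL
    )
    if (is.null(res) || !res$converged) failures <- failures + 1L
    if (!is.null(res)) draws[b, ] <- res$theta
  }
  ok <- stats::complete.cases(draws)
  alpha <- (1 - conf.level) / 2
  ci <- apply(draws[ok, , drop = FALSE], 2, quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  fit$boot_ci <- tibble::tibble(
    term = colnames(draws), conf.low = ci[1, ], conf.high = ci[2, ]
  )
  fit$boot_draws <- draws
  fit$boot_failures <- failures
  if (failures > 0.1 * replicates) {
    warn(sprintf("bootstrap: %d of %d replicates failed", failures, replicates))
  }
  fit
}
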