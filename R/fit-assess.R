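#' Baseline (independence) model chi-square
#'
#' The null model underlying incremental fit indices constrains every
#' covariance to zero and fits only the p variances; its discrepancy has
#' the closed form `chisq = -(n - 1) log det(R)` with `df = p(p-1)/2`,
#' where `R` is the sample correlation matrix.
#'
#' @param S Sample covariance (or correlation) matrix.
#' @param n Sample size.
#' @return A one-row tibble `chisq`, `df`, `p` (number of variables).
#' @export
baseline_chisq <- function(S, n) {
  R <- as_correlation(S)
  detR <- det(R)
  if (detR <= 0) abort("sample correlation matrix is not positive definite")
  tibble::tibble(
    chisq = -(n - 1) * log(detR),
    df = ncol(R) * (ncol(R) - 1) / 2,
    p = ncol(R)
  )
}

#' Global fit indices
#'
#' Computes the survey's index battery from a fitted model and its
#' baseline: CMIN/DF, RMSEA with the close-fit probability
#' P(RMSEA <= 0.05), CFI, TLI, and the chi-square-based AIC
#' (`chisq + 2q`) and BIC (`chisq + q log n`). Classification columns
#' apply the conventional cutoffs RMSEA < 0.05 and CFI/TLI > 0.90.
#'
#' @param fit A [sem_fit()] result, or a one-row data frame / list with
#'   `chisq`, `df`, `n`, `q`.
#' @param baseline A [baseline_chisq()] row (computed from the fit's
#'   sample covariance when omitted).
#' @param rmsea_null RMSEA null value for the close-fit probability.
#' @return A one-row tibble of indices plus `acceptable_*` flags.
#' @export
fit_indices <- function(fit, baseline = NULL, rmsea_null = 0.05) {
  if (inherits(fit, "semloop_fit")) {
    if (is.null(baseline)) baseline <- baseline_chisq(fit$S_sample, fit$n)
    chisq <- fit$chisq; df <- fit$df; n <- fit$n; q <- fit$q
  } else {
    chisq <- fit$chisq; df <- fit$df; n <- fit$n; q <- fit$q
    if (is.null(baseline)) abort("supply `baseline` when `fit` is not a semloop_fit")
  }
  if (df <= 0) abort("fit indices need df > 0 (model is saturated)")
  if (baseline$df <= 0) abort("baseline model has df <= 0")
  chisq_b <- baseline$chisq; df_b <- baseline$df

  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  ncp0 <- rmsea_null^2 * df * (n - 1)
  pclose <- 1 - pchisq(chisq, df, ncp = ncp0)
  denom <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (denom == 0) 1 else 1 - max(chisq - df, 0) / denom
  cfi <- min(max(cfi, 0), 1)
  tli <- ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)

  tibble::tibble(
    chisq = chisq, df = df, cmin_df = chisq / df,
    rmsea = rmsea, rmsea_pclose = pclose,
    cfi = cfi, tli = tli,
    aic = chisq + 2 * q, bic = chisq + q * log(n),
    acceptable_rmsea = rmsea < 0.05,
    acceptable_cfi = cfi > 0.90,
    acceptable_tli = tli > 0.90
  )
}

ram_extend <- function(ram, candidates) {
  ram$free <- dplyr::bind_rows(ram$free, candidates)
  ram
}

default_mi_candidates <- function(ram) {
  # within-construct error covariances not already free
  model <- ram$model
  v <- model$variables
  ind <- v[v$role == "indicator", ]
  have <- ram$free$label
  out <- list()
  for (f in unique(ind$measures)) {
    its <- ind$name[ind$measures == f]
    if (length(its) < 2) next
    pr <- utils::combn(its, 2)
    for (j in seq_len(ncol(pr))) {
      lab <- paste0(pr[1, j], "~~", pr[2, j])
      lab_rev <- paste0(pr[2, j], "~~", pr[1, j])
      if (lab %in% have || lab_rev %in% have) next
      out[[length(out) + 1]] <- tibble::tibble(
        label = lab, matrix = "S", row = pr[1, j], col = pr[2, j],
        type = "error_covariance"
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Modification indices with expected parameter change
#'
#' Score-test modification index for each candidate fixed parameter: the
#' expected chi-square drop if that single parameter were freed, computed
#' from the gradient and Hessian of the discrepancy at the restricted
#' optimum. EPC is the expected value the freed parameter would take;
#' SEPC standardizes it by the model-implied standard deviations of the
#' variables involved. Candidates default to within-construct error
#' covariances (the modification family the survey workflow allows);
#' arbitrary cells can be supplied.
#'
#' @param fit A converged [sem_fit()] result.
#' @param candidates Optional tibble `label`, `matrix` ("A" or "S"),
#'   `row`, `col`, `type` of fixed cells to test.
#' @param threshold Keep entries with MI above this (the survey uses 4,
#'   the 1-df chi-square criterion at alpha = 0.05); `threshold = 0` keeps
#'   all.
#' @return A tibble `term`, `mi`, `epc`, `sepc`, `admissible`, sorted by
#'   decreasing MI. Candidates already free in the model get MI 0.
#' @export
modification_indices <- function(fit, candidates = NULL, threshold = 4) {
  stopifnot(inherits(fit, "semloop_fit"))
  if (!fit$converged) abort("modification indices need a converged fit")
  ram <- fit$ram
  if (is.null(candidates)) candidates <- default_mi_candidates(ram)
  candidates <- tibble::as_tibble(candidates)
  if (!nrow(candidates)) {
    return(tibble::tibble(term = character(), mi = numeric(), epc = numeric(),
                          sepc = numeric(), admissible = logical()))
  }

  already <- candidates$label %in% ram$free$label
  cand <- candidates[!already, , drop = FALSE]
  out0 <- tibble::tibble(term = candidates$label[already], mi = 0,
                         epc = 0, sepc = 0, admissible = TRUE)

  if (nrow(cand)) {
    ext <- ram_extend(ram, cand)
    ob <- objective_factory(ext, fit$S_sample)
    q <- fit$q; m <- nrow(cand)
    theta_ext <- c(fit$theta, setNames(rep(0, m), cand$label))
    g <- ob$gr(theta_ext)
    H <- numDeriv::jacobian(ob$gr, theta_ext)
    H <- (H + t(H)) / 2
    Hff <- H[seq_len(q), seq_len(q)]
    Hff_inv <- tryCatch(solve(Hff), error = function(e) NULL)
    if (is.null(Hff_inv)) abort("information matrix of the free parameters is singular")

    full <- implied_covariance(ram, fit$theta, observed_only = FALSE)
    sds <- sqrt(pmax(diag(full), 1e-12))

    mi <- epc <- sepc <- numeric(m)
    n <- fit$n
    for (j in seq_len(m)) {
      cj <- q + j
      hp <- H[cj, cj] - H[cj, seq_len(q)] %*% Hff_inv %*% H[seq_len(q), cj]
      hp <- max(as.numeric(hp), 1e-12)
      mi[j] <- (n - 1) * g[cj]^2 / (2 * hp)
      epc[j] <- -g[cj] / hp
      sepc[j] <- if (cand$matrix[j] == "A") {
        epc[j] * sds[cand$col[j]] / sds[cand$row[j]]
      } else {
        epc[j] / (sds[cand$row[j]] * sds[cand$col[j]])
      }
    }
    out1 <- tibble::tibble(term = cand$label, mi = mi, epc = epc, sepc = sepc,
                           admissible = cand$type == "error_covariance")
  } else {
    out1 <- out0[0, ]
  }

  out <- dplyr::bind_rows(out1, out0)
  out <- out[order(-out$mi), ]
  out[out$mi > threshold | out$term %in% out0$term, ]
}

#' Compare candidate models and select one
#'
#' Ranks candidate models by the survey's selection logic: among models
#' meeting the fit cutoffs (CFI and TLI above 0.90, RMSEA below 0.05) the
#' lowest BIC wins; if no candidate qualifies, the lowest BIC overall is
#' returned with a flag. Exact index ties keep the first candidate in
#' listing order and are flagged.
#'
#' @param x Either a named list of [sem_fit()] objects (indices computed
#'   here) or a data frame with columns `label`, `aic`, `bic`, `cfi`,
#'   `tli`, `rmsea` (indices entered as data, e.g. from a published
#'   comparison table).
#' @return A tibble of candidates with their indices, `meets_thresholds`,
#'   and `selected`; attributes `selection`, `no_candidate_meets_thresholds`
#'   and `tie`.
#' @export
compare_models <- function(x) {
  if (is.data.frame(x)) {
    tab <- tibble::as_tibble(x)
    stopifnot(all(c("label", "aic", "bic", "cfi", "tli", "rmsea") %in% names(tab)))
  } else {
    stopifnot(is.list(x), length(x) >= 1, !is.null(names(x)))
    ns <- vapply(x, function(f) f$n, numeric(1))
    if (length(unique(ns)) > 1) abort("candidates were fitted to different sample sizes")
    tab <- dplyr::bind_rows(purrr::imap(x, function(f, nm) {
      fi <- fit_indices(f)
      tibble::tibble(label = nm, aic = fi$aic, bic = fi$bic, cfi = fi$cfi,
                     tli = fi$tli, rmsea = fi$rmsea)
    }))
  }
  if (nrow(tab) < 1) abort("no candidates supplied")
  tab$meets_thresholds <- tab$cfi > 0.90 & tab$tli > 0.90 & tab$rmsea < 0.05
  pool <- if (any(tab$meets_thresholds)) which(tab$meets_thresholds) else seq_len(nrow(tab))
  best <- pool[which.min(tab$bic[pool])]
  tie <- sum(tab$bic[pool] == tab$bic[best]) > 1
  tab$selected <- seq_len(nrow(tab)) == best
  attr(tab, "selection") <- tab$label[best]
  attr(tab, "no_candidate_meets_thresholds") <- !any(tab$meets_thresholds)
  attr(tab, "tie") <- tie
  tab
}
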