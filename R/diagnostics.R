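as_correlation <- function(x) {
  x <- as.matrix(x)
  if (isSymmetric(unname(x), tol = 1e-8) && all(abs(diag(x) - 1) < 1e-8)) {
    return(x)
  }
  if (isSymmetric(unname(x), tol = 1e-8)) return(cov2cor(x))
  cor(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Ratio of summed squared correlations to summed squared correlations plus
#' summed squared anti-image partial correlations, overall and per item.
#' Values near 1 indicate that partial correlations are small relative to
#' marginal ones, i.e. the data are factorable.
#'
#' @param x A correlation matrix, covariance matrix, or data frame/matrix
#'   of item responses (converted to correlations).
#' @return A list with `overall` and `per_item` (named vector), both in
#'   `[0, 1]`.
#' @export
kmo <- function(x) {
  R <- as_correlation(x)
  p <- ncol(R)
  if (p < 2) abort("KMO needs at least 2 items")
  Ri <- tryCatch(solve(R), error = function(e) abort("correlation matrix is singular"))
  d <- 1 / sqrt(diag(Ri))
  Q <- -Ri * tcrossprod(d)          # anti-image partial correlations
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  denom_item <- colSums(r2) + colSums(q2)
  if (all(colSums(r2) == 0)) abort("all off-diagonal correlations are zero; KMO undefined")
  list(
    overall = sum(r2) / (sum(r2) + sum(q2)),
    per_item = setNames(colSums(r2) / denom_item, colnames(R))
  )
}

#' Bartlett's test of sphericity
#'
#' Tests the hypothesis that the correlation matrix is the identity,
#' `statistic = -(n - 1 - (2p + 5)/6) log det(R)` against chi-square on
#' `p(p-1)/2` degrees of freedom.
#'
#' @param x Correlation matrix (or data, converted).
#' @param n Sample size (must exceed the number of items).
#' @return A one-row tibble `statistic`, `df`, `p.value`.
#' @export
bartlett_sphericity <- function(x, n) {
  R <- as_correlation(x)
  p <- ncol(R)
  if (n <= p) abort("Bartlett's test needs n > p")
  detR <- det(R)
  if (detR <= 0) abort("correlation matrix is not positive definite")
  stat <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  tibble::tibble(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Mardia's multivariate skewness and kurtosis
#'
#' `b1p = mean of (d_ij)^3` over all ordered pairs and `b2p = mean of
#' (d_ii)^2`, where `d_ij = (x_i - xbar)' S^-1 (x_j - xbar)` with the
#' biased (divide by n) covariance. The skewness test refers
#' `n b1p / 6` to chi-square on `p(p+1)(p+2)/6` df; the kurtosis test
#' standardizes `b2p` against its normal-theory mean `p(p+2)` and variance
#' `8 p (p+2) / n`.
#'
#' @param x Data matrix or data frame (subjects by variables).
#' @return A one-row tibble with `b1p`, `b2p`, both test statistics and
#'   p-values, and a `normal` flag at the 5% level.
#' @export
mardia <- function(x) {
  X <- as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort("Mardia's test needs n > p")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  Si <- tryCatch(solve(S), error = function(e) abort("covariance matrix is singular"))
  D <- Xc %*% Si %*% t(Xc)
  b1p <- mean(D^3)
  b2p <- mean(diag(D)^2)
  skew_stat <- n * b1p / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  kurt_stat <- (b2p - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  tibble::tibble(
    b1p = b1p, b2p = b2p,
    skew_statistic = skew_stat, skew_df = skew_df,
    skew_p = pchisq(skew_stat, skew_df, lower.tail = FALSE),
    kurt_statistic = kurt_stat,
    kurt_p = 2 * pnorm(-abs(kurt_stat)),
    normal = pchisq(skew_stat, skew_df, lower.tail = FALSE) > 0.05 &
      2 * pnorm(-abs(kurt_stat)) > 0.05
  )
}

#' Mahalanobis multivariate outlier screen
#'
#' Flags subjects whose squared Mahalanobis distance exceeds the
#' chi-square quantile at `1 - alpha` (the survey convention uses
#' p < 0.001).
#'
#' @param x Data matrix or data frame.
#' @param alpha Tail probability for the flag threshold.
#' @return A tibble `distance` (squared), `p.value`, `flag` per subject.
#' @export
mahalanobis_outliers <- function(x, alpha = 0.001) {
  X <- as.matrix(x)
  S <- cov(X)
  d2 <- tryCatch(mahalanobis(X, colMeans(X), S),
                 error = function(e) abort("covariance matrix is singular"))
  p <- ncol(X)
  tibble::tibble(
    distance = d2,
    p.value = pchisq(d2, p, lower.tail = FALSE),
    flag = d2 > qchisq(1 - alpha, p)
  )
}

#' Harman's single-factor test for common method bias
#'
#' Share of total variance carried by the first unrotated factor of the
#' full item set; a share above 50% flags likely common-method bias.
#' `method = "pca"` (default) uses the leading eigenvalue of the
#' correlation matrix over p; `"paf"` uses the first principal-axis factor
#' (squared-multiple-correlation communalities) and is the more
#' conservative EFA reading.
#'
#' @param x Data or correlation matrix.
#' @param method `"pca"` or `"paf"`.
#' @param threshold Flag threshold (default 0.5).
#' @return A one-row tibble `share`, `flagged`, `method`.
#' @export
harman_single_factor <- function(x, method = c("pca", "paf"), threshold = 0.5) {
  method <- match.arg(method)
  R <- as_correlation(x)
  p <- ncol(R)
  share <- if (method == "pca") {
    eigen(R, symmetric = TRUE, only.values = TRUE)$values[1] / p
  } else {
    Ri <- tryCatch(solve(R), error = function(e) NULL)
    h2 <- if (is.null(Ri)) rep(1, p) else 1 - 1 / diag(Ri)
    Rr <- R; diag(Rr) <- h2
    max(eigen(Rr, symmetric = TRUE, only.values = TRUE)$values[1], 0) / p
  }
  share <- min(max(share, 0), 1)
  tibble::tibble(share = share, flagged = share > threshold, method = method)
}

#' Composite reliability
#'
#' `CR = (sum lambda)^2 / ((sum lambda)^2 + sum theta)`; the survey's
#' acceptability floor is 0.60.
#'
#' @param loadings Standardized loadings of one construct.
#' @param error_variances Matching indicator error variances.
#' @return The scalar CR.
#' @export
composite_reliability <- function(loadings, error_variances) {
  stopifnot(length(loadings) == length(error_variances))
  s <- sum(loadings)^2
  s / (s + sum(error_variances))
}

#' Average variance extracted
#'
#' `AVE = sum(lambda^2) / k` over a construct's standardized loadings.
#'
#' @param loadings Standardized loadings of one construct.
#' @return The scalar AVE.
#' @export
ave_extracted <- function(loadings) {
  mean(loadings^2)
}

#' Discriminant validity (Fornell-Larcker)
#'
#' Every factor correlation must stay below the square root of the AVE of
#' both constructs involved.
#'
#' @param ave Named vector of AVE per construct.
#' @param factor_cor Factor correlation matrix (dimnames matching `ave`).
#' @return A tibble of construct pairs with `correlation`, `sqrt_ave_min`,
#'   `pass`, plus attribute `all_pass`.
#' @export
discriminant_validity <- function(ave, factor_cor) {
  cs <- names(ave)
  stopifnot(all(cs %in% colnames(factor_cor)))
  pairs <- utils::combn(cs, 2)
  out <- tibble::tibble(
    construct_1 = pairs[1, ], construct_2 = pairs[2, ],
    correlation = factor_cor[t(pairs)],
    sqrt_ave_min = pmin(sqrt(ave[pairs[1, ]]), sqrt(ave[pairs[2, ]]))
  )
  out$pass <- abs(out$correlation) < out$sqrt_ave_min
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' One-way random-effects intraclass correlation
#'
#' ICC(1) from the one-way ANOVA mean squares with the unbalanced-design
#' group-size correction `n0 = (N - sum(n_i^2)/N) / (k - 1)`. An ICC of
#' 0.1 or more recommends a multilevel model.
#'
#' @param values Numeric outcome.
#' @param groups Grouping factor (clusters).
#' @param cutoff Recommendation threshold.
#' @return A one-row tibble `icc`, `ms_between`, `ms_within`, `n_groups`,
#'   `recommend_multilevel`.
#' @export
icc_oneway <- function(values, groups, cutoff = 0.1) {
  groups <- as.factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  ni <- as.numeric(table(groups))
  if (k < 2 || any(ni < 2)) {
    abort("ICC needs at least 2 groups with at least 2 observations each")
  }
  N <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  icc <- (msb - msw) / (msb + (n0 - 1) * msw)
  tibble::tibble(
    icc = icc, ms_between = msb, ms_within = msw, n_groups = k,
    recommend_multilevel = icc >= cutoff
  )
}

#' Loading-ranked serpentine item parceling
#'
#' Items are ranked by (absolute) standardized loading and dealt into
#' parcels serpentine-style (1, 2, 3, 3, 2, 1, ...), balancing parcel
#' loading sums; the parcel score is the mean of its items. Ties keep the
#' declared item order, so assignment is deterministic. An explicit
#' `assignment` overrides the ranking to reproduce any published parceling.
#'
#' @param loadings Named vector of standardized loadings for one construct.
#' @param n_parcels Number of parcels (the survey convention is 3).
#' @param data Optional subject-by-item data; when supplied, parcel score
#'   columns are returned.
#' @param assignment Optional named integer vector item -> parcel.
#' @return A list with `assignment` (tibble `item`, `loading`, `parcel`)
#'   and, when `data` is given, `scores` (tibble of parcel means).
#' @export
parcel_items <- function(loadings, n_parcels = 3, data = NULL, assignment = NULL) {
  items <- names(loadings)
  if (length(items) < n_parcels) {
    abort(sprintf("cannot deal %d items into %d parcels", length(items), n_parcels))
  }
  if (is.null(assignment)) {
    ord <- order(-abs(loadings))  # ties keep declared order (stable)
    cycle <- c(seq_len(n_parcels), rev(seq_len(n_parcels)))
    dealt <- rep_len(cycle, length(items))
    assignment <- integer(length(items))
    assignment[ord] <- dealt
    names(assignment) <- items
  } else {
    stopifnot(all(items %in% names(assignment)))
    assignment <- assignment[items]
  }
  tab <- tibble::tibble(
    item = items, loading = as.numeric(loadings),
    parcel = as.integer(assignment)
  )
  out <- list(assignment = tab)
  if (!is.null(data)) {
    scores <- purrr::map(sort(unique(tab$parcel)), function(pl) {
      rowMeans(as.matrix(data[, tab$item[tab$parcel == pl], drop = FALSE]))
    })
    names(scores) <- paste0("parcel_", sort(unique(tab$parcel)))
    out$scores <- tibble::as_tibble(scores)
  }
  out
}

#' Pre-modeling diagnostics report
#'
#' Runs the survey's assumption battery on an item-response table: overall
#' and per-construct KMO and Bartlett tests, Mardia's multivariate
#' normality tests, Mahalanobis outlier screening at p < 0.001, Harman's
#' single-factor common-method-bias share, and (optionally) the one-way
#' ICC over a clustering column.
#'
#' @param data Subject-by-item data (canonical item column names).
#' @param cluster Optional name of a grouping column for the ICC.
#' @param alpha Outlier tail probability.
#' @return A list `kmo_overall`, `per_construct` (tibble with KMO and
#'   Bartlett per instrument and overall), `mardia`, `outliers`,
#'   `n_outliers`, `harman`, `icc`.
#' @export
run_diagnostics <- function(data, cluster = NULL, alpha = 0.001) {
  lay <- instrument_layout()
  items_of <- function(i) paste0(lay$prefix[i], "_", seq_len(lay$n_items[i]))
  all_items <- unlist(purrr::map(seq_len(nrow(lay)), items_of))
  missing <- setdiff(all_items, names(data))
  if (length(missing)) {
    abort(paste0("missing item columns: ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(data[, all_items])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)

  per <- purrr::map(seq_len(nrow(lay)), function(i) {
    Xi <- X[, items_of(i), drop = FALSE]
    b <- bartlett_sphericity(Xi, n)
    tibble::tibble(
      construct = lay$latent[i], kmo = kmo(Xi)$overall,
      bartlett_chisq = b$statistic, bartlett_df = b$df, bartlett_p = b$p.value
    )
  })
  ov <- bartlett_sphericity(X, n)
  per_construct <- dplyr::bind_rows(
    dplyr::bind_rows(per),
    tibble::tibble(construct = "overall", kmo = kmo(X)$overall,
                   bartlett_chisq = ov$statistic, bartlett_df = ov$df,
                   bartlett_p = ov$p.value)
  )
  outl <- mahalanobis_outliers(X, alpha = alpha)
  list(
    kmo_overall = per_construct$kmo[per_construct$construct == "overall"],
    per_construct = per_construct,
    mardia = mardia(X),
    outliers = outl,
    n_outliers = sum(outl$flag),
    harman = harman_single_factor(X),
    icc = if (!is.null(cluster)) {
      icc_oneway(rowMeans(X), data[[cluster]][stats::complete.cases(as.matrix(data[, all_items]))])
    }
  )
}

#' Listwise deletion under the survey's 5% rule
#'
#' Drops incomplete rows when they are fewer than 5% of the sample;
#' refuses (with an error) otherwise, since listwise deletion is not
#' defensible at higher missingness.
#'
#' @param data Subject-level data frame.
#' @param columns Columns to require complete (default: all).
#' @return The complete-case tibble, with attributes `n_dropped` and
#'   `prop_dropped`.
#' @export
listwise_delete <- function(data, columns = names(data)) {
  cc <- stats::complete.cases(data[, columns, drop = FALSE])
  prop <- mean(!cc)
  if (prop >= 0.05) {
    abort(sprintf("%.1f%% of rows are incomplete; listwise deletion is only applied below 5%%",
                  100 * prop))
  }
  out <- tibble::as_tibble(data[cc, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!cc)
  attr(out, "prop_dropped") <- prop
  out
}
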