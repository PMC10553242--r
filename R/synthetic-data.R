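#' Fitted structural coefficients of the final survey model
#'
#' The unstandardized structural estimates retained in the pruned survey
#' model: nine predictors of depressive symptoms (including the three
#' latent exogenous factors) and five predictors of ADHD symptoms, with
#' the depression-to-ADHD path of 0.73 carrying all depression-mediated
#' indirect effects.
#'
#' @return A tibble `source`, `target`, `value`.
#' @export
final_model_coefficients <- function() {
  tibble::tribble(
    ~source,                ~target,      ~value,
    "chronic_disease",      "depression",  0.19,
    "worry_academic",       "depression",  0.24,
    "stressful_life_event", "depression",  0.07,
    "alcohol_use",          "depression",  0.10,
    "studying_hours",       "depression", -0.02,
    "sleeping_hours",       "depression", -0.03,
    "piu",                  "depression",  0.23,
    "social_support",       "depression", -0.23,
    "insomnia",             "depression",  0.24,
    "year_of_study",        "adhd",       -0.10,
    "mother_education",     "adhd",       -0.09,
    "birth_order",          "adhd",       -0.09,
    "chat_chewing",         "adhd",        0.18,
    "depression",           "adhd",        0.73
  )
}

#' Default covariate marginals of the survey population
#'
#' Category probabilities (and count-scale settings) matching the printed
#' frequency tables of the survey: socio-demographic, clinical/behavioral
#' and academic covariates of 1514 undergraduates.
#'
#' @return A named list; binary entries are `P(yes)`, categorical entries
#'   are probability vectors over codes `1..k`, count/continuous entries
#'   are `list(mean, sd, min, max)` rounded to integers.
#' @export
covariate_marginals <- function() {
  list(
    sex = 0.349,                       # 1 = female
    age = list(mean = 21.3, sd = 1.8, min = 18, max = 30),
    marital_status = c(0.969, 0.026, 0.003, 0.002),
    residence = 0.668,                 # 1 = urban
    mother_education = c(0.306, 0.273, 0.170, 0.251),
    father_education = c(0.158, 0.314, 0.160, 0.368),
    monthly_allowance = list(meanlog = log(1000), sdlog = 0.7, min = 100, max = 10000),
    family_economic_level = c(0.183, 0.787, 0.030),
    partner = 0.797,
    birth_order = c(0.30, 0.22, 0.15, 0.11, 0.08, 0.06, 0.04, 0.04),
    chronic_disease = 0.077,
    parental_psychiatric_illness = 0.083,
    head_trauma = 0.096,
    stressful_life_event = 0.416,
    smoking = 0.066,
    alcohol_use = 0.665,
    current_alcohol_use = 0.492,
    chat_chewing = 0.102,
    cannabis_use = 0.031,
    physical_exercise = 0.744,
    year_of_study = c(0.295, 0.193, 0.307, 0.137, 0.030, 0.038),
    academic_failure = 0.067,
    worry_academic = 0.585,
    sleeping_hours = list(mean = 8, sd = 2, min = 3, max = 14),
    studying_hours = list(mean = 5, sd = 1.5, min = 0, max = 12),
    department_type = 0.5
  )
}

default_loadings <- function() {
  lay <- instrument_layout()
  out <- numeric(0)
  # scale-setting indicator loads 1 (the fixed-to-1 estimation convention);
  # remaining loadings are fixed values cycling through [0.6, 0.8]
  pattern <- c(0.75, 0.65, 0.80, 0.70, 0.60, 0.78, 0.68, 0.72)
  for (i in seq_len(nrow(lay))) {
    k <- lay$n_items[i]
    lam <- c(1, pattern[seq_len(k - 1)])
    names(lam) <- paste0(lay$prefix[i], "_", seq_len(k))
    out <- c(out, lam)
  }
  out
}

default_thresholds <- function() {
  # per-instrument cutpoints on each item's standardized scale, chosen once
  # to land scored prevalences near the survey's printed figures (see the
  # methods vignette); right-skew reflects symptom rarity
  list(
    asrs = c(-0.75, -0.25, 0.25, 0.75),
    phq  = c(-0.20, 0.60, 1.40),
    isi  = c(-0.50, 0.30, 1.00, 1.70),
    osss_1 = c(-1.20, -0.40, 0.40),
    osss = c(-1.60, -0.80, 0.00, 0.80),
    piuq = c(-0.80, 0.00, 0.80, 1.60)
  )
}

#' Configuration for the survey simulator
#'
#' Assembles the generating world for [simulate_survey()]: the final
#' structural model with its fitted coefficients as defaults, fixed factor
#' loadings, disturbance (co)variances, per-item ordinal thresholds,
#' covariate marginals from the survey's frequency tables, declared
#' negative covariances among exogenous predictors, and optional
#' missingness/outlier contamination.
#'
#' @param n Sample size (default: the survey's 1514 completed responses).
#' @param seed Integer seed; one global seed drives every sub-stream.
#' @param structural Tibble `source`, `target`, `value` of structural
#'   coefficients (default [final_model_coefficients()]).
#' @param loadings Named vector of generating loadings per indicator.
#' @param disturbance_cov 2x2 disturbance covariance matrix for
#'   (depression, adhd).
#' @param thresholds Per-instrument cutpoint list (see
#'   `default_thresholds`); cutpoints must be strictly increasing.
#' @param marginals Covariate marginal list (see [covariate_marginals()]);
#'   category probabilities must sum to 1.
#' @param exog_cov Tibble `a`, `b`, `cov` of exogenous covariances on the
#'   generating (pre-discretization) scale.
#' @param missing_rate,outlier_rate Contamination proportions applied by
#'   [inject_missing()] / [inject_outliers()].
#' @return A `semloop_sim_config` list, validated.
#' @export
sim_config <- function(n = 1514, seed = 1,
                       structural = final_model_coefficients(),
                       loadings = default_loadings(),
                       disturbance_cov = matrix(c(0.80, 0.10, 0.10, 0.45), 2, 2),
                       thresholds = default_thresholds(),
                       marginals = covariate_marginals(),
                       exog_cov = NULL,
                       missing_rate = 0, outlier_rate = 0) {
  if (is.null(exog_cov)) {
    exog_cov <- tibble::tribble(
      ~a,                 ~b,               ~cov,
      "insomnia",         "sleeping_hours", -0.27,
      "mother_education", "birth_order",    -0.36,
      "sleeping_hours",   "studying_hours", -0.77,
      "piu",              "insomnia",        0.30,
      "piu",              "social_support", -0.20,
      "insomnia",         "social_support", -0.15
    )
  }
  cfg <- structure(
    list(
      n = n, seed = as.integer(seed), structural = tibble::as_tibble(structural),
      loadings = loadings, disturbance_cov = disturbance_cov,
      thresholds = thresholds, marginals = marginals,
      exog_cov = tibble::as_tibble(exog_cov),
      missing_rate = missing_rate, outlier_rate = outlier_rate
    ),
    class = "semloop_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (nm in names(cfg$thresholds)) {
    tau <- cfg$thresholds[[nm]]
    if (any(diff(tau) <= 0)) {
      abort(paste0("thresholds for '", nm, "' must be strictly increasing"))
    }
  }
  for (nm in names(cfg$marginals)) {
    m <- cfg$marginals[[nm]]
    if (is.numeric(m) && length(m) > 1 && abs(sum(m) - 1) > 1e-6) {
      abort(paste0("marginals for '", nm, "' must sum to 1"))
    }
  }
  B <- structural_loop_matrix(cfg$structural)
  sr <- if (nrow(B)) max(Mod(eigen(B, only.values = TRUE)$values)) else 0
  if (sr >= 1) {
    abort(sprintf("unstable structural loop: eigenvalue stability index %.3f >= 1", sr))
  }
  invisible(cfg)
}

structural_loop_matrix <- function(structural) {
  endo <- c("depression", "adhd")
  B <- matrix(0, 2, 2, dimnames = list(endo, endo))
  sl <- structural[structural$source %in% endo & structural$target %in% endo, ]
  if (nrow(sl)) B[cbind(sl$target, sl$source)] <- sl$value
  B
}

# covariance parameters of the config, as free values on the generating model
sim_truth_theta <- function(cfg, ram) {
  fr <- ram$free
  theta <- numeric(nrow(fr))
  names(theta) <- fr$label
  lay <- instrument_layout()
  item_latent <- setNames(rep(lay$latent, lay$n_items),
                          unlist(purrr::map2(lay$prefix, lay$n_items,
                                             ~ paste0(.x, "_", seq_len(.y)))))
  for (i in seq_len(nrow(fr))) {
    lab <- fr$label[i]; type <- fr$type[i]
    theta[i] <- switch(
      type,
      loading = cfg$loadings[[fr$row[i]]],
      structural = {
        hit <- cfg$structural$value[cfg$structural$source == fr$col[i] &
                                      cfg$structural$target == fr$row[i]]
        if (length(hit)) hit else 0
      },
      error_variance = {
        lam <- cfg$loadings[[fr$row[i]]]
        if (lam == 1) 0.40 else max(1 - lam^2, 0.2)
      },
      exogenous_variance = sim_exog_variance(cfg, fr$row[i]),
      disturbance_variance = cfg$disturbance_cov[
        match(fr$row[i], c("depression", "adhd")),
        match(fr$row[i], c("depression", "adhd"))],
      error_covariance = 0.15,
      exogenous_covariance = {
        hit <- cfg$exog_cov$cov[(cfg$exog_cov$a == fr$row[i] & cfg$exog_cov$b == fr$col[i]) |
                                  (cfg$exog_cov$a == fr$col[i] & cfg$exog_cov$b == fr$row[i])]
        if (length(hit)) hit else 0
      },
      disturbance_covariance = cfg$disturbance_cov[1, 2],
      abort(paste0("unhandled parameter type ", type))
    )
  }
  theta
}

sim_exog_variance <- function(cfg, name) {
  if (name %in% c("piu", "insomnia", "social_support")) return(1)
  m <- cfg$marginals[[name]]
  if (is.null(m)) return(1)
  if (is.list(m)) {
    if (!is.null(m[["sd"]])) return(m[["sd"]]^2)
    # lognormal: variance of exp(meanlog + sdlog Z)
    return((exp(m[["sdlog"]]^2) - 1) * exp(2 * m[["meanlog"]] + m[["sdlog"]]^2))
  }
  if (length(m) == 1) return(m * (1 - m))
  codes <- seq_along(m)
  mu <- sum(codes * m)
  sum((codes - mu)^2 * m)
}

draw_covariates <- function(cfg) {
  n <- cfg$n
  marg <- cfg$marginals
  # correlated block: latent exogenous factors + covariates with declared
  # covariances, generated from a joint Gaussian copula
  block <- c("piu", "insomnia", "social_support",
             "sleeping_hours", "studying_hours", "mother_education", "birth_order")
  sds <- vapply(block, function(v) sqrt(sim_exog_variance(cfg, v)), numeric(1))
  R <- diag(length(block)); dimnames(R) <- list(block, block)
  for (i in seq_len(nrow(cfg$exog_cov))) {
    a <- cfg$exog_cov$a[i]; b <- cfg$exog_cov$b[i]
    if (a %in% block && b %in% block) {
      r <- cfg$exog_cov$cov[i] / (sds[a] * sds[b])
      R[a, b] <- R[b, a] <- max(min(r, 0.95), -0.95)
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) abort("exogenous covariance block is not positive definite")
  Z <- MASS::mvrnorm(n, mu = rep(0, length(block)), Sigma = R)
  colnames(Z) <- block

  out <- tibble::tibble(.rows = n)
  from_probs <- function(z, probs) {
    cuts <- qnorm(cumsum(probs)[-length(probs)])
    findInterval(z, cuts) + 1L
  }
  cont <- function(z, m) {
    pmin(pmax(round(m[["mean"]] + m[["sd"]] * z), m[["min"]]), m[["max"]])
  }
  for (nm in names(marg)) {
    m <- marg[[nm]]
    z <- if (nm %in% block) Z[, nm] else rnorm(n)
    out[[nm]] <- if (is.list(m)) {
      if (!is.null(m[["sd"]])) cont(z, m)
      else pmin(pmax(round(exp(m[["meanlog"]] + m[["sdlog"]] * z), -1),
                     m[["min"]]), m[["max"]])
    } else if (length(m) == 1) {
      as.integer(z < qnorm(m))
    } else {
      from_probs(z, m)
    }
  }
  list(covariates = out,
       latent_exog = Z[, c("piu", "insomnia", "social_support"), drop = FALSE])
}

item_thresholds <- function(cfg, item) {
  th <- cfg$thresholds
  if (item == "osss_1") return(th$osss_1)
  prefix <- sub("_[0-9]+$", "", item)
  th[[prefix]]
}

item_base_code <- function(item) {
  # ASRS/PHQ/ISI are anchored at 0; OSSS-3 and PIUQ-9 at 1
  if (grepl("^(osss|piuq)", item)) 1L else 0L
}

#' Simulate an ordinal survey dataset with known latent structure
#'
#' Draws covariates from their marginal distributions (with the declared
#' negative covariances), generates the latent exogenous factors and the
#' two latent outcomes through the reduced form
#' `eta = (I - B)^-1 (Gamma x + zeta)`, produces continuous indicator
#' responses `Lambda eta + epsilon`, and discretizes each onto its
#' instrument's ordinal scale through fixed thresholds. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `semloop_sim` list: `data` (ordinal item responses plus
#'   covariates, one row per subject), `continuous` (the pre-discretization
#'   indicator responses), `truth` (latent factor scores and disturbances),
#'   `theta_true` (the generating parameter vector on the final model's
#'   RAM), `ram` (that RAM), and `implied` (the implied covariance of the
#'   continuous responses and covariates).
#' @export
simulate_survey <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  model <- adhd_depression_model("final")
  ram <- to_ram(model)
  theta_true <- sim_truth_theta(cfg, ram)

  n <- cfg$n
  lay <- instrument_layout()
  items <- unlist(purrr::map2(lay$prefix, lay$n_items, ~ paste0(.x, "_", seq_len(.y))))

  if (n == 0) {
    empty <- tibble::as_tibble(setNames(
      rep(list(integer(0)), length(items) + 1), c("subject_id", items)))
    return(structure(list(
      data = empty, continuous = empty[0, ], truth = tibble::tibble(),
      theta_true = theta_true, ram = ram,
      implied = implied_covariance(ram, theta_true), config = cfg
    ), class = "semloop_sim"))
  }

  dr <- draw_covariates(cfg)
  covs <- dr$covariates

  # structural predictors on their generating scales
  x_names <- unique(cfg$structural$source[!cfg$structural$source %in%
                                            c("depression", "adhd")])
  X <- matrix(0, n, length(x_names), dimnames = list(NULL, x_names))
  for (nm in x_names) {
    X[, nm] <- if (nm %in% colnames(dr$latent_exog)) dr$latent_exog[, nm] else covs[[nm]]
  }

  B <- structural_loop_matrix(cfg$structural)
  G <- cfg$structural[!cfg$structural$source %in% c("depression", "adhd"), ]
  zeta <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = cfg$disturbance_cov)
  colnames(zeta) <- c("depression", "adhd")
  Gx <- matrix(0, n, 2, dimnames = list(NULL, c("depression", "adhd")))
  for (i in seq_len(nrow(G))) {
    Gx[, G$target[i]] <- Gx[, G$target[i]] + G$value[i] * X[, G$source[i]]
  }
  eta_endo <- t(solve(diag(2) - B, t(Gx + zeta)))
  eta <- cbind(eta_endo,
               dr$latent_exog[, c("piu", "insomnia", "social_support"), drop = FALSE])

  # continuous responses: Lambda eta + correlated errors
  lam <- cfg$loadings[items]
  item_latent <- rep(lay$latent, lay$n_items)
  Theta <- diag(vapply(items, function(it) {
    l <- cfg$loadings[[it]]
    if (l == 1) 0.40 else max(1 - l^2, 0.2)
  }, numeric(1)))
  dimnames(Theta) <- list(items, items)
  ec <- error_covariance_pairs()
  for (i in seq_len(nrow(ec))) {
    Theta[ec$source[i], ec$target[i]] <- Theta[ec$target[i], ec$source[i]] <- 0.15
  }
  eps <- MASS::mvrnorm(n, mu = rep(0, length(items)), Sigma = Theta)
  Ycont <- eta[, item_latent, drop = FALSE] %*% diag(lam) + eps
  colnames(Ycont) <- items

  # discretize on each item's implied standardized scale
  implied <- implied_covariance(ram, theta_true)
  sds <- sqrt(diag(implied)[items])
  ords <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  for (j in seq_along(items)) {
    tau <- item_thresholds(cfg, items[j])
    z <- Ycont[, j] / sds[j]
    ords[, j] <- item_base_code(items[j]) +
      as.integer(findInterval(z, tau))
  }

  data <- dplyr::bind_cols(
    tibble::tibble(subject_id = seq_len(n)),
    tibble::as_tibble(as.data.frame(ords)),
    covs
  )
  continuous <- dplyr::bind_cols(
    tibble::tibble(subject_id = seq_len(n)),
    tibble::as_tibble(as.data.frame(Ycont)),
    covs
  )
  truth <- dplyr::bind_cols(
    tibble::tibble(subject_id = seq_len(n)),
    tibble::as_tibble(as.data.frame(eta)),
    tibble::as_tibble(as.data.frame(zeta)) %>%
      rename(zeta_depression = "depression", zeta_adhd = "adhd")
  )

  out <- structure(
    list(data = data, continuous = continuous, truth = truth,
         theta_true = theta_true, ram = ram, implied = implied, config = cfg),
    class = "semloop_sim"
  )
  if (cfg$missing_rate > 0) {
    out$data <- inject_missing(out$data, cfg$missing_rate, seed = cfg$seed + 1L)
  }
  if (cfg$outlier_rate > 0) {
    out <- inject_outliers(out, cfg$outlier_rate, seed = cfg$seed + 2L)
  }
  out
}

#' @export
print.semloop_sim <- function(x, ...) {
  cat("<semloop_sim> n = ", nrow(x$data), ", seed = ", x$config$seed,
      ", ", ncol(x$data) - 1, " columns\n", sep = "")
  invisible(x)
}

#' Inject missingness completely at random
#'
#' Each subject independently gets a missing covariate cell with
#' probability `rate` (so about `n * rate` subjects are affected,
#' emulating the survey's sporadic predictor-side missingness); the
#' blanked column is chosen uniformly per affected subject. Rates at or
#' above 5% are refused: the downstream workflow handles missingness by
#' listwise deletion, which is only defensible below that bound.
#'
#' @param table Subject-level data frame.
#' @param rate Per-subject missingness probability in `[0, 0.05)`.
#' @param seed Integer seed.
#' @param columns Candidate columns (default: every non-item, non-id
#'   column).
#' @return The table with `NA`s injected.
#' @export
inject_missing <- function(table, rate, seed = 1, columns = NULL) {
  if (rate >= 0.05) {
    abort("missing rate >= 5% is outside the listwise-deletion regime")
  }
  if (rate == 0) return(table)
  if (is.null(columns)) {
    columns <- setdiff(names(table),
                       c("subject_id", grep("^(asrs|phq|isi|osss|piuq)_", names(table), value = TRUE)))
  }
  set.seed(seed)
  hit <- which(runif(nrow(table)) < rate)
  which_col <- sample(columns, length(hit), replace = TRUE)
  for (i in seq_along(hit)) {
    table[[which_col[i]]][hit[i]] <- NA
  }
  table
}

#' Inject multivariate outliers
#'
#' Marks a random subset of subjects and displaces each of their item
#' responses by 3 standard deviations with an independent random sign per
#' item. The signs matter: a coherent all-items shift lies along the
#' common-factor direction and is nearly invisible to Mahalanobis
#' screening (its squared distance grows by roughly 9, far below the
#' chi-square flag threshold), whereas a sign-scrambled displacement of
#' the same magnitude breaks the correlation structure and is the kind of
#' multivariate outlier the p < 0.001 screen targets.
#'
#' @param sim A `semloop_sim` object (or a data frame of item responses).
#' @param rate Proportion of subjects to contaminate.
#' @param seed Integer seed.
#' @return The input with shifted responses and an `outlier` logical
#'   column added to `data` (and `continuous` for sim objects).
#' @export
inject_outliers <- function(sim, rate, seed = 1) {
  if (rate == 0) return(sim)
  is_sim <- inherits(sim, "semloop_sim")
  data <- if (is_sim) sim$data else sim
  items <- grep("^(asrs|phq|isi|osss|piuq)_", names(data), value = TRUE)
  set.seed(seed)
  n <- nrow(data)
  hit <- runif(n) < rate
  if (is_sim) {
    sds <- sqrt(diag(sim$implied)[items])
    for (j in items) {
      sign_j <- sample(c(-3, 3), sum(hit), replace = TRUE)
      sim$continuous[[j]][hit] <- sim$continuous[[j]][hit] + sign_j * sds[[j]]
      tau <- item_thresholds(sim$config, j)
      z <- sim$continuous[[j]][hit] / sds[[j]]
      sim$data[[j]][hit] <- item_base_code(j) + as.integer(findInterval(z, tau))
    }
    sim$data$outlier <- hit
    sim$continuous$outlier <- hit
    return(sim)
  }
  for (j in items) {
    span <- max(data[[j]], na.rm = TRUE) - min(data[[j]], na.rm = TRUE)
    lo <- min(data[[j]], na.rm = TRUE)
    top <- max(data[[j]], na.rm = TRUE)
    shift <- sample(c(-1, 1), sum(hit), replace = TRUE) * ceiling(span / 2)
    data[[j]][hit] <- pmin(pmax(data[[j]][hit] + shift, lo), top)
  }
  data$outlier <- hit
  data
}
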