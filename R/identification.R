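#' Order condition for simultaneous equations
#'
#' Necessary counting rule for identification of each endogenous equation
#' in a non-recursive system: the number of variables excluded from the
#' equation (zero entries in its system-matrix row) must be at least M - 1,
#' where M is the number of endogenous variables in the loop.
#'
#' @param sm A [build_system_matrix()] result.
#' @return A tibble with one row per equation: `equation`, `K` (excluded
#'   count), `M`, `satisfied`.
#' @export
order_condition <- function(sm) {
  stopifnot(is.matrix(sm))
  M <- nrow(sm)
  tibble::tibble(
    equation = rownames(sm),
    K = as.integer(unname(apply(sm, 1, function(r) sum(r == 0)))),
    M = M,
    satisfied = .data$K >= M - 1
  )
}

#' Rank condition for simultaneous equations
#'
#' Sufficient identification rule, evaluated by the classical reduction of
#' the system matrix: for each equation, delete its row and every column in
#' which that row holds a 1; from the remaining submatrix drop all-zero
#' rows, duplicated rows, and rows reproducible as sums of other rows
#' (linear dependence over the rationals). The number of surviving rows is
#' the rank; the equation is identified when rank >= M - 1, and the model
#' when every equation is.
#'
#' @param sm A [build_system_matrix()] result.
#' @return A tibble with one row per equation: `equation`, `rank`,
#'   `identified`, plus attribute `model_identified`.
#' @export
rank_condition <- function(sm) {
  stopifnot(is.matrix(sm))
  M <- nrow(sm)
  out <- tibble::tibble(
    equation = rownames(sm),
    rank = vapply(seq_len(M), function(i) {
      keep_cols <- sm[i, ] == 0
      red <- sm[-i, keep_cols, drop = FALSE]
      red <- red[rowSums(red != 0) > 0, , drop = FALSE]
      if (!nrow(red)) return(0L)
      as.integer(qr(t(red))$rank)
    }, integer(1))
  )
  out$identified <- out$rank >= M - 1
  attr(out, "model_identified") <- all(out$identified)
  out
}

#' Instrument designation for a feedback loop
#'
#' In a non-recursive model with correlated disturbances, each loop
#' equation needs instrumental variables: exogenous variables with a direct
#' structural path into one loop member and none into the other. The
#' returned candidates for a member are the exogenous variables feeding
#' only that member; they instrument the reciprocal path into the *other*
#' member's equation.
#'
#' @param model A [sem_model()] with a declared feedback loop.
#' @return A tibble `member`, `instruments` (list-column), `n`, `flagged`
#'   (`TRUE` when a member has no instrument).
#' @export
designate_instruments <- function(model) {
  if (!length(model$loop)) {
    abort("model has no feedback loop; instruments are only defined for loops")
  }
  stop_if_invalid(model)
  sp <- structural_paths(model)
  exo <- vars_by_role(model, c("latent_exogenous", "observed_exogenous"))
  out <- purrr::map(model$loop, function(m) {
    others <- setdiff(model$loop, m)
    into_m <- sp$source[sp$target == m & sp$source %in% exo]
    into_others <- sp$source[sp$target %in% others & sp$source %in% exo]
    setdiff(into_m, into_others)
  })
  tibble::tibble(
    member = model$loop,
    instruments = out,
    n = lengths(out),
    flagged = lengths(out) == 0
  )
}

#' Count the free parameters of a model
#'
#' Free parameters are: loadings not fixed for scale setting, indicator
#' error variances, structural paths (including both loop paths), variances
#' of exogenous variables (observed and latent), disturbance variances, and
#' all declared covariances (disturbance, error and exogenous covariances).
#'
#' @param model A [sem_model()].
#' @return A one-row tibble with the component counts and their `total`.
#' @seealso [parameter_groups()] for the worked-arithmetic grouping,
#'   [required_sample_size()] for N:q planning.
#' @export
count_free_parameters <- function(model) {
  stop_if_invalid(model)
  p <- model$paths
  ind <- vars_by_role(model, "indicator")
  loadings <- p[p$kind == "loading", , drop = FALSE]
  tibble::tibble(
    loadings_free = sum(!loadings$fixed),
    indicator_error_variances = length(ind),
    structural_paths = sum(p$kind == "structural" & !p$fixed),
    exogenous_variances = length(vars_by_role(model, c("latent_exogenous", "observed_exogenous"))),
    disturbance_variances = length(vars_by_role(model, "latent_endogenous")),
    covariances = sum(p$kind %in% c("disturbance_covariance", "error_covariance",
                                    "exogenous_covariance") & !p$fixed),
    total = .data$loadings_free + .data$indicator_error_variances +
      .data$structural_paths + .data$exogenous_variances +
      .data$disturbance_variances + .data$covariances
  )
}

#' Free-parameter count grouped as in the sample-size worked arithmetic
#'
#' Groups the same free parameters the way the survey's planning arithmetic
#' does: measurement part (free loadings + indicator error variances),
#' outcome-specific exogenous blocks (path + variance per variable, two
#' paths + variance for predictors common to both outcomes), the feedback
#' loop block (two reciprocal paths, two disturbance variances, one
#' disturbance covariance), and declared error covariances.
#'
#' @param model A [sem_model()].
#' @return A tibble `group`, `count`, with attribute `total`.
#' @export
parameter_groups <- function(model) {
  stop_if_invalid(model)
  p <- model$paths
  endo <- vars_by_role(model, "latent_endogenous")
  exo <- vars_by_role(model, c("latent_exogenous", "observed_exogenous"))
  sp <- structural_paths(model)
  loadings <- p[p$kind == "loading", , drop = FALSE]
  measurement <- sum(!loadings$fixed) + length(vars_by_role(model, "indicator"))

  # classify each exogenous variable by the outcomes it predicts
  targets <- purrr::map(exo, function(x) unique(sp$target[sp$source == x]))
  hits <- lengths(targets)
  common <- sum(hits >= 2) * 3L   # two paths + one variance
  specific <- purrr::map_chr(targets[hits == 1], 1)
  specific_counts <- table(factor(specific, levels = endo))
  unused <- sum(hits == 0)        # variance only (no structural role)

  loop_block <- sum(sp$source %in% endo & sp$target %in% endo) +
    length(endo) + sum(p$kind == "disturbance_covariance" & !p$fixed)
  err_cov <- sum(p$kind == "error_covariance" & !p$fixed)
  exog_cov <- sum(p$kind == "exogenous_covariance" & !p$fixed)

  out <- tibble::tibble(
    group = c("measurement", paste0(names(specific_counts), "_specific"),
              "common_predictors", "feedback_loop", "error_covariances",
              "exogenous_covariances", "unused_exogenous_variances"),
    count = c(measurement, as.integer(specific_counts) * 2L, common,
              loop_block, err_cov, exog_cov, unused)
  )
  out <- out[out$count > 0 | out$group %in%
               c("measurement", "feedback_loop", "error_covariances"), ]
  attr(out, "total") <- sum(out$count)
  out
}

#' Required sample size under the N:q rule
#'
#' @param q Total free-parameter count (a number, or the tibble returned by
#'   [count_free_parameters()]).
#' @param ratio Observations per free parameter; the conventional band is
#'   5 to 20 (a ratio outside it is allowed but flagged with a warning
#'   record in the output).
#' @param nonresponse Anticipated non-response proportion in `[0, 0.5)`;
#'   the base size is inflated by `1 + nonresponse` and rounded up.
#' @return A one-row tibble `q`, `ratio`, `nonresponse`, `base_n`,
#'   `final_n`, `warning`.
#' @export
required_sample_size <- function(q, ratio = 10, nonresponse = 0.05) {
  if (is.data.frame(q)) q <- q$total
  stopifnot(length(q) == 1, q > 0)
  if (nonresponse < 0 || nonresponse >= 0.5) {
    abort("`nonresponse` must be in [0, 0.5)")
  }
  warning_rec <- NA_character_
  if (ratio < 5 || ratio > 20) {
    warning_rec <- sprintf("N:q ratio %.1f outside the conventional 5-20 band", ratio)
  }
  base_n <- q * ratio
  tibble::tibble(
    q = q, ratio = ratio, nonresponse = nonresponse,
    base_n = base_n,
    final_n = ceiling(base_n * (1 + nonresponse)),
    warning = warning_rec
  )
}

#' Full identification report for a model
#'
#' Convenience wrapper running the order condition, rank condition,
#' instrument designation (when a loop is present), free-parameter count
#' and N:q sample-size planning in one call.
#'
#' @inheritParams designate_instruments
#' @param ratio,nonresponse Passed to [required_sample_size()].
#' @return A list with `order`, `rank`, `instruments`, `parameter_count`,
#'   `sample_size`, `identified`.
#' @export
identification_report <- function(model, ratio = 10, nonresponse = 0.05) {
  sm <- build_system_matrix(model)
  rk <- rank_condition(sm)
  pc <- count_free_parameters(model)
  list(
    order = order_condition(sm),
    rank = rk,
    instruments = if (length(model$loop)) designate_instruments(model) else NULL,
    parameter_count = pc,
    sample_size = required_sample_size(pc$total, ratio, nonresponse),
    identified = attr(rk, "model_identified")
  )
}
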