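#' Pure confirmatory measurement model of the five instruments
#'
#' All five constructs as correlated factors measured by their items, with
#' no structural part: the model evaluated before parceling and structural
#' estimation.
#'
#' @param error_covariances Include the declared within-construct error
#'   covariance pairs.
#' @return A [sem_model()].
#' @export
cfa_measurement_model <- function(error_covariances = FALSE) {
  meas <- measurement_block()
  lat <- unique(instrument_layout()$latent)
  latents <- tibble::tibble(name = lat, role = "latent_exogenous",
                            scale = NA_integer_, measures = NA_character_)
  prs <- utils::combn(lat, 2)
  paths <- dplyr::bind_rows(
    meas$paths,
    tibble::tibble(source = prs[1, ], target = prs[2, ],
                   kind = "exogenous_covariance", fixed = FALSE, value = NA_real_),
    if (error_covariances) {
      dplyr::mutate(error_covariance_pairs(), kind = "error_covariance",
                    fixed = FALSE, value = NA_real_)
    }
  )
  sem_model(dplyr::bind_rows(latents, meas$variables), paths)
}

parceled_constructs <- function() c("adhd", "depression", "insomnia")

#' Rebuild a study model on parceled indicators
#'
#' Replaces the item indicators of the parceled constructs (ADHD,
#' depression, insomnia) with their three parcel-score indicators, keeping
#' the remaining instruments at item level. Error covariances referencing
#' parceled-away items are dropped.
#'
#' @param form `"hypothesized"` or `"final"` (see [adhd_depression_model()]).
#' @return A [sem_model()] whose parceled indicators are named
#'   `<construct>_p1..p3`.
#' @export
parceled_model <- function(form = c("hypothesized", "final")) {
  form <- match.arg(form)
  base <- adhd_depression_model(form)
  pc <- parceled_constructs()
  v <- base$variables
  drop_items <- v$name[v$role == "indicator" & v$measures %in% pc]
  keep_v <- v[!(v$name %in% drop_items), ]
  parcel_v <- dplyr::bind_rows(purrr::map(pc, function(f) {
    tibble::tibble(name = paste0(f, "_p", 1:3), role = "indicator",
                   scale = NA_integer_, measures = f)
  }))
  p <- base$paths
  keep_p <- p[!(p$source %in% drop_items | p$target %in% drop_items), ]
  parcel_p <- dplyr::bind_rows(purrr::map(pc, function(f) {
    tibble::tibble(source = f, target = paste0(f, "_p", 1:3), kind = "loading",
                   fixed = c(TRUE, FALSE, FALSE), value = c(1, NA, NA))
  }))
  sem_model(dplyr::bind_rows(keep_v, parcel_v),
            dplyr::bind_rows(parcel_p, keep_p), base$loop)
}

#' Pipeline configuration
#'
#' @param input A [sim_config()] (data are generated), a data frame of
#'   item responses and covariates, or a path to a CSV file with the
#'   canonical column layout.
#' @param bootstrap Bootstrap replicates for the selected model (0 skips;
#'   the survey used 3500, the desk-scale default is 200).
#' @param seed Seed for estimation-side randomness (bootstrap).
#' @param cluster Optional clustering column name for the ICC check.
#' @param ratio,nonresponse N:q planning settings.
#' @param hypothesized_model Structural model whose identification is
#'   checked before estimation (default: the study's hypothesized
#'   non-recursive model).
#' @return A `semloop_pipeline_config` list.
#' @export
pipeline_config <- function(input = sim_config(), bootstrap = 200, seed = 1,
                            cluster = NULL, ratio = 10, nonresponse = 0.05,
                            hypothesized_model = NULL) {
  structure(
    list(input = input, bootstrap = bootstrap, seed = as.integer(seed),
         cluster = cluster, ratio = ratio, nonresponse = nonresponse,
         hypothesized_model = hypothesized_model),
    class = "semloop_pipeline_config"
  )
}

#' Run the full survey analysis workflow
#'
#' Executes the study's stages in order: load or simulate the response
#' table; score the five instruments and estimate screening prevalences;
#' run the assumption diagnostics (KMO, Bartlett, Mardia, Mahalanobis
#' outliers, common-method bias, optional ICC); listwise-delete incomplete
#' rows under the 5% rule; fit the confirmatory measurement model; parcel
#' the ADHD, depression and insomnia items; check identification of the
#' hypothesized non-recursive system (order condition, rank condition,
#' instruments, free-parameter count, N:q); fit the candidate structural
#' models on the parceled data; select among them by fit indices and BIC;
#' and decompose direct and indirect effects on the selected model, with
#' bootstrap intervals when requested. A failing stage aborts with its
#' name; an unidentified system stops before any structural estimation.
#'
#' @param config A [pipeline_config()].
#' @return A `semloop_run` with every stage's output and a timing log.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "semloop_pipeline_config"))
  run <- list(config = config)
  log <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = name, seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    out
  }

  data <- t_stage("load", {
    inp <- config$input
    if (inherits(inp, "semloop_sim_config")) {
      run$sim <- simulate_survey(inp)
      run$sim$data
    } else if (is.character(inp)) {
      tibble::as_tibble(utils::read.csv(inp))
    } else {
      tibble::as_tibble(inp)
    }
  })
  run$n_input <- nrow(data)

  run$scores <- t_stage("score", score_instruments(data))
  run$prevalence <- t_stage("prevalence", prevalence_report(run$scores))
  run$diagnostics <- t_stage("diagnostics",
                             run_diagnostics(data, cluster = config$cluster))
  data <- t_stage("listwise_deletion", {
    analysed <- setdiff(names(data), c("subject_id", "outlier"))
    listwise_delete(data, columns = analysed)
  })
  run$n_analysis <- nrow(data)

  run$cfa <- t_stage("cfa", {
    fit <- sem_fit(cfa_measurement_model(), data = data)
    list(fit = fit, indices = fit_indices(fit),
         modifications = modification_indices(fit))
  })

  parcel_data <- t_stage("parceling", {
    est <- run$cfa$fit$estimates
    sds <- sqrt(diag(implied_covariance(run$cfa$fit$ram, run$cfa$fit$theta,
                                        observed_only = FALSE)))
    cols <- list()
    assignments <- list()
    for (f in parceled_constructs()) {
      its <- with(run$cfa$fit$model$variables, name[role == "indicator" & measures == f])
      lam <- vapply(its, function(it) {
        lab <- paste0(f, "=~", it)
        if (lab %in% est$label) est$estimate[est$label == lab] else 1
      }, numeric(1))
      lam_std <- lam * sds[f] / sds[its]    # standardized loadings
      pr <- parcel_items(lam_std, 3, data = data)
      names(pr$scores) <- paste0(f, "_p", 1:3)
      cols[[f]] <- pr$scores
      assignments[[f]] <- dplyr::mutate(pr$assignment, construct = f)
    }
    run$parcels <- dplyr::bind_rows(assignments)
    dplyr::bind_cols(
      data[, !grepl(paste0("^(", paste(c("asrs", "phq", "isi"), collapse = "|"), ")_"),
                    names(data))],
      dplyr::bind_cols(cols)
    )
  })

  run$identification <- t_stage("identification", {
    hm <- config$hypothesized_model
    if (is.null(hm)) hm <- adhd_depression_model("hypothesized")
    rep <- identification_report(hm,
                                 ratio = config$ratio,
                                 nonresponse = config$nonresponse)
    if (!rep$identified) {
      bad <- rep$rank$equation[!rep$rank$identified]
      abort(paste0("structural system not identified for equation(s): ",
                   paste(bad, collapse = ", ")))
    }
    rep
  })

  run$fits <- t_stage("candidates", {
    list(
      hypothesized = sem_fit(parceled_model("hypothesized"), data = parcel_data,
                             se = "none"),
      significant_only = sem_fit(prune_model(parceled_model("final"),
                                             drop_error_cov = TRUE,
                                             drop_exog_cov = TRUE),
                                 data = parcel_data, se = "none"),
      with_error_covariances = sem_fit(prune_model(parceled_model("final"),
                                                   drop_exog_cov = TRUE),
                                       data = parcel_data, se = "none"),
      with_exogenous_covariances = sem_fit(parceled_model("final"),
                                           data = parcel_data)
    )
  })
  run$comparison <- t_stage("selection", compare_models(run$fits))
  selected_label <- attr(run$comparison, "selection")
  run$selected <- run$fits[[selected_label]]
  if (is.null(run$selected$vcov)) {
    run$selected <- t_stage("refit_selected",
                            sem_fit(run$selected$ram, data = parcel_data,
                                    start = run$selected$theta))
  }

  run$effects <- t_stage("effects", {
    eff <- effect_decomposition(run$selected)
    class(eff) <- c("semloop_effects", class(eff))
    eff
  })

  if (config$bootstrap > 0) {
    run$selected <- t_stage("bootstrap", {
      sem_bootstrap(run$selected, parcel_data,
                    replicates = config$bootstrap, seed = config$seed)
    })
    run$effects_ci <- t_stage("effects_ci", {
      draws <- run$selected$boot_draws
      ok <- stats::complete.cases(draws)
      eff_draws <- apply(draws[ok, , drop = FALSE], 1, function(th) {
        e <- effect_decomposition(run$selected$ram, theta = th)
        e$total[match(paste(run$effects$cause, run$effects$outcome),
                      paste(e$cause, e$outcome))]
      })
      qs <- apply(matrix(eff_draws, nrow = nrow(run$effects)), 1,
                  quantile, probs = c(0.025, 0.975), na.rm = TRUE)
      dplyr::mutate(run$effects, total_low = qs[1, ], total_high = qs[2, ])
    })
  }

  run$parcel_data <- parcel_data
  run$log <- dplyr::bind_rows(log)
  class(run) <- "semloop_run"
  run
}

prune_model <- function(model, drop_error_cov = FALSE, drop_exog_cov = FALSE) {
  keep <- rep(TRUE, nrow(model$paths))
  if (drop_error_cov) keep <- keep & model$paths$kind != "error_covariance"
  if (drop_exog_cov) keep <- keep & model$paths$kind != "exogenous_covariance"
  model$paths <- model$paths[keep, ]
  model
}

#' @export
print.semloop_run <- function(x, ...) {
  cat("<semloop_run> ", x$n_input, " subjects in, ", x$n_analysis,
      " analysed\n", sep = "")
  cat("  stages:", paste(x$log$stage, collapse = " -> "), "\n")
  cat("  selected model:", attr(x$comparison, "selection"), "\n")
  invisible(x)
}

#' Export a pipeline run as tables
#'
#' Collects the run's results into the study's table layouts: screening
#' prevalence with Wilson intervals, per-construct diagnostics, model
#' comparison, direct effects of the selected model, and the full
#' direct/indirect/total decomposition (with bootstrap interval columns
#' when available, marked unavailable otherwise). When `dir` is given the
#' tables are written as CSV plus a JSON manifest; re-running the same
#' configuration and seed reproduces the files byte for byte.
#'
#' @param run A [run_pipeline()] result.
#' @param dir Optional output directory.
#' @return A named list of tibbles (invisibly when writing).
#' @export
report_tables <- function(run, dir = NULL) {
  stopifnot(inherits(run, "semloop_run"))
  sel <- run$selected
  est <- tidy(sel, conf.int = TRUE)
  direct <- est[est$type == "structural", ]
  direct <- dplyr::mutate(direct, outcome = sub("~.*$", "", .data$term),
                          predictor = sub("^.*~", "", .data$term))
  eff <- run$effects
  if (!is.null(run$effects_ci)) {
    eff <- run$effects_ci
  } else {
    eff <- dplyr::mutate(eff, total_low = NA_real_, total_high = NA_real_)
  }
  tables <- list(
    prevalence = run$prevalence,
    diagnostics = run$diagnostics$per_construct,
    model_comparison = tibble::as_tibble(run$comparison),
    direct_effects = direct[, c("outcome", "predictor", "estimate", "std.error",
                                "conf.low", "conf.high")],
    effects = eff
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    manifest <- list(
      n_input = run$n_input, n_analysis = run$n_analysis,
      seed = run$config$seed,
      selected_model = attr(run$comparison, "selection"),
      stages = run$log$stage,
      version = as.character(utils::packageVersion("semloop"))
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(tables))
  }
  tables
}
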