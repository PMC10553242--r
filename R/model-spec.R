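#' Declare a structural equation model
#'
#' A `semloop_model` is a declarative description of a latent-variable model:
#' a roster of variables (latent endogenous/exogenous factors, their ordinal
#' indicators, and observed exogenous predictors) plus the free and fixed
#' paths among them. Feedback loops between latent endogenous variables are
#' declared through `loop`, which marks the members of the reciprocal cycle.
#'
#' Variance parameters are implicit: every indicator carries an error
#' variance, every exogenous variable (observed or latent) a variance, and
#' every latent endogenous variable a disturbance variance. Only loadings,
#' structural paths, and covariances are declared as paths.
#'
#' @param variables Data frame with columns `name`, `role` (one of
#'   `"latent_endogenous"`, `"latent_exogenous"`, `"indicator"`,
#'   `"observed_exogenous"`), `scale` (number of ordinal levels for
#'   indicators, `NA` for continuous), and `measures` (for indicators, the
#'   latent variable they load on).
#' @param paths Data frame with columns `source`, `target`, `kind` (one of
#'   `"loading"`, `"structural"`, `"exogenous_covariance"`,
#'   `"error_covariance"`, `"disturbance_covariance"`), `fixed` (logical)
#'   and `value` (the fixed value; `NA` for free parameters).
#' @param loop Character vector naming the latent endogenous variables in
#'   the feedback cycle; empty for recursive models.
#' @return An object of class `semloop_model`.
#' @seealso [validate_model()], [build_system_matrix()], [serialize_model()]
#' @export
sem_model <- function(variables, paths, loop = character(0)) {
  variables <- tibble::as_tibble(variables)
  paths <- tibble::as_tibble(paths)
  if (!all(c("name", "role") %in% names(variables))) {
    abort("`variables` needs columns `name` and `role`.")
  }
  if (!"scale" %in% names(variables)) variables$scale <- NA_integer_
  if (!"measures" %in% names(variables)) variables$measures <- NA_character_
  variables$scale <- as.integer(variables$scale)
  if (!all(c("source", "target", "kind") %in% names(paths))) {
    abort("`paths` needs columns `source`, `target` and `kind`.")
  }
  if (!"fixed" %in% names(paths)) paths$fixed <- FALSE
  if (!"value" %in% names(paths)) paths$value <- NA_real_
  structure(
    list(
      variables = variables[, c("name", "role", "scale", "measures")],
      paths = paths[, c("source", "target", "kind", "fixed", "value")],
      loop = as.character(loop)
    ),
    class = "semloop_model"
  )
}

variable_roles <- c(
  "latent_endogenous", "latent_exogenous", "indicator", "observed_exogenous"
)
path_kinds <- c(
  "loading", "structural", "exogenous_covariance", "error_covariance",
  "disturbance_covariance"
)

#' @export
print.semloop_model <- function(x, ...) {
  counts <- table(factor(x$variables$role, levels = variable_roles))
  cat("<semloop_model>\n")
  cat(sprintf(
    "  %d variables (%d latent endogenous, %d latent exogenous, %d indicators, %d observed exogenous)\n",
    nrow(x$variables), counts[["latent_endogenous"]],
    counts[["latent_exogenous"]], counts[["indicator"]],
    counts[["observed_exogenous"]]
  ))
  cat(sprintf("  %d declared paths, %d fixed\n", nrow(x$paths), sum(x$paths$fixed)))
  if (length(x$loop)) {
    cat("  feedback loop:", paste(x$loop, collapse = " <-> "), "\n")
  } else {
    cat("  recursive (no feedback loop)\n")
  }
  invisible(x)
}

vars_by_role <- function(model, role) {
  model$variables$name[model$variables$role %in% role]
}

structural_paths <- function(model) {
  model$paths[model$paths$kind == "structural", , drop = FALSE]
}

#' Validate a structural model declaration
#'
#' Checks every structural invariant of the declaration: unique names, legal
#' roles and path kinds, indicator assignment, one scale-setting loading
#' fixed to 1 per latent variable, no structural self-loops, no duplicate
#' paths, covariance kinds connecting the right roles, and loop membership
#' actually forming a cycle. Violations are returned as data, not raised.
#'
#' @param model A [sem_model()].
#' @return A tibble with columns `rule`, `where`, `message`; zero rows iff
#'   the model is valid.
#' @export
validate_model <- function(model) {
  v <- model$variables
  p <- model$paths
  bad <- list()
  note <- function(rule, where, message) {
    bad[[length(bad) + 1]] <<- tibble::tibble(
      rule = rule, where = where, message = message
    )
  }

  dup <- v$name[duplicated(v$name)]
  for (d in unique(dup)) note("unique-names", d, "variable name declared more than once")
  for (i in which(!v$role %in% variable_roles)) {
    note("known-role", v$name[i], paste0("unknown role '", v$role[i], "'"))
  }
  lat <- vars_by_role(model, c("latent_endogenous", "latent_exogenous"))
  for (i in which(v$role == "indicator")) {
    if (is.na(v$measures[i]) || !v$measures[i] %in% lat) {
      note("indicator-assignment", v$name[i], "indicator not assigned to a declared latent variable")
    }
    if (!is.na(v$scale[i]) && (v$scale[i] < 2)) {
      note("indicator-scale", v$name[i], "ordinal indicators need at least 2 levels")
    }
  }
  for (i in which(!p$kind %in% path_kinds)) {
    note("known-kind", paste(p$source[i], p$target[i], sep = "->"),
         paste0("unknown path kind '", p$kind[i], "'"))
  }
  known <- v$name
  for (i in seq_len(nrow(p))) {
    if (!p$source[i] %in% known || !p$target[i] %in% known) {
      note("declared-endpoints", paste(p$source[i], p$target[i], sep = "->"),
           "path endpoint is not a declared variable")
    }
  }
  key <- paste(p$source, p$target, p$kind)
  for (k in unique(key[duplicated(key)])) note("no-duplicate-paths", k, "duplicate (source, target, kind)")

  ind <- v$name[v$role == "indicator"]
  for (i in which(p$kind == "loading")) {
    if (!p$target[i] %in% ind) {
      note("loading-target", paste(p$source[i], p$target[i], sep = "->"),
           "loading target must be an indicator")
    }
  }
  for (i in which(p$kind == "structural")) {
    if (p$source[i] == p$target[i]) {
      note("no-self-loop", p$source[i], "structural self-loop is forbidden")
    }
    if (!p$target[i] %in% vars_by_role(model, "latent_endogenous")) {
      note("structural-target", paste(p$source[i], p$target[i], sep = "->"),
           "structural paths must point at a latent endogenous variable")
    }
  }
  for (i in which(p$kind == "error_covariance")) {
    if (!all(c(p$source[i], p$target[i]) %in% ind)) {
      note("error-covariance-roles", paste(p$source[i], p$target[i], sep = "~"),
           "error covariances connect indicators")
    }
  }
  exo <- vars_by_role(model, c("latent_exogenous", "observed_exogenous"))
  for (i in which(p$kind == "exogenous_covariance")) {
    if (!all(c(p$source[i], p$target[i]) %in% exo)) {
      note("exogenous-covariance-roles", paste(p$source[i], p$target[i], sep = "~"),
           "exogenous covariances connect exogenous variables")
    }
  }
  endo <- vars_by_role(model, "latent_endogenous")
  for (i in which(p$kind == "disturbance_covariance")) {
    if (!all(c(p$source[i], p$target[i]) %in% endo)) {
      note("disturbance-covariance-roles", paste(p$source[i], p$target[i], sep = "~"),
           "disturbance covariances connect latent endogenous variables")
    }
  }
  for (i in which(p$fixed & is.na(p$value))) {
    note("fixed-value", paste(p$source[i], p$target[i], sep = "->"),
         "fixed path needs a fixed value")
  }

  # exactly one scale-setting loading fixed to 1 per latent variable
  for (f in lat) {
    ld <- p[p$kind == "loading" & p$source == f, , drop = FALSE]
    nfix <- sum(ld$fixed & !is.na(ld$value) & ld$value == 1)
    if (nfix != 1) {
      note("scale-setting", f,
           sprintf("latent variable needs exactly one loading fixed to 1 (found %d)", nfix))
    }
  }

  if (length(model$loop)) {
    if (!all(model$loop %in% endo)) {
      note("loop-members", paste(model$loop, collapse = ","),
           "loop members must be latent endogenous variables")
    } else {
      sp <- structural_paths(model)
      in_loop <- sp$source %in% model$loop & sp$target %in% model$loop
      g <- sp[in_loop, , drop = FALSE]
      # every member must have an outgoing and an incoming loop edge
      ok <- all(model$loop %in% g$source) && all(model$loop %in% g$target)
      if (!ok) {
        note("loop-cycle", paste(model$loop, collapse = ","),
             "declared loop members do not form a structural cycle")
      }
    }
  }

  if (length(bad)) dplyr::bind_rows(bad) else {
    tibble::tibble(rule = character(), where = character(), message = character())
  }
}

stop_if_invalid <- function(model) {
  viol <- validate_model(model)
  if (nrow(viol)) {
    abort(paste0(
      "invalid model specification:\n",
      paste0("  [", viol$rule, "] ", viol$where, ": ", viol$message, collapse = "\n")
    ))
  }
  invisible(model)
}

#' Build the system matrix of the structural part
#'
#' The system matrix is the device used to check identification of
#' simultaneous (possibly non-recursive) equations: one row per latent
#' endogenous variable, one column per variable in the structural system
#' (exogenous predictors, latent exogenous factors, and the endogenous
#' variables themselves). An entry is 1 when the column variable has a
#' direct structural effect on the row variable, or is the row variable
#' itself; all other entries are 0 and mark excluded variables.
#'
#' @param model A valid [sem_model()] with at least one latent endogenous
#'   variable.
#' @return A binary matrix with endogenous row names and structural-system
#'   column names, of class `system_matrix`.
#' @export
build_system_matrix <- function(model) {
  stop_if_invalid(model)
  endo <- vars_by_role(model, "latent_endogenous")
  if (!length(endo)) abort("model has no latent endogenous variable")
  sp <- structural_paths(model)
  # structural-system columns in declaration order
  cols <- model$variables$name[
    model$variables$name %in% unique(c(sp$source, sp$target, endo))
  ]
  m <- matrix(0L, nrow = length(endo), ncol = length(cols),
              dimnames = list(endo, cols))
  for (i in seq_len(nrow(sp))) m[sp$target[i], sp$source[i]] <- 1L
  for (e in endo) m[e, e] <- 1L
  class(m) <- c("system_matrix", class(m))
  m
}

#' Serialize a model declaration to JSON
#'
#' @param model A [sem_model()].
#' @param pretty Pretty-print the JSON.
#' @return A JSON string with `variables`, `paths` and `loop` keys;
#'   [parse_model()] restores a structurally identical model.
#' @export
serialize_model <- function(model, pretty = TRUE) {
  jsonlite::toJSON(
    list(
      variables = model$variables,
      paths = model$paths,
      loop = model$loop
    ),
    dataframe = "rows", na = "null", null = "null",
    auto_unbox = FALSE, pretty = pretty, digits = NA
  )
}

#' Parse a model declaration from JSON
#'
#' @param text JSON text (or path to a JSON file) produced by
#'   [serialize_model()] or written by hand with the same keys.
#' @return A [sem_model()].
#' @export
parse_model <- function(text) {
  obj <- tryCatch(
    jsonlite::fromJSON(text, simplifyDataFrame = TRUE),
    error = function(e) abort(paste0("malformed model JSON: ", conditionMessage(e)))
  )
  for (key in c("variables", "paths")) {
    if (is.null(obj[[key]]) || !is.data.frame(obj[[key]]) || !nrow(obj[[key]])) {
      abort(paste0("model JSON: key '", key, "' is missing or empty"))
    }
  }
  v <- tibble::as_tibble(obj$variables)
  p <- tibble::as_tibble(obj$paths)
  for (col in c("name", "role")) {
    if (!col %in% names(v)) abort(paste0("model JSON: variables lack field '", col, "'"))
  }
  for (col in c("source", "target", "kind")) {
    if (!col %in% names(p)) abort(paste0("model JSON: paths lack field '", col, "'"))
  }
  badkind <- setdiff(unique(p$kind), path_kinds)
  if (length(badkind)) {
    abort(paste0("model JSON: unknown path kind '", badkind[1], "'"))
  }
  badrole <- setdiff(unique(v$role), variable_roles)
  if (length(badrole)) {
    abort(paste0("model JSON: unknown variable role '", badrole[1], "'"))
  }
  bad <- grep("^[A-Za-z0-9_]+$", v$name, invert = TRUE, value = TRUE)
  if (length(bad)) {
    abort(paste0("model JSON: identifier '", bad[1], "' outside [A-Za-z0-9_]"))
  }
  if (!"value" %in% names(p)) p$value <- NA_real_
  p$value <- as.numeric(p$value)
  loop <- if (is.null(obj$loop)) character(0) else as.character(unlist(obj$loop))
  sem_model(v, p, loop)
}

# ---------------------------------------------------------------------------
# Study fixtures: the ADHD <-> depression survey model
# ---------------------------------------------------------------------------

instrument_layout <- function() {
  tibble::tribble(
    ~latent,          ~prefix, ~n_items, ~scale,
    "depression",     "phq",   9L,       4L,
    "adhd",           "asrs",  6L,       5L,
    "piu",            "piuq",  9L,       5L,
    "insomnia",       "isi",   7L,       5L,
    "social_support", "osss",  3L,       5L
  )
}

covariate_roster <- function() {
  list(
    common = c(
      "year_of_study", "age", "sex", "cannabis_use", "chat_chewing",
      "current_alcohol_use", "head_trauma", "smoking", "alcohol_use",
      "physical_exercise", "academic_failure", "parental_psychiatric_illness",
      "residence", "chronic_disease"
    ),
    depression_only = c(
      "worry_academic", "stressful_life_event", "monthly_allowance",
      "marital_status", "partner", "sleeping_hours", "studying_hours",
      "family_economic_level", "department_type"
    ),
    adhd_only = c("mother_education", "father_education", "birth_order")
  )
}

error_covariance_pairs <- function() {
  tibble::tribble(
    ~source,  ~target,
    "phq_1",  "phq_2",
    "phq_3",  "phq_8",
    "asrs_1", "asrs_2",
    "isi_1",  "isi_2",
    "isi_6",  "isi_7",
    "piuq_1", "piuq_2",
    "piuq_4", "piuq_5"
  )
}

free_path <- function(source, target, kind) {
  tibble::tibble(source = source, target = target, kind = kind,
                 fixed = FALSE, value = NA_real_)
}

measurement_block <- function() {
  lay <- instrument_layout()
  vars <- list()
  paths <- list()
  for (i in seq_len(nrow(lay))) {
    items <- paste0(lay$prefix[i], "_", seq_len(lay$n_items[i]))
    scale <- rep(lay$scale[i], lay$n_items[i])
    if (lay$prefix[i] == "osss") scale[1] <- 4L  # OSSS item 1 has 4 anchors
    vars[[i]] <- tibble::tibble(
      name = items, role = "indicator", scale = scale, measures = lay$latent[i]
    )
    paths[[i]] <- tibble::tibble(
      source = lay$latent[i], target = items, kind = "loading",
      fixed = c(TRUE, rep(FALSE, length(items) - 1)),
      value = c(1, rep(NA_real_, length(items) - 1))
    )
  }
  list(variables = dplyr::bind_rows(vars), paths = dplyr::bind_rows(paths))
}

#' Study models for the ADHD--depression survey
#'
#' Builds the two structural models of the student mental-health survey
#' design this package reproduces. The `"hypothesized"` form carries the
#' full feedback loop between depression and ADHD (reciprocal structural
#' paths with correlated disturbances), 14 predictors common to both
#' outcomes, 12 depression-only predictors (9 observed plus the latent
#' problematic-internet-use, insomnia and social-support factors), 3
#' ADHD-only predictors (mother/father education, birth order), 34 ordinal
#' indicators across five instruments, and 7 within-construct error
#' covariances: 147 free parameters in all. The `"final"` form is the
#' pruned model retained after estimation: the ADHD-to-depression path and
#' all non-significant predictors are dropped, and covariances among the
#' remaining exogenous predictors are freed.
#'
#' @param form `"hypothesized"` or `"final"`.
#' @return A [sem_model()].
#' @export
adhd_depression_model <- function(form = c("hypothesized", "final")) {
  form <- match.arg(form)
  meas <- measurement_block()
  cov_roster <- covariate_roster()

  latents <- tibble::tibble(
    name = c("depression", "adhd", "piu", "insomnia", "social_support"),
    role = c("latent_endogenous", "latent_endogenous", rep("latent_exogenous", 3)),
    scale = NA_integer_, measures = NA_character_
  )

  if (form == "hypothesized") {
    covs <- c(cov_roster$common, cov_roster$depression_only, cov_roster$adhd_only)
    observed <- tibble::tibble(
      name = covs, role = "observed_exogenous",
      scale = NA_integer_, measures = NA_character_
    )
    dep_sources <- c(cov_roster$common, cov_roster$depression_only,
                     "piu", "insomnia", "social_support", "adhd")
    adhd_sources <- c(cov_roster$common, cov_roster$adhd_only, "depression")
    paths <- dplyr::bind_rows(
      meas$paths,
      free_path(dep_sources, "depression", "structural"),
      free_path(adhd_sources, "adhd", "structural"),
      free_path("depression", "adhd", "disturbance_covariance"),
      dplyr::mutate(error_covariance_pairs(), kind = "error_covariance",
                    fixed = FALSE, value = NA_real_)
    )
    loop <- c("depression", "adhd")
  } else {
    covs <- c(
      "chronic_disease", "worry_academic", "stressful_life_event",
      "alcohol_use", "studying_hours", "sleeping_hours",
      "year_of_study", "chat_chewing", "mother_education", "birth_order"
    )
    observed <- tibble::tibble(
      name = covs, role = "observed_exogenous",
      scale = NA_integer_, measures = NA_character_
    )
    dep_sources <- c("chronic_disease", "worry_academic", "stressful_life_event",
                     "alcohol_use", "studying_hours", "sleeping_hours",
                     "piu", "social_support", "insomnia")
    adhd_sources <- c("year_of_study", "mother_education", "birth_order",
                      "chat_chewing", "depression")
    exog_cov <- tibble::tribble(
      ~source,           ~target,
      "insomnia",        "sleeping_hours",
      "mother_education", "birth_order",
      "sleeping_hours",  "studying_hours",
      "piu",             "insomnia",
      "piu",             "social_support",
      "insomnia",        "social_support"
    )
    paths <- dplyr::bind_rows(
      meas$paths,
      free_path(dep_sources, "depression", "structural"),
      free_path(adhd_sources, "adhd", "structural"),
      free_path("depression", "adhd", "disturbance_covariance"),
      dplyr::mutate(exog_cov, kind = "exogenous_covariance",
                    fixed = FALSE, value = NA_real_),
      dplyr::mutate(error_covariance_pairs(), kind = "error_covariance",
                    fixed = FALSE, value = NA_real_)
    )
    loop <- character(0)
  }

  sem_model(dplyr::bind_rows(latents, observed, meas$variables), paths, loop)
}
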