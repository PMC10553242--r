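#' RAM parameterization of a structural model
#'
#' Maps a declarative [sem_model()] onto the reticular-action-model (RAM)
#' matrices: one asymmetric matrix `A` holding every directed path (factor
#' loadings and structural coefficients), one symmetric matrix `S` holding
#' every variance and covariance (exogenous variances, disturbance
#' variances/covariances, indicator error variances/covariances), and a
#' filter selecting the observed nodes. The implied covariance of the
#' observed variables is `F (I-A)^-1 S (I-A)^-T F'`. Observed exogenous
#' predictors enter as observed nodes with free variances, so measurement
#' and structural blocks live in a single matrix pair.
#'
#' Free parameters are labelled `lhs=~rhs` (loadings), `lhs~rhs`
#' (regressions, target on the left) and `a~~b` (variances/covariances).
#'
#' @param model A valid [sem_model()].
#' @param check_identification Refuse models whose structural system fails
#'   the rank condition.
#' @return An object of class `semloop_ram`: node roster, fixed-value
#'   matrices `A` and `S`, the observed-node filter, and a `free` tibble
#'   mapping each free parameter label to its matrix cell.
#' @export
to_ram <- function(model, check_identification = TRUE) {
  stop_if_invalid(model)
  v <- model$variables
  endo <- vars_by_role(model, "latent_endogenous")
  if (check_identification && length(endo) > 1) {
    rk <- rank_condition(build_system_matrix(model))
    if (!attr(rk, "model_identified")) {
      bad <- rk$equation[!rk$identified]
      abort(paste0("model is not identified: rank condition fails for equation(s) ",
                   paste(bad, collapse = ", ")))
    }
  }
  obs <- v$name[v$role %in% c("indicator", "observed_exogenous")]
  latent <- v$name[v$role %in% c("latent_endogenous", "latent_exogenous")]
  nodes <- c(obs, latent)
  k <- length(nodes)
  A <- matrix(0, k, k, dimnames = list(nodes, nodes))
  S <- matrix(0, k, k, dimnames = list(nodes, nodes))

  free <- list()
  add_free <- function(label, matrix, row, col, type) {
    free[[length(free) + 1]] <<- tibble::tibble(
      label = label, matrix = matrix, row = row, col = col, type = type
    )
  }

  p <- model$paths
  for (i in seq_len(nrow(p))) {
    src <- p$source[i]; tgt <- p$target[i]
    if (p$kind[i] %in% c("loading", "structural")) {
      if (p$fixed[i]) {
        A[tgt, src] <- p$value[i]
      } else {
        lab <- if (p$kind[i] == "loading") paste0(src, "=~", tgt) else paste0(tgt, "~", src)
        add_free(lab, "A", tgt, src, p$kind[i])
      }
    } else {
      if (p$fixed[i]) {
        S[src, tgt] <- S[tgt, src] <- p$value[i]
      } else {
        add_free(paste0(src, "~~", tgt), "S", src, tgt, p$kind[i])
      }
    }
  }
  # implicit variances: indicator errors, exogenous variances, disturbances
  for (x in v$name[v$role == "indicator"]) {
    add_free(paste0(x, "~~", x), "S", x, x, "error_variance")
  }
  for (x in v$name[v$role == "observed_exogenous"]) {
    add_free(paste0(x, "~~", x), "S", x, x, "exogenous_variance")
  }
  for (x in v$name[v$role == "latent_exogenous"]) {
    add_free(paste0(x, "~~", x), "S", x, x, "exogenous_variance")
  }
  for (x in endo) {
    add_free(paste0(x, "~~", x), "S", x, x, "disturbance_variance")
  }

  structure(
    list(
      model = model, nodes = nodes, obs = obs, latent = latent,
      endo = endo, A = A, S = S, free = dplyr::bind_rows(free)
    ),
    class = "semloop_ram"
  )
}

#' @export
print.semloop_ram <- function(x, ...) {
  cat("<semloop_ram> ", length(x$nodes), " nodes (", length(x$obs),
      " observed), ", nrow(x$free), " free parameters\n", sep = "")
  invisible(x)
}

#' Fill RAM matrices with parameter values
#'
#' @param ram A [to_ram()] object.
#' @param theta Numeric vector of free-parameter values, in `ram$free`
#'   order (or a named vector matched by label).
#' @return List with filled `A` and `S` matrices.
#' @export
ram_fill <- function(ram, theta) {
  fr <- ram$free
  if (!is.null(names(theta))) {
    idx <- match(fr$label, names(theta))
    if (anyNA(idx)) {
      abort(paste0("no value supplied for parameter ", fr$label[which(is.na(idx))[1]]))
    }
    theta <- theta[idx]
  }
  stopifnot(length(theta) == nrow(fr))
  A <- ram$A; S <- ram$S
  ia <- fr$matrix == "A"
  A[cbind(fr$row[ia], fr$col[ia])] <- theta[ia]
  S[cbind(fr$row[!ia], fr$col[!ia])] <- theta[!ia]
  S[cbind(fr$col[!ia], fr$row[!ia])] <- theta[!ia]
  list(A = A, S = S)
}

#' Model-implied covariance matrix
#'
#' Computes `F (I-A)^-1 S (I-A)^-T F'`, the covariance structure the RAM
#' matrices imply for the observed variables.
#'
#' @param ram A [to_ram()] object.
#' @param theta Free-parameter values (see [ram_fill()]).
#' @param observed_only Return only the observed block (default); otherwise
#'   the covariance of all nodes.
#' @return A symmetric matrix with variable dimnames.
#' @export
implied_covariance <- function(ram, theta, observed_only = TRUE) {
  m <- ram_fill(ram, theta)
  k <- length(ram$nodes)
  IA <- diag(k) - m$A
  E <- tryCatch(solve(IA), error = function(e) {
    abort(paste0("(I - A) is singular: the structural loop is unstable ",
                 "(stability index ", format(stability_index(m$A, ram$endo), digits = 3), ")"))
  })
  full <- E %*% m$S %*% t(E)
  dimnames(full) <- list(ram$nodes, ram$nodes)
  if (observed_only) full[ram$obs, ram$obs, drop = FALSE] else full
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F_ML = log det(Sigma) + tr(S Sigma^-1) - log det(S) - p`, the normal-
#' theory discrepancy between a sample covariance `S` and a model-implied
#' covariance `Sigma`. Nonnegative, and zero exactly when the two agree;
#' `(n - 1) * F_ML` is the model chi-square.
#'
#' @param S Sample covariance matrix (positive definite).
#' @param Sigma Implied covariance matrix (positive definite, same order).
#' @return The scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  if (!isTRUE(all.equal(dim(S), dim(Sigma)))) {
    abort("S and Sigma must have the same order")
  }
  cS <- tryCatch(chol(S), error = function(e) abort("S is not positive definite"))
  cT <- tryCatch(chol(Sigma), error = function(e) abort("Sigma is not positive definite"))
  ld_S <- 2 * sum(log(diag(cS)))
  ld_T <- 2 * sum(log(diag(cT)))
  ld_T + sum(diag(chol2inv(cT) %*% S)) - ld_S - p
}

#' Eigenvalue stability index of the structural loop
#'
#' The largest eigenvalue modulus of the endogenous-on-endogenous
#' coefficient block. The reduced form `(I - B)^-1` exists and the feedback
#' loop converges exactly when the index is below 1.
#'
#' @param x A fitted model ([sem_fit()]), a [to_ram()] object with `theta`,
#'   a filled `A` matrix, or the endogenous coefficient block itself.
#' @param endo Names (or indices) of the endogenous rows/columns when `x`
#'   is a full `A` matrix.
#' @param theta Free-parameter values when `x` is a `semloop_ram`.
#' @return The largest eigenvalue modulus (0 for loop-free systems).
#' @export
stability_index <- function(x, endo = NULL, theta = NULL) {
  if (inherits(x, "semloop_fit")) {
    return(stability_index(ram_fill(x$ram, x$theta)$A, x$ram$endo))
  }
  if (inherits(x, "semloop_ram")) {
    if (is.null(theta)) abort("supply `theta` with a semloop_ram")
    return(stability_index(ram_fill(x, theta)$A, x$endo))
  }
  B <- if (is.null(endo)) x else x[endo, endo, drop = FALSE]
  if (!nrow(B)) return(0)
  max(Mod(eigen(B, only.values = TRUE)$values))
}

#' Direct, indirect and total effect decomposition
#'
#' For a stable system, the total-effect matrix over all nodes is
#' `(I - A)^-1 - I`; restricted to the structural nodes (latent variables
#' and observed exogenous predictors), its entries decompose into the
#' direct effects (the `A` entries) plus all loop-aware indirect paths.
#'
#' @param x A fitted model ([sem_fit()]) or a [to_ram()] object.
#' @param theta Free-parameter values when `x` is a `semloop_ram`.
#' @param outcomes Restrict to these outcome variables (default: the
#'   latent endogenous variables).
#' @return A tibble `cause`, `outcome`, `direct`, `indirect`, `total`,
#'   one row per (cause, outcome) pair with any nonzero effect.
#' @export
effect_decomposition <- function(x, theta = NULL, outcomes = NULL) {
  if (inherits(x, "semloop_fit")) {
    ram <- x$ram; theta <- x$theta
  } else {
    ram <- x
    if (is.null(theta)) abort("supply `theta` with a semloop_ram")
  }
  m <- ram_fill(ram, theta)
  si <- stability_index(m$A, ram$endo)
  if (si >= 1) {
    abort(paste0("structural system is unstable (stability index ",
                 format(si, digits = 3), " >= 1); effects do not converge"))
  }
  k <- length(ram$nodes)
  total_all <- solve(diag(k) - m$A) - diag(k)
  structural <- c(ram$latent,
                  vars_by_role(ram$model, "observed_exogenous"))
  if (is.null(outcomes)) outcomes <- ram$endo
  grid <- expand.grid(cause = setdiff(structural, NULL),
                      outcome = outcomes, stringsAsFactors = FALSE)
  grid <- grid[grid$cause != grid$outcome, ]
  out <- tibble::tibble(
    cause = grid$cause,
    outcome = grid$outcome,
    direct = m$A[cbind(grid$outcome, grid$cause)],
    total = total_all[cbind(grid$outcome, grid$cause)]
  )
  out$indirect <- out$total - out$direct
  out <- out[, c("cause", "outcome", "direct", "indirect", "total")]
  out[abs(out$total) > 1e-12 | abs(out$direct) > 1e-12, ]
}
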