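# small reusable model builders and independent oracles

one_factor_model <- function(k = 3, name = "f1", items = paste0("x", seq_len(k))) {
  var_names <- c(name, items)
  var_measures <- c(NA, rep(name, k))
  vars <- tibble::tibble(
    name = var_names,
    role = c("latent_exogenous", rep("indicator", k)),
    scale = NA_integer_,
    measures = var_measures
  )
  paths <- tibble::tibble(
    source = name, target = items, kind = "loading",
    fixed = c(TRUE, rep(FALSE, k - 1)), value = c(1, rep(NA_real_, k - 1))
  )
  sem_model(vars, paths)
}

two_factor_model <- function() {
  vars <- tibble::tibble(
    name = c("f1", "f2", paste0("x", 1:3), paste0("y", 1:3)),
    role = c("latent_exogenous", "latent_endogenous", rep("indicator", 6)),
    scale = NA_integer_,
    measures = c(NA, NA, rep("f1", 3), rep("f2", 3))
  )
  paths <- dplyr::bind_rows(
    tibble::tibble(source = "f1", target = paste0("x", 1:3), kind = "loading",
                   fixed = c(TRUE, FALSE, FALSE), value = c(1, NA, NA)),
    tibble::tibble(source = "f2", target = paste0("y", 1:3), kind = "loading",
                   fixed = c(TRUE, FALSE, FALSE), value = c(1, NA, NA)),
    tibble::tibble(source = "f1", target = "f2", kind = "structural",
                   fixed = FALSE, value = NA_real_)
  )
  sem_model(vars, paths)
}

two_factor_truth <- function() {
  ram <- to_ram(two_factor_model())
  stats::setNames(c(0.8, 0.9, 0.7, 1.1, 0.5, rep(0.3, 6), 1.0, 0.4),
                  ram$free$label)
}

# two latent endogenous variables in a feedback loop, one instrument each
loop_toy_model <- function() {
  vars <- tibble::tibble(
    name = c("e1", "e2", "z1", "z2",
             paste0("a", 1:3), paste0("b", 1:3)),
    role = c("latent_endogenous", "latent_endogenous",
             "observed_exogenous", "observed_exogenous", rep("indicator", 6)),
    scale = NA_integer_,
    measures = c(NA, NA, NA, NA, rep("e1", 3), rep("e2", 3))
  )
  paths <- dplyr::bind_rows(
    tibble::tibble(source = "e1", target = paste0("a", 1:3), kind = "loading",
                   fixed = c(TRUE, FALSE, FALSE), value = c(1, NA, NA)),
    tibble::tibble(source = "e2", target = paste0("b", 1:3), kind = "loading",
                   fixed = c(TRUE, FALSE, FALSE), value = c(1, NA, NA)),
    tibble::tibble(source = c("z1", "z2", "e1", "e2"),
                   target = c("e1", "e2", "e2", "e1"),
                   kind = "structural", fixed = FALSE, value = NA_real_),
    tibble::tibble(source = "e1", target = "e2", kind = "disturbance_covariance",
                   fixed = FALSE, value = NA_real_)
  )
  sem_model(vars, paths, loop = c("e1", "e2"))
}

loop_toy_truth <- function(b12 = 0.3, b21 = 0.25) {
  ram <- to_ram(loop_toy_model())
  th <- c(
    "e1=~a2" = 0.8, "e1=~a3" = 0.9, "e2=~b2" = 0.7, "e2=~b3" = 1.1,
    "e1~z1" = 0.6, "e2~z2" = 0.5, "e2~e1" = b12, "e1~e2" = b21,
    "e1~~e2" = 0.05,
    "a1~~a1" = 0.3, "a2~~a2" = 0.3, "a3~~a3" = 0.3,
    "b1~~b1" = 0.3, "b2~~b2" = 0.3, "b3~~b3" = 0.3,
    "z1~~z1" = 1, "z2~~z2" = 1,
    "e1~~e1" = 0.5, "e2~~e2" = 0.5
  )
  th[ram$free$label]
}

random_valid_model <- function(n_latent = 2, n_items = 3) {
  lat <- paste0("g", seq_len(n_latent))
  vars <- list(tibble::tibble(name = lat, role = "latent_exogenous",
                              scale = NA_integer_, measures = NA_character_))
  paths <- list()
  for (i in seq_len(n_latent)) {
    items <- paste0(lat[i], "_i", seq_len(n_items))
    vars[[i + 1]] <- tibble::tibble(name = items, role = "indicator",
                                    scale = sample(4:5, n_items, TRUE),
                                    measures = lat[i])
    paths[[i]] <- tibble::tibble(
      source = lat[i], target = items, kind = "loading",
      fixed = c(TRUE, rep(FALSE, n_items - 1)),
      value = c(1, rep(NA_real_, n_items - 1))
    )
  }
  if (n_latent > 1 && stats::runif(1) < 0.7) {
    prs <- utils::combn(lat, 2)
    j <- sample(ncol(prs), 1)
    paths[[length(paths) + 1]] <- tibble::tibble(
      source = prs[1, j], target = prs[2, j], kind = "exogenous_covariance",
      fixed = FALSE, value = NA_real_
    )
  }
  sem_model(dplyr::bind_rows(vars), dplyr::bind_rows(paths))
}

random_system_matrix <- function(n_eq, n_ex) {
  cols <- c(paste0("x", seq_len(n_ex)), paste0("y", seq_len(n_eq)))
  m <- matrix(rbinom(n_eq * length(cols), 1, 0.5), n_eq,
              dimnames = list(paste0("y", seq_len(n_eq)), cols))
  for (i in seq_len(n_eq)) m[i, paste0("y", i)] <- 1L
  class(m) <- c("system_matrix", class(m))
  m
}

# independent brute-force oracles -------------------------------------------

kmo_brute <- function(R) {
  p <- ncol(R)
  Ri <- solve(R)
  num <- 0; den_q <- 0
  Q <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    if (i != j) Q[i, j] <- -Ri[i, j] / sqrt(Ri[i, i] * Ri[j, j])
  }
  r2 <- q2 <- 0
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    r2 <- r2 + R[i, j]^2
    q2 <- q2 + Q[i, j]^2
  }
  r2 / (r2 + q2)
}

mardia_brute <- function(X) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  Si <- solve(S)
  b1 <- 0
  for (i in 1:n) for (j in 1:n) b1 <- b1 + (Xc[i, ] %*% Si %*% Xc[j, ])^3
  b2 <- 0
  for (i in 1:n) b2 <- b2 + (Xc[i, ] %*% Si %*% Xc[i, ])^2
  c(b1p = b1 / n^2, b2p = b2 / n)
}

# total effects by explicit path enumeration over a DAG adjacency matrix
# (A[child, parent] convention); entry [i, j] sums edge products over all
# directed paths j -> i
path_enumeration_total <- function(A) {
  k <- nrow(A)
  memo <- vector("list", k)
  enumerate <- function(from) {
    if (!is.null(memo[[from]])) return(memo[[from]])
    res <- numeric(k)
    children <- which(A[, from] != 0)
    for (ch in children) {
      res[ch] <- res[ch] + A[ch, from]
      res <- res + A[ch, from] * enumerate(ch)
    }
    memo[[from]] <<- res
    res
  }
  total <- matrix(0, k, k, dimnames = dimnames(A))
  for (j in 1:k) total[, j] <- enumerate(j)
  total
}
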