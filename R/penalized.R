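#' Penalty specification for partially penalized fits
#'
#' Describes the penalty applied to the treatment-covariate interaction
#' coefficients only; study intercepts, main effects and the treatment
#' effect are never penalized.
#'
#' @param type \code{"L1"} (lasso), \code{"L2"} (ridge) or
#'   \code{"adaptive"} (weighted L1).
#' @param lambda penalty weight, \eqn{\lambda \ge 0}.
#' @param weights positive per-interaction weights \eqn{\hat w_m}
#'   (adaptive type only; default all 1).
#' @param exponent power \eqn{l} in \eqn{\hat w_m = 1/|\hat\gamma_m|^l}
#'   when weights are derived from a pilot fit (default 1).
#' @return A list of class \code{penalty_spec}.
#' @export
penalty_spec <- function(type = c("L1", "L2", "adaptive"), lambda,
                         weights = NULL, exponent = 1) {
  type <- match.arg(type)
  stopifnot(length(lambda) == 1, lambda >= 0)
  if (!is.null(weights)) stopifnot(all(weights > 0))
  structure(list(type = type, lambda = lambda, weights = weights,
                 exponent = exponent), class = "penalty_spec")
}

#' Log-equispaced grid of penalty values
#'
#' @param n grid size (default 61).
#' @param lo,hi inclusive endpoints (defaults 0.001 and 1000).
#' @return Numeric vector of \code{n} log-equispaced values.
#' @export
lambda_grid <- function(n = 61, lo = 0.001, hi = 1000) {
  stopifnot(n >= 2, lo > 0, lo < hi)
  exp(seq(log(lo), log(hi), length.out = n))
}

# interaction-penalty weights implied by a penalty_spec, given q
# penalized coordinates
penalty_weights <- function(penalty, q) {
  switch(penalty$type,
         L1 = rep(1, q),
         L2 = rep(1, q),
         adaptive = {
           w <- penalty$weights
           if (is.null(w)) w <- rep(1, q)
           stopifnot(length(w) == q)
           w
         })
}

#' Evaluate the partially penalized objective
#'
#' For a continuous outcome the objective is
#' \eqn{(1/2N)\sum_i (y_i - \eta_i)^2 + \lambda \sum_m pen(\gamma_m)};
#' for a binary outcome it is the scaled negative Bernoulli
#' log-likelihood
#' \eqn{-(1/N)\sum_i [y_i \eta_i - \log(1 + e^{\eta_i})]
#' + \lambda \sum_m pen(\gamma_m)}, with
#' \eqn{pen(\gamma) = |\gamma|} (L1), \eqn{\gamma^2} (L2), or
#' \eqn{\hat w_m |\gamma_m|} (adaptive).  Only the interaction block of
#' the coefficient vector is penalized.
#'
#' @param coefs coefficient vector in the column order of
#'   \code{design$A}.
#' @param design an \code{ipd_design} from [build_design()].
#' @param penalty a [penalty_spec()].
#' @return The objective value (a scalar).
#' @export
penalized_objective <- function(coefs, design, penalty) {
  stopifnot(length(coefs) == ncol(design$A))
  N <- length(design$y)
  eta <- drop(design$A %*% coefs)
  loss <- if (design$outcome_type == "continuous")
    sum((design$y - eta)^2) / (2 * N)
  else
    -sum(design$y * eta - log1p(exp(eta))) / N
  gam <- coefs[design$idx_int]
  w <- penalty_weights(penalty, length(gam))
  pen <- switch(penalty$type,
                L1 = sum(abs(gam)),
                L2 = sum(gam^2),
                adaptive = sum(w * abs(gam)))
  loss + penalty$lambda * pen
}

# Weighted-least-squares partial penalty solver in covariance form.
# Minimizes (1/2N) sum obs_w (z - A theta)^2 + lambda * pen(gamma).
# L2 solves the normal equations directly; L1/adaptive run coordinate
# descent with soft thresholding on the penalized coordinates.
# Returns list(theta, iters, converged).
pls_wls <- function(A, z, obs_w, idx_pen, type, lambda, pen_w,
                    theta0 = NULL, tol = 1e-10, max_sweeps = 1e5) {
  N <- length(z)
  q <- ncol(A)
  Aw <- A * obs_w
  G <- crossprod(Aw, A) / N
  c_vec <- drop(crossprod(Aw, z)) / N
  if (any(diag(G) <= 0))
    stop("design column with zero (weighted) variance; cannot fit")
  if (type == "L2") {
    D <- numeric(q); D[idx_pen] <- 1
    theta <- solve(G + 2 * lambda * diag(D, q), c_vec)
    return(list(theta = drop(theta), iters = 1L, converged = TRUE))
  }
  theta <- if (is.null(theta0)) numeric(q) else theta0
  lw <- numeric(q)
  lw[idx_pen] <- lambda * pen_w
  gt <- drop(G %*% theta)
  for (sweep in seq_len(max_sweeps)) {
    d_max <- 0
    for (k in seq_len(q)) {
      r_k <- c_vec[k] - gt[k] + G[k, k] * theta[k]
      new_k <- if (lw[k] > 0)
        sign(r_k) * max(abs(r_k) - lw[k], 0) / G[k, k]
      else r_k / G[k, k]
      d <- new_k - theta[k]
      if (d != 0) {
        theta[k] <- new_k
        gt <- gt + G[, k] * d
        d_max <- max(d_max, abs(d))
      }
    }
    # converge on the largest coefficient update of the sweep: near the
    # optimum the objective stalls long before the coefficients settle
    if (d_max <= tol * max(1, max(abs(theta))))
      return(list(theta = theta, iters = sweep, converged = TRUE))
  }
  list(theta = theta, iters = max_sweeps, converged = FALSE)
}

# Full solver for one lambda on an ipd_design; IRLS wraps the weighted
# least-squares solver for binary outcomes.
pls_solve <- function(design, type, lambda, pen_w, theta0 = NULL,
                      tol = 1e-10, max_irls = 200) {
  idx_pen <- design$idx_int
  if (design$outcome_type == "continuous") {
    res <- pls_wls(design$A, design$y, rep(1, length(design$y)),
                   idx_pen, type, lambda, pen_w, theta0, tol = tol)
    if (!res$converged)
      stop("coordinate descent failed to converge (", res$iters,
           " sweeps)")
    return(res$theta)
  }
  theta <- if (is.null(theta0)) numeric(ncol(design$A)) else theta0
  for (it in seq_len(max_irls)) {
    eta <- drop(design$A %*% theta)
    p_i <- plogis(eta)
    w_i <- pmax(p_i * (1 - p_i), 1e-5)
    z_i <- eta + (design$y - p_i) / w_i
    old <- theta
    theta <- pls_wls(design$A, z_i, w_i, idx_pen, type, lambda, pen_w,
                     theta0 = theta, tol = tol)$theta
    if (max(abs(theta - old)) <= 1e-9 * max(1, max(abs(theta))))
      return(theta)
  }
  stop("IRLS failed to converge after ", max_irls,
       " iterations (last step size ", signif(max(abs(theta - old)), 3),
       ")")
}

# Closed-form partial ridge for continuous outcomes:
# (A'A + 2 N lambda D)^{-1} A'y with D = 1 on interaction coordinates.
# Used directly by pls_wls (in covariance form) and as an independent
# identity in tests.
partial_ridge_closed_form <- function(design, lambda) {
  stopifnot(design$outcome_type == "continuous")
  q <- ncol(design$A)
  D <- numeric(q); D[design$idx_int] <- 1
  N <- length(design$y)
  drop(solve(crossprod(design$A) + 2 * N * lambda * diag(D, q),
             crossprod(design$A, design$y)))
}

# Karush-Kuhn-Tucker residual of a solution: max absolute violation of
# the stationarity conditions (exact-zero L1 coordinates use the
# subgradient condition).  Internal; exercised by the test suite.
kkt_violation <- function(theta, design, penalty) {
  N <- length(design$y)
  eta <- drop(design$A %*% theta)
  resid <- if (design$outcome_type == "continuous") design$y - eta
           else design$y - plogis(eta)
  g <- -drop(crossprod(design$A, resid)) / N  # gradient of the loss
  q <- ncol(design$A)
  w <- penalty_weights(penalty, length(design$idx_int))
  viol <- abs(g)
  for (k in seq_along(design$idx_int)) {
    j <- design$idx_int[k]
    viol[j] <- switch(penalty$type,
      L2 = abs(g[j] + 2 * penalty$lambda * theta[j]),
      {
        lw <- penalty$lambda * w[k]
        if (theta[j] != 0) abs(g[j] + lw * sign(theta[j]))
        else max(abs(g[j]) - lw, 0)
      })
  }
  max(viol)
}

#' Fit a partially penalized model at a fixed penalty
#'
#' Common-effects model (fixed study intercepts, main effects and
#' treatment effect) in which only the treatment-covariate interaction
#' coefficients are penalized.  Continuous outcomes: L1/adaptive
#' penalties are solved by cyclic coordinate descent with soft
#' thresholding on the interaction coordinates; the L2 penalty by the
#' closed-form partially penalized normal equations.  Binary outcomes
#' wrap the same solvers in iteratively reweighted least squares.  L1
#' and adaptive fits can return exact zeros; L2 shrinks without
#' selecting.  No analytic standard errors are produced — use
#' [bootstrap_se()].
#'
#' @param dataset a standardized [ipd_data].
#' @param penalty a [penalty_spec()].
#' @param interaction_subset candidate interaction indices (default all).
#' @param method optional label; defaults to the penalty type.
#' @return An \code{ipd_fit} with \code{lambda_selected = penalty$lambda}.
#' @export
fit_penalized <- function(dataset, penalty, interaction_subset = NULL,
                          method = NULL) {
  stopifnot(inherits(dataset, "ipd_data"), inherits(penalty, "penalty_spec"))
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  design <- build_design(dataset, interaction_subset)
  pen_w <- penalty_weights(penalty, length(design$idx_int))
  theta <- pls_solve(design, penalty$type, penalty$lambda, pen_w)
  pls_as_fit(theta, design, dataset, penalty,
             method %||% switch(penalty$type, L1 = "lasso", L2 = "ridge",
                                adaptive = "adaptive-lasso"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pls_as_fit <- function(theta, design, dataset, penalty, method, ...) {
  cn <- dataset$covariate_meta$name
  gamma_hat <- setNames(rep(0, design$p), cn)
  gamma_hat[design$interaction_subset] <- theta[design$idx_int]
  eta <- drop(design$A %*% theta)
  new_ipd_fit(
    method = method,
    delta_hat = theta[design$idx_treat],
    beta_hat = setNames(theta[design$idx_main], cn),
    gamma_hat = gamma_hat,
    intercepts = setNames(theta[design$idx_study],
                          paste0(".s", seq_len(design$n_studies))),
    interaction_subset = design$interaction_subset,
    scaling = dataset$scaling,
    outcome_type = dataset$outcome_type,
    sigma_hat = if (design$outcome_type == "continuous")
      sqrt(mean((design$y - eta)^2)) else NULL,
    lambda_selected = penalty$lambda,
    penalty_type = penalty$type,
    ...)
}

# Fold assignment: random near-equal folds over patients, optionally
# drawn within study so every fold contains every study.
make_folds <- function(dataset, k, stratify_by_study = FALSE) {
  n <- length(dataset$outcome)
  stopifnot(k >= 2, n >= k)
  if (!stratify_by_study) return(sample(rep(seq_len(k), length.out = n)))
  folds <- integer(n)
  for (j in seq_len(dataset$n_studies)) {
    idx <- which(dataset$study == j)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

subset_ipd <- function(dataset, idx) {
  out <- dataset
  out$study <- dataset$study[idx]
  out$treatment <- dataset$treatment[idx]
  out$outcome <- dataset$outcome[idx]
  out$X <- dataset$X[idx, , drop = FALSE]
  out
}

# held-out deviance: squared error (continuous) or -2 x mean Bernoulli
# log-likelihood (binary)
heldout_deviance <- function(theta, design) {
  eta <- drop(design$A %*% theta)
  if (design$outcome_type == "continuous") mean((design$y - eta)^2)
  else -2 * mean(design$y * eta - log1p(exp(eta)))
}

#' Select the penalty by k-fold cross-validation
#'
#' Patients are randomly partitioned into \code{k} near-equal folds
#' (optionally within study).  For each fold the model is fitted on
#' the remaining folds along the whole penalty grid (warm starts from
#' large to small lambda) and evaluated on the held-out fold using
#' deviance: squared prediction error for continuous outcomes and
#' binomial deviance for binary ones.  Held-out patients use their
#' study's intercept as estimated from the training folds; if a fold
#' removes a study entirely from training, an error asks for
#' study-stratified folds.  The lambda minimizing the mean
#' cross-validation error is selected.
#'
#' @param dataset a standardized [ipd_data].
#' @param type penalty type, as in [penalty_spec()].
#' @param grid candidate lambda values (default [lambda_grid()]).
#' @param k number of folds (default 10).
#' @param weights adaptive weights (adaptive type only).
#' @param stratify_by_study draw folds within each study.
#' @param interaction_subset candidate interaction indices.
#' @param folds optional explicit fold assignment (integer vector in
#'   \code{1..k}, one entry per patient) overriding the random draw.
#' @return A list of class \code{ipd_cv}: \code{lambda_grid},
#'   \code{cv_error}, \code{cv_se} (SD across folds / sqrt(k)),
#'   \code{lambda_min}, \code{folds}.
#' @export
cross_validate_lambda <- function(dataset, type = c("L1", "L2", "adaptive"),
                                  grid = lambda_grid(), k = 10,
                                  weights = NULL,
                                  stratify_by_study = FALSE,
                                  interaction_subset = NULL,
                                  folds = NULL) {
  stopifnot(inherits(dataset, "ipd_data"))
  type <- match.arg(type)
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  if (is.null(folds)) folds <- make_folds(dataset, k, stratify_by_study)
  stopifnot(length(folds) == length(dataset$outcome),
            all(folds %in% seq_len(k)))
  grid_desc <- sort(grid, decreasing = TRUE)
  err <- matrix(NA_real_, k, length(grid_desc))
  for (f in seq_len(k)) {
    train <- subset_ipd(dataset, folds != f)
    test <- subset_ipd(dataset, folds == f)
    if (length(unique(train$study)) < dataset$n_studies)
      stop("fold ", f, " removes an entire study from training; ",
           "use stratify_by_study = TRUE")
    dtr <- build_design(train, interaction_subset)
    dte <- build_design(test, interaction_subset)
    pen_w <- penalty_weights(penalty_spec(type, 0, weights =
                                            if (type == "adaptive") weights),
                             length(dtr$idx_int))
    theta <- NULL
    for (g in seq_along(grid_desc)) {
      theta <- pls_solve(dtr, type, grid_desc[g], pen_w, theta0 = theta)
      err[f, g] <- heldout_deviance(theta, dte)
    }
  }
  cv_error <- colMeans(err)
  stopifnot(all(is.finite(cv_error)))
  structure(list(lambda_grid = grid_desc, cv_error = cv_error,
                 cv_se = apply(err, 2, sd) / sqrt(k),
                 lambda_min = grid_desc[which.min(cv_error)],
                 folds = folds),
            class = "ipd_cv")
}

#' Cross-validated lasso / ridge fits
#'
#' Convenience wrappers: run [cross_validate_lambda()] over the grid,
#' then refit on the full dataset at the selected lambda.
#'
#' @inheritParams cross_validate_lambda
#' @return An \code{ipd_fit} carrying \code{lambda_selected} and the
#'   \code{ipd_cv} object under \code{cv}.
#' @export
fit_lasso <- function(dataset, grid = lambda_grid(), k = 10,
                      stratify_by_study = FALSE, interaction_subset = NULL) {
  cv <- cross_validate_lambda(dataset, "L1", grid, k,
                              stratify_by_study = stratify_by_study,
                              interaction_subset = interaction_subset)
  fit <- fit_penalized(dataset, penalty_spec("L1", cv$lambda_min),
                       interaction_subset, method = "lasso")
  fit$cv <- cv
  fit
}

#' @rdname fit_lasso
#' @export
fit_ridge <- function(dataset, grid = lambda_grid(), k = 10,
                      stratify_by_study = FALSE, interaction_subset = NULL) {
  cv <- cross_validate_lambda(dataset, "L2", grid, k,
                              stratify_by_study = stratify_by_study,
                              interaction_subset = interaction_subset)
  fit <- fit_penalized(dataset, penalty_spec("L2", cv$lambda_min),
                       interaction_subset, method = "ridge")
  fit$cv <- cv
  fit
}

#' Adaptive lasso with ridge-derived weights
#'
#' Three stages: (1) cross-validation-tuned partial ridge fit; (2)
#' adaptive weights \eqn{\hat w_m = 1/|\hat\gamma_{m,ridge}|^l} with
#' \eqn{l = 1} by default; (3) cross-validation-tuned weighted L1 fit.
#' A covariate whose ridge interaction estimate is exactly zero would
#' have infinite weight; it is excluded from the candidate set with a
#' warning.
#'
#' @inheritParams cross_validate_lambda
#' @param exponent weight power \eqn{l}.
#' @return An \code{ipd_fit} (method \code{"adaptive-lasso"}) with the
#'   stage-1 ridge fit under \code{ridge_fit} and the stage-3
#'   cross-validation under \code{cv}.
#' @export
fit_adaptive_lasso <- function(dataset, grid = lambda_grid(), k = 10,
                               exponent = 1, stratify_by_study = FALSE,
                               interaction_subset = NULL) {
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  ridge <- fit_ridge(dataset, grid, k, stratify_by_study,
                     interaction_subset)
  g_ridge <- ridge$gamma_hat[interaction_subset]
  keep <- g_ridge != 0
  if (!all(keep)) {
    warning("dropping covariate(s) with exactly zero ridge interaction ",
            "estimate (infinite adaptive weight): ",
            paste(names(g_ridge)[!keep], collapse = ", "))
    interaction_subset <- interaction_subset[keep]
  }
  if (!length(interaction_subset))
    stop("no candidate interactions left after dropping zero-weight terms")
  w <- 1 / abs(g_ridge[keep])^exponent
  cv <- cross_validate_lambda(dataset, "adaptive", grid, k, weights = w,
                              stratify_by_study = stratify_by_study,
                              interaction_subset = interaction_subset)
  fit <- fit_penalized(dataset,
                       penalty_spec("adaptive", cv$lambda_min, weights = w,
                                    exponent = exponent),
                       interaction_subset, method = "adaptive-lasso")
  fit$cv <- cv
  fit$ridge_fit <- ridge
  fit
}
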