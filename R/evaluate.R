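#' Patient-specific treatment effects from a fit
#'
#' For each patient, the estimated treatment effect
#' \eqn{\hat\delta + \hat\gamma' x_i}, using the model's interaction
#' estimates (exact zeros for excluded or unselected terms).  On the
#' mean-difference scale for continuous outcomes and the log-odds-ratio
#' scale for binary ones.
#'
#' @param fit an \code{ipd_fit}.
#' @param X covariate matrix on the fit's standardized scale (columns
#'   in the order of \code{fit$gamma_hat}).
#' @return Numeric vector of per-patient effects.
#' @export
patient_specific_te <- function(fit, X) {
  stopifnot(inherits(fit, "ipd_fit"))
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(fit$gamma_hat))
  fit$delta_hat + drop(X %*% fit$gamma_hat)
}

#' Mean squared error of the patient-specific treatment effect
#'
#' Mean over all patients of the squared difference between the
#' estimated effect \eqn{\hat\delta + \hat\gamma' x_i} and the true
#' effect \eqn{\delta + \gamma' x_i}, where the truth uses the
#' average (not study-specific) generating parameters.
#'
#' @param fit an \code{ipd_fit}.
#' @param truth an \code{ipd_truth} from the simulator.
#' @param dataset the standardized [ipd_data] the model was fitted to.
#' @return Scalar MSE.
#' @export
pste_mse <- function(fit, truth, dataset) {
  est <- patient_specific_te(fit, dataset$X)
  true_fit <- list(delta_hat = truth$delta, gamma_hat = truth$gamma)
  class(true_fit) <- "ipd_fit"
  tru <- patient_specific_te(true_fit, dataset$X)
  mean((est - tru)^2)
}

#' MSE of the average treatment effect
#'
#' Squared error of the treatment effect at zero (mean) values of all
#' covariates: \eqn{(\hat\delta - \delta)^2}.
#'
#' @inheritParams pste_mse
#' @return Scalar squared error.
#' @export
ate_mse <- function(fit, truth) (fit$delta_hat - truth$delta)^2

#' MSE of the interaction coefficients
#'
#' Mean squared error of the interaction estimates averaged over the
#' covariates that truly are effect modifiers (\code{which = "true"}),
#' or over those that are not (\code{which = "false"}; their true
#' coefficient is 0).  Returns \code{NA} when the requested set is
#' empty.
#'
#' @inheritParams pste_mse
#' @param which \code{"true"} or \code{"false"}.
#' @return Scalar MSE or \code{NA}.
#' @export
em_mse <- function(fit, truth, which = c("true", "false")) {
  which <- match.arg(which)
  p <- length(fit$gamma_hat)
  idx <- if (which == "true") truth$em_indices
         else setdiff(seq_len(p), truth$em_indices)
  if (!length(idx)) return(NA_real_)
  mean((fit$gamma_hat[idx] - truth$gamma[idx])^2)
}

#' Bootstrap standard errors for any estimator
#'
#' Nonparametric bootstrap resampling patients with replacement within
#' each study (preserving the per-study sample sizes and the
#' meta-analytic structure; set \code{within_study = FALSE} for simple
#' pooled resampling).  The supplied fitting function is re-run on each
#' resample; a resample whose fit fails is redrawn (the count of
#' redraws is reported).
#'
#' @param fit_fun function taking a standardized [ipd_data] and
#'   returning an \code{ipd_fit}.
#' @param dataset the standardized [ipd_data].
#' @param B number of bootstrap resamples (at least 2; 1000
#'   recommended for stable percentile intervals).
#' @param within_study resample within study (default) or pooled.
#' @param max_redraws cap on redrawn failing resamples.
#' @return List with \code{se} (named: \code{delta}, \code{gamma}
#'   vector), \code{ci} (2.5/97.5 percentile intervals), \code{draws}
#'   (B x (1+p) matrix of delta and gamma estimates), and
#'   \code{n_failed}.
#' @export
bootstrap_se <- function(fit_fun, dataset, B = 1000,
                         within_study = TRUE, max_redraws = 50) {
  stopifnot(B >= 2)
  p <- ncol(dataset$X)
  draws <- matrix(NA_real_, B, 1 + p,
                  dimnames = list(NULL, c("delta",
                                          dataset$covariate_meta$name)))
  n_failed <- 0
  for (b in seq_len(B)) {
    repeat {
      idx <- if (within_study)
        unlist(lapply(seq_len(dataset$n_studies), function(j) {
          pool <- which(dataset$study == j)
          sample(pool, length(pool), replace = TRUE)
        }))
      else sample(seq_along(dataset$outcome), replace = TRUE)
      fit_b <- tryCatch(fit_fun(subset_ipd(dataset, idx)),
                        error = function(e) NULL)
      if (!is.null(fit_b)) break
      n_failed <- n_failed + 1
      if (n_failed > max_redraws)
        stop("bootstrap: more than ", max_redraws, " failed resamples")
    }
    draws[b, ] <- c(fit_b$delta_hat, fit_b$gamma_hat)
  }
  list(se = apply(draws, 2, sd),
       ci = t(apply(draws, 2, quantile, probs = c(0.025, 0.975))),
       draws = draws, n_failed = n_failed)
}

#' Subgroup profile
#'
#' Raw-scale covariate values for one hypothetical patient, used with
#' [predict_subgroup()].
#'
#' @param ... named covariate values (or a single named vector/list).
#' @return Named numeric vector of class \code{subgroup_profile}.
#' @export
subgroup_profile <- function(...) {
  vals <- list(...)
  if (length(vals) == 1 && is.null(names(vals)) ||
      (length(vals) == 1 && (is.list(vals[[1]]) ||
                             length(vals[[1]]) > 1)))
    vals <- as.list(vals[[1]])
  v <- unlist(vals)
  stopifnot(!is.null(names(v)), all(nzchar(names(v))))
  structure(v, class = "subgroup_profile")
}

#' Predict the treatment effect for a patient subgroup
#'
#' Standardizes a raw-scale covariate profile with the scaling stored
#' in the fit, computes \eqn{\hat\delta + \hat\gamma' x^*}, and returns
#' the effect on the linear-predictor scale (plus the odds-ratio scale
#' for binary-outcome fits).  The 95\% interval comes from posterior
#' draws (Bayesian fits), from bootstrap draws if a [bootstrap_se()]
#' result is supplied, or from the fixed-effect covariance of
#' \eqn{(\hat\delta, \hat\gamma)} where the fit provides one (GLMM and
#' stepwise fits); otherwise no interval is returned.
#'
#' @param fit an \code{ipd_fit} carrying \code{scaling}.
#' @param profile a [subgroup_profile()] covering every covariate.
#' @param boot optional [bootstrap_se()] result for frequentist
#'   penalized fits.
#' @param level interval level (default 0.95).
#' @return List with \code{effect}, \code{lower}, \code{upper} (linear
#'   predictor scale; \code{NA} if no interval source), and for binary
#'   fits \code{odds_ratio} with its interval.
#' @export
predict_subgroup <- function(fit, profile, boot = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ipd_fit"), !is.null(fit$scaling))
  cn <- names(fit$gamma_hat)
  missing_cov <- setdiff(cn, names(profile))
  if (length(missing_cov))
    stop("profile is missing covariate(s): ",
         paste(missing_cov, collapse = ", "))
  unknown <- setdiff(names(profile), cn)
  if (length(unknown))
    stop("unknown covariate(s) in profile: ",
         paste(unknown, collapse = ", "))
  x_star <- (unclass(profile)[cn] - fit$scaling$mean[cn]) /
    fit$scaling$sd[cn]
  effect <- unname(fit$delta_hat + sum(fit$gamma_hat * x_star))
  alpha <- (1 - level) / 2
  lower <- upper <- NA_real_
  q <- length(fit$interaction_subset)
  if (!is.null(fit$draws)) {
    gnm <- if (q == 1) "gamma" else paste0("gamma[", seq_len(q), "]")
    eff_draws <- fit$draws[, "delta"] +
      drop(fit$draws[, gnm, drop = FALSE] %*%
             x_star[fit$interaction_subset])
    lower <- unname(quantile(eff_draws, alpha))
    upper <- unname(quantile(eff_draws, 1 - alpha))
  } else if (!is.null(boot)) {
    eff_draws <- boot$draws[, "delta"] +
      drop(boot$draws[, cn, drop = FALSE] %*% x_star)
    lower <- unname(quantile(eff_draws, alpha))
    upper <- unname(quantile(eff_draws, 1 - alpha))
  } else if (!is.null(fit$vcov_dg)) {
    # vcov_dg rows: treatment, then the interaction terms kept in the
    # final model (attribute cov_idx maps them to covariate indices)
    idx <- attr(fit$vcov_dg, "cov_idx")
    vv <- c(1, x_star[idx])
    se <- sqrt(drop(t(vv) %*% fit$vcov_dg %*% vv))
    zq <- stats::qnorm(1 - alpha)
    lower <- effect - zq * se
    upper <- effect + zq * se
  }
  out <- list(effect = effect, lower = lower, upper = upper)
  if (identical(fit$outcome_type, "binary")) {
    out$odds_ratio <- exp(effect)
    out$odds_ratio_lower <- exp(lower)
    out$odds_ratio_upper <- exp(upper)
  }
  out
}
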