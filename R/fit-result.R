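#' Fit-result container
#'
#' All estimators return an \code{ipd_fit}: the average treatment
#' effect \code{delta_hat} (mean difference or log-odds-ratio scale),
#' the length-p main-effect vector \code{beta_hat}, the length-p
#' interaction vector \code{gamma_hat} (exact zeros for excluded or
#' unselected terms), per-study intercepts, and — where the method
#' provides them — the residual SD, the heterogeneity SD \code{tau_hat}
#' of the treatment effect, standard errors, a selected penalty value,
#' and posterior inclusion probabilities.  The \code{scaling} element
#' records the standardization under which the coefficients are
#' expressed.
#'
#' @param method character method label.
#' @param delta_hat,beta_hat,gamma_hat,intercepts point estimates on
#'   the standardized scale; \code{gamma_hat} must have length p with
#'   zeros outside the fitted interaction subset.
#' @param interaction_subset indices of covariates whose interactions
#'   entered the model.
#' @param sigma_hat,tau_hat,se,lambda_selected,inclusion_prob,vcov_dg,
#'   draws,diagnostics optional method-specific components;
#'   \code{vcov_dg} is the covariance of \code{(delta, gamma)} where a
#'   closed form exists, \code{draws} holds posterior draws for
#'   Bayesian fits.
#' @param scaling the scaling list from the standardized dataset.
#' @param ... further components stored verbatim.
#' @return An object of class \code{ipd_fit}.
#' @keywords internal
new_ipd_fit <- function(method, delta_hat, beta_hat, gamma_hat, intercepts,
                        interaction_subset, scaling,
                        sigma_hat = NULL, tau_hat = NULL, se = NULL,
                        lambda_selected = NULL, inclusion_prob = NULL,
                        vcov_dg = NULL, draws = NULL, diagnostics = NULL,
                        ...) {
  stopifnot(length(beta_hat) == length(gamma_hat))
  out <- setdiff(seq_along(gamma_hat), interaction_subset)
  stopifnot(all(gamma_hat[out] == 0))
  if (!is.null(tau_hat)) stopifnot(tau_hat >= 0)
  structure(list(method = method,
                 delta_hat = unname(delta_hat),
                 beta_hat = beta_hat, gamma_hat = gamma_hat,
                 intercepts = intercepts,
                 interaction_subset = interaction_subset,
                 sigma_hat = sigma_hat, tau_hat = tau_hat, se = se,
                 lambda_selected = lambda_selected,
                 inclusion_prob = inclusion_prob,
                 vcov_dg = vcov_dg, draws = draws,
                 diagnostics = diagnostics, scaling = scaling, ...),
            class = "ipd_fit")
}

#' @export
print.ipd_fit <- function(x, ...) {
  cat(sprintf("<ipd_fit: %s>\n", x$method))
  if (is.null(x$delta_hat)) {  # prior-only run: draws, no estimates
    cat(sprintf("  %d draws of %d monitored parameters\n",
                nrow(x$draws), ncol(x$draws)))
    return(invisible(x))
  }
  cat(sprintf("  average treatment effect: %.4f", x$delta_hat))
  if (!is.null(x$se$delta)) cat(sprintf(" (SE %.4f)", x$se$delta))
  cat("\n")
  if (!is.null(x$tau_hat))
    cat(sprintf("  heterogeneity tau: %.4f\n", x$tau_hat))
  if (!is.null(x$lambda_selected))
    cat(sprintf("  selected lambda: %.4g\n", x$lambda_selected))
  nz <- which(x$gamma_hat != 0)
  cat(sprintf("  nonzero interactions: %d of %d\n",
              length(nz), length(x$gamma_hat)))
  if (length(nz)) {
    g <- x$gamma_hat[nz]
    cat(paste(sprintf("    %s = %.4f", names(x$beta_hat)[nz], g),
              collapse = "\n"), "\n")
  }
  invisible(x)
}
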