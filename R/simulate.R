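#' Simulate patient-level covariates
#'
#' Continuous covariates are drawn jointly multivariate normal with an
#' AR(1) correlation structure, \eqn{\Sigma_{kl} = \rho^{|k-l|}} over
#' the continuous block; binary covariates are i.i.d. Bernoulli(0.5).
#'
#' @param n number of patients.
#' @param config an \code{ipd_scenario} from [make_scenario()].
#' @return n x p numeric matrix with columns \code{x1..xp}.
#' @export
simulate_covariates <- function(n, config) {
  p <- config$n_covariates
  kinds <- config$covariate_kinds
  X <- matrix(0, n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  cont <- which(kinds == "continuous")
  if (length(cont)) {
    Sigma <- config$rho ^ abs(outer(seq_along(cont), seq_along(cont), "-"))
    X[, cont] <- MASS::mvrnorm(n, mu = rep(0, length(cont)), Sigma = Sigma)
  }
  bin <- which(kinds == "binary")
  if (length(bin))
    X[, bin] <- matrix(rbinom(n * length(bin), 1, 0.5), n)
  X
}

#' Draw study-level true parameters
#'
#' Realizes the study-specific coefficients of the random-effects
#' generating model: treatment effects \eqn{d_j \sim N(\delta, \tau^2)},
#' main effects \eqn{b_{j,m} \sim N(\beta_m, \tau_\beta^2)} for
#' non-nuisance covariates (nuisance covariates have \eqn{b_{j,m} = 0}
#' exactly), interaction coefficients
#' \eqn{c_{j,m} \sim N(\gamma_m, \tau_\gamma^2)} for effect modifiers
#' (zero otherwise), and intercepts \eqn{a_j} uniform over the
#' scenario's intercept range.  Scenarios with
#' \code{random_effect_dist = "uniform"} replace each normal draw by
#' its mean plus a Uniform(-w, w) deviate with half-width \code{w}.
#'
#' @param config an \code{ipd_scenario}.
#' @return A list of class \code{ipd_truth} with the average
#'   parameters (\code{delta}, \code{gamma}, \code{beta},
#'   \code{em_indices}) and realized study-level draws (\code{d_j},
#'   \code{a_j}, and J x p matrices \code{b_j}, \code{c_j}).
#' @export
draw_study_params <- function(config) {
  J <- config$n_studies
  p <- config$n_covariates
  re <- function(n, mean, sd) {
    if (identical(config$random_effect_dist, "uniform"))
      mean + runif(n, -config$re_halfwidth, config$re_halfwidth)
    else rnorm(n, mean, sd)
  }
  d_j <- re(J, config$delta, config$tau)
  b_j <- matrix(0, J, p)
  active <- sort(c(config$em_indices, config$prognostic_indices))
  for (m in active) b_j[, m] <- re(J, config$beta[m], config$tau_beta)
  c_j <- matrix(0, J, p)
  for (m in config$em_indices)
    c_j[, m] <- re(J, config$gamma[m], config$tau_gamma)
  a_j <- runif(J, config$intercept_range[1], config$intercept_range[2])
  structure(list(delta = config$delta, gamma = config$gamma,
                 beta = config$beta, em_indices = config$em_indices,
                 d_j = d_j, b_j = b_j, c_j = c_j, a_j = a_j),
            class = "ipd_truth")
}

#' Simulate one multi-study IPD dataset with ground truth
#'
#' Runs the full generating mechanism: per-study sizes drawn uniformly
#' over the configured integer range, covariates via
#' [simulate_covariates()], treatment assignment Bernoulli(0.5), study
#' parameters via [draw_study_params()], and the outcome from the
#' linear predictor \eqn{a_j + b_j'x_i + c_j' x_i t_i + d_j t_i} —
#' Gaussian with residual SD \code{sigma} for continuous outcomes, or
#' Bernoulli through the inverse logit for binary outcomes.
#'
#' Reproducibility follows R's global RNG: call \code{set.seed()}
#' before simulating to make the draw deterministic.
#'
#' @param config an \code{ipd_scenario} from [make_scenario()].
#' @return List with elements \code{dataset} (an [ipd_data], raw
#'   covariate scale) and \code{truth} (an \code{ipd_truth}).
#' @export
simulate_ipd <- function(config) {
  stopifnot(inherits(config, "ipd_scenario"))
  J <- config$n_studies
  sizes <- sample(seq(config$n_patients_range[1],
                      config$n_patients_range[2]), J, replace = TRUE)
  truth <- draw_study_params(config)
  study <- rep(seq_len(J), sizes)
  n <- length(study)
  X <- simulate_covariates(n, config)
  t_i <- rbinom(n, 1, 0.5)
  eta <- truth$a_j[study] +
    rowSums(X * truth$b_j[study, , drop = FALSE]) +
    rowSums(X * truth$c_j[study, , drop = FALSE]) * t_i +
    truth$d_j[study] * t_i
  y <- if (config$outcome_type == "continuous")
    rnorm(n, eta, config$sigma) else rbinom(n, 1, plogis(eta))
  dataset <- ipd_data(study, t_i, y, X,
                      covariate_kinds = config$covariate_kinds,
                      outcome_type = config$outcome_type)
  list(dataset = dataset, truth = truth)
}

#' Observed event rate of a binary-outcome dataset
#'
#' @param dataset an [ipd_data] with binary outcome.
#' @return Proportion of events (mean of the outcome indicator).
#' @export
event_rate <- function(dataset) {
  stopifnot(inherits(dataset, "ipd_data"))
  if (dataset$outcome_type != "binary")
    stop("event_rate is defined for binary outcomes only")
  mean(dataset$outcome)
}
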