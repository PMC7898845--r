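#' MCMC settings
#'
#' @param n_chains number of chains (default 2; Gelman-Rubin needs >= 2).
#' @param n_iter iterations per chain, including burn-in (default 2000).
#' @param n_burnin burn-in iterations discarded per chain (default 200).
#' @param thin thinning interval (default 1).
#' @param seed integer; chain c uses RNG seed \code{seed + c}.
#' @return A list of class \code{mcmc_settings}.
#' @export
mcmc_settings <- function(n_chains = 2, n_iter = 2000, n_burnin = 200,
                          thin = 1, seed = 1) {
  stopifnot(n_burnin < n_iter, n_chains >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 n_burnin = n_burnin, thin = thin, seed = seed),
            class = "mcmc_settings")
}

# default hyperparameters shared by both Bayesian models; the *_fixed
# entries replace the corresponding stochastic node by a supplied
# constant (used for prior-sensitivity runs and for sampler-validation
# tests on conjugate sub-models)
bayes_hyper <- function(...) {
  h <- list(prec_fixed = 1e-3,      # N(0, 1000) on delta, beta, a_j
            sigma_prec_shape = 0.001, sigma_prec_rate = 0.001,
            lambda_shape = 2, lambda_rate = 0.1,
            tau_upper = 5,
            eta_upper = 5, g = 100, inclusion_prior = 0.5,
            sigma_fixed = NULL, tau_fixed = NULL, lambda_fixed = NULL,
            eta_fixed = NULL, ind_fixed = NULL)
  modifyList(h, list(...), keep.null = TRUE)
}

# ---------------------------------------------------------------------
# JAGS model strings

jags_blasso <- function(outcome_type, prior_only = FALSE,
                        fixed = character(0)) {
  lik <- if (outcome_type == "continuous") "
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], prec)
    mu[i] <- a[study[i]] + inprod(X[i,], beta) + inprod(XI[i,], gamma) + d[study[i]] * t[i]
  }" else "
  for (i in 1:N) {
    y[i] ~ dbern(ilogit(mu[i]))
    mu[i] <- a[study[i]] + inprod(X[i,], beta) + inprod(XI[i,], gamma) + d[study[i]] * t[i]
  }"
  # prior-only runs use the unconditional Laplace form: with no
  # likelihood the diffuse Gamma(0.001, 0.001) precision prior can
  # underflow to zero, making the sigma-conditional prior degenerate
  gamma_prior <- if (outcome_type == "continuous" && !prior_only)
    "gamma[m] ~ ddexp(0, lambda / sigma)" else
    "gamma[m] ~ ddexp(0, lambda)"
  sigma_prior <- if (outcome_type != "continuous" || prior_only) ""
  else if ("sigma" %in% fixed) "
  prec <- 1 / (sigma * sigma)" else "
  prec ~ dgamma(sigma_prec_shape, sigma_prec_rate)
  sigma <- 1 / sqrt(prec)"
  lambda_prior <- if ("lambda" %in% fixed) "" else "
  lambda ~ dgamma(lambda_shape, lambda_rate)"
  tau_prior <- if ("tau" %in% fixed) "" else "
  tau ~ dunif(0, tau_upper)"
  paste0("model {", if (!prior_only) lik else "", "
  for (j in 1:J) {
    a[j] ~ dnorm(0, prec_fixed)
    d[j] ~ dnorm(delta, prec_tau)
  }
  delta ~ dnorm(0, prec_fixed)
  for (m in 1:p) { beta[m] ~ dnorm(0, prec_fixed) }
  for (m in 1:q) { ", gamma_prior, " }", lambda_prior, sigma_prior,
  tau_prior, "
  prec_tau <- 1 / (tau * tau)
}")
}

jags_ssvs <- function(outcome_type, prior_only = FALSE,
                      fixed = character(0)) {
  lik <- if (outcome_type == "continuous") "
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], prec)
    mu[i] <- a[study[i]] + inprod(X[i,], beta) + inprod(XI[i,], gamma) + d[study[i]] * t[i]
  }" else "
  for (i in 1:N) {
    y[i] ~ dbern(ilogit(mu[i]))
    mu[i] <- a[study[i]] + inprod(X[i,], beta) + inprod(XI[i,], gamma) + d[study[i]] * t[i]
  }"
  sigma_prior <- if (outcome_type != "continuous" || prior_only) ""
  else if ("sigma" %in% fixed) "
  prec <- 1 / (sigma * sigma)" else "
  prec ~ dgamma(sigma_prec_shape, sigma_prec_rate)
  sigma <- 1 / sqrt(prec)"
  ind_prior <- if ("ind" %in% fixed) "" else "
    ind[m] ~ dbern(inclusion_prior)"
  eta_prior <- if ("eta" %in% fixed) "" else "
  eta ~ dunif(0, eta_upper)"
  tau_prior <- if ("tau" %in% fixed) "" else "
  tau ~ dunif(0, tau_upper)"
  paste0("model {", if (!prior_only) lik else "", "
  for (j in 1:J) {
    a[j] ~ dnorm(0, prec_fixed)
    d[j] ~ dnorm(delta, prec_tau)
  }
  delta ~ dnorm(0, prec_fixed)
  for (m in 1:p) { beta[m] ~ dnorm(0, prec_fixed) }
  for (m in 1:q) {
    gamma[m] ~ dnorm(0, 1 / (eta2 * (1 + (g - 1) * ind[m])))",
  ind_prior, "
  }", eta_prior, "
  eta2 <- eta * eta", sigma_prior, tau_prior, "
  prec_tau <- 1 / (tau * tau)
}")
}

# ---------------------------------------------------------------------
# Log joint densities (up to additive constants); independent of the
# sampler.  The continuous-outcome residual scale is parameterized by
# sigma; the Gamma prior on the precision 1/sigma^2 is transformed
# accordingly (Jacobian 2/sigma^3).

ldlaplace <- function(x, rate) log(rate / 2) - rate * abs(x)

common_log_prior <- function(state, hyper, outcome_type) {
  lp <- 0
  sd_fixed <- 1 / sqrt(hyper$prec_fixed)
  lp <- lp + sum(dnorm(state$a, 0, sd_fixed, log = TRUE)) +
    dnorm(state$delta, 0, sd_fixed, log = TRUE) +
    sum(dnorm(state$beta, 0, sd_fixed, log = TRUE))
  if (state$tau < 0 || state$tau > hyper$tau_upper) return(-Inf)
  lp <- lp + dunif(state$tau, 0, hyper$tau_upper, log = TRUE) +
    sum(dnorm(state$d, state$delta, state$tau, log = TRUE))
  if (outcome_type == "continuous") {
    if (state$sigma <= 0) return(-Inf)
    prec <- 1 / state$sigma^2
    lp <- lp + dgamma(prec, hyper$sigma_prec_shape, hyper$sigma_prec_rate,
                      log = TRUE) + log(2 / state$sigma^3)
  }
  lp
}

log_lik_ipd <- function(state, design) {
  eta <- drop(design$A[, design$idx_study, drop = FALSE] %*% state$a) +
    drop(design$A[, design$idx_main, drop = FALSE] %*% state$beta) +
    drop(design$A[, design$idx_int, drop = FALSE] %*% state$gamma) +
    state$d[design$study] * design$treatment
  if (design$outcome_type == "continuous")
    sum(dnorm(design$y, eta, state$sigma, log = TRUE))
  else
    sum(design$y * eta - log1p(exp(eta)))
}

#' Log joint density of the Bayesian lasso model
#'
#' Evaluates, up to an additive constant, the log joint density of the
#' Bayesian lasso for IPD meta-analysis at a parameter state:
#' Gaussian or Bernoulli-logit likelihood; conditional Laplace prior
#' \eqn{\gamma_m | \sigma, \lambda \sim Laplace(0, \sigma/\lambda)} for
#' continuous outcomes or unconditional
#' \eqn{\gamma_m | \lambda \sim Laplace(0, 1/\lambda)} for binary;
#' random treatment effects \eqn{d_j \sim N(\delta, \tau^2)}; vague
#' N(0, 1000) priors on \eqn{\delta, \beta_m, a_j}; Gamma(0.001, 0.001)
#' on the residual precision; Gamma(shape 2, rate 0.1) on
#' \eqn{\lambda}; Uniform(0, 5) on \eqn{\tau}.  States outside the
#' support return \code{-Inf}.
#'
#' @param state list with elements \code{a} (length J), \code{beta}
#'   (length p), \code{gamma} (length q), \code{delta}, \code{d}
#'   (length J), \code{tau}, \code{lambda}, and \code{sigma}
#'   (continuous outcomes).
#' @param design an \code{ipd_design} from [build_design()].
#' @param hyper hyperparameter overrides (see source of
#'   \code{bayes_hyper}).
#' @return Log density (scalar), \code{-Inf} outside the support.
#' @export
log_posterior_blasso <- function(state, design, hyper = list()) {
  hyper <- do.call(bayes_hyper, hyper)
  if (state$lambda <= 0) return(-Inf)
  lp <- common_log_prior(state, hyper, design$outcome_type)
  if (!is.finite(lp)) return(lp)
  if (design$outcome_type == "continuous") {
    if (state$sigma <= 0) return(-Inf)
    lp <- lp + sum(ldlaplace(state$gamma, state$lambda / state$sigma))
  } else {
    lp <- lp + sum(ldlaplace(state$gamma, state$lambda))
  }
  lp <- lp + dgamma(state$lambda, hyper$lambda_shape, hyper$lambda_rate,
                    log = TRUE)
  lp + log_lik_ipd(state, design)
}

#' Log joint density of the spike-and-slab (SSVS) model
#'
#' As [log_posterior_blasso()] but with the mixture prior
#' \eqn{\gamma_m | I_m \sim (1 - I_m) N(0, \eta^2) + I_m N(0, g\eta^2)}
#' with \eqn{g = 100} fixed, \eqn{I_m \sim Bernoulli(0.5)} and
#' \eqn{\eta \sim Uniform(0, 5)}.
#'
#' @param state as in [log_posterior_blasso()] but with \code{ind}
#'   (0/1 vector, length q) and \code{eta} instead of \code{lambda}.
#' @inheritParams log_posterior_blasso
#' @return Log density (scalar), \code{-Inf} outside the support.
#' @export
log_posterior_ssvs <- function(state, design, hyper = list()) {
  hyper <- do.call(bayes_hyper, hyper)
  if (state$eta <= 0 || state$eta > hyper$eta_upper) return(-Inf)
  if (!all(state$ind %in% c(0, 1))) return(-Inf)
  lp <- common_log_prior(state, hyper, design$outcome_type)
  if (!is.finite(lp)) return(lp)
  sd_g <- state$eta * sqrt(1 + (hyper$g - 1) * state$ind)
  lp <- lp + sum(dnorm(state$gamma, 0, sd_g, log = TRUE)) +
    sum(dbinom(state$ind, 1, hyper$inclusion_prior, log = TRUE)) +
    dunif(state$eta, 0, hyper$eta_upper, log = TRUE)
  lp + log_lik_ipd(state, design)
}

# ---------------------------------------------------------------------
# Gelman-Rubin potential scale reduction factor

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor \eqn{\hat R} computed from the
#' between- and within-chain variances:
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}.  Chains that are
#' constant and identical give 1; chains stuck at distinct constants
#' give \code{Inf}.
#'
#' @param chains list of equal-dimension draw matrices (iterations x
#'   parameters), one per chain; at least two chains.
#' @return Named vector of \eqn{\hat R} per parameter.
#' @export
gelman_rubin <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  dims <- vapply(chains, dim, integer(2))
  stopifnot(all(dims == dims[, 1]))
  n <- dims[1, 1]
  sapply(seq_len(dims[2, 1]), function(k) {
    draws <- vapply(chains, function(ch) ch[, k], numeric(n))
    W <- mean(apply(draws, 2, var))
    B_over_n <- var(colMeans(draws))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }) -> r
  names(r) <- colnames(chains[[1]])
  r
}

# ---------------------------------------------------------------------
# fitting via JAGS

run_jags <- function(model_string, data, monitors, settings) {
  inits <- lapply(seq_len(settings$n_chains), function(c) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = settings$seed + c)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = settings$n_chains,
                          quiet = TRUE)
  stats::update(jm, settings$n_burnin, progress.bar = "none")
  rjags::coda.samples(jm, monitors,
                      n.iter = settings$n_iter - settings$n_burnin,
                      thin = settings$thin, progress.bar = "none")
}

# shared post-processing: summaries, credible intervals, Rhat
bayes_as_fit <- function(samples, dataset, design, method, settings,
                         monitor_rhat) {
  chains <- lapply(samples, function(s) {
    m <- as.matrix(s)
    dimnames(m) <- dimnames(s)
    m
  })
  all_draws <- do.call(rbind, chains)
  post_mean <- colMeans(all_draws)
  post_sd <- apply(all_draws, 2, sd)
  ci <- t(apply(all_draws, 2, quantile, probs = c(0.025, 0.975)))
  rhat_cols <- intersect(monitor_rhat, colnames(all_draws))
  rhat <- if (length(chains) >= 2)
    gelman_rubin(lapply(chains, function(m) m[, rhat_cols, drop = FALSE]))
  else setNames(rep(NA_real_, length(rhat_cols)), rhat_cols)
  diagnostics <- list(rhat = rhat, settings = settings)
  if (any(is.finite(rhat) & rhat > 1.1)) {
    diagnostics$rhat_warning <- paste(
      "Rhat > 1.1 for:", paste(names(rhat)[rhat > 1.1], collapse = ", "))
    warning(diagnostics$rhat_warning)
  }
  vec <- function(prefix, k) {
    nm <- if (k == 1) prefix else paste0(prefix, "[", seq_len(k), "]")
    out <- post_mean[nm]
    out[is.na(out)] <- 0
    unname(out)
  }
  p <- design$p
  q <- length(design$idx_int)
  cn <- dataset$covariate_meta$name
  gamma_hat <- setNames(rep(0, p), cn)
  gamma_sub <- vec("gamma", q)
  gamma_hat[design$interaction_subset] <- gamma_sub
  gamma_se <- setNames(rep(NA_real_, p), cn)
  gamma_se[design$interaction_subset] <-
    post_sd[if (q == 1) "gamma" else paste0("gamma[", seq_len(q), "]")]
  incl <- NULL
  ind_nm <- if (q == 1) "ind" else paste0("ind[", seq_len(q), "]")
  if (all(ind_nm %in% colnames(all_draws))) {
    incl <- setNames(rep(NA_real_, p), cn)
    incl[design$interaction_subset] <- post_mean[ind_nm]
  }
  new_ipd_fit(
    method = method,
    delta_hat = post_mean["delta"],
    beta_hat = setNames(vec("beta", p), cn),
    gamma_hat = gamma_hat,
    intercepts = vec("a", design$n_studies),
    interaction_subset = design$interaction_subset,
    scaling = dataset$scaling,
    outcome_type = design$outcome_type,
    sigma_hat = if ("sigma" %in% names(post_mean))
      unname(post_mean["sigma"]) else NULL,
    tau_hat = if ("tau" %in% names(post_mean))
      unname(post_mean["tau"]) else NULL,
    se = list(delta = unname(post_sd["delta"]),
              gamma = gamma_se,
              tau = if ("tau" %in% names(post_sd))
                unname(post_sd["tau"]) else NULL),
    inclusion_prob = incl,
    lambda_selected = if ("lambda" %in% names(post_mean))
      unname(post_mean["lambda"]) else NULL,
    draws = all_draws, chains = chains, credible = ci,
    diagnostics = diagnostics)
}

bayes_data <- function(design, hyper, extra = character(0)) {
  d <- list(y = design$y, X = design$A[, design$idx_main, drop = FALSE],
            XI = design$A[, design$idx_int, drop = FALSE],
            t = design$treatment, study = design$study,
            N = length(design$y), J = design$n_studies, p = design$p,
            q = length(design$idx_int),
            prec_fixed = hyper$prec_fixed,
            tau_upper = hyper$tau_upper)
  if (design$outcome_type == "continuous") {
    d$sigma_prec_shape <- hyper$sigma_prec_shape
    d$sigma_prec_rate <- hyper$sigma_prec_rate
  }
  d
}

#' Bayesian lasso for treatment-covariate interactions
#'
#' MCMC fit of the one-stage IPD meta-analysis model with a Laplace
#' shrinkage prior on the interaction coefficients and a random
#' treatment effect across studies (see [log_posterior_blasso()] for
#' the full prior specification).  Point estimates are posterior
#' means; posterior SDs serve as standard errors and equal-tailed 95\%
#' credible intervals are attached.  The Gelman-Rubin statistic is
#' computed for the average treatment effect, the heterogeneity SD,
#' and every interaction coefficient; a value above 1.1 triggers a
#' warning stored in the result.
#'
#' With \code{dataset = NULL} the model is sampled from its prior only
#' (no likelihood), which is useful for prior predictive checks.
#'
#' @param dataset a standardized [ipd_data], or \code{NULL} for a
#'   prior-only run.
#' @param settings an [mcmc_settings()].
#' @param interaction_subset candidate interaction indices (default
#'   all).
#' @param hyper hyperparameter overrides.
#' @return An \code{ipd_fit} with posterior \code{draws},
#'   \code{credible} interval matrix, and \code{diagnostics$rhat}.
#' @export
fit_bayes_lasso <- function(dataset, settings = mcmc_settings(),
                            interaction_subset = NULL, hyper = list()) {
  hyper <- do.call(bayes_hyper, hyper)
  if (is.null(dataset)) {
    data <- list(J = 2L, p = 1L, q = 1L, prec_fixed = hyper$prec_fixed,
                 tau_upper = hyper$tau_upper,
                 lambda_shape = hyper$lambda_shape,
                 lambda_rate = hyper$lambda_rate)
    samples <- run_jags(jags_blasso("continuous", prior_only = TRUE),
                        data, c("delta", "gamma", "tau", "lambda"),
                        settings)
    chains <- lapply(samples, as.matrix)
    return(structure(list(method = "bayes-lasso-prior",
                          draws = do.call(rbind, chains),
                          chains = chains, diagnostics = NULL),
                     class = "ipd_fit"))
  }
  stopifnot(inherits(dataset, "ipd_data"))
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  stopifnot(length(interaction_subset) >= 1)
  design <- build_design(dataset, interaction_subset)
  data <- bayes_data(design, hyper)
  data$lambda_shape <- hyper$lambda_shape
  data$lambda_rate <- hyper$lambda_rate
  fixed <- fixed_nodes(data, hyper, design$outcome_type,
                       c("sigma", "tau", "lambda"))
  data <- fixed$data
  monitors <- setdiff(c("delta", "beta", "gamma", "a", "tau", "lambda",
                        if (design$outcome_type == "continuous") "sigma"),
                      fixed$nodes)
  samples <- run_jags(jags_blasso(design$outcome_type,
                                  fixed = fixed$nodes),
                      data, monitors, settings)
  q <- length(design$idx_int)
  monitor_rhat <- c("delta", "tau",
                    if (q == 1) "gamma" else paste0("gamma[", seq_len(q), "]"))
  bayes_as_fit(samples, dataset, design, "bayes-lasso", settings,
               monitor_rhat)
}

# move *_fixed hyper entries into the JAGS data list, dropping the
# now-unused prior hyperparameters
fixed_nodes <- function(data, hyper, outcome_type, candidates) {
  nodes <- character(0)
  for (nd in candidates) {
    val <- hyper[[paste0(nd, "_fixed")]]
    if (is.null(val)) next
    if (nd == "sigma" && outcome_type != "continuous") next
    nodes <- c(nodes, nd)
    data[[nd]] <- val
    drop <- switch(nd,
                   sigma = c("sigma_prec_shape", "sigma_prec_rate"),
                   lambda = c("lambda_shape", "lambda_rate"),
                   tau = "tau_upper",
                   eta = "eta_upper",
                   ind = "inclusion_prior",
                   character(0))
    for (d in drop) data[[d]] <- NULL
  }
  list(data = data, nodes = nodes)
}

#' Stochastic search variable selection (spike-and-slab)
#'
#' MCMC fit of the one-stage IPD meta-analysis model with a
#' spike-and-slab mixture prior on the interaction coefficients (see
#' [log_posterior_ssvs()]): each interaction has a binary inclusion
#' indicator with a Bernoulli(0.5) prior, a narrow N(0, eta^2) prior
#' when excluded and a g-times wider slab when included (g = 100).
#' The posterior mean of each indicator is returned as the covariate's
#' inclusion probability; the point estimate of each interaction is
#' its model-averaged posterior mean.
#'
#' @inheritParams fit_bayes_lasso
#' @return An \code{ipd_fit} with \code{inclusion_prob}, posterior
#'   \code{draws}, \code{credible} intervals, and
#'   \code{diagnostics$rhat}.
#' @export
fit_ssvs <- function(dataset, settings = mcmc_settings(),
                     interaction_subset = NULL, hyper = list()) {
  hyper <- do.call(bayes_hyper, hyper)
  if (is.null(dataset)) {
    data <- list(J = 2L, p = 1L, q = 1L, prec_fixed = hyper$prec_fixed,
                 tau_upper = hyper$tau_upper,
                 eta_upper = hyper$eta_upper, g = hyper$g,
                 inclusion_prior = hyper$inclusion_prior)
    samples <- run_jags(jags_ssvs("continuous", prior_only = TRUE),
                        data, c("delta", "gamma", "tau", "eta", "ind"),
                        settings)
    chains <- lapply(samples, as.matrix)
    return(structure(list(method = "ssvs-prior",
                          draws = do.call(rbind, chains),
                          chains = chains, diagnostics = NULL),
                     class = "ipd_fit"))
  }
  stopifnot(inherits(dataset, "ipd_data"))
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  stopifnot(length(interaction_subset) >= 1)
  design <- build_design(dataset, interaction_subset)
  data <- bayes_data(design, hyper)
  data$eta_upper <- hyper$eta_upper
  data$g <- hyper$g
  data$inclusion_prior <- hyper$inclusion_prior
  fixed <- fixed_nodes(data, hyper, design$outcome_type,
                       c("sigma", "tau", "eta", "ind"))
  data <- fixed$data
  monitors <- setdiff(c("delta", "beta", "gamma", "a", "tau", "eta", "ind",
                        if (design$outcome_type == "continuous") "sigma"),
                      fixed$nodes)
  samples <- run_jags(jags_ssvs(design$outcome_type, fixed = fixed$nodes),
                      data, monitors, settings)
  q <- length(design$idx_int)
  monitor_rhat <- c("delta", "tau",
                    if (q == 1) "gamma" else paste0("gamma[", seq_len(q), "]"))
  bayes_as_fit(samples, dataset, design, "ssvs", settings, monitor_rhat)
}
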