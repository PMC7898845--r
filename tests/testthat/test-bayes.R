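# independent log-density calculator used as the oracle for the
# package's log-posterior functions (explicit formulas, no d*() calls)
ln_norm <- function(x, mu, sd) -0.5 * log(2 * pi) - log(sd) -
  0.5 * ((x - mu) / sd)^2
ln_gamma <- function(x, shape, rate) shape * log(rate) - lgamma(shape) +
  (shape - 1) * log(x) - rate * x

test_that("the Bayesian-lasso log joint matches an independent calculator", {
  ds <- make_toy_dataset(n_per = 10, J = 2, p = 2, gamma = c(0.4, 0),
                         seed = 81)
  des <- build_design(ds)
  st <- list(a = c(0.1, -0.2), beta = c(0.3, 0.1), gamma = c(0.2, -0.1),
             delta = 0.9, d = c(1.0, 0.8), tau = 0.25, sigma = 0.6,
             lambda = 3)
  eta <- st$a[ds$study] + drop(ds$X %*% st$beta) +
    drop(ds$X %*% st$gamma) * ds$treatment + st$d[ds$study] * ds$treatment
  manual <- sum(ln_norm(ds$outcome, eta, st$sigma)) +
    sum(ln_norm(c(st$a, st$beta, st$delta), 0, sqrt(1000))) +
    sum(ln_norm(st$d, st$delta, st$tau)) +
    log(1 / 5) +                                      # tau ~ U(0,5)
    ln_gamma(1 / st$sigma^2, 0.001, 0.001) + log(2 / st$sigma^3) +
    sum(log(st$lambda / (2 * st$sigma)) -
          st$lambda * abs(st$gamma) / st$sigma) +     # Laplace(0, sigma/lambda)
    ln_gamma(st$lambda, 2, 0.1)
  expect_equal(log_posterior_blasso(st, des), manual, tolerance = 1e-10)

  # binary outcome uses the unconditional Laplace prior
  dsb <- make_toy_dataset(n_per = 10, J = 2, p = 2, gamma = c(0.4, 0),
                          outcome_type = "binary", seed = 82)
  desb <- build_design(dsb)
  stb <- st[setdiff(names(st), "sigma")]
  etab <- stb$a[dsb$study] + drop(dsb$X %*% stb$beta) +
    drop(dsb$X %*% stb$gamma) * dsb$treatment +
    stb$d[dsb$study] * dsb$treatment
  manualb <- sum(dsb$outcome * etab - log(1 + exp(etab))) +
    sum(ln_norm(c(stb$a, stb$beta, stb$delta), 0, sqrt(1000))) +
    sum(ln_norm(stb$d, stb$delta, stb$tau)) + log(1 / 5) +
    sum(log(stb$lambda / 2) - stb$lambda * abs(stb$gamma)) +
    ln_gamma(stb$lambda, 2, 0.1)
  expect_equal(log_posterior_blasso(stb, desb), manualb, tolerance = 1e-10)

  # out-of-support states
  expect_identical(log_posterior_blasso(modifyList(st, list(tau = -1)),
                                        des), -Inf)
  expect_identical(log_posterior_blasso(modifyList(st, list(lambda = 0)),
                                        des), -Inf)
})

test_that("vague normal priors are locally flat for the treatment effect", {
  ds <- make_toy_dataset(n_per = 20, J = 2, p = 2, seed = 83)
  des <- build_design(ds)
  st <- list(a = c(0, 0), beta = c(0.2, 0.2), gamma = c(0, 0),
             delta = 0.5, d = c(0.5, 0.5), tau = 0.2, sigma = 0.5,
             lambda = 2)
  st2 <- modifyList(st, list(delta = 1.0, d = c(1.0, 1.0)))
  lik_delta <- ipdshrink:::log_lik_ipd(st2, des) -
    ipdshrink:::log_lik_ipd(st, des) +
    sum(dnorm(st2$d, st2$delta, st2$tau, log = TRUE)) -
    sum(dnorm(st$d, st$delta, st$tau, log = TRUE))
  lp_delta <- log_posterior_blasso(st2, des) -
    log_posterior_blasso(st, des)
  # the only prior contribution is N(0, 1000) on delta: negligible
  expect_equal(lp_delta, lik_delta, tolerance = 1e-3)
  expect_false(isTRUE(all.equal(lp_delta, lik_delta, tolerance = 1e-9)))
})

test_that("the spike-and-slab log joint matches an independent calculator", {
  ds <- make_toy_dataset(n_per = 10, J = 2, p = 2, gamma = c(0.4, 0),
                         seed = 84)
  des <- build_design(ds)
  st <- list(a = c(0.1, -0.2), beta = c(0.3, 0.1), gamma = c(0.2, -0.1),
             delta = 0.9, d = c(1.0, 0.8), tau = 0.25, sigma = 0.6,
             ind = c(1, 0), eta = 0.5)
  eta_lin <- st$a[ds$study] + drop(ds$X %*% st$beta) +
    drop(ds$X %*% st$gamma) * ds$treatment + st$d[ds$study] * ds$treatment
  manual <- sum(ln_norm(ds$outcome, eta_lin, st$sigma)) +
    sum(ln_norm(c(st$a, st$beta, st$delta), 0, sqrt(1000))) +
    sum(ln_norm(st$d, st$delta, st$tau)) + log(1 / 5) +
    ln_gamma(1 / st$sigma^2, 0.001, 0.001) + log(2 / st$sigma^3) +
    ln_norm(st$gamma[1], 0, st$eta * 10) +    # slab: g = 100
    ln_norm(st$gamma[2], 0, st$eta) +         # spike
    2 * log(0.5) + log(1 / 5)                 # Bern(0.5) x2, eta ~ U(0,5)
  expect_equal(log_posterior_ssvs(st, des), manual, tolerance = 1e-10)

  # at gamma_m = 0 switching the indicator changes the prior by -log(g)/2
  st0 <- modifyList(st, list(gamma = c(0, -0.1)))
  st1 <- modifyList(st0, list(ind = c(0, 0)))
  expect_equal(log_posterior_ssvs(st0, des) - log_posterior_ssvs(st1, des),
               -0.5 * log(100), tolerance = 1e-10)

  # with g = 1 the mixture collapses: the indicator is irrelevant
  expect_equal(log_posterior_ssvs(st0, des, hyper = list(g = 1)),
               log_posterior_ssvs(st1, des, hyper = list(g = 1)),
               tolerance = 1e-12)
  expect_identical(log_posterior_ssvs(modifyList(st, list(eta = 6)), des),
                   -Inf)
})

test_that("Gelman-Rubin statistic behaves at its boundary cases", {
  const <- matrix(1, 100, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(gelman_rubin(list(const, const))), c(1, 1))
  expect_equal(unname(gelman_rubin(list(const, const * 2))),
               c(Inf, Inf))
  set.seed(85)
  iid <- function() matrix(rnorm(2000), 1000, 2,
                           dimnames = list(NULL, c("a", "b")))
  expect_lt(max(gelman_rubin(list(iid(), iid()))), 1.01)
  expect_error(gelman_rubin(list(const)))
})

test_that("the sampler reproduces a conjugate Gaussian sub-model", {
  # fixing sigma, tau, eta and the indicators makes the spike-and-slab
  # model jointly Gaussian; its posterior is available in closed form
  set.seed(86)
  n <- 60; J <- 2
  study <- rep(1:2, each = 30); t_i <- rbinom(n, 1, 0.5)
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rnorm(n, 0.3 + 0.2 * X[, 1] + 0.5 * X[, 1] * t_i + t_i, 0.5)
  ds <- standardize_covariates(
    ipd_data(study, t_i, y, X, outcome_type = "continuous"))
  sigma0 <- 0.5; tau0 <- 0.3; eta0 <- 0.4; ind0 <- c(1, 0)
  fit <- fit_ssvs(ds, mcmc_settings(n_iter = 6000, n_burnin = 500,
                                    seed = 86),
                  hyper = list(sigma_fixed = sigma0, tau_fixed = tau0,
                               eta_fixed = eta0, ind_fixed = ind0))
  des <- build_design(ds)
  # theta = (a1, a2, b1, b2, g1, g2, delta, d1, d2)
  M <- cbind(des$A[, 1:2], des$A[, 3:4], des$A[, 6:7], 0,
             des$A[, 5] * (study == 1), des$A[, 5] * (study == 2))
  P <- diag(c(rep(1e-3, 4),
              1 / (eta0^2 * ifelse(ind0 == 1, 100, 1)), 0, 0, 0))
  P[7, 7] <- 1e-3 + J / tau0^2
  P[7, 8] <- P[8, 7] <- P[7, 9] <- P[9, 7] <- -1 / tau0^2
  P[8, 8] <- P[9, 9] <- 1 / tau0^2
  prec_post <- crossprod(M) / sigma0^2 + P
  mu_post <- drop(solve(prec_post, crossprod(M, ds$outcome) / sigma0^2))
  sd_post <- sqrt(diag(solve(prec_post)))
  draws <- fit$draws[, c("delta", "gamma[1]", "gamma[2]")]
  mcse <- apply(draws, 2, sd) / sqrt(nrow(draws) / 10)  # conservative ESS
  est <- c(fit$delta_hat, unname(fit$gamma_hat))
  expect_true(all(abs(est - mu_post[c(7, 5, 6)]) < 3 * mcse))
  expect_equal(unname(apply(draws, 2, sd)), unname(sd_post[c(7, 5, 6)]),
               tolerance = 0.1)
})

test_that("prior-only runs reproduce the stated priors", {
  pr <- fit_bayes_lasso(NULL, mcmc_settings(n_iter = 2700, n_burnin = 200,
                                            seed = 87))
  lam <- pr$draws[, "lambda"]
  expect_equal(mean(lam), 20, tolerance = 3 * sd(lam) / sqrt(length(lam)))
  expect_equal(var(lam), 200, tolerance = 0.15 * 200)
  tau <- pr$draws[, "tau"]
  expect_gt(suppressWarnings(ks.test(tau, punif, 0, 5))$p.value, 0.01)

  prs <- fit_ssvs(NULL, mcmc_settings(n_iter = 2700, n_burnin = 200,
                                      seed = 88))
  incl <- mean(prs$draws[, "ind"])
  expect_equal(incl, 0.5, tolerance = 0.05)
  eta <- prs$draws[, "eta"]
  expect_gt(suppressWarnings(ks.test(eta, punif, 0, 5))$p.value, 0.01)
})

test_that("Bayesian fits are reproducible and shrink null interactions", {
  ds <- make_toy_dataset(n_per = 60, J = 2, p = 4,
                         gamma = c(0.8, 0, 0, 0), seed = 89)
  s <- mcmc_settings(n_iter = 1200, n_burnin = 200, seed = 90)
  f1 <- fit_bayes_lasso(ds, s)
  f2 <- fit_bayes_lasso(ds, s)
  expect_identical(f1$delta_hat, f2$delta_hat)
  expect_identical(f1$gamma_hat, f2$gamma_hat)

  full <- fit_glmm(ds)
  fs <- fit_ssvs(ds, s)
  null_idx <- 2:4
  # posterior means of null interactions sit closer to zero than the
  # unshrunk mixed-model estimates, and the true modifier dominates
  # the inclusion probabilities
  expect_lte(mean(abs(f1$gamma_hat[null_idx])),
             mean(abs(full$gamma_hat[null_idx])))
  expect_lte(mean(abs(fs$gamma_hat[null_idx])),
             mean(abs(full$gamma_hat[null_idx])))
  expect_gt(fs$inclusion_prob[1], max(fs$inclusion_prob[null_idx]))
  expect_true(all(fs$inclusion_prob >= 0 & fs$inclusion_prob <= 1))
  # credible intervals are ordered
  expect_true(all(f1$credible[, 1] <= f1$credible[, 2]))
})
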