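fake_fit <- function(delta, gamma, scaling = NULL, ...) {
  structure(list(delta_hat = delta,
                 gamma_hat = setNames(gamma,
                                      paste0("x", seq_along(gamma))),
                 interaction_subset = seq_along(gamma),
                 scaling = scaling, ...),
            class = "ipd_fit")
}

test_that("patient-specific effects follow delta + gamma'x", {
  fit <- fake_fit(1, c(0.5, 0))
  expect_equal(patient_specific_te(fit, rbind(c(2, 3))), 2.0)
  expect_equal(patient_specific_te(fit, rbind(c(0, 0))), 1.0)
  # no interactions: every patient gets the average effect
  fit0 <- fake_fit(0.7, c(0, 0))
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(patient_specific_te(fit0, X), rep(0.7, 10))
  expect_error(patient_specific_te(fit, matrix(0, 2, 3)))
})

test_that("patient-specific MSE matches brute force and its decomposition", {
  ds <- make_toy_dataset(n_per = 5, J = 2, p = 2, seed = 91)
  truth <- structure(list(delta = 1, gamma = c(0.3, 0), beta = c(0.2, 0.2),
                          em_indices = 1L), class = "ipd_truth")
  # perfect recovery
  expect_equal(pste_mse(fake_fit(1, c(0.3, 0)), truth, ds), 0)
  # pure bias in delta with correct gammas: exactly the squared bias
  expect_equal(pste_mse(fake_fit(1.1, c(0.3, 0)), truth, ds), 0.01)
  # arbitrary fit equals the direct patient-level computation
  fit <- fake_fit(0.8, c(-0.2, 0.4))
  direct <- mean(((0.8 + ds$X %*% c(-0.2, 0.4)) -
                  (1 + ds$X %*% c(0.3, 0)))^2)
  expect_equal(pste_mse(fit, truth, ds), direct, tolerance = 1e-12)
})

test_that("average-treatment-effect and interaction MSEs are as defined", {
  truth <- structure(list(delta = 1, gamma = c(0.2, 0.2, 0),
                          em_indices = c(1L, 2L)), class = "ipd_truth")
  expect_equal(ate_mse(fake_fit(1, c(0, 0, 0)), truth), 0)
  expect_equal(ate_mse(fake_fit(0.8, c(0, 0, 0)), truth), 0.04)
  # all interactions shrunk to zero: true-modifier MSE is gamma^2
  expect_equal(em_mse(fake_fit(1, c(0, 0, 0)), truth, "true"), 0.04)
  expect_equal(em_mse(fake_fit(1, c(0, 0, 0.3)), truth, "false"), 0.09)
  # no true modifiers: the true-modifier MSE is undefined
  truth0 <- structure(list(delta = 1, gamma = c(0, 0, 0),
                           em_indices = integer(0)), class = "ipd_truth")
  expect_true(is.na(em_mse(fake_fit(1, c(0, 0, 0)), truth0, "true")))
  expect_equal(em_mse(fake_fit(1, c(0.1, 0, 0)), truth0, "false"),
               0.01 / 3)
})

test_that("bootstrap SEs: degenerate, deterministic, and near-analytic", {
  ds <- make_toy_dataset(n_per = 40, J = 2, p = 2, seed = 92)
  # estimator that ignores the data: zero bootstrap SE
  const_fun <- function(d) fake_fit(0.5, c(0, 0))
  bs <- bootstrap_se(const_fun, ds, B = 10)
  expect_equal(unname(bs$se), rep(0, 3))
  # determinism under a fixed seed
  fit_fun <- function(d) fit_penalized(d, penalty_spec("L1", 0.01))
  set.seed(93); bs1 <- bootstrap_se(fit_fun, ds, B = 15)
  set.seed(93); bs2 <- bootstrap_se(fit_fun, ds, B = 15)
  expect_identical(bs1$draws, bs2$draws)
  expect_true(all(bs1$ci[, 1] <= bs1$ci[, 2]))
})

test_that("bootstrap SE of the treatment effect approaches the OLS SE", {
  # single large study, no interactions: delta_hat is an OLS coefficient
  ds <- make_toy_dataset(n_per = 400, J = 1, p = 2, seed = 94)
  des <- build_design(ds, interaction_subset = integer(0))
  df <- as.data.frame(des$A); names(df) <- paste0("c", seq_along(df))
  df$y <- des$y
  ols <- summary(lm(y ~ 0 + ., data = df))
  analytic_se <- coef(ols)[paste0("c", des$idx_treat), "Std. Error"]
  fit_fun <- function(d) {
    fit <- fit_penalized(d, penalty_spec("L1", 0),
                         interaction_subset = integer(0))
    fit$gamma_hat[] <- 0
    fit
  }
  set.seed(95)
  bs <- bootstrap_se(fit_fun, ds, B = 400)
  expect_equal(unname(bs$se["delta"]), unname(analytic_se),
               tolerance = 0.15)
})

test_that("subgroup prediction standardizes profiles and forms intervals", {
  raw <- make_toy_dataset(n_per = 80, J = 2, p = 2, gamma = c(0.5, 0),
                          outcome_type = "binary", seed = 96,
                          standardize = FALSE)
  std <- standardize_covariates(raw)
  fit <- fit_glmm(std)
  # profile at the raw covariate means standardizes to x* = 0: the
  # subgroup effect is the average treatment effect, OR = exp(delta)
  prof_mean <- subgroup_profile(x1 = mean(raw$X[, 1]),
                                x2 = mean(raw$X[, 2]))
  pred <- predict_subgroup(fit, prof_mean)
  expect_equal(pred$effect, fit$delta_hat, tolerance = 1e-10)
  expect_equal(pred$odds_ratio, exp(fit$delta_hat), tolerance = 1e-10)
  expect_true(pred$lower < pred$effect && pred$effect < pred$upper)

  # hand-computed example: binary covariate with mean 0.5, SD 0.5,
  # raw value 1 -> standardized 1; gamma = (0.5, 0), delta = 1 -> 1.5
  toy <- fake_fit(1, c(0.5, 0),
                  scaling = list(mean = c(x1 = 0.5, x2 = 0),
                                 sd = c(x1 = 0.5, x2 = 1)))
  expect_equal(predict_subgroup(toy, subgroup_profile(x1 = 1, x2 = 0))$effect,
               1 + 0.5 * 1)

  # null fit: OR = 1 for any profile
  null_fit <- fake_fit(0, c(0, 0), outcome_type = "binary",
                       scaling = list(mean = c(x1 = 0, x2 = 0),
                                      sd = c(x1 = 1, x2 = 1)))
  expect_equal(predict_subgroup(null_fit,
                                subgroup_profile(x1 = 3, x2 = -2))$odds_ratio,
               1)

  expect_error(predict_subgroup(fit, subgroup_profile(x1 = 0)), "missing")
  expect_error(predict_subgroup(fit, subgroup_profile(x1 = 0, x2 = 0,
                                                      zz = 1)), "unknown")
})

test_that("every estimator's subgroup effect at the mean profile is its ATE", {
  raw <- make_toy_dataset(n_per = 60, J = 2, p = 2, gamma = c(0.4, 0),
                          seed = 97, standardize = FALSE)
  std <- standardize_covariates(raw)
  prof <- subgroup_profile(x1 = mean(raw$X[, 1]), x2 = mean(raw$X[, 2]))
  fits <- list(fit_glmm(std), fit_step(std),
               fit_penalized(std, penalty_spec("L1", 0.05)),
               fit_penalized(std, penalty_spec("L2", 0.05)))
  for (f in fits)
    expect_equal(predict_subgroup(f, prof)$effect, f$delta_hat,
                 tolerance = 1e-10)
})
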