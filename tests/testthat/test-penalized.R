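test_that("lambda grid is log-equispaced and inclusive", {
  g <- lambda_grid()
  expect_length(g, 61)
  expect_equal(g[1], 0.001)
  expect_equal(g[61], 1000)
  expect_equal(diff(log(g)), rep(diff(log(c(0.001, 1000))) / 60, 60))
  expect_equal(lambda_grid(3, 0.01, 1), c(0.01, 0.1, 1))
  expect_equal(lambda_grid(2, 0.5, 2), c(0.5, 2))
  expect_error(lambda_grid(3, 1, 0.5))
})

test_that("the penalized objective matches direct arithmetic", {
  # three patients, two studies, one covariate, worked by hand
  ds <- ipd_data(c(1, 1, 2), c(0, 1, 1), c(1.0, 2.0, 0.5),
                 cbind(x1 = c(-1, 0, 1)))
  des <- build_design(ds)  # columns: s1 s2 x1 t x1:t
  coefs <- c(0.5, 0.2, 0.3, 1.0, 0.4)
  eta <- c(0.5 + 0.3 * (-1),
           0.5 + 1.0,
           0.2 + 0.3 * 1 + 1.0 + 0.4 * 1)
  manual_loss <- sum((c(1, 2, 0.5) - eta)^2) / 6
  expect_equal(penalized_objective(coefs, des, penalty_spec("L1", 2)),
               manual_loss + 2 * 0.4)
  expect_equal(penalized_objective(coefs, des, penalty_spec("L2", 2)),
               manual_loss + 2 * 0.16)
  expect_equal(
    penalized_objective(coefs, des,
                        penalty_spec("adaptive", 2, weights = 3)),
    manual_loss + 2 * 3 * 0.4)
  # zero interaction coefficient: penalty term vanishes at any lambda
  coefs0 <- c(0.5, 0.2, 0.3, 1.0, 0)
  expect_equal(penalized_objective(coefs0, des, penalty_spec("L1", 50)),
               penalized_objective(coefs0, des, penalty_spec("L1", 0)))
})

test_that("penalized fits at lambda = 0 reduce to the unpenalized GLM", {
  for (otype in c("continuous", "binary")) {
    ds <- make_toy_dataset(n_per = 60, J = 2, p = 3, gamma = c(0.5, 0, 0),
                           outcome_type = otype, seed = 21)
    ref <- glm_reference(ds)
    for (type in c("L1", "L2")) {
      fit <- fit_penalized(ds, penalty_spec(type, 0))
      expect_equal(fit$delta_hat, unname(ref["t"]), tolerance = 1e-6)
      expect_equal(unname(fit$gamma_hat),
                   unname(ref[grepl(":t$", names(ref))]),
                   tolerance = 1e-6)
      expect_equal(unname(fit$beta_hat), unname(ref[c("x1", "x2", "x3")]),
                   tolerance = 1e-6)
    }
  }
})

test_that("an overwhelming penalty removes interactions but nothing else", {
  ds <- make_toy_dataset(n_per = 60, J = 2, p = 3, gamma = c(0.5, 0.3, 0),
                         seed = 22)
  fit <- fit_penalized(ds, penalty_spec("L1", 1e6))
  expect_identical(unname(fit$gamma_hat), rep(0, 3))  # exactly zero
  ref0 <- glm_reference(ds, interaction_subset = integer(0))
  expect_equal(fit$delta_hat, unname(ref0["t"]), tolerance = 1e-6)
  expect_equal(unname(fit$beta_hat), unname(ref0[c("x1", "x2", "x3")]),
               tolerance = 1e-6)
  # ridge shrinks towards but not exactly to zero at moderate lambda
  frid <- fit_penalized(ds, penalty_spec("L2", 0.5))
  expect_true(all(frid$gamma_hat != 0))
  expect_lt(sum(abs(frid$gamma_hat)), 0.5 + 0.3)
  # and essentially to zero at an enormous one
  frid_big <- fit_penalized(ds, penalty_spec("L2", 1e6))
  expect_lt(max(abs(frid_big$gamma_hat)), 1e-4)
})

test_that("partial ridge equals its closed-form solution", {
  for (s in 1:20) {
    ds <- make_toy_dataset(n_per = 25, J = 2, p = 3,
                           gamma = runif(3, -1, 1), seed = 300 + s)
    lam <- exp(runif(1, log(0.01), log(10)))
    fit <- fit_penalized(ds, penalty_spec("L2", lam))
    des <- build_design(ds)
    # independent route: full normal equations on the raw design
    N <- length(des$y)
    D <- numeric(ncol(des$A)); D[des$idx_int] <- 1
    theta_cf <- solve(crossprod(des$A) + 2 * N * lam * diag(D),
                      crossprod(des$A, des$y))
    expect_equal(unname(fit$gamma_hat),
                 unname(theta_cf[des$idx_int]), tolerance = 1e-8)
    expect_equal(fit$delta_hat, theta_cf[des$idx_treat], tolerance = 1e-8)
  }
})

test_that("solutions satisfy the stationarity (KKT) conditions", {
  for (otype in c("continuous", "binary")) {
    ds <- make_toy_dataset(n_per = 80, J = 2, p = 4,
                           gamma = c(0.8, 0.3, 0, 0),
                           outcome_type = otype, seed = 31)
    des <- build_design(ds)
    for (spec in list(penalty_spec("L1", 0.05),
                      penalty_spec("L2", 0.05),
                      penalty_spec("adaptive", 0.05,
                                   weights = c(0.5, 1, 2, 4)))) {
      fit <- fit_penalized(ds, spec)
      theta <- c(fit$intercepts, fit$beta_hat, fit$delta_hat,
                 fit$gamma_hat)
      expect_lt(ipdshrink:::kkt_violation(theta, des, spec), 1e-6)
    }
  }
})

test_that("the lasso coefficient path shrinks monotonically in lambda", {
  ds <- make_toy_dataset(n_per = 70, J = 2, p = 4,
                         gamma = c(0.8, 0.3, 0, 0), seed = 41)
  l1_norm <- vapply(lambda_grid(), function(l)
    sum(abs(fit_penalized(ds, penalty_spec("L1", l))$gamma_hat)),
    numeric(1))
  expect_true(all(diff(l1_norm) <= 1e-8))
  expect_equal(l1_norm[61], 0)  # fully shrunk at lambda = 1000
})

test_that("coordinate descent agrees with glmnet's penalty.factor route", {
  # glmnet scales the objective identically ((1/2N) RSS + lambda pen)
  # but rescales penalty factors to sum to the number of columns
  for (otype in c("continuous", "binary")) {
    ds <- make_toy_dataset(n_per = 100, J = 2, p = 3,
                           gamma = c(0.6, 0.2, 0), outcome_type = otype,
                           seed = 51)
    des <- build_design(ds)
    pf <- numeric(ncol(des$A)); pf[des$idx_int] <- 1
    for (lam in c(0.02, 0.1)) {
      fit <- fit_penalized(ds, penalty_spec("L1", lam))
      gn <- glmnet::glmnet(
        des$A, des$y,
        family = if (otype == "continuous") "gaussian" else "binomial",
        alpha = 1, penalty.factor = pf, standardize = FALSE,
        intercept = FALSE, lambda = lam * sum(pf) / ncol(des$A),
        thresh = 1e-12)
      theta_gn <- as.numeric(coef(gn))[-1]
      expect_equal(unname(fit$gamma_hat), theta_gn[des$idx_int],
                   tolerance = 2e-3)
      expect_equal(fit$delta_hat, theta_gn[des$idx_treat],
                   tolerance = 2e-3)
    }
  }
})

test_that("adaptive weighting reduces to plain lasso under equal weights", {
  ds <- make_toy_dataset(n_per = 60, J = 2, p = 3, gamma = c(0.5, 0, 0),
                         seed = 61)
  fit_ad <- fit_penalized(ds, penalty_spec("adaptive", 0.05,
                                           weights = rep(2, 3)))
  fit_l1 <- fit_penalized(ds, penalty_spec("L1", 0.10))
  expect_equal(fit_ad$gamma_hat, fit_l1$gamma_hat, tolerance = 1e-8)
  # lambda = 0: weights are irrelevant
  fit_ad0 <- fit_penalized(ds, penalty_spec("adaptive", 0,
                                            weights = c(10, 1, 0.1)))
  ref <- glm_reference(ds)
  expect_equal(unname(fit_ad0$gamma_hat),
               unname(ref[grepl(":t$", names(ref))]), tolerance = 1e-6)
})
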