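# Small deterministic multi-study datasets built in code, independent
# of the package's own simulator (which has its own tests).
make_toy_dataset <- function(n_per = 50, J = 2, p = 3,
                             outcome_type = "continuous",
                             delta = 1, gamma = rep(0, p),
                             beta = rep(0.2, p), intercepts = NULL,
                             d_j = NULL, sigma = 0.5, seed = 1,
                             standardize = TRUE) {
  set.seed(seed)
  study <- rep(seq_len(J), each = n_per)
  n <- length(study)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  t_i <- rbinom(n, 1, 0.5)
  if (is.null(intercepts)) intercepts <- seq(-0.5, 0.5, length.out = J)
  if (is.null(d_j)) d_j <- rep(delta, J)
  eta <- intercepts[study] + drop(X %*% beta) +
    drop(X %*% gamma) * t_i + d_j[study] * t_i
  y <- if (outcome_type == "continuous") rnorm(n, eta, sigma)
       else rbinom(n, 1, plogis(eta))
  ds <- ipd_data(study, t_i, y, X, outcome_type = outcome_type)
  if (standardize) ds <- standardize_covariates(ds) else ds
}

# unpenalized common-effects GLM on the same design, fitted through
# stats::glm -- the independent reference for lambda = 0 reductions
glm_reference <- function(dataset, interaction_subset = NULL) {
  design <- build_design(dataset, interaction_subset)
  df <- as.data.frame(design$A)
  names(df) <- paste0("c", seq_len(ncol(design$A)))
  df$y <- design$y
  fam <- if (dataset$outcome_type == "continuous") gaussian() else binomial()
  fit <- glm(y ~ 0 + ., data = df, family = fam)
  setNames(coef(fit), colnames(design$A))
}
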