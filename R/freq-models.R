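# paste0 recycles zero-length inputs to ""; formula terms need a true
# empty when the index set is empty
term_names <- function(prefix, idx) {
  if (!length(idx)) character(0) else paste0(prefix, idx)
}

# Internal: model frame with safe column names shared by lme4/glm fits.
# Covariates become .x1...xp, interaction columns .i<m> (m = covariate
# index), treatment .t, study a factor .s.
glmm_frame <- function(dataset, interaction_subset) {
  p <- ncol(dataset$X)
  df <- as.data.frame(dataset$X)
  names(df) <- paste0(".x", seq_len(p))
  for (m in interaction_subset)
    df[[paste0(".i", m)]] <- dataset$X[, m] * dataset$treatment
  df$.t <- dataset$treatment
  df$.s <- factor(dataset$study)
  df$.y <- dataset$outcome
  df
}

# Internal: assemble an ipd_fit from a fixed-effect vector/SE table.
fit_from_fixef <- function(method, dataset, interaction_subset, fe, se_fe,
                           vcov_fe = NULL, ...) {
  p <- ncol(dataset$X)
  cn <- dataset$covariate_meta$name
  pick <- function(v, nm, default = 0) {
    out <- setNames(rep(default, length(nm)), nm)
    hit <- intersect(nm, names(v))
    out[hit] <- v[hit]
    out
  }
  main_nm <- paste0(".x", seq_len(p))
  int_nm <- paste0(".i", seq_len(p))
  study_nm <- paste0(".s", seq_len(dataset$n_studies))
  beta_hat <- setNames(pick(fe, main_nm), cn)
  gamma_hat <- setNames(pick(fe, int_nm), cn)
  dg_nm <- c(".t", intersect(int_nm, names(fe)))
  vcov_dg <- NULL
  if (!is.null(vcov_fe)) {
    vcov_dg <- vcov_fe[dg_nm, dg_nm, drop = FALSE]
    attr(vcov_dg, "cov_idx") <- as.integer(sub("^\\.i", "", dg_nm[-1]))
  }
  new_ipd_fit(
    method = method,
    delta_hat = fe[[".t"]],
    beta_hat = beta_hat, gamma_hat = gamma_hat,
    intercepts = pick(fe, study_nm),
    interaction_subset = interaction_subset,
    scaling = dataset$scaling,
    outcome_type = dataset$outcome_type,
    se = list(delta = unname(se_fe[".t"]),
              beta = setNames(pick(se_fe, main_nm, NA_real_), cn),
              gamma = setNames(pick(se_fe, int_nm, NA_real_), cn)),
    vcov_dg = vcov_dg,
    ...)
}

#' Fit a one-stage mixed model with a random treatment effect
#'
#' The reference estimator: a generalized linear mixed model with fixed
#' study-specific intercepts, fixed (common) covariate main effects and
#' treatment-covariate interaction coefficients, and a study-level
#' random treatment effect \eqn{d_j \sim N(\delta, \tau^2)}.  With
#' \code{interaction_subset} covering all covariates this is the
#' "full" model; restricting it to the true effect modifiers gives the
#' "oracle" benchmark.  Continuous outcomes use a linear mixed model,
#' binary outcomes a logistic mixed model estimated by the Laplace
#' approximation.  Singular fits (\eqn{\hat\tau = 0}) are permitted;
#' convergence messages are collected in the result's
#' \code{diagnostics}.
#'
#' @param dataset a standardized [ipd_data].
#' @param interaction_subset covariate indices whose interactions enter
#'   the model (default all).
#' @param main_subset covariate indices whose main effects enter the
#'   model (default all; the oracle restricts these to the covariates
#'   that generated the data).
#' @param method label stored in the result.
#' @return An \code{ipd_fit} with \code{delta_hat} (the mean of the
#'   random treatment effect), \code{tau_hat}, fixed-effect SEs, and —
#'   for continuous outcomes — \code{sigma_hat}.
#' @export
fit_glmm <- function(dataset, interaction_subset = NULL,
                     main_subset = NULL, method = "glmm-full") {
  stopifnot(inherits(dataset, "ipd_data"))
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  if (is.null(main_subset)) main_subset <- seq_len(p)
  interaction_subset <- sort(as.integer(interaction_subset))
  main_subset <- sort(unique(c(as.integer(main_subset),
                               interaction_subset)))
  df <- glmm_frame(dataset, interaction_subset)
  rhs <- paste(c("0", ".s", term_names(".x", main_subset), ".t",
                 term_names(".i", interaction_subset),
                 "(0 + .t | .s)"), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))
  msgs <- character(0)
  fit <- withCallingHandlers({
    if (dataset$outcome_type == "continuous")
      lme4::lmer(fml, data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE))
    else
      lme4::glmer(fml, data = df, family = binomial(), nAGQ = 1L,
                  control = lme4::glmerControl(calc.derivs = FALSE))
  }, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  }, message = function(m) {
    msgs <<- c(msgs, conditionMessage(m))
    invokeRestart("muffleMessage")
  })
  fe <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  dimnames(V) <- list(names(fe), names(fe))
  tau_hat <- sqrt(as.numeric(lme4::VarCorr(fit)$.s[".t", ".t"]))
  fit_from_fixef(method, dataset, interaction_subset,
                 fe = fe, se_fe = setNames(sqrt(diag(V)), names(fe)),
                 vcov_fe = V,
                 tau_hat = tau_hat,
                 sigma_hat = if (dataset$outcome_type == "continuous")
                   sigma(fit) else NULL,
                 diagnostics = list(messages = msgs,
                                    singular = lme4::isSingular(fit)))
}

#' Bidirectional stepwise selection of interaction terms
#'
#' Common-effects GLM (fixed study intercepts, fixed treatment effect,
#' all main effects) in which only the treatment-covariate interaction
#' terms are subject to selection.  Starting from the model with the
#' full interaction set, each step evaluates all single-term additions
#' and deletions of interaction terms and takes the best improvement of
#' the criterion, stopping when none improves.  Main effects, the
#' treatment term and the study intercepts are always retained.
#' Standard errors come from the final model as if it had been
#' prespecified, i.e. they ignore the selection step.
#'
#' @param dataset a standardized [ipd_data].
#' @param criterion \code{"AIC"} (default) or \code{"BIC"}.
#' @param start \code{"full"} (default) to start from all interactions,
#'   \code{"null"} to start from none.
#' @param interaction_subset candidate interaction indices (default all).
#' @return An \code{ipd_fit}; unselected interactions have
#'   \code{gamma_hat} exactly 0.  \code{diagnostics$selected} holds the
#'   selected covariate indices and \code{diagnostics$criterion_value}
#'   the final criterion value.
#' @export
fit_step <- function(dataset, criterion = c("AIC", "BIC"),
                     start = c("full", "null"),
                     interaction_subset = NULL) {
  stopifnot(inherits(dataset, "ipd_data"))
  criterion <- match.arg(criterion)
  start <- match.arg(start)
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  interaction_subset <- sort(as.integer(interaction_subset))
  df <- glmm_frame(dataset, interaction_subset)
  fam <- if (dataset$outcome_type == "continuous") gaussian() else binomial()
  base_rhs <- paste(c("0", ".s", paste0(".x", seq_len(p)), ".t"),
                    collapse = " + ")
  int_terms <- term_names(".i", interaction_subset)
  lower <- as.formula(paste(".y ~", base_rhs))
  upper <- as.formula(paste(".y ~", paste(c(base_rhs, int_terms),
                                          collapse = " + ")))
  init <- glm(if (start == "full") upper else lower, family = fam, data = df)
  k <- if (criterion == "AIC") 2 else log(nrow(df))
  sel <- step(init, scope = list(lower = lower, upper = upper),
              direction = "both", k = k, trace = 0)
  fe <- coef(sel)
  V <- vcov(sel)
  selected <- interaction_subset[paste0(".i", interaction_subset) %in%
                                   names(fe)]
  fit_from_fixef(paste0("step-", tolower(criterion)), dataset,
                 interaction_subset,
                 fe = fe, se_fe = sqrt(diag(V)), vcov_fe = V,
                 sigma_hat = if (dataset$outcome_type == "continuous")
                   sqrt(summary(sel)$dispersion) else NULL,
                 diagnostics = list(selected = selected,
                                    criterion = criterion,
                                    criterion_value =
                                      if (criterion == "AIC") AIC(sel)
                                      else BIC(sel)))
}
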