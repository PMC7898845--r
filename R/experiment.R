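#' Model labels understood by the replication harness
#' @return Character vector of the seven (eight counting the oracle)
#'   model labels.
#' @export
model_labels <- function() {
  c("glmm-oracle", "glmm-full", "step", "lasso", "ridge",
    "adaptive-lasso", "bayes-lasso", "ssvs")
}

#' Fit one model by label
#'
#' Dispatcher used by [run_scenario()] and the command-line interface.
#' The oracle model needs the truth record to know the generating
#' interaction subset (it falls back to the full set with a warning if
#' no truth is given).
#'
#' @param label one of [model_labels()].
#' @param dataset a standardized [ipd_data].
#' @param truth optional \code{ipd_truth} (oracle model only).
#' @param settings [mcmc_settings()] for the Bayesian models.
#' @param grid,k penalty grid and fold count for the penalized models.
#' @return An \code{ipd_fit}.
#' @export
fit_model <- function(label, dataset, truth = NULL,
                      settings = mcmc_settings(),
                      grid = lambda_grid(), k = 10) {
  switch(label,
    "glmm-full" = fit_glmm(dataset, method = "glmm-full"),
    "glmm-oracle" = {
      if (is.null(truth)) {
        warning("no truth supplied; oracle falls back to all interactions")
        fit_glmm(dataset, method = "glmm-oracle")
      } else {
        # the oracle keeps the main effects of the covariates that
        # generated the data and the interactions of the true effect
        # modifiers; with no true effect modifiers it fits an
        # interaction-free model
        fit_glmm(dataset,
                 interaction_subset = truth$em_indices,
                 main_subset = which(truth$beta != 0 | truth$gamma != 0),
                 method = "glmm-oracle")
      }
    },
    "step" = fit_step(dataset),
    "lasso" = fit_lasso(dataset, grid = grid, k = k),
    "ridge" = fit_ridge(dataset, grid = grid, k = k),
    "adaptive-lasso" = fit_adaptive_lasso(dataset, grid = grid, k = k),
    "bayes-lasso" = fit_bayes_lasso(dataset, settings = settings),
    "ssvs" = fit_ssvs(dataset, settings = settings),
    stop("unknown model label: ", label))
}

#' Run one simulation scenario across models and replicates
#'
#' For each replicate: simulate a dataset from the scenario,
#' standardize it, fit every requested model, and record the
#' performance measures.  Replicate r uses RNG seed
#' \code{master_seed + r} for data generation (and seeds the Bayesian
#' chains from the same value), so results are reproducible and
#' independent of execution order.  A model failure in a replicate is
#' logged and that (model, replicate) cell excluded from aggregation.
#'
#' @param scenario an \code{ipd_scenario} from [make_scenario()] or a
#'   scenario id string.
#' @param models character vector of [model_labels()] (default: all).
#' @param n_replicates number of simulated datasets.
#' @param master_seed integer master seed.
#' @param settings [mcmc_settings()] for Bayesian models.
#' @param grid,k penalty grid and fold count for penalized models.
#' @return Data frame of per-(replicate, model) metric rows with
#'   columns \code{scenario_id}, \code{method}, \code{replicate},
#'   \code{pste_mse}, \code{ate_mse}, \code{true_em_mse},
#'   \code{false_em_mse}, \code{se_delta}, \code{tau_hat},
#'   \code{error} (message or NA).  Class \code{ipd_metrics}.
#' @export
run_scenario <- function(scenario, models = model_labels(),
                         n_replicates = 10, master_seed = 1,
                         settings = mcmc_settings(),
                         grid = lambda_grid(), k = 10) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  stopifnot(inherits(scenario, "ipd_scenario"),
            all(models %in% model_labels()), n_replicates >= 1)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    set.seed(master_seed + r)
    sim <- simulate_ipd(scenario)
    ds <- standardize_covariates(sim$dataset)
    set_b <- settings
    set_b$seed <- (master_seed + r) %% .Machine$integer.max
    for (label in models) {
      res <- tryCatch({
        fit <- suppressWarnings(
          fit_model(label, ds, truth = sim$truth, settings = set_b,
                    grid = grid, k = k))
        data.frame(scenario_id = scenario$scenario_id, method = label,
                   replicate = r,
                   pste_mse = pste_mse(fit, sim$truth, ds),
                   ate_mse = ate_mse(fit, sim$truth),
                   true_em_mse = em_mse(fit, sim$truth, "true"),
                   false_em_mse = em_mse(fit, sim$truth, "false"),
                   se_delta = fit$se$delta %||% NA_real_,
                   tau_hat = fit$tau_hat %||% NA_real_,
                   error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(scenario_id = scenario$scenario_id, method = label,
                   replicate = r, pste_mse = NA_real_, ate_mse = NA_real_,
                   true_em_mse = NA_real_, false_em_mse = NA_real_,
                   se_delta = NA_real_, tau_hat = NA_real_,
                   error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ipd_metrics", class(out))
  out
}

#' Aggregate per-replicate metrics
#'
#' Per (scenario, method): the number of successful replicates, the
#' mean of each performance measure, and its Monte-Carlo standard
#' error (SD across replicates / sqrt(n)); \code{NA} with a single
#' replicate.
#'
#' @param rows metric rows from [run_scenario()] (possibly several,
#'   row-bound).
#' @return Data frame, one row per (scenario, method).
#' @export
aggregate_results <- function(rows) {
  stopifnot(nrow(rows) > 0)
  metrics <- c("pste_mse", "ate_mse", "true_em_mse", "false_em_mse",
               "se_delta", "tau_hat")
  keys <- unique(rows[c("scenario_id", "method")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- rows[rows$scenario_id == keys$scenario_id[i] &
                rows$method == keys$method[i], ]
    ok <- sub[is.na(sub$error), ]
    res <- data.frame(scenario_id = keys$scenario_id[i],
                      method = keys$method[i],
                      n_ok = nrow(ok), n_failed = sum(!is.na(sub$error)),
                      stringsAsFactors = FALSE)
    for (m in metrics) {
      v <- ok[[m]][!is.na(ok[[m]])]
      res[[paste0("mean_", m)]] <- if (length(v)) mean(v) else NA_real_
      res[[paste0("mcse_", m)]] <- if (length(v) > 1)
        sd(v) / sqrt(length(v)) else NA_real_
    }
    res
  }))
  rownames(out) <- NULL
  out
}
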