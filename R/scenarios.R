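#' Catalog of simulation scenarios
#'
#' Returns the shipped catalog of 72 simulation scenarios as a data
#' frame, one row per scenario id.  Ids are prefixed \code{C}
#' (continuous outcome) or \code{B} (binary outcome).  Scenarios 1-28
#' form pairs differing only in the number of studies (odd id: 5
#' studies, even id: 10) and cover: 10 covariates (5 nuisance) with 0
#' or 1 effect modifier, or 15 covariates (8 nuisance) with 2 or 3
#' effect modifiers; small or large effect modification; and treatment
#' effect heterogeneity tau of 0.2 or 0.5.  Scenarios 29-36 are special
#' settings shown in pairs differing in heterogeneity: all 10
#' covariates effect modifiers (29, 30; small modification for
#' continuous, large for binary), uniform instead of normal random
#' effects with half-width 0.4 (31) or 1.0 (32), study sizes drawn from
#' Uniform(50, 500) (33, 34), and 30 covariates with a single effect
#' modifier (35, 36).
#'
#' The within-pair ordering of the standard scenarios (which ids carry
#' which number of effect modifiers, magnitude, and tau) is the
#' package's own catalog convention; edit the data frame, or a JSON
#' copy written with \code{\link{write_scenario_catalog}}, to change
#' any pairing.
#'
#' @param file optional path to a JSON catalog (as produced by
#'   \code{write_scenario_catalog}) to load instead of the built-in one.
#' @return Data frame with one row per scenario and columns
#'   \code{scenario_id}, \code{outcome_type}, \code{n_studies},
#'   \code{n_covariates}, \code{n_nuisance}, \code{n_em},
#'   \code{em_magnitude}, \code{tau}, \code{random_effect_dist},
#'   \code{re_halfwidth}, \code{n_patients_lo}, \code{n_patients_hi}.
#' @export
scenario_catalog <- function(file = NULL) {
  if (!is.null(file)) {
    df <- jsonlite::read_json(file, simplifyVector = TRUE)
    return(as.data.frame(df, stringsAsFactors = FALSE))
  }
  base_pairs <- expand.grid(
    tau = c(0.2, 0.5),
    em_magnitude = c("small", "large"),
    block = 1:4,  # 1: p10/em0, 2: p10/em1, 3: p15/em2, 4: p15/em3
    stringsAsFactors = FALSE)
  base_pairs$n_covariates <- c(10, 10, 15, 15)[base_pairs$block]
  base_pairs$n_nuisance <- c(5, 5, 8, 8)[base_pairs$block]
  base_pairs$n_em <- c(0, 1, 2, 3)[base_pairs$block]
  # no-effect-modifier block has no magnitude dimension
  base_pairs <- base_pairs[!(base_pairs$n_em == 0 &
                             base_pairs$em_magnitude == "large"), ]
  base_pairs$em_magnitude[base_pairs$n_em == 0] <- "none"
  ord <- order(base_pairs$block, base_pairs$em_magnitude != "small",
               base_pairs$tau)
  base_pairs <- base_pairs[ord, ]
  rows <- do.call(rbind, lapply(seq_len(nrow(base_pairs)), function(k) {
    b <- base_pairs[k, ]
    data.frame(num = 2 * (k - 1) + 1:2, n_studies = c(5L, 10L),
               n_covariates = b$n_covariates, n_nuisance = b$n_nuisance,
               n_em = b$n_em, em_magnitude = b$em_magnitude, tau = b$tau,
               random_effect_dist = "normal", re_halfwidth = NA_real_,
               n_patients_lo = 50L, n_patients_hi = 100L,
               stringsAsFactors = FALSE)
  }))
  special <- data.frame(
    num = 29:36, n_studies = 5L,
    n_covariates = c(10L, 10L, 10L, 10L, 10L, 10L, 30L, 30L),
    n_nuisance   = c(0L, 0L, 5L, 5L, 5L, 5L, 24L, 24L),
    n_em         = c(10L, 10L, 1L, 1L, 1L, 1L, 1L, 1L),
    em_magnitude = "small",
    tau          = c(0.2, 0.5, NA, NA, 0.2, 0.5, 0.2, 0.5),
    random_effect_dist = c("normal", "normal", "uniform", "uniform",
                           "normal", "normal", "normal", "normal"),
    re_halfwidth = c(NA, NA, 0.4, 1.0, NA, NA, NA, NA),
    n_patients_lo = 50L,
    n_patients_hi = c(100L, 100L, 100L, 100L, 500L, 500L, 100L, 100L),
    stringsAsFactors = FALSE)
  all_rows <- rbind(rows, special)
  out <- do.call(rbind, lapply(c("C", "B"), function(pre) {
    df <- all_rows
    df$scenario_id <- paste0(pre, df$num)
    df$outcome_type <- if (pre == "C") "continuous" else "binary"
    # binary all-effect-modifier scenarios use large modification
    if (pre == "B") df$em_magnitude[df$num %in% c(29, 30)] <- "large"
    df
  }))
  out$num <- NULL
  rownames(out) <- out$scenario_id
  out[c("scenario_id", "outcome_type", "n_studies", "n_covariates",
        "n_nuisance", "n_em", "em_magnitude", "tau",
        "random_effect_dist", "re_halfwidth",
        "n_patients_lo", "n_patients_hi")]
}

#' @rdname scenario_catalog
#' @param path output path for the JSON catalog copy.
#' @export
write_scenario_catalog <- function(path, file = NULL) {
  jsonlite::write_json(scenario_catalog(file), path, pretty = TRUE,
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' Resolve a scenario id into a full simulation configuration
#'
#' Expands a catalog row (or user-supplied overrides) into every
#' parameter of the data-generating mechanism: covariate layout and
#' roles, average coefficient vectors, heterogeneity SDs, residual SD,
#' intercept range, and study-size range.
#'
#' Fixed defaults of the generating mechanism: average treatment effect
#' \code{delta = 1}; main-effect heterogeneity \code{tau_beta = 0.2};
#' interaction heterogeneity \code{tau_gamma = 0.3}; average main
#' effect \code{beta = 0.2} for prognostic factors and effect modifiers
#' and 0 (with no heterogeneity) for nuisance covariates; AR(1)
#' covariate correlation \code{rho = 0.3}; residual SD
#' \code{sigma = 0.5} (continuous); study intercepts
#' Uniform(-1, 1) for continuous and Uniform(-2, -1) for binary
#' outcomes (the latter targets event rates around 30\%).  Covariates
#' are half continuous (rounded up, columns first) and half binary;
#' effect-modifier and prognostic roles alternate between the
#' continuous and binary blocks.  Average effect modification is 0.2
#' ("small") or 0.5 ("large") on the standardized scale.
#'
#' @param scenario_id catalog id such as \code{"C1"} or \code{"B35"}.
#' @param catalog catalog data frame, default [scenario_catalog()].
#' @param ... named overrides applied to the resolved configuration
#'   (e.g. \code{delta = 0}, \code{em_small = 0.3}).
#' @return A list of class \code{ipd_scenario} holding all generator
#'   parameters, including \code{em_indices}, \code{prognostic_indices},
#'   \code{gamma} and \code{beta} vectors of length p.
#' @export
make_scenario <- function(scenario_id, catalog = scenario_catalog(), ...) {
  if (!scenario_id %in% catalog$scenario_id)
    stop("unknown scenario id: ", scenario_id)
  row <- catalog[catalog$scenario_id == scenario_id, ]
  cfg <- list(
    scenario_id = scenario_id,
    outcome_type = row$outcome_type,
    n_studies = row$n_studies,
    n_covariates = row$n_covariates,
    n_nuisance = row$n_nuisance,
    n_em = row$n_em,
    em_magnitude = row$em_magnitude,
    tau = row$tau,
    random_effect_dist = row$random_effect_dist,
    re_halfwidth = row$re_halfwidth,
    n_patients_range = c(row$n_patients_lo, row$n_patients_hi),
    delta = 1, tau_beta = 0.2, tau_gamma = 0.3,
    beta_value = 0.2, rho = 0.3, sigma = 0.5,
    em_small = 0.2, em_large = 0.5,
    intercept_range = if (row$outcome_type == "continuous")
      c(-1, 1) else c(-2, -1)
  )
  dots <- list(...)
  if (length(dots)) cfg[names(dots)] <- dots
  cfg <- resolve_roles(cfg)
  structure(cfg, class = "ipd_scenario")
}

# Assign covariate kinds and roles.  Columns 1..n_cont are continuous,
# the rest binary.  Effect modifiers, then prognostic factors, are
# assigned by alternating between the continuous and binary blocks so
# each role spans both kinds; leftovers are nuisance.
resolve_roles <- function(cfg) {
  p <- cfg$n_covariates
  n_cont <- ceiling(p / 2)
  kinds <- rep(c("continuous", "binary"), c(n_cont, p - n_cont))
  inter <- as.vector(t(cbind(seq_len(n_cont),
                             c(n_cont + seq_len(p - n_cont),
                               rep(NA, 2 * n_cont - p)))))
  inter <- inter[!is.na(inter)]
  n_prog <- p - cfg$n_nuisance - cfg$n_em
  stopifnot(n_prog >= 0)
  cfg$covariate_kinds <- kinds
  cfg$em_indices <- sort(inter[seq_len(cfg$n_em)])
  cfg$prognostic_indices <- sort(inter[cfg$n_em + seq_len(n_prog)])
  cfg$nuisance_indices <- setdiff(seq_len(p),
                                  c(cfg$em_indices, cfg$prognostic_indices))
  gamma_val <- switch(cfg$em_magnitude, small = cfg$em_small,
                      large = cfg$em_large, none = 0)
  cfg$gamma <- replace(rep(0, p), cfg$em_indices, gamma_val)
  cfg$beta <- replace(rep(0, p),
                      c(cfg$em_indices, cfg$prognostic_indices),
                      cfg$beta_value)
  cfg
}

#' @export
print.ipd_scenario <- function(x, ...) {
  cat(sprintf("<scenario %s: %s outcome, J=%d, p=%d (%d nuisance), %d EM (%s), tau=%s, %s random effects>\n",
              x$scenario_id, x$outcome_type, x$n_studies, x$n_covariates,
              x$n_nuisance, x$n_em, x$em_magnitude,
              format(x$tau), x$random_effect_dist))
  invisible(x)
}
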