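#' Construct an IPD dataset
#'
#' Bundles patient-level data from a multi-study randomized comparison
#' into the container used by every estimator in the package: a study
#' label, a binary treatment indicator, an outcome (continuous or
#' binary), and a numeric covariate matrix with per-covariate metadata.
#'
#' @param study integer or factor study label, one entry per patient.
#'   Internally recoded to consecutive integers \code{1..J}.
#' @param treatment binary (0/1) treatment indicator.
#' @param outcome numeric outcome; must be 0/1 when
#'   \code{outcome_type = "binary"}.
#' @param covariates numeric matrix or data frame, one column per
#'   covariate.  Column names are kept (defaults \code{x1..xp}).
#' @param covariate_kinds character vector, \code{"continuous"} or
#'   \code{"binary"} per covariate.  Defaults to guessing binary for
#'   0/1-valued columns.
#' @param outcome_type \code{"continuous"} or \code{"binary"}.
#'
#' @return An object of class \code{ipd_data}: a list with elements
#'   \code{study} (integer, 1..J), \code{treatment}, \code{outcome},
#'   \code{X} (numeric matrix), \code{covariate_meta} (data frame with
#'   columns \code{name}, \code{kind}), \code{outcome_type},
#'   \code{n_studies}, and \code{scaling} (\code{NULL} until
#'   \code{\link{standardize_covariates}} is applied).
#' @seealso [validate_ipd()], [standardize_covariates()], [build_design()]
#' @export
ipd_data <- function(study, treatment, outcome, covariates,
                     covariate_kinds = NULL,
                     outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  stopifnot(length(study) == n, length(treatment) == n, length(outcome) == n)
  study_f <- factor(study)
  if (is.null(covariate_kinds)) {
    covariate_kinds <- ifelse(
      apply(X, 2, function(v) all(v %in% c(0, 1))), "binary", "continuous")
  }
  stopifnot(length(covariate_kinds) == ncol(X),
            all(covariate_kinds %in% c("continuous", "binary")))
  obj <- structure(list(
    study = as.integer(study_f),
    study_labels = levels(study_f),
    treatment = as.numeric(treatment),
    outcome = as.numeric(outcome),
    X = X,
    covariate_meta = data.frame(name = colnames(X),
                                kind = as.character(covariate_kinds),
                                stringsAsFactors = FALSE),
    outcome_type = outcome_type,
    n_studies = nlevels(study_f),
    scaling = NULL
  ), class = "ipd_data")
  obj
}

#' @export
print.ipd_data <- function(x, ...) {
  cat(sprintf("IPD dataset: %d patients, %d studies, %d covariates (%s outcome)%s\n",
              length(x$outcome), x$n_studies, ncol(x$X), x$outcome_type,
              if (!is.null(x$scaling)) ", standardized" else ""))
  cat(sprintf("  treated: %d (%.1f%%)\n", sum(x$treatment == 1),
              100 * mean(x$treatment == 1)))
  invisible(x)
}

#' Validate an IPD dataset
#'
#' Reports conditions that would break model fitting: missing values,
#' non-binary treatment or (for a binary outcome) outcome codes, fewer
#' than two studies, studies with a single treatment arm, and
#' zero-variance covariates (which standardization would divide by
#' zero).  This is a reporting operation; it never throws.
#'
#' @param dataset an [ipd_data] object.
#' @return Character vector of violation messages; empty if the dataset
#'   is fit-ready.
#' @export
validate_ipd <- function(dataset) {
  stopifnot(inherits(dataset, "ipd_data"))
  v <- character(0)
  if (anyNA(dataset$outcome) || anyNA(dataset$X) ||
      anyNA(dataset$treatment) || anyNA(dataset$study))
    v <- c(v, "missing values present (complete data are required)")
  if (!all(dataset$treatment %in% c(0, 1)))
    v <- c(v, "treatment indicator contains values other than 0/1")
  if (dataset$outcome_type == "binary" &&
      !all(dataset$outcome %in% c(0, 1)))
    v <- c(v, "binary outcome contains values other than 0/1")
  if (dataset$n_studies < 2)
    v <- c(v, "fewer than 2 studies (meta-analysis needs J >= 2)")
  for (j in seq_len(dataset$n_studies)) {
    arms <- unique(dataset$treatment[dataset$study == j])
    if (length(arms) < 2)
      v <- c(v, sprintf("single-arm study: study %s has only arm t=%s",
                        dataset$study_labels[j], arms[1]))
  }
  sds <- apply(dataset$X, 2, sd)
  if (any(sds == 0, na.rm = TRUE))
    v <- c(v, sprintf("zero-variance covariate: %s",
                      paste(colnames(dataset$X)[which(sds == 0)],
                            collapse = ", ")))
  v
}

#' Standardize covariates to mean 0, SD 1
#'
#' Centers and scales every covariate column (binary columns included)
#' to sample mean 0 and sample SD 1, pooling patients across studies.
#' Equal penalization of all interaction coefficients presumes this
#' common scale, so all estimators in the package expect a
#' standardized dataset.  The applied means and SDs are stored in the
#' returned dataset's \code{scaling} element so that fitted
#' coefficients can be mapped back to the raw scale (see
#' \code{\link{predict_subgroup}}).  Sample SDs use the n-1
#' denominator.  Re-standardizing an already standardized dataset is a
#' no-op up to floating-point error.
#'
#' @param dataset an [ipd_data] object.
#' @return The dataset with standardized \code{X} and a \code{scaling}
#'   list holding \code{mean} and \code{sd} per covariate.
#' @export
standardize_covariates <- function(dataset) {
  stopifnot(inherits(dataset, "ipd_data"))
  mu <- colMeans(dataset$X)
  sdv <- apply(dataset$X, 2, sd)
  if (any(sdv == 0))
    stop("cannot standardize zero-variance covariate(s): ",
         paste(colnames(dataset$X)[sdv == 0], collapse = ", "))
  dataset$X <- sweep(sweep(dataset$X, 2, mu, "-"), 2, sdv, "/")
  # compose with any earlier standardization so scaling always maps raw -> current
  if (!is.null(dataset$scaling)) {
    mu <- dataset$scaling$mean + mu * dataset$scaling$sd
    sdv <- dataset$scaling$sd * sdv
  }
  dataset$scaling <- list(mean = setNames(mu, colnames(dataset$X)),
                          sd = setNames(sdv, colnames(dataset$X)))
  dataset
}

#' Build the design bundle shared by all estimators
#'
#' Assembles the blocks of the one-stage linear predictor
#' \eqn{a_j + \beta' x_i + \gamma' x_i t_i + \delta t_i}: J unpenalized
#' study-indicator columns (no global intercept), the covariate main
#' effects, the treatment column, and the treatment-covariate
#' interaction block restricted to \code{interaction_subset}.  Column
#' order of the stacked matrix \code{A} is: study indicators, main
#' effects, treatment, interactions; this ordering is relied upon
#' throughout the package.
#'
#' @param dataset a standardized [ipd_data] object.
#' @param interaction_subset integer indices of covariates whose
#'   treatment interactions enter the model.  Default: all covariates.
#'   \code{integer(0)} gives a no-effect-modifier design.
#' @return A list of class \code{ipd_design} with elements \code{A}
#'   (n x (J+p+1+q) matrix), \code{y}, index vectors \code{idx_study},
#'   \code{idx_main}, \code{idx_treat}, \code{idx_int},
#'   \code{interaction_subset}, \code{study}, \code{treatment},
#'   \code{outcome_type}, \code{n_studies}, and \code{p}.
#' @export
build_design <- function(dataset, interaction_subset = NULL) {
  stopifnot(inherits(dataset, "ipd_data"))
  p <- ncol(dataset$X)
  if (is.null(interaction_subset)) interaction_subset <- seq_len(p)
  interaction_subset <- as.integer(interaction_subset)
  if (length(interaction_subset) &&
      (min(interaction_subset) < 1 || max(interaction_subset) > p))
    stop("interaction_subset index out of range 1..", p)
  J <- dataset$n_studies
  S <- matrix(0, nrow(dataset$X), J)
  S[cbind(seq_len(nrow(S)), dataset$study)] <- 1
  colnames(S) <- paste0("study", seq_len(J))
  XI <- dataset$X[, interaction_subset, drop = FALSE] * dataset$treatment
  if (length(interaction_subset))
    colnames(XI) <- paste0(colnames(dataset$X)[interaction_subset], ":t")
  A <- cbind(S, dataset$X, t = dataset$treatment, XI)
  structure(list(
    A = A, y = dataset$outcome,
    idx_study = seq_len(J),
    idx_main = J + seq_len(p),
    idx_treat = J + p + 1L,
    idx_int = if (length(interaction_subset)) J + p + 1L + seq_along(interaction_subset) else integer(0),
    interaction_subset = interaction_subset,
    study = dataset$study, treatment = dataset$treatment,
    outcome_type = dataset$outcome_type, n_studies = J, p = p
  ), class = "ipd_design")
}

#' Read / write IPD datasets as CSV with a JSON sidecar
#'
#' The CSV holds columns \code{study}, \code{treatment}, \code{outcome}
#' followed by the covariates; a sidecar JSON (same path with extension
#' \code{.json}) records the covariate kinds and the outcome type.
#'
#' @param path CSV file path.
#' @param dataset an [ipd_data] object (for writing).
#' @return \code{read_ipd} returns an [ipd_data] object;
#'   \code{write_ipd} invisibly returns \code{path}.
#' @export
read_ipd <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("study", "treatment", "outcome") %in% names(df)))
  meta_path <- paste0(sub("\\.csv$", "", path), ".json")
  covs <- setdiff(names(df), c("study", "treatment", "outcome"))
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    kinds <- unname(meta$covariate_kinds[covs])
    otype <- meta$outcome_type
  } else {
    kinds <- NULL
    otype <- if (all(df$outcome %in% c(0, 1))) "binary" else "continuous"
  }
  ipd_data(df$study, df$treatment, df$outcome, df[covs],
           covariate_kinds = kinds, outcome_type = otype)
}

#' @rdname read_ipd
#' @export
write_ipd <- function(dataset, path) {
  stopifnot(inherits(dataset, "ipd_data"))
  df <- data.frame(study = dataset$study_labels[dataset$study],
                   treatment = dataset$treatment,
                   outcome = dataset$outcome,
                   dataset$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta_path <- paste0(sub("\\.csv$", "", path), ".json")
  jsonlite::write_json(
    list(outcome_type = dataset$outcome_type,
         covariate_kinds = as.list(setNames(dataset$covariate_meta$kind,
                                            dataset$covariate_meta$name))),
    meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
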