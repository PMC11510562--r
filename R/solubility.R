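# SMILES-table interface to the Bayesian ridge: featurize, fit, predict,
# cross-validate, serialize.

#' Fit a solubility model from a SMILES + logS table
#'
#' Featurizes every molecule with an ECFP4-style circular fingerprint and
#' fits a Bayesian ridge regression to the logS column by evidence
#' maximization. By default the final model uses all rows; `cv` requests
#' an additional k-fold cross-validation pass whose out-of-sample RMSE and
#' R-squared are reported alongside the training-set values.
#'
#' @param table Data frame with columns `smiles` and `logS` (and optionally
#'   `id`).
#' @param radius,nbits Fingerprint parameters (see
#'   [circular_fingerprint()]).
#' @param cv Number of cross-validation folds (0 = none).
#' @param molecules Optional list of pre-parsed `molgraph` objects matching
#'   the table rows (skips re-parsing, e.g. when the table came from
#'   [generate_solubility_dataset()]).
#' @param max_iter,tol Passed to [bayes_ridge()].
#' @param cv_seed Seed for the fold assignment when `cv > 0`.
#' @return Object of class `solubility_model`: list with the `bayes_ridge`
#'   `fit`, `radius`, `nbits`, training `metrics`, optional `cv_metrics`,
#'   and `n_molecules`.
#' @export
fit_solubility <- function(table, radius = 2L, nbits = 2048L, cv = 0L,
                           molecules = NULL, max_iter = 300L, tol = 1e-4,
                           cv_seed = 1L) {
  stopifnot(is.data.frame(table), all(c("smiles", "logS") %in% names(table)))
  X <- if (!is.null(molecules)) {
    stopifnot(length(molecules) == nrow(table))
    .featurize_mols(molecules, radius = radius, nbits = nbits)
  } else {
    featurize_table(table, radius = radius, nbits = nbits)
  }
  y <- table$logS
  fit <- bayes_ridge(X, y, max_iter = max_iter, tol = tol)
  metrics <- .fit_metrics(y, fit$fitted.values)

  cv_metrics <- NULL
  if (cv > 1L) {
    cv_metrics <- .with_seed(cv_seed, {
      folds <- sample(rep_len(seq_len(cv), nrow(X)))
      pred <- numeric(nrow(X))
      for (f in seq_len(cv)) {
        hold <- folds == f
        m <- bayes_ridge(X[!hold, , drop = FALSE], y[!hold],
                         max_iter = max_iter, tol = tol)
        pred[hold] <- predict(m, X[hold, , drop = FALSE])
      }
      .fit_metrics(y, pred)
    })
  }

  structure(list(fit = fit, radius = as.integer(radius),
                 nbits = as.integer(nbits), metrics = metrics,
                 cv_metrics = cv_metrics, cv_folds = as.integer(cv),
                 n_molecules = nrow(X)),
            class = "solubility_model")
}

#' @export
print.solubility_model <- function(x, ...) {
  cat(sprintf("Solubility model: ECFP radius %d, %d bits, %d molecules\n",
              x$radius, x$nbits, x$n_molecules))
  print(x$fit)
  cat(sprintf("  training RMSE = %.4f, R^2 = %.4f\n",
              x$metrics$rmse, x$metrics$r_squared))
  if (!is.null(x$cv_metrics)) {
    cat(sprintf("  %d-fold CV RMSE = %.4f, R^2 = %.4f\n", x$cv_folds,
                x$cv_metrics$rmse, x$cv_metrics$r_squared))
  }
  invisible(x)
}

#' @export
coef.solubility_model <- function(object, ...) coef(object$fit)

#' Predict logS for new molecules
#'
#' @param object A `solubility_model`.
#' @param newdata A character vector of SMILES, a list of `molgraph`
#'   objects, a single `molgraph` or `fingerprint`, or a data frame with a
#'   `smiles` column.
#' @param ... Unused.
#' @return Numeric vector of predicted logS values.
#' @export
predict.solubility_model <- function(object, newdata, ...) {
  if (inherits(newdata, "fingerprint")) {
    return(predict(object$fit, newdata))
  }
  if (inherits(newdata, "molgraph")) newdata <- list(newdata)
  if (is.character(newdata)) newdata <- lapply(newdata, parse_smiles)
  if (is.data.frame(newdata)) newdata <- lapply(newdata$smiles, parse_smiles)
  stopifnot(is.list(newdata))
  X <- .featurize_mols(newdata, radius = object$radius, nbits = object$nbits)
  predict(object$fit, X)
}

#' @export
plot.solubility_model <- function(x, ...) plot(x$fit, ...)

#' Serialize / restore a solubility model as JSON
#'
#' Stores weights, intercept, hyperparameters, fingerprint settings and a
#' provenance block (training-table hash when supplied, package version,
#' fit diagnostics). The posterior decomposition is not stored: a restored
#' model predicts and attributes, but cannot produce predictive variances.
#'
#' @param model A `solubility_model`.
#' @param file JSON path.
#' @param training_file Optional path of the training table; its MD5 hash
#'   is recorded for provenance.
#' @export
write_model_json <- function(model, file, training_file = NULL) {
  stopifnot(inherits(model, "solubility_model"))
  fit <- model$fit
  obj <- list(
    format = "soluprint-model-1",
    radius = model$radius, nbits = model$nbits,
    intercept = fit$intercept,
    weights = fit$coefficients,
    alpha = fit$alpha, beta = fit$beta,
    n_iter = fit$n_iter, converged = fit$converged,
    metrics = model$metrics,
    cv_metrics = model$cv_metrics,
    provenance = list(
      package_version = as.character(utils::packageVersion("soluprint")),
      n_molecules = model$n_molecules,
      training_table_md5 = if (!is.null(training_file))
        unname(tools::md5sum(training_file)) else NULL
    )
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_model_json
#' @return `read_model_json()` returns a `solubility_model` whose `fit`
#'   component supports prediction and attribution.
#' @export
read_model_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$format, "soluprint-model-1")) {
    stop("not a soluprint model file", call. = FALSE)
  }
  fit <- structure(list(
    coefficients = obj$weights,
    intercept = obj$intercept,
    alpha = obj$alpha, beta = obj$beta,
    n_iter = obj$n_iter, converged = obj$converged,
    p = length(obj$weights),
    decomposition = NULL
  ), class = "bayes_ridge")
  structure(list(fit = fit, radius = obj$radius, nbits = obj$nbits,
                 metrics = as.list(obj$metrics),
                 cv_metrics = if (!is.null(obj$cv_metrics))
                   as.list(obj$cv_metrics) else NULL,
                 n_molecules = obj$provenance$n_molecules),
            class = "solubility_model")
}
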