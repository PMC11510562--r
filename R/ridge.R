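# Bayesian ridge regression by evidence (type-II maximum likelihood)
# maximization, implemented in closed form via one SVD of the centered
# design. The prior precision alpha and noise precision beta follow the
# MacKay fixed-point updates:
#   gamma = sum_j lambda_j / (alpha + lambda_j),  lambda_j = beta d_j^2
#   alpha <- gamma / m'm
#   beta  <- (N - gamma) / ||y - X m||^2
# The intercept is excluded from the penalty by centering columns and
# target, so b = mean(y) - m . colmeans(X).

#' Exact penalized least-squares solve at fixed hyperparameters
#'
#' Returns the minimizer of `beta * ||yc - Xc m||^2 + alpha * ||m||^2`
#' (equivalently classical ridge with penalty `lambda = alpha/beta`),
#' with the intercept left unpenalized via centering. Zero-variance columns
#' receive weight 0.
#'
#' @param x Numeric design matrix (rows = observations).
#' @param y Numeric response vector.
#' @param alpha Prior (weight) precision, > 0.
#' @param beta Noise precision, > 0.
#' @return List with `m` (weight vector, length `ncol(x)`) and `b`
#'   (intercept).
#' @export
ridge_solve <- function(x, y, alpha, beta) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("rows of `x` must match length of `y`",
                                 call. = FALSE)
  if (nrow(x) < 2L) stop("degenerate input: need at least 2 observations",
                         call. = FALSE)
  if (!(alpha > 0 && beta > 0)) stop("`alpha` and `beta` must be positive",
                                     call. = FALSE)
  dec <- .centered_svd(x, y)
  m <- .posterior_mean(dec, alpha, beta)
  list(m = m, b = dec$y_mean - sum(m * dec$col_means))
}

.centered_svd <- function(x, y) {
  col_means <- colMeans(x)
  y_mean <- mean(y)
  active <- which(apply(x, 2L, function(col) any(col != col[1L])))
  xc <- sweep(x[, active, drop = FALSE], 2L, col_means[active])
  sv <- svd(xc)
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  list(u = sv$u[, keep, drop = FALSE], d = sv$d[keep],
       v = sv$v[, keep, drop = FALSE],
       active = active, p = ncol(x),
       col_means = col_means, y_mean = y_mean,
       yc = y - y_mean, uty = crossprod(sv$u[, keep, drop = FALSE], y - y_mean))
}

# posterior mean weights (full length p; inactive columns zero)
.posterior_mean <- function(dec, alpha, beta) {
  shrink <- dec$d * beta / (alpha + beta * dec$d^2)
  m_act <- dec$v %*% (shrink * dec$uty)
  m <- numeric(dec$p)
  m[dec$active] <- m_act
  m
}

#' Fit a Bayesian ridge regression by evidence maximization
#'
#' Alternates the closed-form posterior mean at the current `(alpha, beta)`
#' with the MacKay fixed-point hyperparameter updates until both relative
#' changes drop below `tol`. The log marginal likelihood (evidence) is
#' recorded at every iteration.
#'
#' @param x Numeric design matrix.
#' @param y Numeric response (here: logS, log10 mol/L).
#' @param max_iter Maximum number of evidence-update iterations.
#' @param tol Relative convergence tolerance applied to both `alpha` and
#'   `beta`.
#' @return An object of class `bayes_ridge` with components `coefficients`,
#'   `intercept`, `alpha`, `beta`, `gamma` (effective number of
#'   parameters), `n_iter`, `converged`, `log_evidence` (per-iteration
#'   trace), `fitted.values`, `residuals`, and the fit dimensions.
#'   Non-convergence at `max_iter` returns the model with
#'   `converged = FALSE` and a warning.
#' @seealso [ridge_solve()] for the fixed-hyperparameter solve;
#'   [fit_solubility()] for the SMILES-table interface.
#' @export
bayes_ridge <- function(x, y, max_iter = 300L, tol = 1e-4) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n != length(y)) stop("rows of `x` must match length of `y`",
                           call. = FALSE)
  if (n < 2L) stop("degenerate input: need at least 2 observations",
                   call. = FALSE)
  if (var(y) == 0) {
    stop("`y` is constant: the noise precision update is undefined",
         call. = FALSE)
  }

  dec <- .centered_svd(x, y)
  d2 <- dec$d^2

  alpha <- 1
  beta <- 1 / var(y)
  log_ev <- numeric(0)
  converged <- FALSE
  iter <- 0L
  m <- numeric(dec$p)
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- .posterior_mean(dec, alpha, beta)
    # yc - Xc m in the SVD basis: Xc m = U (d * V'm)
    resid <- dec$yc -
      as.numeric(dec$u %*% (dec$d * crossprod(dec$v, m[dec$active])))
    rss <- sum(resid^2)
    mtm <- sum(m^2)
    lam <- beta * d2
    gamma <- sum(lam / (alpha + lam))
    log_ev <- c(log_ev, 0.5 * (length(dec$d) * log(alpha) + n * log(beta) -
                                 beta * rss - alpha * mtm -
                                 sum(log(alpha + lam)) - n * log(2 * pi)))
    if (rss <= 1e-12 * sum(dec$yc^2)) {
      # numerically perfect interpolation: the beta update diverges
      # geometrically and carries no further information
      converged <- TRUE
      break
    }
    alpha_new <- if (mtm > 0) gamma / mtm else alpha
    beta_new <- (n - gamma) / rss
    if (abs(alpha_new - alpha) / alpha < tol &&
        abs(beta_new - beta) / beta < tol) {
      alpha <- alpha_new; beta <- beta_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new; beta <- beta_new
  }
  if (!converged) {
    warning(sprintf("evidence maximization did not converge in %d iterations",
                    max_iter))
  }

  m <- .posterior_mean(dec, alpha, beta)
  b <- dec$y_mean - sum(m * dec$col_means)
  fitted_vals <- as.numeric(x %*% m) + b
  lam <- beta * d2
  gamma <- sum(lam / (alpha + lam))

  structure(list(
    coefficients = m,
    intercept = b,
    alpha = alpha,
    beta = beta,
    gamma = gamma,
    n_iter = iter,
    converged = converged,
    log_evidence = log_ev,
    fitted.values = fitted_vals,
    residuals = y - fitted_vals,
    y = y,
    n = n,
    p = dec$p,
    decomposition = dec,
    call = match.call()
  ), class = "bayes_ridge")
}

#' @export
coef.bayes_ridge <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
fitted.bayes_ridge <- function(object, ...) object$fitted.values

#' @export
residuals.bayes_ridge <- function(object, ...) object$residuals

#' Predict from a Bayesian ridge model
#'
#' @param object A `bayes_ridge` fit.
#' @param newdata New design matrix, a `fingerprint` object, or omitted for
#'   fitted values.
#' @param se.fit If `TRUE`, also return the posterior predictive standard
#'   deviation (including the noise term `1/sqrt(beta)`).
#' @param ... Unused.
#' @return Numeric vector of predictions, or a list with `fit` and `se.fit`.
#' @export
predict.bayes_ridge <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "fingerprint")) {
    if (newdata$nbits != object$p) {
      stop(sprintf("fingerprint length %g does not match model (%d bits)",
                   newdata$nbits, object$p), call. = FALSE)
    }
    x <- matrix(as_bit_vector(newdata), nrow = 1L)
  } else {
    x <- as.matrix(newdata)
    if (ncol(x) != object$p) {
      stop(sprintf("newdata has %d columns; model expects %d",
                   ncol(x), object$p), call. = FALSE)
    }
  }
  fit <- as.numeric(x %*% object$coefficients) + object$intercept
  if (!se.fit) return(fit)
  dec <- object$decomposition
  xc <- sweep(x[, dec$active, drop = FALSE], 2L, dec$col_means[dec$active])
  proj <- xc %*% dec$v                              # components in row space
  in_span <- rowSums(proj^2)
  varw <- rowSums(sweep(proj^2, 2L,
                        1 / (object$alpha + object$beta * dec$d^2), `*`)) +
    pmax(rowSums(xc^2) - in_span, 0) / object$alpha # null-space prior term
  list(fit = fit, se.fit = sqrt(1 / object$beta + varw))
}

#' Simulate from the posterior predictive distribution
#'
#' @param object A `bayes_ridge` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @param newdata Optional new design matrix; defaults to the training
#'   design implied by the fitted values.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated responses.
#' @export
simulate.bayes_ridge <- function(object, nsim = 1, seed = NULL,
                                 newdata = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  mu <- if (is.null(newdata)) object$fitted.values
        else predict(object, newdata)
  sims <- replicate(nsim, mu + rnorm(length(mu), 0, 1 / sqrt(object$beta)))
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
print.bayes_ridge <- function(x, ...) {
  cat("Bayesian ridge regression (evidence maximization)\n")
  cat(sprintf("  n = %d, p = %d (%d active columns)\n", x$n, x$p,
              length(x$decomposition$active)))
  cat(sprintf("  alpha = %.6g, beta = %.6g (noise sd = %.4g)\n",
              x$alpha, x$beta, 1 / sqrt(x$beta)))
  cat(sprintf("  %d iterations, converged: %s\n", x$n_iter, x$converged))
  invisible(x)
}

#' @export
summary.bayes_ridge <- function(object, ...) {
  met <- .fit_metrics(object$y, object$fitted.values)
  out <- list(model = object, rmse = met$rmse, r_squared = met$r_squared,
              effective_params = object$gamma,
              noise_sd = 1 / sqrt(object$beta))
  class(out) <- "summary.bayes_ridge"
  out
}

#' @export
print.summary.bayes_ridge <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training RMSE = %.4f, R^2 = %.4f\n", x$rmse, x$r_squared))
  cat(sprintf("  effective number of parameters (gamma) = %.2f\n",
              x$effective_params))
  cat(sprintf("  estimated noise sd (1/sqrt(beta)) = %.4f\n", x$noise_sd))
  invisible(x)
}

#' @export
plot.bayes_ridge <- function(x, ...) {
  plot(x$fitted.values, x$y,
       xlab = "predicted logS", ylab = "observed logS",
       main = "Bayesian ridge fit", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

.fit_metrics <- function(y, yhat) {
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined for a constant response", call. = FALSE)
  }
  list(rmse = sqrt(mean((y - yhat)^2)), r_squared = 1 - ss_res / ss_tot)
}

#' Fit metrics (RMSE and R-squared) of a model on a data set
#'
#' @param model A `bayes_ridge` fit.
#' @param x Design matrix.
#' @param y Observed response.
#' @return List with `rmse` and `r_squared`.
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "bayes_ridge"))
  if (nrow(as.matrix(x)) != length(y)) {
    stop("rows of `x` must match length of `y`", call. = FALSE)
  }
  .fit_metrics(y, predict(model, x))
}
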