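# lasso objective on standardized data: (1/2n) ||y - b0 - X b||^2 + lambda ||b||_1
lasso_objective <- function(X, y, b0, beta, lambda) {
  n <- length(y)
  r <- y - b0 - X %*% beta
  sum(r^2) / (2 * n) + lambda * sum(abs(beta))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# one lasso solve by cyclic coordinate descent on standardized predictors
lasso_fit_one <- function(Xs, yc, lambda, beta_init, tol = 1e-7,
                          max_sweeps = 10000L, track_objective = FALSE) {
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- beta_init
  r <- yc - Xs %*% beta
  obj_path <- if (track_objective)
    lasso_objective(Xs, yc, 0, beta, lambda) else NULL
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      z <- sum(Xs[, j] * r) / n + bj_old        # predictors have unit variance (1/n scaling)
      bj <- soft_threshold(z, lambda)
      if (bj != bj_old) {
        r <- r - Xs[, j] * (bj - bj_old)
        beta[j] <- bj
        delta <- max(delta, abs(bj - bj_old))
      }
    }
    if (track_objective)
      obj_path <- c(obj_path, lasso_objective(Xs, yc, 0, beta, lambda))
    if (delta < tol) break
  }
  list(beta = beta, objective_path = obj_path)
}

# standardize with 1/n variance (glmnet convention) so lambda_max = max |x'y|/n
std_design <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- sqrt(colMeans(sweep(X, 2, xm)^2))
  assert_that(all(xs > 0), "constant predictor column")
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  ym <- mean(y)
  list(Xs = Xs, yc = y - ym, xm = xm, xs = xs, ym = ym)
}

#' LASSO coefficient path by cyclic coordinate descent
#'
#' Minimizes `(1/2n) sum (y - b0 - X beta)^2 + lambda sum |beta|` on
#' predictors standardized to unit (1/n) variance; coefficients are returned
#' on that standardized scale. The default grid has 100 log-spaced lambdas
#' from `lambda_max = max_j |x_j' y| / n` (all-zero solution) down to
#' `1e-4 * lambda_max`, solved warm-started from large to small lambda.
#'
#' @param X numeric matrix, samples x predictors (e.g. module eigengenes).
#' @param y response vector (radiation).
#' @param lambda_grid optional descending lambda values.
#' @param n_lambda,lambda_min_ratio grid construction when `lambda_grid` is
#'   NULL.
#' @param tol coordinate-descent convergence tolerance (max coefficient
#'   change per sweep).
#' @return list: `lambda` (descending), `beta` (predictors x lambdas,
#'   standardized scale), `lambda_max`.
#' @export
lasso_path <- function(X, y, lambda_grid = NULL, n_lambda = 100L,
                       lambda_min_ratio = 1e-4, tol = 1e-7) {
  X <- as.matrix(X)
  assert_that(all(is.finite(X)) && all(is.finite(y)), "non-finite inputs")
  assert_that(nrow(X) == length(y), "X and y must align")
  assert_that(nrow(X) > 2, "need more than 2 samples")
  sd <- std_design(X, y)
  n <- nrow(X)
  lambda_max <- max(abs(crossprod(sd$Xs, sd$yc))) / n
  if (is.null(lambda_grid)) {
    lambda_grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                           length.out = n_lambda))
  } else {
    lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  }
  p <- ncol(X)
  beta <- matrix(0, p, length(lambda_grid),
                 dimnames = list(colnames(X), NULL))
  b <- rep(0, p)
  for (i in seq_along(lambda_grid)) {
    b <- lasso_fit_one(sd$Xs, sd$yc, lambda_grid[i], b, tol = tol)$beta
    beta[, i] <- b
  }
  list(lambda = lambda_grid, beta = beta, lambda_max = lambda_max)
}

#' Cross-validated lambda selection
#'
#' k-fold CV mean squared error per lambda; folds come from a seeded shuffle
#' and the winner is the lambda minimizing mean CV error (lambda.min rule;
#' ties broken toward the larger lambda).
#'
#' @inheritParams lasso_path
#' @param k_folds number of folds (default 10).
#' @param seed RNG seed for the fold shuffle.
#' @return list: `best_lambda`, `cv_table` (lambda, mean_error, se),
#'   `selected` (predictor names with nonzero coefficient at best lambda),
#'   `coef_at_best` (standardized scale), `path`.
#' @export
cv_select_lambda <- function(X, y, k_folds = 10L, lambda_grid = NULL,
                             seed = 1L, n_lambda = 100L,
                             lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(k_folds >= 2 && k_folds <= n, "k_folds must lie in [2, n]")
  path <- lasso_path(X, y, lambda_grid, n_lambda, lambda_min_ratio)
  lambda <- path$lambda
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  assert_that(min(table(fold)) >= 2, "a fold has fewer than 2 samples")
  err <- matrix(NA_real_, k_folds, length(lambda))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    sdt <- std_design(X[tr, , drop = FALSE], y[tr])
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, sdt$xm), 2, sdt$xs, "/")
    b <- rep(0, ncol(X))
    for (i in seq_along(lambda)) {
      b <- lasso_fit_one(sdt$Xs, sdt$yc, lambda[i], b)$beta
      pred <- sdt$ym + Xte %*% b
      err[f, i] <- mean((y[!tr] - pred)^2)
    }
  }
  mean_err <- colMeans(err)
  se <- apply(err, 2, stats::sd) / sqrt(k_folds)
  best_i <- which(mean_err <= min(mean_err) + 1e-15)[1]  # ties -> larger lambda
  coef_best <- path$beta[, best_i]
  list(best_lambda = lambda[best_i],
       cv_table = data.frame(lambda = lambda, mean_error = mean_err, se = se),
       selected = colnames(X)[coef_best != 0],
       coef_at_best = coef_best,
       path = path,
       fold = fold)
}

#' Standardized final model on the selected predictors
#'
#' Refits the selected set by unpenalized OLS on z-scored predictors and
#' response, giving standardized coefficients with t-based 95% confidence
#' intervals and the adjusted R^2; rows are ordered by |coefficient| for a
#' forest-style table.
#'
#' @param X_selected samples x selected-predictors matrix.
#' @param y response vector.
#' @param ci_level confidence level (default 0.95).
#' @return list: `coefficients` (data.frame: predictor, beta_std, ci_low,
#'   ci_high, p), `adjusted_r2`, `p_value` (model F test).
#' @export
standardized_final_model <- function(X_selected, y, ci_level = 0.95) {
  X <- as.matrix(X_selected)
  assert_that(ncol(X) >= 1, "selected set is empty")
  assert_that(nrow(X) > ncol(X) + 1, "need n > p + 1")
  Xz <- apply(X, 2, zscore)
  assert_that(kappa(crossprod(Xz)) < 1e10,
              "selected predictors are collinear; merge them first")
  yz <- zscore(y)
  df <- data.frame(yz = yz, Xz, check.names = FALSE)
  fit <- stats::lm(yz ~ ., data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = ci_level)
  coefs <- data.frame(
    predictor = colnames(X),
    beta_std = unname(stats::coef(fit)[-1]),
    ci_low = ci[-1, 1], ci_high = ci[-1, 2],
    p = sm$coefficients[-1, 4],
    stringsAsFactors = FALSE
  )
  coefs <- coefs[order(-abs(coefs$beta_std)), , drop = FALSE]
  rownames(coefs) <- NULL
  fstat <- sm$fstatistic
  p_model <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(coefficients = coefs, adjusted_r2 = sm$adj.r.squared,
       p_value = unname(p_model))
}
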