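#' Global ordinary least squares baseline
#'
#' Fits `y = b0 + sum_k b_k x_k + e` by QR-based least squares with classical
#' standard errors, two-sided t tests (`n - p - 1` df), R-squared, adjusted
#' R-squared, `RMSE = sqrt(SSR/n)`, and the small-sample AICc
#' `2n ln(sigma_hat) + n ln(2pi) + n (n + trS)/(n - 2 - trS)` with
#' `trS = p + 1` (the hat-matrix trace of a global linear fit), the same
#' convention the spatiotemporal fit uses so the two are comparable.
#'
#' @param X numeric covariate matrix (no intercept column unless
#'   `add_intercept = FALSE`).
#' @param y numeric response.
#' @param add_intercept prepend an intercept column (default TRUE).
#' @return An object of class `ols_fit`: coefficients, `se`, `statistic`
#'   (t), `p` (two-sided p-values), `fitted`, `residuals`, `r2`, `adj_r2`,
#'   `rmse`, `sigma_hat`, `aicc`, `n`, `n_slopes`, `tr_s`.
#' @export
ols_fit <- function(X, y, add_intercept = TRUE) {
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  n <- nrow(X); pc <- ncol(X)
  if (n <= pc)
    stop("need n > number of design columns", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < pc) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):pc]]
    stop("singular design; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  ssr <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  df <- n - pc
  sigma2 <- ssr / df
  XtX_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  r2 <- 1 - ssr / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df
  sigma_hat <- sqrt(ssr / n)
  tr_s <- pc
  # undefined for very small n relative to p; reported as NA rather than error
  aicc <- tryCatch(gtwr_aicc(sigma_hat, n, tr_s),
                   error = function(e) NA_real_)
  structure(list(coefficients = beta, se = se, statistic = tstat, p = pval,
                 fitted = fitted, residuals = resid, r2 = r2,
                 adj_r2 = adj_r2, rmse = sqrt(ssr / n),
                 sigma_hat = sigma_hat, aicc = aicc, n = n,
                 n_slopes = pc - 1, tr_s = tr_s, X = X, y = y),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, p = %d, R2 = %.4f, adj R2 = %.4f, RMSE = %.4f, AICc = %.4f\n",
              as.integer(x$n), as.integer(x$n_slopes), x$r2, x$adj_r2,
              x$rmse, x$aicc))
  tab <- data.frame(coef = x$coefficients, se = x$se, t = x$statistic,
                    p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is the R-squared of regressing
#' column `k` on all other columns plus an intercept. Perfectly collinear
#' columns get `Inf` with a warning. Values above 10 conventionally flag
#' problematic multicollinearity.
#'
#' @param X covariate matrix (no intercept column), >= 2 columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2) stop("need >= 2 columns", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(k) {
    # projection-based auxiliary R2; tolerant of redundancy among the others
    xk <- X[, k]
    qx <- qr(cbind(1, X[, -k, drop = FALSE]))
    res <- qr.resid(qx, xk)
    r2k <- 1 - sum(res^2) / sum((xk - mean(xk))^2)
    if (r2k >= 1 - 1e-12) Inf else 1 / (1 - r2k)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(!is.finite(out)))
    warning("perfect collinearity: infinite VIF for ",
            paste(names(out)[!is.finite(out)], collapse = ", "),
            call. = FALSE)
  out
}

#' Breusch-Pagan test for heteroscedastic residuals
#'
#' Lagrange-multiplier form: `LM = n * R2_aux` where the auxiliary regression
#' explains the squared OLS residuals by the covariates; the p-value comes
#' from a chi-squared distribution with `k` (number of covariates) degrees of
#' freedom. Small p indicates residual variance tied to the covariates.
#'
#' @param fit an `ols_fit`.
#' @param X covariate matrix used in the auxiliary regression (defaults to
#'   the fit's slope columns).
#' @return list with `statistic`, `p`, `df`.
#' @export
breusch_pagan <- function(fit, X = NULL) {
  stopifnot(inherits(fit, "ols_fit"))
  if (is.null(X)) X <- fit$X[, -1, drop = FALSE]
  X <- as.matrix(X)
  u2 <- fit$residuals^2
  r2_aux <- if (stats::sd(u2) == 0) 0 else ols_fit(X, u2)$r2
  lm_stat <- fit$n * r2_aux
  k <- ncol(X)
  list(statistic = lm_stat,
       p = stats::pchisq(lm_stat, df = k, lower.tail = FALSE),
       df = k)
}

#' LASSO with seeded cross-validated penalty selection
#'
#' L1-penalized least squares, objective `(1/2n) ||y - b0 - X b||^2 +
#' alpha ||b||_1` with unpenalized intercept (the glmnet scaling; `alpha`
#' here is glmnet's `lambda`). The penalty is chosen from `alpha_grid` by
#' k-fold cross-validation with a fold assignment fixed by `seed`, so the
#' selection is deterministic. Covariates are assumed pre-standardized
#' (`standardize = FALSE`); at the selected penalty, predictors with exactly
#' zero coefficients form the screened-out set.
#'
#' @param X standardized covariate matrix.
#' @param y numeric response.
#' @param alpha_grid decreasing-sortable penalty grid; `NULL` uses the
#'   glmnet-generated path.
#' @param folds number of CV folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @return An object of class `lasso_fit`: `alpha` (selected penalty),
#'   `coefficients` (named, incl. intercept), `cv_rmse`, `zeroed` (names of
#'   zeroed predictors), `glmnet_fit`.
#' @export
lasso_cv <- function(X, y, alpha_grid = NULL, folds = 5, seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(alpha_grid)) {
    if (length(alpha_grid) == 0) stop("empty penalty grid", call. = FALSE)
    alpha_grid <- sort(unique(alpha_grid), decreasing = TRUE)
  }
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  n <- nrow(X)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  cv <- glmnet::cv.glmnet(X, y, lambda = alpha_grid, foldid = foldid,
                          standardize = FALSE, thresh = 1e-12)
  alpha_star <- cv$lambda.min
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  coefs <- drop(cf)
  slopes <- coefs[-1]
  structure(list(alpha = alpha_star,
                 coefficients = coefs,
                 cv_rmse = sqrt(cv$cvm[cv$lambda == alpha_star][1]),
                 zeroed = names(slopes)[slopes == 0],
                 glmnet_fit = cv),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("LASSO: selected penalty = %.4g, CV RMSE = %.4f, zeroed: %s\n",
              x$alpha, x$cv_rmse,
              if (length(x$zeroed)) paste(x$zeroed, collapse = ", ")
              else "none"))
  invisible(x)
}
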