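#' Gaussian spatial kernel weight
#'
#' `w = exp(-d^2 / (2 b^2))`: 1 at zero distance, strictly decreasing, with
#' `exp(-1/2) ~ 0.61` at one bandwidth.
#'
#' @param d distance(s) in km, `>= 0`.
#' @param b fixed spatial bandwidth in km, `> 0`.
#' @return kernel weight(s) in (0, 1].
#' @export
gtwr_spatial_weight <- function(d, b) {
  if (!is.numeric(b) || length(b) != 1 || b <= 0)
    stop("spatial bandwidth `b` must be a positive scalar", call. = FALSE)
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  exp(-d^2 / (2 * b^2))
}

#' Exponential temporal kernel weight
#'
#' `w = exp(-|t_i - t_j| / h)`: 1 at equal times, exponential decay in the
#' absolute time difference, symmetric in its arguments.
#'
#' @param t_i,t_j time coordinates (years).
#' @param h temporal bandwidth in years, `> 0`.
#' @return kernel weight(s) in (0, 1].
#' @export
gtwr_temporal_weight <- function(t_i, t_j, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("temporal bandwidth `h` must be a positive scalar", call. = FALSE)
  exp(-abs(t_i - t_j) / h)
}

#' Combined spatiotemporal weights for one calibration point
#'
#' Product of the Gaussian spatial kernel and exponential temporal kernel:
#' `w_ij = exp(-d_ij^2/(2 b^2)) * exp(-|t_i - t_j|/h)`. The self-weight is 1.
#'
#' @param i index of the calibration observation.
#' @param coords n x 2 matrix of planar coordinates (km).
#' @param times numeric time coordinates (years).
#' @param b,h spatial (km) and temporal (years) bandwidths.
#' @return numeric weight vector of length n.
#' @export
gtwr_combined_weights <- function(i, coords, times, b, h) {
  d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
  gtwr_spatial_weight(d, b) * gtwr_temporal_weight(times, times[i], h)
}

# Eq.-9-style small-sample AICc of a linear smoother
gtwr_aicc <- function(sigma_hat, n, tr_s) {
  if (n - 2 - tr_s <= 0)
    stop("AICc undefined: n - 2 - tr(S) <= 0 (bandwidths too small)",
         call. = FALSE)
  2 * n * log(sigma_hat) + n * log(2 * pi) + n * (n + tr_s) / (n - 2 - tr_s)
}

# one weighted local fit; returns beta, the projection matrix C_i and hat row
gtwr_local_solve <- function(X, y, wts, i = NULL) {
  Xw <- X * wts
  A <- crossprod(Xw, X)
  Ai <- tryCatch(solve(A), error = function(e)
    stop(sprintf("singular local fit%s: weights too concentrated",
                 if (is.null(i)) "" else paste0(" at observation ", i)),
         call. = FALSE))
  C <- Ai %*% t(Xw)          # (p+1) x n
  list(beta = drop(C %*% y), C = C)
}

#' Fit a geographically and temporally weighted regression
#'
#' Estimates a local coefficient vector at every region-year by weighted
#' least squares, `beta_i = (X' W_i X)^{-1} X' W_i y`, where the diagonal
#' weights combine a fixed Gaussian spatial kernel over centroid distances
#' (bandwidth `bw_spatial`, km) and an exponential temporal kernel over year
#' differences (bandwidth `bw_temporal`, years). Local standard errors use
#' `sigma_hat^2 * diag(C_i C_i')` with `C_i = (X'W_iX)^{-1}X'W_i` and
#' `sigma_hat = sqrt(SSR/n)`; pseudo-t values are `beta/se`. Fit metrics:
#' `R2 = 1 - SSR/SST`, adjusted `R2 = 1 - (1-R2)(n-1)/(n - tr(S))` with the
#' hat-matrix trace as effective parameters, `RMSE = sqrt(SSR/n)`, and the
#' small-sample AICc `2n ln(sigma_hat) + n ln(2pi) +
#' n (n + trS)/(n - 2 - trS)`. As both bandwidths grow, every local fit
#' converges to the global OLS solution and `tr(S)` to `p + 1`.
#'
#' @param panel data.frame with `region_id`, `year`, the outcome column and
#'   covariate columns; complete (no missing region-years).
#' @param region_set a `region_set` supplying centroids in km.
#' @param covariates character vector of covariate column names.
#' @param outcome outcome column name (default `"y"`).
#' @param bw_spatial spatial bandwidth in km (> 0).
#' @param bw_temporal temporal bandwidth in years (> 0).
#' @return An object of class `gtwr_fit`: `local` (long data.frame
#'   `region_id`, `year`, `predictor`, `beta`, `se`, `t`), `beta_mat`
#'   (n x (p+1)), `se_mat`, `fitted`, `residuals`, `hat_diag`, `tr_s`,
#'   `r2`, `adj_r2`, `rmse`, `sigma_hat`, `aicc`, `config`.
#' @export
gtwr_fit <- function(panel, region_set, covariates, outcome = "y",
                     bw_spatial, bw_temporal) {
  stopifnot(inherits(region_set, "region_set"))
  miss <- setdiff(c("region_id", "year", outcome, covariates), names(panel))
  if (length(miss))
    stop("panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  idx <- match(panel$region_id, region_set$regions$region_id)
  if (anyNA(idx))
    stop("panel regions missing from the region set", call. = FALSE)
  coords <- cbind(region_set$regions$u[idx], region_set$regions$v[idx])
  times <- as.numeric(panel$year)
  y <- panel[[outcome]]
  X <- cbind(`(Intercept)` = 1, as.matrix(panel[, covariates, drop = FALSE]))
  n <- nrow(X); pc <- ncol(X)

  beta_mat <- matrix(NA_real_, n, pc, dimnames = list(NULL, colnames(X)))
  var_fac <- matrix(NA_real_, n, pc)
  hat_diag <- numeric(n)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    wts <- gtwr_combined_weights(i, coords, times, bw_spatial, bw_temporal)
    lf <- gtwr_local_solve(X, y, wts, i)
    beta_mat[i, ] <- lf$beta
    var_fac[i, ] <- rowSums(lf$C^2)
    s_i <- drop(X[i, ] %*% lf$C)
    hat_diag[i] <- s_i[i]
    fitted[i] <- sum(X[i, ] * lf$beta)
  }
  resid <- y - fitted
  ssr <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  tr_s <- sum(hat_diag)
  sigma_hat <- sqrt(ssr / n)
  se_mat <- sigma_hat * sqrt(var_fac)
  dimnames(se_mat) <- dimnames(beta_mat)
  r2 <- 1 - ssr / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - tr_s)
  aicc <- gtwr_aicc(sigma_hat, n, tr_s)

  local <- data.frame(
    region_id = rep(panel$region_id, times = pc),
    year = rep(panel$year, times = pc),
    predictor = rep(colnames(X), each = n),
    beta = as.vector(beta_mat),
    se = as.vector(se_mat),
    t = as.vector(beta_mat / se_mat),
    stringsAsFactors = FALSE)

  structure(list(local = local, beta_mat = beta_mat, se_mat = se_mat,
                 fitted = fitted, residuals = resid, hat_diag = hat_diag,
                 tr_s = tr_s, r2 = r2, adj_r2 = adj_r2,
                 rmse = sqrt(ssr / n), sigma_hat = sigma_hat, aicc = aicc,
                 n = n, p = pc - 1,
                 region_id = panel$region_id, year = panel$year,
                 config = list(bw_spatial = bw_spatial,
                               bw_temporal = bw_temporal,
                               covariates = covariates, outcome = outcome)),
            class = "gtwr_fit")
}

#' @export
print.gtwr_fit <- function(x, ...) {
  cat(sprintf(paste0("GTWR fit: n = %d, p = %d, b = %.4g km, h = %.4g yr\n",
                     "  R2 = %.4f, adj R2 = %.4f, RMSE = %.4f, ",
                     "AICc = %.4f, tr(S) = %.2f\n"),
              x$n, x$p, x$config$bw_spatial, x$config$bw_temporal,
              x$r2, x$adj_r2, x$rmse, x$aicc, x$tr_s))
  invisible(x)
}

golden_section <- function(f, lo, hi, tol = 1e-3, max_iter = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  for (it in seq_len(max_iter)) {
    if (abs(b - a) < tol * (abs(a) + abs(b))) break
    if (fc < fd) { b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else { a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d) }
  }
  if (fc < fd) c(x = c, f = fc) else c(x = d, f = fd)
}

#' Select GTWR bandwidths by minimizing AICc
#'
#' Exhaustive evaluation of the AICc over a (log-spaced by default) grid of
#' spatial and temporal bandwidths, optionally followed by golden-section
#' refinement along each axis around the grid minimum. Deterministic; the
#' full AICc surface is returned for inspection. Grid points where the AICc
#' is undefined (effective parameters too close to n) are recorded as `NA`;
#' if every point is undefined, selection fails with an error.
#'
#' @inheritParams gtwr_fit
#' @param b_grid,h_grid candidate bandwidths; defaults are log-spaced grids
#'   of `n_grid` points spanning `[0.1, 10] x` the maximum pairwise centroid
#'   distance (spatial, km) and `[0.25, 10 x time span]` (temporal, years).
#' @param n_grid grid points per axis for the default grids (default 15).
#' @param refine logical; golden-section refinement around the grid minimum
#'   (default TRUE).
#' @return list with `b`, `h`, `aicc`, and `surface` (data.frame `b`, `h`,
#'   `aicc` over the grid).
#' @export
gtwr_select_bandwidths <- function(panel, region_set, covariates,
                                   outcome = "y", b_grid = NULL,
                                   h_grid = NULL, n_grid = 15,
                                   refine = TRUE) {
  idx <- match(panel$region_id, region_set$regions$region_id)
  coords <- cbind(region_set$regions$u[idx], region_set$regions$v[idx])
  if (is.null(b_grid)) {
    maxd <- max(stats::dist(unique(coords)))
    b_grid <- exp(seq(log(0.1 * maxd), log(10 * maxd), length.out = n_grid))
  }
  if (is.null(h_grid)) {
    span <- max(diff(range(as.numeric(panel$year))), 1)
    h_grid <- exp(seq(log(0.25), log(10 * span), length.out = n_grid))
  }
  if (!length(b_grid) || !length(h_grid))
    stop("empty bandwidth grid", call. = FALSE)

  aicc_at <- function(b, h) {
    tryCatch(gtwr_fit(panel, region_set, covariates, outcome,
                      bw_spatial = b, bw_temporal = h)$aicc,
             error = function(e) NA_real_)
  }
  surface <- expand.grid(b = b_grid, h = h_grid, KEEP.OUT.ATTRS = FALSE)
  surface$aicc <- mapply(aicc_at, surface$b, surface$h)
  if (all(is.na(surface$aicc)))
    stop("bandwidth selection failed: AICc undefined on the whole grid",
         call. = FALSE)
  best <- which.min(surface$aicc)
  b_star <- surface$b[best]; h_star <- surface$h[best]
  aicc_star <- surface$aicc[best]

  if (isTRUE(refine)) {
    bracket <- function(grid, x) {
      k <- which(grid == x)
      c(grid[max(1, k - 1)], grid[min(length(grid), k + 1)])
    }
    for (pass in 1:2) {
      bb <- bracket(sort(unique(surface$b)), b_star)
      if (diff(bb) > 0) {
        opt <- golden_section(function(lb)
          aicc_at(exp(lb), h_star), log(bb[1]), log(bb[2]))
        if (is.finite(opt["f"]) && opt["f"] < aicc_star) {
          b_star <- exp(opt[["x"]]); aicc_star <- opt[["f"]]
        }
      }
      hb <- bracket(sort(unique(surface$h)), h_star)
      if (diff(hb) > 0) {
        opt <- golden_section(function(lh)
          aicc_at(b_star, exp(lh)), log(hb[1]), log(hb[2]))
        if (is.finite(opt["f"]) && opt["f"] < aicc_star) {
          h_star <- exp(opt[["x"]]); aicc_star <- opt[["f"]]
        }
      }
    }
  }
  list(b = b_star, h = h_star, aicc = aicc_star, surface = surface)
}

#' Summarize local coefficient distributions
#'
#' Per predictor: mean, sd, min and max of the local estimates over all
#' region-years, and the percent of local estimates whose pseudo-t exceeds
#' `t_cutoff` in absolute value.
#'
#' @param fit a `gtwr_fit`.
#' @param t_cutoff significance cutoff on |pseudo-t| (default 1.96).
#' @return data.frame with `predictor`, `mean`, `sd`, `min`, `max`,
#'   `pct_significant`.
#' @export
coefficient_summary <- function(fit, t_cutoff = 1.96) {
  stopifnot(inherits(fit, "gtwr_fit"))
  sp <- split(fit$local, fit$local$predictor)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    predictor = d$predictor[1],
    mean = mean(d$beta), sd = stats::sd(d$beta),
    min = min(d$beta), max = max(d$beta),
    pct_significant = 100 * mean(abs(d$t) >= t_cutoff),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[match(colnames(fit$beta_mat), out$predictor), ]
}

#' Classify local coefficient strength
#'
#' Bins a coefficient by magnitude: 0 is "none"; |beta| in (0, 0.25) weak,
#' [0.25, 0.5) moderate, [0.5, 1) strong, >= 1 very strong, suffixed with
#' the sign. Bins are right-open on the magnitude scale, mirrored for
#' negative values.
#'
#' @param beta finite numeric vector.
#' @return character vector of labels.
#' @export
classify_strength <- function(beta) {
  if (any(!is.finite(beta)))
    stop("coefficients must be finite", call. = FALSE)
  a <- abs(beta)
  mag <- ifelse(a == 0, "none",
                ifelse(a < 0.25, "weak",
                       ifelse(a < 0.5, "moderate",
                              ifelse(a < 1, "strong", "very strong"))))
  ifelse(mag == "none", "none",
         paste(mag, ifelse(beta > 0, "positive", "negative")))
}

#' Spatial autocorrelation of GTWR residuals
#'
#' Global Moran's I on the fit residuals: pooled (residuals averaged by
#' region across years) or per year. A well-calibrated spatiotemporal fit
#' leaves residuals with Moran's I near its null expectation.
#'
#' @param fit a `gtwr_fit`.
#' @param w a `spatial_weights` over the fit's region set.
#' @param by_year if TRUE, return a named list of per-year results instead
#'   of the pooled result.
#' @param n_perm,seed permutation settings for [global_moran()].
#' @return a `global_moran` (pooled) or named list of them (per year).
#' @export
residual_moran <- function(fit, w, by_year = FALSE, n_perm = 999,
                           seed = NULL) {
  stopifnot(inherits(fit, "gtwr_fit"), inherits(w, "spatial_weights"))
  if (by_year) {
    yrs <- sort(unique(fit$year))
    out <- lapply(yrs, function(yr) {
      sel <- fit$year == yr
      r <- fit$residuals[sel][match(w$region_ids, fit$region_id[sel])]
      global_moran(r, w, n_perm = n_perm, seed = seed)
    })
    names(out) <- yrs
    out
  } else {
    pooled <- tapply(fit$residuals, fit$region_id, mean)
    global_moran(as.numeric(pooled[w$region_ids]), w, n_perm = n_perm,
                 seed = seed)
  }
}
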