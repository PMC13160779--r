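test_that("spatial kernel: origin, bandwidth point, arithmetic oracle, monotonicity", {
  expect_equal(gtwr_spatial_weight(0, 74.8), 1)
  expect_equal(gtwr_spatial_weight(74.8, 74.8), exp(-0.5))
  expect_equal(gtwr_spatial_weight(74.8, 74.8), 0.6065, tolerance = 1e-4)
  b <- 74.8
  expect_equal(gtwr_spatial_weight(3 * b, b), exp(-(3 * b)^2 / (2 * b^2)))
  d <- seq(0, 200, by = 10)
  expect_true(all(diff(gtwr_spatial_weight(d, 50)) < 0))
  expect_error(gtwr_spatial_weight(10, 0), "bandwidth")
  expect_error(gtwr_spatial_weight(-1, 10), "nonnegative")
})

test_that("temporal kernel: equal times, yearly decay, symmetry", {
  expect_equal(gtwr_temporal_weight(2020, 2020, 3.2), 1)
  expect_equal(gtwr_temporal_weight(2021, 2020, 3.2), exp(-1 / 3.2))
  expect_equal(gtwr_temporal_weight(2021, 2020, 3.2), 0.7316,
               tolerance = 1e-4)
  expect_equal(gtwr_temporal_weight(2020, 2022, 1.5),
               gtwr_temporal_weight(2022, 2020, 1.5))
  expect_error(gtwr_temporal_weight(2020, 2021, -1), "bandwidth")
})

test_that("combined weights are the product of the two kernels", {
  set.seed(71)
  coords <- matrix(runif(20, 0, 100), 10, 2)
  times <- sample(2020:2022, 10, replace = TRUE)
  w <- gtwr_combined_weights(3, coords, times, b = 40, h = 2)
  expect_equal(w[3], 1)
  for (j in c(1, 5, 9)) {
    d <- sqrt(sum((coords[j, ] - coords[3, ])^2))
    expect_equal(w[j], gtwr_spatial_weight(d, 40) *
                   gtwr_temporal_weight(times[j], times[3], 2),
                 tolerance = 1e-14)
  }
  # flat kernels: all weights 1
  wflat <- gtwr_combined_weights(3, coords, times, b = 1e12, h = 1e12)
  expect_equal(wflat, rep(1, 10), tolerance = 1e-9)
})

test_that("local weighted solve: unweighted, indicator, and oracle weights", {
  set.seed(72)
  n <- 30
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  y <- drop(X %*% c(1, 2, -1) + rnorm(n, 0, 0.4))
  # all weights 1: the OLS solution
  lf <- gtwr:::gtwr_local_solve(X, y, rep(1, n))
  expect_equal(lf$beta, ols_oracle(X, y), tolerance = 1e-10)
  # indicator weights: OLS on the subset
  sub <- 1:12
  w_ind <- as.numeric(seq_len(n) %in% sub)
  lf2 <- gtwr:::gtwr_local_solve(X, y, w_ind)
  expect_equal(lf2$beta, ols_oracle(X[sub, ], y[sub]), tolerance = 1e-10)
  # random positive weights vs explicit weighted normal equations
  w <- runif(n, 0.05, 1)
  lf3 <- gtwr:::gtwr_local_solve(X, y, w)
  expect_equal(lf3$beta, drop(wls_oracle(X, y, w)), tolerance = 1e-10)
})

test_that("flat-bandwidth GTWR collapses to OLS with tr(S) = p + 1", {
  tp <- make_test_panel(seed = 5, k = 2, noise_sd = 0.3)
  fit <- gtwr_fit(tp$panel, tp$regions, tp$covariates, "y",
                  bw_spatial = 1e9, bw_temporal = 1e9)
  ols <- ols_fit(as.matrix(tp$panel[, tp$covariates]), tp$panel$y)
  expect_lt(max(abs(sweep(fit$beta_mat, 2, ols$coefficients))), 1e-6)
  expect_equal(fit$r2, ols$r2, tolerance = 1e-9)
  expect_equal(fit$fitted, ols$fitted, tolerance = 1e-7)
  expect_equal(fit$tr_s, length(tp$covariates) + 1, tolerance = 1e-6)
  # hat-trace lower bound attained at the flat limit
  expect_gte(fit$tr_s + 1e-6, length(tp$covariates) + 1)
})

test_that("fitted plus residual reconstructs y exactly; metrics are coherent", {
  tp <- make_test_panel(seed = 6, k = 3, noise_sd = 0.25)
  fit <- gtwr_fit(tp$panel, tp$regions, tp$covariates, "y",
                  bw_spatial = 60, bw_temporal = 2)
  expect_equal(fit$fitted + fit$residuals, tp$panel$y, tolerance = 1e-12)
  expect_true(fit$tr_s > 0 && fit$tr_s <= fit$n)
  ssr <- sum(fit$residuals^2)
  expect_equal(fit$rmse, sqrt(ssr / fit$n), tolerance = 1e-12)
  expect_equal(fit$r2, 1 - ssr / sum((tp$panel$y - mean(tp$panel$y))^2),
               tolerance = 1e-12)
  # AICc reproduced term-by-term from its definition
  aicc_hand <- 2 * fit$n * log(fit$sigma_hat) + fit$n * log(2 * pi) +
    fit$n * (fit$n + fit$tr_s) / (fit$n - 2 - fit$tr_s)
  expect_equal(fit$aicc, aicc_hand, tolerance = 1e-12)
})

test_that("AICc is undefined once effective parameters approach n", {
  expect_error(gtwr:::gtwr_aicc(0.5, n = 39, tr_s = 37.5), "AICc undefined")
  expect_error(gtwr:::gtwr_aicc(0.5, n = 10, tr_s = 8), "AICc undefined")
  expect_silent(gtwr:::gtwr_aicc(0.5, n = 39, tr_s = 10))
})

test_that("bandwidth selection: degenerate grid, argmin contract, stationary truth", {
  tp <- make_test_panel(seed = 8, k = 2, noise_sd = 0.25)
  # one-point grid returns that point
  sel1 <- gtwr_select_bandwidths(tp$panel, tp$regions, tp$covariates, "y",
                                 b_grid = 80, h_grid = 2, refine = FALSE)
  expect_equal(sel1$b, 80)
  expect_equal(sel1$h, 2)
  # argmin contract over the evaluated surface
  sel <- gtwr_select_bandwidths(tp$panel, tp$regions, tp$covariates, "y",
                                b_grid = c(20, 60, 180),
                                h_grid = c(0.5, 2, 8), refine = TRUE)
  expect_true(all(sel$aicc <= sel$surface$aicc + 1e-9, na.rm = TRUE))
  # spatially and temporally constant truth prefers large bandwidths
  spec <- list("(Intercept)" = list(a = 1), x1 = list(a = 0.8),
               x2 = list(a = -0.5))
  tpc <- make_test_panel(seed = 9, k = 2, noise_sd = 0.2,
                         surface_spec = spec)
  b_grid <- c(30, 90, 270, 810, 2430)
  selc <- gtwr_select_bandwidths(tpc$panel, tpc$regions, tpc$covariates, "y",
                                 b_grid = b_grid, h_grid = c(0.5, 2, 8, 32),
                                 refine = FALSE)
  expect_gte(selc$b, 270)
})

test_that("coefficient summary: moments oracle and degenerate cases", {
  tp <- make_test_panel(seed = 10, k = 2, noise_sd = 0.25)
  fit <- gtwr_fit(tp$panel, tp$regions, tp$covariates, "y", 60, 2)
  cs <- coefficient_summary(fit, t_cutoff = 1.96)
  expect_equal(cs$predictor, colnames(fit$beta_mat))
  for (r in seq_len(nrow(cs))) {
    b <- fit$beta_mat[, cs$predictor[r]]
    expect_equal(cs$mean[r], sum(b) / length(b), tolerance = 1e-12)
    expect_equal(cs$min[r], min(b))
    expect_equal(cs$max[r], max(b))
    expect_true(cs$min[r] <= cs$mean[r] && cs$mean[r] <= cs$max[r])
  }
  # an absurd cutoff marks nothing significant
  cs_hi <- coefficient_summary(fit, t_cutoff = 1e6)
  expect_equal(cs_hi$pct_significant, rep(0, nrow(cs_hi)))
  # flat-kernel fit: constant local estimates, sd = 0
  fit_flat <- gtwr_fit(tp$panel, tp$regions, tp$covariates, "y", 1e9, 1e9)
  cs_flat <- coefficient_summary(fit_flat)
  expect_equal(cs_flat$sd, rep(0, nrow(cs_flat)), tolerance = 1e-8)
})

test_that("coefficient strength bins and boundary conventions", {
  expect_equal(classify_strength(0.3), "moderate positive")
  expect_equal(classify_strength(0), "none")
  expect_equal(classify_strength(-1.2), "very strong negative")
  expect_equal(classify_strength(c(0.1, 0.25, 0.5, 1, -0.25, -0.5, -1)),
               c("weak positive", "moderate positive", "strong positive",
                 "very strong positive", "moderate negative",
                 "strong negative", "very strong negative"))
  expect_error(classify_strength(NaN), "finite")
})

test_that("residual Moran: pooled equals by-hand aggregation; clustering detected", {
  tp <- make_test_panel(seed = 12, k = 2, noise_sd = 0.3)
  w <- row_standardize(queen_weights(tp$regions))
  fit <- gtwr_fit(tp$panel, tp$regions, tp$covariates, "y", 60, 2)
  rm_pooled <- residual_moran(fit, w, n_perm = 199, seed = 1)
  pooled <- tapply(fit$residuals, fit$region_id, mean)[w$region_ids]
  expect_equal(rm_pooled$I, moran_oracle(as.numeric(pooled), w$W),
               tolerance = 1e-12)
  rm_years <- residual_moran(fit, w, by_year = TRUE, n_perm = 199, seed = 1)
  expect_length(rm_years, 3)
  # white-noise residuals stay near the null expectation on average
  set.seed(99)
  Is <- replicate(20, global_moran(rnorm(13), w, n_perm = 99)$I)
  expect_lt(abs(mean(Is) - (-1 / 12)), 0.1)
  # strongly clustered values are flagged
  xc <- tp$regions$regions$u / 40
  gm <- global_moran(xc, w, n_perm = 499, seed = 2)
  expect_lt(gm$p_perm, 0.05)
})
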