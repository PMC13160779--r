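# Fixtures and brute-force oracles shared across the suite. Oracles are
# deliberately naive (explicit loops, unpivoted elimination) and independent
# of the package's computation paths.

# rectangular grid of square regions as a region_set
make_grid_regions <- function(nx, ny, cell = 10) {
  ids <- sprintf("G%02d", seq_len(nx * ny))
  polys <- list()
  cx <- cy <- numeric(nx * ny)
  k <- 0
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1
    x0 <- (i - 1) * cell; y0 <- (j - 1) * cell
    ring <- cbind(u = c(x0, x0 + cell, x0 + cell, x0, x0),
                  v = c(y0, y0, y0 + cell, y0 + cell, y0))
    polys[[ids[k]]] <- ring
    cx[k] <- x0 + cell / 2; cy[k] <- y0 + cell / 2
  }
  structure(list(
    regions = data.frame(region_id = ids, u = cx, v = cy,
                         stringsAsFactors = FALSE),
    polygons = polys,
    bbox = c(xmin = 0, xmax = nx * cell, ymin = 0, ymax = ny * cell)
  ), class = "region_set")
}

# region_set from explicit polygons (for corner-touch / disjoint cases)
make_regions_from_polys <- function(polys) {
  ids <- names(polys)
  cen <- t(sapply(polys, function(r) c(mean(r[-nrow(r), 1]),
                                       mean(r[-nrow(r), 2]))))
  structure(list(
    regions = data.frame(region_id = ids, u = cen[, 1], v = cen[, 2],
                         stringsAsFactors = FALSE),
    polygons = polys,
    bbox = c(xmin = min(cen[, 1]) - 1, xmax = max(cen[, 1]) + 1,
             ymin = min(cen[, 2]) - 1, ymax = max(cen[, 2]) + 1)
  ), class = "region_set")
}

# synthetic panel with known gradient surfaces, for recovery-style tests
make_test_panel <- function(seed = 1, n_regions = 13, years = 2020:2022,
                            k = 3, noise_sd = 0.25,
                            surface_spec = NULL) {
  regions <- sim_region_lattice(n_regions, seed = seed)
  panel <- sim_covariate_panel(regions, years, seed = seed + 100, k = k,
                               collinear_pair = FALSE)
  if (is.null(surface_spec)) {
    surface_spec <- list("(Intercept)" = list(a = 2, b = 0, c = 0),
                         x1 = list(a = 0, b = 1, c = 0),
                         x2 = list(a = 0.5, b = -0.6, c = 0.1),
                         x3 = list(a = -0.3, b = 0.4, c = 0))
    surface_spec <- surface_spec[seq_len(k + 1)]
  }
  surfaces <- sim_coefficient_surfaces(regions, years, surface_spec)
  covariates <- setdiff(names(surface_spec), "(Intercept)")
  panel$y <- sim_outcome(panel, surfaces, covariates, noise_sd = noise_sd,
                         seed = seed + 200)
  list(regions = regions, panel = panel, surfaces = surfaces,
       covariates = covariates)
}

# align a true coefficient surface with panel row order
true_surface_vector <- function(surfaces, panel, predictor) {
  s <- surfaces[surfaces$predictor == predictor, ]
  s$beta[match(paste(panel$region_id, panel$year),
               paste(s$region_id, s$year))]
}

# unpivoted Gaussian elimination (oracle linear solver)
ge_solve <- function(A, b) {
  n <- nrow(A)
  M <- cbind(A, b)
  for (p in seq_len(n - 1))
    for (i in (p + 1):n) {
      f <- M[i, p] / M[p, p]
      M[i, ] <- M[i, ] - f * M[p, ]
    }
  x <- numeric(n)
  for (i in n:1)
    x[i] <- (M[i, n + 1] - sum(M[i, seq_len(n)][-seq_len(i)] * x[-seq_len(i)])) /
      M[i, i]
  x
}

# normal-equation least squares via the oracle solver
ols_oracle <- function(X, y) ge_solve(crossprod(X), crossprod(X, y))

# weighted normal equations via the oracle solver
wls_oracle <- function(X, y, w) {
  ge_solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
}

# double-loop evaluation of the global Moran statistic
moran_oracle <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  n * num / (sum(W) * sum((x - xb)^2))
}

# explicit-formula Pearson correlation
pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
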