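test_that("region lattice tessellates the rectangle into contiguous polygons", {
  rs <- sim_region_lattice(13, seed = 1)
  expect_s3_class(rs, "region_set")
  expect_equal(nrow(rs$regions), 13)
  expect_length(rs$polygons, 13)
  # tessellation conserves area
  total <- sum(vapply(rs$polygons, gtwr:::polygon_area, numeric(1)))
  expect_equal(total, 180 * 60, tolerance = 1e-8)
  # every region has at least one queen neighbour
  wq <- queen_weights(rs)
  expect_true(all(rowSums(wq$W) >= 1))
  # centroid falls inside the polygon's bounding box
  for (id in rs$regions$region_id) {
    ring <- rs$polygons[[id]]
    cen <- rs$regions[rs$regions$region_id == id, c("u", "v")]
    expect_true(cen$u >= min(ring[, 1]) && cen$u <= max(ring[, 1]))
    expect_true(cen$v >= min(ring[, 2]) && cen$v <= max(ring[, 2]))
  }
})

test_that("region lattice: 4-region case and determinism contract", {
  rs4 <- sim_region_lattice(4, seed = 0)
  expect_equal(length(rs4$polygons), 4)
  expect_equal(sum(vapply(rs4$polygons, gtwr:::polygon_area, numeric(1))),
               180 * 60, tolerance = 1e-8)
  a <- sim_region_lattice(13, seed = 1)
  b <- sim_region_lattice(13, seed = 1)
  expect_identical(a$regions, b$regions)
  expect_identical(a$polygons, b$polygons)
  expect_error(sim_region_lattice(3), "n_regions")
})

test_that("covariate panel: size, standardization, collinear pair, determinism", {
  rs <- sim_region_lattice(13, seed = 1)
  p <- sim_covariate_panel(rs, 2020:2022, seed = 7)
  expect_equal(nrow(p), 39)
  xcols <- paste0("x", 1:8)
  expect_true(all(xcols %in% names(p)))
  for (cn in xcols) {
    expect_equal(mean(p[[cn]]), 0, tolerance = 1e-10)
    expect_equal(sd(p[[cn]]), 1, tolerance = 1e-10)
  }
  expect_gte(cor(p$x1, p$x2), 0.9)
  p_off <- sim_covariate_panel(rs, 2020:2022, seed = 7,
                               collinear_pair = FALSE)
  expect_lt(cor(p_off$x1, p_off$x2), 0.9)
  expect_identical(p, sim_covariate_panel(rs, 2020:2022, seed = 7))
  expect_true(all(p$population > 0))
  expect_error(sim_covariate_panel(rs, years = 2020), "years")
})

test_that("coefficient surfaces follow the gradient + drift recipe", {
  rs <- sim_region_lattice(13, seed = 1)
  # pure east-west gradient: westmost -1, eastmost +1
  s <- sim_coefficient_surfaces(rs, 2020:2022, list(x1 = list(a = 0, b = 1)))
  west <- rs$regions$region_id[which.min(rs$regions$u)]
  east <- rs$regions$region_id[which.max(rs$regions$u)]
  expect_equal(s$beta[s$region_id == west & s$year == 2020], -1)
  expect_equal(s$beta[s$region_id == east & s$year == 2020], 1)
  expect_true(any(s$beta < 0) && any(s$beta > 0))  # sign flip across space
  # degenerate constant surface
  s2 <- sim_coefficient_surfaces(rs, 2020:2022, list(x1 = list(a = 0.5)))
  expect_true(all(s2$beta == 0.5))
  # time drift c * (t - t0)
  s3 <- sim_coefficient_surfaces(rs, c(2020, 2022),
                                 list(x1 = list(a = 0, b = 1, c = 0.1)))
  d <- s3$beta[s3$year == 2022] - s3$beta[s3$year == 2020]
  expect_equal(d, rep(0.2, 13), tolerance = 1e-12)
})

test_that("outcome generation matches the linear predictor", {
  rs <- sim_region_lattice(13, seed = 1)
  panel <- sim_covariate_panel(rs, 2020:2022, seed = 7, k = 2,
                               collinear_pair = FALSE)
  # constant model: intercept only
  s0 <- sim_coefficient_surfaces(rs, 2020:2022,
                                 list("(Intercept)" = list(a = 2)))
  y0 <- sim_outcome(panel, s0, covariates = character(0), noise_sd = 0,
                    seed = 1)
  expect_equal(y0, rep(2, 39))
  # noiseless outcome equals sum(beta * x) to machine precision
  spec <- list("(Intercept)" = list(a = 1), x1 = list(a = 0, b = 1),
               x2 = list(a = -0.5, c = 0.2))
  surf <- sim_coefficient_surfaces(rs, 2020:2022, spec)
  y <- sim_outcome(panel, surf, c("x1", "x2"), noise_sd = 0, seed = 1)
  eta <- 1 + true_surface_vector(surf, panel, "x1") * panel$x1 +
    true_surface_vector(surf, panel, "x2") * panel$x2
  expect_equal(y, eta, tolerance = 1e-14)
  # empirical noise sd close to the requested value
  devs <- replicate(40, {
    yn <- sim_outcome(panel, surf, c("x1", "x2"), noise_sd = 0.5,
                      seed = sample.int(1e6, 1))
    yn - eta
  })
  expect_equal(sd(as.vector(devs)), 0.5, tolerance = 0.05)
  expect_error(sim_outcome(panel, surf, c("x1", "x2", "x9")), "missing")
})

test_that("component series: lockdown pulse, baseline, determinism", {
  cs <- sim_component_series(36, lockdown_start = 5, lockdown_len = 6,
                             pulse = 30, noise_sd = 1, seed = 3)
  win <- 5:10
  expect_true(all(cs$M_R[win][2:5] > 0))
  expect_true(all(cs$M_C[win][2:5] < 0))
  # zero noise: everything exactly at baseline outside the window
  cs0 <- sim_component_series(24, lockdown_start = 6, lockdown_len = 4,
                              pulse = 30, noise_sd = 0, seed = 1)
  pre <- 1:5
  for (nm in c("M_R", "M_C", "E_R", "E_C", "R_R", "R_C"))
    expect_equal(cs0[[nm]][pre], rep(0, 5))
  expect_true(all(as.matrix(cs[-1]) > -100))
  expect_identical(cs, sim_component_series(36, 5, 6, 30, 1, seed = 3))
  expect_error(sim_component_series(12, lockdown_start = 10,
                                    lockdown_len = 6), "window")
})

test_that("GeoJSON round trip preserves geometry and ids", {
  rs <- sim_region_lattice(6, seed = 2)
  tf <- tempfile(fileext = ".geojson")
  write_region_geojson(rs, tf)
  back <- read_region_geojson(tf)
  expect_equal(back$regions$region_id, rs$regions$region_id)
  expect_equal(back$regions$u, rs$regions$u, tolerance = 1e-10)
  for (id in rs$regions$region_id)
    expect_equal(unname(back$polygons[[id]]), unname(rs$polygons[[id]]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  unlink(tf)
})
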