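#' Simulate a contiguous lattice of irregular planar regions
#'
#' Tessellates a rectangle into `n_regions` contiguous, irregularly shaped
#' polygons by taking the Voronoi diagram of jittered grid points, clipped to
#' the rectangle. Coordinates are planar kilometres; the default rectangle is
#' 180 x 60 km, the rough aspect of a mid-size Caribbean island divided into
#' about a dozen police/administrative regions. The tessellation guarantees
#' that every region shares a boundary with at least one other, so Queen and
#' Rook contiguity graphs are always connected enough for spatial analysis.
#'
#' @param n_regions number of regions (>= 4).
#' @param seed integer seed; the lattice is reproducible from `(n_regions, seed)`.
#' @param width,height rectangle dimensions in km.
#' @param jitter jitter amplitude as a fraction of the grid spacing, in (0, 0.5).
#' @return An object of class `region_set`: a list with
#'   * `regions`: data.frame with `region_id`, centroid `u`, `v` (km),
#'   * `polygons`: named list of closed coordinate matrices (columns `u`, `v`),
#'   * `bbox`: `c(xmin, xmax, ymin, ymax)`.
#' @export
sim_region_lattice <- function(n_regions = 13, seed = 1,
                               width = 180, height = 60, jitter = 0.35) {
  if (!is.numeric(n_regions) || length(n_regions) != 1 || n_regions < 4)
    stop("`n_regions` must be a single integer >= 4", call. = FALSE)
  n_regions <- as.integer(n_regions)
  set.seed(seed)

  # grid roughly matching the rectangle's aspect, then keep the first n cells
  ncol_grid <- max(2L, ceiling(sqrt(n_regions * width / height)))
  nrow_grid <- max(1L, ceiling(n_regions / ncol_grid))
  dx <- width / ncol_grid
  dy <- height / nrow_grid
  ij <- expand.grid(i = seq_len(ncol_grid), j = seq_len(nrow_grid))
  ij <- ij[seq_len(n_regions), , drop = FALSE]
  px <- (ij$i - 0.5) * dx + stats::runif(n_regions, -jitter, jitter) * dx
  py <- (ij$j - 0.5) * dy + stats::runif(n_regions, -jitter, jitter) * dy
  px <- pmin(pmax(px, 1e-6), width - 1e-6)
  py <- pmin(pmax(py, 1e-6), height - 1e-6)

  dd <- deldir::deldir(px, py, rw = c(0, width, 0, height))
  tiles <- deldir::tile.list(dd)

  ids <- sprintf("R%02d", seq_len(n_regions))
  polygons <- vector("list", n_regions)
  cx <- cy <- numeric(n_regions)
  for (k in seq_len(n_regions)) {
    ring <- cbind(u = tiles[[k]]$x, v = tiles[[k]]$y)
    ring <- rbind(ring, ring[1, , drop = FALSE])     # close the ring
    polygons[[k]] <- ring
    cen <- polygon_centroid(ring)
    cx[k] <- cen[1]; cy[k] <- cen[2]
  }
  names(polygons) <- ids
  structure(list(
    regions  = data.frame(region_id = ids, u = cx, v = cy,
                          stringsAsFactors = FALSE),
    polygons = polygons,
    bbox     = c(xmin = 0, xmax = width, ymin = 0, ymax = height)
  ), class = "region_set")
}

# area-weighted centroid of a closed ring (shoelace formulas)
polygon_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  i <- seq_len(n - 1)
  cr <- x[i] * y[i + 1] - x[i + 1] * y[i]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x[i]), mean(y[i])))
  c(sum((x[i] + x[i + 1]) * cr) / (6 * a),
    sum((y[i] + y[i + 1]) * cr) / (6 * a))
}

polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  i <- seq_len(length(x) - 1)
  abs(sum(x[i] * y[i + 1] - x[i + 1] * y[i])) / 2
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set: %d regions, bbox %.0f x %.0f km\n",
              nrow(x$regions), x$bbox["xmax"] - x$bbox["xmin"],
              x$bbox["ymax"] - x$bbox["ymin"]))
  invisible(x)
}

#' Simulate a standardized covariate panel over regions and years
#'
#' Draws `k` covariates per region-year from a multivariate normal with an
#' exchangeable correlation structure (`rho` off-diagonal) and, optionally,
#' one deliberately collinear pair (`collinear_rho`), then standardizes each
#' column to mean 0, sd 1 (sample sd). The collinear pair exercises
#' multicollinearity screening (VIF, LASSO) downstream; the exchangeable 0.3
#' background reflects the moderate mutual correlation typical of regional
#' socioeconomic indicators.
#'
#' @param region_set a `region_set` from [sim_region_lattice()].
#' @param years integer vector of at least two years.
#' @param seed integer seed.
#' @param k number of covariates (default 8).
#' @param rho exchangeable off-diagonal correlation.
#' @param collinear_pair logical; make columns 1 and 2 correlated at
#'   `collinear_rho`.
#' @param collinear_rho target correlation for the collinear pair.
#' @return data.frame with columns `region_id`, `year`, `x1..xk`,
#'   `population`; one row per region-year, no missing cells.
#' @export
sim_covariate_panel <- function(region_set, years = 2020:2022, seed = 1,
                                k = 8, rho = 0.3, collinear_pair = TRUE,
                                collinear_rho = 0.95) {
  stopifnot(inherits(region_set, "region_set"))
  if (length(years) < 2) stop("need >= 2 years", call. = FALSE)
  ids <- region_set$regions$region_id
  if (length(ids) == 0) stop("empty region set", call. = FALSE)
  n <- length(ids) * length(years)
  set.seed(seed)

  R <- matrix(rho, k, k); diag(R) <- 1
  if (isTRUE(collinear_pair) && k >= 2) R[1, 2] <- R[2, 1] <- collinear_rho
  L <- chol(R)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% L
  Z <- scale(Z)  # exact mean 0, sample sd 1 per column
  colnames(Z) <- paste0("x", seq_len(k))

  pop <- round(exp(stats::rnorm(length(ids), log(250000), 0.5)))
  panel <- expand.grid(region_id = ids, year = as.integer(years),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  panel <- panel[order(panel$year, match(panel$region_id, ids)), ]
  rownames(panel) <- NULL
  panel <- cbind(panel, as.data.frame(Z))
  panel$population <- pop[match(panel$region_id, ids)]
  panel
}

#' Simulate smooth spatially varying true coefficient surfaces
#'
#' Each surface is linear in the rescaled east-west coordinate and in time:
#' `beta(region, year) = a + b * u_scaled + c * (year - min(year))`, where
#' `u_scaled` maps region centroids' horizontal coordinate to `[-1, 1]`.
#' A nonzero `b` produces an east-west gradient; with `a = 0` the surface
#' changes sign across the island, mimicking predictors whose association
#' flips between western and eastern regions.
#'
#' @param region_set a `region_set`.
#' @param years integer years.
#' @param surface_spec named list; each element a list/vector with components
#'   `a`, `b`, `c`. Must include an `"(Intercept)"` entry when used with
#'   [sim_outcome()].
#' @return data.frame with columns `predictor`, `region_id`, `year`, `beta`.
#' @export
sim_coefficient_surfaces <- function(region_set, years, surface_spec) {
  stopifnot(inherits(region_set, "region_set"))
  u <- region_set$regions$u
  if (diff(range(u)) < 1e-12) {
    u_scaled <- rep(0, length(u))
  } else {
    u_scaled <- 2 * (u - min(u)) / (max(u) - min(u)) - 1
  }
  t0 <- min(years)
  out <- lapply(names(surface_spec), function(nm) {
    s <- as.list(surface_spec[[nm]])
    s$a <- if (is.null(s$a)) 0 else s$a
    s$b <- if (is.null(s$b)) 0 else s$b
    s$c <- if (is.null(s$c)) 0 else s$c
    g <- expand.grid(region_id = region_set$regions$region_id,
                     year = as.integer(years),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$predictor <- nm
    g$beta <- s$a + s$b * u_scaled[match(g$region_id,
                                         region_set$regions$region_id)] +
      s$c * (g$year - t0)
    g[, c("predictor", "region_id", "year", "beta")]
  })
  out <- do.call(rbind, out)
  stopifnot(all(is.finite(out$beta)))
  rownames(out) <- NULL
  out
}

#' Simulate the outcome of a spatially varying coefficient model
#'
#' Computes `y = beta_0(region, year) + sum_k beta_k(region, year) * x_k +
#' eps` with `eps ~ Normal(0, noise_sd^2)`. With `noise_sd = 0` the outcome
#' equals the linear predictor to machine precision, which is what parameter
#' recovery tests rely on.
#'
#' @param panel covariate panel from [sim_covariate_panel()].
#' @param surfaces coefficient surfaces from [sim_coefficient_surfaces()];
#'   must cover `"(Intercept)"` and every covariate used.
#' @param covariates character vector of covariate column names; defaults to
#'   every surface predictor other than the intercept.
#' @param noise_sd nonnegative noise standard deviation.
#' @param seed integer seed for the noise draw.
#' @return numeric outcome vector aligned with `panel` rows.
#' @export
sim_outcome <- function(panel, surfaces, covariates = NULL,
                        noise_sd = 0.25, seed = 1) {
  stopifnot(noise_sd >= 0)
  preds <- unique(surfaces$predictor)
  if (!"(Intercept)" %in% preds)
    stop("surfaces must include an \"(Intercept)\" entry", call. = FALSE)
  if (is.null(covariates)) covariates <- setdiff(preds, "(Intercept)")
  missing_surf <- setdiff(covariates, preds)
  if (length(missing_surf))
    stop("missing coefficient surface for: ",
         paste(missing_surf, collapse = ", "), call. = FALSE)
  key <- paste(panel$region_id, panel$year)
  beta_of <- function(nm) {
    s <- surfaces[surfaces$predictor == nm, ]
    s$beta[match(key, paste(s$region_id, s$year))]
  }
  eta <- beta_of("(Intercept)")
  for (nm in covariates) eta <- eta + beta_of(nm) * panel[[nm]]
  if (anyNA(eta)) stop("surfaces do not cover every panel cell", call. = FALSE)
  set.seed(seed)
  eta + stats::rnorm(nrow(panel), 0, noise_sd)
}

#' Simulate monthly activity-stream percent changes with a lockdown pulse
#'
#' Produces the six streams feeding the isolation index: residential and
#' commercial mobility (`M_R`, `M_C`), residential and commercial electricity
#' (`E_R`, `E_C`), stay-at-home and between-area movement range (`R_R`,
#' `R_C`), each as percent change from baseline per month. During the
#' lockdown window residential streams rise and commercial streams fall by a
#' raised-cosine pulse of amplitude `pulse`; Gaussian noise of sd `noise_sd`
#' is added throughout. All values stay above -100 so level form
#' `1 + p/100` remains strictly positive.
#'
#' @param n_months length of the series.
#' @param lockdown_start,lockdown_len first month and length (months) of the
#'   lockdown window; must lie inside the series.
#' @param pulse pulse amplitude in percent points (default 30).
#' @param noise_sd noise sd in percent points (default 2).
#' @param seed integer seed.
#' @return An object of class `component_series`: a data.frame with columns
#'   `month`, `M_R`, `M_C`, `E_R`, `E_C`, `R_R`, `R_C`, plus attribute
#'   `lockdown = c(start, end)`.
#' @export
sim_component_series <- function(n_months = 36, lockdown_start = 3,
                                 lockdown_len = 4, pulse = 30, noise_sd = 2,
                                 seed = 1) {
  if (lockdown_start < 1 || lockdown_start + lockdown_len - 1 > n_months)
    stop("lockdown window must lie inside the series", call. = FALSE)
  set.seed(seed)
  m <- seq_len(n_months)
  in_win <- m >= lockdown_start & m < lockdown_start + lockdown_len
  shape <- numeric(n_months)
  # raised cosine over the window: 0 at the edges, 1 at the centre
  tt <- (m[in_win] - lockdown_start + 0.5) / lockdown_len
  shape[in_win] <- sin(pi * tt)^2

  res_names <- c("M_R", "E_R", "R_R")
  com_names <- c("M_C", "E_C", "R_C")
  out <- data.frame(month = m)
  for (nm in res_names)
    out[[nm]] <- pulse * shape + stats::rnorm(n_months, 0, noise_sd)
  for (nm in com_names)
    out[[nm]] <- -pulse * shape + stats::rnorm(n_months, 0, noise_sd)
  for (nm in c(res_names, com_names))
    out[[nm]] <- pmax(out[[nm]], -99)   # keep level form positive
  out <- out[, c("month", "M_R", "M_C", "E_R", "E_C", "R_R", "R_C")]
  attr(out, "lockdown") <- c(start = lockdown_start,
                             end = lockdown_start + lockdown_len - 1)
  class(out) <- c("component_series", "data.frame")
  out
}

#' Write region geometries as GeoJSON (planar km coordinates)
#'
#' @param region_set a `region_set`.
#' @param path output file path.
#' @param properties optional data.frame of extra per-region properties,
#'   matched to regions by row order or by a `region_id` column.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region_set, path, properties = NULL) {
  stopifnot(inherits(region_set, "region_set"))
  ids <- region_set$regions$region_id
  feats <- lapply(seq_along(ids), function(k) {
    props <- list(region_id = ids[k],
                  centroid_u = region_set$regions$u[k],
                  centroid_v = region_set$regions$v[k])
    if (!is.null(properties)) {
      row <- if ("region_id" %in% names(properties))
        properties[match(ids[k], properties$region_id), , drop = FALSE]
      else properties[k, , drop = FALSE]
      for (nm in setdiff(names(row), "region_id")) props[[nm]] <- row[[nm]]
    }
    ring <- region_set$polygons[[ids[k]]]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) unname(ring[i, ])))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read region geometries from GeoJSON written by [write_region_geojson()]
#'
#' @param path GeoJSON file path (FeatureCollection of single-ring Polygons
#'   with a `region_id` property; planar km coordinates).
#' @return a `region_set`.
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  polys <- list(); ids <- character(0)
  for (f in gj$features) {
    id <- as.character(f$properties$region_id)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    colnames(ring) <- c("u", "v")
    polys[[id]] <- ring
    ids <- c(ids, id)
  }
  cen <- t(vapply(polys, polygon_centroid, numeric(2)))
  allx <- unlist(lapply(polys, function(r) r[, 1]))
  ally <- unlist(lapply(polys, function(r) r[, 2]))
  structure(list(
    regions = data.frame(region_id = ids, u = cen[, 1], v = cen[, 2],
                         stringsAsFactors = FALSE),
    polygons = polys,
    bbox = c(xmin = min(allx), xmax = max(allx),
             ymin = min(ally), ymax = max(ally))
  ), class = "region_set")
}
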