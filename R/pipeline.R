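#' Build a run configuration for the full pipeline
#'
#' All tunable parameters of the end-to-end analysis live in one serializable
#' list so a run is reproducible from its config alone. Defaults describe the
#' reference synthetic study: 13 regions observed over 2020-2022 (39
#' region-year rows), 8 standardized covariates with one collinear pair,
#' east-west gradient coefficient surfaces with one sign flip, Gaussian
#' outcome noise, and a lockdown-pulse isolation-index series.
#'
#' @param seed master integer seed.
#' @param n_regions number of regions.
#' @param years integer years.
#' @param k number of covariates.
#' @param noise_sd outcome noise sd.
#' @param surface_spec named list of coefficient-surface specs
#'   (see [sim_coefficient_surfaces()]); `NULL` for the defaults.
#' @param weights_method one of "queen", "rook", "knn".
#' @param knn_k k for knn weights.
#' @param n_perm Moran permutations.
#' @param alpha LISA significance level.
#' @param bw_spatial,bw_temporal fixed bandwidths; `NULL` (default) selects
#'   both by AICc.
#' @param underreporting scenario fractions.
#' @param delta_x standardized shift for the offset table (SD units).
#' @param out_dir output directory (`NULL`: no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_regions = 13, years = 2020:2022, k = 8,
                       noise_sd = 0.25, surface_spec = NULL,
                       weights_method = "queen", knn_k = 4, n_perm = 999,
                       alpha = 0.05, bw_spatial = NULL, bw_temporal = NULL,
                       underreporting = c(0.10, 0.25, 0.40), delta_x = 0.5,
                       out_dir = NULL) {
  if (is.null(surface_spec)) {
    surface_spec <- list(
      "(Intercept)" = list(a = 2, b = 0, c = 0),
      x1 = list(a = 0, b = 1, c = 0.05),    # east-west sign flip
      x2 = list(a = 0.5, b = 0, c = 0),
      x3 = list(a = 0.25, b = 0.5, c = 0),
      x4 = list(a = -0.4, b = 0, c = 0))
    extra <- setdiff(paste0("x", seq_len(k)), names(surface_spec))
    for (nm in extra) surface_spec[[nm]] <- list(a = 0.1, b = 0, c = 0)
  }
  structure(list(seed = seed, n_regions = n_regions, years = years, k = k,
                 noise_sd = noise_sd, surface_spec = surface_spec,
                 weights_method = weights_method, knn_k = knn_k,
                 n_perm = n_perm, alpha = alpha, bw_spatial = bw_spatial,
                 bw_temporal = bw_temporal, underreporting = underreporting,
                 delta_x = delta_x, out_dir = out_dir),
            class = "run_config")
}

#' Validate region geometries against a panel
#'
#' Checks region-id agreement in both directions, panel completeness (every
#' region-year cell present exactly once), positive populations, and missing
#' values; collects every violation instead of stopping at the first.
#'
#' @param region_set a `region_set`.
#' @param panel a region-year panel data.frame.
#' @param outcome outcome column name, checked if present.
#' @return data.frame with columns `check` and `detail`; zero rows when the
#'   inputs are clean.
#' @export
validate_inputs <- function(region_set, panel, outcome = "y") {
  v <- list()
  add <- function(check, detail)
    v[[length(v) + 1]] <<- data.frame(check = check, detail = detail,
                                      stringsAsFactors = FALSE)
  ids <- region_set$regions$region_id
  in_panel <- unique(panel$region_id)
  for (id in setdiff(in_panel, ids))
    add("cross_reference", sprintf("panel region %s absent from geometry", id))
  for (id in setdiff(ids, in_panel))
    add("cross_reference", sprintf("geometry region %s absent from panel", id))
  years <- sort(unique(panel$year))
  cells <- table(panel$region_id, panel$year)
  for (id in intersect(ids, in_panel))
    for (yr in years) {
      cnt <- if (id %in% rownames(cells)) cells[id, as.character(yr)] else 0
      if (cnt == 0)
        add("completeness", sprintf("missing cell (%s, %s)", id, yr))
      if (cnt > 1)
        add("duplication", sprintf("duplicated cell (%s, %s)", id, yr))
    }
  if ("population" %in% names(panel) && any(panel$population <= 0))
    add("population", sprintf("%d nonpositive population value(s)",
                              sum(panel$population <= 0)))
  if (outcome %in% names(panel) && anyNA(panel[[outcome]]))
    add("missing_outcome", sprintf("%d missing outcome value(s)",
                                   sum(is.na(panel[[outcome]]))))
  if (length(v)) do.call(rbind, v)
  else data.frame(check = character(0), detail = character(0))
}

#' Run the full spatiotemporal study pipeline on synthetic data
#'
#' Executes every stage in order: synthetic region lattice and panel ->
#' isolation-index series -> spatial weights (queen, rook, knn) -> global
#' Moran per method and year + LISA classes -> OLS baseline with VIF, LASSO
#' screening and Breusch-Pagan -> GTWR with AICc bandwidth selection (or the
#' fixed bandwidths in the config) -> residual Moran -> underreporting
#' scenarios at frozen bandwidths -> standardized offset table. Deterministic
#' for a fixed config; when `out_dir` is set, all stage tables, the region
#' GeoJSON (with LISA classes as properties) and a JSON report are written
#' there.
#'
#' @param config a `run_config`.
#' @return a named list (`report`) of all stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  note("stage synth: n_regions=%d years=%s k=%d noise_sd=%g seed=%d",
       config$n_regions, paste(range(config$years), collapse = "-"),
       config$k, config$noise_sd, seed)
  regions <- sim_region_lattice(config$n_regions, seed = seed)
  panel <- sim_covariate_panel(regions, config$years, seed = seed + 1,
                               k = config$k)
  surfaces <- sim_coefficient_surfaces(regions, config$years,
                                       config$surface_spec)
  covariates <- setdiff(names(config$surface_spec), "(Intercept)")
  panel$y <- sim_outcome(panel, surfaces, covariates,
                         noise_sd = config$noise_sd, seed = seed + 2)

  comp <- sim_component_series(n_months = 12 * length(config$years),
                               seed = seed + 3)
  iso <- isolation_index(comp)
  iso_year <- yearly_isolation(iso, years = config$years)
  panel$isolation <- iso_year$isolation[match(panel$year, iso_year$year)]

  violations <- validate_inputs(regions, panel)
  if (nrow(violations))
    stop("stage validate failed:\n",
         paste(violations$detail, collapse = "\n"), call. = FALSE)
  note("stage validate: clean (%d rows)", nrow(panel))

  wq <- row_standardize(queen_weights(regions))
  wr <- row_standardize(rook_weights(regions))
  wk <- row_standardize(knn_weights(regions, k = config$knn_k))
  weights_list <- list(queen = wq, rook = wr, knn = wk)
  note("stage weights: queen/rook/knn(k=%d), row-standardized", config$knn_k)

  moran_tab <- yearly_moran_panel(panel, weights_list, outcome = "y",
                                  n_perm = config$n_perm, seed = seed + 4)
  w_main <- weights_list[[config$weights_method]]
  lisa <- lapply(sort(unique(panel$year)), function(yr) {
    sub <- panel[panel$year == yr, ]
    x <- sub$y[match(w_main$region_ids, sub$region_id)]
    lm_tab <- local_moran(x, w_main, n_perm = config$n_perm,
                          alpha = config$alpha, seed = seed + 5)
    lm_tab$year <- yr
    lm_tab
  })
  lisa <- do.call(rbind, lisa)
  note("stage moran: n_perm=%d alpha=%g method=%s", config$n_perm,
       config$alpha, config$weights_method)

  X <- as.matrix(panel[, covariates, drop = FALSE])
  ols <- ols_fit(X, panel$y)
  vif_tab <- vif(X)
  bp <- breusch_pagan(ols)
  lasso <- lasso_cv(X, panel$y, folds = 5, seed = seed + 6)
  note("stage ols: R2=%.4f; BP stat=%.4f p=%.4f; LASSO penalty=%.4g",
       ols$r2, bp$statistic, bp$p, lasso$alpha)

  if (is.null(config$bw_spatial) || is.null(config$bw_temporal)) {
    sel <- gtwr_select_bandwidths(panel, regions, covariates, "y")
    bw <- c(b = sel$b, h = sel$h)
    bw_mode <- "aicc-selected"
  } else {
    sel <- NULL
    bw <- c(b = config$bw_spatial, h = config$bw_temporal)
    bw_mode <- "fixed"
  }
  fit <- gtwr_fit(panel, regions, covariates, "y",
                  bw_spatial = bw[["b"]], bw_temporal = bw[["h"]])
  note("stage gtwr: %s b=%.4g km h=%.4g yr; R2=%.4f adjR2=%.4f AICc=%.4f",
       bw_mode, bw[["b"]], bw[["h"]], fit$r2, fit$adj_r2, fit$aicc)

  coef_sum <- coefficient_summary(fit)
  model_comparison <- data.frame(
    model = c("OLS", "GTWR"),
    r2 = c(ols$r2, fit$r2), adj_r2 = c(ols$adj_r2, fit$adj_r2),
    aicc = c(ols$aicc, fit$aicc), rmse = c(ols$rmse, fit$rmse))
  resid_I <- residual_moran(fit, w_main, n_perm = config$n_perm,
                            seed = seed + 7)

  scen <- scenario_analysis(panel, regions, covariates, "y",
                            bw_spatial = bw[["b"]], bw_temporal = bw[["h"]],
                            xs = config$underreporting)
  offsets <- offset_table(fit, delta_x = config$delta_x)
  note("stage sensitivity: x in {%s}; offsets at delta_x=%g SD",
       paste(config$underreporting, collapse = ", "), config$delta_x)

  report <- list(
    config = unclass(config)[setdiff(names(config), "surface_spec")],
    regions = regions, panel = panel, surfaces = surfaces,
    isolation = iso, isolation_yearly = iso_year,
    weights = weights_list,
    moran = moran_tab, lisa = lisa,
    ols = ols, vif = vif_tab, breusch_pagan = bp, lasso = lasso,
    bandwidths = list(mode = bw_mode, b = bw[["b"]], h = bw[["h"]],
                      surface = if (!is.null(sel)) sel$surface),
    gtwr = fit, coefficient_summary = coef_sum,
    model_comparison = model_comparison,
    residual_moran = resid_I,
    scenarios = scen, offsets = offsets,
    log = log_lines)

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  lisa_wide <- stats::reshape(
    report$lisa[, c("region_id", "year", "class")],
    idvar = "region_id", timevar = "year", direction = "wide")
  write_region_geojson(report$regions,
                       file.path(out_dir, "regions.geojson"),
                       properties = lisa_wide)
  wt(report$panel, "panel.tsv")
  wt(report$moran, "moran.tsv")
  wt(report$lisa, "lisa.tsv")
  wt(report$gtwr$local, "gtwr_local.tsv")
  wt(report$coefficient_summary, "coefficient_summary.tsv")
  wt(report$model_comparison, "model_comparison.tsv")
  wt(as.data.frame(report$scenarios), "scenarios.tsv")
  wt(report$offsets, "offsets.tsv")
  write_weights_triplet(report$weights$queen,
                        file.path(out_dir, "weights_queen.tsv"))
  write_gal(report$weights$queen, file.path(out_dir, "weights_queen.gal"))
  ols <- report$ols
  json <- list(
    config = report$config,
    ols = list(coefficients = as.list(ols$coefficients),
               r2 = ols$r2, adj_r2 = ols$adj_r2, rmse = ols$rmse,
               aicc = ols$aicc),
    vif = as.list(report$vif),
    breusch_pagan = report$breusch_pagan,
    lasso = list(penalty = report$lasso$alpha,
                 cv_rmse = report$lasso$cv_rmse,
                 zeroed = report$lasso$zeroed),
    bandwidths = report$bandwidths[c("mode", "b", "h")],
    gtwr = list(r2 = report$gtwr$r2, adj_r2 = report$gtwr$adj_r2,
                rmse = report$gtwr$rmse, aicc = report$gtwr$aicc,
                tr_s = report$gtwr$tr_s),
    residual_moran = list(I = report$residual_moran$I,
                          p = report$residual_moran$p_perm),
    log = report$log)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
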