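#' @title Spatial weight matrices for region polygons
#' @description Construction of Queen and Rook contiguity and k-nearest-
#'   neighbour weights from `region_set` polygons, with row standardization
#'   and plain-text export (sparse triplet and GAL adjacency formats).
#' @name spatial-weights
NULL

new_spatial_weights <- function(W, method, ids, k = NA_integer_,
                                row_standardized = FALSE) {
  dimnames(W) <- list(ids, ids)
  structure(list(W = W, method = method, k = k,
                 row_standardized = row_standardized,
                 S0 = sum(W), region_ids = ids),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %s%s, n = %d, S0 = %.4g%s\n",
              x$method, if (!is.na(x$k)) sprintf(" (k = %d)", x$k) else "",
              length(x$region_ids), x$S0,
              if (x$row_standardized) ", row-standardized" else ""))
  invisible(x)
}

# snapped vertex keys of a polygon ring (closing vertex dropped)
ring_vertex_keys <- function(ring, snap) {
  ring <- ring[-nrow(ring), , drop = FALSE]
  paste(round(ring[, 1] / snap), round(ring[, 2] / snap))
}

# undirected snapped edge keys of a polygon ring
ring_edge_keys <- function(ring, snap) {
  v <- ring_vertex_keys(rbind(ring, ring[1, ]), snap)  # keep closure
  n <- length(v)
  a <- v[-n]; b <- v[-1]
  keep <- a != b
  paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]), sep = "|")
}

contiguity_matrix <- function(region_set, keys_fun, snap) {
  stopifnot(inherits(region_set, "region_set"))
  ids <- region_set$regions$region_id
  n <- length(ids)
  if (n < 2) stop("need at least 2 regions", call. = FALSE)
  keys <- lapply(region_set$polygons[ids], keys_fun, snap = snap)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (any(keys[[i]] %in% keys[[j]])) W[i, j] <- W[j, i] <- 1
  if (any(rowSums(W) == 0))
    warning("isolate region(s) with no neighbours: ",
            paste(ids[rowSums(W) == 0], collapse = ", "), call. = FALSE)
  W
}

#' Queen contiguity weights
#'
#' Regions are neighbours iff their polygons share any boundary point (a
#' vertex suffices). Boundary matching compares vertices snapped to a
#' tolerance grid, robust to floating-point tessellation output.
#'
#' @param region_set a `region_set`.
#' @param snap snapping tolerance in km (default 1e-9).
#' @return a binary symmetric `spatial_weights` object.
#' @export
queen_weights <- function(region_set, snap = 1e-9) {
  W <- contiguity_matrix(region_set, ring_vertex_keys, snap)
  new_spatial_weights(W, "queen", region_set$regions$region_id)
}

#' Rook contiguity weights
#'
#' Regions are neighbours iff their polygons share a boundary segment of
#' positive length (a full snapped edge); corner-only contact does not count.
#'
#' @inheritParams queen_weights
#' @return a binary symmetric `spatial_weights` object.
#' @export
rook_weights <- function(region_set, snap = 1e-9) {
  W <- contiguity_matrix(region_set, ring_edge_keys, snap)
  new_spatial_weights(W, "rook", region_set$regions$region_id)
}

#' k-nearest-neighbour weights from region centroids
#'
#' Each region is linked to its `k` nearest centroids by Euclidean distance;
#' the resulting matrix is generally asymmetric. Distance ties are broken by
#' lowest region index for determinism.
#'
#' @param region_set a `region_set` (centroids in km).
#' @param k number of neighbours, `1 <= k < n`.
#' @return a binary `spatial_weights` object with `k` unit entries per row.
#' @export
knn_weights <- function(region_set, k = 4) {
  stopifnot(inherits(region_set, "region_set"))
  ids <- region_set$regions$region_id
  n <- length(ids)
  if (k < 1 || k >= n) stop("`k` must satisfy 1 <= k < n", call. = FALSE)
  xy <- as.matrix(region_set$regions[, c("u", "v")])
  D <- as.matrix(stats::dist(xy))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])   # ties -> lowest index
    W[i, (seq_len(n)[-i])[ord[seq_len(k)]]] <- 1
  }
  new_spatial_weights(W, "knn", ids, k = as.integer(k))
}

#' Row-standardize a spatial weight matrix
#'
#' Divides each nonempty row by its sum so rows sum to 1; empty rows
#' (isolates) are left as zeros. After standardization `S0` equals the number
#' of regions with at least one neighbour. Idempotent.
#'
#' @param w a `spatial_weights` object.
#' @return the row-standardized `spatial_weights`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  rs <- rowSums(w$W)
  W <- w$W
  nz <- rs > 0
  W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  out <- w
  out$W <- W
  out$row_standardized <- TRUE
  out$S0 <- sum(W)
  out
}

#' Write weights as sparse triplet text (columns i, j, w)
#' @param w a `spatial_weights`.
#' @param path output path (tab-separated, header row, region ids as labels).
#' @return `path`, invisibly.
#' @export
write_weights_triplet <- function(w, path) {
  idx <- which(w$W != 0, arr.ind = TRUE)
  out <- data.frame(i = w$region_ids[idx[, 1]],
                    j = w$region_ids[idx[, 2]],
                    w = w$W[idx])
  out <- out[order(out$i, out$j), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write weights as a GAL-style adjacency listing
#'
#' First line: number of regions. Then, per region, a line `id n_neighbours`
#' followed by a line listing the neighbour ids.
#'
#' @inheritParams write_weights_triplet
#' @return `path`, invisibly.
#' @export
write_gal <- function(w, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(length(w$region_ids)), con)
  for (i in seq_along(w$region_ids)) {
    nb <- w$region_ids[w$W[i, ] != 0]
    writeLines(c(paste(w$region_ids[i], length(nb)),
                 paste(nb, collapse = " ")), con)
  }
  invisible(path)
}
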