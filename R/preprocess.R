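#' Convert event counts to rates per `scale` population
#'
#' @param cases nonnegative counts.
#' @param population positive population counts (recycled like base R).
#' @param scale rate denominator scale; the default 1e4 reports cases per
#'   10,000 population, conventional for region-level incidence.
#' @return numeric rate vector `scale * cases / population`.
#' @export
rate_per <- function(cases, population, scale = 1e4) {
  if (any(!is.finite(population)) || any(population <= 0))
    stop("`population` must be positive everywhere", call. = FALSE)
  if (any(cases < 0, na.rm = TRUE))
    stop("`cases` must be nonnegative", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("`scale` must be a positive scalar", call. = FALSE)
  scale * cases / population
}

#' Z-score standardization with invertible metadata
#'
#' Centers and scales `x` to mean 0 and sd 1, storing the original mean and
#' sd so the transform can be inverted with [unscale()]. The sd convention is
#' the sample sd (n - 1 denominator).
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return An object of class `standardized`: list with `values`, `mu`,
#'   `sigma`.
#' @export
zscore <- function(x) {
  if (length(x) < 2) stop("need length >= 2", call. = FALSE)
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0)
    stop("constant vector: z-score undefined (zero variance)", call. = FALSE)
  structure(list(values = (x - mu) / sigma, mu = mu, sigma = sigma),
            class = "standardized")
}

#' Invert a z-score transform
#' @param z a `standardized` object from [zscore()].
#' @return the original-scale vector.
#' @export
unscale <- function(z) {
  stopifnot(inherits(z, "standardized"))
  z$values * z$sigma + z$mu
}

#' @export
print.standardized <- function(x, ...) {
  cat(sprintf("standardized vector (n = %d, mu = %.4g, sigma = %.4g)\n",
              length(x$values), x$mu, x$sigma))
  invisible(x)
}

#' Min-max normalization to [0, 1]
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @return `(x - min) / (max - min)`; endpoints map to 0 and 1.
#' @export
minmax <- function(x) {
  r <- range(x, na.rm = FALSE)
  if (!all(is.finite(r)) || r[2] <= r[1])
    stop("constant vector: min-max normalization undefined", call. = FALSE)
  (x - r[1]) / (r[2] - r[1])
}
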