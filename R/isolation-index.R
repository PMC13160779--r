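#' Convert percent-change series to strictly positive level form
#'
#' A percent change `p` from baseline becomes the level `1 + p/100`, so the
#' baseline month maps to level 1 (log contribution 0) and the log argument
#' stays positive for all `p > -100`.
#'
#' @param p numeric percent-change vector, all entries > -100.
#' @return positive level vector.
#' @export
pct_to_level <- function(p) {
  if (any(!is.finite(p)) || any(p <= -100))
    stop("percent changes must be finite and > -100", call. = FALSE)
  1 + p / 100
}

.stream_names <- c("M_R", "M_C", "E_R", "E_C", "R_R", "R_C")
.residential  <- c("M_R", "E_R", "R_R")
.commercial   <- c("M_C", "E_C", "R_C")

check_components <- function(components) {
  miss <- setdiff(.stream_names, names(components))
  if (length(miss))
    stop("missing component streams: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(components)
}

#' Composite isolation index from six activity streams
#'
#' Computes, per time point, the log-scale contrast of residential versus
#' non-residential activity:
#' `I = ln X_MR + ln X_ER + ln X_RR - ln X_MC - ln X_EC - ln X_RC`,
#' where each level `X = 1 + p/100` comes from a percent-change stream
#' (residential/commercial mobility, residential/commercial electricity,
#' stay-at-home/between-area movement range). Residential streams carry
#' weight +1 (they indicate confinement), non-residential streams weight -1.
#' The index is 0 when every stream sits at baseline and rises when people
#' stay home while commercial activity contracts.
#'
#' @param components a `component_series` (or data.frame with columns
#'   `M_R`, `M_C`, `E_R`, `E_C`, `R_R`, `R_C` in percent-change form).
#' @return An object of class `isolation_index`: data.frame with `month`
#'   (if present), the six signed log contributions (`c_M_R`, ...), and `I`
#'   equal to their rowwise sum.
#' @export
isolation_index <- function(components) {
  check_components(components)
  lens <- vapply(.stream_names, function(nm) length(components[[nm]]),
                 integer(1))
  if (length(unique(lens)) != 1)
    stop("component streams must have equal length", call. = FALSE)
  out <- data.frame(month = if (!is.null(components$month)) components$month
                    else seq_len(lens[1]))
  for (nm in .stream_names) {
    sgn <- if (nm %in% .residential) 1 else -1
    out[[paste0("c_", nm)]] <- sgn * log(pct_to_level(components[[nm]]))
  }
  out$I <- rowSums(out[, paste0("c_", .stream_names)])
  class(out) <- c("isolation_index", "data.frame")
  out
}

#' Internal-consistency correlation matrix of the component streams
#'
#' Pearson correlations among the standardized component streams; used to
#' check that the streams feeding the composite index move together the way
#' its construction assumes (residential streams mutually positive,
#' residential-commercial pairs negative during confinement).
#'
#' @param components a `component_series`.
#' @return symmetric 6 x 6 correlation matrix with unit diagonal.
#' @export
component_consistency <- function(components) {
  check_components(components)
  m <- sapply(.stream_names, function(nm) {
    v <- components[[nm]]
    if (length(v) < 3) stop("series length must be >= 3", call. = FALSE)
    if (stats::sd(v) == 0)
      stop("constant stream: ", nm, call. = FALSE)
    zscore(v)$values
  })
  stats::cor(m)
}

#' Correlate the isolation index with an outcome series
#'
#' Pearson correlation with a two-sided p-value from the t reference
#' distribution (`t = r * sqrt((n-2)/(1-r^2))` on n-2 df).
#'
#' @param I numeric index series.
#' @param dv numeric outcome series (e.g. monthly case counts), same length.
#' @return list with `r`, `p`, `n`.
#' @export
correlate_with_outcome <- function(I, dv) {
  if (length(I) != length(dv) || length(I) < 3)
    stop("series must have equal length >= 3", call. = FALSE)
  if (stats::sd(I) == 0 || stats::sd(dv) == 0)
    stop("zero-variance input", call. = FALSE)
  ct <- stats::cor.test(I, dv, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(I))
}

#' Aggregate a monthly index to one value per year
#'
#' The regression covariate form of the index: mean of the monthly index over
#' each calendar year, applied uniformly across regions (the component
#' streams are island-wide, so the covariate varies by year only).
#'
#' @param index an `isolation_index`.
#' @param months_per_year months per year block (default 12); the series is
#'   split into consecutive blocks starting at its first month.
#' @param years optional year labels, one per block.
#' @return data.frame with `year` and `isolation`.
#' @export
yearly_isolation <- function(index, months_per_year = 12, years = NULL) {
  stopifnot(inherits(index, "isolation_index"))
  n <- nrow(index)
  block <- (seq_len(n) - 1) %/% months_per_year + 1
  agg <- tapply(index$I, block, mean)
  yrs <- if (is.null(years)) as.integer(names(agg)) else years
  data.frame(year = yrs, isolation = as.numeric(agg))
}
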