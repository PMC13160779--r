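#' Published yearly domestic violence counts, Puerto Rico police regions
#'
#' The island-wide police-reported domestic violence counts for the COVID-19
#' study period: 3,560 (2020), 7,876 (2021), 5,573 (2022), totalling 17,009
#' over 2020-2022. These printed totals are inputs (e.g. to underreporting
#' arithmetic and consistency checks), not outputs of any model here.
#'
#' @return data.frame with columns `year` and `cases`.
#' @export
pr_reported_counts <- function() {
  data.frame(year = 2020:2022, cases = c(3560L, 7876L, 5573L))
}
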