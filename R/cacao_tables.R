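#' Published cacao contingency tables (worked-example inputs)
#'
#' The 10 x 10 reference-vs-computed contingency tables for the ensemble
#' method over all ten chromosomes of the cacao STR panel, as published:
#' one for the complete 952-sample set and one for the curated
#' 559-sample subsample. Rows are the ten reference genetic groups of
#' cacao (Amelonado, Contamana, Criollo, Curaray, Guiana, Iquitos,
#' Maranon, Nacional, Nanay, Purus), columns the matched computed
#' partitions in the same label order. These serve as exact worked
#' examples for the evaluation metrics.
#'
#' @param which `"complete"` (n = 952) or `"subsample"` (n = 559).
#' @return a labeled `contingency_table`.
#' @export
cacao_contingency <- function(which = c("complete", "subsample")) {
  which <- match.arg(which)
  labels <- c("Amelonado", "Contamana", "Criollo", "Curaray", "Guiana",
              "Iquitos", "Maranon", "Nacional", "Nanay", "Purus")
  if (which == "complete") {
    counts <- rbind(
      c(68, 1, 0, 0, 6, 1, 4, 0, 1, 13),
      c(0, 63, 0, 0, 0, 0, 0, 3, 1, 2),
      c(0, 0, 39, 0, 0, 0, 0, 0, 0, 0),
      c(0, 1, 0, 114, 0, 0, 0, 2, 0, 0),
      c(0, 0, 0, 0, 58, 0, 1, 0, 0, 0),
      c(0, 0, 0, 0, 0, 99, 2, 1, 6, 9),
      c(2, 1, 0, 0, 0, 0, 138, 0, 0, 2),
      c(2, 0, 1, 2, 0, 1, 0, 46, 0, 0),
      c(0, 0, 0, 0, 0, 1, 0, 0, 151, 0),
      c(0, 1, 2, 1, 0, 0, 0, 7, 0, 99))
  } else {
    counts <- rbind(
      c(46, 0, 0, 0, 7, 0, 0, 0, 0, 0),
      c(0, 48, 0, 0, 0, 0, 0, 0, 0, 0),
      c(0, 0, 27, 0, 0, 0, 0, 0, 0, 0),
      c(0, 1, 0, 64, 0, 0, 0, 0, 0, 0),
      c(0, 0, 0, 0, 41, 0, 0, 0, 0, 0),
      c(0, 0, 0, 0, 0, 66, 0, 0, 4, 0),
      c(0, 0, 5, 1, 0, 0, 95, 1, 0, 0),
      c(0, 0, 0, 0, 0, 0, 0, 29, 0, 0),
      c(0, 0, 0, 0, 0, 0, 0, 0, 62, 0),
      c(0, 1, 0, 0, 0, 6, 0, 3, 0, 52))
  }
  contingency_from_counts(counts, labels, labels)
}
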