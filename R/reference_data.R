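# Published composition summary for the Cyphonocerus sanguineus klapperichi
# mitogenome (GenBank MW365445), used as a regression fixture: the skew
# statistic recomputed from the printed percentages must reproduce the
# printed skews at 2 decimals.

#' Published composition table of the C. sanguineus klapperichi mitogenome
#'
#' Nucleotide composition and skewness of the firefly *Cyphonocerus
#' sanguineus klapperichi* mitogenome (GenBank MW365445), as published:
#' percentages per region at 1 decimal and AT/GC skews at 2 decimals. Used
#' as a regression fixture for the skew arithmetic — [at_skew()] and
#' [gc_skew()] applied to the percentage columns reproduce the skew columns.
#'
#' @return data frame with columns `region`, `size_bp`, `pctA`, `pctC`,
#'   `pctG`, `pctT`, `pctAT`, `pctGC`, `at_skew`, `gc_skew`.
#' @export
csk_composition <- function() {
  data.frame(
    region = c("Full genome", "PCGs", "1st codon position",
               "2nd codon position", "3rd codon position", "tRNAs",
               "rRNAs", "CR"),
    size_bp = c(16443L, 11008L, 3669L, 3669L, 3669L, 1432L, 2034L, 1776L),
    pctA = c(42.5, 41.1, 33.2, 25.2, 37.8, 41.6, 47.0, 45.6),
    pctC = c(13.9, 14.6, 12.2, 14.9, 10.6, 12.9, 13.1, 11.6),
    pctG = c(9.4, 10.3, 15.5, 12.3, 9.3, 9.6, 6.4, 7.2),
    pctT = c(34.2, 34.0, 39.1, 47.7, 42.4, 35.9, 33.5, 35.6),
    pctAT = c(76.7, 75.1, 72.3, 72.9, 80.2, 77.5, 80.5, 81.2),
    pctGC = c(23.3, 24.9, 27.7, 27.2, 19.9, 22.5, 19.5, 18.8),
    at_skew = c(0.11, 0.09, -0.08, -0.31, -0.06, 0.07, 0.17, 0.12),
    gc_skew = c(-0.19, -0.17, 0.12, -0.10, -0.07, -0.15, -0.34, -0.23),
    stringsAsFactors = FALSE
  )
}
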