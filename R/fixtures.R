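# Bundled reference data.

#' Reference table of the most case-prevalent ovarian-failure profile variants
#'
#' The printed table of the most prevalent variants of the reported
#' ovarian-failure profile (hg19, 1-based coordinates): genomic position,
#' coding and protein change, dbSNP identifier where known, annotation term,
#' gene, the number of affected cases out of 118, and mean/sd coverage. Six
#' of the seventeen variants are shared by twenty or more cases.
#'
#' @return a data.frame with one row per variant.
#' @examples
#' tbl <- of_reference_variants()
#' sum(tbl$n_cases >= 20)
#' @export
of_reference_variants <- function() {
  path <- system.file("extdata", "of_reference_variants.tsv",
                      package = "ofprofiler", mustWork = TRUE)
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(character = "chrom")))
}
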