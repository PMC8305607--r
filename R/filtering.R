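# Effect-class, reference-frequency and per-call quality filters with
# per-stage accounting.

.MODERATE_TERMS <- c(
  "missense_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant",
  "splice_acceptor_variant", "splice_donor_variant"
)

.DELETERIOUS_TERMS <- c(
  "frameshift_variant",
  "stop_gained", "stop_lost",
  "protein_protein_contact",
  "structural_interaction_variant",
  "disruptive_inframe_deletion", "disruptive_inframe_insertion"
)

#' Filter configuration
#'
#' Thresholds of the variant-filtering stage. Defaults: reference-panel MAF
#' strictly below 0.05 (variants absent from the panel are always retained),
#' per-call coverage of at least 100 reads, genotype quality of at least 20
#' and an alternate-allele read fraction of at least 0.2 for non-reference
#' calls. The GQ and AD cut-offs are conventional values; the coverage and
#' MAF thresholds are the study's headline criteria.
#'
#' @param maf_max variants with panel MAF `>= maf_max` are removed (strict
#'   boundary: MAF 0.05 is removed at the default).
#' @param min_depth minimum DP per call; calls below it are demoted to
#'   missing (boundary inclusive: DP 100 passes at the default).
#' @param min_gq minimum genotype quality per call.
#' @param min_ad_fraction minimum `ad_alt / dp` for non-reference calls.
#' @param moderate_terms,deleterious_terms annotation term sets defining the
#'   moderate / deleterious effect classes; anything else is excluded.
#' @export
filter_config <- function(maf_max = 0.05, min_depth = 100, min_gq = 20,
                          min_ad_fraction = 0.2,
                          moderate_terms = .MODERATE_TERMS,
                          deleterious_terms = .DELETERIOUS_TERMS) {
  stopifnot(maf_max > 0, maf_max < 1, min_depth >= 0,
            min_ad_fraction >= 0, min_ad_fraction <= 1)
  structure(list(
    maf_max = maf_max, min_depth = min_depth, min_gq = min_gq,
    min_ad_fraction = min_ad_fraction,
    moderate_terms = moderate_terms, deleterious_terms = deleterious_terms
  ), class = "filter_config")
}

#' Classify an annotation term into an effect class
#'
#' Total, deterministic mapping from SnpEff-style annotation terms to
#' `"MODERATE"`, `"DELETERIOUS"` or `"EXCLUDED"`. Terms may be `&`-joined
#' (as in `structural_interaction_variant&missense_variant`); a record is
#' deleterious if any joined term is in the deleterious set, else moderate if
#' any is in the moderate set, else excluded.
#'
#' @param term character vector of annotation terms.
#' @param config a [filter_config()].
#' @return character vector of effect classes, same length as `term`.
#' @export
classify_effect <- function(term, config = filter_config()) {
  vapply(strsplit(as.character(term), "&", fixed = TRUE), function(parts) {
    if (any(parts %in% config$deleterious_terms)) "DELETERIOUS"
    else if (any(parts %in% config$moderate_terms)) "MODERATE"
    else "EXCLUDED"
  }, character(1))
}

#' Remove variants without a moderate or deleterious predicted effect
#'
#' @param x a `cohort_matrix`
#' @param config a [filter_config()]
#' @export
filter_by_effect <- function(x, config = filter_config()) {
  cls <- classify_effect(x$variants$effect_term, config)
  x$variants$effect_class <- cls
  subset_cohort(x, variants = cls != "EXCLUDED")
}

#' Remove variants common in the reference panel
#'
#' Variants absent from the panel (`panel_maf` is `NA`) are retained;
#' variants present are kept only if their MAF is strictly below
#' `config$maf_max`.
#'
#' @param x a `cohort_matrix` (panel MAFs attached, see
#'   [annotate_panel_maf()]).
#' @param config a [filter_config()]
#' @export
filter_by_reference_frequency <- function(x, config = filter_config()) {
  maf <- x$variants$panel_maf
  subset_cohort(x, variants = is.na(maf) | maf < config$maf_max)
}

#' Demote low-quality calls and drop variants left without carriers
#'
#' Quality gating is per call: a call with `dp < min_depth`, `gq < min_gq`,
#' or (for non-reference calls) `ad_alt/dp < min_ad_fraction` is set to
#' missing, so one bad sample does not delete a cohort-wide variant. A call
#' whose quality fields are absent fails the gate. Variants whose
#' non-reference calls all become missing are then removed. Matrices without
#' recorded quality fields pass through unchanged.
#'
#' @param x a `cohort_matrix`
#' @param config a [filter_config()]
#' @return `list(matrix = <cohort_matrix>, n_demoted = <count>)`
#' @export
filter_by_quality <- function(x, config = filter_config()) {
  if (is.null(x$dp) && is.null(x$gq) && is.null(x$ad)) {
    return(list(matrix = x, n_demoted = 0L))
  }
  called <- !is.na(x$geno)
  fail <- matrix(FALSE, nrow(x$geno), ncol(x$geno))
  gate <- function(v) { v[is.na(v)] <- -Inf; v }  # absent quality fails
  if (!is.null(x$dp)) fail <- fail | gate(x$dp) < config$min_depth
  if (!is.null(x$gq)) fail <- fail | gate(x$gq) < config$min_gq
  nonref <- called & x$geno > 0
  if (!is.null(x$ad) && !is.null(x$dp)) {
    frac <- x$ad / pmax(x$dp, 1)
    frac[is.na(frac)] <- -Inf
    fail <- fail | (nonref & frac < config$min_ad_fraction)
  }
  demote <- called & fail
  x$geno[demote] <- NA_integer_
  for (f in c("gq", "dp", "ad")) if (!is.null(x[[f]])) x[[f]][demote] <- NA_real_

  had_carrier <- rowSums(nonref) > 0
  has_carrier <- rowSums(!is.na(x$geno) & x$geno > 0) > 0
  keep <- !(had_carrier & !has_carrier)
  list(matrix = subset_cohort(x, variants = keep), n_demoted = sum(demote))
}

#' Apply the full filter cascade with per-stage accounting
#'
#' Composition order: predicted effect class (excluded terms removed), then
#' reference-panel frequency, then per-call quality. The report telescopes:
#' each stage's input count equals the previous stage's output count.
#'
#' @param x a `cohort_matrix`
#' @param config a [filter_config()]
#' @return `list(matrix, report)` where `report` is a data.frame with columns
#'   `stage`, `n_in`, `n_out` plus an attribute `n_demoted` (calls set to
#'   missing by the quality gate).
#' @export
apply_filters <- function(x, config = filter_config()) {
  stages <- character(0); n_in <- integer(0); n_out <- integer(0)
  step <- function(name, before, after) {
    stages <<- c(stages, name)
    n_in <<- c(n_in, before); n_out <<- c(n_out, after)
  }
  n0 <- nrow(x$geno)
  x1 <- filter_by_effect(x, config);               step("effect_class", n0, nrow(x1$geno))
  x2 <- filter_by_reference_frequency(x1, config); step("reference_frequency", nrow(x1$geno), nrow(x2$geno))
  q <- filter_by_quality(x2, config);              step("call_quality", nrow(x2$geno), nrow(q$matrix$geno))
  report <- data.frame(stage = stages, n_in = n_in, n_out = n_out,
                       stringsAsFactors = FALSE)
  attr(report, "n_demoted") <- q$n_demoted
  list(matrix = q$matrix, report = report)
}

#' Write a filter report as TSV
#' @param report the report component of [apply_filters()]
#' @param path file path
#' @export
write_filter_report <- function(report, path) {
  data.table::fwrite(report, path, sep = "\t")
  invisible(path)
}
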