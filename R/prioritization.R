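# Construction of the disease-associated variant profile: variants prevalent
# in cases and absent from controls.

#' Profile-selection configuration
#'
#' @param case_prev_min minimum fraction of cases carrying a variant
#'   (default 0.10, the "at least 10 percent of cases" rule).
#' @param control_carrier_max maximum number of control carriers allowed
#'   (default 0: complete absence from controls).
#' @export
profile_config <- function(case_prev_min = 0.10, control_carrier_max = 0L) {
  stopifnot(case_prev_min > 0, case_prev_min <= 1, control_carrier_max >= 0)
  structure(list(case_prev_min = case_prev_min,
                 control_carrier_max = as.integer(control_carrier_max)),
            class = "profile_config")
}

#' Carrier count required by the case-prevalence rule
#'
#' Ceiling of the exact product, so that "at least 10 percent of 118 cases"
#' requires 12 carriers. A small guard keeps floating-point representations
#' of exact products (e.g. `0.2 * 10`) from being rounded up spuriously.
#'
#' @param n_case number of cases.
#' @param case_prev_min minimum case-carrier fraction.
#' @export
required_case_carriers <- function(n_case, case_prev_min = 0.10) {
  as.integer(ceiling(case_prev_min * n_case - 1e-9))
}

#' Select the disease-associated variant profile
#'
#' Keeps variants carried by at least `ceiling(case_prev_min * n_case)` cases
#' and by at most `control_carrier_max` controls. Carrier counts are taken
#' over non-missing calls, but the prevalence threshold is defined against
#' the full case cohort size (missing case genotypes therefore count as
#' non-carriers for the rule). The profile is ordered by descending
#' case-carrier count, ties broken by genomic coordinate.
#'
#' @param x a `cohort_matrix` with at least one case and one control.
#' @param config a [profile_config()].
#' @return an object of class `variant_profile`: `variants` (annotation plus
#'   `case_carriers`, `control_carriers`), `accumulation` (named per-case
#'   count of profile variants carried), `n_case` and the threshold used.
#' @export
select_profile <- function(x, config = profile_config()) {
  stopifnot(inherits(x, "cohort_matrix"))
  nc <- n_cases(x)
  if (nc == 0 || n_controls(x) == 0) {
    stop("profile selection requires at least one case and one control")
  }
  case <- x$geno[, x$labels == "CASE", drop = FALSE]
  ctrl <- x$geno[, x$labels == "CONTROL", drop = FALSE]
  case_carriers <- rowSums(case > 0, na.rm = TRUE)
  control_carriers <- rowSums(ctrl > 0, na.rm = TRUE)
  need <- required_case_carriers(nc, config$case_prev_min)
  sel <- case_carriers >= need & control_carriers <= config$control_carrier_max
  if (!any(sel)) warning("no variant satisfies the profile criteria")

  variants <- cbind(
    x$variants[sel, , drop = FALSE],
    data.frame(case_carriers = case_carriers[sel],
               control_carriers = control_carriers[sel])
  )
  chrom_rank <- suppressWarnings(as.numeric(variants$chrom))
  chrom_rank[is.na(chrom_rank)] <- 1e6 + as.numeric(factor(variants$chrom[is.na(chrom_rank)]))
  ord <- order(-variants$case_carriers, chrom_rank, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  acc <- colSums(case[rownames(x$geno) %in% variant_key(variants), , drop = FALSE] > 0,
                 na.rm = TRUE)
  structure(list(
    variants = variants,
    accumulation = acc,
    n_case = nc,
    required_carriers = need,
    config = config
  ), class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat(sprintf(
    "variant_profile: %d variants (>= %d of %d cases, <= %d control carriers)\n",
    nrow(x$variants), x$required_carriers, x$n_case,
    x$config$control_carrier_max
  ))
  invisible(x)
}

#' Histogram of per-patient profile-variant accumulation
#'
#' @param profile a `variant_profile`.
#' @return named integer vector mapping accumulation count to number of
#'   cases; counts sum to the case cohort size. An empty profile yields all
#'   cases at count 0.
#' @export
accumulation_histogram <- function(profile) {
  stopifnot(inherits(profile, "variant_profile"))
  tab <- table(profile$accumulation)
  setNames(as.integer(tab), names(tab))
}

#' Write the profile and per-sample accumulation as TSV
#' @param profile a `variant_profile`
#' @param variants_path,accumulation_path output paths (`NULL` to skip one).
#' @export
write_profile <- function(profile, variants_path = NULL, accumulation_path = NULL) {
  if (!is.null(variants_path)) {
    data.table::fwrite(profile$variants, variants_path, sep = "\t")
  }
  if (!is.null(accumulation_path)) {
    data.table::fwrite(
      data.frame(sample = names(profile$accumulation),
                 n_profile_variants = as.integer(profile$accumulation)),
      accumulation_path, sep = "\t"
    )
  }
  invisible(profile)
}
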