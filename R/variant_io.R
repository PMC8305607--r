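# Reading annotated VCFs and phenotype labels into the in-memory cohort model,
# plus serialisation of the intermediate genotype matrix.

#' Construct a cohort matrix
#'
#' The central container of the package: a variants x samples genotype matrix
#' with case/control labels, per-variant annotation (effect term, reference
#' panel MAF) and optional per-call quality fields.
#'
#' Genotypes are coded `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `NA` (missing call).
#'
#' @param geno integer matrix (variants x samples) of genotype codes; row
#'   names are variant keys `chrom:pos:ref:alt` (generated when absent),
#'   column names are sample identifiers.
#' @param labels per-sample phenotype, `"CASE"` or `"CONTROL"`; either a
#'   named vector covering every column of `geno` or an unnamed vector in
#'   column order.
#' @param variants optional `data.frame` of per-variant annotation with
#'   columns `chrom`, `pos`, `ref`, `alt` and optionally `effect_term`,
#'   `gene`, `panel_maf` (`NA` meaning absent from the reference panel).
#' @param gq,dp,ad optional numeric matrices of the same shape as `geno`
#'   holding genotype quality, position depth and alternate-allele depth.
#' @return an object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(geno, labels, variants = NULL,
                          gq = NULL, dp = NULL, ad = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("S%03d", seq_len(ncol(geno)))
  }
  samples <- colnames(geno)
  if (!is.null(names(labels))) {
    missing <- setdiff(samples, names(labels))
    if (length(missing) > 0) {
      stop("samples without a phenotype label: ", paste(missing, collapse = ", "))
    }
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop("`labels` must cover every sample")
  }
  labels <- toupper(as.character(labels))
  bad <- setdiff(unique(labels), .PHENOTYPES)
  if (length(bad) > 0) stop("unknown phenotype token(s): ", paste(bad, collapse = ", "))

  if (is.null(variants)) {
    variants <- data.frame(
      chrom = "1", pos = seq_len(nrow(geno)),
      ref = "A", alt = "T", stringsAsFactors = FALSE
    )
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "ref", "alt")) {
    if (is.null(variants[[col]])) stop("`variants` lacks column ", col)
  }
  if (nrow(variants) != nrow(geno)) stop("variants/geno row mismatch")
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based, VCF convention)")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (is.null(variants$effect_term)) {
    variants$effect_term <- rep_len("missense_variant", nrow(variants))
  }
  if (is.null(variants$gene)) variants$gene <- rep_len(NA_character_, nrow(variants))
  if (is.null(variants$panel_maf)) variants$panel_maf <- rep_len(NA_real_, nrow(variants))
  key <- variant_key(variants)
  if (anyDuplicated(key)) {
    stop("duplicate variant keys: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(geno) <- key
  rownames(variants) <- NULL

  check_qual <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), dim(geno))) stop("`", what, "` must match geno dimensions")
    dimnames(m) <- dimnames(geno)
    storage.mode(m) <- "double"
    m
  }
  out <- structure(list(
    variants = variants,
    samples = samples,
    labels = setNames(labels, samples),
    geno = geno,
    gq = check_qual(gq, "gq"),
    dp = check_qual(dp, "dp"),
    ad = check_qual(ad, "ad")
  ), class = "cohort_matrix")
  dpm <- out$dp; adm <- out$ad
  if (!is.null(dpm) && !is.null(adm)) {
    bad <- !is.na(dpm) & !is.na(adm) & adm > dpm
    if (any(bad)) stop("ad_alt exceeds dp for ", sum(bad), " call(s)")
  }
  out
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf(
    "cohort_matrix: %d variants x %d samples (%d cases, %d controls)\n",
    nrow(x$geno), length(x$samples),
    sum(x$labels == "CASE"), sum(x$labels == "CONTROL")
  ))
  if (!is.null(x$dp)) cat("per-call quality fields: GQ/DP/AD present\n")
  invisible(x)
}

#' Variant keys of a cohort matrix or variant table
#'
#' @param x a `cohort_matrix` or a data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(x) {
  if (inherits(x, "cohort_matrix")) x <- x$variants
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Number of cases / controls
#' @param x a `cohort_matrix`
#' @export
n_cases <- function(x) sum(x$labels == "CASE")

#' @rdname n_cases
#' @export
n_controls <- function(x) sum(x$labels == "CONTROL")

#' Subset a cohort matrix by variant and/or sample
#'
#' @param x a `cohort_matrix`
#' @param variants logical/integer/character index over variants
#' @param samples logical/integer/character index over samples
#' @export
subset_cohort <- function(x, variants = NULL, samples = NULL) {
  vi <- variants %||% seq_len(nrow(x$geno))
  si <- samples %||% x$samples
  if (is.character(vi)) vi <- match(vi, rownames(x$geno))
  sub <- function(m) if (is.null(m)) NULL else m[vi, si, drop = FALSE]
  cohort_matrix(
    geno = x$geno[vi, si, drop = FALSE],
    labels = x$labels[si],
    variants = x$variants[vi, , drop = FALSE],
    gq = sub(x$gq), dp = sub(x$dp), ad = sub(x$ad)
  )
}

# ---- VCF ingestion ---------------------------------------------------------

# Zygosity of one split alt allele. `gt` is the raw GT string, `alt_idx` the
# 1-based index of the alt allele in the original record. Mixed heterozygous
# genotypes (e.g. 1/2) are HET for each involved alt.
.gt_code <- function(gt, alt_idx) {
  out <- rep(NA_integer_, length(gt))
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  n_alt <- vapply(alleles, function(a) {
    if (length(a) == 0 || anyNA(a) || all(a == "." | a == "")) return(NA_integer_)
    sum(a == as.character(alt_idx))
  }, integer(1))
  out[!is.na(n_alt)] <- pmin(n_alt[!is.na(n_alt)], 2L)
  out
}

#' Read a SnpEff-annotated VCF into split per-alt records
#'
#' Parses a VCF 4.x file (plain or bgzipped) carrying a pipe-delimited `ANN`
#' INFO field and per-sample `GT`/`GQ`/`DP`/`AD` FORMAT fields. Multi-allelic
#' records are split into one record per alternate allele; the annotation of
#' each split record is the `ANN` entry whose first subfield matches the
#' alternate allele. Records without a matching annotation are dropped with a
#' reported count (never silently).
#'
#' @param path VCF file path.
#' @param ann_dialect annotation dialect; only `"snpeff"` (the standard
#'   `allele|effect|impact|gene|...` ANN layout) is implemented.
#' @return a list of class `vcf_records` with elements `variants`
#'   (data.frame: chrom, pos, ref, alt, effect_term, gene), matrices `geno`,
#'   `gq`, `dp`, `ad`, the `samples` vector and `n_dropped`.
#' @export
read_annotated_vcf <- function(path, ann_dialect = "snpeff") {
  ann_dialect <- match.arg(ann_dialect, "snpeff")
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  samples <- colnames(gt)[-1]

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[1])
  }
  info <- fix[, "INFO"]
  ann_raw <- ifelse(
    grepl("(^|;)ANN=", info),
    sub(".*(?:^|;)ANN=([^;]*).*", "\\1", info),
    NA_character_
  )
  get_fmt <- function(key, numeric = TRUE) {
    m <- tryCatch(
      vcfR::extract.gt(vcf, element = key, as.numeric = numeric),
      error = function(e) NULL
    )
    m
  }
  gt_str <- vcfR::extract.gt(vcf, element = "GT")
  gq_m <- get_fmt("GQ")
  dp_m <- get_fmt("DP")
  ad_m <- tryCatch(vcfR::extract.gt(vcf, element = "AD"), error = function(e) NULL)

  rows <- vector("list", nrow(fix))
  n_dropped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    anns <- if (is.na(ann_raw[i])) character(0) else
      strsplit(ann_raw[i], ",", fixed = TRUE)[[1]]
    ann_allele <- vapply(strsplit(anns, "|", fixed = TRUE), `[`, "", 1)
    per_alt <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      hit <- which(ann_allele == alts[k])[1]
      if (is.na(hit)) { n_dropped <- n_dropped + 1L; next }
      f <- strsplit(anns[hit], "|", fixed = TRUE)[[1]]
      geno_k <- .gt_code(gt_str[i, ], k)
      ad_k <- rep(NA_real_, length(samples))
      if (!is.null(ad_m)) {
        parts <- strsplit(ad_m[i, ], ",", fixed = TRUE)
        ad_k <- vapply(parts, function(p) {
          if (length(p) >= k + 1) suppressWarnings(as.numeric(p[k + 1])) else NA_real_
        }, numeric(1))
      }
      per_alt[[k]] <- list(
        variant = data.frame(
          chrom = fix[i, "CHROM"], pos = pos[i],
          ref = fix[i, "REF"], alt = alts[k],
          effect_term = if (length(f) >= 2) f[2] else NA_character_,
          gene = if (length(f) >= 4) f[4] else NA_character_,
          stringsAsFactors = FALSE
        ),
        geno = geno_k,
        gq = if (is.null(gq_m)) rep(NA_real_, length(samples)) else as.numeric(gq_m[i, ]),
        dp = if (is.null(dp_m)) rep(NA_real_, length(samples)) else as.numeric(dp_m[i, ]),
        ad = ad_k
      )
    }
    rows[[i]] <- per_alt[!vapply(per_alt, is.null, TRUE)]
  }
  rows <- unlist(rows, recursive = FALSE)
  if (n_dropped > 0) {
    message("read_annotated_vcf: dropped ", n_dropped,
            " alt allele(s) without a matching ANN annotation")
  }
  if (length(rows) == 0) stop("no annotated records in ", path)
  bind <- function(what) do.call(rbind, lapply(rows, `[[`, what))
  variants <- do.call(rbind, lapply(rows, `[[`, "variant"))
  out <- list(
    variants = variants,
    geno = bind("geno"),
    gq = bind("gq"),
    dp = bind("dp"),
    ad = bind("ad"),
    samples = samples,
    n_dropped = n_dropped
  )
  colnames(out$geno) <- samples
  for (m in c("gq", "dp", "ad")) colnames(out[[m]]) <- samples
  class(out) <- "vcf_records"
  out
}

#' Read a two-column sample/phenotype TSV
#'
#' @param path TSV with columns sample, phenotype (header optional); phenotype
#'   tokens are `case`/`control` in any letter case.
#' @return named character vector of `"CASE"`/`"CONTROL"` keyed by sample.
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "phenotype"),
                          colClasses = "character")
  if (nrow(dt) > 0 && tolower(dt$sample[1]) == "sample") dt <- dt[-1, ]
  if (anyDuplicated(dt$sample)) {
    stop("duplicate sample row(s) in label file: ",
         paste(unique(dt$sample[duplicated(dt$sample)]), collapse = ", "))
  }
  ph <- toupper(dt$phenotype)
  bad <- setdiff(unique(ph), .PHENOTYPES)
  if (length(bad) > 0) stop("unknown phenotype token(s): ", paste(bad, collapse = ", "))
  setNames(ph, dt$sample)
}

#' Read a reference allele-frequency panel table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @return data.frame keyed by variant; variants absent from the table are,
#'   downstream, treated as absent from the reference panel.
#' @export
read_panel <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(dt))) {
    stop("panel table must have columns: ", paste(need, collapse = ", "))
  }
  as.data.frame(dt)
}

#' Assemble a cohort matrix from parsed VCF records and labels
#'
#' @param records a `vcf_records` object from [read_annotated_vcf()].
#' @param labels named phenotype vector from [read_labels()]; must cover every
#'   VCF sample.
#' @param panel optional panel data.frame from [read_panel()] used to attach
#'   per-variant reference MAFs (`NA` = absent from panel).
#' @return a `cohort_matrix` preserving the input variant order.
#' @export
build_cohort_matrix <- function(records, labels, panel = NULL) {
  stopifnot(inherits(records, "vcf_records"))
  missing <- setdiff(records$samples, names(labels))
  if (length(missing) > 0) {
    stop("VCF sample(s) absent from labels: ", paste(missing, collapse = ", "))
  }
  variants <- records$variants
  variants$panel_maf <- NA_real_
  m <- cohort_matrix(
    geno = records$geno, labels = labels[records$samples],
    variants = variants, gq = records$gq, dp = records$dp, ad = records$ad
  )
  if (!is.null(panel)) m <- annotate_panel_maf(m, panel)
  m
}

#' Attach reference-panel minor allele frequencies to a cohort matrix
#'
#' @param x a `cohort_matrix`
#' @param panel data.frame with `chrom`, `pos`, `ref`, `alt`, `maf`
#' @return the matrix with `variants$panel_maf` filled in (`NA` = absent).
#' @export
annotate_panel_maf <- function(x, panel) {
  key <- variant_key(x)
  pkey <- paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")
  x$variants$panel_maf <- panel$maf[match(key, pkey)]
  x
}

# ---- matrix serialisation --------------------------------------------------

.MATRIX_TAG <- "#ofprofiler_matrix v1"

#' Write / read the intermediate cohort matrix
#'
#' Long-format tab-separated serialisation with a one-line schema header;
#' `read_matrix(write_matrix(x))` reproduces `x` field for field, including
#' missing calls and quality matrices.
#'
#' @param x a `cohort_matrix`
#' @param path file path
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "cohort_matrix"))
  nv <- nrow(x$geno); ns <- length(x$samples)
  long <- data.table::data.table(
    chrom = rep(x$variants$chrom, ns),
    pos = rep(x$variants$pos, ns),
    ref = rep(x$variants$ref, ns),
    alt = rep(x$variants$alt, ns),
    effect_term = rep(x$variants$effect_term, ns),
    gene = rep(x$variants$gene, ns),
    panel_maf = rep(x$variants$panel_maf, ns),
    sample = rep(x$samples, each = nv),
    phenotype = rep(unname(x$labels), each = nv),
    gt = as.vector(x$geno),
    gq = if (is.null(x$gq)) NA_real_ else as.vector(x$gq),
    dp = if (is.null(x$dp)) NA_real_ else as.vector(x$dp),
    ad = if (is.null(x$ad)) NA_real_ else as.vector(x$ad)
  )
  writeLines(.MATRIX_TAG, path)
  data.table::fwrite(long, path, sep = "\t", append = TRUE, col.names = TRUE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tag <- readLines(path, n = 1)
  if (!identical(tag, .MATRIX_TAG)) {
    stop("matrix file version tag mismatch: expected '", .MATRIX_TAG,
         "', found '", tag, "'")
  }
  long <- data.table::fread(path, sep = "\t", skip = 1, na.strings = "NA",
                            colClasses = list(character = c("chrom", "ref", "alt", "sample")))
  key <- paste(long$chrom, long$pos, long$ref, long$alt, sep = ":")
  vkeys <- unique(key)
  skeys <- unique(long$sample)
  vi <- match(key, vkeys); si <- match(long$sample, skeys)
  shape <- function(v, mode = "double") {
    m <- matrix(if (mode == "integer") NA_integer_ else NA_real_,
                nrow = length(vkeys), ncol = length(skeys),
                dimnames = list(vkeys, skeys))
    m[cbind(vi, si)] <- v
    m
  }
  first <- !duplicated(key)
  variants <- data.frame(
    chrom = long$chrom[first], pos = long$pos[first],
    ref = long$ref[first], alt = long$alt[first],
    effect_term = long$effect_term[first], gene = long$gene[first],
    panel_maf = long$panel_maf[first], stringsAsFactors = FALSE
  )
  sfirst <- !duplicated(long$sample)
  labels <- setNames(long$phenotype[sfirst], long$sample[sfirst])
  all_na <- function(m) all(is.na(m))
  gq <- shape(long$gq); dp <- shape(long$dp); ad <- shape(long$ad)
  cohort_matrix(
    geno = shape(long$gt, "integer"), labels = labels, variants = variants,
    gq = if (all_na(gq)) NULL else gq,
    dp = if (all_na(dp)) NULL else dp,
    ad = if (all_na(ad)) NULL else ad
  )
}
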