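# Synthetic annotated case/control cohorts with the statistical structure the
# analysis assumes: a planted profile of rare non-synonymous variants shared
# by cases and absent from controls, two case subtypes with strongly
# subtype-aligned carrier pools, an optional control-enriched ("protective")
# variant, and a rare background.

#' Simulation configuration
#'
#' The defaults emulate the study conditions this package models: 118 cases
#' and 32 controls; a planted profile of 66 rare missense variants, each
#' carried by at least 10 percent of cases and by no control; two case
#' subtypes (17 vs 101) with subtype-characteristic variants; per-patient
#' accumulation of profile variants within 1-15 with mode 9; one
#' control-enriched variant at 14/32 controls vs 4/118 cases; and a rare
#' background with reference-panel MAF below 0.05 or absent from the panel.
#'
#' Carrier pools are strongly subtype-aligned: the subtype-A-characteristic
#' variants are near-fixed within subtype A and essentially absent from B,
#' while the common pool is carried mainly by subtype B with a small
#' cross-subtype rate. This is what a cleanly separable two-subtype taxonomy
#' implies about the underlying carrier structure; see the methods vignette.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_profile_variants total planted profile size.
#' @param subtype_split fractions of cases in subtypes A and B (sums to 1).
#' @param n_subtype_exclusive subtype-characteristic variants per subtype.
#' @param n_a_shared additional A-enriched variants that remain part of the
#'   shared profile (low carriage in B).
#' @param prevalence_range interval of per-variant case-carrier fractions for
#'   the common pool.
#' @param accumulation list `(min, max, mode)` constraining per-case counts
#'   of profile variants; generation is retried until the histogram mode is
#'   within 1 of the target.
#' @param protective data.frame of control-enriched variants with columns
#'   `control_frac`, `case_frac` (carrier fractions planted exactly).
#' @param n_background number of background variants.
#' @param background_panel_absent fraction of background absent from the
#'   reference panel.
#' @param background_common_frac fraction of background planted with panel
#'   MAF at or above 0.05 (removed by the frequency filter).
#' @param background_syn_frac fraction of background annotated synonymous
#'   (removed by the effect filter).
#' @param hom_alt_fraction probability a carrier is homozygous alternate
#'   (rare variants are overwhelmingly heterozygous).
#' @param noise_flip per-call genotype flip rate applied after planting
#'   (0 -> 1, 1 -> 0, 2 -> 1).
#' @param missing_rate per-call missing rate.
#' @param depth_mean,depth_sd,depth_floor,depth_ceiling read-depth model.
#' @param exclusive_prev within-subtype carrier rate of subtype-exclusive
#'   variants (subtype A; subtype B exclusives use the prevalence range).
#' @param a_shared_prev within-A carrier rate of the A-enriched shared pool.
#' @param cross_a_on_b carrier rate of subtype-A cases on the common (B-home)
#'   pool.
#' @param cross_b_on_a carrier rate of subtype-B cases on the A-enriched
#'   shared pool.
#' @param seed integer seed; identical configurations give byte-identical
#'   outputs.
#' @export
sim_config <- function(n_cases = 118, n_controls = 32,
                       n_profile_variants = 66,
                       subtype_split = c(A = 17 / 118, B = 101 / 118),
                       n_subtype_exclusive = 3, n_a_shared = 4,
                       prevalence_range = c(0.10, 0.27),
                       accumulation = list(min = 1, max = 15, mode = 9),
                       protective = data.frame(control_frac = 14 / 32,
                                               case_frac = 4 / 118),
                       n_background = 300,
                       background_panel_absent = 0.3,
                       background_common_frac = 0.1,
                       background_syn_frac = 0.4,
                       hom_alt_fraction = 0.1,
                       noise_flip = 0.02, missing_rate = 0.01,
                       depth_mean = 250, depth_sd = 80,
                       depth_floor = 120, depth_ceiling = 1500,
                       exclusive_prev = 0.95, a_shared_prev = 0.75,
                       cross_a_on_b = 0.01, cross_b_on_a = 0.03,
                       seed = 1L) {
  stopifnot(
    abs(sum(subtype_split) - 1) < 1e-8,
    all(prevalence_range > 0), all(prevalence_range <= 1),
    prevalence_range[1] < prevalence_range[2],
    hom_alt_fraction >= 0, hom_alt_fraction <= 1,
    noise_flip >= 0, noise_flip < 1, missing_rate >= 0, missing_rate < 1,
    accumulation$min >= 0, accumulation$max >= accumulation$min,
    n_profile_variants >= 2 * n_subtype_exclusive + n_a_shared
  )
  structure(as.list(environment()), class = "sim_config")
}

# carrier probability from an allele frequency under Hardy-Weinberg
.hwe_carrier <- function(maf) 1 - (1 - maf)^2

# draw zygosity codes for a carrier indicator matrix
.zygosity <- function(carrier, hom_frac) {
  g <- matrix(0L, nrow(carrier), ncol(carrier))
  idx <- which(carrier)
  g[idx] <- ifelse(runif(length(idx)) < hom_frac, 2L, 1L)
  g
}

# plant profile carriers among cases; returns carrier matrix (variants x
# cases) honouring the per-variant floor and per-case accumulation envelope,
# or NULL when this attempt is irreparable
.plant_profile_once <- function(rates, subtype, cfg, need) {
  nv <- nrow(rates); ncase <- length(subtype)
  pmat <- t(vapply(seq_len(nv), function(v) {
    ifelse(subtype == "A", rates$rate_A[v], rates$rate_B[v])
  }, numeric(ncase)))
  carrier <- matrix(runif(nv * ncase) < pmat, nv, ncase)

  home <- ifelse(rates$rate_A >= rates$rate_B, "A", "B")
  # per-variant floor: add carriers from the home subtype, preferring cases
  # with the fewest profile variants so the accumulation envelope survives
  for (v in which(rowSums(carrier) < need)) {
    pool <- which(!carrier[v, ] & subtype == home[v])
    if (length(pool) == 0) pool <- which(!carrier[v, ])
    deficit <- need - sum(carrier[v, ])
    if (deficit > length(pool)) return(NULL)
    acc <- colSums(carrier)[pool]
    carrier[v, pool[order(acc)][seq_len(deficit)]] <- TRUE
  }
  acc <- colSums(carrier)
  # per-case envelope
  for (i in which(acc < cfg$accumulation$min)) {
    addable <- which(!carrier[, i] &
                       (home == subtype[i] | rates$role == "shared_profile"))
    if (length(addable) == 0) return(NULL)
    k <- cfg$accumulation$min - sum(carrier[, i])
    carrier[sample(addable, k), i] <- TRUE
  }
  for (i in which(acc > cfg$accumulation$max)) {
    over <- sum(carrier[, i]) - cfg$accumulation$max
    # only drop carriers from variants comfortably above the floor
    droppable <- which(carrier[, i] & rowSums(carrier) > need)
    if (length(droppable) < over) return(NULL)
    carrier[sample(droppable, over), i] <- FALSE
  }
  if (any(rowSums(carrier) < need)) return(NULL)
  acc <- colSums(carrier)
  if (any(acc < cfg$accumulation$min) || any(acc > cfg$accumulation$max)) {
    return(NULL)
  }
  carrier
}

#' Generate a synthetic annotated cohort
#'
#' Builds the truth genotype matrix (planted profile, protective and
#' background variants), applies the genotype noise and missingness models,
#' attaches per-call quality fields, and optionally writes the cohort as a
#' VCF 4.2 file with SnpEff-style `ANN` annotations plus label, panel and
#' truth tables, so the real parser path can be exercised.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, `cohort.vcf`,
#'   `labels.tsv`, `panel.tsv`, `truth_variants.tsv`, `truth_samples.tsv`
#'   and `config.yaml` are written there.
#' @return an object of class `synthetic_cohort`: `cohort` (a
#'   `cohort_matrix` including noise and missingness, panel MAFs attached),
#'   `truth` (`subtype` per sample; `roles` per variant with planted carrier
#'   counts and rates; `planted_geno`, the pre-noise genotype matrix),
#'   `panel` (reference-frequency table), `config` and, when written,
#'   `paths`.
#' @export
generate_cohort <- function(config = sim_config(), dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  ncase <- cfg$n_cases; nctrl <- cfg$n_controls
  case_ids <- sprintf("OF%03d", seq_len(ncase))
  ctrl_ids <- sprintf("CT%03d", seq_len(nctrl))
  nA <- round(cfg$subtype_split[["A"]] * ncase)
  subtype <- sample(c(rep("A", nA), rep("B", ncase - nA)))
  names(subtype) <- case_ids

  need <- required_case_carriers(ncase, 0.10)
  nex <- cfg$n_subtype_exclusive
  n_common <- cfg$n_profile_variants - 2 * nex - cfg$n_a_shared
  roles <- data.frame(
    role = c(rep("profile_A", nex),
             rep("shared_profile", cfg$n_a_shared),
             rep("profile_B", nex),
             rep("shared_profile", n_common)),
    pool = c(rep("A_exclusive", nex), rep("A_shared", cfg$n_a_shared),
             rep("B_exclusive", nex), rep("B_common", n_common)),
    stringsAsFactors = FALSE
  )
  pr <- cfg$prevalence_range
  roles$rate_A <- 0; roles$rate_B <- 0
  roles$rate_A[roles$pool == "A_exclusive"] <- cfg$exclusive_prev
  roles$rate_A[roles$pool == "A_shared"] <- cfg$a_shared_prev
  roles$rate_B[roles$pool == "A_shared"] <- cfg$cross_b_on_a
  roles$rate_B[roles$pool == "B_exclusive"] <- runif(nex, pr[1] + 0.03, 0.20)
  iB <- roles$pool == "B_common"
  roles$rate_B[iB] <- pr[1] + 0.02 + (pr[2] + 0.04 - pr[1] - 0.02) *
    rbeta(sum(iB), 0.7, 3.5)
  roles$rate_A[iB] <- cfg$cross_a_on_b

  carrier <- NULL
  for (attempt in seq_len(200)) {
    cand <- .plant_profile_once(roles, subtype, cfg, need)
    if (is.null(cand)) next
    acc <- colSums(cand)
    counts <- tabulate(acc, nbins = cfg$accumulation$max)
    mode_hat <- which.max(counts)
    if (abs(mode_hat - cfg$accumulation$mode) <= 1) { carrier <- cand; break }
  }
  if (is.null(carrier)) {
    stop("could not satisfy the accumulation constraints in 200 attempts; ",
         "the profile size, prevalence range and accumulation envelope are ",
         "jointly infeasible")
  }

  n_prof <- cfg$n_profile_variants
  geno_case <- .zygosity(carrier, cfg$hom_alt_fraction)
  geno <- cbind(geno_case, matrix(0L, n_prof, nctrl))

  # control-enriched ("protective") variants, planted with exact counts;
  # case carriers confined to subtype B
  prot <- cfg$protective
  n_prot <- if (is.null(prot)) 0L else nrow(prot)
  if (n_prot > 0) {
    for (i in seq_len(n_prot)) {
      n_ctrl_carr <- round(prot$control_frac[i] * nctrl)
      n_case_carr <- round(prot$case_frac[i] * ncase)
      row <- integer(ncase + nctrl)
      carriers_case <- sample(which(subtype == "B"), n_case_carr)
      carriers_ctrl <- ncase + sample.int(nctrl, n_ctrl_carr)
      row[c(carriers_case, carriers_ctrl)] <-
        ifelse(runif(n_case_carr + n_ctrl_carr) < cfg$hom_alt_fraction, 2L, 1L)
      geno <- rbind(geno, row)
    }
  }

  # rare background, same carrier probability in both groups
  nbg <- cfg$n_background
  bg_maf <- numeric(nbg); bg_panel <- rep(NA_real_, nbg)
  bg_role <- character(nbg)
  if (nbg > 0) {
    u <- runif(nbg)
    common <- u < cfg$background_common_frac
    absent <- !common & (u < cfg$background_common_frac + cfg$background_panel_absent)
    rare <- !common & !absent
    bg_maf[common] <- runif(sum(common), 0.05, 0.30)
    bg_maf[absent] <- runif(sum(absent), 0.001, 0.01)
    bg_maf[rare] <- 0.049 * rbeta(sum(rare), 0.8, 3)
    bg_panel[common] <- bg_maf[common]
    bg_panel[rare] <- bg_maf[rare]
    bg_role <- ifelse(common, "background_common", "background")
    p_carrier <- .hwe_carrier(bg_maf)
    bg_carrier <- matrix(runif(nbg * (ncase + nctrl)) <
                           rep(p_carrier, ncase + nctrl), nbg, ncase + nctrl)
    geno <- rbind(geno, .zygosity(bg_carrier, cfg$hom_alt_fraction))
  }

  nv <- nrow(geno)
  samples <- c(case_ids, ctrl_ids)
  colnames(geno) <- samples

  # variant coordinates, alleles, annotation terms
  chrom <- sort(sample(1:22, nv, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(nv), chrom), function(idx) {
    sort(sample.int(5e7, length(idx)))
  }), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  effect <- rep("missense_variant", nv)
  role_all <- c(roles$role, rep("protective", n_prot), bg_role)
  is_bg <- role_all == "background" | role_all == "background_common"
  bg_idx <- which(role_all == "background")
  n_syn <- round(cfg$background_syn_frac * length(bg_idx))
  syn_idx <- bg_idx[seq_len(n_syn)]
  effect[syn_idx] <- "synonymous_variant"
  del_pool <- setdiff(bg_idx, syn_idx)
  effect[del_pool[seq_len(min(length(del_pool), round(0.1 * length(bg_idx))))]] <-
    "frameshift_variant"
  gene <- sprintf("G%04d", seq_len(nv))

  panel_maf <- c(rep(NA_real_, n_prof),                  # profile: panel-absent
                 rep(0.04, n_prot),                      # protective: rare, present
                 bg_panel)

  variants <- data.frame(
    chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
    effect_term = effect, gene = gene, panel_maf = panel_maf,
    stringsAsFactors = FALSE
  )
  planted_geno <- geno
  planted_case_carriers <- rowSums(geno[, case_ids, drop = FALSE] > 0)
  planted_control_carriers <- rowSums(geno[, ctrl_ids, drop = FALSE] > 0)

  # genotype noise, then missingness
  if (cfg$noise_flip > 0) {
    flip <- matrix(runif(length(geno)) < cfg$noise_flip, nv)
    geno[flip] <- ifelse(geno[flip] == 0L, 1L, ifelse(geno[flip] == 1L, 0L, 1L))
  }
  if (cfg$missing_rate > 0) {
    geno[matrix(runif(length(geno)) < cfg$missing_rate, nv)] <- NA_integer_
  }

  dp <- matrix(pmin(cfg$depth_ceiling,
                    pmax(cfg$depth_floor,
                         round(rnorm(nv * length(samples),
                                     cfg$depth_mean, cfg$depth_sd)))),
               nv)
  gq <- matrix(pmin(99, pmax(40, round(rnorm(nv * length(samples), 85, 10)))), nv)
  frac <- matrix(0.005, nv, length(samples))
  frac[!is.na(geno) & geno == 1L] <- 0.5
  frac[!is.na(geno) & geno == 2L] <- 0.93
  ad <- matrix(rbinom(nv * length(samples), as.vector(dp), as.vector(frac)), nv)
  miss <- is.na(geno)
  dp[miss] <- NA_real_; gq[miss] <- NA_real_; ad[miss] <- NA_real_

  labels <- setNames(c(rep("CASE", ncase), rep("CONTROL", nctrl)), samples)
  cohort <- cohort_matrix(geno, labels, variants, gq = gq, dp = dp, ad = ad)
  key <- variant_key(cohort)
  rownames(planted_geno) <- key
  panel <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, maf = variants$panel_maf, stringsAsFactors = FALSE
  )
  panel <- panel[!is.na(panel$maf), , drop = FALSE]

  roles_out <- data.frame(
    variant = key, role = role_all,
    pool = c(roles$pool, rep(NA_character_, n_prot), rep(NA_character_, nbg)),
    rate_A = c(roles$rate_A, rep(NA, n_prot), rep(NA, nbg)),
    rate_B = c(roles$rate_B, rep(NA, n_prot), rep(NA, nbg)),
    planted_case_carriers = planted_case_carriers,
    planted_control_carriers = planted_control_carriers,
    stringsAsFactors = FALSE
  )
  truth <- list(
    subtype = c(subtype, setNames(rep("C", nctrl), ctrl_ids)),
    roles = roles_out,
    planted_geno = planted_geno
  )
  out <- structure(list(cohort = cohort, truth = truth, panel = panel,
                        config = cfg, paths = NULL),
                   class = "synthetic_cohort")
  if (!is.null(dir)) out$paths <- .write_cohort_files(out, dir)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d variants x %d samples (seed %d)\n",
    nrow(x$cohort$geno), length(x$cohort$samples), x$config$seed
  ))
  print(table(role = x$truth$roles$role))
  invisible(x)
}

# ---- VCF / file emission ---------------------------------------------------

.geno_to_gt <- function(g) {
  ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L])
}

.write_cohort_vcf <- function(cohort, path) {
  v <- cohort$variants
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name'\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic Depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t")
  )
  impact <- ifelse(v$effect_term %in% .DELETERIOUS_TERMS, "HIGH",
                   ifelse(v$effect_term %in% .MODERATE_TERMS, "MODERATE", "LOW"))
  info <- sprintf("ANN=%s|%s|%s|%s", v$alt, v$effect_term, impact, v$gene)
  fmt_call <- function(g, gq, dp, ad) {
    ifelse(is.na(g), "./.:.:.:.",
           sprintf("%s:%d:%d:%d,%d", .geno_to_gt(g), as.integer(gq),
                   as.integer(dp), as.integer(dp - ad), as.integer(ad)))
  }
  calls <- vapply(seq_along(cohort$samples), function(j) {
    fmt_call(cohort$geno[, j], cohort$gq[, j], cohort$dp[, j], cohort$ad[, j])
  }, character(nrow(v)))
  body <- cbind(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                "GT:GQ:DP:AD", calls)
  lines <- apply(body, 1, paste, collapse = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

.write_cohort_files <- function(syn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    labels = file.path(dir, "labels.tsv"),
    panel = file.path(dir, "panel.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    config = file.path(dir, "config.yaml")
  )
  .write_cohort_vcf(syn$cohort, paths$vcf)
  data.table::fwrite(
    data.frame(sample = syn$cohort$samples,
               phenotype = tolower(unname(syn$cohort$labels))),
    paths$labels, sep = "\t", col.names = FALSE
  )
  data.table::fwrite(syn$panel, paths$panel, sep = "\t")
  data.table::fwrite(syn$truth$roles, paths$truth_variants, sep = "\t")
  data.table::fwrite(
    data.frame(sample = names(syn$truth$subtype),
               subtype = unname(syn$truth$subtype)),
    paths$truth_samples, sep = "\t"
  )
  cfg <- syn$config
  cfg$protective <- as.list(cfg$protective)
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (is.numeric(x)) as.vector(x) else x
  }), paths$config)
  paths
}

#' Generate an external screening population
#'
#' Individuals are mostly free of profile variants; configured fractions
#' carry the full planted signature of a case subtype — every variant
#' characteristic of that subtype (within-subtype carrier rate of at least
#' 0.5) is carried, and the rest of the profile is drawn at the subtype's
#' per-variant rates. Genotypes are returned encoded on the cohort's
#' profile variants, ready for [screen_population()].
#'
#' @param syn a `synthetic_cohort` from [generate_cohort()].
#' @param n number of individuals.
#' @param fractions named fractions of subtype-signature carriers, e.g.
#'   `c(A = 0.005, B = 0.024)`; each individual's type is drawn
#'   independently. Must sum to at most 1.
#' @param seed integer seed.
#' @param dir optional directory; writes `external.vcf` when given.
#' @return list with `features` (individuals x profile variants), `truth`
#'   (planted type per individual: `"A"`, `"B"` or `"none"`) and `paths`.
#' @export
generate_external_population <- function(syn, n = 1271,
                                         fractions = c(A = 0.005, B = 0.024),
                                         seed = 1L, dir = NULL) {
  stopifnot(inherits(syn, "synthetic_cohort"))
  if (sum(fractions) > 1) stop("signature fractions sum to more than 1")
  set.seed(seed)
  roles <- syn$truth$roles
  prof <- roles[roles$role %in% c("profile_A", "profile_B", "shared_profile"), ]
  keys <- prof$variant
  ids <- sprintf("EXT%04d", seq_len(n))
  if (n == 0) {
    return(list(features = matrix(0L, 0, length(keys),
                                  dimnames = list(NULL, keys)),
                truth = character(0), paths = NULL))
  }
  type <- sample(c(names(fractions), "none"), n, replace = TRUE,
                 prob = c(fractions, 1 - sum(fractions)))
  enc <- matrix(0L, n, length(keys), dimnames = list(ids, keys))
  for (tp in intersect(unique(type), c("A", "B"))) {
    rows <- which(type == tp)
    rate <- if (tp == "A") prof$rate_A else prof$rate_B
    signature <- rate >= 0.5 |
      (tp == "A" & prof$pool == "A_exclusive") |
      (tp == "B" & prof$pool == "B_exclusive")
    p <- ifelse(signature, 1, rate)
    carrier <- matrix(runif(length(rows) * length(keys)) <
                        rep(p, each = length(rows)),
                      length(rows), length(keys))
    enc[rows, ] <- t(.zygosity(t(carrier), syn$config$hom_alt_fraction))
  }
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    vi <- match(keys, variant_key(syn$cohort))
    variants <- syn$cohort$variants[vi, , drop = FALSE]
    dp <- matrix(syn$config$depth_mean, length(keys), n)
    ext <- cohort_matrix(t(enc), setNames(rep("CONTROL", n), ids), variants,
                         gq = matrix(99, length(keys), n), dp = dp,
                         ad = round(dp * ifelse(t(enc) > 0, 0.5, 0)))
    paths <- list(vcf = file.path(dir, "external.vcf"))
    .write_cohort_vcf(ext, paths$vcf)
  }
  list(features = enc, truth = setNames(type, ids), paths = paths)
}
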