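# Independent oracles and small hand fixtures shared across the suite.

# two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins (combinatorial probabilities, no distribution function)
bf_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  prob <- vapply(support, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(N, k))
  }, numeric(1))
  obs <- prob[support == a]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# literal step-up rule: q_i = min over j with p_(j) >= p_(i) of p_(j)*m/rank(j)
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- match(seq_len(m), ord)   # rank of each p in the sorted order
  vapply(seq_len(m), function(i) {
    js <- which(p[ord] >= p[i] - 1e-15)
    min(1, min(p[ord][js] * m / js))
  }, numeric(1))
}

# Jaccard by explicit set enumeration of (variant, zygosity) pairs
bf_jaccard <- function(x, y) {
  sx <- paste(which(x > 0), x[x > 0]); sy <- paste(which(y > 0), y[y > 0])
  if (length(sx) == 0 && length(sy) == 0) return(1)
  length(intersect(sx, sy)) / length(union(sx, sy))
}

# hand-built cohort: genotype codes given per variant (rows) x sample (cols)
toy_cohort <- function(geno, n_case, n_control, ...) {
  labels <- c(rep("CASE", n_case), rep("CONTROL", n_control))
  cohort_matrix(geno, labels, ...)
}

# three-sample annotated VCF exercising multi-allelic splitting, a record
# without annotation (must be dropped with a count) and a missing call
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "100", ".", "A", "C", ".", "PASS",
            "ANN=C|missense_variant|MODERATE|G1", "GT:GQ:DP:AD",
            "0/1:99:150:80,70", "0/0:99:200:198,2", "1/1:80:120:6,114"),
          collapse = "\t"),
    paste(c("1", "200", ".", "A", "C,T", ".", "PASS",
            paste0("ANN=C|missense_variant|MODERATE|G2,",
                   "T|synonymous_variant|LOW|G2"), "GT:GQ:DP:AD",
            "1/2:90:180:10,85,85", "0/1:85:140:70,68,2", "0/2:95:160:80,2,78"),
          collapse = "\t"),
    paste(c("1", "300", ".", "G", "T", ".", "PASS", ".", "GT:GQ:DP:AD",
            "0/1:99:150:75,75", "0/0:99:150:149,1", "0/0:99:150:150,0"),
          collapse = "\t"),
    paste(c("2", "50", ".", "C", "G", ".", "PASS",
            "ANN=G|frameshift_variant|HIGH|G3", "GT:GQ:DP:AD",
            "./.:.:.:.", "0/1:99:99:50,49", "0/0:20:150:149,1"),
          collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# quick default-free generator call used by several files
quiet_cohort <- function(...) generate_cohort(sim_config(...))
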