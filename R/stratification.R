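# Genotype-aware Jaccard similarity, agglomerative clustering and
# cluster-number selection (Ball and Hartigan indexes).

#' Encode genotype profiles over the profile variants
#'
#' Per sample, per profile variant: 0 for homozygous reference or missing,
#' 1 for heterozygous, 2 for homozygous alternate. This encoding is the
#' genotype profile compared by the Jaccard coefficient and the feature
#' space of the subtype classifier.
#'
#' @param x a `cohort_matrix`.
#' @param profile a `variant_profile`, or a character vector of variant keys.
#' @return integer matrix, samples in rows, profile variants in columns.
#' @export
encode_genotypes <- function(x, profile) {
  keys <- if (inherits(profile, "variant_profile")) variant_key(profile$variants)
          else as.character(profile)
  if (length(keys) == 0) stop("profile is empty; nothing to encode")
  enc <- matrix(0L, nrow = length(x$samples), ncol = length(keys),
                dimnames = list(x$samples, keys))
  present <- intersect(keys, rownames(x$geno))
  g <- t(x$geno[present, , drop = FALSE])
  g[is.na(g)] <- 0L
  enc[, present] <- g
  enc
}

#' Jaccard similarity of two genotype profiles
#'
#' The profiles are sets of (variant, zygosity) pairs over the profile
#' variants: a shared variant only matches when the zygosity also matches.
#' Two empty profiles (identical absence) have similarity 1; an empty and a
#' non-empty profile have similarity 0.
#'
#' @param x,y integer code vectors (0/1/2) over the same variants.
#' @return similarity in `[0, 1]`; the clustering distance is `1 - J`.
#' @export
jaccard_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  match_ <- sum(x == y & x > 0)
  union <- sum(x > 0) + sum(y > 0) - match_
  if (union == 0) return(1)
  match_ / union
}

#' All-pairs Jaccard similarity matrix
#'
#' @param enc encoded genotype matrix from [encode_genotypes()] (samples in
#'   rows); row names must be unique sample identifiers.
#' @return symmetric similarity matrix of class `similarity_matrix` with
#'   unit diagonal.
#' @export
pairwise_similarity <- function(enc) {
  if (nrow(enc) < 2) stop("need at least two profiles")
  if (is.null(rownames(enc))) rownames(enc) <- sprintf("S%03d", seq_len(nrow(enc)))
  if (anyDuplicated(rownames(enc))) stop("duplicate sample identifiers")
  het <- (enc == 1L) * 1; hom <- (enc == 2L) * 1
  match_ <- tcrossprod(het) + tcrossprod(hom)     # same variant, same zygosity
  n <- rowSums(enc > 0L)
  union <- outer(n, n, `+`) - match_              # union of (variant, zygosity) pairs
  sim <- ifelse(union == 0, 1, match_ / pmax(union, 1))
  diag(sim) <- 1
  sim <- (sim + t(sim)) / 2                        # exact symmetry
  dimnames(sim) <- list(rownames(enc), rownames(enc))
  class(sim) <- c("similarity_matrix", class(sim))
  sim
}

#' Agglomerative clustering on Jaccard distance
#'
#' @param sim similarity matrix from [pairwise_similarity()].
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward.D2"`.
#' @return an `hclust` merge tree on distance `1 - similarity`.
#' @export
hierarchical_cluster <- function(sim, linkage = "average") {
  linkage <- match.arg(linkage, c("average", "single", "complete", "ward.D2"))
  d <- 1 - unclass(sim)
  if (any(!is.finite(d))) stop("non-finite distances")
  hclust(as.dist(d), method = linkage)
}

# total within-cluster sum of squared distances to cluster centroids
.wss <- function(features, labels) {
  labels <- as.character(labels)
  sum(vapply(split(seq_len(nrow(features)), labels), function(idx) {
    block <- features[idx, , drop = FALSE]
    ctr <- colMeans(block)
    sum(sweep(block, 2, ctr)^2)
  }, numeric(1)))
}

#' Ball index
#'
#' Mean within-cluster dispersion `W_k / k`, where `W_k` is the total
#' within-cluster sum of squared distances to cluster centroids in the
#' numeric genotype encoding. The associated decision rule picks the k with
#' the largest drop between successive index values.
#'
#' @param features numeric matrix, samples in rows (typically
#'   [encode_genotypes()] output).
#' @param labels cluster assignment for each row.
#' @export
ball_index <- function(features, labels) {
  k <- length(unique(labels))
  tab <- table(labels)
  if (any(tab == 0)) stop("empty cluster")
  .wss(features, labels) / k
}

#' Hartigan index
#'
#' `(W_k / W_{k+1} - 1) * (n - k - 1)` comparing the k-cluster partition
#' with the (k+1)-cluster partition. The associated decision rule picks the
#' smallest k whose index drops to 10 or below.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels_k,labels_k1 partitions into k and k+1 clusters.
#' @export
hartigan_index <- function(features, labels_k, labels_k1) {
  k <- length(unique(labels_k))
  n <- nrow(features)
  wk <- .wss(features, labels_k)
  wk1 <- .wss(features, labels_k1)
  if (wk == wk1) return(0)
  if (wk1 == 0) return(Inf)
  (wk / wk1 - 1) * (n - k - 1)
}

#' Choose the number of clusters from a dendrogram scan
#'
#' For each k in `k_range` the dendrogram is cut and both indexes evaluated
#' on the genotype encoding. Decision rules: Ball picks the k with the
#' maximum difference between successive index values; Hartigan keeps adding
#' clusters while the index still exceeds 10 anywhere up the scan, i.e. k is
#' one past the last index value above 10 (and the smallest candidate when
#' no value exceeds 10). The "one past the last crossing" form is robust to
#' dendrogram cuts whose sum-of-squares gain is not monotone in k, where the
#' textbook "first k at or below 10" stops too early. When the two rules
#' disagree the Hartigan choice is returned with a warning.
#'
#' @param hc an `hclust` tree.
#' @param features numeric matrix, samples in rows, used for the indexes.
#' @param k_range candidate cluster numbers (within `[1, n - 1]`).
#' @return `list(k, k_ball, k_hartigan, trace)` where `trace` is a
#'   data.frame of (k, W, ball, hartigan).
#' @export
select_k <- function(hc, features, k_range = 1:8) {
  n <- nrow(features)
  k_range <- sort(unique(k_range))
  if (min(k_range) < 1 || max(k_range) > n - 1) stop("k_range outside [1, n-1]")
  ks <- c(k_range, max(k_range) + 1)            # one extra cut for Hartigan
  cuts <- lapply(ks, function(k) cutree(hc, k = min(k, n)))
  w <- vapply(cuts, function(lb) .wss(features, lb), numeric(1))
  ball <- w[seq_along(k_range)] / k_range
  hart <- vapply(seq_along(k_range), function(i) {
    hartigan_index(features, cuts[[i]], cuts[[i + 1]])
  }, numeric(1))

  k_ball <- if (length(k_range) < 2) k_range[1] else {
    diffs <- ball[-length(ball)] - ball[-1]
    k_range[-1][which.max(diffs)]
  }
  above <- which(hart > 10)
  k_hart <- if (length(above) == 0) k_range[1] else {
    target <- k_range[max(above)] + 1
    min(max(k_range), min(k_range[k_range >= target], target))
  }
  if (k_ball != k_hart) {
    warning(sprintf("Ball (k=%d) and Hartigan (k=%d) disagree; using Hartigan",
                    k_ball, k_hart))
  }
  list(
    k = k_hart, k_ball = k_ball, k_hartigan = k_hart,
    trace = data.frame(k = k_range, W = w[seq_along(k_range)],
                       ball = ball, hartigan = hart)
  )
}

#' Stratify a cohort into genomic subtypes
#'
#' Encodes the genotype profiles over the selected variants, computes the
#' Jaccard similarity of every pair of samples, clusters on the Jaccard
#' distance and cuts the tree at the chosen number of clusters. Clusters are
#' named by content: the cluster holding the most controls is `"C"`, the
#' remaining clusters are `"A"`, `"B"`, ... by increasing size.
#'
#' @param x a `cohort_matrix`.
#' @param profile a `variant_profile` (or variant keys) defining the profile.
#' @param linkage linkage method, see [hierarchical_cluster()].
#' @param k fixed number of clusters, or `NULL` to choose with [select_k()].
#' @param k_range scan range for [select_k()].
#' @return an object of class `clustering_result`: `hclust`, `similarity`,
#'   `k`, named per-sample `labels`, and the `index_trace` when k was
#'   selected automatically.
#' @export
stratify_cohort <- function(x, profile, linkage = "average", k = NULL,
                            k_range = 1:8) {
  enc <- encode_genotypes(x, profile)
  sim <- pairwise_similarity(enc)
  hc <- hierarchical_cluster(sim, linkage)
  trace <- NULL
  if (is.null(k)) {
    sel <- select_k(hc, enc, k_range)
    k <- sel$k
    trace <- sel$trace
  }
  raw <- cutree(hc, k = k)
  labels <- .name_clusters(raw, x$labels)
  structure(list(
    hclust = hc, similarity = sim, encoded = enc, k = k,
    labels = labels, index_trace = trace
  ), class = "clustering_result")
}

# control-dominant cluster -> "C"; remaining clusters by increasing size ->
# "A", "B", then "D", "E", ... for any extras
.name_clusters <- function(raw, phenotypes) {
  ids <- sort(unique(raw))
  ctrl_counts <- vapply(ids, function(i) sum(phenotypes[raw == i] == "CONTROL"),
                        numeric(1))
  sizes <- vapply(ids, function(i) sum(raw == i), numeric(1))
  cname <- ids[which.max(ctrl_counts)]
  others <- ids[ids != cname]
  others <- others[order(sizes[match(others, ids)])]
  nm <- setNames(rep(NA_character_, length(ids)), ids)
  nm[as.character(cname)] <- "C"
  pool <- setdiff(LETTERS, "C")
  nm[as.character(others)] <- pool[seq_along(others)]
  setNames(nm[as.character(raw)], names(raw))
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d samples in %d clusters\n",
              length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths carry the merge heights of the agglomerative tree.
#'
#' @param x a `clustering_result` or an `hclust`.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @export
dendrogram_newick <- function(x, path = NULL) {
  hc <- if (inherits(x, "clustering_result")) x$hclust else x
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}
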