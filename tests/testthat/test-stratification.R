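test_that("genotype-aware Jaccard matches set enumeration", {
  x <- c(1L, 2L, 0L); y <- c(1L, 1L, 0L)
  # shared variant with different zygosity does not match
  expect_equal(jaccard_similarity(x, y), 1 / 3)
  expect_equal(jaccard_similarity(x, x), 1)
  expect_equal(jaccard_similarity(c(1L, 0L), c(0L, 2L)), 0)
  # identical absence counts as identical; empty vs non-empty as disjoint
  expect_equal(jaccard_similarity(c(0L, 0L), c(0L, 0L)), 1)
  expect_equal(jaccard_similarity(c(0L, 0L), c(1L, 0L)), 0)

  set.seed(11)
  for (i in 1:50) {
    a <- sample(0:2, 12, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    b <- sample(0:2, 12, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    expect_equal(jaccard_similarity(a, b), bf_jaccard(a, b))
  }
})

test_that("jaccard distance behaves as a metric on random triples", {
  set.seed(13)
  for (i in 1:200) {
    trip <- replicate(3, sample(0:2, 10, replace = TRUE, prob = c(0.5, 0.4, 0.1)))
    d <- function(u, v) 1 - jaccard_similarity(u, v)
    dxy <- d(trip[, 1], trip[, 2]); dxz <- d(trip[, 1], trip[, 3])
    dyz <- d(trip[, 2], trip[, 3])
    expect_lte(dxy, dxz + dyz + 1e-12)
    expect_equal(dxy, d(trip[, 2], trip[, 1]))
  }
})

test_that("pairwise similarity equals the brute-force double loop", {
  set.seed(17)
  enc <- matrix(sample(0:2, 9 * 20, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                nrow = 9, dimnames = list(paste0("P", 1:9), NULL))
  sim <- pairwise_similarity(enc)
  expect_true(isSymmetric(unclass(sim)))
  expect_equal(unname(diag(sim)), rep(1, 9))
  for (i in 1:9) for (j in 1:9) {
    expect_equal(sim[i, j], bf_jaccard(enc[i, ], enc[j, ]),
                 tolerance = 1e-12)
  }
  # identical profiles give an all-ones matrix
  same <- matrix(rep(c(1L, 0L, 2L), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(unclass(pairwise_similarity(same))), matrix(1, 3, 3))

  rownames(enc) <- rep("dup", 9)
  expect_error(pairwise_similarity(enc), "duplicate")
})

test_that("two planted groups separate at the top split", {
  set.seed(19)
  g1 <- matrix(rep(c(rep(1L, 6), rep(0L, 6)), 5), nrow = 5, byrow = TRUE)
  g2 <- matrix(rep(c(rep(0L, 6), rep(1L, 6)), 4), nrow = 4, byrow = TRUE)
  # small within-group perturbations
  enc <- rbind(g1, g2)
  enc[cbind(1:9, sample(12, 9, TRUE))] <- 2L
  rownames(enc) <- paste0("S", 1:9)
  hc <- hierarchical_cluster(pairwise_similarity(enc))
  cut <- cutree(hc, 2)
  expect_equal(length(unique(cut[1:5])), 1L)
  expect_equal(length(unique(cut[6:9])), 1L)
  expect_true(cut[1] != cut[9])

  # n = 2: a single merge at the pair's distance
  two <- enc[1:2, ]
  hc2 <- hierarchical_cluster(pairwise_similarity(two))
  expect_equal(hc2$height, 1 - jaccard_similarity(two[1, ], two[2, ]))
})

test_that("dispersion indexes match their defining formulas", {
  set.seed(23)
  feats <- matrix(rnorm(30), nrow = 10)
  labels <- rep(1:2, each = 5)
  wss_hand <- sum(scale(feats[1:5, ], scale = FALSE)^2) +
    sum(scale(feats[6:10, ], scale = FALSE)^2)
  expect_equal(ball_index(feats, labels), wss_hand / 2)

  # every point its own cluster: zero dispersion
  expect_equal(ball_index(feats, 1:10), 0)
  # no improvement from k to k+1 gives a zero Hartigan index
  labels3 <- labels; labels3[10] <- 3
  w2 <- ball_index(feats, labels) * 2
  w3 <- ball_index(feats, labels3) * 3
  expect_equal(hartigan_index(feats, labels, labels3),
               (w2 / w3 - 1) * (10 - 2 - 1))
  expect_equal(hartigan_index(feats, labels, labels), 0)
})

test_that("cluster-number selection finds planted structure", {
  set.seed(29)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  feats <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(10 * 2, sd = 0.6), ncol = 2), 2, centers[i, ], `+`)
  }))
  rownames(feats) <- paste0("S", seq_len(nrow(feats)))
  hc <- hclust(dist(feats), method = "average")
  sel <- suppressWarnings(select_k(hc, feats, 1:6))
  expect_equal(sel$k, 3)
  expect_equal(sel$trace$k, 1:6)
  expect_true(all(diff(sel$trace$W) <= 1e-9))

  # two tight groups: both rules agree on k = 2
  feats2 <- feats[1:20, ]
  hc2 <- hclust(dist(feats2), method = "average")
  sel2 <- select_k(hc2, feats2, 1:5)
  expect_equal(sel2$k, 2)
  expect_equal(sel2$k_ball, 2)

  # one homogeneous blob: no index value demands a split
  set.seed(31)
  blob <- matrix(rnorm(50 * 3, sd = 0.2), ncol = 3)
  rownames(blob) <- paste0("S", 1:50)
  hcb <- hclust(dist(blob), method = "average")
  expect_equal(suppressWarnings(select_k(hcb, blob, 1:5))$k, 1)

  expect_error(select_k(hc, feats, 1:200), "k_range")
})

test_that("joint clustering recovers the planted taxonomy and is order-invariant", {
  skip_if_not_installed("mclust")
  syn <- quiet_cohort(seed = 7, noise_flip = 0, missing_rate = 0)
  m <- apply_filters(syn$cohort)$matrix
  prof <- select_profile(m)
  cr <- suppressWarnings(stratify_cohort(m, prof))
  expect_equal(cr$k, 3)
  truth <- syn$truth$subtype[names(cr$labels)]
  expect_equal(mclust::adjustedRandIndex(truth, cr$labels), 1)
  # content-based names: all controls in C, case clusters A smaller than B
  expect_true(all(cr$labels[m$labels == "CONTROL"] == "C"))
  expect_lt(sum(cr$labels == "A"), sum(cr$labels == "B"))
  # within-subtype similarity exceeds between-subtype similarity
  simAA <- mean(cr$similarity[truth == "A", truth == "A"])
  simAB <- mean(cr$similarity[truth == "A", truth == "B"])
  simBB <- mean(cr$similarity[truth == "B", truth == "B"])
  expect_gt(simAA, simAB)
  expect_gt(simBB, simAB)

  perm <- sample(length(m$samples))
  crp <- stratify_cohort(subset_cohort(m, samples = m$samples[perm]),
                         prof, k = 3)
  expect_equal(mclust::adjustedRandIndex(cr$labels[names(crp$labels)],
                                         crp$labels), 1)

  nwk <- dendrogram_newick(cr)
  expect_match(nwk, "^\\(")
  expect_true(grepl(names(cr$labels)[1], nwk, fixed = TRUE))
})
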