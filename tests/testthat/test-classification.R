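# deterministic separable fixture: class decided by two signature variants
.separable_fixture <- function(n_a = 15, n_b = 45, n_c = 20, p_noise = 8,
                               seed = 101) {
  set.seed(seed)
  n <- n_a + n_b + n_c
  labels <- factor(rep(c("A", "B", "C"), c(n_a, n_b, n_c)))
  feats <- matrix(sample(0:1, n * p_noise, replace = TRUE), nrow = n)
  sig_a <- as.integer(labels == "A")
  sig_b <- as.integer(labels == "B")
  feats <- cbind(sigA1 = sig_a, sigA2 = sig_a * 2L, sigB1 = sig_b, feats)
  colnames(feats) <- paste0("v", seq_len(ncol(feats)))
  rownames(feats) <- paste0("S", seq_len(n))
  list(features = feats, labels = setNames(labels, rownames(feats)))
}

test_that("feature encoding maps genotypes to 0/1/2 with missing as 0", {
  g <- rbind(c(0L, 1L, 2L), c(NA, 0L, 1L))
  v <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                  effect_term = "missense_variant")
  m <- toy_cohort(g, 2, 1, variants = v)
  enc <- encode_genotypes(m, variant_key(m))
  expect_equal(unname(enc),
               matrix(c(0L, 0L, 1L, 0L, 2L, 1L), nrow = 3, byrow = TRUE))
  # an all-reference sample encodes as the zero vector
  expect_equal(unname(enc[1, ]), c(0L, 0L))
  # variants absent from the matrix encode as zero columns
  enc2 <- encode_genotypes(m, c(variant_key(m), "9:9:A:T"))
  expect_equal(unname(enc2[, 3]), c(0L, 0L, 0L))
})

test_that("stratified folds preserve class proportions within one sample", {
  labels <- factor(rep(c("A", "B", "C"), c(17, 101, 32)))
  set.seed(5)
  for (r in 1:10) {
    folds <- stratified_folds(labels, 10)
    tab <- table(labels, folds)
    expect_true(all(abs(tab - outer(table(labels) / 10, rep(1, 10))) <= 1))
  }
})

test_that("confusion-matrix metrics match hand formulas", {
  cm <- matrix(c(50, 3, 2,
                 4, 90, 6,
                 0, 1, 44), nrow = 3, byrow = TRUE)
  met <- confusion_metrics(cm)
  expect_equal(met$accuracy, (50 + 90 + 44) / sum(cm))
  expect_equal(met$sensitivity[1], 50 / 55)
  expect_equal(met$specificity[1], (sum(cm) - 55 - 4 - 0) / (sum(cm) - 55))
  expect_equal(met$precision[2], 90 / 94)
  po <- (50 + 90 + 44) / sum(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  expect_equal(met$kappa, (po - pe) / (1 - pe))
})

test_that("cross-validation is perfect on separable data and reproducible", {
  fx <- .separable_fixture()
  cfg <- cv_config(n_repeats = 2, n_trees = 100, seed = 9)
  rep1 <- cross_validate(fx$features, fx$labels, cfg)
  expect_equal(rep1$summary$mean[rep1$summary$metric == "accuracy"], 1)
  expect_equal(rep1$summary$mean[rep1$summary$metric == "kappa"], 1)
  expect_equal(sum(rep1$pooled_confusion), 2 * 80)
  expect_equal(unname(rowSums(rep1$pooled_confusion)), c(15, 45, 20) * 2)
  # case/control collapse of the same fit
  expect_equal(rep1$summary_collapsed$mean[
    rep1$summary_collapsed$metric == "sens_case"], 1)

  rep2 <- cross_validate(fx$features, fx$labels, cfg)
  expect_identical(rep1$per_repeat, rep2$per_repeat)
  expect_identical(rep1$mdi, rep2$mdi)

  expect_error(cross_validate(fx$features, factor(rep("A", 80)), cfg),
               "two classes")
})

test_that("permuted labels drive accuracy to chance and kappa to zero", {
  fx <- .separable_fixture(seed = 202)
  set.seed(33)
  shuffled <- setNames(sample(fx$labels), names(fx$labels))
  rep_null <- cross_validate(fx$features, shuffled,
                             cv_config(n_repeats = 5, n_trees = 100, seed = 3))
  acc <- rep_null$summary$mean[rep_null$summary$metric == "accuracy"]
  expect_lt(abs(acc - 45 / 80), 0.12)
  expect_lt(abs(rep_null$summary$mean[rep_null$summary$metric == "kappa"]), 0.1)
})

test_that("honest in-fold reselection never beats naive selection on noisy data", {
  syn <- quiet_cohort(seed = 21)      # default flip noise and missingness
  m <- apply_filters(syn$cohort)$matrix
  prof <- select_profile(m)
  feats <- encode_genotypes(m, prof)
  labs <- syn$truth$subtype[rownames(feats)]
  cfg <- cv_config(n_repeats = 1, n_trees = 150, seed = 12)
  naive <- cross_validate(feats, labs, cfg)
  honest <- cross_validate(NULL, labs[m$samples], cfg, mode = "honest",
                           cohort = m)
  acc_n <- naive$summary$mean[naive$summary$metric == "accuracy"]
  acc_h <- honest$summary$mean[honest$summary$metric == "accuracy"]
  expect_lte(acc_h, acc_n + 0.05)
})

test_that("final model round-trips, is deterministic, and ranks planted signal first", {
  fx <- .separable_fixture()
  cfg <- cv_config(n_trees = 200, seed = 4)
  model <- train_final(fx$features, fx$labels, cfg)
  # training accuracy on the separable fixture
  pred <- predict_subtype(model, fx$features)
  expect_equal(colnames(pred)[max.col(pred)], as.character(fx$labels))
  expect_equal(unname(rowSums(pred)), rep(1, nrow(pred)), tolerance = 1e-9)

  model2 <- train_final(fx$features, fx$labels, cfg)
  expect_equal(predict_subtype(model2, fx$features), pred)

  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  reloaded <- readRDS(path)
  set.seed(99)
  probe <- matrix(sample(0:2, 100 * ncol(fx$features), replace = TRUE),
                  nrow = 100, dimnames = list(NULL, colnames(fx$features)))
  expect_equal(predict_subtype(reloaded, probe), predict_subtype(model, probe))

  imp <- mdi_importance(model)
  expect_equal(sum(imp$mdi), 1, tolerance = 1e-9)
  expect_true(all(imp$mdi >= 0))
  expect_true(all(c("v1", "v2", "v3") %in% imp$variant[1:4]))
})

test_that("importance is symmetric under identical features", {
  set.seed(55)
  labels <- factor(rep(c("A", "B"), each = 30))
  base <- as.integer(labels == "A")
  feats <- cbind(f1 = base, f2 = base, f3 = base, f4 = base)
  feats <- feats + 0L
  rownames(feats) <- paste0("S", 1:60)
  model <- train_final(feats, labels, cv_config(n_trees = 500, seed = 8))
  imp <- mdi_importance(model)
  expect_lt(diff(range(imp$mdi)), 0.12)
})

test_that("screening assigns only confident classes and handles empty input", {
  fx <- .separable_fixture()
  model <- train_final(fx$features, fx$labels, cv_config(n_trees = 300, seed = 6))

  # a full subtype-A signature individual
  a_sig <- matrix(0L, 1, ncol(fx$features),
                  dimnames = list("ext1", colnames(fx$features)))
  a_sig[, c("v1", "v2")] <- c(1L, 2L)
  scr_a <- screen_population(model, a_sig)
  expect_equal(scr_a$class, "A")
  expect_gte(scr_a$score, 0.9)

  # a profile-free individual is control-like or unassigned, never A/B
  zero <- matrix(0L, 1, ncol(fx$features),
                 dimnames = list("ext2", colnames(fx$features)))
  scr_0 <- screen_population(model, zero)
  expect_true(scr_0$class %in% c("C", "UNASSIGNED"))

  # variants absent from the external schema encode as zero
  partial <- a_sig[, 1:3, drop = FALSE]
  expect_equal(screen_population(model, partial)$class, "A")

  empty <- screen_population(model, a_sig[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(attr(empty, "counts")), 0L)

  dup <- rbind(a_sig, a_sig)
  rownames(dup) <- c("x", "x")
  expect_error(screen_population(model, dup), "duplicate")
})
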