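test_that("annotation terms map to effect classes totally and deterministically", {
  expect_equal(classify_effect("missense_variant"), "MODERATE")
  expect_equal(classify_effect("5_prime_UTR_variant"), "MODERATE")
  expect_equal(classify_effect("splice_donor_variant"), "MODERATE")
  expect_equal(classify_effect("frameshift_variant"), "DELETERIOUS")
  expect_equal(classify_effect("stop_gained"), "DELETERIOUS")
  expect_equal(classify_effect("synonymous_variant"), "EXCLUDED")
  expect_equal(classify_effect("intergenic_region"), "EXCLUDED")
  # &-joined terms: deleterious dominates, then moderate
  expect_equal(classify_effect("structural_interaction_variant&missense_variant"),
               "DELETERIOUS")
  expect_equal(classify_effect("missense_variant&intron_variant"), "MODERATE")
})

.freq_fixture <- function() {
  g <- matrix(1L, 4, 4)
  v <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                  effect_term = "missense_variant",
                  panel_maf = c(NA, 0.04, 0.05, 0.2))
  toy_cohort(g, 2, 2, variants = v)
}

test_that("reference-frequency filter keeps panel-absent and strictly rare variants", {
  m <- .freq_fixture()
  kept <- filter_by_reference_frequency(m)
  # absent -> kept; 0.04 -> kept; 0.05 -> removed (strict); 0.2 -> removed
  expect_equal(kept$variants$pos, c(1L, 2L))

  # empty panel: nothing annotated, matrix unchanged
  m$variants$panel_maf <- NA_real_
  expect_equal(nrow(filter_by_reference_frequency(m)$geno), 4L)
})

test_that("quality gating is per call, with inclusive coverage boundary", {
  g <- matrix(c(1L, 0L, 0L,
                1L, 1L, 0L), nrow = 2, byrow = TRUE)
  dp <- matrix(c(150, 200, 99,
                 99, 100, 150), nrow = 2, byrow = TRUE)
  gq <- matrix(99, 2, 3)
  ad <- matrix(c(70, 2, 1,
                 45, 50, 1), nrow = 2, byrow = TRUE)
  v <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                  effect_term = "missense_variant")
  m <- toy_cohort(g, 2, 1, variants = v, dp = dp, gq = gq, ad = ad)
  res <- filter_by_quality(m)
  # dp = 99 fails (coverage >= 100), dp = 100 passes the boundary
  expect_true(is.na(res$matrix$geno[2, 1]))
  expect_equal(res$matrix$geno[2, 2], 1L)
  expect_equal(res$matrix$geno[1, 1], 1L)
  expect_equal(res$n_demoted, 2L)  # (2,S1) non-ref and (1,S3) dp 99 hom-ref

  # a variant whose only carrier fails DP is removed entirely
  g2 <- matrix(c(1L, 0L, 0L), 1, 3)
  m2 <- toy_cohort(g2, 2, 1,
                   variants = data.frame(chrom = "1", pos = 9, ref = "A",
                                         alt = "G",
                                         effect_term = "missense_variant"),
                   dp = matrix(c(50, 200, 200), 1, 3),
                   gq = matrix(99, 1, 3), ad = matrix(c(25, 0, 0), 1, 3))
  expect_equal(nrow(filter_by_quality(m2)$matrix$geno), 0L)

  # low alt fraction on a non-reference call fails the AD gate
  m3 <- toy_cohort(matrix(c(1L, 1L), 1, 2), 1, 1,
                   variants = data.frame(chrom = "1", pos = 3, ref = "A",
                                         alt = "G",
                                         effect_term = "missense_variant"),
                   dp = matrix(500, 1, 2), gq = matrix(99, 1, 2),
                   ad = matrix(c(250, 50), 1, 2))
  res3 <- filter_by_quality(m3)
  expect_equal(unname(res3$matrix$geno[1, ]), c(1L, NA))
})

test_that("the cascade telescopes and matches generator truth counts", {
  syn <- quiet_cohort(seed = 4, noise_flip = 0, missing_rate = 0)
  fl <- apply_filters(syn$cohort)
  r <- fl$report
  expect_equal(r$stage, c("effect_class", "reference_frequency", "call_quality"))
  expect_equal(r$n_in[-1], r$n_out[-length(r$n_out)])

  roles <- syn$truth$roles
  n_syn <- sum(syn$cohort$variants$effect_term == "synonymous_variant")
  expect_equal(r$n_in[1] - r$n_out[1], n_syn)
  expect_equal(r$n_in[2] - r$n_out[2], sum(roles$role == "background_common"))
  # default depth model sits above the coverage gate: no quality removals
  expect_equal(r$n_in[3], r$n_out[3])

  # all planted profile variants survive every filter at zero noise
  prof_keys <- roles$variant[grepl("profile", roles$role)]
  expect_true(all(prof_keys %in% variant_key(fl$matrix)))
})

test_that("filters are contractive, idempotent, and effect/frequency commute", {
  syn <- quiet_cohort(seed = 5, n_background = 80)
  m <- syn$cohort
  fl1 <- apply_filters(m)
  expect_true(all(variant_key(fl1$matrix) %in% variant_key(m)))
  fl2 <- apply_filters(fl1$matrix)
  expect_identical(unname(fl2$matrix$geno), unname(fl1$matrix$geno))
  expect_identical(variant_key(fl2$matrix), variant_key(fl1$matrix))

  ab <- filter_by_reference_frequency(filter_by_effect(m))
  ba <- filter_by_effect(filter_by_reference_frequency(m))
  expect_identical(variant_key(ab), variant_key(ba))

  # identity configuration passes everything through
  all_terms <- unique(m$variants$effect_term)
  cfg <- filter_config(maf_max = 1 - 1e-9, min_depth = 0, min_gq = 0,
                       min_ad_fraction = 0, moderate_terms = all_terms)
  expect_equal(nrow(apply_filters(m, cfg)$matrix$geno), nrow(m$geno))

  # all-excluded fixture empties at the effect stage
  g <- matrix(1L, 2, 3)
  v <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                  effect_term = "synonymous_variant")
  fl3 <- apply_filters(toy_cohort(g, 2, 1, variants = v))
  expect_equal(nrow(fl3$matrix$geno), 0L)
  expect_equal(fl3$report$n_out[1], 0L)
})
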