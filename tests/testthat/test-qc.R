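test_that("sample missingness is the exact missing fraction with boundary behaviour", {
  G <- matrix(0L, 3, 100)
  G[2, 1:3] <- NA   # 3% missing
  G[3, ] <- NA      # all missing
  ped <- data.frame(fid = c("a", "b", "c"), iid = c("a", "b", "c"),
                    pid = "0", mid = "0", sex = 1L, aff = 1L)
  map <- data.frame(chr = 1L, snp = sprintf("m%03d", 1:100), cm = 0,
                    pos = 1:100 * 10L, a1 = "A", a2 = "B")
  co <- pedigree_cohort(ped, G, map)
  miss <- sample_missingness(co)
  expect_equal(unname(miss), c(0, 0.03, 1))
  expect_true(miss[2] > 0.02)           # flagged at the 2% threshold
  # exactly 2% is retained (strict inequality)
  G2 <- matrix(0L, 2, 100); G2[1, 1:2] <- NA
  co2 <- pedigree_cohort(ped[1:2, ], G2, map)
  expect_equal(unname(sample_missingness(co2)), c(0.02, 0))
})

test_that("heterozygosity rate and z-filter behave as defined", {
  # one sample with genotypes AA, AB, BB -> het rate 1/3
  G <- rbind(c(0L, 1L, 2L), c(0L, 0L, 2L), c(0L, 1L, 1L), c(2L, 1L, 0L))
  ped <- data.frame(fid = letters[1:4], iid = letters[1:4], pid = "0",
                    mid = "0", sex = 1L, aff = 1L)
  map <- data.frame(chr = 1L, snp = c("m1", "m2", "m3"), cm = 0,
                    pos = c(10L, 20L, 30L), a1 = "A", a2 = "B")
  co <- pedigree_cohort(ped, G, map)
  hf <- heterozygosity_filter(co)
  expect_equal(hf$report$het_rate[1], 1 / 3)

  # all identical rates: zero SD -> warn, retain all
  co$geno <- rbind(c(0L, 1L, 2L), c(2L, 1L, 0L), c(0L, 1L, 0L), c(2L, 1L, 2L))
  expect_warning(hf2 <- heterozygosity_filter(co), "zero variance")
  expect_identical(hf2$keep, co$ped$iid)

  # a planted outlier beyond 3 SD is removed
  co3 <- simulate_cohort(cohort_spec(n_families = 40, n_unrelated_cases = 20,
                                     n_unrelated_controls = 20,
                                     n_markers = 300, seed = 13))
  inj <- inject_qc_artifacts(co3, artifact_spec(het_outlier_fraction = 0.01,
                                                het_outlier_shift = 0.9,
                                                seed = 3))
  hf3 <- heterozygosity_filter(inj$cohort)
  expect_true(all(inj$log$het_outliers %in%
                    hf3$report$iid[hf3$report$removed]))
})

test_that("Mendel counter matches exhaustive trio and duo enumeration", {
  for (gf in c(0:2, NA)) for (gm in c(0:2, NA)) for (gc in 0:2) {
    if (is.na(gf) && is.na(gm)) next
    co <- make_family_cohort(list(list(
      gf = matrix(gf, 1, 1), gm = matrix(gm, 1, 1),
      kids = matrix(gc, 1, 1), aff = c(1L, 1L, 2L))))
    if (is.na(gf)) co$geno[1, 1] <- NA
    if (is.na(gm)) co$geno[2, 1] <- NA
    me <- mendel_errors(co)
    expected <- as.integer(!oracle_mendel_consistent(gc, gf, gm))
    info <- paste("gf", gf, "gm", gm, "gc", gc)
    expect_identical(unname(me$per_sample[3]), expected, info = info)
    expect_identical(unname(me$per_marker[1]), expected, info = info)
    # each genotyped parent is implicated in the error
    if (expected == 1L) {
      expect_identical(unname(me$per_sample[1]), as.integer(!is.na(gf)), info = info)
      expect_identical(unname(me$per_sample[2]), as.integer(!is.na(gm)), info = info)
    }
  }
})

test_that("specific Mendel cases: forced het is consistent, duo violation counted", {
  # parents AA x AA (dosage 2,2), child AB -> 1 error
  co <- make_family_cohort(list(list(gf = matrix(2L, 1, 1),
                                     gm = matrix(2L, 1, 1),
                                     kids = matrix(1L, 1, 1),
                                     aff = c(1L, 1L, 2L))))
  expect_identical(unname(mendel_errors(co)$per_sample[3]), 1L)
  # parents AA x BB, child AB -> 0 errors
  co2 <- make_family_cohort(list(list(gf = matrix(2L, 1, 1),
                                      gm = matrix(0L, 1, 1),
                                      kids = matrix(1L, 1, 1),
                                      aff = c(1L, 1L, 2L))))
  expect_identical(sum(mendel_errors(co2)$per_sample), 0L)
  # duo: genotyped parent AA, child BB -> 1 error
  co3 <- make_family_cohort(list(list(gf = matrix(2L, 1, 1),
                                      gm = matrix(0L, 1, 1),
                                      kids = matrix(0L, 1, 1),
                                      aff = c(1L, 1L, 2L))))
  co3$geno[2, 1] <- NA
  expect_identical(unname(mendel_errors(co3)$per_sample[3]), 1L)
})

test_that("marker filters apply strict thresholds and drop monomorphic loci", {
  co <- simulate_cohort(cohort_spec(n_families = 0, n_unrelated_cases = 0,
                                    n_unrelated_controls = 50,
                                    n_markers = 10, seed = 3))
  co$geno[, 1] <- 0L                    # monomorphic: MAF = 0
  co$geno[1:2, 2] <- NA                 # 4% missing  -> removed
  co$geno[1, 3] <- NA                   # 2% missing  -> retained (strict)
  mf <- marker_filters(co)
  rep <- mf$report
  expect_true(rep$removed[1])
  expect_identical(rep$maf[1], 0)
  expect_true(rep$removed[2])
  expect_false(rep$removed[3])

  # Mendel counts: > 3 removed, exactly 3 retained
  fams <- replicate(4, list(gf = matrix(2L, 1, 2), gm = matrix(2L, 1, 2),
                            kids = matrix(c(1L, 1L), 1, 2),
                            aff = c(1L, 1L, 2L)), simplify = FALSE)
  co4 <- make_family_cohort(fams)
  co4$geno[12, 2] <- 2L   # fourth child consistent at marker 2 -> 3 errors
  # make markers polymorphic and clean elsewhere so only Mendel matters
  mf4 <- marker_filters(co4)
  expect_identical(unname(mendel_errors(co4)$per_marker), c(4L, 3L))
  expect_true(mf4$report$removed[1])    # 4 errors > 3
  expect_false(mf4$report$mendel[2] > 3)
})

test_that("r-squared matches a direct correlation oracle and pruning is sound", {
  set.seed(5)
  g1 <- sample(0:2, 200, TRUE); g2 <- sample(0:2, 200, TRUE)
  expect_equal(dosage_r2(g1, g2), cor(g1, g2)^2, tolerance = 1e-12)

  co <- simulate_cohort(cohort_spec(n_families = 0, n_unrelated_cases = 0,
                                    n_unrelated_controls = 120,
                                    n_markers = 60, ld_block_length = 1,
                                    within_block_r = 0, n_chromosomes = 1,
                                    seed = 17))
  # duplicated marker: r^2 = 1, exactly one of the pair retained
  co$geno[, 2] <- co$geno[, 1]
  kept <- ld_prune(co, r2_max = 0.2, window = 20, step = 5)
  expect_identical(sum(c("snp00001", "snp00002") %in% kept), 1L)

  # retained set has no within-window pair at or above the threshold
  G <- co$geno[, kept]
  idx <- match(kept, co$map$snp)
  for (w in seq(1, length(kept) - 1)) {
    for (v in (w + 1):min(w + 19, length(kept))) {
      if (co$map$chr[idx[w]] != co$map$chr[idx[v]]) next
      if (idx[v] - idx[w] >= 20) next
      expect_lt(dosage_r2(G[, w], G[, v]), 0.2)
    }
  }

  # 5 copies of one marker in a window -> exactly 1 retained
  co2 <- co
  for (j in 31:34) co2$geno[, j] <- co2$geno[, 30]
  kept2 <- ld_prune(co2, r2_max = 0.2, window = 20, step = 5)
  expect_identical(sum(sprintf("snp%05d", 30:34) %in% kept2), 1L)

  # independent markers are all retained
  co3 <- simulate_cohort(cohort_spec(n_families = 0, n_unrelated_cases = 0,
                                     n_unrelated_controls = 500,
                                     n_markers = 30, ld_block_length = 1,
                                     within_block_r = 0, seed = 19))
  expect_gte(length(ld_prune(co3, r2_max = 0.2, window = 15, step = 5)), 28)
})

test_that("GRM is symmetric and duplicated samples have off-diagonal equal to diagonal", {
  co <- simulate_cohort(cohort_spec(n_families = 0, n_unrelated_cases = 0,
                                    n_unrelated_controls = 40,
                                    n_markers = 100, seed = 23))
  G <- rbind(co$geno, co$geno[1, ])
  K <- grm_matrix(G)
  expect_equal(K, t(K), tolerance = 1e-12)
  expect_equal(K[41, 1], K[41, 41], tolerance = 1e-12)
  expect_equal(K[41, 1], K[1, 1], tolerance = 1e-12)
})

test_that("ancestry filter recovers exactly the planted admixed samples", {
  co <- simulate_cohort(cohort_spec(n_families = 0, n_unrelated_cases = 0,
                                    n_unrelated_controls = 150,
                                    n_markers = 400, ld_block_length = 1,
                                    within_block_r = 0, seed = 29))
  ref <- simulate_cohort(cohort_spec(n_families = 0, n_unrelated_cases = 0,
                                     n_unrelated_controls = 100,
                                     n_markers = 400, ld_block_length = 1,
                                     within_block_r = 0, seed = 29))
  inj <- inject_qc_artifacts(co, artifact_spec(admixed_fraction = 2 / 150,
                                               admixture_weight = 0.9,
                                               seed = 31))
  anc <- ancestry_outlier_filter(inj$cohort, ref, k_sd = 5)
  expect_setequal(anc$report$iid[anc$report$removed], inj$log$admixed)
  # a clean homogeneous cohort keeps nearly everyone (PCA noise on a
  # small marker panel can produce rare false positives)
  anc0 <- ancestry_outlier_filter(co, ref, k_sd = 5)
  expect_lte(sum(anc0$report$removed), ceiling(0.03 * n_samples(co)))
  # a sample sitting exactly at the reference centroid has E = 0
  expect_gte(min(anc0$report$E), 0)
})

test_that("top PCs of the GRM separate a planted two-population structure", {
  co <- simulate_cohort(cohort_spec(n_families = 0, n_unrelated_cases = 0,
                                    n_unrelated_controls = 120,
                                    n_markers = 600, ld_block_length = 1,
                                    within_block_r = 0, seed = 41))
  inj <- inject_qc_artifacts(co, artifact_spec(admixed_fraction = 0.5,
                                               admixture_weight = 0.8,
                                               seed = 43))
  K <- grm_matrix(inj$cohort$geno)
  expect_equal(K, t(K), tolerance = 1e-12)
  eig <- eigen(K, symmetric = TRUE)
  expect_true(all(abs(Im(eig$values)) == 0))
  sc <- eig$vectors[, 1:3] %*% diag(sqrt(pmax(eig$values[1:3], 0)))
  lab <- as.integer(inj$cohort$ped$iid %in% inj$log$admixed) + 1L
  sil <- cluster::silhouette(lab, stats::dist(sc))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("qc chain is idempotent on its own output", {
  co <- simulate_cohort(cohort_spec(n_families = 30, n_unrelated_cases = 15,
                                    n_unrelated_controls = 15,
                                    n_markers = 150, seed = 37))
  inj <- inject_qc_artifacts(co, artifact_spec(
    missing_rates = setNames(c(0.05, 0.04), co$ped$iid[1:2]), seed = 3))
  q1 <- run_qc(inj$cohort)
  q2 <- run_qc(q1$cohort)
  expect_identical(q2$cohort$ped$iid, q1$cohort$ped$iid)
  expect_identical(q2$cohort$map$snp, q1$cohort$map$snp)
})
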